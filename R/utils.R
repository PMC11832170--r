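# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn inform hash
#' @importFrom tibble tibble as_tibble
NULL

stop_bad <- function(msg, ..., class = "nmdscreen_error") {
  rlang::abort(sprintf(msg, ...), class = class)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_bad("%s is missing required column(s): %s", what,
             paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Pairwise Hamming distances between equal-length strings
#'
#' Used for barcode matching and manifest validation. All strings in `a` and
#' `b` must share one length.
#'
#' @param a,b Character vectors of equal-length strings.
#' @return An integer matrix of dimension `length(a)` x `length(b)`.
#' @keywords internal
#' @noRd
hamming_matrix <- function(a, b) {
  lens <- unique(nchar(c(a, b)))
  if (length(lens) != 1) {
    stop_bad("hamming_matrix() requires equal-length strings (saw lengths %s)",
             paste(lens, collapse = ", "))
  }
  L <- lens
  am <- matrix(unlist(strsplit(a, "", fixed = TRUE), use.names = FALSE),
               nrow = length(a), byrow = TRUE)
  bm <- matrix(unlist(strsplit(b, "", fixed = TRUE), use.names = FALSE),
               nrow = length(b), byrow = TRUE)
  d <- matrix(0L, nrow = length(a), ncol = length(b))
  for (j in seq_len(L)) {
    d <- d + outer(am[, j], bm[, j], `!=`)
  }
  storage.mode(d) <- "integer"
  dimnames(d) <- list(a, b)
  d
}

min_pairwise_hamming <- function(x) {
  if (length(x) < 2) return(Inf)
  d <- hamming_matrix(x, x)
  diag(d) <- NA_integer_
  min(d, na.rm = TRUE)
}

# Reverse complement for plain character vectors (ACGTN alphabet).
revcomp_chr <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", stringi::stri_reverse(x))
}

# DNA bases used by the simulator and synthetic panel.
DNA_BASES <- c("A", "C", "G", "T")

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

# Serialize floats the way the TSV outputs promise (6 significant digits by
# default, full precision on request).
format_num <- function(x, sig = 6L) {
  if (is.null(sig)) x else signif(x, sig)
}
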