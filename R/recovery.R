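# Mutant-transcript recovery analysis on treated vs control variant counts.

VARIANT_CLASSES <- c("frameshift_indel", "nonsense", "other_snv", "control_snp")
VARIANT_SAMPLES <- c("treated_1", "treated_2", "control_1", "control_2")
VARIANT_COUNT_COLS <- as.vector(t(outer(c("m_", "w_"), VARIANT_SAMPLES, paste0)))

#' Read a per-variant read-count table
#'
#' The table carries, for each somatic variant, mutant (`m_`) and wild-type
#' (`w_`) read counts at the variant site in the four samples of a
#' treated/control duplicate design, plus annotations: columns `variant_id`,
#' `gene`, `mutation_class` (`frameshift_indel`, `nonsense`, `other_snv`,
#' `control_snp`), `zygosity` (`heterozygous` / `homozygous`), `m_treated_1`,
#' `w_treated_1`, `m_treated_2`, `w_treated_2`, `m_control_1`, `w_control_1`,
#' `m_control_2`, `w_control_2`, and optionally `nmd_predicted` (logical).
#'
#' @param path TSV path.
#' @return A validated tibble of variant records.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop_bad("variant table not found: %s", path)
  count_types <- stats::setNames(
    rep(list(readr::col_integer()), length(VARIANT_COUNT_COLS)),
    VARIANT_COUNT_COLS)
  tbl <- readr::read_tsv(
    path,
    col_types = do.call(readr::cols, c(
      list(variant_id = readr::col_character(),
           gene = readr::col_character(),
           mutation_class = readr::col_character(),
           zygosity = readr::col_character()),
      count_types)),
    progress = FALSE, show_col_types = FALSE)
  validate_variant_table(tbl)
}

#' Validate a variant record table
#'
#' @param tbl A data frame of variant records (see [read_variant_table()]).
#' @return The validated tibble.
#' @export
validate_variant_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  assert_cols(tbl, c("variant_id", "gene", "mutation_class", "zygosity",
                     VARIANT_COUNT_COLS), "variant table")
  bad <- which(!tbl$mutation_class %in% VARIANT_CLASSES)
  if (length(bad) > 0) {
    stop_bad("variant table row %d has unknown mutation_class '%s'",
             bad[1], tbl$mutation_class[bad[1]])
  }
  bad <- which(!tbl$zygosity %in% c("heterozygous", "homozygous"))
  if (length(bad) > 0) {
    stop_bad("variant table row %d has unknown zygosity '%s'",
             bad[1], tbl$zygosity[bad[1]])
  }
  for (col in VARIANT_COUNT_COLS) {
    x <- tbl[[col]]
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    if (length(bad) > 0) {
      stop_bad("variant table row %d: %s is not a non-negative integer",
               bad[1], col)
    }
  }
  if (anyDuplicated(tbl$variant_id)) {
    stop_bad("duplicate variant_id '%s'",
             tbl$variant_id[duplicated(tbl$variant_id)][1])
  }
  tbl
}

#' Read variant records from a VCF with per-sample allele depths
#'
#' Maps each sample's `AD` field (ref,alt depths) to wild-type / mutant read
#' counts. The four VCF samples are matched to the design roles through
#' `sample_map`; 1-based VCF coordinates are preserved in the variant id
#' (`CHROM:POS:REF:ALT`). Zygosity is taken from the first control sample's
#' genotype (`0/1` or `0|1` heterozygous; `1/1`, `1|1` homozygous).
#' The mutation class is read from the INFO key `class_field` when present,
#' else set to `other_snv`.
#'
#' Requires the `vcfR` package.
#'
#' @param path VCF path (plain or bgzipped).
#' @param sample_map Named character vector mapping the roles
#'   `treated_1`, `treated_2`, `control_1`, `control_2` to VCF sample names.
#' @param class_field INFO key holding the mutation class (default `CLASS`).
#' @return A validated variant-record tibble, as from [read_variant_table()].
#' @export
read_variant_vcf <- function(path, sample_map, class_field = "CLASS") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_bad("read_variant_vcf() requires the vcfR package")
  }
  if (!file.exists(path)) stop_bad("VCF not found: %s", path)
  if (!setequal(names(sample_map), VARIANT_SAMPLES)) {
    stop_bad("sample_map must name exactly: %s",
             paste(VARIANT_SAMPLES, collapse = ", "))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  ad <- vcfR::extract.gt(v, element = "AD")
  gt <- vcfR::extract.gt(v, element = "GT")
  missing_s <- setdiff(sample_map, colnames(ad))
  if (length(missing_s) > 0) {
    stop_bad("VCF lacks sample '%s' named in sample_map", missing_s[1])
  }
  info <- vcfR::extract.info(v, element = class_field)
  n <- nrow(fix)
  out <- tibble(
    variant_id = paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"],
                       fix[, "ALT"], sep = ":"),
    gene = fix[, "CHROM"],
    mutation_class = ifelse(is.na(info) | !(info %in% VARIANT_CLASSES),
                            "other_snv", info),
    zygosity = ifelse(gt[, sample_map[["control_1"]]] %in%
                        c("1/1", "1|1"), "homozygous", "heterozygous")
  )
  for (role in VARIANT_SAMPLES) {
    parts <- stringr::str_split_fixed(ad[, sample_map[[role]]], ",", 2)
    out[[paste0("w_", role)]] <- as.integer(parts[, 1])
    out[[paste0("m_", role)]] <- as.integer(parts[, 2])
  }
  validate_variant_table(out[, c("variant_id", "gene", "mutation_class",
                                 "zygosity", VARIANT_COUNT_COLS)])
}

#' Apply the recovery inclusion filter
#'
#' A variant is analyzable only if it is heterozygous and covered by at least
#' `min_depth` reads (mutant + wild-type, default 5) at the variant site in
#' *all four* samples; the depth boundary is inclusive.
#'
#' @param variants A validated variant table.
#' @param min_depth Minimum per-sample site depth (default 5).
#' @return The table with an added logical `pass_filter` column.
#' @export
filter_variants <- function(variants, min_depth = 5L) {
  tbl <- validate_variant_table(variants)
  depth_ok <- rep(TRUE, nrow(tbl))
  for (s in VARIANT_SAMPLES) {
    depth_ok <- depth_ok &
      (tbl[[paste0("m_", s)]] + tbl[[paste0("w_", s)]]) >= min_depth
  }
  tbl$pass_filter <- tbl$zygosity == "heterozygous" & depth_ok
  tbl
}

#' Fold change and recovery call per variant
#'
#' For each filtered variant the mutant allele fraction is computed per
#' sample, averaged over the two treated and the two control replicates, and
#' the fold change \eqn{FC = \mathrm{MAF}_{treated} / \mathrm{MAF}_{control}}
#' is compared to the recovery threshold `r` (default 2, inclusive: "at least
#' two-fold"). When the mean control MAF is exactly 0 a pseudocount
#' (default 0.5) is added to the mutant and wild-type counts of all four
#' samples before recomputing, keeping FC finite while preserving ordering.
#'
#' The MAF denominator is mutant over total reads at the site,
#' `m / (m + w)`; set `maf_denominator = "wildtype"` for the mutant-to-
#' wild-type ratio `m / w` variant of the statistic.
#'
#' @param variants A variant table; [filter_variants()] is applied first if
#'   it has not been already (variants failing the filter get `recovered =
#'   FALSE` and missing FC).
#' @param r Recovery fold threshold (default 2; inclusive).
#' @param pseudocount Added to all counts when the mean control MAF is 0.
#' @param min_depth Passed to [filter_variants()] when needed.
#' @param maf_denominator `"total"` (default) or `"wildtype"`.
#' @return A tibble of class `nmd_recovery`: `variant_id`, `gene`,
#'   `mutation_class`, `zygosity`, `pass_filter`, per-sample `maf_*`,
#'   `maf_treated`, `maf_control`, `fold_change`, `recovered` (plus
#'   `nmd_predicted` when present in the input).
#' @export
recovery_fold <- function(variants, r = 2, pseudocount = 0.5,
                          min_depth = 5L,
                          maf_denominator = c("total", "wildtype")) {
  maf_denominator <- match.arg(maf_denominator)
  tbl <- if ("pass_filter" %in% names(variants)) {
    as_tibble(variants)
  } else {
    filter_variants(variants, min_depth = min_depth)
  }
  if (r <= 0) stop_bad("fold threshold r must be positive")

  maf_of <- function(m, w) {
    if (maf_denominator == "total") {
      ifelse(m + w > 0, m / (m + w), NA_real_)
    } else {
      ifelse(w > 0, m / w, NA_real_)
    }
  }
  sample_maf <- function(pseudo) {
    out <- list()
    for (s in VARIANT_SAMPLES) {
      out[[s]] <- maf_of(tbl[[paste0("m_", s)]] + pseudo,
                         tbl[[paste0("w_", s)]] + pseudo)
    }
    out
  }
  raw <- sample_maf(0)
  maf_treated <- (raw$treated_1 + raw$treated_2) / 2
  maf_control <- (raw$control_1 + raw$control_2) / 2
  # zero-control policy: pseudocount all four samples, recompute everything
  zero_ctrl <- !is.na(maf_control) & maf_control == 0
  if (any(zero_ctrl)) {
    ps <- sample_maf(pseudocount)
    for (s in VARIANT_SAMPLES) raw[[s]][zero_ctrl] <- ps[[s]][zero_ctrl]
    maf_treated[zero_ctrl] <-
      (ps$treated_1[zero_ctrl] + ps$treated_2[zero_ctrl]) / 2
    maf_control[zero_ctrl] <-
      (ps$control_1[zero_ctrl] + ps$control_2[zero_ctrl]) / 2
  }
  fc <- maf_treated / maf_control

  keep <- intersect(c("variant_id", "gene", "mutation_class", "zygosity",
                      "nmd_predicted", "pass_filter"), names(tbl))
  out <- tbl[, keep]
  out$maf_treated_1 <- raw$treated_1
  out$maf_treated_2 <- raw$treated_2
  out$maf_control_1 <- raw$control_1
  out$maf_control_2 <- raw$control_2
  out$maf_treated <- maf_treated
  out$maf_control <- maf_control
  out$fold_change <- ifelse(out$pass_filter, fc, NA_real_)
  out$recovered <- out$pass_filter & !is.na(fc) & fc >= r
  structure(out, class = c("nmd_recovery", class(out)), r = r)
}

#' Recovery rates stratified by mutation class
#'
#' Counts and rates are computed over variants passing the inclusion filter
#' only. A class with no passing variants reports a missing rate, not 0.
#'
#' @param recovery An `nmd_recovery` table from [recovery_fold()].
#' @return A tibble with `mutation_class`, `n_pass`, `n_recovered`,
#'   `recovery_rate`.
#' @export
stratify_recovery <- function(recovery) {
  tbl <- as_tibble(recovery)
  assert_cols(tbl, c("mutation_class", "pass_filter", "recovered"),
              "recovery records")
  bad <- setdiff(unique(tbl$mutation_class), VARIANT_CLASSES)
  if (length(bad) > 0) stop_bad("unknown mutation class '%s'", bad[1])
  tbl |>
    dplyr::group_by(.data$mutation_class) |>
    dplyr::summarise(
      n_pass = sum(.data$pass_filter),
      n_recovered = sum(.data$recovered),
      recovery_rate = ifelse(.data$n_pass > 0,
                             .data$n_recovered / .data$n_pass, NA_real_),
      .groups = "drop"
    )
}

#' Two-proportion chi-squared test
#'
#' Tests equality of two binomial proportions via the 2x2 chi-squared
#' statistic, with the Yates continuity correction applied by default and
#' capped so the corrected statistic can never go negative:
#' \deqn{\chi^2 = \frac{N (\max(0, |ad - bc| - N/2))^2}{r_1 r_2 c_1 c_2}}
#' with the `N/2` term dropped when `continuity = FALSE`. The p-value comes
#' from the chi-squared distribution with 1 degree of freedom. This matches
#' `stats::prop.test()` on its default two-sided test.
#'
#' @param a1,n1 Successes and trials in group 1.
#' @param a2,n2 Successes and trials in group 2.
#' @param continuity Apply the Yates correction (default `TRUE`).
#' @return A one-row tibble: `estimate1`, `estimate2`, `statistic`,
#'   `p_value`, `df`, `continuity`.
#' @export
#' @examples
#' two_proportion_test(30, 100, 10, 100, continuity = FALSE)  # chi2 = 12.5
two_proportion_test <- function(a1, n1, a2, n2, continuity = TRUE) {
  if (!is_count(c(a1, n1, a2, n2))) {
    stop_bad("counts must be non-negative integers")
  }
  if (n1 <= 0 || n2 <= 0 || a1 > n1 || a2 > n2) {
    stop_bad("need 0 <= a_i <= n_i and n_i > 0")
  }
  a <- as.numeric(a1); b <- as.numeric(n1 - a1)
  c_ <- as.numeric(a2); d <- as.numeric(n2 - a2)
  N <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop_bad("degenerate 2x2 table: a zero row or column margin")
  }
  cross <- abs(a * d - b * c_)
  if (continuity) cross <- max(0, cross - N / 2)
  chi2 <- N * cross^2 / (r1 * r2 * c1 * c2)
  tibble(
    estimate1 = a1 / n1,
    estimate2 = a2 / n2,
    statistic = chi2,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    df = 1L,
    continuity = continuity
  )
}

#' @rdname recovery_fold
#' @param x An `nmd_recovery` table.
#' @param ... Unused.
#' @export
glance.nmd_recovery <- function(x, ...) {
  tibble(
    n_variants = nrow(x),
    n_pass = sum(x$pass_filter),
    n_recovered = sum(x$recovered),
    recovery_rate = ifelse(sum(x$pass_filter) > 0,
                           sum(x$recovered) / sum(x$pass_filter), NA_real_),
    r = attr(x, "r")
  )
}

#' Write recovery-stage artifacts
#'
#' @param recovery `nmd_recovery` table.
#' @param summary Class summary from [stratify_recovery()].
#' @param test Optional one-row test tibble from [two_proportion_test()].
#' @param dir Output directory.
#' @param sig Significant digits for serialized floats (default 6).
#' @return Invisibly, the paths written.
#' @export
write_recovery_outputs <- function(recovery, summary, test = NULL, dir,
                                   sig = 6L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(recovery = file.path(dir, "recovery.tsv"),
             summary = file.path(dir, "class_summary.tsv"),
             test = file.path(dir, "test.json"))
  rec_out <- dplyr::mutate(as_tibble(recovery), dplyr::across(
    dplyr::where(is.double), \(x) format_num(x, sig)))
  readr::write_tsv(rec_out, paths["recovery"], progress = FALSE)
  readr::write_tsv(as_tibble(summary), paths["summary"], progress = FALSE)
  if (!is.null(test)) {
    jsonlite::write_json(as.list(test), paths["test"], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}
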