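# Streaming FASTQ demultiplexing and allele classification.

open_read_con <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, open = "rt") else file(path, open = "rt")
}

# Match observed barcode strings against a reference set: unique nearest
# barcode within max_mismatches wins; ties or no match leave NA. Works on the
# unique observed values so cost is independent of read count.
match_barcodes <- function(observed, ref_tbl, id_col, bc_len, max_mm) {
  ids <- rep(NA_character_, length(observed))
  ok <- !is.na(observed) & nchar(observed) == bc_len
  if (!any(ok)) return(ids)
  uo <- unique(observed[ok])
  d <- hamming_matrix(uo, ref_tbl$sequence)
  within <- d <= max_mm
  n_within <- rowSums(within)
  assign_idx <- ifelse(n_within == 1, max.col(within, ties.method = "first"),
                       NA_integer_)
  lookup <- stats::setNames(ref_tbl[[id_col]][assign_idx], uo)
  ids[ok] <- unname(lookup[observed[ok]])
  ids
}

#' Demultiplex reads to plates and wells by dual barcodes
#'
#' Extracts the plate and well barcode at the manifest's fixed offsets from
#' each read and assigns each axis to the unique manifest barcode within
#' `max_mismatches` Hamming distance; a tie between two barcodes, no barcode
#' within range, or a read too short for the barcode window all leave that
#' axis unassigned (`NA`).
#'
#' @param reads A data frame with columns `read_id` and `sequence` (a bare
#'   character vector of sequences is also accepted).
#' @param manifest A [barcode_manifest()].
#' @return The input as a tibble with added `plate_id` and `well_id` columns
#'   (`NA` = unassigned).
#' @export
demultiplex_reads <- function(reads, manifest) {
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("read", seq_along(reads)),
                    sequence = reads)
  }
  reads <- as_tibble(reads)
  assert_cols(reads, c("read_id", "sequence"), "reads")
  s <- toupper(reads$sequence)
  po <- manifest$plate_offset
  wo <- manifest$well_offset
  plate_obs <- substr(s, po + 1L, po + manifest$plate_bc_length)
  well_obs <- substr(s, wo + 1L, wo + manifest$well_bc_length)
  reads$plate_id <- match_barcodes(plate_obs, manifest$plate_barcodes,
                                   "plate_id", manifest$plate_bc_length,
                                   manifest$max_mismatches)
  reads$well_id <- match_barcodes(well_obs, manifest$well_barcodes,
                                  "well_id", manifest$well_bc_length,
                                  manifest$max_mismatches)
  # a well without a plate (or vice versa) is unassigned on both axes:
  # a count must be addressable to one (plate, well)
  half <- xor(is.na(reads$plate_id), is.na(reads$well_id))
  reads$plate_id[half] <- NA_character_
  reads$well_id[half] <- NA_character_
  reads
}

#' Classify reads to alleles of an amplicon panel
#'
#' Each read is searched (both strands) for every allele's diagnostic-window
#' substring. Exactly one window found: the read is classified to that allele.
#' More than one: `ambiguous`. None: `unclassified`.
#'
#' @param reads A data frame with columns `read_id`, `sequence`, or a bare
#'   character vector of sequences.
#' @param panel An [amplicon_panel()].
#' @return A tibble with added `gene`, `allele_id` and `class_status`
#'   (`classified` / `ambiguous` / `unclassified`) columns.
#' @export
classify_alleles <- function(reads, panel) {
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("read", seq_along(reads)),
                    sequence = reads)
  }
  reads <- as_tibble(reads)
  assert_cols(reads, c("read_id", "sequence"), "reads")
  s <- toupper(reads$sequence)
  n <- length(s)
  hits <- matrix(FALSE, nrow = n, ncol = nrow(panel))
  for (j in seq_len(nrow(panel))) {
    w <- panel$window_seq[j]
    hits[, j] <- stringi::stri_detect_fixed(s, w) |
      stringi::stri_detect_fixed(s, revcomp_chr(w))
  }
  n_hit <- rowSums(hits)
  one <- n_hit == 1L
  idx <- rep(NA_integer_, n)
  idx[one] <- max.col(hits, ties.method = "first")[one]
  reads$gene <- ifelse(one, panel$gene[idx], NA_character_)
  reads$allele_id <- ifelse(one, panel$allele_id[idx], NA_character_)
  reads$class_status <- dplyr::case_when(
    n_hit == 1L ~ "classified",
    n_hit > 1L ~ "ambiguous",
    .default = "unclassified"
  )
  reads
}

new_run_totals <- function() {
  c(reads_seen = 0, reads_assigned = 0, reads_unassigned = 0,
    reads_classified = 0, reads_ambiguous = 0, reads_unclassified = 0)
}

#' Count allele-assigned reads per well from FASTQ
#'
#' Streams one or more single-end FASTQ files (optionally gzip-compressed) in
#' chunks, demultiplexes each read to a (plate, well) by its dual barcodes,
#' classifies assigned reads against the amplicon panel, and accumulates the
#' (plate, well, gene, allele) count matrix. Each read contributes at most one
#' count; no well-ordering of the input is assumed, and the result is
#' invariant to read order.
#'
#' Totals always reconcile:
#' `reads_seen = reads_assigned + reads_unassigned` and
#' `reads_classified + reads_ambiguous + reads_unclassified = reads_assigned`.
#'
#' @param fastq Character vector of FASTQ paths (plain or `.gz`).
#' @param manifest A [barcode_manifest()].
#' @param panel An [amplicon_panel()].
#' @param plate_map Optional plate map tibble; when given, counts are restricted
#'   to wells present in it (reads demultiplexed to unmapped wells are dropped
#'   from the matrix but still counted in the totals).
#' @param min_mean_quality Optional minimum mean base quality (Phred); reads
#'   below it are discarded as unassigned. `NULL` (default) disables quality
#'   filtering — base qualities are parsed but unused.
#' @param chunk_size Reads per streaming chunk.
#' @param verbose Emit a per-file message.
#' @return An object of class `allele_counts`: a list with `counts`
#'   (tibble `plate_id`, `well_id`, `gene`, `allele_id`, `n`) and `totals`
#'   (named numeric vector of read-fate counts). Supports [generics::tidy()]
#'   and [generics::glance()].
#' @export
count_alleles <- function(fastq, manifest, panel, plate_map = NULL,
                          min_mean_quality = NULL,
                          chunk_size = 500000L, verbose = FALSE) {
  stopifnot(inherits(manifest, "barcode_manifest"),
            inherits(panel, "amplicon_panel"))
  missing_files <- fastq[!file.exists(fastq)]
  if (length(missing_files) > 0) {
    stop_bad("FASTQ not found: %s", missing_files[1])
  }
  totals <- new_run_totals()
  acc <- list()
  allowed_key <- if (!is.null(plate_map)) {
    paste(plate_map$plate_id, plate_map$well_id)
  }
  for (f in fastq) {
    con <- open_read_con(f)
    record_offset <- 0L
    tryCatch({
    repeat {
      lines <- readLines(con, n = 4L * chunk_size)
      if (length(lines) == 0) break
      if (length(lines) %% 4L != 0) {
        stop_bad("truncated FASTQ record at record %d of %s",
                 record_offset + length(lines) %/% 4L + 1L, f)
      }
      n <- length(lines) %/% 4L
      heads <- lines[seq(1L, by = 4L, length.out = n)]
      seqs <- lines[seq(2L, by = 4L, length.out = n)]
      plus <- lines[seq(3L, by = 4L, length.out = n)]
      quals <- lines[seq(4L, by = 4L, length.out = n)]
      bad <- !startsWith(heads, "@") | !startsWith(plus, "+")
      if (any(bad)) {
        stop_bad("malformed FASTQ record at record %d of %s",
                 record_offset + which(bad)[1], f)
      }
      totals["reads_seen"] <- totals["reads_seen"] + n

      keep <- rep(TRUE, n)
      if (!is.null(min_mean_quality)) {
        mq <- vapply(quals, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                     USE.NAMES = FALSE)
        keep <- mq >= min_mean_quality
      }
      chunk <- demultiplex_reads(
        tibble(read_id = substring(heads, 2L), sequence = seqs)[keep, ],
        manifest)
      assigned <- !is.na(chunk$plate_id)
      totals["reads_assigned"] <- totals["reads_assigned"] + sum(assigned)
      totals["reads_unassigned"] <- totals["reads_unassigned"] +
        (n - sum(assigned))
      if (any(assigned)) {
        cls <- classify_alleles(chunk[assigned, ], panel)
        totals["reads_classified"] <- totals["reads_classified"] +
          sum(cls$class_status == "classified")
        totals["reads_ambiguous"] <- totals["reads_ambiguous"] +
          sum(cls$class_status == "ambiguous")
        totals["reads_unclassified"] <- totals["reads_unclassified"] +
          sum(cls$class_status == "unclassified")
        cls <- cls[cls$class_status == "classified", ]
        if (!is.null(allowed_key)) {
          cls <- cls[paste(cls$plate_id, cls$well_id) %in% allowed_key, ]
        }
        if (nrow(cls) > 0) {
          acc[[length(acc) + 1L]] <- dplyr::count(
            cls, .data$plate_id, .data$well_id, .data$gene, .data$allele_id)
        }
      }
      record_offset <- record_offset + n
    }
    }, finally = close(con))
    if (verbose) {
      inform(sprintf("%s: %d records", f, record_offset))
    }
  }
  counts <- if (length(acc) == 0) {
    tibble(plate_id = character(), well_id = character(),
           gene = character(), allele_id = character(), n = integer())
  } else {
    dplyr::bind_rows(acc) |>
      dplyr::group_by(.data$plate_id, .data$well_id, .data$gene,
                      .data$allele_id) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
      dplyr::arrange(.data$plate_id, .data$well_id, .data$gene,
                     .data$allele_id)
  }
  structure(list(counts = counts, totals = totals),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "<allele_counts> %d wells; reads seen %d, assigned %d (%.1f%%), classified %d\n",
    nrow(dplyr::distinct(x$counts, .data$plate_id, .data$well_id)),
    t[["reads_seen"]], t[["reads_assigned"]],
    if (t[["reads_seen"]] > 0) 100 * t[["reads_assigned"]] / t[["reads_seen"]] else 0,
    t[["reads_classified"]]))
  invisible(x)
}

#' @rdname count_alleles
#' @param x An `allele_counts` object.
#' @param ... Unused.
#' @export
tidy.allele_counts <- function(x, ...) x$counts

#' @rdname count_alleles
#' @export
glance.allele_counts <- function(x, ...) {
  as_tibble(as.list(x$totals)) |>
    dplyr::mutate(unassigned_rate = ifelse(
      .data$reads_seen > 0, .data$reads_unassigned / .data$reads_seen, NA_real_))
}

#' Write an allele count matrix and its run summary
#'
#' @param counts An `allele_counts` object from [count_alleles()].
#' @param counts_path Output TSV path (`plate_id`, `well_id`, `gene`,
#'   `allele_id`, `count`).
#' @param summary_path Optional JSON path for the run totals.
#' @return Invisibly, `counts`.
#' @export
write_allele_counts <- function(counts, counts_path, summary_path = NULL) {
  out <- counts$counts
  names(out)[names(out) == "n"] <- "count"
  readr::write_tsv(out, counts_path, progress = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      c(as.list(counts$totals),
        list(unassigned_rate =
               if (counts$totals[["reads_seen"]] > 0)
                 counts$totals[["reads_unassigned"]] / counts$totals[["reads_seen"]]
               else NA_real_)),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(counts)
}

#' Read an allele count TSV back into an `allele_counts` object
#'
#' @param path Counts TSV written by [write_allele_counts()].
#' @return An `allele_counts` object (totals reconstructed from the counts:
#'   read-fate totals other than classified reads are unknown and set to `NA`).
#' @export
read_allele_counts <- function(path) {
  if (!file.exists(path)) stop_bad("counts TSV not found: %s", path)
  tbl <- readr::read_tsv(path, col_types = "ccccd", progress = FALSE)
  assert_cols(tbl, c("plate_id", "well_id", "gene", "allele_id", "count"),
              "counts TSV")
  if (!is_count(tbl$count)) stop_bad("counts must be non-negative integers")
  names(tbl)[names(tbl) == "count"] <- "n"
  totals <- new_run_totals()
  totals[] <- NA_real_
  totals["reads_classified"] <- sum(tbl$n)
  structure(list(counts = tbl, totals = totals), class = "allele_counts")
}
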