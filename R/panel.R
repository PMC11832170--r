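#' Construct an amplicon allele panel
#'
#' The panel is the pseudo-reference the screen counts against: for every
#' amplicon (gene) it holds the wild-type sequence and one sequence per
#' clone-specific mutant allele, each with a diagnostic window — the short
#' interval spanning the engineered edit (plus flank) whose exact sequence
#' distinguishes that allele from every other allele of the gene. A read is
#' classified to an allele when it contains that allele's diagnostic-window
#' substring (either strand) and no other allele's.
#'
#' Validation enforces: windows lie within their sequence; each gene has
#' exactly one wild-type and at least one mutant allele; within a gene the
#' window substrings are pairwise distinct; and no allele's window occurs in
#' any other allele's full sequence (either strand), so error-free reads can
#' never be ambiguous.
#'
#' @param alleles A data frame with columns `gene`, `allele_id`, `sequence`,
#'   `window_start`, `window_end` (0-based, half-open), `is_mutant` (logical),
#'   `clone_line` (empty string for wild-type alleles).
#' @return A tibble of class `amplicon_panel` with an added `window_seq`
#'   column.
#' @export
amplicon_panel <- function(alleles) {
  p <- as_tibble(alleles)
  assert_cols(p, c("gene", "allele_id", "sequence", "window_start",
                   "window_end", "is_mutant", "clone_line"),
              "amplicon panel")
  p$sequence <- toupper(p$sequence)
  p$is_mutant <- as.logical(p$is_mutant)
  p$window_start <- as.integer(p$window_start)
  p$window_end <- as.integer(p$window_end)
  if (anyDuplicated(p$allele_id)) {
    stop_bad("duplicate allele_id '%s' in panel",
             p$allele_id[duplicated(p$allele_id)][1])
  }
  bad <- which(p$window_start < 0 | p$window_end <= p$window_start |
                 p$window_end > nchar(p$sequence))
  if (length(bad) > 0) {
    stop_bad("diagnostic window of allele '%s' lies outside its sequence",
             p$allele_id[bad[1]])
  }
  p$window_seq <- substr(p$sequence, p$window_start + 1L, p$window_end)

  for (g in unique(p$gene)) {
    sub <- p[p$gene == g, ]
    n_wt <- sum(!sub$is_mutant)
    if (n_wt != 1 || sum(sub$is_mutant) < 1) {
      stop_bad("gene %s must have exactly one wild-type and >=1 mutant allele (has %d wt, %d mutant)",
               g, n_wt, sum(sub$is_mutant))
    }
    if (anyDuplicated(sub$window_seq)) {
      stop_bad("gene %s has alleles with identical diagnostic windows", g)
    }
  }
  # cross-containment: an allele's window must identify only that allele
  for (i in seq_len(nrow(p))) {
    w <- p$window_seq[i]
    others <- p$sequence[-i]
    hit <- stringi::stri_detect_fixed(others, w) |
      stringi::stri_detect_fixed(others, revcomp_chr(w))
    if (any(hit)) {
      stop_bad("diagnostic window of '%s' also occurs in allele '%s'",
               p$allele_id[i], p$allele_id[-i][hit][1])
    }
  }
  class(p) <- c("amplicon_panel", class(p))
  p
}

#' Read an amplicon panel from FASTA + windows TSV
#'
#' FASTA headers encode `gene|allele_id|is_mutant|clone_line`; the sidecar TSV
#' has columns `allele_id`, `window_start`, `window_end` (0-based, half-open).
#'
#' @param fasta_path Path to the panel FASTA.
#' @param windows_path Path to the diagnostic-window TSV.
#' @return An [amplicon_panel()].
#' @export
read_amplicon_panel <- function(fasta_path, windows_path) {
  if (!file.exists(fasta_path)) stop_bad("panel FASTA not found: %s", fasta_path)
  if (!file.exists(windows_path)) stop_bad("panel windows TSV not found: %s", windows_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 4)) {
    stop_bad("panel FASTA header '%s' is not gene|allele_id|is_mutant|clone_line",
             names(seqs)[lengths(parts) != 4][1])
  }
  meta <- do.call(rbind, parts)
  win <- utils::read.delim(windows_path, stringsAsFactors = FALSE)
  assert_cols(win, c("allele_id", "window_start", "window_end"), "windows TSV")
  tbl <- tibble(
    gene = meta[, 1],
    allele_id = meta[, 2],
    sequence = unname(as.character(seqs)),
    is_mutant = meta[, 3] %in% c("TRUE", "true", "1", "mutant"),
    clone_line = ifelse(meta[, 4] == "NA", "", meta[, 4])
  )
  tbl <- dplyr::left_join(tbl, as_tibble(win), by = "allele_id")
  if (anyNA(tbl$window_start)) {
    stop_bad("allele '%s' has no diagnostic window in %s",
             tbl$allele_id[is.na(tbl$window_start)][1], windows_path)
  }
  amplicon_panel(tbl[, c("gene", "allele_id", "sequence", "window_start",
                         "window_end", "is_mutant", "clone_line")])
}

#' Write an amplicon panel to FASTA + windows TSV
#'
#' @param panel An [amplicon_panel()].
#' @param fasta_path,windows_path Output paths.
#' @return Invisibly, the panel.
#' @export
write_amplicon_panel <- function(panel, fasta_path, windows_path) {
  seqs <- Biostrings::DNAStringSet(panel$sequence)
  names(seqs) <- paste(panel$gene, panel$allele_id, panel$is_mutant,
                       ifelse(panel$clone_line == "", "NA", panel$clone_line),
                       sep = "|")
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.table(
    data.frame(allele_id = panel$allele_id,
               window_start = panel$window_start,
               window_end = panel$window_end),
    windows_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(panel)
}

#' Describe the cell-line pool behind a screen
#'
#' The screen pools `n_lines` isogenic lines in equal ratio; each mutant
#' reporter allele is carried by `n_carriers` of those lines at a zygosity
#' dosage (0.5 heterozygous, 1.0 homozygous/hemizygous). The expected maximum
#' mutant fraction of allele *a* is \eqn{e_a = n_a \delta_a / N}: the mutant
#' allele fraction that full NMD blockade with equal per-cell expression would
#' approach. Raw MAFs are divided by \eqn{e_a}, correcting for the number of
#' cell lines and for heterozygous mutations.
#'
#' The wild-type dosage of a gene, used by the simulator's analytic
#' expectation, is derived as \eqn{W_g = N - \sum_{a \in g} n_a \delta_a}.
#'
#' @param n_lines Number of equally mixed lines in the pool.
#' @param carriers A data frame with columns `allele_id`, `gene`,
#'   `n_carriers`, `dosage`.
#' @return An object of class `pool_design`.
#' @export
#' @examples
#' pool_design(3, tibble::tibble(
#'   allele_id = "TP53_clone221_mut", gene = "TP53", n_carriers = 1, dosage = 1))
pool_design <- function(n_lines, carriers) {
  carriers <- as_tibble(carriers)
  assert_cols(carriers, c("allele_id", "gene", "n_carriers", "dosage"),
              "pool design carriers")
  if (!is_count(n_lines) || n_lines < 1) stop_bad("n_lines must be a positive integer")
  if (anyDuplicated(carriers$allele_id)) {
    stop_bad("pool design lists allele '%s' twice",
             carriers$allele_id[duplicated(carriers$allele_id)][1])
  }
  with(carriers, {
    if (any(n_carriers < 1 | n_carriers > n_lines)) {
      stop_bad("each n_carriers must satisfy 1 <= n_a <= N = %d", n_lines)
    }
    if (any(!dosage %in% c(0.5, 1.0))) {
      stop_bad("dosage must be 0.5 (heterozygous) or 1.0 (homozygous/hemizygous)")
    }
  })
  carriers$expected_max_fraction <- carriers$n_carriers * carriers$dosage / n_lines
  if (any(carriers$expected_max_fraction <= 0 | carriers$expected_max_fraction > 1)) {
    stop_bad("expected maximum fractions must lie in (0, 1]")
  }
  wt <- carriers |>
    dplyr::group_by(gene) |>
    dplyr::summarise(wt_dosage = n_lines - sum(n_carriers * dosage),
                     .groups = "drop")
  if (any(wt$wt_dosage < 0)) {
    stop_bad("gene %s has more mutant dosage than the pool holds",
             wt$gene[wt$wt_dosage < 0][1])
  }
  structure(list(n_lines = as.integer(n_lines), carriers = carriers,
                 wt_dosage = wt),
            class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("<pool_design> %d lines, %d mutant reporter allele(s)\n",
              x$n_lines, nrow(x$carriers)))
  print(x$carriers)
  invisible(x)
}

design_e <- function(design, allele_id) {
  i <- match(allele_id, design$carriers$allele_id)
  if (anyNA(i)) {
    stop_bad("allele '%s' is not in the pool design",
             allele_id[is.na(i)][1])
  }
  design$carriers$expected_max_fraction[i]
}

#' Read / write a pool design YAML
#'
#' @param path YAML path with keys `n_lines` and `carriers` (a list of
#'   `allele_id`, `gene`, `n_carriers`, `dosage` entries).
#' @return A [pool_design()].
#' @export
read_pool_design <- function(path) {
  if (!file.exists(path)) stop_bad("pool design not found: %s", path)
  y <- yaml::read_yaml(path)
  carriers <- purrr::map_dfr(y$carriers, as_tibble)
  pool_design(y$n_lines, carriers)
}

#' @rdname read_pool_design
#' @param design A [pool_design()].
#' @export
write_pool_design <- function(design, path) {
  yaml::write_yaml(list(
    n_lines = design$n_lines,
    carriers = purrr::pmap(
      design$carriers[, c("allele_id", "gene", "n_carriers", "dosage")],
      \(allele_id, gene, n_carriers, dosage)
        list(allele_id = allele_id, gene = gene,
             n_carriers = n_carriers, dosage = dosage))
  ), path)
  invisible(design)
}

#' Default three-line pool design
#'
#' Two STAG2 knockout clones and one TP53 knockout clone mixed in equal ratio
#' (N = 3), each carrying its clone-specific truncating mutation at full
#' dosage, so every reporter allele has expected maximum fraction 1/3.
#'
#' @return A [pool_design()].
#' @export
default_pool_design <- function() {
  pool_design(3L, tibble(
    allele_id = c("STAG2_clone2_mut", "STAG2_clone8_mut", "TP53_clone221_mut"),
    gene = c("STAG2", "STAG2", "TP53"),
    n_carriers = 1L,
    dosage = 1.0
  ))
}

# Deterministic pseudo-random DNA (internal fixed seed; independent of the
# user's RNG state).
random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(DNA_BASES, n, replace = TRUE),
                               collapse = ""))
}

#' Default synthetic amplicon panel
#'
#' A synthetic stand-in for the screen's targeted STAG2/TP53 amplicons:
#' per gene, a fixed pseudo-random wild-type amplicon and clone-specific
#' truncating edits (two STAG2 frameshift deletions, one TP53 insertion).
#' Sequences are generated deterministically in code — they are *not* the
#' original primer/amplicon sequences — but reproduce their structure: fixed
#' read-slot length, indel edits, and unambiguous diagnostic windows (the
#' wild-type window spans every edit site of its gene; each mutant window
#' spans its own indel junction).
#'
#' @param amplicon_length Length of the amplicon slot in the read (default
#'   132 nt: a 150 nt read minus the 8 nt plate and 10 nt well barcodes).
#' @param flank Diagnostic-window flank on each side of an edit (default 10).
#' @return An [amplicon_panel()].
#' @export
default_amplicon_panel <- function(amplicon_length = 132L, flank = 10L) {
  refs <- list(
    STAG2 = random_dna(amplicon_length + 30L, seed = 20111L),
    TP53 = random_dna(amplicon_length + 30L, seed = 20112L)
  )
  # gene-specific edits: (type, 0-based position, length)
  edits <- list(
    STAG2_clone2_mut = list(gene = "STAG2", clone = "RPE1_STAG2_2",
                            type = "del", pos = 60L, len = 4L),
    STAG2_clone8_mut = list(gene = "STAG2", clone = "RPE1_STAG2_8",
                            type = "del", pos = 78L, len = 2L),
    TP53_clone221_mut = list(gene = "TP53", clone = "RPE1_TP53_221",
                             type = "ins", pos = 66L, len = 1L)
  )
  rows <- list()
  for (g in names(refs)) {
    ref <- refs[[g]]
    g_edits <- edits[purrr::map_chr(edits, "gene") == g]
    pos <- purrr::map_int(g_edits, "pos")
    len <- purrr::map_int(g_edits, "len")
    # wild-type window spans every edit site of the gene
    wt_start <- max(0L, min(pos) - flank)
    wt_end <- min(amplicon_length, max(pos + len) + flank)
    rows[[paste0(g, "_wt")]] <- tibble(
      gene = g, allele_id = paste0(g, "_wt"),
      sequence = substr(ref, 1, amplicon_length),
      window_start = wt_start, window_end = wt_end,
      is_mutant = FALSE, clone_line = ""
    )
    for (aid in names(g_edits)) {
      e <- g_edits[[aid]]
      if (e$type == "del") {
        mut_full <- paste0(substr(ref, 1, e$pos),
                           substr(ref, e$pos + e$len + 1L, nchar(ref)))
        junction_end <- e$pos  # bases inserted after the junction: none
      } else {
        ins <- substr(random_dna(e$len + 3L, seed = 31000L + e$pos), 1, e$len)
        mut_full <- paste0(substr(ref, 1, e$pos), ins,
                           substr(ref, e$pos + 1L, nchar(ref)))
        junction_end <- e$pos + e$len
      }
      rows[[aid]] <- tibble(
        gene = g, allele_id = aid,
        sequence = substr(mut_full, 1, amplicon_length),
        window_start = max(0L, e$pos - flank),
        window_end = min(amplicon_length, junction_end + flank),
        is_mutant = TRUE, clone_line = e$clone
      )
    }
  }
  amplicon_panel(dplyr::bind_rows(rows))
}

#' Generate a default barcode manifest
#'
#' Plate barcodes (8 nt) and well barcodes (10 nt) are drawn deterministically
#' (fixed internal seed) under a greedy minimum-Hamming-distance-3 filter, so
#' the manifest satisfies the separation invariant for `max_mismatches = 1`.
#'
#' @param n_plates Number of plates (up to 384).
#' @param n_wells Wells per plate (default 96, ids `A1..H12`).
#' @param read_length Read length the offsets assume (default 150).
#' @return A [barcode_manifest()] with the plate barcode at offset 0 and the
#'   well barcode in the final 10 nt of the read.
#' @export
default_barcode_manifest <- function(n_plates, n_wells = 96L,
                                     read_length = 150L) {
  plate_seqs <- generate_barcodes(n_plates, len = 8L, min_dist = 3L,
                                  seed = 48101L)
  well_seqs <- generate_barcodes(n_wells, len = 10L, min_dist = 3L,
                                 seed = 48102L)
  barcode_manifest(
    plate_barcodes = stats::setNames(plate_seqs,
                                     sprintf("P%02d", seq_len(n_plates))),
    well_barcodes = stats::setNames(well_seqs, well_ids_96(n_wells)),
    plate_offset = 0L,
    well_offset = read_length - 10L
  )
}

# Greedy random barcode design at a minimum pairwise Hamming distance.
generate_barcodes <- function(n, len, min_dist, seed) {
  withr::with_seed(seed, {
    accepted <- character(0)
    tries <- 0L
    while (length(accepted) < n) {
      tries <- tries + 1L
      if (tries > 200000L) stop_bad("barcode generation failed to converge")
      cand <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      if (length(accepted) == 0 ||
          min(hamming_matrix(cand, accepted)) >= min_dist) {
        accepted <- c(accepted, cand)
      }
    }
    accepted
  })
}
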