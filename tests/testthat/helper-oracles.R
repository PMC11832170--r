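# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive (per-element loops, no shared code with the package
# internals) so package results can be checked against a second route.

hamming1 <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Quadratic-time demultiplexer: for one read, scan every barcode.
oracle_assign_barcode <- function(read_seq, barcodes, offset, len, max_mm) {
  obs <- substr(read_seq, offset + 1, offset + len)
  if (nchar(obs) < len) return(NA_character_)
  d <- vapply(barcodes$sequence, function(b) hamming1(obs, b), numeric(1))
  hit <- which(d <= max_mm)
  if (length(hit) == 1) barcodes[[1]][hit] else NA_character_
}

# Quadratic-time classifier: scan every allele window on both strands.
oracle_classify <- function(read_seq, panel) {
  rc <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  hits <- integer(0)
  for (j in seq_len(nrow(panel))) {
    w <- panel$window_seq[j]
    if (grepl(w, read_seq, fixed = TRUE) ||
        grepl(rc(w), read_seq, fixed = TRUE)) {
      hits <- c(hits, j)
    }
  }
  if (length(hits) == 1) panel$allele_id[hits] else
    if (length(hits) > 1) "AMBIGUOUS" else "UNCLASSIFIED"
}

# Full per-read recount over a FASTQ file, one read at a time.
oracle_recount <- function(fastq_path, manifest, panel) {
  con <- if (grepl("\\.gz$", fastq_path)) gzfile(fastq_path, "rt")
         else file(fastq_path, "rt")
  on.exit(close(con))
  counts <- list()
  totals <- c(seen = 0, assigned = 0, classified = 0)
  repeat {
    rec <- readLines(con, n = 4)
    if (length(rec) == 0) break
    totals["seen"] <- totals["seen"] + 1
    s <- rec[2]
    plate <- oracle_assign_barcode(s, manifest$plate_barcodes,
                                   manifest$plate_offset,
                                   manifest$plate_bc_length,
                                   manifest$max_mismatches)
    well <- oracle_assign_barcode(s, manifest$well_barcodes,
                                  manifest$well_offset,
                                  manifest$well_bc_length,
                                  manifest$max_mismatches)
    if (is.na(plate) || is.na(well)) next
    totals["assigned"] <- totals["assigned"] + 1
    allele <- oracle_classify(s, panel)
    if (allele %in% c("AMBIGUOUS", "UNCLASSIFIED")) next
    totals["classified"] <- totals["classified"] + 1
    key <- paste(plate, well, allele, sep = "\r")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  list(counts = counts, totals = totals)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Hand recomputation of the corrected MAF for scalar inputs.
oracle_corrected_maf <- function(m, w, n_carriers, dosage, n_lines) {
  e <- n_carriers * dosage / n_lines
  raw <- if (m + w == 0) NA_real_ else m / (m + w)
  list(raw = raw, corrected = raw / e)
}

# Hand recomputation of the null threshold from a vector of control values.
oracle_threshold <- function(values, k) {
  mu <- sum(values) / length(values)
  s2 <- sum((values - mu)^2) / (length(values) - 1)
  mu + k * sqrt(s2)
}

# Naive row scan of the recovery inclusion filter.
oracle_filter <- function(tbl, min_depth) {
  out <- logical(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    r <- tbl[i, ]
    ok <- r$zygosity == "heterozygous"
    for (s in c("treated_1", "treated_2", "control_1", "control_2")) {
      ok <- ok && (r[[paste0("m_", s)]] + r[[paste0("w_", s)]]) >= min_depth
    }
    out[i] <- ok
  }
  out
}

# Closed-form 2x2 chi-squared from the contingency-table margins.
oracle_chi2 <- function(a1, n1, a2, n2, yates) {
  a <- as.numeric(a1); b <- as.numeric(n1 - a1)
  cc <- as.numeric(a2); d <- as.numeric(n2 - a2)
  N <- a + b + cc + d
  num <- abs(a * d - b * cc)
  if (yates) num <- max(0, num - N / 2)
  N * num^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
}

# --- tiny fixtures -----------------------------------------------------------

# A 2-plate x 4-well manifest with default-length barcodes (distance >= 3);
# reads are 30 nt: plate bc @0, 12 nt amplicon @8, well bc @20.
tiny_manifest <- function(max_mismatches = 1L) {
  barcode_manifest(
    plate_barcodes = c(P1 = "AAAAAAAA", P2 = "CCCCCCCC"),
    well_barcodes = c(A1 = "AAAAAAAAAA", A2 = "CCCCCCCCCC",
                      A3 = "GGGGGGGGGG", A4 = "TTTTTTTTTT"),
    plate_offset = 0L, well_offset = 20L,
    max_mismatches = max_mismatches
  )
}

# A one-gene panel whose amplicons fit the 12 nt slot of tiny_manifest reads.
tiny_panel <- function() {
  amplicon_panel(tibble::tibble(
    gene = c("G1", "G1"),
    allele_id = c("G1_wt", "G1_mut"),
    sequence = c("AACCGGTTAACC", "AACCTTGGAACC"),
    window_start = c(2, 2),
    window_end = c(8, 8),
    is_mutant = c(FALSE, TRUE),
    clone_line = c("", "clone1")
  ))
}

tiny_design <- function() {
  pool_design(2L, tibble::tibble(
    allele_id = "G1_mut", gene = "G1", n_carriers = 1L, dosage = 1.0))
}

# Build a tiny FASTQ on disk from read sequences.
write_tiny_fastq <- function(seqs, path, ids = NULL) {
  ids <- ids %||% paste0("r", seq_along(seqs))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+",
                           strrep("I", nchar(seqs))))
  writeLines(lines, path)
  path
}

# Read built for tiny_manifest()/tiny_panel(): barcode + amplicon + barcode.
tiny_read <- function(plate_bc, amplicon, well_bc) {
  stopifnot(nchar(amplicon) == 12)
  paste0(plate_bc, amplicon, well_bc)
}

# All single-substitution variants of a barcode sequence.
one_sub_variants <- function(seq) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_along(chars)) {
    for (b in setdiff(bases, chars[i])) {
      v <- chars
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}
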