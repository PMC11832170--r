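#' Construct a dual-barcode manifest
#'
#' A manifest describes how each read encodes its plate and well of origin:
#' an 8 nt plate barcode at a fixed offset (embedded in the forward-primer
#' region) and a 10 nt well barcode at a second fixed offset (reverse-primer
#' region). Barcode sets must be pairwise distinct and separated by a Hamming
#' distance greater than `2 * max_mismatches`, which guarantees that any read
#' whose true barcode acquired at most `max_mismatches` substitutions is still
#' assigned to its true plate/well (and never to a wrong one).
#'
#' @param plate_barcodes A tibble with columns `plate_id`, `sequence`, or a
#'   named character vector of plate barcode sequences.
#' @param well_barcodes A tibble with columns `well_id`, `sequence`, or a
#'   named character vector of well barcode sequences.
#' @param plate_offset,well_offset 0-based position of each barcode within the
#'   read.
#' @param max_mismatches Maximum Hamming distance tolerated per barcode when
#'   demultiplexing (default 1). Ties are left unassigned.
#' @param plate_bc_length,well_bc_length Expected barcode lengths (8 and 10 nt).
#' @return An object of class `barcode_manifest`.
#' @export
#' @examples
#' bm <- barcode_manifest(
#'   plate_barcodes = c(P1 = "ACGTACGT", P2 = "TGCATGCA"),
#'   well_barcodes  = c(A1 = "AAACCCGGGT", A2 = "TTTGGGCCCA"),
#'   plate_offset = 0, well_offset = 140
#' )
barcode_manifest <- function(plate_barcodes, well_barcodes,
                             plate_offset = 0L, well_offset = 140L,
                             max_mismatches = 1L,
                             plate_bc_length = 8L, well_bc_length = 10L) {
  plate_barcodes <- as_barcode_tbl(plate_barcodes, "plate_id")
  well_barcodes <- as_barcode_tbl(well_barcodes, "well_id")
  if (!is_count(max_mismatches) || length(max_mismatches) != 1) {
    stop_bad("max_mismatches must be a single non-negative integer")
  }
  if (!is_count(plate_offset) || !is_count(well_offset)) {
    stop_bad("barcode offsets must be non-negative integers")
  }
  m <- structure(
    list(
      plate_barcodes = plate_barcodes,
      well_barcodes = well_barcodes,
      plate_offset = as.integer(plate_offset),
      well_offset = as.integer(well_offset),
      max_mismatches = as.integer(max_mismatches),
      plate_bc_length = as.integer(plate_bc_length),
      well_bc_length = as.integer(well_bc_length)
    ),
    class = "barcode_manifest"
  )
  validate_barcode_manifest(m)
}

as_barcode_tbl <- function(x, id_col) {
  if (is.character(x)) {
    if (is.null(names(x))) stop_bad("barcode vectors must be named by %s", id_col)
    x <- tibble(!!id_col := names(x), sequence = unname(x))
  }
  x <- as_tibble(x)
  assert_cols(x, c(id_col, "sequence"), "barcode table")
  x$sequence <- toupper(x$sequence)
  x[, c(id_col, "sequence")]
}

validate_barcode_set <- function(tbl, id_col, expected_len, max_mismatches, what) {
  if (nrow(tbl) == 0) stop_bad("%s barcode set is empty", what)
  if (anyDuplicated(tbl[[id_col]])) {
    dup <- tbl[[id_col]][duplicated(tbl[[id_col]])][1]
    stop_bad("duplicate %s id '%s' in manifest", what, dup)
  }
  lens <- unique(nchar(tbl$sequence))
  if (length(lens) != 1 || lens != expected_len) {
    stop_bad("all %s barcodes must be %d nt (saw lengths %s)", what,
             expected_len, paste(lens, collapse = ", "))
  }
  if (any(bad <- !grepl("^[ACGT]+$", tbl$sequence))) {
    stop_bad("%s barcode '%s' contains non-ACGT characters", what,
             tbl[[id_col]][bad][1])
  }
  if (anyDuplicated(tbl$sequence)) {
    seqs <- tbl$sequence
    dup_seq <- seqs[duplicated(seqs)][1]
    ids <- tbl[[id_col]][seqs == dup_seq]
    stop_bad("%s barcodes '%s' and '%s' share sequence %s", what,
             ids[1], ids[2], dup_seq)
  }
  d <- min_pairwise_hamming(tbl$sequence)
  if (d <= 2 * max_mismatches) {
    stop_bad(paste0("%s barcode set has minimum pairwise Hamming distance %d, ",
                    "which does not exceed 2 * max_mismatches = %d; ",
                    "unambiguous assignment is not guaranteed"),
             what, d, 2L * max_mismatches)
  }
  invisible(tbl)
}

validate_barcode_manifest <- function(m) {
  validate_barcode_set(m$plate_barcodes, "plate_id", m$plate_bc_length,
                       m$max_mismatches, "plate")
  validate_barcode_set(m$well_barcodes, "well_id", m$well_bc_length,
                       m$max_mismatches, "well")
  m
}

#' @export
print.barcode_manifest <- function(x, ...) {
  cat(sprintf(
    "<barcode_manifest> %d plates x %d wells; plate bc %dnt @%d, well bc %dnt @%d; max mismatches %d\n",
    nrow(x$plate_barcodes), nrow(x$well_barcodes),
    x$plate_bc_length, x$plate_offset,
    x$well_bc_length, x$well_offset, x$max_mismatches))
  invisible(x)
}

#' Read a barcode manifest from a TSV plus a YAML config
#'
#' The TSV has columns `kind` (`plate` or `well`), `id`, and `sequence`; the
#' YAML config carries `plate_barcode_offset`, `well_barcode_offset` and
#' `max_mismatches`. Malformed rows are reported with their line number.
#'
#' @param tsv_path Path to the barcode TSV.
#' @param config Path to a YAML config file, or a named list with the same
#'   keys.
#' @return A validated [barcode_manifest()].
#' @export
read_barcode_manifest <- function(tsv_path, config) {
  if (!file.exists(tsv_path)) stop_bad("barcode TSV not found: %s", tsv_path)
  if (is.character(config)) {
    if (!file.exists(config)) stop_bad("barcode config not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  tbl <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  assert_cols(tbl, c("kind", "id", "sequence"), "barcode TSV")
  bad <- which(!tbl$kind %in% c("plate", "well") |
                 is.na(tbl$id) | tbl$id == "" |
                 !grepl("^[ACGTacgt]+$", tbl$sequence))
  if (length(bad) > 0) {
    # +1 for the header line
    stop_bad("malformed barcode row at line %d of %s", bad[1] + 1L, tsv_path)
  }
  plate <- tbl[tbl$kind == "plate", ]
  well <- tbl[tbl$kind == "well", ]
  barcode_manifest(
    plate_barcodes = tibble(plate_id = plate$id, sequence = plate$sequence),
    well_barcodes = tibble(well_id = well$id, sequence = well$sequence),
    plate_offset = config$plate_barcode_offset %||% 0L,
    well_offset = config$well_barcode_offset %||% 140L,
    max_mismatches = config$max_mismatches %||% 1L
  )
}

#' Write a barcode manifest to TSV + YAML
#'
#' @param manifest A [barcode_manifest()].
#' @param tsv_path,config_path Output paths.
#' @return Invisibly, the manifest.
#' @export
write_barcode_manifest <- function(manifest, tsv_path, config_path) {
  tbl <- rbind(
    data.frame(kind = "plate", id = manifest$plate_barcodes$plate_id,
               sequence = manifest$plate_barcodes$sequence),
    data.frame(kind = "well", id = manifest$well_barcodes$well_id,
               sequence = manifest$well_barcodes$sequence)
  )
  utils::write.table(tbl, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(
    list(plate_barcode_offset = manifest$plate_offset,
         well_barcode_offset = manifest$well_offset,
         max_mismatches = manifest$max_mismatches),
    config_path
  )
  invisible(manifest)
}

PLATE_MAP_ROLES <- c("library", "positive_control", "negative_control", "empty")

#' Read a plate map CSV
#'
#' The plate map assigns a compound (or control role) to every well:
#' columns `plate_id`, `well_id`, `compound_id`,
#' `role` (one of `library`, `positive_control`, `negative_control`, `empty`).
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per well.
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) stop_bad("plate map not found: %s", path)
  pm <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  validate_plate_map(pm)
}

#' Validate a plate map tibble
#'
#' @param pm A data frame with plate map columns.
#' @return The validated tibble.
#' @export
validate_plate_map <- function(pm) {
  pm <- as_tibble(pm)
  assert_cols(pm, c("plate_id", "well_id", "compound_id", "role"), "plate map")
  bad <- which(!pm$role %in% PLATE_MAP_ROLES)
  if (length(bad) > 0) {
    stop_bad("plate map row %d has unknown role '%s'", bad[1], pm$role[bad[1]])
  }
  key <- paste(pm$plate_id, pm$well_id)
  if (anyDuplicated(key)) {
    stop_bad("plate map assigns well %s twice", key[duplicated(key)][1])
  }
  pm
}

write_plate_map <- function(pm, path) {
  readr::write_csv(pm, path, progress = FALSE)
  invisible(pm)
}

#' Standard 96-well identifiers
#'
#' @param n Number of wells (default 96; must divide into rows of 12).
#' @return Character vector `A1 ... H12` in row-major order.
#' @export
well_ids_96 <- function(n = 96L) {
  rows <- LETTERS[1:8]
  ids <- as.vector(t(outer(rows, 1:12, paste0)))
  ids[seq_len(n)]
}
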