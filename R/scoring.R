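# Per-well MAF statistics, pooled-control null model, hit calling, plate QC.

#' Pool-corrected mutant allele fraction
#'
#' The screen's readout for one reporter allele in one well. The raw mutant
#' allele fraction is `m / (m + w)` — mutant reads over total reads at the
#' amplicon. Because a reporter mutation is carried by only some lines of the
#' pool and possibly heterozygously, the raw fraction is divided by the
#' allele's expected maximum fraction \eqn{e_a = n_a \delta_a / N} from the
#' [pool_design()], so that complete NMD blockade with equal per-cell
#' expression scores near 1 regardless of pool composition.
#'
#' Wells with `m + w = 0` get missing (`NA`) fractions, never 0; alleles with
#' depth below `min_depth` are flagged `low_coverage` (they are excluded from
#' null fitting and disqualify hit calls).
#'
#' @param m,w Non-negative integer vectors of mutant and wild-type read
#'   counts.
#' @param allele_id Character vector of mutant allele ids (recycled if length
#'   1); must exist in the design.
#' @param design A [pool_design()].
#' @param min_depth Minimum `m + w` for a usable fraction (default 200).
#' @return A tibble with columns `allele_id`, `mutant_reads`,
#'   `wildtype_reads`, `depth`, `raw_maf`, `corrected_maf`, `low_coverage`.
#' @export
#' @examples
#' d <- default_pool_design()
#' corrected_maf(150, 850, "STAG2_clone2_mut", d)  # raw 0.15, corrected 0.45
corrected_maf <- function(m, w, allele_id, design, min_depth = 200L) {
  if (!is_count(m) || !is_count(w)) {
    stop_bad("mutant and wild-type read counts must be non-negative integers")
  }
  n <- max(length(m), length(w), length(allele_id))
  m <- rep_len(as.numeric(m), n)
  w <- rep_len(as.numeric(w), n)
  allele_id <- rep_len(allele_id, n)
  e <- design_e(design, allele_id)
  depth <- m + w
  raw <- ifelse(depth > 0, m / depth, NA_real_)
  tibble(
    allele_id = allele_id,
    mutant_reads = m,
    wildtype_reads = w,
    depth = depth,
    raw_maf = raw,
    corrected_maf = raw / e,
    low_coverage = depth < min_depth
  )
}

#' Score all wells of a screen
#'
#' Expands an allele count matrix into per-well [corrected_maf()] records:
#' for every mutant reporter allele in the design, the mutant read count is
#' paired with the wild-type read count of the same gene in the same well.
#' Wells listed in the plate map (roles other than `empty`) but absent from
#' the counts appear with zero depth and missing MAF.
#'
#' @param counts An `allele_counts` object from [count_alleles()], or its
#'   counts tibble.
#' @param design A [pool_design()].
#' @param panel An [amplicon_panel()] (names the wild-type allele per gene).
#' @param plate_map Optional plate map; wells with role `empty` are dropped,
#'   missing wells are filled with zero counts.
#' @param min_depth Passed to [corrected_maf()].
#' @return A tibble with one row per (plate, well, mutant allele):
#'   `plate_id`, `well_id`, `gene`, `allele_id`, `mutant_reads`,
#'   `wildtype_reads`, `depth`, `raw_maf`, `corrected_maf`, `low_coverage`.
#' @export
score_wells <- function(counts, design, panel, plate_map = NULL,
                        min_depth = 200L) {
  tbl <- if (inherits(counts, "allele_counts")) counts$counts else as_tibble(counts)
  assert_cols(tbl, c("plate_id", "well_id", "gene", "allele_id", "n"),
              "counts")
  wt_ids <- panel$allele_id[!panel$is_mutant]
  names(wt_ids) <- panel$gene[!panel$is_mutant]
  carriers <- design$carriers

  wells <- if (!is.null(plate_map)) {
    dplyr::filter(plate_map, .data$role != "empty") |>
      dplyr::distinct(.data$plate_id, .data$well_id)
  } else {
    dplyr::distinct(tbl, .data$plate_id, .data$well_id)
  }

  grid <- tidyr::crossing(wells,
                          carriers[, c("allele_id", "gene")])
  wt_counts <- tbl |>
    dplyr::filter(.data$allele_id %in% wt_ids) |>
    dplyr::select("plate_id", "well_id", "gene", wt_n = "n")
  mut_counts <- tbl |>
    dplyr::filter(.data$allele_id %in% carriers$allele_id) |>
    dplyr::select("plate_id", "well_id", "allele_id", mut_n = "n")
  grid <- grid |>
    dplyr::left_join(mut_counts, by = c("plate_id", "well_id", "allele_id")) |>
    dplyr::left_join(wt_counts, by = c("plate_id", "well_id", "gene")) |>
    dplyr::mutate(mut_n = dplyr::coalesce(.data$mut_n, 0),
                  wt_n = dplyr::coalesce(.data$wt_n, 0))

  rec <- corrected_maf(grid$mut_n, grid$wt_n, grid$allele_id, design,
                       min_depth = min_depth)
  dplyr::bind_cols(grid[, c("plate_id", "well_id", "gene")], rec) |>
    dplyr::arrange(.data$plate_id, .data$well_id, .data$allele_id)
}

#' Fit the pooled vehicle-control null model
#'
#' Pools the corrected MAFs of all usable negative-control (DMSO) wells
#' across plates and, per reporter allele, computes the control mean
#' \eqn{\mu}, sample standard deviation \eqn{\sigma} (n-1 denominator) and
#' the hit threshold \eqn{T = \mu + k\sigma} (default `k = 5`). A
#' `fixed_threshold` overrides the fitted thresholds for every allele (the
#' screen this models reported a single pooled threshold of 0.46).
#'
#' Controls flagged `low_coverage` or with missing MAF are excluded, as are
#' controls on plates that failed QC when a `qc` table is supplied.
#'
#' @param mafs A tibble from [score_wells()]. If `plate_map` is supplied only
#'   `negative_control` wells are used; otherwise all rows are treated as
#'   controls.
#' @param k Standard-deviation multiplier (default 5).
#' @param plate_map Optional plate map used to select negative-control wells.
#' @param qc Optional [plate_qc()] table; controls on failed plates are
#'   dropped before pooling.
#' @param fixed_threshold Optional fixed threshold applied to every allele.
#' @return A tibble of class `nmd_null` with columns `allele_id`,
#'   `control_mean`, `control_sd`, `n_controls`, `k`, `threshold`.
#' @export
fit_null <- function(mafs, k = 5, plate_map = NULL, qc = NULL,
                     fixed_threshold = NULL) {
  if (k < 0) stop_bad("k must be non-negative")
  tbl <- as_tibble(mafs)
  assert_cols(tbl, c("allele_id", "corrected_maf", "low_coverage"),
              "MAF records")
  if (!is.null(plate_map)) {
    neg <- dplyr::filter(plate_map, .data$role == "negative_control")
    tbl <- dplyr::semi_join(tbl, neg, by = c("plate_id", "well_id"))
  }
  if (!is.null(qc)) {
    tbl <- dplyr::semi_join(tbl, dplyr::filter(qc, .data$passed),
                            by = "plate_id")
  }
  usable <- dplyr::filter(tbl, !.data$low_coverage, !is.na(.data$corrected_maf))
  fit <- usable |>
    dplyr::group_by(.data$allele_id) |>
    dplyr::summarise(control_mean = mean(.data$corrected_maf),
                     control_sd = stats::sd(.data$corrected_maf),
                     n_controls = dplyr::n(), .groups = "drop")
  if (is.null(fixed_threshold)) {
    if (nrow(fit) == 0 || any(fit$n_controls < 2)) {
      stop_bad(paste0("need >=2 usable control values per allele to fit the ",
                      "null model (or set fixed_threshold)"))
    }
    fit$threshold <- fit$control_mean + k * fit$control_sd
  } else {
    # keep whatever control summaries exist; threshold is imposed
    all_ids <- unique(c(fit$allele_id, unique(tbl$allele_id)))
    fit <- dplyr::left_join(tibble(allele_id = all_ids), fit, by = "allele_id")
    fit$n_controls <- dplyr::coalesce(fit$n_controls, 0L)
    fit$threshold <- fixed_threshold
  }
  fit$k <- k
  fit <- fit[, c("allele_id", "control_mean", "control_sd", "n_controls",
                 "k", "threshold")]
  structure(fit, class = c("nmd_null", class(fit)),
            fixed_threshold = fixed_threshold)
}

#' @rdname fit_null
#' @param x An `nmd_null` object.
#' @param ... Unused.
#' @export
tidy.nmd_null <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "nmd_null")
  attr(out, "fixed_threshold") <- NULL
  out
}

#' @rdname fit_null
#' @export
glance.nmd_null <- function(x, ...) {
  tibble(n_alleles = nrow(x),
         k = x$k[1],
         fixed_threshold = attr(x, "fixed_threshold") %||% NA_real_,
         min_threshold = min(x$threshold),
         max_threshold = max(x$threshold))
}

#' Plate-level quality control from control wells
#'
#' A plate passes when its mean positive-control corrected MAF is at least
#' `q` times its mean negative-control corrected MAF (default `q = 2`; the
#' emetine positive controls of the modelled screen ran three- to fourfold
#' above DMSO). A zero negative-control mean with a positive
#' positive-control mean gives an infinite ratio and passes; a plate missing
#' either control fails with a reason.
#'
#' @param mafs A tibble from [score_wells()].
#' @param plate_map Plate map naming control wells.
#' @param q Required positive/negative ratio (default 2).
#' @return A tibble with one row per plate: `plate_id`, `pos_control_mean`,
#'   `neg_control_mean`, `pos_neg_ratio`, `passed`, `reason`.
#' @export
plate_qc <- function(mafs, plate_map, q = 2) {
  tbl <- as_tibble(mafs)
  roles <- plate_map[, c("plate_id", "well_id", "role")]
  joined <- dplyr::inner_join(tbl, roles, by = c("plate_id", "well_id")) |>
    dplyr::filter(.data$role %in% c("positive_control", "negative_control"),
                  !.data$low_coverage, !is.na(.data$corrected_maf))
  out <- tibble(plate_id = sort(unique(plate_map$plate_id)))
  stats <- joined |>
    dplyr::group_by(.data$plate_id, .data$role) |>
    dplyr::summarise(mean_maf = mean(.data$corrected_maf), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role", values_from = "mean_maf")
  for (col in c("positive_control", "negative_control")) {
    if (!col %in% names(stats)) stats[[col]] <- NA_real_
  }
  out <- dplyr::left_join(out, stats, by = "plate_id") |>
    dplyr::rename(pos_control_mean = "positive_control",
                  neg_control_mean = "negative_control")
  out$pos_neg_ratio <- dplyr::case_when(
    is.na(out$pos_control_mean) | is.na(out$neg_control_mean) ~ NA_real_,
    out$neg_control_mean > 0 ~ out$pos_control_mean / out$neg_control_mean,
    out$pos_control_mean > 0 ~ Inf,
    .default = NaN
  )
  out$passed <- !is.na(out$pos_neg_ratio) & !is.nan(out$pos_neg_ratio) &
    out$pos_neg_ratio >= q
  out$reason <- dplyr::case_when(
    is.na(out$pos_control_mean) ~ "missing usable positive control",
    is.na(out$neg_control_mean) ~ "missing usable negative control",
    is.nan(out$pos_neg_ratio) ~ "both control means zero",
    !out$passed ~ sprintf("pos/neg ratio %.3g < %.3g", out$pos_neg_ratio, q),
    .default = ""
  )
  out
}

#' Call compound hits against the control null
#'
#' A library well is a hit only when the corrected MAF of *every* mutant
#' reporter allele strictly exceeds its threshold ("greater than", so
#' boundary equality is not a hit), the well has no low-coverage or missing
#' allele, and its plate passed QC. Output is sorted by the minimum
#' per-allele exceedance margin, descending.
#'
#' @param mafs A tibble from [score_wells()].
#' @param null An `nmd_null` model from [fit_null()].
#' @param plate_map Plate map (library wells are scored).
#' @param qc Optional [plate_qc()] table.
#' @return A tibble of class `nmd_hits`: one row per library well with
#'   `plate_id`, `well_id`, `compound_id`, per-allele corrected-MAF columns
#'   (`maf_<allele_id>`), `min_margin`, `is_hit`, `qc_flags`. The long
#'   per-allele table (with thresholds) is attached and available via
#'   [generics::tidy()].
#' @export
call_hits <- function(mafs, null, plate_map, qc = NULL) {
  lib <- dplyr::filter(plate_map, .data$role == "library")
  thr <- tibble(allele_id = null$allele_id, threshold = null$threshold)
  need <- unique(thr$allele_id)

  long <- dplyr::inner_join(as_tibble(mafs), lib[, c("plate_id", "well_id",
                                                     "compound_id")],
                            by = c("plate_id", "well_id")) |>
    dplyr::left_join(thr, by = "allele_id") |>
    dplyr::mutate(margin = .data$corrected_maf - .data$threshold)

  failed_plates <- if (!is.null(qc)) qc$plate_id[!qc$passed] else character(0)

  per_well <- long |>
    dplyr::group_by(.data$plate_id, .data$well_id, .data$compound_id) |>
    dplyr::summarise(
      n_alleles = dplyr::n_distinct(.data$allele_id),
      any_low = any(.data$low_coverage | is.na(.data$corrected_maf)),
      all_exceed = all(!is.na(.data$corrected_maf) &
                         .data$corrected_maf > .data$threshold),
      min_margin = if (all(!is.na(.data$margin))) min(.data$margin) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      missing_allele = .data$n_alleles < length(need),
      failed_plate = .data$plate_id %in% failed_plates,
      is_hit = .data$all_exceed & !.data$any_low & !.data$missing_allele &
        !.data$failed_plate,
      qc_flags = trimws(paste0(
        ifelse(.data$any_low, "low_coverage ", ""),
        ifelse(.data$missing_allele, "missing_allele ", ""),
        ifelse(.data$failed_plate, "failed_plate", "")))
    )
  # wells in the plate map with no MAF records at all
  missing_wells <- dplyr::anti_join(
    lib[, c("plate_id", "well_id", "compound_id")],
    per_well, by = c("plate_id", "well_id"))
  if (nrow(missing_wells) > 0) {
    missing_wells <- dplyr::mutate(missing_wells,
      n_alleles = 0L, any_low = TRUE, all_exceed = FALSE,
      min_margin = NA_real_, missing_allele = TRUE,
      failed_plate = .data$plate_id %in% failed_plates,
      is_hit = FALSE, qc_flags = "missing_allele")
    per_well <- dplyr::bind_rows(per_well, missing_wells)
  }

  wide <- long |>
    dplyr::select("plate_id", "well_id", "allele_id", "corrected_maf") |>
    dplyr::mutate(allele_id = paste0("maf_", .data$allele_id)) |>
    tidyr::pivot_wider(names_from = "allele_id",
                       values_from = "corrected_maf")
  out <- per_well |>
    dplyr::left_join(wide, by = c("plate_id", "well_id")) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$min_margin)),
                   dplyr::desc(.data$min_margin)) |>
    dplyr::select(-"any_low", -"all_exceed", -"missing_allele",
                  -"failed_plate")
  structure(out, class = c("nmd_hits", class(out)),
            alleles = long, null = null)
}

#' @rdname call_hits
#' @param x An `nmd_hits` table.
#' @param ... Unused.
#' @export
tidy.nmd_hits <- function(x, ...) attr(x, "alleles")

#' @rdname call_hits
#' @export
glance.nmd_hits <- function(x, ...) {
  tibble(n_wells = nrow(x),
         n_hits = sum(x$is_hit),
         hit_rate = ifelse(nrow(x) > 0, sum(x$is_hit) / nrow(x), NA_real_),
         n_flagged = sum(x$qc_flags != ""))
}

#' Per-concentration MAF table for one compound
#'
#' Reshapes corrected MAF records measured across a concentration series into
#' a tidy long table of (concentration, allele, corrected MAF). Reporting
#' only: no curve is fitted.
#'
#' @param mafs A tibble with columns `concentration`, `allele_id`,
#'   `corrected_maf` (e.g., [score_wells()] output joined to a concentration
#'   map), and optionally `compound_id`.
#' @return A tibble sorted by concentration then allele.
#' @export
dose_response <- function(mafs) {
  tbl <- as_tibble(mafs)
  assert_cols(tbl, c("concentration", "allele_id", "corrected_maf"),
              "dose-response records")
  if (dplyr::n_distinct(tbl$concentration) < 2) {
    stop_bad("dose_response() needs at least 2 distinct concentrations")
  }
  key <- paste(tbl$concentration, tbl$allele_id)
  if (anyDuplicated(key)) {
    stop_bad("duplicate (concentration, allele) row: %s",
             key[duplicated(key)][1])
  }
  keep <- intersect(c("compound_id", "concentration", "allele_id",
                      "corrected_maf"), names(tbl))
  dplyr::arrange(tbl[, keep], .data$concentration, .data$allele_id)
}

#' Write scoring artifacts
#'
#' @param mafs Per-well MAF tibble from [score_wells()].
#' @param null `nmd_null` model.
#' @param hits `nmd_hits` table.
#' @param qc [plate_qc()] table.
#' @param dir Output directory (created if needed).
#' @param sig Significant digits for serialized floats (default 6; `NULL` for
#'   full precision).
#' @return Invisibly, the paths written.
#' @export
write_screen_outputs <- function(mafs, null, hits, qc, dir, sig = 6L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    maf = file.path(dir, "well_maf.tsv"),
    null = file.path(dir, "null_model.json"),
    hits = file.path(dir, "hits.tsv"),
    qc = file.path(dir, "plate_qc.tsv")
  )
  maf_out <- dplyr::mutate(mafs, dplyr::across(
    dplyr::where(is.double), \(x) format_num(x, sig)))
  readr::write_tsv(maf_out, paths["maf"], progress = FALSE)
  jsonlite::write_json(
    purrr::pmap(tidy(null), \(allele_id, control_mean, control_sd,
                               n_controls, k, threshold)
      list(allele_id = allele_id, mean = control_mean, sd = control_sd,
           n_controls = n_controls, k = k, threshold = threshold)),
    paths["null"], auto_unbox = TRUE, digits = NA)
  hits_out <- dplyr::mutate(as_tibble(hits), dplyr::across(
    dplyr::where(is.double), \(x) format_num(x, sig)))
  readr::write_tsv(hits_out, paths["hits"], progress = FALSE)
  readr::write_tsv(as_tibble(qc), paths["qc"], progress = FALSE)
  invisible(paths)
}
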