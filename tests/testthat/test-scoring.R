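test_that("corrected MAF matches hand recomputation and its invariants", {
  d <- default_pool_design()  # e = 1/3 per allele

  r <- corrected_maf(0, 1000, "STAG2_clone2_mut", d)
  expect_equal(r$raw_maf, 0)
  expect_equal(r$corrected_maf, 0)

  r <- corrected_maf(500, 1000, "STAG2_clone2_mut", d)
  expect_equal(r$raw_maf, 1 / 3)
  expect_equal(r$corrected_maf, 1)  # complete-inhibition identity

  r <- corrected_maf(150, 850, "TP53_clone221_mut", d)
  expect_equal(r$raw_maf, 0.15)
  expect_equal(r$corrected_maf, 0.45)

  het <- pool_design(3L, tibble::tibble(
    allele_id = "a", gene = "G", n_carriers = 1L, dosage = 0.5))
  r <- corrected_maf(100, 1100, "a", het)
  expect_equal(r$raw_maf, 1 / 12)
  expect_equal(r$corrected_maf, 0.5)

  # zero depth is missing, never zero
  r <- corrected_maf(0, 0, "a", het)
  expect_true(is.na(r$raw_maf) && is.na(r$corrected_maf))
  expect_true(r$low_coverage)

  expect_error(corrected_maf(1, 1, "nope", d), "not in the pool design")
  expect_error(corrected_maf(-1, 1, "a", het), "non-negative")

  # scale invariance: (cm, cw) has identical fractions, exactly
  set.seed(11)
  m <- sample(0:500, 50, replace = TRUE)
  w <- sample(1:500, 50)
  for (c_ in c(2L, 7L, 100L)) {
    a <- corrected_maf(m, w, "a", het)
    b <- corrected_maf(c_ * m, c_ * w, "a", het)
    expect_identical(a$raw_maf, b$raw_maf)
    expect_identical(a$corrected_maf, b$corrected_maf)
  }

  # brute-force equivalence on random inputs
  set.seed(12)
  for (i in 1:200) {
    n_lines <- sample(2:6, 1)
    nc <- sample(seq_len(n_lines), 1)
    dos <- sample(c(0.5, 1), 1)
    des <- pool_design(n_lines, tibble::tibble(
      allele_id = "a", gene = "G", n_carriers = nc, dosage = dos))
    mm <- sample(0:10000, 1); ww <- sample(0:10000, 1)
    got <- corrected_maf(mm, ww, "a", des)
    want <- oracle_corrected_maf(mm, ww, nc, dos, n_lines)
    if (mm + ww == 0) {
      expect_true(is.na(got$raw_maf))
    } else {
      expect_equal(got$raw_maf, want$raw, tolerance = 1e-12)
      expect_equal(got$corrected_maf, want$corrected, tolerance = 1e-12)
    }
  }
})

test_that("null model pools controls with n-1 SD and k-sigma thresholds", {
  ctrl <- function(vals) tibble::tibble(
    allele_id = "a", corrected_maf = vals, low_coverage = FALSE)

  # zero variance
  n0 <- fit_null(ctrl(rep(0.10, 4)), k = 5)
  expect_equal(n0$control_mean, 0.10)
  expect_equal(n0$control_sd, 0)
  expect_equal(n0$threshold, 0.10)

  # hand-computed: mean 0.10, sd 0.0141421, T = 0.1707107
  n1 <- fit_null(ctrl(c(0.08, 0.09, 0.10, 0.10, 0.11, 0.12)), k = 5)
  expect_equal(n1$control_mean, 0.10)
  expect_equal(n1$control_sd, 0.0141421, tolerance = 1e-5)
  expect_equal(n1$threshold, 0.1707107, tolerance = 1e-6)

  # fixed threshold overrides every allele
  n2 <- fit_null(ctrl(c(0.1, 0.2)), k = 5, fixed_threshold = 0.46)
  expect_equal(n2$threshold, 0.46)
  n3 <- fit_null(ctrl(0.1)[0, ], k = 5, fixed_threshold = 0.46)
  expect_equal(nrow(n3), 0)  # no alleles observed at all

  # low-coverage controls are excluded
  x <- ctrl(c(0.1, 0.1, 9.9))
  x$low_coverage[3] <- TRUE
  expect_equal(fit_null(x, k = 1)$control_mean, 0.1)

  # <2 usable controls without a fixed threshold errors
  expect_error(fit_null(ctrl(0.1), k = 5), ">=2 usable control")

  # brute-force equivalence on random control sets
  set.seed(13)
  for (i in 1:100) {
    vals <- runif(sample(2:30, 1))
    k <- runif(1, 0, 8)
    got <- fit_null(ctrl(vals), k = k)
    expect_equal(got$threshold, oracle_threshold(vals, k), tolerance = 1e-12)
  }
})

make_maf_tbl <- function(mafs_by_well, alleles = c("a1", "a2", "a3")) {
  # mafs_by_well: named list well_id -> numeric vector over alleles
  purrr::imap_dfr(mafs_by_well, function(v, w) tibble::tibble(
    plate_id = "P1", well_id = w, gene = "G", allele_id = alleles,
    mutant_reads = 1000 * v, wildtype_reads = 1000 * (1 - v),
    depth = 1000, raw_maf = v, corrected_maf = v, low_coverage = FALSE))
}

test_that("hit calling is a strict all-allele conjunction with QC gating", {
  null <- structure(tibble::tibble(
    allele_id = c("a1", "a2", "a3"),
    control_mean = 0.1, control_sd = 0.05, n_controls = 10, k = 5,
    threshold = 0.46), class = c("nmd_null", "tbl_df", "tbl", "data.frame"))
  pm <- tibble::tibble(
    plate_id = "P1", well_id = c("W1", "W2", "W3"),
    compound_id = c("c1", "c2", "c3"), role = "library")
  mafs <- make_maf_tbl(list(
    W1 = c(0.50, 0.48, 0.47),   # all above -> hit
    W2 = c(0.50, 0.48, 0.46),   # one exactly at threshold -> not a hit
    W3 = c(0.50, 0.50, 0.45)))  # one below -> not a hit
  hits <- call_hits(mafs, null, pm)
  expect_equal(hits$is_hit[match(c("W1", "W2", "W3"), hits$well_id)],
               c(TRUE, FALSE, FALSE))
  # sorted by min margin, descending
  expect_equal(hits$well_id[1], "W1")
  expect_equal(hits$min_margin[1], 0.47 - 0.46)

  # failed plate QC disqualifies
  qc_bad <- tibble::tibble(plate_id = "P1", passed = FALSE)
  expect_false(any(call_hits(mafs, null, pm, qc = qc_bad)$is_hit))

  # low coverage on any allele disqualifies
  mafs2 <- make_maf_tbl(list(W1 = c(0.50, 0.48, 0.47)))
  mafs2$low_coverage[2] <- TRUE
  h2 <- call_hits(mafs2, null, pm[1, ])
  expect_false(h2$is_hit)
  expect_match(h2$qc_flags, "low_coverage")

  # missing allele record flags the well and never calls a hit
  mafs3 <- make_maf_tbl(list(W1 = c(0.50, 0.48, 0.47)))[-2, ]
  h3 <- call_hits(mafs3, null, pm[1, ])
  expect_false(h3$is_hit)
  expect_match(h3$qc_flags, "missing_allele")
})

test_that("hit calls are monotone in counts and in k", {
  d <- pool_design(3L, tibble::tibble(
    allele_id = c("a1", "a2", "a3"), gene = c("G1", "G2", "G3"),
    n_carriers = 1L, dosage = 1.0))
  pm <- tibble::tibble(plate_id = "P1", well_id = "W1", compound_id = "c1",
                       role = "library")
  base_m <- c(300, 280, 260); base_w <- c(700, 720, 740)
  mk <- function(m) {
    purrr::map_dfr(1:3, function(i) dplyr::bind_cols(
      tibble::tibble(plate_id = "P1", well_id = "W1", gene = paste0("G", i)),
      corrected_maf(m[i], base_w[i], paste0("a", i), d)))
  }
  null_at <- function(k) structure(tibble::tibble(
    allele_id = c("a1", "a2", "a3"), control_mean = 0.3, control_sd = 0.1,
    n_controls = 10, k = k, threshold = 0.3 + k * 0.1),
    class = c("nmd_null", "tbl_df", "tbl", "data.frame"))

  # increasing any allele's mutant count never turns a hit into a non-hit
  null <- null_at(5)
  was_hit <- call_hits(mk(base_m), null, pm)$is_hit
  for (i in 1:3) {
    for (extra in c(1, 50, 1000)) {
      m2 <- base_m; m2[i] <- m2[i] + extra
      now_hit <- call_hits(mk(m2), null, pm)$is_hit
      if (was_hit) expect_true(now_hit)
    }
  }
  # increasing k never adds hits
  hits_by_k <- vapply(c(0, 1, 3, 5, 8),
                      function(k) call_hits(mk(base_m), null_at(k), pm)$is_hit,
                      logical(1))
  expect_true(all(diff(as.integer(hits_by_k)) <= 0))
})

test_that("plate QC compares control means with degenerate-ratio rules", {
  pm <- tibble::tibble(
    plate_id = "P1",
    well_id = c("A1", "A2", "B1", "B2"),
    compound_id = c("emetine", "emetine", "DMSO", "DMSO"),
    role = c("positive_control", "positive_control",
             "negative_control", "negative_control"))
  mk <- function(pos, neg) tibble::tibble(
    plate_id = "P1", well_id = c("A1", "A2", "B1", "B2"), gene = "G",
    allele_id = "a", mutant_reads = 0, wildtype_reads = 0, depth = 1000,
    raw_maf = 0, corrected_maf = c(pos, pos, neg, neg), low_coverage = FALSE)

  qc <- plate_qc(mk(0.35, 0.10), pm, q = 2)
  expect_equal(qc$pos_neg_ratio, 3.5)
  expect_true(qc$passed)

  qc <- plate_qc(mk(0.10, 0.10), pm, q = 2)
  expect_equal(qc$pos_neg_ratio, 1)
  expect_false(qc$passed)

  qc <- plate_qc(mk(0.10, 0), pm, q = 2)
  expect_equal(qc$pos_neg_ratio, Inf)
  expect_true(qc$passed)

  # a plate with no usable controls fails with a reason
  qc <- plate_qc(mk(0.35, 0.10)[0, ], pm, q = 2)
  expect_false(qc$passed)
  expect_match(qc$reason, "missing")
})

test_that("dose-response tables are tidy, validated reporting", {
  tbl <- tidyr::crossing(concentration = 10^(0:5) * 1e-3,
                         allele_id = c("a1", "a2", "a3")) |>
    dplyr::mutate(corrected_maf = seq(0, 1, length.out = 18))
  out <- dose_response(tbl)
  expect_equal(nrow(out), 18)
  expect_equal(dplyr::n_distinct(out$concentration), 6)
  expect_error(dose_response(tbl[tbl$concentration == 1e-3, ]),
               "at least 2")
  expect_error(dose_response(dplyr::bind_rows(tbl, tbl[1, ])), "duplicate")
  all_zero <- dplyr::mutate(tbl, corrected_maf = 0)
  expect_equal(nrow(dose_response(all_zero)), 18)
})

test_that("score_wells pairs mutant and wild-type counts per gene and well", {
  d <- tiny_design()
  p <- tiny_panel()
  counts <- tibble::tibble(
    plate_id = "P1", well_id = c("A1", "A1", "A2"),
    gene = "G1", allele_id = c("G1_mut", "G1_wt", "G1_wt"),
    n = c(150, 850, 500))
  pm <- tibble::tibble(plate_id = "P1", well_id = c("A1", "A2", "A3"),
                       compound_id = c("x", "y", "z"), role = "library")
  s <- score_wells(counts, d, p, plate_map = pm, min_depth = 100)
  expect_equal(nrow(s), 3)  # one mutant allele x three mapped wells
  a1 <- s[s$well_id == "A1", ]
  expect_equal(a1$raw_maf, 0.15)
  expect_equal(a1$corrected_maf, 0.30)  # e = 1/2
  a2 <- s[s$well_id == "A2", ]
  expect_equal(a2$mutant_reads, 0)
  expect_equal(a2$raw_maf, 0)
  a3 <- s[s$well_id == "A3", ]  # absent from counts entirely
  expect_true(is.na(a3$raw_maf))
  expect_true(a3$low_coverage)
})
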