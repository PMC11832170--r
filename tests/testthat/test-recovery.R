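make_variant <- function(id = "v1", class = "frameshift_indel",
                         zygosity = "heterozygous",
                         mt1 = 20, wt1 = 80, mt2 = 20, wt2 = 80,
                         mc1 = 10, wc1 = 90, mc2 = 10, wc2 = 90,
                         nmd = TRUE) {
  tibble::tibble(
    variant_id = id, gene = paste0("GENE_", id), mutation_class = class,
    zygosity = zygosity,
    m_treated_1 = mt1, w_treated_1 = wt1, m_treated_2 = mt2, w_treated_2 = wt2,
    m_control_1 = mc1, w_control_1 = wc1, m_control_2 = mc2, w_control_2 = wc2,
    nmd_predicted = nmd)
}

test_that("inclusion filter requires heterozygosity and depth in all samples", {
  v <- dplyr::bind_rows(
    make_variant("v1", mt1 = 3, wt1 = 2, mt2 = 2, wt2 = 3,
                 mc1 = 5, wc1 = 0, mc2 = 0, wc2 = 5),          # 5,5,5,5 pass
    make_variant("v2", mt1 = 3, wt1 = 2, mt2 = 2, wt2 = 3,
                 mc1 = 4, wc1 = 0, mc2 = 0, wc2 = 5),          # one at 4 fail
    make_variant("v3", zygosity = "homozygous",
                 mt1 = 100, wt1 = 0, mt2 = 100, wt2 = 0,
                 mc1 = 100, wc1 = 0, mc2 = 100, wc2 = 0))      # zygosity fail
  out <- filter_variants(v, min_depth = 5)
  expect_equal(out$pass_filter, c(TRUE, FALSE, FALSE))

  # naive row-scan oracle on randomized tables, exact agreement
  set.seed(21)
  for (i in 1:5) {
    n <- 400
    tbl <- make_variant(sprintf("r%04d", 1:n))
    for (col in grep("^[mw]_", names(tbl), value = TRUE)) {
      tbl[[col]] <- sample(0:8, n, replace = TRUE)
    }
    tbl$zygosity <- sample(c("heterozygous", "homozygous"), n, replace = TRUE)
    d_min <- sample(3:7, 1)
    expect_identical(filter_variants(tbl, d_min)$pass_filter,
                     oracle_filter(tbl, d_min))
  }
})

test_that("fold change, inclusive threshold and zero-control pseudocount", {
  # FC exactly 2.0 is recovered ("at least two-fold" is inclusive)
  v <- make_variant(mt1 = 20, wt1 = 80, mt2 = 20, wt2 = 80,
                    mc1 = 10, wc1 = 90, mc2 = 10, wc2 = 90)
  out <- recovery_fold(v)
  expect_equal(out$fold_change, 2.0)
  expect_true(out$recovered)

  # FC 1.9 is not
  v <- make_variant(mt1 = 19, wt1 = 81, mt2 = 19, wt2 = 81)
  out <- recovery_fold(v)
  expect_equal(out$fold_change, 1.9)
  expect_false(out$recovered)

  # zero control MAF: pseudocount 0.5 on every count of all four samples
  v <- make_variant(mt1 = 30, wt1 = 70, mt2 = 30, wt2 = 70,
                    mc1 = 0, wc1 = 100, mc2 = 0, wc2 = 100)
  out <- recovery_fold(v, pseudocount = 0.5)
  expect_equal(out$maf_control, 0.5 / 101, tolerance = 1e-7)
  expect_equal(out$maf_treated, 30.5 / 101, tolerance = 1e-7)
  expect_equal(out$fold_change, 61.0, tolerance = 1e-7)
  expect_true(out$recovered)

  # failing the filter leaves FC missing and recovered FALSE
  v <- make_variant(zygosity = "homozygous")
  out <- recovery_fold(v)
  expect_true(is.na(out$fold_change))
  expect_false(out$recovered)

  # replicate aggregation is the arithmetic mean of per-replicate MAFs
  v <- make_variant(mt1 = 10, wt1 = 90, mt2 = 30, wt2 = 70)
  out <- recovery_fold(v)
  expect_equal(out$maf_treated, (0.1 + 0.3) / 2)

  # scale invariance without pseudocount: c * all counts leaves FC unchanged
  set.seed(22)
  for (i in 1:50) {
    counts <- sample(1:200, 8, replace = TRUE)
    v1 <- make_variant(mt1 = counts[1], wt1 = counts[2], mt2 = counts[3],
                       wt2 = counts[4], mc1 = counts[5], wc1 = counts[6],
                       mc2 = counts[7], wc2 = counts[8])
    c_ <- sample(2:9, 1)
    v2 <- make_variant(mt1 = c_ * counts[1], wt1 = c_ * counts[2],
                       mt2 = c_ * counts[3], wt2 = c_ * counts[4],
                       mc1 = c_ * counts[5], wc1 = c_ * counts[6],
                       mc2 = c_ * counts[7], wc2 = c_ * counts[8])
    expect_identical(recovery_fold(v1)$fold_change,
                     recovery_fold(v2)$fold_change)
  }

  # the mutant/wild-type denominator variant is exposed by config
  v <- make_variant(mt1 = 20, wt1 = 80, mt2 = 20, wt2 = 80,
                    mc1 = 10, wc1 = 90, mc2 = 10, wc2 = 90)
  out <- recovery_fold(v, maf_denominator = "wildtype")
  expect_equal(out$maf_treated, 0.25)
  expect_equal(out$fold_change, (20 / 80) / (10 / 90))
})

test_that("class stratification reports rates over passing variants only", {
  v <- dplyr::bind_rows(
    make_variant(sprintf("i%02d", 1:10), class = "frameshift_indel",
                 mt1 = c(rep(30, 4), rep(10, 6)),
                 mt2 = c(rep(30, 4), rep(10, 6))),
    make_variant("h1", class = "nonsense", zygosity = "homozygous"),
    make_variant("s1", class = "control_snp", mt1 = 10, mt2 = 10))
  out <- stratify_recovery(recovery_fold(v))
  indel <- out[out$mutation_class == "frameshift_indel", ]
  expect_equal(indel$n_pass, 10)
  expect_equal(indel$n_recovered, 4)
  expect_equal(indel$recovery_rate, 0.4)
  # class where nothing passes: rate is missing, not zero
  nonsense <- out[out$mutation_class == "nonsense", ]
  expect_equal(nonsense$n_pass, 0)
  expect_true(is.na(nonsense$recovery_rate))

  bad <- recovery_fold(make_variant())
  bad$mutation_class <- "mystery"
  expect_error(stratify_recovery(bad), "unknown mutation class")
})

test_that("two-proportion chi-squared matches the closed form and prop.test", {
  # worked values for the (30/100 vs 10/100) table
  expect_equal(two_proportion_test(30, 100, 10, 100,
                                   continuity = FALSE)$statistic, 12.5)
  expect_equal(two_proportion_test(30, 100, 10, 100)$statistic, 11.28125)
  # identical proportions
  t0 <- two_proportion_test(20, 100, 20, 100)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # degenerate margins error
  expect_error(two_proportion_test(0, 10, 0, 10), "degenerate")
  expect_error(two_proportion_test(10, 10, 5, 5), "degenerate")

  # 1000 random tables against closed form (both corrections) and the
  # independently implemented stats::prop.test route
  set.seed(23)
  for (i in 1:1000) {
    n1 <- sample(2:300, 1); n2 <- sample(2:300, 1)
    a1 <- sample(0:n1, 1); a2 <- sample(0:n2, 1)
    if ((a1 + a2) == 0 || (a1 + a2) == (n1 + n2)) next
    for (cont in c(TRUE, FALSE)) {
      got <- two_proportion_test(a1, n1, a2, n2, continuity = cont)
      want <- oracle_chi2(a1, n1, a2, n2, yates = cont)
      expect_equal(got$statistic, want, tolerance = 1e-9)
      ref <- suppressWarnings(stats::prop.test(c(a1, a2), c(n1, n2),
                                               correct = cont))
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    }
  }
})

test_that("variant tables round-trip through TSV and are validated", {
  v <- dplyr::bind_rows(make_variant("v1"), make_variant("v2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(v, f)
  back <- read_variant_table(f)
  expect_equal(as.data.frame(back), as.data.frame(v))

  bad <- v; bad$m_treated_1[2] <- -3
  readr::write_tsv(bad, f)
  expect_error(read_variant_table(f), "row 2")

  bad <- v; bad$mutation_class[1] <- "wild"
  readr::write_tsv(bad, f)
  expect_error(read_variant_table(f), "row 1.*wild")

  incomplete <- v[, setdiff(names(v), "m_control_2")]
  readr::write_tsv(incomplete, f)
  expect_error(suppressWarnings(read_variant_table(f)), "m_control_2")
})

test_that("a VCF with per-sample allele depths yields the same records", {
  v <- dplyr::bind_rows(
    make_variant("v1", mt1 = 12, wt1 = 88, mt2 = 9, wt2 = 91,
                 mc1 = 3, wc1 = 97, mc2 = 4, wc2 = 96),
    make_variant("v2", zygosity = "homozygous", mt1 = 50, wt1 = 0))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gt_of <- function(zyg) if (zyg == "homozygous") "1/1" else "0/1"
  rows <- vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    fmt <- function(m, w) sprintf("%s:%d,%d", gt_of(r$zygosity), w, m)
    paste(sprintf("chr%d", i), 1000 + i, r$variant_id, "A", "T", ".", "PASS",
          sprintf("CLASS=%s", r$mutation_class), "GT:AD",
          fmt(r$m_treated_1, r$w_treated_1), fmt(r$m_treated_2, r$w_treated_2),
          fmt(r$m_control_1, r$w_control_1), fmt(r$m_control_2, r$w_control_2),
          sep = "\t")
  }, character(1))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"mutation class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"allele depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "T1", "T2", "C1", "C2", sep = "\t"),
    rows), vcf)
  rec <- read_variant_vcf(vcf, sample_map = c(
    treated_1 = "T1", treated_2 = "T2", control_1 = "C1", control_2 = "C2"))
  count_cols <- grep("^[mw]_", names(rec), value = TRUE)
  expect_equal(as.data.frame(rec[, count_cols]),
               as.data.frame(v[, count_cols]))
  expect_equal(rec$mutation_class, v$mutation_class)
  expect_equal(rec$zygosity, v$zygosity)
  # 1-based VCF coordinates preserved in ids
  expect_equal(rec$variant_id, c("chr1:1001:A:T", "chr2:1002:A:T"))
})
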