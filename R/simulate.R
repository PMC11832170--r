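# Synthetic screens and variant tables with analytic ground truth.

#' Analytic expected mutant fraction under the pool mixture model
#'
#' Under equal per-cell expression, a mutant allele carried by \eqn{n_a}
#' lines at dosage \eqn{\delta_a} and transcribed at escape ratio
#' \eqn{\theta} (mutant-transcript output relative to an unsuppressed allele)
#' contributes \eqn{n_a \delta_a \theta} transcript dosage, against the
#' gene's total wild-type dosage \eqn{W_g = N - \sum_{a' \in g} n_{a'}
#' \delta_{a'}}. Since the MAF of allele *a* counts only reads matching *a*
#' or the wild-type sequence, its expectation is
#' \deqn{\frac{n_a \delta_a \theta}{n_a \delta_a \theta + W_g}.}
#' At \eqn{\theta = 1} (full NMD blockade) this is the allele's raw-MAF
#' ceiling; at \eqn{\theta = 0}, 0.
#'
#' @param design A [pool_design()].
#' @param allele_id Mutant allele id(s) in the design.
#' @param theta Escape ratio(s), non-negative (recycled against `allele_id`).
#' @return Numeric vector of expected raw mutant allele fractions in `[0, 1]`.
#' @export
#' @examples
#' d <- default_pool_design()
#' expected_mutant_fraction(d, "TP53_clone221_mut", 1)     # 1/3
#' expected_mutant_fraction(d, "TP53_clone221_mut", 1 / 6) # 0.076923
expected_mutant_fraction <- function(design, allele_id, theta) {
  if (any(theta < 0)) stop_bad("theta must be non-negative")
  i <- match(allele_id, design$carriers$allele_id)
  if (anyNA(i)) {
    stop_bad("allele '%s' is not in the pool design", allele_id[is.na(i)][1])
  }
  n <- max(length(i), length(theta))
  i <- rep_len(i, n)
  theta <- rep_len(theta, n)
  mut_dose <- design$carriers$n_carriers[i] * design$carriers$dosage[i] * theta
  wt <- design$wt_dosage$wt_dosage[
    match(design$carriers$gene[i], design$wt_dosage$gene)]
  ifelse(mut_dose + wt > 0, mut_dose / (mut_dose + wt), 0)
}

#' Configuration for the screen simulator
#'
#' Defaults reproduce the modelled screen's stated conditions: 96-well
#' plates with two positive-control (emetine) and six negative-control
#' (DMSO) wells each; a three-line pool with per-gene baseline NMD escape
#' \eqn{\theta_0} of 1/20 (STAG2, 20-fold suppression) and 1/6 (TP53,
#' 6-fold); a positive-control effect multiplier of 3.5 (emetine ran three-
#' to fourfold above DMSO); per-well sequencing depth negative-binomially
#' dispersed around a mean of 56,753 reads; and a per-base substitution
#' error rate of 0.001.
#'
#' @param n_plates Number of plates.
#' @param wells_per_plate Wells per plate (max 96).
#' @param n_pos,n_neg Positive / negative control wells per plate.
#' @param design A [pool_design()].
#' @param panel An [amplicon_panel()]; allele ids must match the design.
#' @param theta0 Named per-gene baseline escape ratio.
#' @param f_pos Positive-control effect multiplier on \eqn{\theta_0}.
#' @param spiked_effects Named numeric vector: library compound id ->
#'   inhibition effect multiplier (all >= 1). These compounds are placed at
#'   seeded-random library wells; every other library compound has effect 1.
#' @param error_rate Per-base substitution error rate, in `[0, 0.25)`.
#' @param depth_mean,depth_size Negative-binomial per-well depth (mean and
#'   size/dispersion).
#' @param read_length Read length (default 150 nt).
#' @param seed Integer seed; the simulator is byte-reproducible given a seed.
#' @param gzip Write gzip-compressed FASTQ.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_plates = 1L, wells_per_plate = 96L,
                              n_pos = 2L, n_neg = 6L,
                              design = default_pool_design(),
                              panel = default_amplicon_panel(),
                              theta0 = c(STAG2 = 1 / 20, TP53 = 1 / 6),
                              f_pos = 3.5,
                              spiked_effects = c(),
                              error_rate = 0.001,
                              depth_mean = 56753, depth_size = 20,
                              read_length = 150L,
                              seed = 1L, gzip = FALSE) {
  genes <- unique(design$carriers$gene)
  if (!all(genes %in% names(theta0))) {
    stop_bad("theta0 must name every gene in the design (%s)",
             paste(genes, collapse = ", "))
  }
  if (any(theta0 <= 0)) stop_bad("baseline escape ratios theta0 must be > 0")
  if (length(spiked_effects) > 0) {
    if (is.null(names(spiked_effects)) || any(names(spiked_effects) == "")) {
      stop_bad("spiked_effects must be named by compound id")
    }
    if (any(spiked_effects < 1)) {
      stop_bad("spiked inhibitor effects must be >= 1")
    }
    if (any(names(spiked_effects) %in% c("DMSO", "emetine"))) {
      stop_bad("cannot request a spiked effect on a control compound")
    }
  }
  if (error_rate < 0 || error_rate >= 0.25) {
    stop_bad("error_rate must lie in [0, 0.25)")
  }
  if (n_pos + n_neg >= wells_per_plate) {
    stop_bad("controls (%d) must leave room for library wells", n_pos + n_neg)
  }
  mism <- setdiff(design$carriers$allele_id, panel$allele_id)
  if (length(mism) > 0) {
    stop_bad("design allele '%s' is missing from the panel", mism[1])
  }
  structure(list(
    n_plates = as.integer(n_plates), wells_per_plate = as.integer(wells_per_plate),
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    design = design, panel = panel, theta0 = theta0, f_pos = f_pos,
    spiked_effects = spiked_effects, error_rate = error_rate,
    depth_mean = depth_mean, depth_size = depth_size,
    read_length = as.integer(read_length), seed = as.integer(seed),
    gzip = isTRUE(gzip)
  ), class = "screen_sim_config")
}

# Control wells sit at fixed positions spread over the plate; the layout is
# part of the generated plate map, not assumed anywhere downstream.
control_layout <- function(n_pos, n_neg) {
  pos <- c("A1", "H12", "D1", "E12")[seq_len(n_pos)]
  neg <- c("A12", "B1", "C6", "D7", "F6", "G12", "H1", "E2")[seq_len(n_neg)]
  list(pos = pos, neg = neg)
}

build_plate_map <- function(cfg) {
  lay <- control_layout(cfg$n_pos, cfg$n_neg)
  wells <- well_ids_96(cfg$wells_per_plate)
  maps <- vector("list", cfg$n_plates)
  lib_counter <- 0L
  for (p in seq_len(cfg$n_plates)) {
    plate_id <- sprintf("P%02d", p)
    role <- rep("library", length(wells))
    role[wells %in% lay$pos] <- "positive_control"
    role[wells %in% lay$neg] <- "negative_control"
    compound <- character(length(wells))
    compound[role == "positive_control"] <- "emetine"
    compound[role == "negative_control"] <- "DMSO"
    n_lib <- sum(role == "library")
    compound[role == "library"] <-
      sprintf("compound_%04d", lib_counter + seq_len(n_lib))
    lib_counter <- lib_counter + n_lib
    maps[[p]] <- tibble(plate_id = plate_id, well_id = wells,
                        compound_id = compound, role = role)
  }
  pm <- dplyr::bind_rows(maps)
  # place spiked inhibitors at random library wells (seeded caller RNG)
  if (length(cfg$spiked_effects) > 0) {
    lib_idx <- which(pm$role == "library")
    if (length(cfg$spiked_effects) > length(lib_idx)) {
      stop_bad("more spiked compounds than library wells")
    }
    slot <- sample(lib_idx, length(cfg$spiked_effects))
    pm$compound_id[slot] <- names(cfg$spiked_effects)
  }
  pm
}

# Per-allele sampling probabilities for one well: each allele's transcript
# dosage over the pool, mutants scaled by theta0[gene] * f.
allele_probs <- function(cfg, f) {
  panel <- cfg$panel
  carriers <- cfg$design$carriers
  dose <- numeric(nrow(panel))
  for (j in seq_len(nrow(panel))) {
    if (panel$is_mutant[j]) {
      k <- match(panel$allele_id[j], carriers$allele_id)
      dose[j] <- carriers$n_carriers[k] * carriers$dosage[k] *
        cfg$theta0[[panel$gene[j]]] * f
    } else {
      k <- match(panel$gene[j], cfg$design$wt_dosage$gene)
      dose[j] <- cfg$design$wt_dosage$wt_dosage[k]
    }
  }
  dose / sum(dose)
}

# Vectorized i.i.d. substitution errors over a character vector of reads.
apply_substitutions <- function(reads, error_rate, read_length) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  k <- stats::rbinom(length(reads), read_length, error_rate)
  tot <- sum(k)
  if (tot == 0) return(reads)
  rows <- rep(which(k > 0), k[k > 0])
  pos <- sample.int(read_length, tot, replace = TRUE)
  shift <- sample.int(3L, tot, replace = TRUE)
  o <- order(rows)
  rows <- rows[o]; pos <- pos[o]; shift <- shift[o]
  pass <- sequence(rle(rows)$lengths)
  for (p in unique(pass)) {
    sel <- pass == p
    r <- rows[sel]
    s <- reads[r]
    old <- substr(s, pos[sel], pos[sel])
    idx <- match(old, DNA_BASES)
    new <- DNA_BASES[((idx - 1L + shift[sel]) %% 4L) + 1L]
    substr(s, pos[sel], pos[sel]) <- new
    reads[r] <- s
  }
  reads
}

#' Simulate a pooled NMD screen as barcoded FASTQ
#'
#' Generates, per plate, a single-end FASTQ lane plus the plate map, barcode
#' manifest, amplicon panel and a truth manifest sufficient to recompute
#' every expectation analytically. Per well, depth is drawn
#' negative-binomially; each read picks an allele with probability
#' proportional to its transcript dosage in the pool (mutant alleles scaled
#' by \eqn{\theta_0 \times f} for the well's effect multiplier `f`), takes
#' that allele's amplicon sequence flanked by the well's plate and well
#' barcodes, and acquires i.i.d. substitution errors. Read ids encode the
#' true plate, well and allele, so truth is recoverable per read. Outputs are
#' byte-reproducible for a fixed seed.
#'
#' @param config A [screen_sim_config()].
#' @param dir Output directory (created).
#' @return A list of class `screen_sim` with elements `fastq` (paths),
#'   `manifest`, `panel`, `plate_map`, `truth` (per-well tibble:
#'   `plate_id`, `well_id`, `compound_id`, `role`, `effect`, `depth`, and
#'   expected per-allele raw fractions), and `paths` for every artifact
#'   written.
#' @export
simulate_screen <- function(config, dir = tempfile("screen_sim_")) {
  stopifnot(inherits(config, "screen_sim_config"))
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- default_barcode_manifest(cfg$n_plates, cfg$wells_per_plate,
                                       cfg$read_length)
  slot_len <- cfg$read_length - manifest$plate_bc_length -
    manifest$well_bc_length
  if (any(nchar(cfg$panel$sequence) < slot_len)) {
    stop_bad("panel amplicons must be at least %d nt for %d nt reads",
             slot_len, cfg$read_length)
  }
  withr::with_seed(cfg$seed, {
    pm <- build_plate_map(cfg)
    effects <- rep(1, nrow(pm))
    effects[pm$role == "positive_control"] <- cfg$f_pos
    spiked <- match(pm$compound_id, names(cfg$spiked_effects))
    effects[!is.na(spiked)] <- cfg$spiked_effects[spiked[!is.na(spiked)]]

    depths <- stats::rnbinom(nrow(pm), size = cfg$depth_size,
                             mu = cfg$depth_mean)

    panel <- cfg$panel
    plate_bc <- stats::setNames(manifest$plate_barcodes$sequence,
                                manifest$plate_barcodes$plate_id)
    well_bc <- stats::setNames(manifest$well_barcodes$sequence,
                               manifest$well_barcodes$well_id)
    amplicons <- substr(panel$sequence, 1,
                        cfg$read_length - manifest$plate_bc_length -
                          manifest$well_bc_length)
    qual_line <- strrep("I", cfg$read_length)

    fastq_paths <- character(cfg$n_plates)
    for (p in seq_len(cfg$n_plates)) {
      plate_id <- sprintf("P%02d", p)
      sel <- which(pm$plate_id == plate_id)
      well_of_read <- rep.int(sel, depths[sel])
      allele_idx <- integer(length(well_of_read))
      at <- 0L
      for (row in sel) {
        d <- depths[row]
        if (d == 0) next
        probs <- allele_probs(cfg, effects[row])
        n_allele <- as.vector(stats::rmultinom(1, d, probs))
        allele_idx[at + seq_len(d)] <- rep.int(seq_len(nrow(panel)), n_allele)
        at <- at + d
      }
      # interleave wells so the stream carries no well ordering
      ord <- sample.int(length(well_of_read))
      well_of_read <- well_of_read[ord]
      allele_idx <- allele_idx[ord]
      seqs <- paste0(plate_bc[[plate_id]], amplicons[allele_idx],
                     well_bc[pm$well_id[well_of_read]])
      seqs <- apply_substitutions(seqs, cfg$error_rate, cfg$read_length)
      n_reads <- length(well_of_read)
      lines <- character(4L * n_reads)
      lines[seq.int(1L, by = 4L, length.out = n_reads)] <-
        paste0("@sim:", plate_id, ":", pm$well_id[well_of_read], ":",
               panel$allele_id[allele_idx], ":", seq_len(n_reads))
      lines[seq.int(2L, by = 4L, length.out = n_reads)] <- seqs
      lines[seq.int(3L, by = 4L, length.out = n_reads)] <- "+"
      lines[seq.int(4L, by = 4L, length.out = n_reads)] <- qual_line
      fq <- file.path(dir, paste0("plate_", plate_id,
                                  if (cfg$gzip) ".fastq.gz" else ".fastq"))
      con <- if (cfg$gzip) gzfile(fq, "wb") else file(fq, "wb")
      writeLines(lines, con, sep = "\n", useBytes = TRUE)
      close(con)
      fastq_paths[p] <- fq
    }

    truth <- pm
    truth$effect <- effects
    truth$depth <- depths
    for (a in cfg$design$carriers$allele_id) {
      g <- cfg$design$carriers$gene[cfg$design$carriers$allele_id == a]
      truth[[paste0("expected_frac_", a)]] <-
        expected_mutant_fraction(cfg$design, a, cfg$theta0[[g]] * effects)
    }

    paths <- list(
      fastq = fastq_paths,
      plate_map = file.path(dir, "plate_map.csv"),
      barcode_tsv = file.path(dir, "barcodes.tsv"),
      barcode_config = file.path(dir, "barcodes.yaml"),
      panel_fasta = file.path(dir, "panel.fasta"),
      panel_windows = file.path(dir, "panel_windows.tsv"),
      pool_design = file.path(dir, "pool_design.yaml"),
      truth = file.path(dir, "truth.json")
    )
    write_plate_map(pm, paths$plate_map)
    write_barcode_manifest(manifest, paths$barcode_tsv, paths$barcode_config)
    write_amplicon_panel(panel, paths$panel_fasta, paths$panel_windows)
    write_pool_design(cfg$design, paths$pool_design)
    jsonlite::write_json(
      list(seed = cfg$seed,
           config_hash = rlang::hash(cfg[setdiff(names(cfg), "panel")]),
           theta0 = as.list(cfg$theta0), f_pos = cfg$f_pos,
           error_rate = cfg$error_rate, depth_mean = cfg$depth_mean,
           depth_size = cfg$depth_size,
           spiked_effects = as.list(cfg$spiked_effects),
           wells = truth),
      paths$truth, auto_unbox = TRUE, digits = NA, dataframe = "rows")

    structure(list(fastq = fastq_paths, manifest = manifest, panel = panel,
                   plate_map = pm, truth = truth, paths = paths,
                   config = cfg),
              class = "screen_sim")
  })
}

#' Configuration for the variant-table simulator
#'
#' Emulates the treated/control duplicate variant-count tables the recovery
#' stage consumes: per variant, a control mutant allele fraction `q` drawn
#' from a class-specific Beta distribution, independent per-sample site
#' depths (negative binomial), control mutant counts `Binomial(depth, q)`
#' and treated counts `Binomial(depth, min(1, q f))` for the class's true
#' fold `f` (`control_snp` fixed at `f = 1`).
#'
#' Default baseline Betas put NMD-suppressed heterozygous classes near MAF
#' 0.1 (between the 1/6- and 1/20-fold suppression the reporter genes
#' showed) and neutral heterozygous classes near 0.5.
#'
#' @param n_per_class Named integer vector: variants per mutation class
#'   (classes with 0 are absent from the output).
#' @param fold Named numeric vector: true treated/control fold per class;
#'   `control_snp` must be 1.
#' @param beta_shapes Named list of `c(shape1, shape2)` per class for the
#'   control-MAF Beta.
#' @param depth_mean,depth_size Negative-binomial per-sample site depth;
#'   `depth_size = Inf` gives fixed depth.
#' @param min_depth Lower truncation for drawn depths (default 1).
#' @param prop_homozygous Fraction of variants simulated homozygous
#'   (default 0; they exist to exercise the zygosity filter).
#' @param seed Integer seed.
#' @return A list of class `variant_sim_config`.
#' @export
variant_sim_config <- function(n_per_class = c(frameshift_indel = 100L,
                                               nonsense = 50L,
                                               other_snv = 100L,
                                               control_snp = 50L),
                               fold = c(frameshift_indel = 3,
                                        nonsense = 3,
                                        other_snv = 1,
                                        control_snp = 1),
                               beta_shapes = list(
                                 frameshift_indel = c(3, 27),
                                 nonsense = c(3, 27),
                                 other_snv = c(20, 20),
                                 control_snp = c(20, 20)),
                               depth_mean = 150, depth_size = 5,
                               min_depth = 1L,
                               prop_homozygous = 0,
                               seed = 1L) {
  bad <- setdiff(names(n_per_class), VARIANT_CLASSES)
  if (length(bad) > 0) stop_bad("unknown mutation class '%s'", bad[1])
  if (!is_count(n_per_class)) stop_bad("n_per_class must be counts")
  if (any(fold < 0)) stop_bad("true folds must be >= 0")
  if (!is.na(fold["control_snp"]) && fold[["control_snp"]] != 1) {
    stop_bad("control_snp variants are null by definition: fold must be 1")
  }
  structure(list(n_per_class = n_per_class, fold = fold,
                 beta_shapes = beta_shapes, depth_mean = depth_mean,
                 depth_size = depth_size, min_depth = as.integer(min_depth),
                 prop_homozygous = prop_homozygous,
                 seed = as.integer(seed)),
            class = "variant_sim_config")
}

#' Simulate a treated/control variant count table with known truth
#'
#' @param config A [variant_sim_config()].
#' @return A list of class `variant_sim` with `variants` (a table in the
#'   layout [read_variant_table()] expects, `nmd_predicted` set for the
#'   NMD-target classes) and `truth` (per variant: control MAF `q`, true
#'   fold, class, whether `q * f` saturated at 1).
#' @export
simulate_variant_table <- function(config) {
  stopifnot(inherits(config, "variant_sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    rows <- list()
    truth <- list()
    for (cls in names(cfg$n_per_class)) {
      n <- cfg$n_per_class[[cls]]
      if (n == 0) next
      sh <- cfg$beta_shapes[[cls]]
      f <- cfg$fold[[cls]]
      q <- stats::rbeta(n, sh[1], sh[2])
      p_treat <- pmin(1, q * f)
      ids <- sprintf("%s_%04d", cls, seq_len(n))
      zyg <- ifelse(stats::runif(n) < cfg$prop_homozygous,
                    "homozygous", "heterozygous")
      draw_depth <- function(n) {
        d <- if (is.infinite(cfg$depth_size)) {
          rep(round(cfg$depth_mean), n)
        } else {
          stats::rnbinom(n, size = cfg$depth_size, mu = cfg$depth_mean)
        }
        pmax(d, cfg$min_depth)
      }
      tab <- tibble(variant_id = ids,
                    gene = sprintf("GENE_%s", ids),
                    mutation_class = cls, zygosity = zyg)
      for (s in VARIANT_SAMPLES) {
        d <- draw_depth(n)
        p <- if (startsWith(s, "treated")) p_treat else q
        m <- stats::rbinom(n, d, p)
        tab[[paste0("m_", s)]] <- m
        tab[[paste0("w_", s)]] <- d - m
      }
      tab$nmd_predicted <- cls %in% c("frameshift_indel", "nonsense")
      rows[[cls]] <- tab
      truth[[cls]] <- tibble(variant_id = ids, mutation_class = cls,
                             control_maf = q, true_fold = f,
                             saturated = q * f > 1)
    }
    variants <- validate_variant_table(dplyr::bind_rows(rows))
    structure(list(variants = variants,
                   truth = dplyr::bind_rows(truth),
                   config = cfg),
              class = "variant_sim")
  })
}
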