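# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_jitter
#'   facet_wrap labs scale_y_log10 theme_bw
NULL

#' Plot per-well corrected MAFs against the hit thresholds
#'
#' One panel per reporter allele: corrected MAF of every scored library well,
#' with the allele's hit threshold as a horizontal line. Hits (if a hit table
#' is given) are highlighted.
#'
#' @param mafs A tibble from [score_wells()].
#' @param null An `nmd_null` model from [fit_null()].
#' @param hits Optional `nmd_hits` table; adds hit highlighting.
#' @return A ggplot object.
#' @export
plot_screen_maf <- function(mafs, null, hits = NULL) {
  df <- dplyr::left_join(
    as_tibble(mafs),
    tibble(allele_id = null$allele_id, threshold = null$threshold),
    by = "allele_id")
  df$well <- paste(df$plate_id, df$well_id)
  if (!is.null(hits)) {
    hit_wells <- paste(hits$plate_id, hits$well_id)[hits$is_hit]
    df$hit <- df$well %in% hit_wells
  } else {
    df$hit <- FALSE
  }
  ggplot(df, aes(x = .data$well, y = .data$corrected_maf,
                 colour = .data$hit)) +
    geom_point(size = 0.6, alpha = 0.7) +
    geom_hline(aes(yintercept = .data$threshold), linetype = "dashed") +
    facet_wrap(~allele_id, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    labs(x = NULL, y = "corrected MAF",
         title = "Per-well corrected mutant allele fraction") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' @rdname plot_screen_maf
#' @param object An `nmd_hits` table.
#' @param ... Unused.
#' @export
autoplot.nmd_hits <- function(object, ...) {
  long <- attr(object, "alleles")
  null <- attr(object, "null")
  plot_screen_maf(long, null, hits = object)
}

#' Plot recovery fold changes by mutation class
#'
#' Fold change (log scale) of every variant passing the inclusion filter,
#' jittered within mutation class, with the recovery threshold as a
#' horizontal line.
#'
#' @param object An `nmd_recovery` table from [recovery_fold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmd_recovery <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$pass_filter,
                      !is.na(.data$fold_change), .data$fold_change > 0)
  r <- attr(object, "r") %||% 2
  ggplot(df, aes(x = .data$mutation_class, y = .data$fold_change,
                 colour = .data$recovered)) +
    geom_jitter(width = 0.25, size = 0.8, alpha = 0.7) +
    geom_hline(yintercept = r, linetype = "dashed") +
    scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    labs(x = NULL, y = "treated / control MAF fold change",
         title = "Mutant-transcript recovery by mutation class") +
    theme_bw()
}

#' Plot a dose-response MAF series
#'
#' @param dr A tidy table from [dose_response()].
#' @return A ggplot object.
#' @export
plot_dose_response <- function(dr) {
  ggplot(dr, aes(x = .data$concentration, y = .data$corrected_maf,
                 colour = .data$allele_id, group = .data$allele_id)) +
    geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    labs(x = "concentration", y = "corrected MAF", colour = "allele") +
    theme_bw()
}
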