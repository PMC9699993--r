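#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the distance function and its fits
#'
#' Per-bin geometric-mean estimates of \eqn{f(d)} on the log-log scale
#' with the cubic, linear and theoretical fits overlaid.
#'
#' @param object A `chic_null_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chic_null_model
#' @export
autoplot.chic_null_model <- function(object, ...) {
  est <- object$bin_estimates |> dplyr::filter(!.data$empty)
  grid <- exp(seq(log(min(est$center)), log(max(est$center)),
                  length.out = 200))
  lines <- purrr::imap_dfr(object$all_fits, function(f, nm) {
    tibble::tibble(kind = nm, d = grid, f = eval_distance_fit(f, grid))
  })
  ggplot2::ggplot(est, ggplot2::aes(x = .data$center, y = .data$geo_mean)) +
    ggplot2::geom_point(size = 1.5, alpha = 0.7) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(x = .data$d, y = .data$f,
                                    colour = .data$kind)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance (bp)", y = "f(d): geometric mean count",
                  colour = "fit") +
    ggplot2::theme_minimal()
}

#' Bait-bait score symmetry plot
#'
#' \eqn{score_{ij}} against \eqn{score_{ji}} for bait-bait pairs, with
#' the significance threshold marked in both directions, the identity
#' line, and the five largest squared deviations labelled by fragment
#' ids.
#'
#' @param object A `chic_scored` tibble.
#' @param threshold Score threshold to mark (default 5).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chic_scored
#' @export
autoplot.chic_scored <- function(object, threshold = 5, ...) {
  bb <- bait_bait_directed(object)
  top <- bb |>
    dplyr::mutate(sq_dev = (.data$score_ij - .data$score_ji)^2) |>
    dplyr::arrange(dplyr::desc(.data$sq_dev)) |>
    dplyr::slice_head(n = 5)
  ggplot2::ggplot(bb, ggplot2::aes(x = .data$score_ij, y = .data$score_ji)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, colour = "darkorange") +
    ggplot2::geom_vline(xintercept = threshold, colour = "darkorange") +
    ggplot2::geom_text(data = top,
                       ggplot2::aes(label = paste0(.data$lo, "-", .data$hi)),
                       vjust = -0.6, size = 2.8) +
    ggplot2::labs(x = "score (forward)", y = "score (reverse)") +
    ggplot2::theme_minimal()
}

#' Weight curve against observed priors
#'
#' @param object A `chic_weight_curve`.
#' @param observed_prior Optional [observed_prior()] tibble to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chic_weight_curve
#' @export
autoplot.chic_weight_curve <- function(object, observed_prior = NULL, ...) {
  rng <- if (!is.null(observed_prior)) range(observed_prior$center)
         else c(1e4, 1.5e6)
  grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = 200))
  p <- ggplot2::ggplot(
    tibble::tibble(d = grid, w = eval_weight_curve(object, grid)),
    ggplot2::aes(x = .data$d, y = .data$w)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance (bp)", y = "prior probability") +
    ggplot2::theme_minimal()
  if (!is.null(observed_prior)) {
    p <- p + ggplot2::geom_point(
      data = observed_prior |> dplyr::filter(!.data$empty),
      ggplot2::aes(x = .data$center, y = .data$prior),
      inherit.aes = FALSE, size = 1.5, alpha = 0.7)
  }
  p
}

#' Plot the bin-wise KS battery
#'
#' D statistic per distance bin, coloured by Bonferroni significance.
#'
#' @param ks_table Output of [bonferroni_ks()].
#' @param binning The binning used.
#' @return A ggplot.
#' @export
plot_ks_table <- function(ks_table, binning = distance_bins()) {
  dat <- ks_table |>
    dplyr::left_join(binning |> dplyr::select("bin", "center"), by = "bin")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$center, y = .data$d_statistic,
                                    colour = .data$significant_after_bonferroni)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "bin center (bp)", y = "KS D statistic",
                  colour = "rejected") +
    ggplot2::theme_minimal()
}
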