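#' Evaluate a four-parameter logistic weight curve
#'
#' The prior probability of a true interaction at distance `d` is modelled
#' as a bounded logistic in log distance,
#' \eqn{w(d) = L + (U - L) / (1 + e^{s (\log d - m)})},
#' with lower/upper asymptotes \eqn{L \le U} in \eqn{[0, 1]}, midpoint `m`
#' on the log-distance axis and slope \eqn{s \ge 0}, so the curve is
#' monotone non-increasing in distance.
#'
#' @param params Numeric vector `c(lower, upper, midpoint, slope)` or a
#'   `chic_weight_curve`.
#' @param distance_bp Distances in bp.
#' @return Prior probabilities in `[0, 1]`.
#' @export
eval_weight_curve <- function(params, distance_bp) {
  if (inherits(params, "chic_weight_curve")) params <- params$params
  p <- params
  p[1] + (p[2] - p[1]) / (1 + exp(p[4] * (log(distance_bp) - p[3])))
}

#' Fit the weight curve to observed interaction priors
#'
#' Least-squares fit of the four-parameter bounded logistic to the
#' observed per-bin prior probability of interaction (the fraction of
#' tested pairs called reproducibly significant in each distance bin).
#' Bins with no observed interactions are excluded from the objective —
#' they would force an infinite log prior — but their number is reported,
#' since dropping bins deflates the RSS. Monotonicity is enforced by
#' constraining the slope non-negative; the optimiser (`L-BFGS-B`) is
#' restarted from 3 deterministic initial points.
#'
#' @param observed_prior Tibble with `center` (bin center, bp), `prior`
#'   (proportion in `[0,1]`) and logical `empty` (no observed
#'   interactions). A bare numeric vector is accepted and paired with
#'   `binning` centers (zeros treated as empty bins).
#' @param binning A [distance_bins()] tibble.
#' @return A `chic_weight_curve`: list with `params`
#'   (`lower`, `upper`, `midpoint`, `slope`), `rss` over contributing
#'   bins, and `n_zero_bins`.
#' @export
fit_weight_curve <- function(observed_prior, binning = distance_bins()) {
  if (is.numeric(observed_prior)) {
    observed_prior <- tibble::tibble(
      center = binning$center[seq_along(observed_prior)],
      prior = observed_prior,
      empty = observed_prior == 0)
  }
  use <- observed_prior |> dplyr::filter(!.data$empty)
  n_zero <- sum(observed_prior$empty)
  if (nrow(use) < 4) {
    stop("need at least 4 distance bins with observed interactions to fit ",
         "the weight curve, got ", nrow(use), call. = FALSE)
  }
  x <- log(use$center); y <- use$prior
  obj <- function(p) sum((y - (p[1] + (p[2] - p[1]) /
                                 (1 + exp(p[4] * (x - p[3])))))^2)
  lo <- c(0, 0, min(x) - 2, 0)
  hi <- c(1, 1, max(x) + 2, 50)
  starts <- list(
    c(max(min(y), 0), min(max(y), 1), stats::median(x), 2),
    c(0, min(max(y) * 1.2, 1), stats::quantile(x, 0.25, names = FALSE), 5),
    c(min(y) * 0.5, min(max(y), 1), stats::quantile(x, 0.75, names = FALSE), 0.5)
  )
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("weight-curve optimisation failed", call. = FALSE)
  p <- best$par
  if (p[1] > p[2]) p[c(1, 2)] <- p[c(2, 1)]  # keep lower <= upper
  structure(list(
    params = stats::setNames(p, c("lower", "upper", "midpoint", "slope")),
    rss = best$value,
    n_zero_bins = n_zero
  ), class = "chic_weight_curve")
}

#' @export
print.chic_weight_curve <- function(x, ...) {
  cat("<chic_weight_curve> lower:", signif(x$params[1], 4),
      " upper:", signif(x$params[2], 4),
      " midpoint:", signif(x$params[3], 4),
      " slope:", signif(x$params[4], 4), "\n")
  cat("  rss:", signif(x$rss, 5), " zero bins excluded:", x$n_zero_bins, "\n")
  invisible(x)
}

#' @rdname fit_weight_curve
#' @param x A `chic_weight_curve`.
#' @param ... Unused.
#' @method tidy chic_weight_curve
#' @export
tidy.chic_weight_curve <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname fit_weight_curve
#' @method glance chic_weight_curve
#' @export
glance.chic_weight_curve <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_zero_bins = x$n_zero_bins)
}

#' Observed per-bin prior probability of interaction
#'
#' The empirical quantity the weight curve is fitted to: per distance bin,
#' the fraction of tested cis pairs whose log p-value falls below `rho` in
#' *all* replicates — reproducible interactions being taken as true.
#' Pairs absent from any replicate count as non-reproducible.
#'
#' @param scored_replicates List of scored tibbles (from
#'   [compute_scores()]), one per replicate, sharing `bait_id`/`other_id`.
#' @param rho Log p-value cutoff defining a robust interaction
#'   (default -10).
#' @param binning A [distance_bins()] tibble.
#' @return Tibble `bin`, `center`, `n_pairs`, `n_reproducible`, `prior`,
#'   `empty` (no reproducible interactions observed in the bin).
#' @export
observed_prior <- function(scored_replicates, rho = -10,
                           binning = distance_bins()) {
  stopifnot(length(scored_replicates) >= 1)
  combined <- purrr::imap(scored_replicates, function(df, i) {
    df |>
      dplyr::filter(!is.na(.data$distance_bp)) |>
      dplyr::distinct(.data$bait_id, .data$other_id, .keep_all = TRUE) |>
      dplyr::transmute(.data$bait_id, .data$other_id, .data$distance_bp,
                       robust = .data$log_p < rho)
  }) |>
    purrr::reduce(function(a, b) {
      dplyr::inner_join(a, b, by = c("bait_id", "other_id", "distance_bp"),
                        suffix = c("", ".y")) |>
        dplyr::mutate(robust = .data$robust & .data$robust.y) |>
        dplyr::select(-"robust.y")
    })
  combined |>
    dplyr::mutate(bin = assign_bins(.data$distance_bp, binning)) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     n_reproducible = sum(.data$robust), .groups = "drop") |>
    dplyr::right_join(binning |> dplyr::select("bin", "center"), by = "bin") |>
    dplyr::arrange(.data$bin) |>
    dplyr::mutate(
      n_pairs = dplyr::coalesce(.data$n_pairs, 0L),
      n_reproducible = dplyr::coalesce(.data$n_reproducible, 0L),
      prior = ifelse(.data$n_pairs > 0, .data$n_reproducible / .data$n_pairs, 0),
      empty = .data$n_reproducible == 0)
}
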