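#' Per-bin distance-function estimates
#'
#' Estimates the background distance function \eqn{f(d)} — expected read
#' count as a function of genomic separation — as the geometric mean of the
#' *non-zero* counts between bait/other-end pairs in each distance bin.
#' Bins with no positive counts are flagged empty rather than set to zero:
#' an empty bin carries no information about \eqn{f}.
#'
#' @param interactions A tibble with at least `count` and `distance_bp`
#'   columns (cis pairs; trans rows with `NA` distance are dropped).
#' @param binning A [distance_bins()] tibble.
#' @return A tibble with one row per bin: `bin`, `center`, `geo_mean`
#'   (`NA` when empty), `n_nonzero`, `n_pairs`, `empty`.
#' @export
estimate_distance_function <- function(interactions, binning = distance_bins()) {
  if (nrow(interactions) == 0) stop("no interactions supplied", call. = FALSE)
  dat <- interactions |>
    dplyr::mutate(bin = assign_bins(.data$distance_bp, binning)) |>
    dplyr::filter(!is.na(.data$bin))
  if (nrow(dat) == 0) stop("no cis interactions within the binning range", call. = FALSE)
  per_bin <- dat |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(
      geo_mean = if (any(.data$count > 0))
        exp(mean(log(.data$count[.data$count > 0]))) else NA_real_,
      n_nonzero = sum(.data$count > 0),
      n_pairs = dplyr::n(),
      .groups = "drop"
    )
  binning |>
    dplyr::select("bin", "center") |>
    dplyr::left_join(per_bin, by = "bin") |>
    dplyr::mutate(
      n_nonzero = dplyr::coalesce(.data$n_nonzero, 0L),
      n_pairs = dplyr::coalesce(.data$n_pairs, 0L),
      empty = is.na(.data$geo_mean)
    )
}

new_distance_fit <- function(kind, coefficients, rss, fit_range_bp = c(1e4, 1.5e6)) {
  structure(
    list(kind = kind, coefficients = coefficients, rss = rss,
         fit_range_bp = fit_range_bp, curvature_K = NA_real_),
    class = "chic_distance_fit"
  )
}

#' @export
print.chic_distance_fit <- function(x, ...) {
  cat("<chic_distance_fit> kind:", x$kind, "\n")
  cat("  coefficients:", paste(signif(x$coefficients, 5), collapse = ", "), "\n")
  cat("  rss:", signif(x$rss, 5),
      " curvature K:", signif(x$curvature_K, 5), "\n")
  invisible(x)
}

#' Fit distance-decay curves on the log-log scale
#'
#' Fits three forms to the per-bin geometric-mean estimates of the distance
#' function, all by ordinary least squares on \eqn{(\log d_b, \log \hat f_b)}:
#' * cubic: \eqn{\log f(d) = a_0 + a_1 \log d + a_2 (\log d)^2 + a_3 (\log d)^3}
#' * linear: \eqn{\log f(d) = b_0 + b_1 \log d}
#' * theoretical: \eqn{\log f(d) = c_0 - \log d}, the power law
#'   \eqn{f(d) \propto d^{-1}} expected for long-range polymer contacts;
#'   only the intercept is estimated.
#'
#' @param bin_estimates Output of [estimate_distance_function()] (empty bins
#'   are skipped).
#' @param binning The binning used (kept for the fit range).
#' @return A named list of three `chic_distance_fit` objects
#'   (`cubic`, `linear`, `theoretical`), each carrying its RSS and
#'   curvature `K` (see [curvature_K()]).
#' @export
fit_distance_curves <- function(bin_estimates, binning = distance_bins()) {
  use <- bin_estimates |> dplyr::filter(!.data$empty)
  if (nrow(use) < 5) {
    stop("need at least 5 non-empty distance bins to fit, got ", nrow(use),
         call. = FALSE)
  }
  x <- log(use$center)
  y <- log(use$geo_mean)
  if (stats::sd(x) < 1e-12) stop("degenerate input: distances collinear", call. = FALSE)

  lin <- stats::lm(y ~ x)
  cub <- stats::lm(y ~ x + I(x^2) + I(x^3))
  c0 <- mean(y + x)  # least squares with slope fixed at -1

  fits <- list(
    cubic = new_distance_fit("cubic",
      stats::setNames(stats::coef(cub), c("a0", "a1", "a2", "a3")),
      sum(stats::resid(cub)^2)),
    linear = new_distance_fit("linear",
      stats::setNames(stats::coef(lin), c("b0", "b1")),
      sum(stats::resid(lin)^2)),
    theoretical = new_distance_fit("theoretical",
      c(c0 = c0),
      sum((y - (c0 - x))^2))
  )
  lapply(fits, function(f) { f$curvature_K <- curvature_K(f); f })
}

# y(x) = log f(e^x) and derivatives, as polynomial coefficient vector
fit_poly_coef <- function(fit) {
  switch(fit$kind,
    cubic = unname(fit$coefficients),
    linear = c(unname(fit$coefficients), 0, 0),
    theoretical = c(unname(fit$coefficients), -1, 0, 0),
    stop("unsupported fit kind: ", fit$kind, call. = FALSE)
  )
}

#' Evaluate a fitted distance function
#'
#' Returns \eqn{f(d)} for a `chic_distance_fit`. Outside the fit range the
#' log-log curve is extrapolated linearly, continuing with the slope at the
#' nearer range boundary (exact for linear/theoretical fits; tangent-line
#' continuation for the cubic).
#'
#' @param fit A `chic_distance_fit`.
#' @param distance_bp Distances in bp (positive).
#' @return Expected background counts \eqn{f(d)}.
#' @export
eval_distance_fit <- function(fit, distance_bp) {
  a <- fit_poly_coef(fit)
  lo <- log(fit$fit_range_bp[1]); hi <- log(fit$fit_range_bp[2])
  x <- log(distance_bp)
  yv <- function(x) a[1] + a[2] * x + a[3] * x^2 + a[4] * x^3
  yd <- function(x) a[2] + 2 * a[3] * x + 3 * a[4] * x^2
  y <- yv(pmin(pmax(x, lo), hi))
  y <- ifelse(x < lo, yv(lo) + yd(lo) * (x - lo), y)
  y <- ifelse(x > hi, yv(hi) + yd(hi) * (x - hi), y)
  exp(y)
}

#' Integrated curvature of a distance fit
#'
#' Deviation of the fitted decay from a pure power law, measured as
#' \eqn{K = \int \kappa(x)\,dx} with
#' \eqn{\kappa = |y''| / (1 + y'^2)^{3/2}} and \eqn{y(x) = \log f(e^x)},
#' integrated over \eqn{[\log 10^4, \log 1.5 \times 10^6]}. A power law is
#' a straight line on the log-log scale, so `K = 0` exactly for the linear
#' and theoretical fits; `K` is invariant to vertical shifts of the curve.
#'
#' @param fit A `chic_distance_fit`.
#' @return Non-negative curvature integral.
#' @export
curvature_K <- function(fit) {
  a <- fit_poly_coef(fit)
  if (abs(a[3]) < 1e-300 && abs(a[4]) < 1e-300) return(0)
  lo <- log(fit$fit_range_bp[1]); hi <- log(fit$fit_range_bp[2])
  kappa <- function(x) {
    yp <- a[2] + 2 * a[3] * x + 3 * a[4] * x^2
    ypp <- 2 * a[3] + 6 * a[4] * x
    abs(ypp) / (1 + yp^2)^1.5
  }
  stats::integrate(kappa, lo, hi, rel.tol = 1e-10,
                   subdivisions = 500L)$value
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_distance_curves
#' @param x A `chic_distance_fit`.
#' @param ... Unused.
#' @method tidy chic_distance_fit
#' @export
tidy.chic_distance_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname fit_distance_curves
#' @method glance chic_distance_fit
#' @export
glance.chic_distance_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, rss = x$rss, curvature_K = x$curvature_K,
                 n_coef = length(x$coefficients))
}
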