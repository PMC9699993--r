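#' Estimate fragment-level biases
#'
#' Two-pass ratio estimator for multiplicative fragment biases under the
#' background model \eqn{E[X_{ij}] = s_i s_j f(d)}. The bait-end bias
#' \eqn{s_i} is treated as *fixed* per bait: observed total cis counts for
#' the bait divided by the total expected under \eqn{f(d)} with unit
#' biases, then normalised to geometric mean 1 across baits. Other-end
#' biases are treated as *draws from a random distribution*: other ends
#' are stratified into `n_pools` quantile pools by their marginal counts,
#' and each pool is summarised by the empirical distribution of the
#' analogous observed/expected ratios (normalised to overall geometric
#' mean 1). This fixed-vs-random asymmetry is what makes bait-bait scores
#' direction-dependent.
#'
#' @param interactions Tibble with `bait_id`, `other_id`, `count`,
#'   `distance_bp` (cis rows used).
#' @param distance_fit A `chic_distance_fit` (the active \eqn{f(d)}).
#' @param binning A [distance_bins()] tibble (defines the usable range).
#' @param n_pools Number of other-end quantile pools (default 5).
#' @return A list with `bait_bias` (tibble `fragment_id`, `bias`,
#'   `n_pairs`), `other_end_pools` (tibble `fragment_id`, `pool`),
#'   `pool_bias` (tibble `pool`, `mean_bias`, and list-column `biases`
#'   with each pool's empirical ratio distribution), and
#'   `unestimable_baits` (ids with no usable pairs).
#' @export
estimate_biases <- function(interactions, distance_fit,
                            binning = distance_bins(), n_pools = 5) {
  up <- attr(binning, "upper_bp")
  cis <- interactions |>
    dplyr::filter(!is.na(.data$distance_bp),
                  .data$distance_bp > 0, .data$distance_bp <= up) |>
    dplyr::mutate(expected = eval_distance_fit(distance_fit, .data$distance_bp))

  all_baits <- unique(interactions$bait_id)
  bait <- cis |>
    dplyr::group_by(fragment_id = .data$bait_id) |>
    dplyr::summarise(raw = sum(.data$count) / sum(.data$expected),
                     n_pairs = dplyr::n(), .groups = "drop")
  unestimable <- c(setdiff(all_baits, bait$fragment_id),
                   bait$fragment_id[bait$raw <= 0])
  bait <- bait |> dplyr::filter(.data$raw > 0)
  if (nrow(bait) == 0) stop("no baits with usable cis pairs", call. = FALSE)
  bait <- bait |>
    dplyr::mutate(bias = .data$raw / exp(mean(log(.data$raw)))) |>
    dplyr::select("fragment_id", "bias", "n_pairs")

  # other ends: marginal-count quantile pools, ratio distribution per pool
  oe <- cis |>
    dplyr::left_join(bait |> dplyr::select("fragment_id", bait_bias = "bias"),
                     by = c(bait_id = "fragment_id")) |>
    dplyr::filter(!is.na(.data$bait_bias)) |>
    dplyr::group_by(fragment_id = .data$other_id) |>
    dplyr::summarise(marginal = sum(.data$count),
                     raw = sum(.data$count) / sum(.data$expected * .data$bait_bias),
                     .groups = "drop")
  k <- max(1L, min(n_pools, dplyr::n_distinct(oe$marginal)))
  oe <- oe |>
    dplyr::mutate(pool = as.integer(dplyr::ntile(rank(.data$marginal,
                                                      ties.method = "first"), k)))
  pos <- oe |> dplyr::filter(.data$raw > 0)
  gm <- exp(mean(log(pos$raw)))
  oe <- oe |> dplyr::mutate(norm = .data$raw / gm)
  pool_bias <- oe |>
    dplyr::filter(.data$norm > 0) |>
    dplyr::group_by(pool = .data$pool) |>
    dplyr::summarise(mean_bias = mean(.data$norm),
                     biases = list(.data$norm), .groups = "drop")

  list(
    bait_bias = bait,
    other_end_pools = oe |> dplyr::select("fragment_id", "pool"),
    pool_bias = pool_bias,
    unestimable_baits = unique(unestimable)
  )
}

#' Estimate the global negative binomial dispersion
#'
#' Profile maximum likelihood for the dispersion `r` shared by all pairs,
#' holding the per-pair means \eqn{\mu_{ij} = s_i s_j f(d)} fixed.
#' Optimised over \eqn{\log r} by golden-section search; under-dispersed
#' (Poisson-like) data hits the cap `r = 1e6` and triggers a warning.
#'
#' @param interactions Tibble with `count` and `distance_bp`.
#' @param model A `chic_null_model` (or any list with `distance_fit`,
#'   `bait_bias`, `other_end_pools`, `pool_bias`) supplying the means.
#' @param binning A [distance_bins()] tibble.
#' @return Positive dispersion estimate.
#' @export
estimate_dispersion <- function(interactions, model, binning = distance_bins()) {
  mu <- pair_means(interactions, model, binning)
  keep <- !is.na(mu) & mu > 0
  x <- interactions$count[keep]; mu <- mu[keep]
  if (length(x) == 0) stop("no usable pairs for dispersion estimation", call. = FALSE)
  nll <- function(logr) {
    -sum(stats::dnbinom(x, size = exp(logr), mu = mu, log = TRUE))
  }
  cap <- 1e6
  opt <- stats::optimize(nll, interval = c(log(1e-3), log(cap)), tol = 1e-6)
  r_hat <- exp(opt$minimum)
  # Poisson data have Pearson chi-square about n; anything within two
  # standard errors of that carries no overdispersion signal
  pearson <- sum((x - mu)^2 / mu)
  n <- length(x)
  if (r_hat > 0.98 * cap || pearson <= n * (1 + 2 * sqrt(2 / n))) {
    warning("data not overdispersed relative to the model; ",
            "dispersion capped at 1e6", call. = FALSE)
    r_hat <- cap
  }
  r_hat
}

#' Estimate technical-noise levels from trans pairs
#'
#' The Poisson technical-noise mean \eqn{\lambda} is estimated from
#' trans-chromosomal pairs, which the Brownian background cannot produce.
#' Baits are stratified into `n_pools` quantile pools by their total
#' marginal reads (a depth/brightness proxy); within a pool, \eqn{\lambda} is the total observed trans reads
#' divided by the number of *possible* trans pairs (baits in the pool times
#' trans-chromosomal other ends). Also reports the mean number of observed
#' trans pairs per bait, a depth diagnostic.
#'
#' @param interactions Tibble with `bait_id`, `other_id`, `count`,
#'   `distance_bp` (`NA` distance = trans).
#' @param n_trans_fragments Number of possible trans other-end fragments
#'   per bait (from the fragment map).
#' @param n_pools Number of bait pools (default 5).
#' @return A list with `lambda_pools` (tibble `pool`, `lambda`, `n_baits`),
#'   `bait_pool` (tibble `fragment_id`, `pool`),
#'   `mean_trans_pairs_per_bait`, and `per_bait` (trans totals).
#' @export
estimate_lambda <- function(interactions, n_trans_fragments, n_pools = 5) {
  trans <- interactions |> dplyr::filter(is.na(.data$distance_bp))
  baits <- unique(interactions$bait_id)
  marginal <- interactions |>
    dplyr::group_by(fragment_id = .data$bait_id) |>
    dplyr::summarise(total_reads = sum(.data$count), .groups = "drop")
  per_bait <- tibble::tibble(fragment_id = baits) |>
    dplyr::left_join(marginal, by = "fragment_id") |>
    dplyr::left_join(
      trans |>
        dplyr::group_by(fragment_id = .data$bait_id) |>
        dplyr::summarise(trans_reads = sum(.data$count),
                         trans_pairs = sum(.data$count > 0), .groups = "drop"),
      by = "fragment_id") |>
    dplyr::mutate(total_reads = dplyr::coalesce(.data$total_reads, 0L),
                  trans_reads = dplyr::coalesce(.data$trans_reads, 0L),
                  trans_pairs = dplyr::coalesce(.data$trans_pairs, 0L))
  if (nrow(trans) == 0 || sum(per_bait$trans_reads) == 0) {
    warning("no trans reads present; all lambda estimates are 0", call. = FALSE)
  }
  k <- max(1L, min(n_pools, nrow(per_bait)))
  per_bait <- per_bait |>
    dplyr::mutate(pool = as.integer(dplyr::ntile(
      rank(.data$total_reads, ties.method = "first"), k)))
  pools <- per_bait |>
    dplyr::group_by(pool = .data$pool) |>
    dplyr::summarise(
      lambda = sum(.data$trans_reads) / (dplyr::n() * n_trans_fragments),
      n_baits = dplyr::n(), .groups = "drop")
  list(
    lambda_pools = pools,
    bait_pool = per_bait |> dplyr::select("fragment_id", "pool"),
    mean_trans_pairs_per_bait = mean(per_bait$trans_pairs),
    per_bait = per_bait
  )
}

# expected count s_i * s_j * f(d) for each row; NA for trans / unestimable
pair_means <- function(interactions, model, binning = distance_bins()) {
  up <- attr(binning, "upper_bp")
  dat <- interactions |>
    dplyr::left_join(model$bait_bias |>
                       dplyr::select("fragment_id", s_bait = "bias"),
                     by = c(bait_id = "fragment_id")) |>
    dplyr::left_join(model$other_end_pools, by = c(other_id = "fragment_id")) |>
    dplyr::left_join(model$pool_bias |> dplyr::select("pool", s_other = "mean_bias"),
                     by = "pool")
  ok <- !is.na(dat$distance_bp) & dat$distance_bp > 0 & dat$distance_bp <= up
  mu <- rep(NA_real_, nrow(dat))
  scale <- if (is.null(model$mean_scale)) 1 else model$mean_scale
  mu[ok] <- scale * dat$s_bait[ok] * dat$s_other[ok] *
    eval_distance_fit(model$distance_fit, dat$distance_bp[ok])
  mu
}

#' Estimate a complete background model
#'
#' Convenience wrapper running the full estimation cascade on one
#' replicate's interaction table: per-bin distance function, the three
#' log-log fits (the cubic is taken as the active \eqn{f(d)}), fragment
#' biases, dispersion, and per-pool technical noise.
#'
#' @param interactions Interaction tibble (`bait_id`, `other_id`, `count`,
#'   `distance_bp`).
#' @param n_trans_fragments Possible trans other ends per bait (for
#'   \eqn{\lambda}); 0 trans rows give \eqn{\lambda = 0}.
#' @param binning A [distance_bins()] tibble.
#' @param active_fit Which distance fit drives scoring
#'   (`"cubic"`, `"linear"` or `"theoretical"`).
#' @param n_pools Quantile pools for other-end biases and \eqn{\lambda}.
#' @return A `chic_null_model`: list with `distance_fit`, `all_fits`,
#'   `bin_estimates`, `dispersion_r`, `bait_bias`, `other_end_pools`,
#'   `pool_bias`, `lambda_pools`, `bait_lambda_pool`, `binning`.
#' @export
estimate_null_model <- function(interactions, n_trans_fragments = 0,
                                binning = distance_bins(),
                                active_fit = "cubic", n_pools = 5) {
  bins <- estimate_distance_function(interactions, binning)
  fits <- fit_distance_curves(bins, binning)
  active <- fits[[active_fit]]
  biases <- estimate_biases(interactions, active, binning, n_pools)
  model <- structure(
    list(distance_fit = active, all_fits = fits, bin_estimates = bins,
         bait_bias = biases$bait_bias,
         other_end_pools = biases$other_end_pools,
         pool_bias = biases$pool_bias,
         unestimable_baits = biases$unestimable_baits,
         mean_scale = 1,
         binning = binning),
    class = "chic_null_model")
  # calibrate the arithmetic scale: the geometric-mean distance estimates
  # sit below the arithmetic mean by a dispersion-dependent factor, so a
  # single multiplicative correction matches total expected to observed
  mu0 <- pair_means(interactions, model, binning)
  ok <- !is.na(mu0)
  model$mean_scale <- sum(interactions$count[ok]) / sum(mu0[ok])
  model$dispersion_r <- estimate_dispersion(interactions, model, binning)
  if (n_trans_fragments > 0 && any(is.na(interactions$distance_bp))) {
    lam <- estimate_lambda(interactions, n_trans_fragments, n_pools)
    model$lambda_pools <- lam$lambda_pools
    model$bait_lambda_pool <- lam$bait_pool
    model$mean_trans_pairs_per_bait <- lam$mean_trans_pairs_per_bait
  } else {
    model$lambda_pools <- tibble::tibble(pool = 1L, lambda = 0, n_baits = NA_integer_)
    model$bait_lambda_pool <- tibble::tibble(
      fragment_id = unique(interactions$bait_id), pool = 1L)
    model$mean_trans_pairs_per_bait <- 0
  }
  model
}

#' @export
print.chic_null_model <- function(x, ...) {
  cat("<chic_null_model>\n")
  cat("  distance fit:", x$distance_fit$kind,
      "(K =", signif(x$distance_fit$curvature_K, 4), ")\n")
  cat("  dispersion r:", signif(x$dispersion_r, 5), "\n")
  cat("  baits:", nrow(x$bait_bias), " other-end pools:", nrow(x$pool_bias), "\n")
  cat("  lambda pools:", paste(signif(x$lambda_pools$lambda, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a background model from known parameters
#'
#' Builds a `chic_null_model` directly from ground-truth parameters, e.g.
#' the generator's, bypassing estimation. Useful for scoring simulated
#' data with the generating model and for oracle tests.
#'
#' @param distance_fit A `chic_distance_fit`.
#' @param dispersion_r Positive dispersion.
#' @param bait_bias Tibble `fragment_id`, `bias`.
#' @param other_end_bias Tibble `fragment_id`, `bias` (each fragment its
#'   own pool of one; pool mean = own bias).
#' @param lambda Single technical-noise mean applied to all pairs.
#' @param binning A [distance_bins()] tibble.
#' @return A `chic_null_model`.
#' @export
null_model_from_truth <- function(distance_fit, dispersion_r, bait_bias,
                                  other_end_bias, lambda = 0,
                                  binning = distance_bins()) {
  structure(list(
    distance_fit = distance_fit,
    all_fits = list(),
    bin_estimates = NULL,
    dispersion_r = dispersion_r,
    bait_bias = bait_bias,
    other_end_pools = tibble::tibble(fragment_id = other_end_bias$fragment_id,
                                     pool = seq_len(nrow(other_end_bias))),
    pool_bias = tibble::tibble(pool = seq_len(nrow(other_end_bias)),
                               mean_bias = other_end_bias$bias,
                               biases = as.list(other_end_bias$bias)),
    unestimable_baits = integer(),
    mean_scale = 1,
    lambda_pools = tibble::tibble(pool = 1L, lambda = lambda,
                                  n_baits = NA_integer_),
    bait_lambda_pool = tibble::tibble(fragment_id = bait_bias$fragment_id,
                                      pool = 1L),
    mean_trans_pairs_per_bait = NA_real_,
    binning = binning
  ), class = "chic_null_model")
}
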