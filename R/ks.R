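#' Discrete Kolmogorov-Smirnov statistic
#'
#' \eqn{D = \max_k |\hat F_n(k) - F(k)|} over the integer atoms of the
#' observed sample and the model support (the discrete convention: both
#' CDFs are compared at the atoms, not between them).
#'
#' @param observed_counts Non-negative integer sample.
#' @param model_cdf Either a function mapping counts to cumulative
#'   probabilities, or a two-column data frame (`count`, `cdf`) defining a
#'   right-continuous step CDF.
#' @return D statistic in `[0, 1]`.
#' @export
ks_statistic_discrete <- function(observed_counts, model_cdf) {
  if (length(observed_counts) == 0) stop("empty observation set", call. = FALSE)
  if (is.data.frame(model_cdf)) {
    tab <- model_cdf[order(model_cdf$count), ]
    stopifnot(!is.unsorted(tab$cdf), max(tab$cdf) <= 1 + 1e-12)
    atoms <- sort(unique(c(observed_counts, tab$count)))
    F_model <- stats::approx(tab$count, tab$cdf, xout = atoms,
                             method = "constant", rule = 2, f = 0,
                             yleft = 0)$y
  } else {
    atoms <- sort(unique(observed_counts))
    F_model <- model_cdf(atoms)
  }
  F_emp <- stats::ecdf(observed_counts)(atoms)
  max(abs(F_emp - F_model))
}

# reference pool as an O(1)-lookup integer CDF over 0..M
pool_cdf <- function(pool) {
  m <- max(pool, 1L)
  list(cdf = cumsum(tabulate(pool + 1L, nbins = m + 1L)) / length(pool),
       m = m)
}

# exact sup-distance over all integer atoms between the ECDF of sample
# `x` and a reference pool ECDF. Both CDFs are integer step functions,
# so the sup is attained at a sample atom, at the end of a plateau
# between consecutive sample atoms, or below the first atom.
d_stat_vs_pool <- function(x, pool) {
  pc <- if (is.list(pool)) pool else pool_cdf(pool)
  lookup <- function(t) ifelse(t < 0, 0, pc$cdf[pmin(t, pc$m) + 1])
  xs <- sort(unique(x))
  f_emp <- cumsum(tabulate(match(x, xs), nbins = length(xs))) / length(x)
  f_pool_at <- lookup(xs)
  f_pool_end <- c(lookup(xs[-1] - 1), 1)
  max(abs(f_emp - f_pool_at),
      abs(f_emp - f_pool_end),
      lookup(xs[1] - 1))
}

# draw `n` counts from the bin-wise null: d ~ U(lower, upper),
# s1, s2 ~ empirical bias distributions, X ~ NB(s1 s2 f(d), r)
draw_bin_null <- function(n, model, lower, upper,
                          bait_biases = model$bait_bias$bias,
                          pool_all = unlist(model$pool_bias$biases)) {
  d <- stats::runif(n, lower, upper)
  s1 <- sample(bait_biases, n, replace = TRUE)
  s2 <- sample(pool_all, n, replace = TRUE)
  scale <- if (is.null(model$mean_scale)) 1 else model$mean_scale
  mu <- scale * s1 * s2 * eval_distance_fit(model$distance_fit, d)
  stats::rnbinom(n, size = model$dispersion_r, mu = mu)
}

#' Monte-Carlo KS goodness-of-fit test for one distance bin
#'
#' Tests whether the observed counts in a distance bin are consistent
#' with the background \eqn{X \sim \mathrm{NB}(s_1 s_2 f(d), r)} with
#' \eqn{d \sim U(d_b - w/2, d_b + w/2)} and biases drawn from their
#' estimated empirical distributions. The model CDF is the pooled
#' empirical CDF of an independent simulation pool; `n_sim` simulated
#' replicates of `n_pairs` draws give the null distribution of D, and
#' \eqn{p = (1 + \#\{D_\mathrm{sim} \ge D_\mathrm{obs}\}) / (1 +
#' n_\mathrm{sim})} (the standard Monte-Carlo estimator, so p can never
#' fall below \eqn{1/(n_\mathrm{sim}+1)}).
#'
#' @param bin_pairs Interaction tibble slice for the bin (all observed
#'   pairs are used for \eqn{D_\mathrm{obs}}).
#' @param model A `chic_null_model`.
#' @param bin Bin index into `binning`.
#' @param binning A [distance_bins()] tibble.
#' @param n_sim Simulated replicates (default 5000).
#' @param n_pairs Pairs per simulated replicate (default 5000).
#' @param seed RNG seed.
#' @return One-row tibble: `bin`, `label`, `d_statistic`, `mc_p`,
#'   `n_sim`, `n_pairs_per_sim`, `n_observed`.
#' @export
ks_monte_carlo <- function(bin_pairs, model, bin, binning = distance_bins(),
                           n_sim = 5000, n_pairs = 5000, seed = 1) {
  if (nrow(bin_pairs) == 0) stop("no observed pairs in bin", call. = FALSE)
  if (n_sim < 100) warning("n_sim < 100: Monte-Carlo p-value floor is ",
                           signif(1 / (n_sim + 1), 3), call. = FALSE)
  lower <- binning$lower[bin]; upper <- binning$upper[bin]
  bb <- model$bait_bias$bias
  pa <- unlist(model$pool_bias$biases)
  with_seed(seed + bin, {
    # two independent pools: pool 2 furnishes the model CDF, pool 1 the
    # null distribution of D (sample-splitting, avoids self-comparison)
    pool2 <- pool_cdf(draw_bin_null(n_sim * n_pairs, model, lower, upper,
                                    bb, pa))
    d_sim <- numeric(n_sim)
    for (i in seq_len(n_sim)) {
      d_sim[i] <- d_stat_vs_pool(draw_bin_null(n_pairs, model, lower, upper,
                                               bb, pa),
                                 pool2)
    }
    d_obs <- d_stat_vs_pool(bin_pairs$count, pool2)
    tibble::tibble(
      bin = bin, label = binning$label[bin], d_statistic = d_obs,
      mc_p = (1 + sum(d_sim >= d_obs)) / (1 + n_sim),
      n_sim = as.integer(n_sim), n_pairs_per_sim = as.integer(n_pairs),
      n_observed = nrow(bin_pairs))
  })
}

#' Bin-wise Bonferroni correction for the KS battery
#'
#' Flags each bin significant iff its Monte-Carlo p-value is below
#' `alpha` divided by the number of bins tested.
#'
#' @param results Row-bound [ks_monte_carlo()] results.
#' @param alpha Family-wise level (default 0.05).
#' @return `results` with `significant_after_bonferroni` added.
#' @export
bonferroni_ks <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) stop("no KS results", call. = FALSE)
  results |>
    dplyr::mutate(significant_after_bonferroni =
                    .data$mc_p < alpha / nrow(results))
}

#' Technical-noise trend diagnostic
#'
#' The estimation pools are ordered by increasing marginal counts, so
#' under a well-behaved library the per-pool \eqn{\lambda} distributions'
#' medians and variances should both trend upwards from left to right.
#' Reports per-pool summaries and a flag that is `TRUE` iff both the
#' medians and the variances are non-decreasing (ties allowed).
#'
#' @param lambda_values Tibble with `pool` (ordered strata) and `value`
#'   (per-unit \eqn{\lambda} estimates within the pool).
#' @return List with `summaries` (per-pool median, quartiles, variance,
#'   n) and `trend_ok`.
#' @export
lambda_trend_diagnostic <- function(lambda_values) {
  stopifnot(dplyr::n_distinct(lambda_values$pool) >= 2)
  s <- lambda_values |>
    dplyr::group_by(pool = .data$pool) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      q1 = stats::quantile(.data$value, 0.25, names = FALSE),
      q3 = stats::quantile(.data$value, 0.75, names = FALSE),
      variance = if (dplyr::n() > 1) stats::var(.data$value) else 0,
      n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$pool)
  nondec <- function(x) all(diff(x) >= -1e-12)
  list(summaries = s, trend_ok = nondec(s$median) && nondec(s$variance))
}
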