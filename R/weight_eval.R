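#' Lack-of-monotonicity statistic
#'
#' \eqn{\mathrm{LOM}(v_1, \ldots, v_n) = 1 - |v_n - v_1| /
#' \sum_{i} |v_{i+1} - v_i|}: 0 for any monotone (non-strictly) sequence,
#' approaching 1 for maximally oscillating ones. A constant sequence is
#' monotone by convention (returned as 0 with a warning, since the
#' denominator vanishes).
#'
#' @param v Ordered numeric sequence, length >= 2.
#' @return LOM in `[0, 1]`.
#' @examples
#' lack_of_monotonicity(c(1, 3, 2)) # 2/3
#' @export
lack_of_monotonicity <- function(v) {
  stopifnot(length(v) >= 2)
  denom <- sum(abs(diff(v)))
  if (denom == 0) {
    warning("constant sequence: LOM defined as 0 by convention", call. = FALSE)
    return(0)
  }
  1 - abs(v[length(v)] - v[1]) / denom
}

#' Weight-curve fit RSS with zero-bin accounting
#'
#' Residual sum of squares of a fitted weight curve against the observed
#' per-bin priors, computed on the probability scale over bins with
#' observed interactions only. Bins with none are excluded — the model
#' would put an infinite log prior there — but their count is reported,
#' because every excluded bin deflates the RSS while marking a failure of
#' the fitted form to represent the data.
#'
#' @param curve A `chic_weight_curve` (or params vector).
#' @param observed_prior Tibble with `center`, `prior`, `empty` (see
#'   [observed_prior()]).
#' @return List with `rss` and `n_zero_bins`.
#' @export
weight_fit_rss <- function(curve, observed_prior) {
  use <- observed_prior |> dplyr::filter(!.data$empty)
  if (nrow(use) == 0) stop("all bins empty: RSS undefined", call. = FALSE)
  pred <- eval_weight_curve(curve, use$center)
  list(rss = sum((use$prior - pred)^2),
       n_zero_bins = sum(observed_prior$empty))
}

#' Re-estimate weights and compare calling outcomes
#'
#' Audits how much the choice of weight parameters matters: fits the
#' weight curve to the observed priors at each candidate robustness
#' cutoff (-10 and, when it exists, the \eqn{\rho^*} solving
#' \eqn{g(\rho) = 0.05}), keeps the lower-RSS fit, rescores every
#' replicate with it, and reports the Jaccard concordance of significant
#' sets (default vs re-estimated weights) together with the change in
#' score correlation, percent reversible, FDR at the NST, and FNR
#' (all deltas are custom minus default).
#'
#' @param replicate_interactions List of interaction tibbles.
#' @param model A `chic_null_model`.
#' @param default_weights The weights used for the default scoring
#'   (`chic_weight_curve`, params vector, or `NULL` for unit weights).
#' @param binning A [distance_bins()] tibble.
#' @param threshold Score threshold (default 5).
#' @param rho Primary robustness cutoff (default -10).
#' @return List with `lom`, `rss`, `n_zero_bins`, `rho_used`,
#'   `custom_curve`, `reweight_jaccard`, `delta_stats` (tibble), and the
#'   per-setting statistics.
#' @export
reweight_and_compare <- function(replicate_interactions, model,
                                 default_weights = NULL,
                                 binning = distance_bins(),
                                 threshold = 5, rho = -10) {
  score_all <- function(w) {
    purrr::map(replicate_interactions, compute_scores, model = model,
               weights = w)
  }
  scored_default <- score_all(default_weights)

  rho_star <- solve_rho(scored_default[[1]], 0.05, threshold)
  candidates <- if (is.na(rho_star)) rho else unique(c(rho, rho_star))
  if (is.na(rho_star)) {
    message("rho* solving g(rho) = 0.05 absent; proceeding with rho = ", rho)
  }

  fits <- purrr::map(candidates, function(rc) {
    op <- observed_prior(scored_default, rho = rc, binning = binning)
    curve <- tryCatch(fit_weight_curve(op, binning), error = function(e) NULL)
    list(rho = rc, prior = op, curve = curve)
  })
  fits <- purrr::keep(fits, ~ !is.null(.x$curve))
  if (length(fits) == 0) {
    stop("weight curve could not be fitted at any candidate rho", call. = FALSE)
  }
  best <- fits[[which.min(purrr::map_dbl(fits, ~ .x$curve$rss))]]

  nonempty <- best$prior |> dplyr::filter(!.data$empty)
  lom <- if (nrow(nonempty) >= 2) lack_of_monotonicity(nonempty$prior)
         else NA_real_
  rssinfo <- weight_fit_rss(best$curve, best$prior)

  scored_custom <- score_all(best$curve)
  sig_sets <- function(scored) {
    purrr::map(scored, function(df) {
      df <- df |> dplyr::filter(.data$score > threshold)
      paste(pmin(df$bait_id, df$other_id), pmax(df$bait_id, df$other_id))
    })
  }
  sd_ <- sig_sets(scored_default); sc_ <- sig_sets(scored_custom)
  all_d <- unique(unlist(sd_)); all_c <- unique(unlist(sc_))
  reweight_jaccard <- if (length(all_d) == 0 && length(all_c) == 0)
    NA_real_ else jaccard(all_d, all_c)

  stats_for <- function(scored) {
    sym <- suppressWarnings(score_symmetry(scored[[1]]))
    multi <- length(scored) >= 2
    tibble::tibble(
      score_correlation = sym$correlation,
      percent_reversible = suppressWarnings(
        percent_reversible(scored[[1]], threshold)),
      fdr_at_nst = if (multi) {
        s <- sig_sets(scored)
        if (all(lengths(s) == 0)) NA_real_ else 1 - jaccard(s)
      } else NA_real_,
      fnr = tryCatch(fnr_g(scored[[1]], rho, threshold),
                     error = function(e) NA_real_))
  }
  st_d <- stats_for(scored_default)
  st_c <- stats_for(scored_custom)
  delta <- tibble::tibble(
    statistic = names(st_d),
    default = unlist(st_d), custom = unlist(st_c),
    delta = unlist(st_c) - unlist(st_d))

  list(lom = lom, rss = rssinfo$rss, n_zero_bins = rssinfo$n_zero_bins,
       rho_used = best$rho, rho_star = rho_star, custom_curve = best$curve,
       observed_prior = best$prior,
       reweight_jaccard = reweight_jaccard, delta_stats = delta,
       scored_default = scored_default, scored_custom = scored_custom)
}
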