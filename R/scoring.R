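#' Score interactions against the background model
#'
#' For each directed pair the upper-tail log p-value of the observed count
#' is computed under the Delaporte null with mean
#' \eqn{\mu = s_\mathrm{bait} \cdot s_\mathrm{other} \cdot f(d)},
#' dispersion `r` and the bait's pool \eqn{\lambda}; the score is the
#' weighted, soft-thresholded evidence
#' \eqn{\mathrm{score} = \max(0, -\log p + \log w(d))}
#' with \eqn{w(d)} the prior-probability weight. Thresholding the score at
#' \eqn{\alpha} therefore demands evidence beyond that of a proximal pair
#' with p-value \eqn{e^{-\alpha}}.
#'
#' Bait-bait pairs are emitted in both directions. In the default
#' (asymmetric) mode the bait-role fragment uses its *fixed* bait bias
#' while the other-role fragment is represented by its pool's expected
#' bias — the structural asymmetry that makes \eqn{score_{ij} \ne
#' score_{ji}}. With `symmetrized = TRUE` both roles use fixed bait
#' biases and the two directions agree exactly.
#'
#' @param pairs Interaction tibble (`bait_id`, `other_id`, `count`,
#'   `distance_bp`); trans rows (`NA` distance) are not scored.
#' @param model A `chic_null_model`.
#' @param weights A `chic_weight_curve`, or a numeric
#'   `c(lower, upper, midpoint, slope)`; `NULL` gives unit weights
#'   (\eqn{w \equiv 1}, pure p-value scoring).
#' @param symmetrized Use fixed biases for both roles of bait-bait pairs.
#' @return Tibble of class `chic_scored`: `bait_id`, `other_id`,
#'   `distance_bp`, `count`, `mu`, `log_p`, `weight`, `score`,
#'   `bait_bait`. Pairs whose bias is unestimable are dropped (count
#'   reported via a message).
#' @export
compute_scores <- function(pairs, model, weights = NULL, symmetrized = FALSE) {
  up <- attr(model$binning, "upper_bp")
  cis <- pairs |>
    dplyr::filter(!is.na(.data$distance_bp), .data$distance_bp > 0) |>
    dplyr::select("bait_id", "other_id", "count", "distance_bp")

  bait_set <- model$bait_bias$fragment_id
  bb <- cis |> dplyr::filter(.data$other_id %in% bait_set)
  # emit the reverse direction for bait-bait pairs not already present
  have <- paste(cis$bait_id, cis$other_id)
  rev_bb <- tibble::tibble(bait_id = bb$other_id, other_id = bb$bait_id,
                           count = bb$count, distance_bp = bb$distance_bp) |>
    dplyr::filter(!paste(.data$bait_id, .data$other_id) %in% have)
  dat <- dplyr::bind_rows(cis, rev_bb) |>
    dplyr::mutate(bait_bait = .data$other_id %in% bait_set)

  dat <- dat |>
    dplyr::left_join(model$bait_bias |>
                       dplyr::select("fragment_id", s_bait = "bias"),
                     by = c(bait_id = "fragment_id")) |>
    dplyr::left_join(model$other_end_pools, by = c(other_id = "fragment_id")) |>
    dplyr::left_join(model$pool_bias |>
                       dplyr::select("pool", s_pool = "mean_bias"),
                     by = "pool") |>
    dplyr::left_join(model$bait_bias |>
                       dplyr::select("fragment_id", s_other_fixed = "bias"),
                     by = c(other_id = "fragment_id")) |>
    dplyr::left_join(model$bait_lambda_pool |>
                       dplyr::rename(lpool = "pool"),
                     by = c(bait_id = "fragment_id")) |>
    dplyr::left_join(model$lambda_pools |>
                       dplyr::select(lpool = "pool", "lambda"),
                     by = "lpool")
  dat$lambda[is.na(dat$lambda)] <- 0
  if (symmetrized) {
    # direction-invariant noise for bait-bait pairs: pair-mean lambda
    lam_of <- stats::setNames(dat$lambda, paste(dat$bait_id, dat$other_id))
    rev_lam <- unname(lam_of[paste(dat$other_id, dat$bait_id)])
    bbrow <- dat$bait_bait & !is.na(rev_lam)
    dat$lambda[bbrow] <- (dat$lambda[bbrow] + rev_lam[bbrow]) / 2
  }
  dat <- dat |>
    dplyr::mutate(s_other = dplyr::case_when(
      symmetrized & .data$bait_bait ~ .data$s_other_fixed,
      !is.na(.data$s_pool) ~ .data$s_pool,
      .data$bait_bait ~ .data$s_other_fixed,
      TRUE ~ NA_real_
    ))

  dropped <- sum(is.na(dat$s_bait) | is.na(dat$s_other))
  if (dropped > 0) {
    message(dropped, " pair(s) dropped: unestimable fragment bias")
    dat <- dat |> dplyr::filter(!is.na(.data$s_bait), !is.na(.data$s_other))
  }

  scale <- if (is.null(model$mean_scale)) 1 else model$mean_scale
  mu <- scale * dat$s_bait * dat$s_other *
    eval_distance_fit(model$distance_fit, dat$distance_bp)
  log_p <- upper_tail_log_p(dat$count, mu, model$dispersion_r, dat$lambda)
  w <- if (is.null(weights)) rep(1, nrow(dat)) else
    pmin(1, pmax(eval_weight_curve(weights, dat$distance_bp), 0))
  score <- pmax(0, -log_p + log(w))

  out <- dat |>
    dplyr::transmute(.data$bait_id, .data$other_id, .data$distance_bp,
                     .data$count, mu = mu, log_p = log_p, weight = w,
                     score = score, .data$bait_bait)
  class(out) <- c("chic_scored", class(out))
  out
}
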