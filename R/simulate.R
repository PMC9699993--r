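#' Generate a synthetic restriction-fragment map
#'
#' Tiles one synthetic chromosome (`chrS`) with contiguous fragments whose
#' lengths are gamma-distributed around `mean_len_bp` (default 4000 bp,
#' HindIII-like), plus a decoy chromosome (`chrD`) that furnishes
#' trans-chromosomal pairs for technical-noise estimation. A deterministic,
#' evenly spaced subset of the `chrS` fragments is designated baits.
#'
#' @param n_fragments Number of fragments on the main chromosome (>= 10).
#' @param mean_len_bp Mean fragment length in bp.
#' @param bait_fraction Fraction of main-chromosome fragments that are
#'   baits; must yield at least one bait.
#' @param seed RNG seed (results are identical for identical seeds).
#' @param n_decoy_fragments Fragments on the decoy chromosome (no baits).
#' @return A `chic_fragment_map`.
#' @export
generate_fragment_map <- function(n_fragments, mean_len_bp = 4000,
                                  bait_fraction = 0.1, seed = 1,
                                  n_decoy_fragments = max(10L, n_fragments %/% 2L)) {
  stopifnot(n_fragments >= 10, mean_len_bp > 0,
            bait_fraction > 0, bait_fraction < 1)
  n_baits <- floor(n_fragments * bait_fraction)
  if (n_baits < 1) {
    stop("bait_fraction ", bait_fraction, " yields 0 baits for ",
         n_fragments, " fragments", call. = FALSE)
  }
  with_seed(seed, {
    frag_chr <- function(chrom, n, id0) {
      # shape 4 gamma: realistic spread of restriction-fragment lengths
      len <- pmax(150, round(stats::rgamma(n, shape = 4,
                                           scale = mean_len_bp / 4)))
      end <- cumsum(len)
      tibble::tibble(chrom = chrom, start = c(1, end[-n] + 1), end = end,
                     fragment_id = id0 + seq_len(n))
    }
    main <- frag_chr("chrS", n_fragments, 0L)
    decoy <- frag_chr("chrD", n_decoy_fragments, n_fragments)
    bait_ids <- main$fragment_id[round(seq(1, n_fragments,
                                           length.out = n_baits))]
    fragments <- dplyr::bind_rows(main, decoy) |>
      dplyr::mutate(midpoint = (.data$start + .data$end) / 2,
                    is_bait = .data$fragment_id %in% bait_ids,
                    bait_name = ifelse(.data$is_bait,
                                       paste0("bait_", .data$fragment_id),
                                       NA_character_))
    structure(list(fragments = fragments, bait_ids = sort(bait_ids)),
              class = "chic_fragment_map")
  })
}

#' Ground-truth background model for simulation
#'
#' Builds a fully specified `chic_null_model` with known parameters:
#' a theoretical decay \eqn{f(d) = e^{c_0}/d}, global dispersion `r`,
#' log-normal fragment biases (baits sdlog 0.25, other ends sdlog 0.5,
#' both geometric-mean 1 by construction of the log-normal on the log
#' scale after centring), and per-bait technical-noise pools with
#' \eqn{\lambda} increasing across strata (brighter baits carry more
#' technical noise, as in real capture libraries).
#'
#' @param map A `chic_fragment_map`.
#' @param c0 Log-intercept of the theoretical decay (default `log(5e6)`,
#'   giving ~500 expected background reads at 10 kb and ~3 at 1.5 Mb).
#' @param dispersion_r Negative binomial dispersion (default 2).
#' @param bait_bias_sdlog,other_bias_sdlog Log-normal sdlog for bait and
#'   other-end biases.
#' @param lambda_range Range of per-pool technical-noise means, assigned
#'   to `n_lambda_pools` bait strata in increasing order.
#' @param n_lambda_pools Number of \eqn{\lambda} strata.
#' @param seed RNG seed for the bias draws.
#' @return A `chic_null_model` whose `pool_bias` holds each fragment's
#'   own true bias.
#' @export
truth_model <- function(map, c0 = log(5e6), dispersion_r = 2,
                        bait_bias_sdlog = 0.25, other_bias_sdlog = 0.5,
                        lambda_range = c(0.001, 0.01), n_lambda_pools = 5,
                        seed = 1) {
  fr <- map$fragments
  with_seed(seed + 1L, {
    bait_bias <- tibble::tibble(
      fragment_id = map$bait_ids,
      bias = stats::rlnorm(length(map$bait_ids), 0, bait_bias_sdlog))
    bait_bias$bias <- bait_bias$bias / geo_mean(bait_bias$bias)
    other_bias <- tibble::tibble(
      fragment_id = fr$fragment_id,
      bias = stats::rlnorm(nrow(fr), 0, other_bias_sdlog))
    other_bias$bias <- other_bias$bias / geo_mean(other_bias$bias)
    fit <- new_distance_fit("theoretical", c(c0 = c0), rss = 0)
    fit$curvature_K <- 0
    model <- null_model_from_truth(fit, dispersion_r, bait_bias, other_bias)
    k <- min(n_lambda_pools, length(map$bait_ids))
    model$lambda_pools <- tibble::tibble(
      pool = seq_len(k),
      lambda = seq(lambda_range[1], lambda_range[2], length.out = k),
      n_baits = NA_integer_)
    model$bait_lambda_pool <- tibble::tibble(
      fragment_id = map$bait_ids,
      pool = as.integer(dplyr::ntile(rank(bait_bias$bias,
                                          ties.method = "first"), k)))
    model
  })
}

#' Spike a set of true interactions
#'
#' Each cis bait/other-end pair within `max_dist_bp` is declared a true
#' interaction independently with probability given by the logistic prior
#' curve at its distance; true pairs receive an effect multiplier drawn
#' uniformly from `effect_range`. Bait-bait pairs are sampled once as
#' undirected pairs (`bait_id < other_id`).
#'
#' @param map A `chic_fragment_map`.
#' @param prior_params Logistic prior `c(lower, upper, midpoint, slope)`
#'   (see [eval_weight_curve()]); must be monotone non-increasing into
#'   `[0, 1]`.
#' @param effect_range Multiplier range for true pairs (default
#'   `c(3, 10)`).
#' @param seed RNG seed.
#' @param max_dist_bp Maximum cis distance considered.
#' @return A `chic_truth`: list with `true_pairs` (tibble `bait_id`,
#'   `other_id`, `distance_bp`, `multiplier`), `prior_params`,
#'   `effect_range`, `seed`.
#' @export
sample_truth <- function(map, prior_params = c(0.0005, 0.03, 12, 2),
                         effect_range = c(3, 10), seed = 1,
                         max_dist_bp = 1.5e6) {
  stopifnot(prior_params[1] >= 0, prior_params[2] <= 1,
            prior_params[1] <= prior_params[2], prior_params[4] >= 0)
  pairs <- cis_pair_grid(map, max_dist_bp)
  with_seed(seed + 2L, {
    pr <- eval_weight_curve(prior_params, pairs$distance_bp)
    is_true <- stats::runif(nrow(pairs)) < pr
    true_pairs <- pairs[is_true, ] |>
      dplyr::mutate(multiplier = stats::runif(sum(is_true), effect_range[1],
                                              effect_range[2]))
    structure(list(true_pairs = true_pairs, prior_params = prior_params,
                   effect_range = effect_range, seed = seed),
              class = "chic_truth")
  })
}

# all tested cis pairs: bait x same-chrom fragment within range;
# bait-bait pairs appear once, keyed bait_id < other_id
cis_pair_grid <- function(map, max_dist_bp = 1.5e6) {
  fr <- map$fragments
  baits <- fr |> dplyr::filter(.data$is_bait)
  out <- purrr::map_dfr(seq_len(nrow(baits)), function(b) {
    same <- fr |>
      dplyr::filter(.data$chrom == baits$chrom[b],
                    .data$fragment_id != baits$fragment_id[b])
    d <- abs(same$midpoint - baits$midpoint[b])
    keep <- d > 0 & d <= max_dist_bp
    tibble::tibble(bait_id = baits$fragment_id[b],
                   other_id = same$fragment_id[keep],
                   distance_bp = d[keep])
  })
  out |>
    dplyr::filter(!(.data$other_id %in% map$bait_ids &
                      .data$other_id < .data$bait_id))
}

#' Simulate replicate count tables
#'
#' For each replicate and tested cis pair, draws
#' \eqn{X \sim \mathrm{NB}(m \cdot s_i s_j f(d),\, r) +
#' \mathrm{Pois}(\lambda_\mathrm{pool})} where the multiplier `m` exceeds
#' 1 only for pairs in the truth set; trans pairs (bait x decoy-chromosome
#' fragment) are pure Poisson noise. Replicates share the truth set and
#' model but use independent noise streams derived from `seed`.
#'
#' @param map A `chic_fragment_map`.
#' @param model A ground-truth `chic_null_model` (see [truth_model()]).
#' @param truth A `chic_truth` from [sample_truth()], or `NULL` for pure
#'   background.
#' @param n_replicates Number of replicates.
#' @param seed RNG seed.
#' @param max_dist_bp Maximum cis distance simulated.
#' @return List of interaction tibbles (`bait_id`, `other_id`, `count`,
#'   `distance_bp`; trans rows have `NA` distance and only non-zero
#'   counts are kept), one per replicate, each with attribute
#'   `replicate_id`.
#' @export
simulate_counts <- function(map, model, truth = NULL, n_replicates = 2,
                            seed = 1, max_dist_bp = 1.5e6) {
  pairs <- cis_pair_grid(map, max_dist_bp)
  # per-fragment truth biases: other_end_pools maps fragment -> own pool
  oe <- model$other_end_pools |>
    dplyr::left_join(model$pool_bias |>
                       dplyr::select("pool", bias = "mean_bias"), by = "pool")
  s_all <- stats::setNames(oe$bias, oe$fragment_id)
  s_bait <- stats::setNames(model$bait_bias$bias, model$bait_bias$fragment_id)
  lam_pool <- stats::setNames(model$lambda_pools$lambda, model$lambda_pools$pool)
  bait_lam <- stats::setNames(
    lam_pool[as.character(model$bait_lambda_pool$pool)],
    model$bait_lambda_pool$fragment_id)

  mult <- rep(1, nrow(pairs))
  if (!is.null(truth) && nrow(truth$true_pairs) > 0) {
    key <- paste(pairs$bait_id, pairs$other_id)
    tkey <- paste(truth$true_pairs$bait_id, truth$true_pairs$other_id)
    hit <- match(key, tkey)
    mult[!is.na(hit)] <- truth$true_pairs$multiplier[hit[!is.na(hit)]]
  }
  mu <- mult * s_bait[as.character(pairs$bait_id)] *
    s_all[as.character(pairs$other_id)] *
    eval_distance_fit(model$distance_fit, pairs$distance_bp)
  lam <- unname(bait_lam[as.character(pairs$bait_id)])
  lam[is.na(lam)] <- 0

  fr <- map$fragments
  baits <- fr |> dplyr::filter(.data$is_bait)
  trans_grid <- purrr::map_dfr(seq_len(nrow(baits)), function(b) {
    other <- fr$fragment_id[fr$chrom != baits$chrom[b]]
    tibble::tibble(bait_id = baits$fragment_id[b], other_id = other)
  })
  trans_lam <- unname(bait_lam[as.character(trans_grid$bait_id)])
  trans_lam[is.na(trans_lam)] <- 0

  purrr::map(seq_len(n_replicates), function(rep_i) {
    with_seed(seed + 1000L * rep_i, {
      cis_counts <- stats::rnbinom(nrow(pairs), size = model$dispersion_r,
                                   mu = mu) +
        stats::rpois(nrow(pairs), lam)
      tcounts <- stats::rpois(nrow(trans_grid), trans_lam)
      out <- dplyr::bind_rows(
        pairs |> dplyr::mutate(count = cis_counts) |>
          dplyr::select("bait_id", "other_id", "count", "distance_bp"),
        trans_grid[tcounts > 0, ] |>
          dplyr::mutate(count = tcounts[tcounts > 0],
                        distance_bp = NA_real_))
      attr(out, "replicate_id") <- paste0("rep", rep_i)
      out
    })
  })
}

#' Apply copy-number and translocation perturbations
#'
#' Emulates the count distortions of an aberrant genome. Pairs with an
#' anchor midpoint inside a CNV region have their counts rescaled by the
#' region multiplier — binomial thinning for multipliers below 1,
#' Poisson top-up for multipliers above 1 — preserving integer counts with
#' mean scaled by the multiplier. A breakpoint `c(pos1, pos2)` fuses the
#' two loci: pairs whose anchors flank both positions are resampled from
#' the background model at the shortened effective distance
#' `d - (pos2 - pos1)` while keeping their apparent distance, mimicking a
#' deletion/translocation that brings distal loci into contact.
#'
#' @param map A `chic_fragment_map`.
#' @param counts One interaction tibble (a [simulate_counts()] element).
#' @param cnv_regions Tibble with `start`, `end`, `multiplier` (and
#'   optionally `chrom`, default `chrS`); regions must not overlap.
#' @param breakpoint Optional numeric `c(pos1, pos2)` on `chrS`.
#' @param model Ground-truth `chic_null_model` (needed to resample fused
#'   pairs).
#' @param seed RNG seed.
#' @return Perturbed interaction tibble, same shape as `counts`.
#' @export
apply_perturbations <- function(map, counts, cnv_regions = NULL,
                                breakpoint = NULL, model = NULL, seed = 1) {
  out <- counts
  fr <- map$fragments
  mid <- stats::setNames(fr$midpoint, fr$fragment_id)
  m1 <- unname(mid[as.character(out$bait_id)])
  m2 <- unname(mid[as.character(out$other_id)])
  with_seed(seed + 3L, {
    if (!is.null(cnv_regions) && nrow(cnv_regions) > 0) {
      stopifnot(all(cnv_regions$multiplier > 0))
      reg <- cnv_regions |> dplyr::arrange(.data$start)
      if (nrow(reg) > 1 && any(reg$start[-1] <= reg$end[-nrow(reg)])) {
        stop("CNV regions overlap", call. = FALSE)
      }
      for (k in seq_len(nrow(reg))) {
        hit <- (m1 >= reg$start[k] & m1 <= reg$end[k]) |
          (m2 >= reg$start[k] & m2 <= reg$end[k])
        m <- reg$multiplier[k]
        if (m == 1 || !any(hit)) next
        x <- out$count[hit]
        out$count[hit] <- if (m < 1) {
          stats::rbinom(length(x), x, m)
        } else {
          x + stats::rpois(length(x), x * (m - 1))
        }
      }
    }
    if (!is.null(breakpoint)) {
      stopifnot(length(breakpoint) == 2, !is.null(model))
      p1 <- min(breakpoint); p2 <- max(breakpoint)
      lo <- pmin(m1, m2); hi <- pmax(m1, m2)
      span <- !is.na(out$distance_bp) & lo <= p1 & hi >= p2
      if (any(span)) {
        d_eff <- pmax(out$distance_bp[span] - (p2 - p1), 150)
        oe <- model$other_end_pools |>
          dplyr::left_join(model$pool_bias |>
                             dplyr::select("pool", bias = "mean_bias"),
                           by = "pool")
        s_all <- stats::setNames(oe$bias, oe$fragment_id)
        s_bait <- stats::setNames(model$bait_bias$bias,
                                  model$bait_bias$fragment_id)
        mu <- unname(s_bait[as.character(out$bait_id[span])]) *
          unname(s_all[as.character(out$other_id[span])]) *
          eval_distance_fit(model$distance_fit, d_eff)
        out$count[span] <- stats::rnbinom(sum(span),
                                          size = model$dispersion_r, mu = mu)
      }
    }
  })
  out
}
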