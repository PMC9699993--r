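#' Jaccard index of finite sets
#'
#' \eqn{J(A_1, \ldots, A_K) = |\cap_k A_k| / |\cup_k A_k|}.
#'
#' @param ... Two or more vectors treated as sets, or a single list of
#'   them.
#' @return Jaccard index in `[0, 1]`; error when all sets are empty.
#' @examples
#' jaccard(c(1, 2, 3), c(2, 3, 4))
#' @export
jaccard <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]])) sets <- sets[[1]]
  stopifnot(length(sets) >= 2)
  u <- unique(unlist(sets))
  if (length(u) == 0) stop("Jaccard undefined: all sets empty", call. = FALSE)
  inter <- purrr::reduce(sets, intersect)
  length(inter) / length(u)
}

# undirected bait-bait pairs with forward/reverse scores attached
bait_bait_directed <- function(scored) {
  bb <- scored |> dplyr::filter(.data$bait_bait)
  if (nrow(bb) == 0) return(bb)
  bb |>
    dplyr::mutate(lo = pmin(.data$bait_id, .data$other_id),
                  hi = pmax(.data$bait_id, .data$other_id),
                  fwd = .data$bait_id == .data$lo) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(
      score_ij = .data$score[.data$fwd][1],
      score_ji = .data$score[!.data$fwd][1],
      distance_bp = .data$distance_bp[1], .groups = "drop") |>
    dplyr::filter(!is.na(.data$score_ij), !is.na(.data$score_ji))
}

#' Score symmetry for bait-bait pairs
#'
#' The caller treats the bait-end bias as fixed and the other-end bias as
#' random, so for a bait-bait pair the two directions of scoring need not
#' agree. Reports the Pearson correlation between \eqn{score_{ij}} and
#' \eqn{score_{ji}} over pairs where at least one direction is non-zero
#' (pairs that are zero in both directions would artificially inflate the
#' correlation) and the five pairs with the largest squared deviation
#' \eqn{(score_{ij} - score_{ji})^2}.
#'
#' @param scored A `chic_scored` tibble containing both directions of the
#'   bait-bait pairs.
#' @return List with `correlation` (`NA` with a warning when fewer than 3
#'   usable pairs), `n_used`, and `top_deviations` (up to 5 rows).
#' @export
score_symmetry <- function(scored) {
  bb <- bait_bait_directed(scored)
  use <- bb |> dplyr::filter(.data$score_ij > 0 | .data$score_ji > 0)
  if (nrow(use) < 3) {
    warning("fewer than 3 bait-bait pairs with a non-zero score; ",
            "correlation not computed", call. = FALSE)
    return(list(correlation = NA_real_, n_used = nrow(use),
                top_deviations = use))
  }
  corr <- if (stats::sd(use$score_ij) == 0 || stats::sd(use$score_ji) == 0)
    NA_real_ else stats::cor(use$score_ij, use$score_ji)
  top <- use |>
    dplyr::mutate(sq_dev = (.data$score_ij - .data$score_ji)^2) |>
    dplyr::arrange(dplyr::desc(.data$sq_dev)) |>
    dplyr::slice_head(n = 5)
  list(correlation = corr, n_used = nrow(use), top_deviations = top)
}

#' Proportion of reversible bait-bait interactions
#'
#' A bait-bait interaction is *reversible* at a threshold when its
#' significance does not depend on the direction of scoring. The summary
#' is the proportion significant in both directions relative to those
#' significant in at least one — the Jaccard index of the two directed
#' significant sets.
#'
#' @param scored A `chic_scored` tibble with both directions present.
#' @param threshold Score threshold (default 5, strict `>`).
#' @return Proportion in `[0, 1]`; `NA` with a warning when no pair is
#'   significant in either direction.
#' @export
percent_reversible <- function(scored, threshold = 5) {
  bb <- bait_bait_directed(scored)
  both <- sum(bb$score_ij > threshold & bb$score_ji > threshold)
  either <- sum(bb$score_ij > threshold | bb$score_ji > threshold)
  if (either == 0) {
    warning("no bait-bait pair significant in either direction; ",
            "percent reversible undefined", call. = FALSE)
    return(NA_real_)
  }
  both / either
}

#' False-negative rate for robust interactions
#'
#' \eqn{g(\rho) = |\{(i,j): score_{ij} < t \wedge \log p_{ij} < \rho\}| /
#' |\{(i,j): \log p_{ij} < \rho\}|}: the fraction of pairs with strong
#' raw evidence (log p below \eqn{\rho}) that nevertheless fail the score
#' threshold. At \eqn{\rho = -10} this is an FNR for reproducible
#' interactions.
#'
#' @param scored A `chic_scored` tibble (or any tibble with `log_p` and
#'   `score`).
#' @param rho Negative log p cutoff defining robust pairs (default -10).
#' @param threshold Score threshold (default 5); scores strictly below
#'   `threshold` count as failures.
#' @return FNR in `[0, 1]`; error when no pair has `log_p < rho`.
#' @export
fnr_g <- function(scored, rho = -10, threshold = 5) {
  robust <- scored$log_p < rho
  if (!any(robust)) {
    stop("no pairs with log p < ", rho, "; g(rho) undefined", call. = FALSE)
  }
  sum(robust & scored$score < threshold) / sum(robust)
}

#' Solve for the robustness cutoff coherent with the score threshold
#'
#' Finds \eqn{\rho^*} with \eqn{g(\rho^*) = } `target` by a grid scan of
#' \eqn{g} over \eqn{\rho \in [-50, -1]} at step 0.1 followed by
#' bisection between the bracketing grid points. Returns `NA` (with a
#' warning) when no crossing exists on the grid.
#'
#' @param scored A `chic_scored` tibble.
#' @param target Target FNR (default 0.05).
#' @param threshold Score threshold (default 5).
#' @param tol Bisection tolerance on \eqn{|g(\rho) - \mathrm{target}|}.
#' @return \eqn{\rho^*} or `NA`.
#' @export
solve_rho <- function(scored, target = 0.05, threshold = 5, tol = 0.005) {
  grid <- seq(-50, -1, by = 0.1)
  g <- vapply(grid, function(r) {
    if (!any(scored$log_p < r)) NA_real_
    else fnr_g(scored, r, threshold)
  }, numeric(1))
  ok <- which(!is.na(g))
  if (length(ok) == 0) {
    warning("no rho in [-50, -1] has robust pairs", call. = FALSE)
    return(NA_real_)
  }
  hit <- ok[abs(g[ok] - target) <= 1e-12]
  if (length(hit) > 0) return(grid[hit[1]])
  sgn <- sign(g[ok] - target)
  flip <- which(diff(sgn) != 0)
  if (length(flip) == 0) {
    warning("g(rho) does not cross ", target, " on the grid", call. = FALSE)
    return(NA_real_)
  }
  lo <- grid[ok[flip[1]]]; hi <- grid[ok[flip[1] + 1]]
  glo <- g[ok[flip[1]]]
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    gm <- fnr_g(scored, mid, threshold)
    if (abs(gm - target) <= tol) return(mid)
    if (sign(gm - target) == sign(glo - target)) { lo <- mid; glo <- gm }
    else hi <- mid
  }
  (lo + hi) / 2
}

#' Replicate-reproducibility FDR proxy
#'
#' Under the assumption that true interactions are significant in all
#' replicates and false ones are not,
#' \eqn{\mathrm{FDR} = 1 - J(A_1, \ldots, A_K)} where \eqn{A_k} is
#' replicate k's significant set.
#'
#' @param significant_sets List (>= 2) of per-replicate significant-pair
#'   identifiers.
#' @return FDR proxy in `[0, 1]`.
#' @export
replicate_fdr <- function(significant_sets) {
  stopifnot(length(significant_sets) >= 2)
  1 - jaccard(significant_sets)
}

#' Bonferroni (FWER) score threshold from the smallest distance bin
#'
#' Thresholding at a score \eqn{\alpha} requires the evidence for an
#' interaction to exceed that of a proximal pair with p-value
#' \eqn{e^{-\alpha}}, so controlling FWER at `alpha` over the
#' \eqn{n} pairs of the smallest distance bin imposes
#' \eqn{-\log(\alpha / n) = \log(n/\alpha)}, strictly increasing in n.
#'
#' @param n_pairs_smallest_bin Number of testable pairs in the first bin.
#' @param alpha Family-wise level (default 0.05).
#' @return Score threshold.
#' @examples
#' fwer_score_threshold(163000) # ~ 15
#' @export
fwer_score_threshold <- function(n_pairs_smallest_bin, alpha = 0.05) {
  if (n_pairs_smallest_bin < 1) stop("need at least one pair", call. = FALSE)
  log(n_pairs_smallest_bin / alpha)
}

#' Integer score threshold achieving a target FNR
#'
#' Scans integer thresholds 0..100 and returns the one whose
#' \eqn{g(\rho)}-based FNR is closest to `target_fnr`, ties broken toward
#' the smaller (more sensitive) threshold.
#'
#' @param scored A `chic_scored` tibble.
#' @param target_fnr Target FNR (default 0.2).
#' @param rho Robustness cutoff (default -10).
#' @param t_max Largest threshold scanned.
#' @return Integer threshold.
#' @export
sst_for_fnr <- function(scored, target_fnr = 0.2, rho = -10, t_max = 100) {
  if (!any(scored$log_p < rho)) {
    stop("no robust pairs (log p < ", rho, ")", call. = FALSE)
  }
  ts <- 0:t_max
  fnr <- vapply(ts, function(t) fnr_g(scored, rho, t), numeric(1))
  ts[which.min(abs(fnr - target_fnr))]  # which.min takes the first = smallest t
}

#' Score threshold minimising the replicate-FDR proxy
#'
#' Minimises \eqn{t \mapsto 1 - J(\{score > t\}_\mathrm{rep})} over
#' \eqn{t \in [0, 10^4]} starting from `init`, using either
#' bound-constrained quasi-Newton (`L-BFGS-B`, forward-difference
#' gradients with step 0.5) or the derivative-free Nelder-Mead simplex.
#' The objective is piecewise constant in t, so the two strategies can
#' land on very different plateaus — that divergence is part of what this
#' audit surfaces. Thresholds where no replicate calls anything get
#' objective 1 (worst). The returned threshold is rounded to the nearest
#' integer and the achieved FDR re-evaluated there.
#'
#' @param replicate_scores List (>= 2) of `chic_scored` tibbles.
#' @param optimiser `"quasi_newton"` or `"simplex"`.
#' @param init Starting threshold (default 5).
#' @return List with `threshold` (integer), `achieved_fdr`, `optimiser`,
#'   `convergence`.
#' @export
sst_minimising_fdr <- function(replicate_scores,
                               optimiser = c("quasi_newton", "simplex"),
                               init = 5) {
  optimiser <- match.arg(optimiser)
  stopifnot(length(replicate_scores) >= 2)
  sig_sets <- function(t) {
    purrr::map(replicate_scores, function(df) {
      df <- df |> dplyr::filter(.data$score > t)
      paste(pmin(df$bait_id, df$other_id), pmax(df$bait_id, df$other_id))
    })
  }
  obj <- function(t) {
    t <- t[1]
    if (t < 0 || t > 1e4) return(1)
    sets <- sig_sets(t)
    if (all(lengths(sets) == 0)) return(1)
    1 - jaccard(sets)
  }
  fit <- if (optimiser == "quasi_newton") {
    stats::optim(init, obj, method = "L-BFGS-B", lower = 0, upper = 1e4,
                 control = list(ndeps = 0.5))
  } else {
    # one-dimensional Nelder-Mead (optim's default method), as used in
    # interactive analyses despite its warning for 1-d problems
    suppressWarnings(stats::optim(init, obj, method = "Nelder-Mead"))
  }
  if (is.null(fit$par) || !is.finite(fit$par)) {
    stop("optimiser failed: ", fit$message, call. = FALSE)
  }
  t_int <- max(0L, as.integer(round(fit$par)))
  list(threshold = t_int, achieved_fdr = obj(t_int), optimiser = optimiser,
       convergence = fit$convergence)
}

#' Assemble the threshold report
#'
#' Computes the full battery of suggested score thresholds (SSTs) and
#' quality statistics around the normal score threshold (NST) of 5:
#' the SST fixing FNR at `target_fnr`, the SSTs minimising the
#' replicate-FDR proxy under each optimiser, the FWER-controlling SST
#' from the smallest distance bin, achieved FDR and FNR at the NST, the
#' robustness cutoff \eqn{\rho^*} solving \eqn{g(\rho) = 0.05}, and
#' significant-interaction counts.
#'
#' @param replicate_scores List of `chic_scored` tibbles (>= 2 for
#'   FDR-based entries; with one replicate those entries are `NA`).
#' @param binning A [distance_bins()] tibble.
#' @param nst Normal score threshold (default 5).
#' @param target_fnr Target FNR for the FNR-based SST.
#' @param rho Robustness cutoff (default -10).
#' @return One-row tibble with the threshold battery.
#' @export
threshold_report <- function(replicate_scores, binning = distance_bins(),
                             nst = 5, target_fnr = 0.2, rho = -10) {
  first <- replicate_scores[[1]]
  n_b0 <- sum(!is.na(first$distance_bp) &
                assign_bins(first$distance_bp, binning) == 1L, na.rm = TRUE)
  sst_fwer <- round(fwer_score_threshold(max(n_b0, 1)))
  multi <- length(replicate_scores) >= 2
  sig_count <- function(t) {
    mean(vapply(replicate_scores,
                function(df) sum(df$score > t), numeric(1)))
  }
  fdr_at <- function(t) {
    if (!multi) return(NA_real_)
    sets <- purrr::map(replicate_scores, function(df) {
      df <- df |> dplyr::filter(.data$score > t)
      paste(pmin(df$bait_id, df$other_id), pmax(df$bait_id, df$other_id))
    })
    if (all(lengths(sets) == 0)) return(NA_real_)
    1 - jaccard(sets)
  }
  qn <- if (multi) sst_minimising_fdr(replicate_scores, "quasi_newton", nst)
        else list(threshold = NA_integer_, achieved_fdr = NA_real_)
  nm <- if (multi) sst_minimising_fdr(replicate_scores, "simplex", nst)
        else list(threshold = NA_integer_, achieved_fdr = NA_real_)
  tibble::tibble(
    nst = nst,
    sst_fnr = sst_for_fnr(first, target_fnr, rho),
    fdr_at_nst = fdr_at(nst),
    sst_fdr_quasi_newton = qn$threshold,
    fdr_at_sst_quasi_newton = qn$achieved_fdr,
    sst_fdr_simplex = nm$threshold,
    fdr_at_sst_simplex = nm$achieved_fdr,
    sst_fwer = sst_fwer,
    n_significant_at_nst = sig_count(nst),
    n_significant_at_sst_fwer = sig_count(sst_fwer),
    fnr_at_nst = fnr_g(first, rho, nst),
    rho_star = solve_rho(first, 0.05, nst),
    n_pairs_smallest_bin = n_b0
  )
}
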