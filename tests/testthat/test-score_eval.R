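test_that("the Jaccard index follows set arithmetic", {
  expect_equal(jaccard(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(jaccard(c(1, 2), c(3, 4)), 0)
  expect_equal(jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard(list(c("a", "b"), c("b", "c"), c("b", "d"))), 1 / 4)
  expect_error(jaccard(integer(0), integer(0)), "empty")
})

test_that("the replicate FDR proxy is one minus the Jaccard index", {
  expect_equal(replicate_fdr(list(c("a", "b", "c"), c("b", "c", "d"))), 0.5)
  expect_equal(replicate_fdr(list(1:3, 1:3, 1:3)), 0)
  expect_equal(replicate_fdr(list(1:2, 3:4)), 1)
  # identity on random set systems
  set.seed(77)
  for (i in 1:100) {
    sets <- purrr::map(1:sample(2:4, 1),
                       ~ sample(letters, sample(1:10, 1)))
    expect_equal(replicate_fdr(sets), 1 - jaccard(sets))
  }
})

test_that("score symmetry correlation matches the product-moment formula", {
  # perfect symmetry
  sym <- score_symmetry(make_bb_scored(c(2, 4, 6), c(2, 4, 6)))
  expect_equal(sym$correlation, 1)
  # hand case: all four pairs kept (each has a non-zero direction)
  sc <- make_bb_scored(c(1, 2, 3, 0), c(2, 4, 6, 5))
  sym <- score_symmetry(sc)
  expect_equal(sym$n_used, 4)
  expect_equal(sym$correlation, cor(c(1, 2, 3, 0), c(2, 4, 6, 5)))
  # top deviations ranked by squared difference
  expect_equal(sym$top_deviations$sq_dev,
               sort((c(1, 2, 3, 0) - c(2, 4, 6, 5))^2, decreasing = TRUE))
  # all-zero pairs excluded; absent with warning
  expect_warning(z <- score_symmetry(make_bb_scored(c(0, 0, 0), c(0, 0, 0))),
                 "correlation not computed")
  expect_true(is.na(z$correlation))
})

test_that("percent reversible is the Jaccard of the two directed significant sets", {
  # directions (6,7), (6,2), (1,0): both {p1}, either {p1, p2} -> 0.5
  expect_equal(percent_reversible(make_bb_scored(c(6, 6, 1), c(7, 2, 0))), 0.5)
  expect_equal(percent_reversible(make_bb_scored(c(8, 9), c(7, 6))), 1)
  expect_warning(
    p <- percent_reversible(make_bb_scored(c(1, 2), c(0, 3))), "undefined")
  expect_true(is.na(p))
  # symmetric under swapping direction labels
  a <- percent_reversible(make_bb_scored(c(6, 2, 9), c(1, 7, 9)))
  b <- percent_reversible(make_bb_scored(c(1, 7, 9), c(6, 2, 9)))
  expect_equal(a, b)
})

test_that("g(rho) counts robust pairs failing the score threshold", {
  sc <- make_scored(score = c(6, 7, 2, 3, 9), log_p = rep(-11, 5))
  expect_equal(fnr_g(sc, rho = -10, threshold = 5), 2 / 5)
  expect_equal(fnr_g(make_scored(score = rep(8, 4), log_p = rep(-12, 4))), 0)
  expect_equal(fnr_g(make_scored(score = rep(1, 4), log_p = rep(-12, 4))), 1)
  expect_error(fnr_g(make_scored(score = 1, log_p = -2), rho = -10), "-10")
})

test_that("solve_rho brackets and bisects the g = target crossing", {
  # construction: robust pairs fail the threshold only at mild log p,
  # so g decreases monotonically as rho deepens
  n <- 2000
  lp <- -seq(1, 41, length.out = n)
  sc <- make_scored(score = ifelse(lp < -12, 10, 0), log_p = lp)
  rho <- solve_rho(sc, target = 0.05, threshold = 5)
  expect_false(is.na(rho))
  expect_lte(abs(fnr_g(sc, rho, 5) - 0.05), 0.005)
  # independent grid-scan oracle agrees on the crossing location
  grid <- seq(-50, -1, by = 0.1)
  g <- vapply(grid, function(r) {
    if (!any(sc$log_p < r)) return(NA_real_)
    fnr_g(sc, r, 5)
  }, numeric(1))
  lo <- max(grid[!is.na(g) & g <= 0.05])
  hi <- min(grid[!is.na(g) & g > 0.05])
  expect_gte(rho, lo - 0.1)
  expect_lte(rho, hi + 0.1)
  # g identically zero: no crossing, absent with a warning
  all_called <- make_scored(score = rep(10, 50),
                            log_p = seq(-1, -30, length.out = 50))
  expect_warning(r0 <- solve_rho(all_called), "does not cross")
  expect_true(is.na(r0))
})

test_that("the FWER threshold is log(n/alpha) with exact log-additivity", {
  expect_equal(fwer_score_threshold(1), -log(0.05), tolerance = 1e-12)
  expect_equal(fwer_score_threshold(1), 2.9957, tolerance = 1e-4)
  expect_equal(fwer_score_threshold(163000), 14.998, tolerance = 1e-3)
  for (n in c(10, 500, 163000)) {
    expect_equal(fwer_score_threshold(2 * n),
                 fwer_score_threshold(n) + log(2), tolerance = 1e-12)
  }
  expect_error(fwer_score_threshold(0), "at least one")
})

test_that("the FNR-targeting threshold matches the exhaustive integer scan", {
  set.seed(5)
  for (i in 1:10) {
    scores <- round(runif(40, 0, 30), 1)
    sc <- make_scored(score = scores, log_p = rep(-12, 40))
    target <- sample(c(0.1, 0.2, 0.5), 1)
    got <- sst_for_fnr(sc, target_fnr = target, rho = -10)
    # oracle: scan all integer thresholds, closest FNR, smallest t on ties
    fnr <- vapply(0:100, function(t) mean(scores < t), numeric(1))
    oracle <- (0:100)[which.min(abs(fnr - target))]
    expect_identical(got, oracle)
  }
  # all robust scores far above any threshold: t = 0 attains FNR 0
  expect_identical(sst_for_fnr(make_scored(score = rep(50, 5),
                                           log_p = rep(-12, 5)),
                               target_fnr = 0.2), 0L)
  expect_error(sst_for_fnr(make_scored(score = 1, log_p = -1)), "robust")
})

test_that("FDR-minimising thresholds reproduce the optimiser-dependence phenomenon", {
  # staircase objective decreasing to a plateau at [8, 9.4)
  strong <- 9.4
  r1 <- make_scored(c(rep(strong, 5), (1:32) / 4))
  r2 <- make_scored(c(rep(strong, 5), rep(0, 32)))
  scan <- fdr_scan_oracle(list(r1, r2))
  expect_equal(scan$argmin, 8)
  expect_equal(scan$min, 0)
  # the simplex walks down the staircase to the scan optimum
  nm <- sst_minimising_fdr(list(r1, r2), "simplex", init = 5)
  expect_equal(nm$achieved_fdr, scan$min)
  expect_true(nm$threshold %in% 8:9)
  # quasi-Newton stalls where the staircase is locally flat (the
  # discontinuous-objective failure mode); its result is still a valid
  # threshold and is reported with diagnostics
  qn <- sst_minimising_fdr(list(r1, r2), "quasi_newton", init = 5)
  expect_true(qn$threshold >= 0 && qn$threshold <= 1e4)
  expect_true(is.numeric(qn$achieved_fdr))
  # identical replicates: flat zero objective, both stay near the init
  qn0 <- sst_minimising_fdr(list(r1, r1), "quasi_newton", init = 5)
  nm0 <- sst_minimising_fdr(list(r1, r1), "simplex", init = 5)
  expect_equal(qn0$achieved_fdr, 0)
  expect_equal(nm0$achieved_fdr, 0)
  expect_lte(abs(qn0$threshold - 5), 1)
})

test_that("significant sets are nested under rising thresholds", {
  set.seed(12)
  sc <- make_scored(score = runif(100, 0, 12))
  sizes <- vapply(0:12, function(t) sum(sc$score > t), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the threshold report assembles the full battery", {
  map <- generate_fragment_map(500, seed = 23)
  gm <- truth_model(map, seed = 23)
  truth <- sample_truth(map, seed = 23)
  reps <- simulate_counts(map, gm, truth, 2, seed = 23)
  scored <- purrr::map(reps, compute_scores, model = gm,
                       weights = truth$prior_params)
  rep_out <- threshold_report(scored)
  expect_equal(rep_out$nst, 5)
  expect_true(rep_out$sst_fwer >= 1)
  expect_true(rep_out$fnr_at_nst >= 0 && rep_out$fnr_at_nst <= 1)
  expect_true(is.na(rep_out$fdr_at_nst) ||
                (rep_out$fdr_at_nst >= 0 && rep_out$fdr_at_nst <= 1))
  expect_gte(rep_out$n_significant_at_nst,
             rep_out$n_significant_at_sst_fwer)
})
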