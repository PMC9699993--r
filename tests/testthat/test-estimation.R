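test_that("dispersion is recovered by profile likelihood and capped when absent", {
  map <- generate_fragment_map(600, seed = 11)
  gm <- truth_model(map, dispersion_r = 2, lambda_range = c(0, 0), seed = 11)
  reps <- simulate_counts(map, gm, NULL, 1, seed = 11)
  r_hat <- estimate_dispersion(reps[[1]], gm)
  expect_lt(abs(r_hat - 2) / 2, 0.10)
  # doubling all means and resimulating leaves recovery unbiased
  gm2 <- gm
  gm2$distance_fit$coefficients["c0"] <- gm$distance_fit$coefficients["c0"] + log(2)
  reps2 <- simulate_counts(map, gm2, NULL, 1, seed = 12)
  r_hat2 <- estimate_dispersion(reps2[[1]], gm2)
  expect_lt(abs(r_hat2 - 2) / 2, 0.10)
  # Poisson-like data hits the cap with a warning
  pois <- reps[[1]]
  mu <- chicbench:::pair_means(pois, gm)
  set.seed(1)
  pois$count <- rpois(nrow(pois), ifelse(is.na(mu), 0.01, mu))
  expect_warning(r_cap <- estimate_dispersion(pois, gm), "capped")
  expect_equal(r_cap, 1e6)
})

test_that("bias estimation recovers homogeneous and spiked fragments", {
  map <- generate_fragment_map(600, seed = 3)
  # homogeneous: all true biases 1
  gm <- truth_model(map, bait_bias_sdlog = 0, other_bias_sdlog = 0,
                    lambda_range = c(0, 0), seed = 3)
  reps <- simulate_counts(map, gm, NULL, 1, seed = 3)
  est <- estimate_biases(reps[[1]], gm$distance_fit)
  # per-bait ratio noise is bounded by the NB dispersion, so individual
  # estimates scatter around 1 while the ensemble centres tightly on it
  expect_true(all(abs(est$bait_bias$bias - 1) < 0.5))
  expect_lt(mean(abs(est$bait_bias$bias - 1)), 0.10)
  # imposed normalisation: geometric mean exactly 1
  expect_equal(exp(mean(log(est$bait_bias$bias))), 1, tolerance = 1e-9)
  # one bait spiked to s = 2 among unit baits
  gm2 <- gm
  spiked <- gm2$bait_bias$fragment_id[5]
  gm2$bait_bias$bias[5] <- 2
  reps2 <- simulate_counts(map, gm2, NULL, 1, seed = 4)
  est2 <- estimate_biases(reps2[[1]], gm2$distance_fit)
  s_hat <- est2$bait_bias$bias[est2$bait_bias$fragment_id == spiked]
  expect_gt(s_hat, 1.6)
  expect_lt(s_hat, 2.4)
})

test_that("lambda pools are read ratios over possible trans pairs", {
  # 10 observed trans pairs totalling 5 reads over 100 possible pairs
  tbl <- tibble::tibble(
    bait_id = rep(1L, 11),
    other_id = 100 + 1:11,
    count = c(2L, 1L, rep(0L, 6), 1L, 1L, 3L),
    distance_bp = c(rep(NA_real_, 10), 40000))
  lam <- estimate_lambda(tbl, n_trans_fragments = 100, n_pools = 1)
  expect_equal(lam$lambda_pools$lambda, 5 / 100)
  # no trans reads -> all zero with a warning
  cis_only <- tibble::tibble(bait_id = 1L, other_id = 2L, count = 3L,
                             distance_bp = 40000)
  expect_warning(lam0 <- estimate_lambda(cis_only, 100), "no trans")
  expect_true(all(lam0$lambda_pools$lambda == 0))
})

test_that("lambda pool medians track increasing noise strata", {
  map <- generate_fragment_map(600, seed = 21)
  gm <- truth_model(map, lambda_range = c(0.005, 0.05), seed = 21)
  reps <- simulate_counts(map, gm, NULL, 1, seed = 21)
  n_trans <- sum(map$fragments$chrom == "chrD")
  lam <- estimate_lambda(reps[[1]], n_trans)
  # grouped by the generating noise strata, per-bait rate medians follow
  # the increasing lambda sequence
  vals <- lam$per_bait |>
    dplyr::select("fragment_id", "trans_reads") |>
    dplyr::inner_join(gm$bait_lambda_pool, by = "fragment_id") |>
    dplyr::transmute(pool = .data$pool, value = .data$trans_reads / n_trans)
  diag <- lambda_trend_diagnostic(vals)
  expect_true(all(diff(diag$summaries$median) >= 0))
  # depth-stratified pooling recovers the broad trend: top pool above bottom
  est_pools <- lam$lambda_pools
  expect_gt(est_pools$lambda[nrow(est_pools)], est_pools$lambda[1])
})

test_that("the full estimation cascade produces a usable calibrated model", {
  map <- generate_fragment_map(600, seed = 7)
  gm <- truth_model(map, seed = 7)
  truth <- sample_truth(map, seed = 7)
  reps <- simulate_counts(map, gm, truth, 1, seed = 7)
  n_trans <- sum(map$fragments$chrom == "chrD")
  model <- estimate_null_model(reps[[1]], n_trans_fragments = n_trans)
  expect_s3_class(model, "chic_null_model")
  expect_gt(model$dispersion_r, 0)
  # calibration: total expected matches total observed
  mu <- chicbench:::pair_means(reps[[1]], model)
  ok <- !is.na(mu)
  expect_equal(sum(reps[[1]]$count[ok]) / sum(mu[ok]), 1, tolerance = 1e-6)
  # recovered decay slope close to the generating power law
  expect_lt(abs(model$all_fits$linear$coefficients["b1"] + 1), 0.1)
})
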