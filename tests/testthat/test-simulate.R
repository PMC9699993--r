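test_that("fragment maps are contiguous, deterministic and correctly sized", {
  map1 <- generate_fragment_map(100, mean_len_bp = 4000, bait_fraction = 0.1,
                                seed = 7)
  map2 <- generate_fragment_map(100, mean_len_bp = 4000, bait_fraction = 0.1,
                                seed = 7)
  expect_identical(map1$fragments, map2$fragments)
  main <- map1$fragments |> dplyr::filter(.data$chrom == "chrS")
  expect_equal(nrow(main), 100)
  expect_equal(length(map1$bait_ids), 10)
  # contiguity: next start = previous end + 1
  expect_true(all(main$start[-1] == main$end[-nrow(main)] + 1))
  # total span within 20% of n * mean length
  expect_lt(abs(max(main$end) - 100 * 4000) / (100 * 4000), 0.2)
  # a bait fraction yielding zero baits is an error
  expect_error(generate_fragment_map(100, bait_fraction = 0.001), "0 baits")
})

test_that("truth sampling follows the prior curve", {
  map <- generate_fragment_map(300, seed = 3)
  # prior identically zero: empty truth set
  t0 <- sample_truth(map, prior_params = c(0, 0, 12, 1), seed = 1)
  expect_equal(nrow(t0$true_pairs), 0)
  # prior identically one: every tested pair is true
  t1 <- sample_truth(map, prior_params = c(1, 1, 12, 1), seed = 1)
  expect_equal(nrow(t1$true_pairs), nrow(chicbench:::cis_pair_grid(map)))
  expect_true(all(t1$true_pairs$multiplier >= 3 &
                    t1$true_pairs$multiplier <= 10))
  # logistic prior: per-bin empirical true fraction within binomial bounds
  pp <- c(0.01, 0.4, 12, 2)
  tr <- sample_truth(map, prior_params = pp, seed = 3)
  grid <- chicbench:::cis_pair_grid(map)
  b <- distance_bins(width_bp = 300000, upper_bp = 1500000)
  grid$bin <- assign_bins(grid$distance_bp, b)
  grid$true <- paste(grid$bait_id, grid$other_id) %in%
    paste(tr$true_pairs$bait_id, tr$true_pairs$other_id)
  checks <- grid |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(k = sum(.data$true), n = dplyr::n(),
                     p = mean(eval_weight_curve(pp, .data$distance_bp)),
                     .groups = "drop")
  for (i in seq_len(nrow(checks))) {
    ci <- qbinom(c(0.0005, 0.9995), checks$n[i], checks$p[i])
    expect_gte(checks$k[i], ci[1])
    expect_lte(checks$k[i], ci[2])
  }
})

test_that("simulated counts reproduce the generating moments", {
  # unit biases, no noise, no truth: per-bin mean tracks f(d), NB var/mean
  map <- generate_fragment_map(3000, bait_fraction = 0.1, seed = 5)
  gm <- truth_model(map, dispersion_r = 2, bait_bias_sdlog = 0,
                    other_bias_sdlog = 0, lambda_range = c(0, 0), seed = 5)
  reps <- simulate_counts(map, gm, NULL, 1, seed = 5)
  b <- distance_bins()
  dat <- reps[[1]] |>
    dplyr::mutate(bin = assign_bins(.data$distance_bp, b)) |>
    dplyr::filter(!is.na(.data$bin), .data$bin >= 20, .data$bin <= 40)
  stats <- dat |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(m = mean(.data$count), v = var(.data$count),
                     mu = mean(eval_distance_fit(gm$distance_fit,
                                                 .data$distance_bp)),
                     n = dplyr::n(), .groups = "drop")
  expect_true(all(stats$n > 2500))
  expect_true(all(abs(stats$m - stats$mu) / stats$mu < 0.05))
  # NB moment identity: var/mean ~ 1 + mean/r at r = 2
  expect_true(all(abs(stats$v / stats$m - (1 + stats$mu / 2)) /
                    (1 + stats$mu / 2) < 0.10))
  # determinism
  reps2 <- simulate_counts(map, gm, NULL, 1, seed = 5)
  expect_identical(reps[[1]], reps2[[1]])
})

test_that("replicates share truth but draw independent noise", {
  map <- generate_fragment_map(300, seed = 8)
  gm <- truth_model(map, seed = 8)
  truth <- sample_truth(map, prior_params = c(0.01, 0.2, 12, 2), seed = 8)
  reps <- simulate_counts(map, gm, truth, 2, seed = 8)
  expect_length(reps, 2)
  cis1 <- reps[[1]] |> dplyr::filter(!is.na(.data$distance_bp))
  cis2 <- reps[[2]] |> dplyr::filter(!is.na(.data$distance_bp))
  # cis grids coincide; trans rows differ because only non-zero
  # technical-noise draws are recorded
  expect_equal(cis1$bait_id, cis2$bait_id)
  expect_equal(cis1$other_id, cis2$other_id)
  expect_false(identical(cis1$count, cis2$count))
})

test_that("CNV perturbations rescale counts by the region multiplier", {
  map <- generate_fragment_map(600, seed = 13)
  gm <- truth_model(map, bait_bias_sdlog = 0, other_bias_sdlog = 0,
                    lambda_range = c(0, 0), seed = 13)
  reps <- simulate_counts(map, gm, NULL, 1, seed = 13)
  # identity: multiplier 1 everywhere, no breakpoint
  same <- apply_perturbations(map, reps[[1]],
                              cnv_regions = tibble::tibble(
                                start = 1, end = 5e5, multiplier = 1),
                              model = gm, seed = 13)
  expect_identical(same$count, reps[[1]]$count)
  # multiplier 2 doubles the mean for affected pairs
  reg <- tibble::tibble(start = 1, end = 8e5, multiplier = 2)
  pert <- apply_perturbations(map, reps[[1]], cnv_regions = reg,
                              model = gm, seed = 13)
  mid <- map$fragments$midpoint[match(reps[[1]]$bait_id,
                                      map$fragments$fragment_id)]
  mid2 <- map$fragments$midpoint[match(reps[[1]]$other_id,
                                       map$fragments$fragment_id)]
  hit <- !is.na(reps[[1]]$distance_bp) & (mid <= 8e5 | mid2 <= 8e5)
  ratio <- mean(pert$count[hit]) / mean(reps[[1]]$count[hit])
  expect_lt(abs(ratio - 2), 0.10 * 2)
  # untouched pairs unchanged
  expect_identical(pert$count[!hit], reps[[1]]$count[!hit])
  # overlapping regions rejected
  expect_error(apply_perturbations(map, reps[[1]],
                                   cnv_regions = tibble::tibble(
                                     start = c(1, 3e5), end = c(5e5, 7e5),
                                     multiplier = c(2, 3)),
                                   model = gm, seed = 1), "overlap")
})

test_that("breakpoint fusion lifts spanning pairs to the short-range regime", {
  map <- generate_fragment_map(600, seed = 17)
  gm <- truth_model(map, bait_bias_sdlog = 0, other_bias_sdlog = 0,
                    lambda_range = c(0, 0), seed = 17)
  reps <- simulate_counts(map, gm, NULL, 1, seed = 17)
  # fuse loci ~1.19 Mb apart: spanning pairs behave like ~10 kb pairs
  bp <- c(6e5, 6e5 + 1.19e6)
  pert <- apply_perturbations(map, reps[[1]], breakpoint = bp,
                              model = gm, seed = 17)
  mid <- map$fragments$midpoint[match(reps[[1]]$bait_id,
                                      map$fragments$fragment_id)]
  mid2 <- map$fragments$midpoint[match(reps[[1]]$other_id,
                                       map$fragments$fragment_id)]
  lo <- pmin(mid, mid2); hi <- pmax(mid, mid2)
  span <- !is.na(reps[[1]]$distance_bp) & lo <= bp[1] & hi >= bp[2]
  expect_gt(sum(span), 20)
  m_pert <- mean(pert$count[span])
  m_expected <- mean(eval_distance_fit(gm$distance_fit,
                                       pmax(reps[[1]]$distance_bp[span] -
                                              diff(bp), 150)))
  expect_lt(abs(m_pert - m_expected) / m_expected, 0.15)
  # far larger than the unperturbed long-range counts
  expect_gt(m_pert, 5 * mean(reps[[1]]$count[span]))
})
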