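#' Default pipeline configuration
#'
#' Desk-scale defaults: a 1000-fragment synthetic chromosome (about 4 Mb
#' of HindIII-like fragments, 100 baits) plus a decoy chromosome, two
#' replicates, a theoretical \eqn{f(d) = e^{c_0}/d} background with
#' dispersion 2, log-normal biases, technical noise increasing across
#' five pools, and a logistic interaction prior. The KS battery runs at
#' reduced simulation settings (200 simulations of 500 pairs) so a full
#' run stays interactive; production-scale settings (5000/5000) are a
#' config change.
#'
#' @param seed Master seed; every stochastic stage derives its stream
#'   from it.
#' @param ... Overrides for any default entry.
#' @return Named list of configuration values.
#' @export
chic_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_fragments = 1000, mean_len_bp = 4000, bait_fraction = 0.1,
    n_replicates = 2,
    c0 = log(5e6), dispersion_r = 2,
    bait_bias_sdlog = 0.25, other_bias_sdlog = 0.5,
    lambda_range = c(0.001, 0.01), n_lambda_pools = 5,
    prior_params = c(0.0005, 0.03, 12, 2), effect_range = c(3, 10),
    binning_width_bp = 20000, binning_upper_bp = 1500000,
    active_fit = "cubic", n_pools = 5,
    ks_n_sim = 200, ks_n_pairs = 500,
    nst = 5, target_fnr = 0.2, rho = -10,
    cnv_regions = NULL, breakpoint = NULL,
    sections = c("ks", "distance", "lambda", "symmetry", "thresholds",
                 "weights"),
    rmap = NULL, baitmap = NULL, chinput = NULL
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full simulate-call-evaluate pipeline
#'
#' Executes every stage in order: synthetic data generation (or reading
#' the rmap/baitmap/chinput paths named in the config), background-model
#' estimation, scoring, and the full diagnostic battery. Every stochastic
#' step is seeded from `config$seed`, so reruns are bit-identical.
#'
#' @param config A [chic_config()] list.
#' @param outdir Optional directory; when given, every report section is
#'   written as a TSV plus a `summary.txt`.
#' @return A `chic_eval_report`: list with sections `ks_table`,
#'   `distance_fits`, `lambda_diagnostics`, `symmetry`, `thresholds`,
#'   `weights`, plus `model`, `scored`, `truth`, `map` and `provenance`.
#'   Disabled or inapplicable sections are `NULL` with the reason in
#'   `skipped`.
#' @export
chic_pipeline <- function(config = chic_config(), outdir = NULL) {
  t0 <- Sys.time()
  binning <- distance_bins(config$binning_width_bp, config$binning_upper_bp)
  skipped <- list()

  if (!is.null(config$chinput)) {
    for (p in c(config$rmap, config$baitmap, unlist(config$chinput))) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
    map <- read_fragment_map(config$rmap, config$baitmap)
    replicates <- purrr::map(unlist(config$chinput), read_interactions,
                             map = map)
    truth <- NULL
    gen_model <- NULL
  } else {
    map <- generate_fragment_map(config$n_fragments, config$mean_len_bp,
                                 config$bait_fraction, seed = config$seed)
    gen_model <- truth_model(map, config$c0, config$dispersion_r,
                             config$bait_bias_sdlog, config$other_bias_sdlog,
                             config$lambda_range, config$n_lambda_pools,
                             seed = config$seed)
    truth <- sample_truth(map, config$prior_params, config$effect_range,
                          seed = config$seed)
    replicates <- simulate_counts(map, gen_model, truth,
                                  config$n_replicates, seed = config$seed)
    if (!is.null(config$cnv_regions) || !is.null(config$breakpoint)) {
      replicates <- purrr::imap(replicates, function(x, i) {
        apply_perturbations(map, x, config$cnv_regions, config$breakpoint,
                            gen_model, seed = config$seed + i)
      })
    }
  }

  bait_chrom <- map$fragments$chrom[match(map$bait_ids[1],
                                          map$fragments$fragment_id)]
  n_trans <- sum(map$fragments$chrom != bait_chrom)
  model <- estimate_null_model(replicates[[1]], n_trans_fragments = n_trans,
                               binning = binning,
                               active_fit = config$active_fit,
                               n_pools = config$n_pools)
  default_weights <- if (!is.null(truth)) truth$prior_params else NULL
  scored <- purrr::map(replicates, compute_scores, model = model,
                       weights = default_weights)

  report <- list(map = map, model = model, truth = truth, scored = scored,
                 replicates = replicates)

  want <- function(s) s %in% config$sections

  if (want("ks")) {
    dat <- replicates[[1]] |>
      dplyr::mutate(bin = assign_bins(.data$distance_bp, binning)) |>
      dplyr::filter(!is.na(.data$bin))
    bins_present <- sort(unique(dat$bin))
    report$ks_table <- purrr::map_dfr(bins_present, function(b) {
      ks_monte_carlo(dat |> dplyr::filter(.data$bin == b), model, b,
                     binning, config$ks_n_sim, config$ks_n_pairs,
                     seed = config$seed)
    }) |> bonferroni_ks()
  } else skipped$ks <- "disabled in config"

  if (want("distance")) {
    report$distance_fits <- purrr::map_dfr(model$all_fits, glance)
  } else skipped$distance <- "disabled in config"

  if (want("lambda")) {
    lam <- estimate_lambda(replicates[[1]], n_trans, config$n_pools)
    vals <- lam$per_bait |>
      dplyr::transmute(pool = .data$pool,
                       value = .data$trans_reads / n_trans)
    report$lambda_diagnostics <- c(
      if (dplyr::n_distinct(vals$pool) >= 2) lambda_trend_diagnostic(vals)
      else list(summaries = NULL, trend_ok = NA),
      list(lambda_pools = lam$lambda_pools,
           mean_trans_pairs_per_bait = lam$mean_trans_pairs_per_bait))
  } else skipped$lambda <- "disabled in config"

  if (want("symmetry")) {
    sym <- suppressWarnings(score_symmetry(scored[[1]]))
    sym$percent_reversible <- suppressWarnings(
      percent_reversible(scored[[1]], config$nst))
    report$symmetry <- sym
  } else skipped$symmetry <- "disabled in config"

  if (want("thresholds")) {
    if (length(scored) >= 2) {
      report$thresholds <- threshold_report(scored, binning, config$nst,
                                            config$target_fnr, config$rho)
    } else {
      report$thresholds <- threshold_report(scored, binning, config$nst,
                                            config$target_fnr, config$rho)
      skipped$thresholds_fdr <-
        "replicate-FDR statistics need >= 2 replicates"
    }
  } else skipped$thresholds <- "disabled in config"

  if (want("weights")) {
    report$weights <- reweight_and_compare(replicates, model,
                                           default_weights, binning,
                                           config$nst, config$rho)
  } else skipped$weights <- "disabled in config"

  report$skipped <- skipped
  report$provenance <- list(
    config = config,
    package_version = as.character(utils::packageVersion("chicbench")),
    r_version = R.version.string,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(report) <- "chic_eval_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write an evaluation report as TSVs plus a text summary
#'
#' KS p-values at the Monte-Carlo floor are printed as `"<1/(n_sim+1)"`.
#'
#' @param report A `chic_eval_report`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$ks_table)) {
    ks <- report$ks_table |>
      dplyr::mutate(mc_p_printed = ifelse(
        .data$mc_p <= 1 / (.data$n_sim + 1) + 1e-12,
        sprintf("<%.6g", 1 / (.data$n_sim + 1)),
        sprintf("%.6g", .data$mc_p)))
    readr::write_tsv(ks, file.path(outdir, "ks_table.tsv"))
  }
  if (!is.null(report$distance_fits)) {
    readr::write_tsv(report$distance_fits,
                     file.path(outdir, "distance_fits.tsv"))
  }
  if (!is.null(report$lambda_diagnostics$summaries)) {
    readr::write_tsv(report$lambda_diagnostics$summaries,
                     file.path(outdir, "lambda_pools.tsv"))
  }
  if (!is.null(report$symmetry)) {
    readr::write_tsv(
      tibble::tibble(statistic = c("score_correlation", "percent_reversible",
                                   "n_used"),
                     value = c(report$symmetry$correlation,
                               report$symmetry$percent_reversible,
                               report$symmetry$n_used)),
      file.path(outdir, "symmetry.tsv"))
    if (nrow(report$symmetry$top_deviations) > 0) {
      readr::write_tsv(report$symmetry$top_deviations,
                       file.path(outdir, "symmetry_top_deviations.tsv"))
    }
  }
  if (!is.null(report$thresholds)) {
    readr::write_tsv(report$thresholds, file.path(outdir, "thresholds.tsv"))
  }
  if (!is.null(report$weights)) {
    w <- report$weights
    readr::write_tsv(
      tibble::tibble(
        statistic = c("lom", "rss", "n_zero_bins", "rho_used",
                      "reweight_jaccard"),
        value = c(w$lom, w$rss, w$n_zero_bins, w$rho_used,
                  w$reweight_jaccard)),
      file.path(outdir, "weight_eval.tsv"))
    readr::write_tsv(w$delta_stats, file.path(outdir, "weight_deltas.tsv"))
  }
  for (i in seq_along(report$scored)) {
    write_scored_interactions(report$scored[[i]],
                              file.path(outdir, sprintf("scores_rep%d.tsv", i)))
  }
  writeLines(utils::capture.output(print(report)),
             file.path(outdir, "summary.txt"))
  invisible(outdir)
}

#' @export
print.chic_eval_report <- function(x, ...) {
  cat("== CHi-C calling evaluation report ==\n")
  cat("fragments:", nrow(x$map$fragments), " baits:", length(x$map$bait_ids),
      " replicates:", length(x$scored), "\n")
  cat("dispersion r:", signif(x$model$dispersion_r, 4), "\n")
  if (!is.null(x$distance_fits)) {
    cat("distance fits (rss | K):\n")
    for (i in seq_len(nrow(x$distance_fits))) {
      cat(sprintf("  %-12s %8.4f | %.4f\n", x$distance_fits$kind[i],
                  x$distance_fits$rss[i], x$distance_fits$curvature_K[i]))
    }
  }
  if (!is.null(x$ks_table)) {
    cat("KS battery:", sum(x$ks_table$significant_after_bonferroni),
        "of", nrow(x$ks_table), "bins rejected after Bonferroni\n")
  }
  if (!is.null(x$lambda_diagnostics)) {
    cat("lambda trend upward:", x$lambda_diagnostics$trend_ok, "\n")
  }
  if (!is.null(x$symmetry)) {
    cat("bait-bait score correlation:", signif(x$symmetry$correlation, 4),
        " percent reversible:",
        signif(100 * x$symmetry$percent_reversible, 4), "%\n")
  }
  if (!is.null(x$thresholds)) {
    t <- x$thresholds
    cat("thresholds: NST", t$nst, "| SST(FNR)", t$sst_fnr,
        "| SST(FDR,QN)", t$sst_fdr_quasi_newton,
        "| SST(FDR,NM)", t$sst_fdr_simplex,
        "| SST(FWER)", t$sst_fwer, "\n")
    cat("  FDR at NST:", signif(t$fdr_at_nst, 4),
        " FNR at NST:", signif(t$fnr_at_nst, 4),
        " rho*:", signif(t$rho_star, 4), "\n")
  }
  if (!is.null(x$weights)) {
    cat("weighting: LOM", signif(x$weights$lom, 4),
        "| RSS", signif(x$weights$rss, 4),
        "| zero bins", x$weights$n_zero_bins,
        "| reweight Jaccard", signif(x$weights$reweight_jaccard, 4), "\n")
  }
  if (length(x$skipped) > 0) {
    cat("skipped:", paste(names(x$skipped), unlist(x$skipped),
                          sep = ": ", collapse = "; "), "\n")
  }
  invisible(x)
}
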