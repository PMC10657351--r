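#' Configure an analysis run
#'
#' @param n_perm Permutations for the covariance-ratio test.
#' @param seed Master seed; every stochastic stage derives its seed from it
#'   and the stage name, so runs are reproducible end to end.
#' @param wrist_policy Wrist handling for modularity partitions
#'   (`"excluded"`, `"to_HW"`, `"to_AW"`).
#' @param disparity_metric `"variance"` or `"median_dist_centroid"`.
#' @param model_policy Per-slice model policy for [sigma2_profile()].
#' @param log10_cr Log10-transform trait values before the CR test (removes
#'   mean differences between regions)?
#' @param cutoff RDA cutoff on the 35-slice axis.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(n_perm = 999L, seed = 1L, wrist_policy = "excluded",
                       disparity_metric = "variance",
                       model_policy = "best_aicc", log10_cr = TRUE,
                       cutoff = 10.5) {
  structure(list(n_perm = n_perm, seed = as.integer(seed),
                 wrist_policy = wrist_policy,
                 disparity_metric = disparity_metric,
                 model_policy = model_policy, log10_cr = log10_cr,
                 cutoff = cutoff),
            class = "run_config")
}

stage_seed <- function(config, stage) {
  (config$seed * 1009L + sum(utf8ToInt(stage))) %% 2147483647L
}

#' Run the full spanwise-evolution analysis
#'
#' For each trait profile: the covariance-ratio modularity test (log10 by
#' default, wrist per policy), the per-slice disparity profile and its
#' regression-discontinuity test at the wrist, the per-slice sigma^2 profile
#' (AICc-best model per slice by default) and its RDA, and per-slice
#' phylogenetic signal (Blomberg's K, Pagel's lambda). Produces a summary
#' table with one row per trait (mean K/lambda and mean disparity/sigma^2 by
#' region, plus the two RDA p-values).
#'
#' @param profiles A named list of `"trait_profile"` objects (36- or
#'   35-slice), e.g. from [summarize_species()] or [generate_study()].
#' @param tree A `"phylo"` containing all species.
#' @param config A [run_config()].
#' @param out_dir Optional directory: writes per-trait TSVs, a
#'   markdown report and a profile plot.
#' @return A list of class `"wing_analysis"`: per trait `modularity`,
#'   `disparity`, `disparity_rda`, `sigma2`, `sigma2_rda`, `signal`; plus
#'   `summary` (the per-trait table) and `config`.
#' @export
run_pipeline <- function(profiles, tree, config = run_config(),
                         out_dir = NULL) {
  if (inherits(profiles, "trait_profile")) profiles <- list(profiles)
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, `[[`, "", "trait")
  results <- lapply(names(profiles), function(tr) {
    pr <- profiles[[tr]]
    ## modularity: wrist per policy, optional log10
    pr_cr <- standardize_profiles(pr, wrist_policy = config$wrist_policy,
                                  log10 = config$log10_cr)
    mod <- cr_permutation_test(pr_cr, n_perm = config$n_perm,
                               seed = stage_seed(config, paste0("cr_", tr)))
    ## disparity + sigma2 on the wrist-excluded 35-slice profile, raw scale
    pr_an <- standardize_profiles(pr, wrist_policy = "excluded")
    disp <- disparity_profile(pr_an, metric = config$disparity_metric)
    s2 <- sigma2_profile(pr_an, tree, model_policy = config$model_policy)
    sig <- signal_profile(pr_an, tree)
    list(trait = tr, modularity = mod,
         disparity = disp, disparity_rda = rda(disp, cutoff = config$cutoff),
         sigma2 = s2, sigma2_rda = rda(s2, cutoff = config$cutoff),
         signal = sig)
  })
  names(results) <- names(profiles)
  summary_tab <- do.call(rbind, lapply(results, function(r) {
    hw <- r$disparity$region == "HW"; aw <- r$disparity$region == "AW"
    data.frame(
      trait = r$trait,
      lambda_hw = mean(r$signal$pagel_lambda[hw], na.rm = TRUE),
      k_hw = mean(r$signal$blomberg_k[hw], na.rm = TRUE),
      lambda_aw = mean(r$signal$pagel_lambda[aw], na.rm = TRUE),
      k_aw = mean(r$signal$blomberg_k[aw], na.rm = TRUE),
      disparity_hw = mean(r$disparity$value[hw], na.rm = TRUE),
      disparity_aw = mean(r$disparity$value[aw], na.rm = TRUE),
      sigma2_hw = mean(r$sigma2$value[hw], na.rm = TRUE),
      sigma2_aw = mean(r$sigma2$value[aw], na.rm = TRUE),
      cr = r$modularity$cr, cr_p = r$modularity$p_value,
      disparity_rda_p = r$disparity_rda$p_delta,
      sigma2_rda_p = r$sigma2_rda$p_delta,
      row.names = NULL)
  }))
  out <- list(results = results, summary = summary_tab, config = config)
  class(out) <- "wing_analysis"
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' @export
print.wing_analysis <- function(x, ...) {
  cat("spanwise wing-shape evolution analysis\n")
  cat(sprintf("  traits: %s\n", paste(names(x$results), collapse = ", ")))
  print(x$summary, digits = 3)
  invisible(x)
}

write_analysis <- function(analysis, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(analysis$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mod_rows <- do.call(rbind, lapply(analysis$results, function(r)
    data.frame(trait = r$trait, transform = "log10",
               wrist_policy = analysis$config$wrist_policy,
               cr = r$modularity$cr, p = r$modularity$p_value,
               n_perm = r$modularity$n_perm,
               seed = analysis$config$seed)))
  utils::write.table(mod_rows, file.path(out_dir, "modularity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (r in analysis$results) {
    write_span_profile(r$disparity,
                       file.path(out_dir, paste0("disparity_", r$trait, ".tsv")),
                       trait = r$trait)
    write_span_profile(r$sigma2,
                       file.path(out_dir, paste0("sigma2_", r$trait, ".tsv")),
                       trait = r$trait)
    utils::write.table(r$signal,
                       file.path(out_dir, paste0("signal_", r$trait, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(render_report(analysis), file.path(out_dir, "report.md"))
  grDevices::png(file.path(out_dir, "profiles.png"), width = 1200,
                 height = 400 * length(analysis$results), res = 110)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(analysis)
  invisible(out_dir)
}

render_report <- function(analysis) {
  s <- analysis$summary
  lines <- c("# Spanwise evolutionary dynamics of wing shape", "",
             sprintf("Seed %d; %d CR permutations; wrist policy: %s; disparity metric: %s.",
                     analysis$config$seed, analysis$config$n_perm,
                     analysis$config$wrist_policy,
                     analysis$config$disparity_metric), "",
             "| trait | HW lambda, K | AW lambda, K | disparity HW \\| AW | sigma2 HW \\| AW | CR (p) | disparity RDA p | sigma2 RDA p |",
             "|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "| %s | %.2f, %.2f | %.2f, %.2f | %.4g \\| %.4g | %.4g \\| %.4g | %.2f (%.3g) | %.3g | %.3g |",
      s$trait[i], s$lambda_hw[i], s$k_hw[i], s$lambda_aw[i], s$k_aw[i],
      s$disparity_hw[i], s$disparity_aw[i], s$sigma2_hw[i], s$sigma2_aw[i],
      s$cr[i], s$cr_p[i], s$disparity_rda_p[i], s$sigma2_rda_p[i]))
  }
  lines
}

#' Plot spanwise disparity and rate profiles
#'
#' One panel per trait: disparity (dashed) and sigma^2 (solid, rescaled)
#' against slice position, armwing blue, handwing red, wrist cutoff dotted.
#'
#' @param x A `"wing_analysis"`.
#' @param ... Ignored.
#' @export
plot.wing_analysis <- function(x, ...) {
  k <- length(x$results)
  op <- graphics::par(mfrow = c(k, 1), mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op), add = TRUE)
  for (r in x$results) {
    d <- r$disparity; s <- r$sigma2
    col <- ifelse(d$region == "HW", "firebrick", "steelblue")
    graphics::plot(d$slice, d$value, type = "b", lty = 2, pch = 1, col = col,
                   xlab = "slice (base to tip)", ylab = "disparity",
                   main = r$trait)
    graphics::abline(v = x$config$cutoff, lty = 3)
    sc <- max(d$value, na.rm = TRUE) / max(s$value, na.rm = TRUE)
    graphics::lines(s$slice, s$value * sc, type = "b", pch = 16, col = col)
    graphics::axis(4, at = graphics::axTicks(2),
                   labels = signif(graphics::axTicks(2) / sc, 2))
    graphics::mtext("sigma2", side = 4, line = 2.5, cex = 0.7)
  }
  invisible(x)
}
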