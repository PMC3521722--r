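#' Scenario-choice error rates from pseudo-observed datasets
#'
#' Simulates `n_pods` pseudo-observed datasets (PODs) from each scenario's
#' prior, classifies every POD against the reference table by highest
#' scenario posterior probability, and tallies the confusion matrix. Type I
#' error for scenario s is the fraction of s-PODs not assigned to s; type II
#' error for s is, pooled over all other true scenarios, the fraction of
#' non-s PODs assigned to s (the chance the inferred scenario is the wrong
#' one). A per-true-scenario conditional type II breakdown is kept in the
#' matrix itself.
#'
#' @param table a [build_reference_table()] result; PODs reuse its scenarios,
#'   priors and sampling design.
#' @param n_pods PODs per scenario.
#' @param tolerance retained fraction for each classification.
#' @return object of class `confusion_matrix`: `counts` (true x inferred),
#'   `type1`, `type2` (pooled), `n_pods`.
#' @export
run_pods <- function(table, n_pods = 100, tolerance = 0.01) {
  scen <- table$scenarios
  k <- length(scen)
  if (k < 2) stop("need at least 2 scenarios for error estimation")
  nms <- vapply(scen, function(s) s$name, "")
  cfg <- table$config
  offs <- copy_offsets(cfg)
  sid <- rep(seq_along(cfg$offsets), times = 2L * cfg$n_diploids) - 1L
  ns <- length(cfg$offsets)
  counts <- matrix(0L, k, k, dimnames = list(true = nms, inferred = nms))
  for (s in seq_len(k)) {
    draws <- sample_prior(scen[[s]], n_pods)
    for (i in seq_len(n_pods)) {
      traj <- draw_trajectory(scen[[s]], draws[i, ])
      rates <- draw_locus_rates(draws$mu_mean[i], cfg$n_loci,
                                table$model$shape)
      mat <- .sim_dataset_cpp(offs, cfg$n_loci, traj$breaks, traj$N, rates,
                              draws$gsm_p[i], cfg$founder,
                              cfg$state_bounds[1], cfg$state_bounds[2])
      sv <- summaries_from_matrix(mat, sid, ns) # default all-pairs panel
      chosen <- scenario_posteriors(table, sv, tolerance)$chosen
      counts[s, chosen] <- counts[s, chosen] + 1L
    }
  }
  type1 <- 1 - diag(counts) / n_pods
  type2 <- vapply(seq_len(k), function(j)
    sum(counts[-j, j]) / ((k - 1) * n_pods), 0)
  names(type1) <- names(type2) <- nms
  structure(list(counts = counts, type1 = type1, type2 = type2,
                 n_pods = n_pods),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (", x$n_pods, "PODs per scenario )\n")
  print(x$counts)
  cat(sprintf("type I : %s (range %.1f%%-%.1f%%)\n",
              paste(sprintf("%.3f", x$type1), collapse = " "),
              100 * min(x$type1), 100 * max(x$type1)))
  cat(sprintf("type II: %s (range %.1f%%-%.1f%%)\n",
              paste(sprintf("%.3f", x$type2), collapse = " "),
              100 * min(x$type2), 100 * max(x$type2)))
  invisible(x)
}

#' Write a confusion matrix as TSV
#'
#' Layout: one row per true scenario, inferred-scenario counts in columns,
#' followed by the per-scenario type I and pooled type II error estimates.
#'
#' @param cm a `confusion_matrix`.
#' @param path output path.
#' @export
write_confusion_tsv <- function(cm, path) {
  df <- as.data.frame(cm$counts)
  df <- cbind(true_scenario = rownames(cm$counts), df,
              type1 = cm$type1, type2_pooled = cm$type2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
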