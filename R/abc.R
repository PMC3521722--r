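#' Build an ABC reference table
#'
#' Simulates `n_per_scenario` datasets under each competing demographic
#' scenario (parameters drawn from their priors), computes the summary
#' vector of each, and records per-statistic scale factors (median absolute
#' deviation over all rows; falling back to the standard deviation, then to
#' 1, for degenerate statistics) used to normalize Euclidean distances.
#'
#' @param scenarios list of [make_scenario()] objects.
#' @param n_per_scenario simulations per scenario (>= 100).
#' @param config a [sample_config()] mirroring the observed study design.
#' @param model a [mutation_model()]; per-locus rates are redrawn for every
#'   simulated dataset around that dataset's prior-drawn mean rate.
#' @return object of class `reference_table`: `draws` (data.frame of
#'   scenario labels and parameter draws), `sumstats` (matrix), `scale`,
#'   `config`, `model`, `scenarios`.
#' @export
build_reference_table <- function(scenarios, n_per_scenario, config,
                                  model = mutation_model()) {
  stopifnot(n_per_scenario >= 100)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, function(s) s$name, "")
  offs <- copy_offsets(config)
  sid <- rep(seq_along(config$offsets), times = 2L * config$n_diploids) - 1L
  ns <- length(config$offsets)
  fst_pairs <- default_fst_pairs(ns)
  pm <- pairs_matrix(fst_pairs)
  draw_list <- list()
  stat_list <- list()
  for (sc in scenarios) {
    draws <- sample_prior(sc, n_per_scenario)
    stats_m <- matrix(NA_real_, n_per_scenario, 4L * ns + length(fst_pairs))
    for (i in seq_len(n_per_scenario)) {
      traj <- draw_trajectory(sc, draws[i, ])
      rates <- draw_locus_rates(draws$mu_mean[i], config$n_loci, model$shape)
      mat <- .sim_dataset_cpp(offs, config$n_loci, traj$breaks, traj$N,
                              rates, draws$gsm_p[i], config$founder,
                              config$state_bounds[1], config$state_bounds[2])
      stats_m[i, ] <- .summaries_cpp(mat, sid, ns, pm)
    }
    draw_list[[sc$name]] <- draws
    stat_list[[sc$name]] <- stats_m
  }
  draws <- bind_union(draw_list)
  sumstats <- do.call(rbind, stat_list)
  colnames(sumstats) <- stat_panel_names(ns, fst_pairs)
  scale <- apply(sumstats, 2, function(x) {
    s <- stats::mad(x)
    if (!is.finite(s) || s <= 0) s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      warning("statistic constant across reference table; scale set to 1")
      s <- 1
    }
    s
  })
  structure(list(draws = draws, sumstats = sumstats, scale = scale,
                 config = config, model = model, scenarios = scenarios),
            class = "reference_table")
}

# rbind data.frames with differing columns (NA-filled union)
bind_union <- function(lst) {
  cols <- unique(unlist(lapply(lst, names)))
  out <- lapply(lst, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA_real_
    d[cols]
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.reference_table <- function(x, ...) {
  cat("reference_table:", nrow(x$sumstats), "simulations,",
      length(x$scenarios), "scenario(s),",
      ncol(x$sumstats), "summary statistics\n")
  print(table(x$draws$scenario))
  invisible(x)
}

# normalized deviations (simulated - observed) / scale and distances
normalized_deviations <- function(table, observed, rows = NULL) {
  obs <- as.numeric(observed)[match(colnames(table$sumstats), names(observed))]
  if (anyNA(obs))
    stop("observed summary vector does not carry the table's statistics")
  S <- if (is.null(rows)) table$sumstats else table$sumstats[rows, , drop = FALSE]
  sweep(sweep(S, 2, obs), 2, table$scale, "/")
}

#' Rejection step
#'
#' Retains the `ceiling(tolerance * n)` reference-table rows closest to the
#' observed summary vector in normalized Euclidean distance (per-statistic
#' scale factors from the table); distance ties break by row index.
#'
#' @param table a [build_reference_table()] result.
#' @param observed a named [summary_vector()] over the table's statistics.
#' @param tolerance retained fraction in (0, 1\].
#' @return list with `index` (retained row indices), `distance` (their
#'   distances, ascending) and `dmax`.
#' @export
rejection <- function(table, observed, tolerance = 0.01) {
  stopifnot(tolerance > 0, tolerance <= 1)
  D <- normalized_deviations(table, observed)
  d <- sqrt(rowSums(D^2))
  k <- ceiling(tolerance * length(d))
  ord <- order(d, seq_along(d))[seq_len(k)]
  list(index = ord, distance = d[ord], dmax = d[ord[k]])
}

#' Scenario posterior probabilities
#'
#' Model choice works in discriminant coordinates: the normalized summary
#' deviations of the whole reference table are projected onto their linear
#' discriminant axes (at most scenarios - 1 of them), the closest
#' `tolerance` fraction of rows to the observed data is retained by
#' Euclidean distance in that space, and a multinomial logistic regression
#' of the scenario label on the discriminant scores (Epanechnikov distance
#' weights, small ridge via weight decay) is evaluated at the observed
#' point. The projection discards within-class summary variation that
#' carries no information about the scenario label, so the observation sits
#' inside the retained cloud and the logit interpolates instead of
#' extrapolating — with the full high-dimensional summary vector, no
#' simulation is close to the data and a logit evaluated there is
#' unstable. The direct estimate (scenario composition of the retained
#' set) is always reported alongside; it is also the fallback, flagged,
#' when the regression is degenerate or fails.
#'
#' @inheritParams rejection
#' @return list: `prob` (primary probabilities, sum 1), `direct`,
#'   `logistic`, `chosen` (ties toward the scenario with fewer parameters),
#'   `degenerate`, `fallback`, `retained` (`index`, `distance` in
#'   discriminant coordinates).
#' @export
scenario_posteriors <- function(table, observed, tolerance = 0.01) {
  stopifnot(tolerance > 0, tolerance <= 1)
  all_names <- vapply(table$scenarios, function(s) s$name, "")
  D <- normalized_deviations(table, observed)
  lab_full <- factor(table$draws$scenario, levels = all_names)
  proj <- tryCatch(lda_project(D, lab_full), error = function(e) NULL)
  if (is.null(proj)) { # e.g. a single-scenario table
    S <- D
  } else {
    S <- proj$scores
  }
  d <- sqrt(rowSums(S^2))
  k <- ceiling(tolerance * length(d))
  ord <- order(d, seq_along(d))[seq_len(k)]
  rej <- list(index = ord, distance = d[ord], dmax = d[ord[k]])
  lab <- lab_full[ord]
  direct <- as.numeric(table(lab)) / length(lab)
  names(direct) <- all_names
  degenerate <- length(unique(as.character(lab))) < 2L
  fallback <- FALSE
  logistic <- direct
  if (!degenerate && !is.null(proj)) {
    w <- epanechnikov(rej$distance, rej$dmax)
    pr <- tryCatch({
      df <- as.data.frame(S[ord, , drop = FALSE])
      df$.scenario <- droplevels(lab)
      fit <- nnet::multinom(.scenario ~ ., data = df, weights = w,
                            decay = 1e-6, trace = FALSE, maxit = 500)
      nd <- as.data.frame(matrix(0, 1, ncol(S),
                                 dimnames = list(NULL, colnames(S))))
      p <- predict(fit, newdata = nd, type = "probs")
      lev <- levels(df$.scenario)
      if (length(lev) == 2L) stats::setNames(c(1 - p, p), lev)
      else stats::setNames(as.numeric(p), lev)
    }, error = function(e) NULL)
    if (is.null(pr)) {
      fallback <- TRUE
    } else {
      logistic <- stats::setNames(rep(0, length(all_names)), all_names)
      logistic[names(pr)] <- pr
      logistic <- logistic / sum(logistic)
    }
  }
  prob <- if (fallback || degenerate) direct else logistic
  ord2 <- order(-prob, vapply(table$scenarios[all_names], n_parameters, 0L))
  list(prob = prob, direct = direct, logistic = logistic,
       chosen = all_names[ord2[1]], degenerate = degenerate,
       fallback = fallback, retained = rej)
}

# Fisher discriminant axes of the retained deviations; `origin` is the
# projection of deviation zero (the observed data) in the same coordinates
lda_project <- function(X, lab) {
  # drop constant columns so the within-class covariance is invertible
  keep <- apply(X, 2, function(x) stats::sd(x) > 1e-12)
  X <- X[, keep, drop = FALSE]
  fit <- MASS::lda(X, grouping = lab)
  sc <- X %*% fit$scaling
  colnames(sc) <- paste0("LD", seq_len(ncol(sc)))
  orig <- matrix(0, 1, ncol(X)) %*% fit$scaling
  colnames(orig) <- colnames(sc)
  list(scores = sc, origin = orig)
}

epanechnikov <- function(d, dmax) {
  if (dmax <= 0) return(rep(1, length(d)))
  w <- 1 - (d / dmax)^2
  pmax(w, 1e-8) # the boundary particle keeps a vanishing positive weight
}

#' Local-linear regression adjustment of parameter posteriors
#'
#' Beaumont-style adjustment: the chosen scenario's retained parameter draws
#' are logit-transformed onto their prior bounds, regressed on the
#' normalized summary deviations with Epanechnikov kernel weights in
#' distance, residual-corrected to deviation zero, and back-transformed —
#' so adjusted values always stay inside the prior bounds. If fewer rows
#' than summaries + 2 are retained the adjustment is skipped (flagged).
#'
#' The retained count is floored at `min_per_covariate` rows per summary
#' statistic (when the scenario has that many rows): a local-linear fit
#' with barely more rows than covariates overfits, which shrinks the
#' residual spread and produces spuriously narrow posterior intervals.
#' Fifteen observations per covariate is the usual regression rule of
#' thumb.
#'
#' @param table a [build_reference_table()] result.
#' @param observed a named [summary_vector()].
#' @param scenario scenario name whose parameters are estimated.
#' @param tolerance retained fraction of that scenario's rows.
#' @param adjust set `FALSE` to return the plain rejection sample.
#' @param min_per_covariate minimum retained rows per summary statistic
#'   used by the regression.
#' @return list: `samples` (data.frame of adjusted draws), `weights`,
#'   `unadjusted`, `adjusted` (logical flag), `bounds`.
#' @export
adjust_parameters <- function(table, observed, scenario, tolerance = 0.01,
                              adjust = TRUE, min_per_covariate = 15L) {
  sc <- table$scenarios[[scenario]]
  if (is.null(sc)) stop("scenario '", scenario, "' not in reference table")
  rows <- which(table$draws$scenario == scenario)
  if (length(rows) < 30) stop("fewer than 30 reference rows for ", scenario)
  D <- normalized_deviations(table, observed, rows)
  d <- sqrt(rowSums(D^2))
  k <- ceiling(tolerance * length(rows))
  if (adjust)
    k <- max(k, min(length(rows), min_per_covariate * ncol(D)))
  ord <- order(d, seq_along(d))[seq_len(k)]
  keep <- rows[ord]
  dk <- d[ord]
  w <- epanechnikov(dk, dk[k])
  pnames <- c(sc$ne_params, sc$time_params)
  theta <- as.matrix(table$draws[keep, pnames, drop = FALSE])
  bounds <- param_bounds(sc)
  X <- D[ord, , drop = FALSE]
  did_adjust <- FALSE
  if (adjust && k >= ncol(X) + 2) {
    Z <- theta
    for (j in seq_along(pnames)) {
      b <- bounds[[pnames[j]]]
      Z[, j] <- logit_bounded(theta[, j], b[1], b[2])
    }
    fit <- stats::lm.wfit(cbind(1, X), Z, w)
    B <- as.matrix(fit$coefficients)[-1, , drop = FALSE]
    B[is.na(B)] <- 0
    Zadj <- Z - X %*% B
    for (j in seq_along(pnames)) {
      b <- bounds[[pnames[j]]]
      theta[, j] <- inv_logit_bounded(Zadj[, j], b[1], b[2])
    }
    did_adjust <- TRUE
  }
  list(samples = as.data.frame(theta),
       unadjusted = as.data.frame(table$draws[keep, pnames, drop = FALSE]),
       weights = w, adjusted = did_adjust, bounds = bounds,
       index = keep, distance = dk)
}

logit_bounded <- function(x, lo, hi) {
  eps <- 1e-9 * (hi - lo)
  x <- pmin(pmax(x, lo + eps), hi - eps)
  log((x - lo) / (hi - x))
}

inv_logit_bounded <- function(z, lo, hi) lo + (hi - lo) / (1 + exp(-z))

#' Weighted posterior summary (median and 95% interval)
#'
#' Weighted quantiles by linear interpolation of the weighted empirical CDF;
#' with equal weights this reduces exactly to R's type-7 quantiles.
#'
#' @param samples numeric vector of posterior draws.
#' @param weights optional nonnegative weights.
#' @param probs quantiles to report.
#' @return named vector `median`, `q025`, `q975` (or the requested probs).
#' @export
posterior_summary <- function(samples, weights = NULL,
                              probs = c(0.5, 0.025, 0.975)) {
  q <- wquantile(samples, weights, probs)
  stats::setNames(q, c("median", "q025", "q975")[seq_along(probs)])
}

wquantile <- function(x, w = NULL, probs) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x), all(w >= 0), sum(w) > 0)
  if (length(x) == 1L) return(rep(x, length(probs)))
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  p <- (cw - w) / (cw[length(cw)] - w[length(w)])
  stats::approx(p, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Is a posterior effectively flat across its prior?
#'
#' Reports "not estimable" when the central 95% interval covers more than
#' 90% of the prior range — the behaviour seen when the data carry no
#' information on an event time.
#'
#' @param summary a [posterior_summary()] result.
#' @param bounds the parameter's prior bounds.
#' @export
is_flat_posterior <- function(summary, bounds) {
  unname((summary["q975"] - summary["q025"]) > 0.9 * (bounds[2] - bounds[1]))
}

#' Percent change in Ne, as reported in result tables
#'
#' Declines are reported as the percent lost,
#' `trunc(100 * (1 - after/before))`; increases as the percent ratio,
#' `trunc(100 * after/before)`; both truncated toward zero.
#'
#' @param n_before,n_after Ne before and after the change (before > 0).
#' @return integer percent.
#' @export
percent_change <- function(n_before, n_after) {
  stopifnot(n_before > 0)
  if (n_after <= n_before) as.integer(trunc(100 * (1 - n_after / n_before)))
  else as.integer(trunc(100 * n_after / n_before))
}

# Ne-change reporting per scenario: list of (label, before, after) parameter
# name pairs used for the percent-change column
change_pairs <- function(scenario_name) {
  switch(scenario_name,
    constant = list(),
    increasing = list(c("N_anc", "N_cur")),
    bottleneck = list(c("N_pre", "N_post")),
    fluctuating = list(c("N_anc", "N_hist"), c("N_hist", "N_pres")),
    stop("unknown scenario"))
}

#' Full ABC analysis of one observed summary vector
#'
#' Scenario choice (rejection + logistic regression) followed by
#' local-linear-adjusted parameter posteriors under the chosen scenario,
#' with medians, 0.025/0.975 quantiles, percent change in Ne and timing
#' estimability.
#'
#' @inheritParams rejection
#' @return object of class `abc_result`.
#' @export
abc_analysis <- function(table, observed, tolerance = 0.01) {
  post <- scenario_posteriors(table, observed, tolerance)
  sc <- table$scenarios[[post$chosen]]
  adj <- adjust_parameters(table, observed, post$chosen, tolerance)
  pnames <- c(sc$ne_params, sc$time_params)
  summaries <- lapply(stats::setNames(pnames, pnames), function(p)
    posterior_summary(adj$samples[[p]], adj$weights))
  flat <- vapply(sc$time_params, function(p)
    is_flat_posterior(summaries[[p]], adj$bounds[[p]]), TRUE)
  changes <- lapply(change_pairs(sc$template), function(pr) {
    list(from = pr[1], to = pr[2],
         percent = percent_change(summaries[[pr[1]]]["median"],
                                  summaries[[pr[2]]]["median"]))
  })
  structure(list(posteriors = post, chosen = post$chosen,
                 parameters = summaries, samples = adj$samples,
                 weights = adj$weights, adjusted = adj$adjusted,
                 changes = changes, timing_flat = flat,
                 tolerance = tolerance),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat("abc_result: best-fit scenario =", x$chosen,
      sprintf("(p.pr. = %.2f)\n", x$posteriors$prob[x$chosen]))
  for (p in names(x$parameters)) {
    s <- x$parameters[[p]]
    cat(sprintf("  %-8s median %.4g  [%.4g, %.4g]%s\n", p, s["median"],
                s["q025"], s["q975"],
                if (isTRUE(x$timing_flat[p])) "  (not estimable)" else ""))
  }
  for (ch in x$changes)
    cat(sprintf("  change %s -> %s: %d%%\n", ch$from, ch$to, ch$percent))
  invisible(x)
}

#' Persist a reference table as TSV plus a JSON sidecar
#'
#' @param table a `reference_table`.
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @export
save_reference_table <- function(table, prefix) {
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  df <- cbind(table$draws, as.data.frame(table$sumstats))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  pr0 <- table$scenarios[[1]]$prior
  meta <- list(
    stat_names = colnames(table$sumstats),
    scale = as.list(table$scale),
    scenario_names = vapply(table$scenarios, function(s) s$name, ""),
    scenario_templates = vapply(table$scenarios, function(s) s$template, ""),
    prior = pr0[c("ne_bounds", "recent_time_bounds", "ancient_time_bounds",
                  "mu_mean_bounds", "mu_shape", "gsm_p_bounds")],
    config = unclass(table$config),
    model = table$model[c("mu_mean", "gsm_p", "shape", "state_bounds")])
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Load a reference table saved by [save_reference_table()]
#' @param prefix path prefix used when saving.
#' @export
load_reference_table <- function(prefix) {
  df <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  stat_names <- meta$stat_names
  sumstats <- as.matrix(df[stat_names])
  draws <- df[setdiff(names(df), stat_names)]
  prior <- do.call(prior_spec, meta$prior)
  scen <- mapply(function(tp, lb) make_scenario(tp, prior, label = lb),
                 meta$scenario_templates, meta$scenario_names,
                 SIMPLIFY = FALSE)
  names(scen) <- meta$scenario_names
  cfg <- sample_config(meta$config$offsets, meta$config$n_diploids,
                       meta$config$n_loci, meta$config$founder,
                       meta$config$state_bounds)
  mod <- mutation_model(meta$model$mu_mean, meta$model$gsm_p,
                        shape = meta$model$shape,
                        state_bounds = meta$model$state_bounds)
  structure(list(draws = draws, sumstats = sumstats,
                 scale = unlist(meta$scale)[stat_names], config = cfg,
                 model = mod, scenarios = scen),
            class = "reference_table")
}
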