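#' Run configuration for the end-to-end pipeline
#'
#' A fully serializable description of one analysis run: inputs, study
#' configuration, scenario priors, ABC settings and seed. A run's config +
#' seed reproduce its outputs.
#'
#' @param genepop path to the GenePop input (ignored by `cmd_*` calls fed an
#'   in-memory dataset).
#' @param dates collection dates (`"YYYY-MM"`), one per POP block, oldest
#'   first.
#' @param generations_per_year calendar-to-generation conversion.
#' @param scenarios scenario names to compare.
#' @param prior a [prior_spec()].
#' @param n_per_scenario simulations per scenario for the reference table.
#' @param tolerance retained fraction.
#' @param n_pods PODs per scenario for error estimation.
#' @param seed integer seed for all stochastic stages.
#' @param outdir output directory.
#' @param founder,state_bounds simulator allele-state settings.
#' @param mu_shape per-locus mutation-rate Gamma shape.
#' @param exclude_loci locus names dropped on import.
#' @export
run_config <- function(genepop = NULL, dates = NULL,
                       generations_per_year = 24,
                       scenarios = c("constant", "increasing", "bottleneck",
                                     "fluctuating"),
                       prior = prior_spec(), n_per_scenario = 10000,
                       tolerance = 0.01, n_pods = 100, seed = 1L,
                       outdir = "serialabc_out", founder = 20,
                       state_bounds = c(1, 40), mu_shape = 2,
                       exclude_loci = character()) {
  structure(list(genepop = genepop, dates = dates,
                 generations_per_year = generations_per_year,
                 scenarios = scenarios, prior = prior,
                 n_per_scenario = n_per_scenario, tolerance = tolerance,
                 n_pods = n_pods, seed = as.integer(seed), outdir = outdir,
                 founder = founder, state_bounds = state_bounds,
                 mu_shape = mu_shape, exclude_loci = exclude_loci),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file mirroring the [run_config()] fields; prior bounds
#'   under a `prior:` block.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pr <- if (is.null(y$prior)) prior_spec() else do.call(prior_spec, y$prior)
  y$prior <- pr
  do.call(run_config, y[names(y) %in% names(formals(run_config))])
}

write_run_config <- function(config, path) {
  out <- unclass(config)
  out$prior <- unclass(out$prior)
  yaml::write_yaml(out, path)
  invisible(path)
}

load_input_dataset <- function(config) {
  ds <- read_genepop(config$genepop)
  ds <- drop_loci(ds, config$exclude_loci)
  if (!is.null(config$dates)) ds <- set_sample_dates(ds, config$dates)
  assign_generations(ds, study_config(config$generations_per_year))
}

prepare_outdir <- function(config, stage) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(config$outdir,
                                     paste0(stage, "_config.yaml")))
}

#' Diversity-trend stage: per-time-point statistics and paired tests
#'
#' Reads the GenePop input, computes per-time-point mean heterozygosity,
#' rarefied allelic richness and effective allele number with standard
#' errors, and paired-t P values comparing the earliest time point with the
#' second and the latest. Writes `trends.tsv` to the output directory.
#'
#' @param config a [run_config()].
#' @param dataset optional in-memory [genotype_dataset()] overriding the
#'   config's input path.
#' @return the trend data.frame, invisibly written as TSV.
#' @export
cmd_sumstats <- function(config, dataset = NULL) {
  set.seed(config$seed)
  if (is.null(dataset)) dataset <- load_input_dataset(config)
  tr <- trend_report(dataset)
  if (length(dataset$samples) < 2)
    message("fewer than 2 time points: paired comparisons omitted")
  prepare_outdir(config, "sumstats")
  utils::write.table(tr, file.path(config$outdir, "trends.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr
}

#' Build (or reuse) the reference table for a config
#'
#' @inheritParams cmd_sumstats
#' @param cache optional path prefix: when the cached table exists it is
#'   loaded instead of re-simulated, otherwise the fresh table is saved
#'   there.
#' @export
cmd_simulate_reference <- function(config, dataset = NULL, cache = NULL) {
  if (!is.null(cache) && file.exists(paste0(cache, ".tsv")))
    return(load_reference_table(cache))
  set.seed(config$seed)
  if (is.null(dataset)) dataset <- load_input_dataset(config)
  cfg <- sample_config(generation_offsets(dataset),
                       vapply(dataset$genotypes, function(g) dim(g)[1], 0L),
                       length(dataset$loci), config$founder,
                       config$state_bounds)
  scen <- lapply(config$scenarios, make_scenario, prior = config$prior)
  names(scen) <- config$scenarios
  model <- mutation_model(mean(config$prior$mu_mean_bounds),
                          mean(config$prior$gsm_p_bounds),
                          shape = config$mu_shape,
                          state_bounds = config$state_bounds)
  tab <- build_reference_table(scen, config$n_per_scenario, cfg, model)
  if (!is.null(cache)) save_reference_table(tab, cache)
  tab
}

#' Inference stage: scenario choice and parameter posteriors
#'
#' Builds (or loads) the reference table, runs rejection + logistic scenario
#' choice and local-linear parameter adjustment under the chosen scenario,
#' and writes `abc_result.json` plus a result-table-shaped `abc_result.tsv`
#' (scenario, posterior probability, Ne medians with 0.025/0.975 quantiles,
#' timing, percent change).
#'
#' @inheritParams cmd_simulate_reference
#' @param table optional pre-built [build_reference_table()] result.
#' @export
cmd_infer <- function(config, dataset = NULL, table = NULL, cache = NULL) {
  if (is.null(dataset)) dataset <- load_input_dataset(config)
  if (is.null(table)) table <- cmd_simulate_reference(config, dataset, cache)
  set.seed(config$seed + 1L)
  obs <- summary_vector(dataset)
  res <- abc_analysis(table, obs, config$tolerance)
  prepare_outdir(config, "infer")
  sink <- file.path(config$outdir, "abc_result.json")
  jsonlite::write_json(abc_result_json(res), sink, auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(abc_result_table(res),
                     file.path(config$outdir, "abc_result.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res
}

abc_result_json <- function(res) {
  list(chosen = res$chosen,
       posterior_probability = as.list(res$posteriors$prob),
       direct_probability = as.list(res$posteriors$direct),
       adjusted = res$adjusted,
       parameters = lapply(res$parameters, as.list),
       timing_flat = as.list(res$timing_flat),
       changes = lapply(res$changes, function(ch)
         list(from = ch$from, to = ch$to, percent = ch$percent)),
       tolerance = res$tolerance)
}

abc_result_table <- function(res) {
  rows <- lapply(names(res$parameters), function(p) {
    s <- res$parameters[[p]]
    data.frame(scenario = res$chosen,
               posterior_probability = unname(res$posteriors$prob[res$chosen]),
               parameter = p, median = unname(s["median"]),
               q025 = unname(s["q025"]), q975 = unname(s["q975"]),
               not_estimable = isTRUE(res$timing_flat[p]))
  })
  out <- do.call(rbind, rows)
  for (ch in res$changes)
    out$change_percent[out$parameter == ch$to] <- ch$percent
  out
}

#' Confidence stage: scenario-choice error rates
#'
#' Wraps [run_pods()] and writes `confusion.tsv` in the true-by-inferred
#' layout with per-scenario type I and pooled type II error estimates.
#'
#' @inheritParams cmd_infer
#' @export
cmd_confidence <- function(config, dataset = NULL, table = NULL,
                           cache = NULL) {
  if (is.null(table)) table <- cmd_simulate_reference(config, dataset, cache)
  set.seed(config$seed + 2L)
  cm <- run_pods(table, config$n_pods, config$tolerance)
  prepare_outdir(config, "confidence")
  write_confusion_tsv(cm, file.path(config$outdir, "confusion.tsv"))
  cm
}

#' Synthetic-study stage: emit a template dataset + truth sidecar
#'
#' @param config a [run_config()]; `outdir` receives `<name>.gen` and
#'   `<name>_truth.json`.
#' @param name a [study_template_names()] entry.
#' @param seed template seed (defaults to the config seed).
#' @export
cmd_synth <- function(config, name, seed = config$seed) {
  tpl <- study_template(name, seed = seed)
  st <- generate_study(tpl)
  prepare_outdir(config, "synth")
  write_genepop(st$dataset, file.path(config$outdir, paste0(name, ".gen")))
  write_truth(st$truth, file.path(config$outdir,
                                  paste0(name, "_truth.json")))
  invisible(st)
}
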