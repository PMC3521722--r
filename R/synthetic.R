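#' Study-like synthetic dataset templates
#'
#' Ground-truth generators that emulate the temporal-sampling designs of the
#' nine mosquito populations analysed in the study system this package
#' targets: sampling dates and sizes follow the published design tables, and
#' the "truth" demographic parameters are the published posterior medians,
#' so every pipeline stage can be exercised end to end without any external
#' download. The generated data are synthetic — coalescent simulations under
#' the truth — not the real genotypes.
#'
#' @param name preset name; see [study_template_names()] (e.g.
#'   `"punta_europa"`, `"ukomba"`, `"tiko"`).
#' @param seed RNG seed stored in the template.
#' @return object of class `study_template`.
#' @export
study_template <- function(name, seed = 1L) {
  if (!name %in% names(study_presets))
    stop("unknown template '", name, "'; available: ",
         paste(names(study_presets), collapse = ", "))
  p <- study_presets[[name]]
  make_study_template(label = name, dates = p$dates, sizes = p$sizes,
                      n_loci = p$n_loci, truth = p$truth, seed = seed)
}

#' Build a custom study template
#'
#' @param label template label.
#' @param dates character vector of `"YYYY-MM"` collection dates (oldest
#'   first; must span at most 7 years).
#' @param sizes diploid sample sizes, each within the study's 32-119 range.
#' @param n_loci number of microsatellite loci (12-17 in the study designs;
#'   11 in the negative controls).
#' @param truth list with `scenario` (name) and its parameter values; must
#'   satisfy the scenario's ordering constraints.
#' @param generations_per_year calendar-to-generation conversion (24).
#' @param mu_mean,gsm_p,shape mutation-model truth values.
#' @param seed RNG seed.
#' @export
make_study_template <- function(label, dates, sizes, n_loci, truth,
                                generations_per_year = 24, mu_mean = 5e-4,
                                gsm_p = 0.22, shape = 2, seed = 1L) {
  stopifnot(length(dates) == length(sizes), length(dates) >= 1)
  d <- lapply(dates, parse_ym)
  fr <- vapply(d, ym_frac, 0)
  if (diff(range(fr)) > 7) stop("sampling dates must span at most 7 years")
  if (any(sizes < 32 | sizes > 119))
    stop("diploid sample sizes must lie in 32-119")
  sc <- make_scenario(truth$scenario)
  pars <- unlist(truth[c(sc$ne_params, sc$time_params)])
  if (anyNA(pars)) stop("truth is missing scenario parameters")
  if (!sc$constraint(as.list(pars)))
    stop("truth violates the ", truth$scenario, " ordering constraints")
  structure(list(label = label, dates = dates, sizes = as.integer(sizes),
                 n_loci = as.integer(n_loci), truth = truth,
                 generations_per_year = generations_per_year,
                 mu_mean = mu_mean, gsm_p = gsm_p, shape = shape,
                 seed = as.integer(seed)),
            class = "study_template")
}

# sampling designs from the study's design table; truths from its posterior
# medians (bottleneck/fluctuating/increasing) — all synthetic stand-ins
study_presets <- list(
  punta_europa = list(
    dates = c("2004-04", "2006-09", "2007-08", "2010-04"),
    sizes = c(119, 63, 78, 94), n_loci = 13,
    truth = list(scenario = "bottleneck", N_pre = 15700, N_post = 3230,
                 t = 314)),
  ukomba = list(
    dates = c("2007-03", "2009-05", "2010-02"), sizes = c(78, 46, 95),
    n_loci = 14,
    truth = list(scenario = "fluctuating", N_anc = 938, N_hist = 13000,
                 N_pres = 2570, t1 = 958, t2 = 74)),
  mongomo = list(
    dates = c("2007-02", "2009-04", "2010-05"), sizes = c(83, 56, 53),
    n_loci = 13,
    truth = list(scenario = "bottleneck", N_pre = 1770, N_post = 750,
                 t = 57)),
  yengue = list(
    dates = c("2007-02", "2009-05", "2010-05"), sizes = c(62, 92, 32),
    n_loci = 16,
    truth = list(scenario = "bottleneck", N_pre = 13200, N_post = 1900,
                 t = 88)),
  niefang = list(
    dates = c("2007-05", "2009-08"), sizes = c(48, 34), n_loci = 13,
    truth = list(scenario = "bottleneck", N_pre = 10300, N_post = 4600,
                 t = 80)),
  arena_blanca = list(
    dates = c("2009-04", "2010-09"), sizes = c(89, 68), n_loci = 13,
    truth = list(scenario = "bottleneck", N_pre = 1090, N_post = 261,
                 t = 61)),
  cogo = list(
    dates = c("2007-04", "2007-11", "2010-06"), sizes = c(70, 76, 50),
    n_loci = 12,
    truth = list(scenario = "increasing", N_anc = 1510, N_cur = 17100,
                 t = 2500)),
  tiko = list(
    dates = c("2003-09", "2006-08"), sizes = c(52, 52), n_loci = 11,
    truth = list(scenario = "increasing", N_anc = 1458, N_cur = 5102,
                 t = 4120)),
  fanzana = list(
    dates = c("2002-08", "2006-09"), sizes = c(43, 89), n_loci = 11,
    truth = list(scenario = "increasing", N_anc = 15700, N_cur = 18560,
                 t = 1250)))

#' Names of the shipped study templates
#' @export
study_template_names <- function() names(study_presets)

template_offsets <- function(template) {
  fr <- vapply(lapply(template$dates, parse_ym), ym_frac, 0)
  as.integer(round(template$generations_per_year * (max(fr) - fr)))
}

template_config <- function(template, founder = 20, state_bounds = c(1, 40)) {
  sample_config(template_offsets(template), template$sizes,
                template$n_loci, founder, state_bounds)
}

#' Generate a synthetic study dataset with known truth
#'
#' Converts the template's calendar dates to generation offsets, simulates a
#' temporal genotype dataset under the truth demography via the serial
#' coalescent, and returns the dataset together with a serializable truth
#' record for recovery scoring. Deterministic given the template seed.
#'
#' @param template a [study_template()] / [make_study_template()] object.
#' @return list with `dataset` (a [genotype_dataset()] carrying dates and
#'   offsets) and `truth`.
#' @export
generate_study <- function(template) {
  set.seed(template$seed)
  cfg <- template_config(template)
  draw <- c(list(scenario = template$truth$scenario),
            template$truth[setdiff(names(template$truth), "scenario")],
            list(mu_mean = template$mu_mean, gsm_p = template$gsm_p))
  rates <- draw_locus_rates(template$mu_mean, template$n_loci,
                            template$shape)
  model <- mutation_model(template$mu_mean, template$gsm_p,
                          locus_rates = rates, shape = template$shape)
  ds <- simulate_dataset(draw, cfg, model)
  for (i in seq_along(ds$samples)) {
    ds$samples[[i]]$label <- paste0(template$label, "_", template$dates[i])
    ds$samples[[i]]$date <- parse_ym(template$dates[i])
  }
  truth <- list(label = template$label, scenario = template$truth$scenario,
                params = template$truth[setdiff(names(template$truth),
                                                "scenario")],
                mu_mean = template$mu_mean, gsm_p = template$gsm_p,
                shape = template$shape, locus_rates = rates,
                generations_per_year = template$generations_per_year,
                offsets = cfg$offsets, sizes = template$sizes,
                n_loci = template$n_loci, seed = template$seed)
  list(dataset = ds, truth = truth)
}

#' Generate a negative-control dataset (no bottleneck truth)
#'
#' As [generate_study()], restricted to `constant` or `increasing` truths —
#' the demographies of populations never exposed to vector control.
#'
#' @inheritParams generate_study
#' @export
generate_negative_control <- function(template) {
  if (!template$truth$scenario %in% c("constant", "increasing"))
    stop("negative controls must have constant or increasing truth, got ",
         template$truth$scenario)
  generate_study(template)
}

#' Write / read a truth record as JSON
#' @param truth a truth record from [generate_study()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path)
  jsonlite::read_json(path, simplifyVector = TRUE)
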