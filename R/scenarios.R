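#' Uniform prior specification for demographic scenarios
#'
#' All demographic parameters get independent uniform priors: effective
#' sizes on `ne_bounds` (diploid individuals); event times (integer
#' generations before the most recent sample) on one of two ranges
#' depending on the role of the event. Recent events — the bottleneck time
#' `t` and the fluctuating scenario's decline time `t2`, i.e. the changes
#' an intervention-era study interrogates — draw from
#' `recent_time_bounds`; ancient events — the expansion times of the
#' increasing (`t`) and fluctuating (`t1`) scenarios — draw from
#' `ancient_time_bounds`. Structuring the time priors by event role mirrors
#' how such analyses are set up per population: the recent range brackets
#' the monitored era, the ancient range reaches thousands of generations
#' back so long-term growth remains distinguishable from a recent decline.
#' The microsatellite mutation model gets a mean rate prior on
#' `mu_mean_bounds` (per locus per generation), a per-locus Gamma
#' dispersion (`mu_shape`; `Inf` means all loci share the mean rate) and a
#' geometric step-size parameter prior on `gsm_p_bounds` (0 = strict
#' single-step mutation).
#'
#' @param ne_bounds,recent_time_bounds,ancient_time_bounds,mu_mean_bounds,gsm_p_bounds
#'   numeric length-2 lower/upper bounds.
#' @param mu_shape Gamma shape for per-locus rate variation around the mean.
#' @export
prior_spec <- function(ne_bounds = c(10, 1e5),
                       recent_time_bounds = c(1, 500),
                       ancient_time_bounds = c(500, 5000),
                       mu_mean_bounds = c(1e-4, 1e-3), mu_shape = 2,
                       gsm_p_bounds = c(0.1, 0.3)) {
  chk <- function(b, nm, lo = -Inf, hi = Inf) {
    if (length(b) != 2 || !(b[1] <= b[2])) stop("bad bounds for ", nm)
    if (b[1] < lo || b[2] > hi) stop(nm, " bounds outside allowed range")
  }
  chk(ne_bounds, "ne")
  chk(recent_time_bounds, "recent_time")
  chk(ancient_time_bounds, "ancient_time")
  chk(mu_mean_bounds, "mu_mean", 0, 1e-2)
  chk(gsm_p_bounds, "gsm_p", 0, 1)
  structure(list(ne_bounds = ne_bounds,
                 recent_time_bounds = recent_time_bounds,
                 ancient_time_bounds = ancient_time_bounds,
                 mu_mean_bounds = mu_mean_bounds, mu_shape = mu_shape,
                 gsm_p_bounds = gsm_p_bounds),
            class = "prior_spec")
}

scenario_defs <- list(
  constant = list(
    ne = "N_cur", times = character(), time_class = character(),
    constraint = function(p) TRUE),
  increasing = list(
    ne = c("N_anc", "N_cur"), times = "t", time_class = "ancient",
    constraint = function(p) p[["N_anc"]] < p[["N_cur"]]),
  bottleneck = list(
    ne = c("N_pre", "N_post"), times = "t", time_class = "recent",
    constraint = function(p) p[["N_post"]] < p[["N_pre"]]),
  fluctuating = list(
    ne = c("N_anc", "N_hist", "N_pres"), times = c("t1", "t2"),
    time_class = c("ancient", "recent"),
    constraint = function(p) p[["N_hist"]] > p[["N_anc"]] &&
      p[["N_hist"]] > p[["N_pres"]] && p[["t1"]] > p[["t2"]]))

#' Demographic scenario templates
#'
#' The four competing piecewise-constant Ne histories fitted to each
#' population:
#' * `constant` — one Ne throughout (`N_cur`).
#' * `increasing` — ancestral `N_anc` grows to `N_cur` at time `t`
#'   (`N_anc < N_cur`).
#' * `bottleneck` — pre-change `N_pre` drops to `N_post` at time `t`
#'   (`N_post < N_pre`), the signature expected when vector control
#'   suppresses a population.
#' * `fluctuating` — expansion then decline: ancestral `N_anc` to a larger
#'   historical `N_hist` at `t1`, then down to `N_pres` at `t2`
#'   (`t1 > t2`, `N_hist > N_anc`, `N_hist > N_pres`).
#'
#' Times are integer generations before the most recent sample.
#'
#' @param name one of `"constant"`, `"increasing"`, `"bottleneck"`,
#'   `"fluctuating"`.
#' @param prior a [prior_spec()].
#' @param label display label for the scenario (defaults to `name`); lets
#'   two variants of the same template (e.g. different priors) compete in
#'   one analysis.
#' @return object of class `demographic_scenario` with fields `name`
#'   (label), `template`, `ne_params`, `time_params`, `constraint` and
#'   `prior`.
#' @export
make_scenario <- function(name, prior = prior_spec(), label = name) {
  if (!name %in% names(scenario_defs))
    stop("unknown scenario '", name, "'; expected one of: ",
         paste(names(scenario_defs), collapse = ", "))
  def <- scenario_defs[[name]]
  structure(list(name = label, template = name, ne_params = def$ne,
                 time_params = def$times, time_class = def$time_class,
                 constraint = def$constraint, prior = prior),
            class = "demographic_scenario")
}

# trajectory for one draw row of a given scenario (draw rows carry the
# scenario label; the trajectory shape comes from the template)
draw_trajectory <- function(scenario, draw) {
  p <- as.list(draw)
  p$scenario <- scenario$template
  to_trajectory(p)
}

#' Number of demographic parameters of a scenario
#' @param scenario a `demographic_scenario`.
#' @export
n_parameters <- function(scenario)
  length(scenario$ne_params) + length(scenario$time_params)

# uniform bounds for every parameter of a scenario (demography + mutation)
param_bounds <- function(scenario) {
  pr <- scenario$prior
  tb <- lapply(scenario$time_class, function(cl)
    if (cl == "recent") pr$recent_time_bounds else pr$ancient_time_bounds)
  c(stats::setNames(rep(list(pr$ne_bounds), length(scenario$ne_params)),
                    scenario$ne_params),
    stats::setNames(tb, scenario$time_params))
}

#' Draw parameter values from a scenario's priors
#'
#' Ne values are uniform on the prior bounds; event times are uniform
#' integers >= 1. Ordering constraints are enforced by resampling until
#' acceptance, which preserves the uniform marginals conditional on the
#' constraint. Mutation parameters (mean rate, geometric step parameter) are
#' drawn alongside. Uses R's global RNG; call `set.seed()` for
#' reproducibility.
#'
#' @param scenario a [make_scenario()] object.
#' @param n number of draws.
#' @param max_tries abort if the constraint rejects this many candidate
#'   vectors in a row.
#' @return data.frame with one row per draw: scenario name, demographic
#'   parameters, `mu_mean`, `gsm_p`.
#' @export
sample_prior <- function(scenario, n = 1, max_tries = 1e5) {
  pr <- scenario$prior
  nn <- length(scenario$ne_params)
  nt <- length(scenario$time_params)
  tb <- lapply(scenario$time_class, function(cl)
    if (cl == "recent") pr$recent_time_bounds else pr$ancient_time_bounds)
  draw_block <- function(m) {
    ne <- matrix(stats::runif(m * nn, pr$ne_bounds[1], pr$ne_bounds[2]),
                 m, nn, dimnames = list(NULL, scenario$ne_params))
    tm <- if (nt > 0)
      vapply(seq_len(nt), function(j)
        floor(stats::runif(m, tb[[j]][1], tb[[j]][2] + 1)),
        numeric(m))
      else matrix(0, m, 0)
    if (nt > 0 && m == 1) tm <- matrix(tm, 1, nt)
    if (nt > 0) colnames(tm) <- scenario$time_params
    cbind(ne, tm)
  }
  out <- matrix(NA_real_, 0, nn + nt)
  tries <- 0L
  while (nrow(out) < n) {
    cand <- draw_block(max(n - nrow(out), 64L))
    ok <- apply(cand, 1, scenario$constraint)
    if (!any(ok)) {
      tries <- tries + nrow(cand)
      if (tries > max_tries)
        stop("prior constraint acceptance too low for scenario ",
             scenario$name)
    } else tries <- 0L
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  df <- as.data.frame(out)
  df$mu_mean <- stats::runif(n, pr$mu_mean_bounds[1], pr$mu_mean_bounds[2])
  df$gsm_p <- stats::runif(n, pr$gsm_p_bounds[1], pr$gsm_p_bounds[2])
  cbind(data.frame(scenario = scenario$name, stringsAsFactors = FALSE), df)
}

#' Piecewise-constant Ne trajectory of a parameter draw
#'
#' Converts a scenario draw into the step function Ne(g) over generations
#' before present, encoded as ascending epoch breakpoints plus one Ne per
#' epoch (the last epoch extends to infinity). Looking backwards: a
#' bottleneck at `t` means Ne(g) = `N_post` for g < t and `N_pre` for
#' g >= t.
#'
#' @param draw a one-row data.frame (or named list) from [sample_prior()],
#'   or a named list with `scenario` and the scenario's parameters.
#' @return object of class `ne_trajectory`: `list(breaks, N)`.
#' @export
to_trajectory <- function(draw) {
  p <- as.list(draw)
  traj <- switch(p$scenario,
    constant = list(breaks = numeric(), N = p$N_cur),
    increasing = list(breaks = p$t, N = c(p$N_cur, p$N_anc)),
    bottleneck = list(breaks = p$t, N = c(p$N_post, p$N_pre)),
    fluctuating = list(breaks = c(p$t2, p$t1),
                       N = c(p$N_pres, p$N_hist, p$N_anc)),
    stop("unknown scenario '", p$scenario, "'"))
  traj$breaks <- as.numeric(traj$breaks)
  traj$N <- as.numeric(traj$N)
  if (any(traj$N <= 0)) stop("nonpositive Ne in trajectory")
  structure(traj, class = "ne_trajectory")
}

#' Evaluate an Ne trajectory
#' @param trajectory an `ne_trajectory`.
#' @param g generations before present (vectorized, g >= 0).
#' @return Ne at each g (right-continuous step function, total on `[0,Inf)`).
#' @export
ne_at <- function(trajectory, g) {
  idx <- findInterval(g, trajectory$breaks) + 1L
  trajectory$N[idx]
}
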