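small_table <- function(n = 250, seed = 301) {
  set.seed(seed)
  cfg <- sample_config(c(48, 0), c(10, 10), 5)
  build_reference_table(two_scenarios(), n, cfg)
}

test_that("reference tables are balanced, scaled and re-normalizable", {
  tab <- small_table(120)
  expect_equal(nrow(tab$sumstats), 240)
  expect_equal(as.vector(table(tab$draws$scenario)), c(120, 120))
  expect_true(all(tab$scale > 0))
  # normalization idempotence: re-scaled statistics have MAD 1
  norm <- sweep(tab$sumstats, 2, tab$scale, "/")
  mads <- apply(norm, 2, mad)
  expect_equal(unname(mads[mads > 0]),
               rep(1, sum(mads > 0)), tolerance = 1e-12)
  expect_error(build_reference_table(two_scenarios(), 50,
                                     sample_config(0, 5, 2)), ">= 100")
})

test_that("rejection retains the closest rows, with brute-force agreement", {
  tab <- small_table(100)
  obs <- tab$sumstats[17, ]
  # a simulated row used as observation has distance zero and is retained
  rej <- rejection(tab, obs, tolerance = 0.01)
  expect_equal(rej$distance[1], 0)
  expect_true(17 %in% rej$index)
  # tolerance 1 keeps everything
  expect_length(rejection(tab, obs, 1)$index, 200)
  # brute-force distance oracle over the whole 200-row table
  d <- numeric(200)
  for (i in 1:200) {
    acc <- 0
    for (j in seq_along(obs))
      acc <- acc + ((tab$sumstats[i, j] - obs[j]) / tab$scale[j])^2
    d[i] <- sqrt(acc)
  }
  k <- ceiling(0.1 * 200)
  expect_equal(rejection(tab, obs, 0.1)$index,
               order(d, seq_along(d))[seq_len(k)])
  expect_error(rejection(tab, c(bogus = 1), 0.1), "statistics")
})

test_that("rejection is invariant to rescaling a statistic with its scale", {
  tab <- small_table(100, seed = 302)
  obs <- tab$sumstats[3, ] * 1.01
  r1 <- rejection(tab, obs, 0.05)
  tab2 <- tab
  tab2$sumstats[, "He_1"] <- tab2$sumstats[, "He_1"] * 37
  tab2$scale["He_1"] <- tab2$scale["He_1"] * 37
  obs2 <- obs
  obs2["He_1"] <- obs2["He_1"] * 37
  r2 <- rejection(tab2, obs2, 0.05)
  expect_equal(r1$index, r2$index)
})

test_that("scenario posteriors are a simplex and spot degenerate retention", {
  tab <- small_table(150, seed = 303)
  obs <- summaries_at_mean(tab)
  sp <- scenario_posteriors(tab, obs, 0.1)
  expect_equal(sum(sp$prob), 1, tolerance = 1e-9)
  expect_true(all(sp$prob >= 0))
  expect_equal(sum(sp$direct), 1, tolerance = 1e-9)

  # indistinguishable scenarios: same generating distribution under two
  # labels gives probabilities near 1/2
  set.seed(304)
  x <- rnorm(2000)
  tabf <- fake_table(runif(2000, -10, 10), cbind(x, rnorm(2000)),
                     c("s1", "s2"),
                     scenario = rep(c("constant", "increasing"), each = 1000))
  spf <- scenario_posteriors(tabf, c(s1 = 0, s2 = 0), 0.25)
  expect_lt(max(abs(spf$prob - 0.5)), 0.15)
  expect_lt(max(abs(spf$direct - 0.5)), 0.15)

  # single-scenario retention is flagged and gives probability one
  tabd <- fake_table(c(runif(500, -10, 10), runif(500, -10, 10)),
                     c(rnorm(500, 0, 0.1), rnorm(500, 100, 0.1)),
                     "s1", scenario = rep(c("constant", "increasing"),
                                          each = 500))
  spd <- scenario_posteriors(tabd, c(s1 = 0), 0.05)
  expect_true(spd$degenerate)
  expect_equal(unname(spd$prob["constant"]), 1)
})

test_that("well-separated scenarios are recovered with high posterior", {
  set.seed(305)
  cfg <- sample_config(0, 30, 30)
  scen <- list(
    small = make_scenario("constant", prior_spec(ne_bounds = c(50, 200)),
                          label = "small"),
    large = make_scenario("constant", prior_spec(ne_bounds = c(5e4, 2e5)),
                          label = "large"))
  tab <- build_reference_table(scen, 600, cfg)
  hits <- replicate(50, {
    ds <- simulate_dataset(list(scenario = "constant",
                                N_cur = runif(1, 5e4, 2e5),
                                mu_mean = 5e-4, gsm_p = 0.2), cfg)
    sp <- scenario_posteriors(tab, summary_vector(ds, fst_pairs = list()),
                              0.05)
    sp$chosen == "large" && sp$prob["large"] > 0.9
  })
  expect_gte(mean(hits), 0.9)
})

test_that("local-linear adjustment is a no-op at zero deviation and respects bounds", {
  # all simulated summaries equal the observation: regression has nothing to
  # correct, adjusted == unadjusted
  set.seed(306)
  theta <- runif(500, -10, 10)
  tab <- fake_table(theta, rep(1.7, 500), "s1")
  adj <- adjust_parameters(tab, c(s1 = 1.7), "constant", tolerance = 0.2)
  expect_equal(adj$samples$N_cur, adj$unadjusted$N_cur, tolerance = 1e-9)

  # adjusted draws always stay inside the prior bounds
  for (i in 1:20) {
    th <- runif(400, -10, 10)
    tabb <- fake_table(th, th + rnorm(400, 0, 2), "s1")
    a <- adjust_parameters(tabb, c(s1 = runif(1, -12, 12)), "constant",
                           tolerance = 0.25)
    expect_true(all(a$samples$N_cur >= -10 & a$samples$N_cur <= 10))
    expect_true(a$adjusted)
  }
})

test_that("adjustment reproduces the Gaussian conjugate posterior", {
  # parameter = mean of a Normal with known sd; summary = sample mean of
  # n = 25 draws; flat prior posterior: N(xbar_obs, sigma^2 / n)
  set.seed(307)
  nsim <- 1e5; n <- 25; sigma <- 1
  theta <- runif(nsim, -10, 10)
  xbar <- rnorm(nsim, theta, sigma / sqrt(n))
  tab <- fake_table(theta, xbar, "xbar")
  adj <- adjust_parameters(tab, c(xbar = 2), "constant", tolerance = 0.01)
  m <- sum(adj$weights * adj$samples$N_cur) / sum(adj$weights)
  v <- sum(adj$weights * (adj$samples$N_cur - m)^2) / sum(adj$weights)
  expect_lt(abs(m - 2), 0.1 * 2)
  expect_lt(abs(v - sigma^2 / n) / (sigma^2 / n), 0.1)
  # the unadjusted rejection posterior is wider than the regression-corrected
  vu <- var(adj$unadjusted$N_cur)
  expect_gt(vu, v)
})

test_that("tolerance 1 without adjustment returns the prior", {
  set.seed(308)
  nsim <- 1e4
  theta <- runif(nsim, -10, 10)
  tab <- fake_table(theta, rnorm(nsim), "s1")
  adj <- adjust_parameters(tab, c(s1 = 0), "constant", tolerance = 1,
                           adjust = FALSE)
  ks <- suppressWarnings(ks.test(adj$samples$N_cur, runif(nsim, -10, 10)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("weighted quantiles reduce to type-7 and summarize posteriors", {
  expect_equal(unname(posterior_summary(7)), c(7, 7, 7))
  s <- posterior_summary(1:1000)
  expect_equal(unname(s), c(500.5, 25.975, 975.025))
  # equal explicit weights match the unweighted path
  s2 <- posterior_summary(1:1000, weights = rep(0.2, 1000))
  expect_equal(s, s2)
  x <- c(1, 2, 3, 10)
  expect_equal(unname(posterior_summary(x, probs = 0.5)["median"]),
               unname(quantile(x, 0.5)))
  expect_true(s["q025"] <= s["median"] && s["median"] <= s["q975"])
})

test_that("flat posteriors across the prior are reported as not estimable", {
  set.seed(309)
  flat <- posterior_summary(runif(5000, 1, 5000))
  expect_true(is_flat_posterior(flat, c(1, 5000)))
  peaked <- posterior_summary(rnorm(5000, 100, 5))
  expect_false(is_flat_posterior(peaked, c(1, 5000)))
})

test_that("percent change reproduces the published reporting convention", {
  expect_identical(percent_change(15700, 3230), 79L)
  expect_identical(percent_change(1510, 17100), 1132L)
  expect_identical(percent_change(100, 100), 0L)
  expect_identical(percent_change(13200, 1900), 85L)
  expect_error(percent_change(0, 10))
})

test_that("reference tables round-trip through TSV + JSON persistence", {
  tab <- small_table(100, seed = 310)
  pre <- file.path(withr::local_tempdir(), "reftab")
  save_reference_table(tab, pre)
  back <- load_reference_table(pre)
  expect_equal(back$sumstats, tab$sumstats, tolerance = 1e-12)
  expect_equal(back$draws$scenario, tab$draws$scenario)
  expect_equal(back$scale, tab$scale, tolerance = 1e-12)
  expect_equal(names(back$scenarios), names(tab$scenarios))
  obs <- tab$sumstats[5, ]
  expect_equal(rejection(back, obs, 0.05)$index,
               rejection(tab, obs, 0.05)$index)
})
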