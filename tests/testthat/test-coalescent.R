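const_traj <- function(N) to_trajectory(list(scenario = "constant", N_cur = N))

test_that("genealogies respect the serial sampling design", {
  set.seed(201)
  cfg <- sample_config(c(72, 24, 0), c(3, 4, 5), n_loci = 1)
  tr <- simulate_genealogy(const_traj(500), cfg)
  expect_equal(tr$n_tips, 24)
  expect_equal(tr$time[seq_len(24)],
               rep(c(72, 24, 0), times = 2 * c(3, 4, 5)))
  expect_equal(sum(is.na(tr$parent)), 1) # one root
  expect_true(all(tr$time[tr$parent[!is.na(tr$parent)]] >=
                    tr$time[which(!is.na(tr$parent))]))
  expect_error(simulate_genealogy(list(breaks = numeric(), N = -1), cfg),
               "nonpositive")
})

test_that("pairwise coalescence times match the closed form E[T2] = 2N", {
  set.seed(202)
  cfg <- sample_config(0, 1, 1) # one diploid = two gene copies
  N <- 400
  tm <- replicate(4000, tmrca(simulate_genealogy(const_traj(N), cfg)))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * N), 3 * se)
})

test_that("total tree length matches 4N * sum(1/i)", {
  set.seed(203)
  n <- 10
  cfg <- sample_config(0, n / 2, 1)
  N <- 250
  L <- replicate(4000, total_branch_length(simulate_genealogy(const_traj(N), cfg)))
  expected <- 4 * N * sum(1 / seq_len(n - 1))
  se <- sd(L) / sqrt(length(L))
  expect_lt(abs(mean(L) - expected), 3 * se)
})

test_that("no coalescence happens before the older sample enters when N is huge", {
  set.seed(204)
  g <- 50
  # enormous N during [0, g): coalescence there is astronomically unlikely
  traj <- structure(list(breaks = g, N = c(1e8, 100)), class = "ne_trajectory")
  cfg <- sample_config(c(g, 0), c(4, 4), 1)
  for (i in 1:100) {
    tr <- simulate_genealogy(traj, cfg)
    internal <- tr$time[-seq_len(tr$n_tips)]
    expect_true(all(internal >= g))
  }
})

test_that("mutation-free trees return the founder allele everywhere", {
  set.seed(205)
  cfg <- sample_config(c(24, 0), c(5, 5), 1)
  tr <- simulate_genealogy(const_traj(300), cfg)
  tips <- drop_mutations(tr, mutation_model(mu_mean = 0, gsm_p = 0), founder = 20)
  expect_equal(tips, rep(20L, 20))
})

test_that("branch mutation counts are Poisson(mu x length)", {
  # two tips hanging from a root at depth T: each tip's displacement parity
  # equals its mutation-count parity under single-step mutation (reflection
  # preserves parity), so P(odd displacement) = (1 - exp(-2 mu T)) / 2
  set.seed(206)
  tree <- structure(list(parent = c(3L, 3L, NA), time = c(0, 0, 100),
                         n_tips = 2L), class = "genealogy")
  mod <- mutation_model(mu_mean = 3e-3, gsm_p = 0, state_bounds = c(1, 2000))
  lam <- 3e-3 * 100
  tips <- replicate(1e4, drop_mutations(tree, mod, founder = 1000))
  odd <- mean((abs(tips - 1000) %% 2) == 1)
  p <- (1 - exp(-2 * lam)) / 2
  se <- sqrt(p * (1 - p) / length(tips))
  expect_lt(abs(odd - p), 3 * se)
})

test_that("single-step equilibrium heterozygosity matches Ohta-Kimura", {
  set.seed(207)
  N <- 1000; mu <- 1e-3
  cfg <- sample_config(0, 10, 1, founder = 200, state_bounds = c(1, 400))
  mod <- mutation_model(mu, gsm_p = 0, locus_rates = mu,
                        state_bounds = c(1, 400))
  draw <- list(scenario = "constant", N_cur = N)
  he <- replicate(3000, {
    ds <- simulate_dataset(draw, cfg, mod)
    unbiased_heterozygosity(allele_counts(as.vector(ds$genotypes[[1]])))
  })
  expected <- 1 - (1 + 8 * N * mu)^(-0.5)
  se <- sd(he) / sqrt(length(he))
  expect_lt(abs(mean(he) - expected), 3 * se)
})

test_that("per-locus rate draws have the configured mean and dispersion", {
  expect_equal(draw_locus_rates(5e-4, 7, shape = Inf), rep(5e-4, 7))
  set.seed(208)
  r <- draw_locus_rates(5e-4, 1e4, shape = 2)
  expect_lt(abs(mean(r) - 5e-4), 3 * sd(r) / sqrt(length(r)))
  r2 <- draw_locus_rates(5e-4, 1e5, shape = 2)
  shape_mom <- mean(r2)^2 / var(r2) # method-of-moments recovery
  expect_lt(abs(shape_mom - 2) / 2, 0.05)
})

test_that("simulated datasets have the requested dimensions and bounds", {
  set.seed(209)
  cfg <- sample_config(c(150, 75, 0), c(20, 20, 20), 13)
  draw <- list(scenario = "bottleneck", N_pre = 5000, N_post = 500, t = 100,
               mu_mean = 5e-4, gsm_p = 0.2)
  ds <- simulate_dataset(draw, cfg)
  expect_length(ds$samples, 3)
  expect_length(ds$loci, 13)
  expect_equal(vapply(ds$genotypes, function(g) dim(g)[1], 0L), rep(20L, 3))
  expect_equal(generation_offsets(ds), c(150L, 75L, 0L))
  expect_true(all(unlist(ds$genotypes) >= 1 & unlist(ds$genotypes) <= 40))
})

test_that("the same seed reproduces a dataset and different seeds do not", {
  cfg <- sample_config(c(24, 0), c(8, 8), 5)
  draw <- list(scenario = "constant", N_cur = 2000, mu_mean = 5e-4,
               gsm_p = 0.2)
  set.seed(42); a <- simulate_dataset(draw, cfg)
  set.seed(42); b <- simulate_dataset(draw, cfg)
  set.seed(43); c3 <- simulate_dataset(draw, cfg)
  expect_identical(a, b)
  expect_false(identical(a, c3))
})

test_that("bottlenecks depress allelic diversity relative to constant size", {
  set.seed(210)
  cfg <- sample_config(0, 30, 30)
  bot <- list(scenario = "bottleneck", N_pre = 10000, N_post = 100, t = 50,
              mu_mean = 5e-4, gsm_p = 0.2)
  con <- list(scenario = "constant", N_cur = 10000, mu_mean = 5e-4,
              gsm_p = 0.2)
  lower <- replicate(100, {
    a_bot <- summary_vector(simulate_dataset(bot, cfg), fst_pairs = list())["A_1"]
    a_con <- summary_vector(simulate_dataset(con, cfg), fst_pairs = list())["A_1"]
    a_bot < a_con
  })
  expect_gte(mean(lower), 0.95)
})

test_that("mean heterozygosity increases with N mu", {
  set.seed(211)
  cfg <- sample_config(0, 15, 5)
  mod <- mutation_model(5e-4, gsm_p = 0, locus_rates = rep(5e-4, 5))
  mean_he <- vapply(c(200, 2000, 20000), function(N) {
    mean(replicate(150, summary_vector(
      simulate_dataset(list(scenario = "constant", N_cur = N), cfg, mod),
      fst_pairs = list())["He_1"]))
  }, 0)
  expect_true(all(diff(mean_he) > 0))
})

test_that("loci are exchangeable within a dataset", {
  set.seed(212)
  cfg <- sample_config(0, 15, 2)
  draw <- list(scenario = "constant", N_cur = 2000, mu_mean = 5e-4,
               gsm_p = 0.2)
  he <- replicate(400, {
    ds <- simulate_dataset(draw, cfg)
    c(unbiased_heterozygosity(allele_counts(as.vector(ds$genotypes[[1]][, 1, ]))),
      unbiased_heterozygosity(allele_counts(as.vector(ds$genotypes[[1]][, 2, ]))))
  })
  ks <- suppressWarnings(ks.test(he[1, ], he[2, ]))
  expect_gt(ks$p.value, 0.01)
})

test_that("genealogies export to Newick", {
  skip_if_not_installed("ape")
  set.seed(213)
  cfg <- sample_config(c(10, 0), c(2, 2), 1)
  tr <- simulate_genealogy(const_traj(100), cfg)
  nwk <- genealogy_newick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(ph), 8)
  expect_equal(sum(ph$edge.length), total_branch_length(tr), tolerance = 1e-6)
})
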