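test_that("unbiased heterozygosity matches its closed form", {
  expect_equal(unbiased_heterozygosity(allele_counts(c(7, 7, 7, 7))), 0)
  expect_equal(unbiased_heterozygosity(allele_counts(c(5, 5, 9, 9))), 2/3)
  expect_equal(unbiased_heterozygosity(allele_counts(c(5, 9))), 1)
  expect_error(unbiased_heterozygosity(allele_counts(5)), "fewer than 2")
})

test_that("effective allele number is inverse homozygosity", {
  expect_equal(effective_alleles(allele_counts(rep(4, 6))), 1)
  expect_equal(effective_alleles(allele_counts(c(4, 4, 9, 9))), 2)
  expect_equal(effective_alleles(allele_counts(c(rep(4, 6), rep(9, 2)))), 1.6)
  expect_error(effective_alleles(allele_counts(integer())), "empty")
})

test_that("rarefied richness equals the exhaustive subsample oracle", {
  # the worked toy: copies {A,A,A,B}, g = 2 -> 1.5
  expect_equal(rarefied_allelic_richness(allele_counts(c(5, 5, 5, 9)), 2), 1.5)
  # full-sample rarefaction returns the observed allele count
  cc <- allele_counts(c(10, 10, 12, 14, 14, 14))
  expect_equal(rarefied_allelic_richness(cc, cc$n_copies), 3)
  expect_equal(rarefied_allelic_richness(allele_counts(rep(8, 9)), 4), 1)
  expect_error(rarefied_allelic_richness(cc, 7), "exceeds")
  set.seed(7)
  for (i in 1:10) {
    copies <- sample(5:9, sample(4:12, 1), replace = TRUE)
    g <- sample(2:length(copies), 1)
    expect_equal(rarefied_allelic_richness(allele_counts(copies), g),
                 rarefaction_bruteforce(copies, g))
  }
})

test_that("rarefied richness is nondecreasing in subsample size", {
  set.seed(11)
  copies <- sample(10:20, 30, replace = TRUE)
  cc <- allele_counts(copies)
  ar <- vapply(2:30, function(g) rarefied_allelic_richness(cc, g), 0)
  expect_true(all(diff(ar) >= -1e-12))
  expect_equal(ar[29], length(unique(copies)))
})

test_that("allele-size variance and M ratio evaluate directly", {
  expect_equal(allele_size_variance(allele_counts(c(6, 6, 6))), 0)
  expect_equal(allele_size_variance(allele_counts(c(10, 12))), 2)
  set.seed(3)
  copies <- sample(5:25, 40, replace = TRUE)
  expect_equal(allele_size_variance(allele_counts(copies)), var(copies))
  expect_equal(m_index(allele_counts(rep(9, 5))), 1)
  expect_equal(m_index(allele_counts(c(10, 11, 12))), 1)
  expect_equal(m_index(allele_counts(c(10, 14))), 0.4)
})

test_that("temporal theta matches an independent Weir-Cockerham coding", {
  # no differentiation: duplicated sample, many individuals
  set.seed(5)
  g <- array(sample(10:14, 2 * 200 * 2, replace = TRUE), c(200, 2, 2))
  ds <- genotype_dataset(c("L1", "L2"),
                         list(temporal_sample("a"), temporal_sample("b")),
                         list(g, g))
  expect_lt(abs(pairwise_fst(ds)), 0.01)

  # complete differentiation: fixed alternative alleles
  ga <- array(10L, c(50, 1, 2)); gb <- array(20L, c(50, 1, 2))
  ds2 <- genotype_dataset("L1",
                          list(temporal_sample("a"), temporal_sample("b")),
                          list(ga, gb))
  expect_gt(pairwise_fst(ds2), 0.97)

  # biallelic toy vs the independently coded theta formula
  make_geno <- function(n_aa, n_ab, n_bb) {
    g <- array(NA_integer_, c(n_aa + n_ab + n_bb, 1, 2))
    g[, 1, 1] <- c(rep(10L, n_aa), rep(10L, n_ab), rep(12L, n_bb))
    g[, 1, 2] <- c(rep(10L, n_aa), rep(12L, n_ab), rep(12L, n_bb))
    g
  }
  ds3 <- genotype_dataset("L1",
                          list(temporal_sample("t1"), temporal_sample("t2")),
                          list(make_geno(12, 6, 2), make_geno(3, 9, 8)))
  n1 <- 20; n2 <- 20
  p1 <- (2 * 12 + 6) / 40; p2 <- (2 * 3 + 9) / 40
  expect_equal(pairwise_fst(ds3),
               wc_theta_biallelic_oracle(n1, n2, p1, p2, 6 / 20, 9 / 20),
               tolerance = 1e-12)
  mono <- genotype_dataset("L1",
                           list(temporal_sample("a"), temporal_sample("b")),
                           list(array(10L, c(5, 1, 2)), array(10L, c(5, 1, 2))))
  expect_error(pairwise_fst(mono), "polymorphic")
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3)), 1)
  d0 <- paired_t_test(c(2, 3, 4), c(1, 2, 3)) # constant nonzero difference
  expect_equal(as.numeric(d0), 0)
  expect_true(isTRUE(attr(d0, "degenerate")))
  set.seed(9)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(paired_t_test(x, y), paired_t_oracle(x, y))
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("summary vector composes the per-statistic operations", {
  # monomorphic single-sample dataset
  g <- array(7L, c(4, 2, 2))
  ds <- genotype_dataset(c("L1", "L2"), list(temporal_sample("s")), list(g))
  sv <- summary_vector(ds)
  expect_equal(unname(sv[c("He_1", "A_1", "V_1", "M_1")]), c(0, 1, 0, 1))

  set.seed(21)
  ds <- random_dataset(n_samples = 2, n_ind = 12, n_loci = 4, p_missing = 0.1)
  sv <- summary_vector(ds)
  he <- mean(vapply(1:4, function(l) unbiased_heterozygosity(
    allele_counts(as.vector(ds$genotypes[[1]][, l, ]))), 0))
  v <- mean(vapply(1:4, function(l) allele_size_variance(
    allele_counts(as.vector(ds$genotypes[[1]][, l, ]))), 0))
  m <- mean(vapply(1:4, function(l) m_index(
    allele_counts(as.vector(ds$genotypes[[1]][, l, ]))), 0))
  expect_equal(unname(sv["He_1"]), he)
  expect_equal(unname(sv["V_1"]), v)
  expect_equal(unname(sv["M_1"]), m)
  expect_equal(unname(sv["Fst_1_2"]), pairwise_fst(ds, 1, 2))

  # permuting individuals leaves the vector unchanged
  perm <- ds
  ix <- sample(12)
  perm$genotypes[[1]] <- perm$genotypes[[1]][ix, , , drop = FALSE]
  expect_equal(summary_vector(perm), sv)

  expect_error(summary_vector(ds, stats = "Hobs"), "unknown statistic")
})

test_that("summary values are invariant to locus order", {
  set.seed(22)
  ds <- random_dataset(n_samples = 2, n_ind = 10, n_loci = 5)
  shuf <- ds
  ix <- c(3, 1, 5, 2, 4)
  shuf$loci <- shuf$loci[ix]
  shuf$genotypes <- lapply(shuf$genotypes, function(g) g[, ix, , drop = FALSE])
  expect_equal(summary_vector(shuf), summary_vector(ds))
})

test_that("trend report mirrors the per-time-point table layout", {
  set.seed(30)
  ds <- random_dataset(n_samples = 3, n_ind = 15, n_loci = 6)
  ds <- set_sample_dates(ds, c("2007-02", "2009-04", "2010-05"))
  ds <- assign_generations(ds)
  tr <- trend_report(ds)
  expect_equal(nrow(tr), 3)
  expect_true(all(c("HEXP", "SE_HEXP", "P_EL_HEXP", "AR", "SE_AR",
                    "P_EL_AR", "AE") %in% names(tr)))
  expect_true(all(tr$SE_HEXP >= 0) && all(tr$SE_AR >= 0))
  expect_true(is.na(tr$P_EL_HEXP[1])) # earliest row is the baseline
  expect_true(all(tr$P_EL_HEXP[2:3] >= 0 & tr$P_EL_HEXP[2:3] <= 1))
})
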