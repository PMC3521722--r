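# in-code fixtures shared across the suite

# random valid genotype dataset with optional missing calls
random_dataset <- function(n_samples = 2, n_ind = 5, n_loci = 3,
                           allele_range = c(3, 30), p_missing = 0) {
  loci <- paste0("L", seq_len(n_loci))
  samples <- lapply(seq_len(n_samples), function(i)
    temporal_sample(paste0("S", i), generation_offset = (n_samples - i) * 24))
  genotypes <- lapply(seq_len(n_samples), function(i) {
    g <- array(sample(allele_range[1]:allele_range[2],
                      n_ind * n_loci * 2, replace = TRUE),
               dim = c(n_ind, n_loci, 2))
    if (p_missing > 0) {
      miss <- matrix(stats::runif(n_ind * n_loci) < p_missing, n_ind, n_loci)
      for (r in seq_len(n_ind)) for (l in seq_len(n_loci))
        if (miss[r, l]) g[r, l, ] <- NA_integer_
    }
    g
  })
  genotype_dataset(loci, samples, genotypes)
}

# exhaustive-enumeration oracle for hypergeometric rarefaction: mean number
# of distinct alleles over all subsets of g gene copies
rarefaction_bruteforce <- function(copies, g) {
  idx <- utils::combn(length(copies), g)
  mean(apply(idx, 2, function(j) length(unique(copies[j]))))
}

# textbook paired t-test oracle
paired_t_oracle <- function(x, y) {
  d <- x - y
  t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  2 * stats::pt(-abs(t), df = length(d) - 1)
}

# independently coded Weir-Cockerham theta for a single biallelic locus,
# two populations, straight from the 1984 variance components
wc_theta_biallelic_oracle <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  comp <- function(pa1, pa2, ha1, ha2) {
    pbar <- (n1 * pa1 + n2 * pa2) / (r * nbar)
    s2 <- (n1 * (pa1 - pbar)^2 + n2 * (pa2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * ha1 + n2 * ha2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    c(a, b, hbar / 2)
  }
  # both alleles of the biallelic locus contribute components
  v <- comp(p1, p2, h1, h2) + comp(1 - p1, 1 - p2, h1, h2)
  v[1] / sum(v)
}

# tiny fabricated reference table around a single 1-parameter scenario; used
# for regression-adjustment oracles where the mapping parameter -> summary
# is analytically known
fake_table <- function(theta, sumstats, stat_names, bounds = c(-10, 10),
                       scenario = rep("constant", length(theta))) {
  sumstats <- as.matrix(sumstats)
  colnames(sumstats) <- stat_names
  scale <- apply(sumstats, 2, function(x) {
    s <- stats::mad(x); if (!is.finite(s) || s <= 0) s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) s <- 1
    s
  })
  pr <- prior_spec(ne_bounds = bounds)
  scen <- lapply(unique(scenario), make_scenario, prior = pr)
  names(scen) <- unique(scenario)
  structure(list(draws = data.frame(scenario = scenario, N_cur = theta),
                 sumstats = sumstats, scale = scale, config = NULL,
                 model = NULL, scenarios = scen),
            class = "reference_table")
}

# pseudo-observation at the centre of a reference table's summary cloud
summaries_at_mean <- function(tab) {
  obs <- colMeans(tab$sumstats)
  names(obs) <- colnames(tab$sumstats)
  obs
}

two_scenarios <- function(prior = prior_spec()) {
  s <- lapply(c("constant", "bottleneck"), make_scenario, prior = prior)
  names(s) <- c("constant", "bottleneck")
  s
}

four_scenarios <- function(prior = prior_spec()) {
  nm <- c("constant", "increasing", "bottleneck", "fluctuating")
  s <- lapply(nm, make_scenario, prior = prior)
  names(s) <- nm
  s
}
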