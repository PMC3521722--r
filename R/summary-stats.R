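#' Allele counts at one locus
#'
#' Tabulates gene copies (allele sizes in repeat units) at a single locus for
#' one temporal sample; missing calls are dropped beforehand.
#'
#' @param copies integer vector of allele sizes over gene copies (`NA`
#'   allowed; dropped).
#' @param locus locus name.
#' @return object of class `allele_counts` with fields `locus`, `counts`
#'   (named vector, allele size -> gene-copy count) and `n_copies`.
#' @export
allele_counts <- function(copies, locus = "locus") {
  copies <- copies[!is.na(copies)]
  tab <- table(copies)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(list(locus = locus, counts = counts,
                 n_copies = sum(counts)), class = "allele_counts")
}

ac_freqs <- function(counts) counts$counts / counts$n_copies
ac_sizes <- function(counts) as.integer(names(counts$counts))

#' Nei's unbiased expected heterozygosity
#'
#' \eqn{H_E = \frac{n}{n-1}(1 - \sum_i p_i^2)} with \eqn{n} gene copies and
#' allele frequencies \eqn{p_i}. Sensitive to a loss of common variation;
#' under a bottleneck it declines more slowly than allelic richness.
#'
#' @param counts an [allele_counts()] object.
#' @return value in \[0, 1\].
#' @export
unbiased_heterozygosity <- function(counts) {
  n <- counts$n_copies
  if (n < 2) stop("H_E undefined for fewer than 2 gene copies")
  p <- ac_freqs(counts)
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Effective number of alleles
#'
#' \eqn{A_e = 1 / \sum_i p_i^2}: the number of equifrequent alleles that
#' would give the same homozygosity.
#'
#' @inheritParams unbiased_heterozygosity
#' @return value >= 1.
#' @export
effective_alleles <- function(counts) {
  if (counts$n_copies < 1) stop("empty allele counts")
  1 / sum(ac_freqs(counts)^2)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies (hypergeometric rarefaction):
#' \eqn{A_R(g) = \sum_i [1 - \binom{n-c_i}{g} / \binom{n}{g}]} over alleles
#' with copy counts \eqn{c_i}. Rarefaction makes allele counts comparable
#' across temporal samples of unequal size; richness is the statistic most
#' sensitive to recent bottlenecks because rare alleles are lost first.
#'
#' @inheritParams unbiased_heterozygosity
#' @param g gene-copy subsample size, `2 <= g <= n_copies`.
#' @export
rarefied_allelic_richness <- function(counts, g) {
  n <- counts$n_copies
  if (g > n) stop("rarefaction size g exceeds available gene copies")
  if (g < 2) stop("rarefaction size g must be >= 2")
  ci <- counts$counts
  # C(n-c, g) / C(n, g) as a stable product
  ratio <- vapply(ci, function(c) {
    if (n - c < g) return(0)
    prod((n - c - seq_len(g) + 1) / (n - seq_len(g) + 1))
  }, 0)
  sum(1 - ratio)
}

#' Unbiased variance of allele size over gene copies
#'
#' @inheritParams unbiased_heterozygosity
#' @export
allele_size_variance <- function(counts) {
  if (counts$n_copies < 2) stop("variance undefined for fewer than 2 copies")
  x <- rep(ac_sizes(counts), counts$counts)
  stats::var(x)
}

#' Garza-Williamson M ratio
#'
#' Number of observed alleles divided by the allele-size range plus one.
#' Bottlenecks knock out alleles across the range faster than they shrink
#' the range itself, depressing M.
#'
#' @inheritParams unbiased_heterozygosity
#' @return value in (0, 1\].
#' @export
m_index <- function(counts) {
  if (counts$n_copies < 1) stop("empty allele counts")
  sz <- ac_sizes(counts)
  length(sz) / (max(sz) - min(sz) + 1)
}

#' Multi-locus Weir-Cockerham theta between two temporal samples
#'
#' Estimates \eqn{F_{ST}} between two temporal samples of one population from
#' the 1984 variance components (a, b, c) summed over alleles and loci; may be
#' slightly negative around zero differentiation. Temporal \eqn{F_{ST}}
#' carries the drift signal between sampling times and so scales inversely
#' with Ne.
#'
#' @param dataset a [genotype_dataset()].
#' @param sample_a,sample_b indices of the two temporal samples (defaults:
#'   first and last in dataset order).
#' @export
pairwise_fst <- function(dataset, sample_a = 1L,
                         sample_b = length(dataset$samples)) {
  ga <- dataset$genotypes[[sample_a]]
  gb <- dataset$genotypes[[sample_b]]
  num <- 0; den <- 0; usable <- FALSE
  for (l in seq_along(dataset$loci)) {
    a1 <- ga[, l, , drop = FALSE]; b1 <- gb[, l, , drop = FALSE]
    ka <- !is.na(a1[, 1, 1]); kb <- !is.na(b1[, 1, 1])
    n1 <- sum(ka); n2 <- sum(kb)
    if (n1 < 1 || n2 < 1) next
    alleles <- sort(unique(c(a1[ka, 1, ], b1[kb, 1, ])))
    if (length(alleles) < 2) next
    usable <- TRUE
    nbar <- (n1 + n2) / 2
    r <- 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p1 <- sum(a1[ka, 1, ] == al) / (2 * n1)
      p2 <- sum(b1[kb, 1, ] == al) / (2 * n2)
      h1 <- sum(xor(a1[ka, 1, 1] == al, a1[ka, 1, 2] == al)) / n1
      h2 <- sum(xor(b1[kb, 1, 1] == al, b1[kb, 1, 2] == al)) / n2
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (!usable) stop("no polymorphic locus shared by the two samples")
  if (den == 0) 0 else num / den
}

#' Paired t-test across loci
#'
#' Two-sided paired t-test on per-locus differences, used to compare mean
#' heterozygosity or allelic richness between time points. By convention all
#' differences exactly zero gives P = 1; zero within-pair variance with a
#' nonzero mean difference gives P = 0 with attribute `degenerate = TRUE`.
#'
#' @param x,y numeric vectors over the same loci, length >= 2.
#' @return the two-sided P value.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 loci for a paired t-test")
  d <- x - y
  if (all(d == 0)) return(1)
  if (stats::var(d) == 0) return(structure(0, degenerate = TRUE))
  stats::t.test(x, y, paired = TRUE)$p.value
}

# per-sample per-locus allele_counts, missing dropped
sample_locus_counts <- function(dataset, s, l) {
  allele_counts(as.vector(dataset$genotypes[[s]][, l, ]), dataset$loci[l])
}

# one-sample statistic panel; conventions keep the map total on monomorphic
# and tiny inputs (H_E = 0, variance = 0 when n < 2)
one_sample_stats <- function(counts) {
  n <- counts$n_copies
  if (n == 0) return(c(He = 0, A = 0, V = 0, M = 0))
  p <- ac_freqs(counts)
  sz <- ac_sizes(counts)
  he <- if (n > 1) (n / (n - 1)) * (1 - sum(p^2)) else 0
  v <- if (n > 1) stats::var(rep(sz, counts$counts)) else 0
  c(He = he, A = length(sz), V = v,
    M = length(sz) / (max(sz) - min(sz) + 1))
}

#' ABC summary-statistic vector for a dataset
#'
#' Per temporal sample, locus-averaged: unbiased expected heterozygosity
#' (`He`), allele count (`A`), unbiased allele-size variance (`V`) and the
#' M ratio (`M`); plus Weir-Cockerham theta between each configured sample
#' pair (default: every pair of temporal samples — the drift pattern across
#' pairs carries the timing signal of a size change within the sampled
#' window). The name order is fixed for a given configuration, so vectors
#' from observed and simulated datasets are comparable position by
#' position.
#'
#' @param dataset a [genotype_dataset()].
#' @param stats one-sample statistics to include, a subset of
#'   `c("He","A","V","M")` in that order.
#' @param fst_pairs list of integer pairs of sample indices for temporal
#'   theta; `NULL` (default) uses all pairs `i < j`.
#' @return named numeric vector (class `summary_vector`).
#' @export
summary_vector <- function(dataset, stats = c("He", "A", "V", "M"),
                           fst_pairs = NULL) {
  allowed <- c("He", "A", "V", "M")
  if (!all(stats %in% allowed))
    stop("unknown statistic: ", paste(setdiff(stats, allowed), collapse = ", "))
  stats <- allowed[allowed %in% stats]
  ns <- length(dataset$samples)
  if (ns < 1 || length(dataset$loci) < 1) stop("empty dataset")
  if (is.null(fst_pairs)) fst_pairs <- default_fst_pairs(ns)
  out <- numeric(0)
  for (s in seq_len(ns)) {
    per_locus <- vapply(seq_along(dataset$loci), function(l)
      one_sample_stats(sample_locus_counts(dataset, s, l)),
      numeric(4))
    m <- rowMeans(per_locus)[stats]
    names(m) <- paste0(stats, "_", s)
    out <- c(out, m)
  }
  for (pr in fst_pairs) {
    v <- pairwise_fst(dataset, pr[1], pr[2])
    names(v) <- paste0("Fst_", pr[1], "_", pr[2])
    out <- c(out, v)
  }
  structure(out, class = c("summary_vector", "numeric"))
}

default_fst_pairs <- function(ns) {
  if (ns < 2) return(list())
  utils::combn(ns, 2, simplify = FALSE)
}

stat_panel_names <- function(n_samples, fst_pairs,
                             stats = c("He", "A", "V", "M")) {
  nm <- as.vector(vapply(seq_len(n_samples),
                         function(s) paste0(stats, "_", s),
                         character(length(stats))))
  c(nm, vapply(fst_pairs, function(p) paste0("Fst_", p[1], "_", p[2]), ""))
}

# fast path: identical panel computed in C++ straight from the simulator's
# gene-copy matrix (no missing data); must agree exactly with summary_vector()
summaries_from_matrix <- function(alleles, sample_id, n_samples,
                                  fst_pairs = default_fst_pairs(n_samples)) {
  pm <- pairs_matrix(fst_pairs)
  v <- .summaries_cpp(alleles, as.integer(sample_id), as.integer(n_samples),
                      pm)
  names(v) <- stat_panel_names(n_samples, fst_pairs)
  v
}

pairs_matrix <- function(fst_pairs) {
  if (length(fst_pairs) == 0) return(matrix(0L, 2, 0))
  vapply(fst_pairs, function(p) as.integer(p) - 1L, integer(2))
}

#' Temporal trend report of diversity statistics
#'
#' Per time point: locus-mean unbiased heterozygosity and rarefied allelic
#' richness with standard errors across loci, and the effective number of
#' alleles; plus paired-t P values comparing the earliest time point with the
#' second and with the latest (`P_EL` columns attach to the compared row).
#' Richness is rarefied to the smallest per-locus gene-copy count across time
#' points.
#'
#' @param dataset a [genotype_dataset()].
#' @return data.frame with one row per temporal sample: `Sample`, `Year`,
#'   `N`, `HEXP`, `SE_HEXP`, `P_EL_HEXP`, `AR`, `SE_AR`, `P_EL_AR`, `AE`.
#' @export
trend_report <- function(dataset) {
  ns <- length(dataset$samples)
  nl <- length(dataset$loci)
  he <- ar <- ae <- matrix(NA_real_, ns, nl)
  for (l in seq_len(nl)) {
    cl <- lapply(seq_len(ns), function(s) sample_locus_counts(dataset, s, l))
    g <- max(2L, min(vapply(cl, function(x) x$n_copies, 0L)))
    for (s in seq_len(ns)) {
      he[s, l] <- unbiased_heterozygosity(cl[[s]])
      ar[s, l] <- rarefied_allelic_richness(cl[[s]], g)
      ae[s, l] <- effective_alleles(cl[[s]])
    }
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  out <- data.frame(
    Sample = vapply(dataset$samples, function(s) s$label, ""),
    Year = vapply(dataset$samples, function(s)
      if (is.null(s$date)) NA_character_ else format_ym(s$date), ""),
    N = vapply(dataset$genotypes, function(g) dim(g)[1], 0L),
    HEXP = rowMeans(he), SE_HEXP = apply(he, 1, se),
    P_EL_HEXP = NA_real_,
    AR = rowMeans(ar), SE_AR = apply(ar, 1, se),
    P_EL_AR = NA_real_,
    AE = rowMeans(ae))
  if (ns >= 2) {
    cmp <- unique(c(2L, ns))
    for (s in cmp) {
      out$P_EL_HEXP[s] <- as.numeric(paired_t_test(he[1, ], he[s, ]))
      out$P_EL_AR[s] <- as.numeric(paired_t_test(ar[1, ], ar[s, ]))
    }
  }
  out
}
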