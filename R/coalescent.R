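#' Temporal sampling design for the simulator
#'
#' @param offsets integer generation offsets (gbp) of the temporal samples,
#'   one per sample; 0 is the most recent.
#' @param n_diploids diploid individuals per sample (same length).
#' @param n_loci number of independent microsatellite loci.
#' @param founder founder allele size (repeat units) at the root of every
#'   genealogy.
#' @param state_bounds allele-state bounds (repeat units); mutation steps
#'   reflect at the bounds. The default 40 contiguous states matches the
#'   bounded-ladder convention of microsatellite simulators.
#' @export
sample_config <- function(offsets, n_diploids, n_loci, founder = 20,
                          state_bounds = c(1, 40)) {
  stopifnot(length(offsets) == length(n_diploids),
            all(offsets >= 0), all(n_diploids >= 1), n_loci >= 1,
            state_bounds[1] < state_bounds[2],
            founder >= state_bounds[1], founder <= state_bounds[2])
  structure(list(offsets = as.numeric(offsets),
                 n_diploids = as.integer(n_diploids),
                 n_loci = as.integer(n_loci), founder = as.integer(founder),
                 state_bounds = as.integer(state_bounds)),
            class = "sample_config")
}

# generation offset of every gene copy, sample-block order
copy_offsets <- function(config)
  rep(config$offsets, times = 2L * config$n_diploids)

#' Generalized stepwise mutation model
#'
#' Mutations arrive as a Poisson process along branches at per-locus rate
#' `mu`; each mutation shifts the repeat count by ±s with s >= 1 geometric
#' with parameter `gsm_p` (`P(S=s) = (1-p) p^{s-1}`), direction symmetric,
#' reflecting at the allele-state bounds. `gsm_p = 0` degenerates to the
#' strict single-step model (SMM); larger values add the multi-repeat jumps
#' that mimic the infinite-allele component of microsatellite mutation.
#'
#' @param mu_mean mean mutation rate per locus per generation.
#' @param gsm_p geometric parameter in `[0, 1)`.
#' @param locus_rates optional explicit per-locus rates; when `NULL` the
#'   simulator draws them around `mu_mean` (see [draw_locus_rates()]).
#' @param shape Gamma shape for per-locus rate variation; `Inf` pins all
#'   loci to `mu_mean`.
#' @param state_bounds allele-state bounds.
#' @export
mutation_model <- function(mu_mean = 5e-4, gsm_p = 0.22, locus_rates = NULL,
                           shape = 2, state_bounds = c(1, 40)) {
  stopifnot(mu_mean >= 0, mu_mean < 1, gsm_p >= 0, gsm_p < 1,
            state_bounds[2] - state_bounds[1] >= 1)
  if (!is.null(locus_rates) && any(locus_rates <= 0 | locus_rates >= 1))
    stop("locus rates must lie in (0, 1)")
  structure(list(mu_mean = mu_mean, gsm_p = gsm_p,
                 locus_rates = locus_rates, shape = shape,
                 state_bounds = as.integer(state_bounds)),
            class = "mutation_model")
}

#' Draw per-locus mutation rates around a mean
#'
#' Rates are Gamma-distributed with mean `mu_mean` and the given shape
#' (rate heterogeneity across microsatellite loci); `shape = Inf` returns
#' `mu_mean` for every locus (the "same mean value" mode).
#'
#' @param mu_mean mean rate.
#' @param n_loci number of loci.
#' @param shape Gamma shape parameter.
#' @export
draw_locus_rates <- function(mu_mean, n_loci, shape = 2) {
  if (!is.finite(shape) || mu_mean == 0) return(rep(mu_mean, n_loci))
  r <- stats::rgamma(n_loci, shape = shape, rate = shape / mu_mean)
  pmin(pmax(r, 1e-12), 1 - 1e-12)
}

#' Simulate a serial-coalescent genealogy
#'
#' Gene copies enter the (backward-time) coalescent at their sample's
#' generation offset; while k lineages are active, pairwise coalescence
#' occurs at rate k(k-1)/(2·2N(t)) per generation in continuous time, with
#' N(t) read from the piecewise-constant trajectory (waiting times are drawn
#' epoch by epoch, so boundary crossings are exact).
#'
#' @param trajectory an [to_trajectory()] result (or `list(breaks, N)`).
#' @param config a [sample_config()]; one genealogy covers all its gene
#'   copies at one locus.
#' @return object of class `genealogy`: `parent` (index of each node's
#'   parent, `NA` at the root), `time` (gbp, tips first in input order),
#'   `n_tips`, `tip_sample` (sample index of each tip).
#' @export
simulate_genealogy <- function(trajectory, config) {
  tt <- copy_offsets(config)
  if (length(tt) < 2) stop("need at least 2 gene copies")
  res <- .sim_tree_cpp(tt, trajectory$breaks, trajectory$N)
  parent <- res$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(parent = parent, time = res$time, n_tips = res$n_tips,
                 tip_sample = rep(seq_along(config$offsets),
                                  times = 2L * config$n_diploids)),
            class = "genealogy")
}

#' Total branch length of a genealogy (generations)
#' @param tree a `genealogy`.
#' @export
total_branch_length <- function(tree) {
  ok <- !is.na(tree$parent)
  sum(tree$time[tree$parent[ok]] - tree$time[ok])
}

#' Time to the most recent common ancestor (gbp)
#' @param tree a `genealogy`.
#' @export
tmrca <- function(tree) max(tree$time)

#' Drop mutations on a genealogy
#'
#' Assigns the founder allele to the root and mutates down every branch:
#' the number of mutations on a branch is Poisson with mean `mu` times the
#' branch length, each stepping the allele by a symmetric geometric step
#' (see [mutation_model()]), reflected at the state bounds.
#'
#' @param tree a [simulate_genealogy()] result.
#' @param model a [mutation_model()]; `mu_mean` is used as the rate.
#' @param founder founder allele size.
#' @return integer vector of tip allele sizes, in tip order.
#' @export
drop_mutations <- function(tree, model, founder = 20) {
  parent0 <- tree$parent
  parent0[is.na(parent0)] <- 0L
  .drop_mutations_cpp(parent0 - 1L, tree$time, tree$n_tips,
                      model$mu_mean, model$gsm_p, as.integer(founder),
                      model$state_bounds[1], model$state_bounds[2])
}

#' Export a genealogy as Newick
#'
#' Debugging aid; requires the `ape` package.
#' @param tree a `genealogy`.
#' @return a Newick string.
#' @export
genealogy_newick <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export needs the 'ape' package")
  n <- tree$n_tips
  m <- 2L * n - 1L
  root <- which(is.na(tree$parent))
  edge <- cbind(tree$parent[-root], seq_len(m)[-root])
  # ape numbering: tips 1..n keep their ids; internal nodes renumbered with
  # the root first
  internal <- sort(unique(edge[, 1]))
  remap <- integer(m)
  remap[seq_len(n)] <- seq_len(n)
  remap[root] <- n + 1L
  rest <- setdiff(internal, root)
  remap[rest] <- n + 1L + seq_along(rest)
  ph <- list(edge = cbind(remap[edge[, 1]], remap[edge[, 2]]),
             edge.length = tree$time[edge[, 1]] - tree$time[edge[, 2]],
             tip.label = paste0("t", seq_len(n)), Nnode = n - 1L)
  class(ph) <- "phylo"
  ape::write.tree(ph)
}

#' Simulate a multi-locus temporal genotype dataset
#'
#' One independent genealogy plus mutation layer per locus; gene copies are
#' paired into diploids within each temporal sample. Because coalescent tips
#' are exchangeable, pairing consecutive copies is equivalent to random
#' pairing under random mating.
#'
#' @param draw a one-row parameter draw from [sample_prior()] (or a named
#'   list with `scenario` and parameters); its `mu_mean` / `gsm_p` override
#'   the mutation model's when present.
#' @param config a [sample_config()].
#' @param model a [mutation_model()]; per-locus rates are drawn via
#'   [draw_locus_rates()] unless fixed in the model.
#' @return a [genotype_dataset()] with samples labelled `S1..Sk` carrying
#'   the configured generation offsets.
#' @export
simulate_dataset <- function(draw, config, model = mutation_model()) {
  p <- as.list(draw)
  traj <- to_trajectory(p)
  mu_mean <- if (!is.null(p$mu_mean)) p$mu_mean else model$mu_mean
  gsm_p <- if (!is.null(p$gsm_p)) p$gsm_p else model$gsm_p
  rates <- if (!is.null(model$locus_rates)) {
    stopifnot(length(model$locus_rates) == config$n_loci)
    model$locus_rates
  } else draw_locus_rates(mu_mean, config$n_loci, model$shape)
  mat <- .sim_dataset_cpp(copy_offsets(config), config$n_loci,
                          traj$breaks, traj$N, rates, gsm_p,
                          config$founder, config$state_bounds[1],
                          config$state_bounds[2])
  matrix_to_dataset(mat, config)
}

# gene-copy matrix (sample-block rows, consecutive pairs = individuals)
# -> genotype_dataset
matrix_to_dataset <- function(mat, config) {
  loci <- paste0("L", seq_len(config$n_loci))
  samples <- list()
  genotypes <- list()
  row0 <- 0L
  for (s in seq_along(config$offsets)) {
    nd <- config$n_diploids[s]
    g <- array(NA_integer_, dim = c(nd, config$n_loci, 2L))
    idx <- row0 + seq_len(2L * nd)
    g[, , 1] <- mat[idx[seq(1, length(idx), 2)], , drop = FALSE]
    g[, , 2] <- mat[idx[seq(2, length(idx), 2)], , drop = FALSE]
    row0 <- row0 + 2L * nd
    samples[[s]] <- temporal_sample(paste0("S", s),
                                    generation_offset = config$offsets[s])
    genotypes[[s]] <- g
  }
  genotype_dataset(loci, samples, genotypes)
}

# inverse of matrix_to_dataset for observed data without missing calls
dataset_to_matrix <- function(dataset) {
  nl <- length(dataset$loci)
  rows <- lapply(dataset$genotypes, function(g) {
    nd <- dim(g)[1]
    m <- matrix(NA_integer_, 2L * nd, nl)
    m[seq(1, 2 * nd, 2), ] <- g[, , 1]
    m[seq(2, 2 * nd, 2), ] <- g[, , 2]
    m
  })
  do.call(rbind, rows)
}
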