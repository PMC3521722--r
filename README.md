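# serialabc

Coalescent Approximate Bayesian Computation (ABC) for detecting and
quantifying changes in **effective population size (Ne)** from
**temporally sampled microsatellite genotypes** — the study design used to
ask whether vector-control interventions (indoor residual spraying,
long-lasting insecticidal nets) actually suppressed malaria-mosquito
populations, rather than merely repelling them from traps.

## Who it is for

Population geneticists and vector-control programmes with diploid
microsatellite data (GenePop files) for the *same* population sampled at
two or more time points spanning tens to hundreds of generations, who want
to (i) test whether a recent demographic decline best explains the data,
(ii) estimate the pre- and post-change Ne with credible intervals, and
(iii) know how often that model choice would be wrong.

## The method

Genotypes are summarised per temporal sample by locus-averaged unbiased
expected heterozygosity *H*<sub>E</sub> = *n*/(*n*−1) (1 − Σ*p*<sub>i</sub>²),
allele count, allele-size variance and the Garza–Williamson *M* ratio, and
between samples by Weir–Cockerham temporal θ (F<sub>ST</sub>) for every
sample pair. Four competing piecewise-constant Ne histories are simulated
under a **serial coalescent** (lineages enter at their sampling
generations; pairwise coalescence at rate *k*(*k*−1)/(2·2*N*(*t*))) with a
**generalized stepwise mutation model** for repeat counts (Poisson
mutations along branches; symmetric geometric steps, parameter *P*, with
*P* = 0 the strict single-step model):

| scenario | parameters | shape |
|---|---|---|
| constant | N_cur | one epoch |
| increasing | N_anc < N_cur, ancient time t | old growth |
| bottleneck | N_pre > N_post, recent time t | intervention-era decline |
| fluctuating | N_anc < N_hist > N_pres, t1 > t2 | expansion then decline |

Parameters are drawn from uniform priors; a reference table of simulated
summary vectors is built per scenario; the closest simulations to the
observed summaries are retained (normalized Euclidean distance, 1% by
default); scenario posterior probabilities come from a weighted
multinomial logistic regression in linear-discriminant coordinates; and
the chosen scenario's parameters are estimated by Beaumont local-linear
regression adjustment on a logit scale, reported as medians with
0.025/0.975 quantiles and a percent change in Ne. Type I/II error rates of
the scenario choice are estimated from pseudo-observed datasets. Calendar
dates convert to generations at 24 generations per year, the standard
assumption for Afrotropical anophelines.

## Worked example

Generate a synthetic study emulating a four-time-point intervention design
(119/63/78/94 mosquitoes, 13 loci, 2004–2010) whose ground truth is a
bottleneck from Ne 15,700 to 3,230 at 314 generations before present, then
run the full inference:

```r
library(serialabc)
set.seed(7)
st  <- generate_study(study_template("punta_europa", seed = 7))
obs <- summary_vector(st$dataset)
cfg <- sample_config(generation_offsets(st$dataset),
                     vapply(st$dataset$genotypes, function(g) dim(g)[1], 0L),
                     length(st$dataset$loci))
scen <- lapply(c("constant", "increasing", "bottleneck", "fluctuating"),
               make_scenario)
names(scen) <- vapply(scen, function(s) s$name, "")
tab <- build_reference_table(scen, 5000, cfg)   # ~1 min on one core
res <- abc_analysis(tab, obs, tolerance = 0.01)
print(res)
```

```
abc_result: best-fit scenario = bottleneck (p.pr. = 0.72)
  N_pre    median 2.003e+04  [5027, 8.422e+04]
  N_post   median 2564  [1759, 3824]
  t        median 232.7  [80.72, 447.3]
  change N_pre -> N_post: 87%
```

The bottleneck model wins (posterior probability 0.72 against the three
alternatives); the post-intervention Ne interval [1759, 3824] contains the
true 3,230; the timing interval [81, 447] contains the true 314; and the
percent-change column reports the decline as trunc(100 × (1 −
N_post/N_pre)). Diversity trends per time point (the descriptive table a
field report would show) come from `trend_report(st$dataset)`, and
scenario-choice error rates from `run_pods(tab)`.

A YAML-driven command line mirroring this pipeline
(`sumstats | simulate-reference | infer | confidence | synth`) is in
`inst/cli/serialabc-cli.R`.

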