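# lfgsim

Recombination and the rate of adaptation on fitness landscapes with
low-fitness genotypes.

## The problem

Bacteria recombine by transformation: free environmental DNA is taken up and
replaces the homologous allele in the recipient. Whether this speeds up or
slows down adaptation depends on the fitness landscape. `lfgsim` is for
population geneticists and modelers studying landscapes with *limited peak
accessibility*: a smooth, single-peaked baseline over `L` biallelic loci,

    m(k) = 1 − s · k^ε

(`k` = number of deleterious alleles, `m(0) = 1` at the peak "11…1"), on
which a chosen set of intermediate genotypes — the *fitness topography* — is
overridden to Malthusian fitness 0 ("low-fitness genotypes", LFGs). LFGs
induce sign epistasis and block mutational paths to the peak.

The central quantity is the recombination effect

    T_fix = t_fix(r) / t_fix(r = 0),

the ratio of the times until the fittest genotype (nearly) fixes with and
without recombination. `T_fix > 1`: recombination decelerates adaptation.

Two model layers share the landscape machinery:

* an **infinite-population ODE model** (mutation at rate `μ` per locus,
  selection on Malthusian fitness, transformation at total genome rate `r`,
  i.e. `r/L` per locus), with event-detected fixation times, linkage
  disequilibrium, and the closed-form two-locus critical rate
  `r_c = m(11) − m(00)` above which a reciprocal-sign-epistasis valley
  becomes uninvadable;
* a **finite-population Moran-type simulator** (birth `B·e^{m_i}·n_i`, death
  `B·(N/N0)·n_i`, per-neighbour mutation `μ·n_i`, transformation
  `(r/L)·n_i·A_l/N`), exact Gillespie SSA with optional tau-leaping, for the
  Fisher–Muller regime where drift-generated linkage disequilibrium makes
  recombination *accelerate* adaptation.

Screening utilities enumerate or sample topographies (locus-permutation
symmetry classes are detected and used to make exhaustive screens cheap),
aggregate `T_fix` distributions by LFG count, compare screens across
parameters, and estimate physiological epistasis by nonlinear regression of
fitness against mutation count.

## Worked example

```r
library(lfgsim)

## the two-locus fitness valley: both intermediates are LFGs
valley <- build_landscape(2, s = 0.05, eps = 1,
                          topography = fitness_topography(2, c("01", "10")))
valley
#> Fitness landscape: L = 2 | s = 0.05 | eps = 1 | 2 LFG(s)
#>   genotype k is_lfg   m
#> 1       00 2  FALSE 0.9
#> 2       01 1   TRUE 0.0
#> 3       10 1   TRUE 0.0
#> 4       11 0  FALSE 1.0

params <- dynamics_params(mu = 1e-5, r = 0.05)
t_fix_ratio(valley, params)
#> T_fix = 1.63078  (t[r=0.05] = 401.612, t[r=0] = 246.271)

critical_recombination_rate(valley)   # equals m(11) - m(00) = 2s
#> [1] 0.1
```

Recombination slows the valley crossing by 63% here, and above `r = 0.1` the
peak genotype could not invade at all.

In a finite population the sign flips on typical multi-LFG landscapes:

```r
topo <- sample_topographies(4, n_lfgs = 3, count = 1, seed = 11)[[1]]
l4 <- build_landscape(4, s = 0.05, eps = 1, topography = topo)

t_fix_ratio(l4, params)                       # infinite N: deceleration
#> T_fix = 1.0373  (t[r=0.05] = 301.666, t[r=0] = 290.818)

stochastic_t_fix(l4, stoch_params(N0 = 1e4, mu = 1e-4, r = 0.05,
                                  n_reps = 10), seed = 1)
#> stochastic T_fix = 0.6896 (mean t[r=0.05] = 135.32 over 10,
#>                            mean t[r=0] = 196.231 over 10)
```

At `N0·μ = 1` the Fisher–Muller effect (recombination combining beneficial
mutations from competing lineages) outweighs the epistatic deceleration:
`T_fix` drops from 1.04 to 0.69.

A command-line interface wrapping the same functions ships at
`inst/exec/lfgsim` (subcommands `enumerate`, `screen-det`, `screen-stoch`,
`epistasis`, `summarize`, `rank-compare`), writing TSV tables with JSON
manifests that echo the full effective configuration.

See `vignettes/lfg-recombination-model.Rmd` for the model definitions, the
rate conventions, the tau-leaping scheme, and the reasoning behind the
numerical defaults.

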