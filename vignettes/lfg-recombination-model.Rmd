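---
title: "Modeling recombination on fitness landscapes with low-fitness genotypes"
author: "lfgsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling recombination on fitness landscapes with low-fitness genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfgsim)
```

## The question

Bacterial transformation — the uptake of free environmental DNA and its
homologous integration into the genome — is a widespread form of
recombination. Whether it speeds up or slows down adaptation depends on the
shape of the fitness landscape. `lfgsim` studies a family of landscapes with
a single global peak whose mutational approach routes are partially blocked:
a smooth baseline landscape over `L` biallelic loci on which some
intermediate genotypes are designated *low-fitness genotypes* (LFGs) with
relative Malthusian fitness zero. LFGs create sign epistasis: a mutation that
is beneficial on one background steps into a fitness hole on another. The
package quantifies the effect of recombination as

\[
T_\mathrm{fix} \;=\; \frac{t_\mathrm{fix}(\text{with recombination})}
                          {t_\mathrm{fix}(\text{without recombination})},
\]

where \(t_\mathrm{fix}\) is the time until the fittest genotype (all
beneficial alleles) first exceeds a frequency threshold. \(T_\mathrm{fix}>1\)
means recombination decelerates adaptation.

## The landscape

Genotypes are length-`L` binary strings; allele 1 is beneficial. Genotype `g`
is stored as the integer whose bit `b` holds the allele at locus `b`, and
strings are printed most-significant-locus first, so `"1111"` is the peak.
With `k(g)` the number of 0-alleles, the baseline Malthusian fitness is

\[
m(k) = 1 - s\,k^{\varepsilon},
\]

so the peak has fitness 1, `s` is the fitness reduction per deleterious
allele, and \(\varepsilon\) tunes one-dimensional magnitude epistasis.
\(\varepsilon = 1\) is additive. \(\varepsilon > 1\) makes fitness fall
faster than linearly in `k` (antagonistic action of beneficial mutations,
negative epistasis); \(\varepsilon < 1\) is the synergistic, positive case.
Construction rejects any parameter combination with \(s\,L^{\varepsilon} > 1\)
(a negative fitness at `k = L`).

A *fitness topography* is the set of intermediate genotypes overridden to
`m = 0`; the extremes (`all-0`, `all-1`) are never LFGs. An LFG is not
inviable — on the Malthusian scale zero simply means far less fit than any
non-LFG. For `L = 4` there are 14 intermediate genotypes, so
\(\sum_{j\le 10}\binom{14}{j} = 15914\) topographies with up to ten LFGs.
Because the baseline depends on genotypes only through `k`, any permutation
of locus positions maps the model onto itself; `orbit_classes()` groups
topographies into equivalence classes under this symmetry and screens only
need one representative per class (class sizes then weight all summary
statistics — this is exact, not an approximation, and is tested as an
invariant).

## Infinite populations: the ODE model

Genotype frequencies \(x_i\) follow

\[
\dot x_i \;=\; \mu \sum_{j \in N(i)} x_j \;-\; \mu L\, x_i
\;+\; (m_i - \bar m)\, x_i
\;+\; \rho \sum_{\ell} \big[ x_{i \oplus \ell}\, p_\ell(a_{i\ell})
                             - x_i\, p_\ell(1 - a_{i\ell}) \big],
\]

with \(N(i)\) the Hamming-1 neighbours, \(\bar m = \sum_g x_g m_g\),
\(i \oplus \ell\) the genotype `i` with locus \(\ell\) flipped,
\(a_{i\ell}\) the allele of `i` at \(\ell\), and \(p_\ell(a)\) the population
frequency of allele `a` at locus \(\ell\). The recombination terms encode
transformation as single-allele replacement: the free-DNA pool consists of
length-one fragments whose allele frequencies mirror the population, and an
uptake that inserts the allele the acceptor already carries changes nothing
(the replacement indicator is zero for no-ops). The right-hand side sums to
zero analytically, so frequencies stay on the simplex.

**Rate convention.** `r` is the *total* per-genome uptake rate; each locus is
replaced at rate \(\rho = r/L\). This is the convention under which the
two-locus critical-rate result below takes the clean form
\(r_c = m_{11} - m_{00}\), independent of how one scales `L`. The per-locus
alternative (\(\rho = r\)) is available as
`dynamics_params(rate_convention = "per_locus")`.

### Fixation times and the critical recombination rate

Integration starts from a population monomorphic for the least-fit genotype
and uses `deSolve::lsoda` (adaptive, stiff-capable) with relative tolerance
`1e-8` and absolute tolerance `1e-12`; threshold crossings
(`fixation_threshold = 0.99` by default) are located by the solver's event
detection (`lsodar` root finding), not by interpolating coarse output.
Non-fixation by `t_max` is a flagged result, not an error — it is a real
outcome: on a two-locus landscape with both intermediates LFGs (a reciprocal
sign-epistasis valley), recombination with the resident breaks the peak
genotype down into the valley faster than selection amplifies it whenever

\[ r > r_c = m_{11} - m_{00}, \]

as a linearization of the mutation-free dynamics at the `00`-fixation fixed
point shows: the perturbation growth rate of the peak genotype is
\((m_{11}-m_{00}) - r\). `critical_recombination_rate()` computes \(r_c\)
two independent ways — bisection on the sign of the dominant Jacobian
eigenvalue (the Jacobian is evaluated numerically on the reduced simplex
coordinates), and bisection on the long-time ODE outcome after a small
inoculum of the peak genotype. The inoculum must be small (default `3e-5`):
the valley genotypes it spawns depress mean fitness by an amount proportional
to the inoculum and shift the apparent invasion boundary by the same order.
With the default horizon the two routes agree with each other and with
\(m_{11}-m_{00}\) to better than `1e-4`.

### Measures along trajectories

`pairwise_LD()` reports \(D = f_{11} - p_a p_b\) for a locus pair, and
`time_to_mean_fitness()` is an alternative adaptation clock (first time
\(\bar m\) exceeds a threshold) that rank-correlates strongly with the
fixation time across topographies (tested). On the additive, LFG-free
landscape no linkage disequilibrium ever forms and \(T_\mathrm{fix} = 1\):
recombination is neutral. This null requires tight solver tolerances to
verify at the `1e-9` level; the check integrates with `rtol = 1e-12`,
`atol = 1e-16`.

## Finite populations: the stochastic model

The finite-population model is a continuous-time Moran-type process over
genotype compartments with counts \(n_i\), \(N = \sum_i n_i\):

* **birth** at rate \(B f_i n_i\), with \(f_i = e^{m_i}\) the Fisherean
  fitness (an LFG divides at the baseline rate: \(f(0)=1\));
* **death** at rate \(B (N/N_0)\, n_i\);
* **mutation** to each Hamming-1 neighbour at rate \(\mu n_i\);
* **transformation** at locus \(\ell\) at rate
  \((r/L)\, n_i\, A_\ell / N\), where \(A_\ell\) counts the individuals
  carrying the allele opposite to `i`'s at \(\ell\) (the free-DNA pool again
  mirrors the population).

Birth and death are independent \(\pm 1\) events, so population size must be
regulated by the density-dependent death term. This closure is the simplest
one compatible with independent state-change vectors; its quasi-equilibrium
population size is \(N_0 \bar f\), which equals \(N_0\) exactly for a neutral
(`m = 0`) population — the homeostasis test uses exactly that setting. The
rate functions sit behind a single seam (`event_rates()` mirrors them in R
for inspection) so alternative closures can be swapped.

### Exact simulation and tau-leaping

The reference algorithm is Gillespie's exact SSA. For large compartments the
simulator optionally advances by Poisson leaps: channels whose source
compartment exceeds `tau_leap_threshold` (default 100) are leapt over a step
\(\tau\) chosen by the standard mean/variance bound (relative compartment
change at most `tau_eps = 0.03` per leap), while the remaining channels run
exactly (one exponential clock over the small-channel total; if it fires
within \(\tau\) the leap is shortened and one exact event is executed). A
leap that would drive any count negative is re-drawn with \(\tau\) halved,
falling back to an exact step. When a candidate \(\tau\) is worth fewer than
ten exact events the step is taken exactly. Correctness is defined against
pure SSA: the fixation-time distributions with and without leaping are
compared by a two-sample test in the suite, and a two-genotype
mutation-free invasion experiment reproduces the Moran-model fixation
probability within binomial error.

All replicates derive child seeds deterministically from one master seed
(`sample.int` under the master seed), so arms and replicates are
independently reproducible; with equal seeds the event sequence is identical,
and scaling \(B\), \(\mu\), `r` together only rescales the clock (both are
tested exactly).

### The mean-field limit and the convergence check

The infinite-\(N\) frequency dynamics of this process have selection term
\(B\,(f_i - \bar f)\,x_i\), *not* \((m_i - \bar m)\,x_i\): the two agree only
to first order in fitness differences, and on these landscapes fitness
differences are not small by construction (the peak is pinned at \(m = 1\),
so \(e^{\bar m}\) rescales selection by a factor near \(e\) relative to
mutation). The ODE module therefore exposes
`dynamics_params(fitness_scale = "fisherean")`, the exact mean-field limit of
the simulator, and the convergence test measures the sup-norm distance
between the replicate-averaged peak-frequency trajectory and that limit at
\(N_0 = 10^3, 10^4, 10^5\). The distance must fall monotonically. The test
runs at \(\mu = 10^{-3}\): establishment of new mutants is then nearly
deterministic and the remaining deviation is dominated by drift, which
vanishes with \(N_0\). At lower \(\mu\) the deviation still falls
monotonically, but it is dominated by the stochastic waiting time for
establishment, which decays only logarithmically in \(N_0\) — that lag *is*
the Fisher–Muller ingredient, not a simulator artifact.

## Screens and the recombination effect

`screen_deterministic()` maps \(T_\mathrm{fix}\) over topographies and
parameter grids (deterministic order, resumable by topography id);
`summarize_by_lfg_count()` turns a screen into box-plot statistics (type-7
quantiles, 1.5 IQR whiskers) with orbit-class weights expanded exactly.
At the standard parameter set the full four-locus screen over all
topographies with 0–6 LFGs (6476 landscapes, 401 orbit classes) shows the
median \(T_\mathrm{fix}\) rising with the number of LFGs and above 1
whenever LFGs are present, while a handful of multi-LFG topographies
nevertheless accelerate (\(T_\mathrm{fix} < 1\)) — position matters, not just
count. `rank_concordance()` compares two screens; the recombination effect of
a topography is robust to `s` and \(\mu\) but varies substantially between
recombination rates.

`screen_stochastic()` samples topographies, runs both arms of the stochastic
model per population size, and keeps the deterministic \(T_\mathrm{fix}\) as
a reference column. In finite populations drift generates negative linkage
disequilibrium among beneficial mutations (clonal interference), which
recombination resolves — the Fisher–Muller effect. At intermediate
\(N_0\mu\) this outweighs the epistatic deceleration: stochastic
\(T_\mathrm{fix}\) falls below its deterministic counterpart and below 1 on
most sampled 3-LFG topographies. The packaged check uses 10 sampled
topographies at \(N_0 = 10^4\), \(\mu = 10^{-4}\) (so \(N_0\mu = 1\), inside
the strong-selection strong-mutation regime where concurrent polymorphism
makes recombination matter) with 10 replicates per arm — enough for the sign
of the effect; published-scale screens (50 topographies, 50 replicates) run
through the same functions.

## Physiological epistasis

`estimate_physiological_epistasis()` regresses the fitness deficit
\(1 - m_g\) against \(k_g^{\hat\varepsilon}\) over all \(2^L\) genotypes
(LFGs enter at fitness 0), by multi-start profiled nonlinear least squares
(starts \(\hat\varepsilon \in \{0.25, 0.5, 1, 2, 4\}\); for a fixed exponent
the scale is linear, so the 1-D profile is optimized with `nlminb` on the log
scale). Two variants exist:

* `fix_b = TRUE` (default): the scale is anchored at the landscape's `s`, so
  \(\hat\varepsilon\) measures pure curvature. Every 6-LFG landscape then has
  \(\hat\varepsilon > 1\) (positive epistasis in the deleterious-mutation
  convention), as expected when holes are punched below a linear baseline.
* `fix_b = FALSE`: both scale and exponent free. This variant recovers
  \((s, \varepsilon)\) exactly on LFG-free landscapes but can *flatten* on
  topographies whose LFGs sit near the peak (`k = 1`): a large scale with a
  tiny exponent fits the high deficits at small `k` better, driving
  \(\hat\varepsilon\) toward zero. Because that artifact contradicts the
  qualitative character of these landscapes, the anchored variant is the
  default.

Either way, \(\hat\varepsilon\) is a poor predictor of the recombination
effect: across all 3003 six-LFG landscapes the correlation with
\(T_\mathrm{fix}\) explains under a quarter of the variance at the standard
parameter set (and depends strongly on the recombination rate at which
\(T_\mathrm{fix}\) is measured), so one-dimensional curvature summaries
cannot substitute for the actual topography.

## Defaults and numerical choices

| Parameter | Default | Meaning |
|---|---|---|
| `L` | 4 | loci (screens); 2 for the analytic valley case |
| `s` | 0.05 | fitness reduction per deleterious allele (Malthusian, per unit time) |
| `eps` | 1.0 | baseline epistasis exponent (dimensionless) |
| `mu` | 1e-5 | mutation rate per locus per unit time |
| `r` | 0.05 | total per-genome uptake rate per unit time |
| deterministic threshold | 0.99 | peak frequency defining fixation |
| stochastic threshold | 0.95 | same, finite populations |
| `B` | 1 | birth/death clock scale |
| `N0` | 1e4 | carrying-capacity parameter |
| `n_reps` | 50 | replicates per arm |
| `tau_leap_threshold` | 100 | compartment size above which leaps apply |
| `tau_eps` | 0.03 | relative compartment change per leap |

The numeric values of the standard parameter set are *inferred defaults*,
chosen as the midpoints of the parameter sweeps the screens explore; they are
echoed verbatim into every output manifest. Tests and the bundled analysis
script scale problem sizes down (0–6 LFGs rather than 0–10, 10 rather than
50 replicates) — the medians-by-count and sign results are stable under
these reductions because orbit weighting keeps the deterministic screen
exact and the stochastic effects tested are sign effects, not fine
quantiles.

Degenerate inputs are rejected at construction (negative rates, thresholds
outside (0,1), `s L^eps > 1`, LFGs on the extremes, oversampling a
topography class). Frequencies returned by the integrator are clipped at
zero and renormalized only when the simplex drift exceeds `1e-8`, and each
intervention is counted in an attribute.

## What the generator does and does not emulate

Enumerated and sampled topographies cover the model's own universe
exhaustively or uniformly — they are the study conditions, not noisy data.
What passing tests on them do *not* establish: behavior on empirical
landscapes with heterogeneous selection coefficients per locus, fitnesses
between 0 and the baseline (the LFG overlay is all-or-nothing), linked-locus
fragment uptake (fragments here are single alleles), explicit free-DNA pool
dynamics or competence regulation, or diploid genetics. The two-locus
analytic results are exact within the model; all multi-locus statements are
numerical screens.
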