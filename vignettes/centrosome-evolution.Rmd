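---
title: "Modelling the early evolution of tetraploid cells: centrosome loss by asymmetric clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the early evolution of tetraploid cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrodyn)
library(dplyr)
```

## The biological problem

Cytokinesis failure produces a binucleate, tetraploid cell that carries
twice the normal complement of both chromosomes and centrosomes. Extra
centrosomes predispose the cell to multipolar mitoses, which scatter the
genome across three or four daughters; yet cell populations evolved from
newly formed tetraploids end up with near-tetraploid chromosome numbers
and a *normal* centrosome number. `centrodyn` implements the quantitative
machinery behind this observation in two human cell lines, DLD-1
(pseudodiploid colorectal cancer) and RPE-1 p53^−/−^ (non-cancer,
hTERT-immortalized): a combinatorial model of chromosome partitioning in
multipolar divisions, linear ODE models of centrosome-class population
dynamics, their eigen steady states, parameter fitting and sensitivity
scans, and a stochastic lineage simulator that generates the synthetic
data every deterministic result is tested against.

## Random chromosome partitioning in multipolar divisions

A division with `p` poles of a mother with `k` replicated copies of each
of `M` nonhomologous chromosomes is modelled with three assumptions:
sister chromatids always go to different poles, the pole pair receiving
each sister pair is uniform over all unordered pairs of distinct poles,
and chromosomes partition independently. Each chromosome type then has
$\binom{p}{2}^k$ equally likely assignments, and a *given* daughter cell
misses a chromosome entirely (nullisomy) or keeps a single chromatid
(monosomy) with per-chromosome probabilities

$$q_{\mathrm{null}} = \Big(\frac{p-2}{p}\Big)^{k}, \qquad
  q_{\mathrm{mono}} = \frac{2k\,(p-2)^{k-1}}{p^{k}},$$

mutually exclusive events whose sum is the combined probability. Because
chromosome types are i.i.d., the number of affected chromosomes in a
daughter is $B(M, q)$ and the chance of at least one event is
$1-(1-q)^M$. For a tetraploid human cell ($k=4$, $M=23$) dividing
tripolarly, nearly every daughter bears a monosomy or worse:

```{r partition}
partition_event_probs(partition_spec(n_chromosome_types = 23, ploidy = 4,
                                     n_poles = 3))
```

The per-chromosome binomial parameter is called `q_event` in the
documentation to keep it apart from the population model's `q` (the
probability that a normal cell divides without cytokinesis failure); the
symbols collide in the source material.

Two edge cases are worth stating. A bipolar division (`p = 2`) forces
every pole to receive all `k` chromatids, so no missegregation occurs —
except in the degenerate `k = 1` case, where "all chromatids" is a single
chromatid and every daughter is trivially monosomic; the closed forms and
the exhaustive-enumeration oracle agree on this. All oracle checks in the
test suite use exact integer counting over all $\binom{p}{2}^k$
assignments (for $k \le 4$, $p \le 4$), compared by cross-multiplied
integer identities so equality is exact, not approximate.

## Population dynamics of centrosome classes

Cells are classed by mitotic centrosome number: C2 (normal), C4 (doubled,
the product of cytokinesis failure), C6 (tripled, the extra-centrosome
daughter of an asymmetrically clustered bipolar division), and — in
Model II — SC, "super-clustering" C4 cells that cluster their extra
centrosomes efficiently and divide bipolarly. The fate rules are:

* a C2 cell divides at rate $b_{C2}$; with probability $q$ normally
  (two C2), otherwise its cytokinesis fails and it becomes one binucleate
  C4 (Model I) or, with probability $v$, an SC cell (Model II);
* a C4 cell divides at rate $b_{C4}$; with probability $p$ bipolarly —
  symmetrically (two C4) with probability $r$, asymmetrically
  (C2 + C6) otherwise — and multipolarly with probability $1-p$, in which
  case all progeny die except that a viable C4 daughter survives with
  probability $fs$ (one combined constant);
* an SC cell divides at rate $b_{C2}$, symmetrically (two SC) with
  probability $r_S$, asymmetrically (C2 + C6) otherwise;
* C2/SC, C4 and C6 cells die at rates $d_{C2}$, $d_{C4}$, $d_{C6}$; C6
  divisions are multipolar and fatal, which is folded into $d_{C6}$.

These rules yield a linear constant-coefficient system
$\mathrm{d}X/\mathrm{d}t = P X$; `build_rate_matrix()` assembles $P$ for
either model, and setting $v = 0$ collapses Model II onto Model I exactly.
All rates are per day, matching the published units.

`centro_preset()` ships the published parameter table verbatim for both
cell lines, together with the measured day-0 fraction of normal cells
(`alpha` = 0.10 for DLD-1, 0.127 for RPE-1 p53^−/−^). The day-0 state
splits the extra-centrosome cells between SC and C4 in proportion
$v : (1-v)$: the source never states the initial SC share, but the day-0
population was created by one induced cytokinesis-failure event and $v$
is precisely the probability that such an event yields an SC cell. The
rule is a pluggable argument (`sc_seeding = "none"` starts all
extra-centrosome cells as C4), so the assumption is testable rather than
baked in.

```{r model2}
params <- centro_preset("dld1")
traj <- simulate_population(params, model = "II", days = 12, step = 0.5)
day12 <- traj[traj$time == 12, ]
c(extra_pct = 100 * extra_centrosome_fraction(day12),
  sc_share_pct = 100 * sc_share_of_extra(day12))
```

The observable scored experimentally is the fraction of cells with
supernumerary centrosomes; `extra_centrosome_fraction()` includes C6
cells by default (any cell with more than the normal number), with
`include_C6 = FALSE` available because the published convention is
unstated — under the fitted parameters C6 cells are a sub-percent
population and the two conventions are nearly indistinguishable.

### Numerical solution

The default solver is the matrix exponential, exact for a linear
constant-coefficient system: $P$ is eigen-decomposed once and
$X(t) = V e^{\Lambda t} V^{-1} X(0)$ is evaluated at each output time.
If the eigenvector matrix is numerically ill-conditioned
(reciprocal condition number below $10^{-10}$ — a defective or nearly
defective $P$, which no valid parameter set produces in practice), the
solver falls back to scaling-and-squaring (`Matrix::expm`) per time
point. An adaptive integrator (`deSolve::lsoda`, absolute tolerance
$10^{-12}$, relative $10^{-10}$) is retained behind `method = "ode"` as
an independent cross-check; the test suite requires $10^{-8}$ relative
agreement between the two routes over the full 12-day DLD-1 trajectory,
which is why the adaptive tolerances are set well below that.

## Steady state: the leading eigenpair

Whenever division outpaces death the total population grows without
bound, but the per-type *fractions* $f_i = X_i / \sum_j X_j$ obey
$\mathrm{d}f/\mathrm{d}t = Pf - C(t)f$ with
$C(t) = \sum_j (\sum_k P_{kj}) f_j$, and converge to the normalized
eigenvector of $P$ associated with the largest eigenvalue; that
eigenvalue is the asymptotic exponential growth rate. `steady_state()`
computes the pair, selecting by largest real part and *raising a
diagnostic error* if two real parts lie within $10^{-9}$ of the maximum
(the analysis assumes a unique dominant mode; silently picking one would
hide a modelling problem). The eigenvector sign is fixed by requiring a
non-negative dominant entry before normalizing to sum one.

`verify_against_integration()` closes the loop without trusting the
eigen-solver: it integrates the full system to a long horizon, normalizes,
and compares in $L_\infty$, refusing horizons too short for the spectral
gap ($e^{-\mathrm{gap}\cdot T} \ge \mathrm{tol}$). It also checks that the
late-time log-growth slope of the total population equals the leading
eigenvalue. The suite runs this consistency check for both presets and
for 50 random valid parameter draws.

```{r steady}
steady_state(build_rate_matrix(centro_preset("rpe1_p53ko"), "II"))
```

## Fitting and sensitivity

`fit_time_course()` fits any subset of $\{v, r_S, b_{C2}, b_{C4}, q\}$ to
an observed extra-centrosome time course by least squares on fractions
(the published objective is unstated; unweighted is the default, with
optional binomial inverse-variance weights when per-day cell counts are
recorded). Bounds default to the published fitting ranges
($v \in [0, 0.6]$, $r_S \in [0.5, 1]$, $b_{C2} \in [0.8, 1.2]$,
$b_{C4} \in [0.6, 1]$, $q \in [0.975, 1]$). Optimization is fully
deterministic: a regular grid of five points per free dimension seeds
bounded local refinement (L-BFGS-B with central finite differences at
step $10^{-5}$ — the step matters; the default $10^{-3}$ stalls the
refinement around $10^{-9}$ in the loss) and the best refined optimum is
returned, along with per-start losses so multi-modality is visible.
Observation days default to the experimental cadence
$\{0, 2, \dots, 12\}$.

`sensitivity_scan()` sweeps one parameter with the others fixed and
reports the steady-state or fixed-day extra-centrosome fraction, the
monotone direction, and the metric range. Two structural facts the suite
asserts: under Model I the steady-state fraction of extra-centrosome
cells is non-increasing in $q$ (cytokinesis failure is the only source of
new extra-centrosome cells), and under Model II the metric's range is
largest for $r_S$ among the fitted parameters (asymmetric SC divisions
are the only leak from the self-sustaining SC compartment).

### What is and is not identifiable

With seven time points and binomial noise at $n = 300$ cells scored per
day, the two Model II fitting parameters are *not* equally identifiable
from the extra-centrosome fraction. A linearized (Cramér–Rao) analysis
at the DLD-1 fitted point gives standard errors of about 0.03 for $v$
and 0.006 for $r_S$; but across the full fitting box the median bound
for $v$ rises to roughly 0.16, because at small $r_S$ the SC compartment
dies out and the observable barely depends on $v$ at all. Noiseless
recovery is accurate to better than 0.02 for both parameters anywhere in
the box (the optimum is then exact); under noise, the suite asserts a
pooled median recovery error (both parameters, twenty random truths)
below 0.05 and a per-parameter median for $r_S$ below 0.05, and makes no
per-parameter claim for $v$ outside the well-identified regime — no
estimator could honour one.

## The stochastic generator

`simulate_lineages()` is an exact continuous-time (Gillespie) simulation
of the branching process whose mean-field limit is the ODE system; its
per-event core is compiled code driven by R's RNG, so a single
`set.seed()`-style root seed makes entire multi-replicate runs
reproducible (replicates consume one RNG stream sequentially). Exponential
waiting times use the published per-day rates directly — the reason a
continuous-time scheme was chosen over discrete generations. When the
population exceeds the cap (default $2\times10^4$) it is uniformly
subsampled back to the cap, mirroring experimental passaging; this keeps
twelve-day runs at desk scale despite mean-field growth of order
$e^{14}$, and leaves expected fractions unbiased (asserted by a
capped-versus-uncapped comparison). An optional event log records every
division and death with cell ids, event kind and daughter types, for
lineage-level checks.

`sample_observations()` emulates the experimental read-out: on each
sampling day the observed count of extra-centrosome cells among $n$
scored cells is $\mathrm{Binomial}(n, f)$ at the simulation's true
fraction $f$. The default $n = 300$ reflects the scale of cells scored
per time point in the source data. `simulate_karyotype_evolution()`
couples the lineage rules to the partitioning model: bipolar divisions
copy the karyotype (no missegregation), multipolar divisions draw
per-chromosome partitions with the tripolar/tetrapolar split at 50:50 by
default (both modes occur at comparable frequency in newly formed
tetraploids; exact proportions are only available graphically), and a
viability filter removes nullisomic daughters (always lethal) and,
optionally, monosomic ones (survival probability defaults to 1 because
only certain monosomies are lethal).

What the generator deliberately does not emulate: cell-cycle phase
structure (the model tracks mitotic classes only), density-dependent
rates, spatial or contact effects, and the occasional trinucleated
daughters of incomplete multipolar cytokinesis beyond the single $fs$
survival parameter. Passing tests therefore validate the machinery under
the model's own assumptions, not those features of real cultures.

## Bespoke statistics

`symmetry_score()` quantifies DNA-distribution asymmetry at ana-/telophase:
per-pole signal fractions are divided by the even share $1/p$ and the
score is the standard deviation of the ratios — 0 for a perfectly even
division. The population-SD convention (divisor $p$) is the default since
a cell's poles are its complete set of measurements, with the sample
convention available. `classify_karyotype()` bins chromosome counts into
near-diploid, highly aneuploid, and near-tetraploid; the source never
prints its bin edges, so the defaults (46 ± ~10% → [41, 51] and
92 ± ~10% → [83, 101]) are explicit, visible configuration rather than
hidden constants.

## Problem sizes used in validation

The suite validates the stochastic–deterministic correspondence with 200
replicates of 5 000 cells over a 4-day horizon (ensemble mean fractions
within three standard errors of the ODE), Monte-Carlo partition
frequencies at $10^5$ draws (four binomial standard errors), 50 random
parameter draws for the steady-state consistency check, and 20 random
truths for parameter recovery. These sizes give the sampling-error bars
quoted above while keeping a full run of the default suite in the
minutes range.

## Known limitations

* The models are linear in abundances: no crowding, no interaction
  between classes beyond the fate table.
* `fs` is a single lumped survival probability; the underlying
  multipolar-fate structure is not resolved further, matching the
  published parameterization.
* The karyotype simulator assigns every cell the C4 division/death rates
  and does not feed chromosome content back into fitness beyond the
  viability filter.
* The symmetry score and karyotype bins operate on numbers the user
  supplies; image quantification is out of scope.
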