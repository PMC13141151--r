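---
title: "Hybrid stochastic-deterministic simulation of ODE models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid stochastic-deterministic simulation of ODE models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridsim)
```

## The problem

Biochemical models routinely mix species present at a handful of copies per
cell (mRNAs, promoter states, synaptic tags) with species present at
thousands to millions of copies (proteins, metabolites). The low-copy
species need a discrete stochastic description; treating the abundant ones
the same way wastes almost all of the computational effort on events that
individually do not matter. Hybrid solvers split the system, but most of
them require an explicit reaction network, and many models of interest are
written directly as ODEs with effective rate laws where no unique network
exists. `hybridsim` works directly on the ODE right-hand side: it decides
*automatically* which species to treat stochastically, derives birth-death
stochastic updates from the ODE fluxes, and couples them to stiff ODE
integration in one event-driven loop.

The pipeline is:

1. (optional) convert concentrations to molecule counts
   (`convert_to_counts()`);
2. deterministic pre-simulation (`run_presim()`) and per-species feature
   extraction (`extract_features()`);
3. regime assignment by a calibrated random forest (`predict_partition()`),
   trained on a synthetic corpus (`generate_corpus()`) labeled by an
   abundance-quantile rule (`label_by_rule()`);
4. hybrid simulation (`build_hybrid_system()`, `simulate_hybrid()`,
   `run_ensemble()`), with exact-SSA / tau-leaping / Haseltine-Rawlings /
   pure-ODE baselines (`ssa_direct()`, `tau_leap()`, `hr_hybrid()`,
   `ode_solve()`) and benchmark statistics (`compare_methods()`).

The partition is computed once, before the run, and stays fixed: online
reclassification is out of scope by design.

## Units and the count adapter

Stochastic updates only make sense in molecule numbers. For a species
declared in concentration units inside compartment $c$ the adapter uses
$\Omega = N_A V_c u$ molecules per concentration unit ($N_A =
6.02214076\times 10^{23}\,\mathrm{mol}^{-1}$, $V_c$ in litres, $u$ the
molar-unit factor from the enumerated set M/mM/µM/nM — no free-text unit
parsing). The converted model evolves $n = \Omega \circ x$ with drift
$\dot n = \Omega \circ f(n/\Omega, t)$; time units are untouched. Per-
compartment volumes make multi-compartment models (e.g. synaptic vs
dendritic pools) work without touching the equations.

## Production-degradation decomposition of the drift

The stochastic channels need non-negative birth and death fluxes per
species with $f^+ - f^- = f$. When the user does not supply them, the
zero-clamp rule derives a minimal split:

$$f^+_i(x,t) = \max\!\big(f_i(x\,[x_i{=}0],\, t),\, 0\big), \qquad
  f^-_i(x,t) = \max\!\big(f^+_i(x,t) - f_i(x,t),\, 0\big).$$

The rationale: degradation of mass-action type is proportional to the
species itself and vanishes at zero copies, so evaluating the drift with
the focal species clamped to zero isolates production. For any drift whose
production terms do not involve the species itself the split is exact at
all non-negative states, and $f^-_i = 0$ whenever $x_i = 0$, so the jump
process can never be pushed negative. Autocatalytic production
($f^+ \propto x_i$) breaks the identity; this is detected on a fixed probe
set (initial state plus 32 states scaled componentwise by Uniform(0.1, 10),
seed 1234), flagged, and reported with a warning asking for an explicit
decomposition — the engines refuse to build channels from a split that is
flagged inconsistent. Drifts undefined at $x_i = 0$ (e.g. terms dividing by
$x_i$) are likewise rejected with instructions to supply an explicit split.
How constant sinks that do not vanish at zero copies "should" behave is
genuinely ambiguous; we clip $f^-$ at zero and count the clips during
simulation, warning when more than 0.1% of evaluations were clipped.

## Pre-simulation and features

`run_presim()` integrates the drift with `deSolve`'s lsoda (stiff-capable,
adaptive; default rtol $10^{-6}$, atol $10^{-9}$) on a uniform grid,
defaulting to horizon 500 time units and 2001 points. The horizon is a
compromise: long enough for the families in the training corpus to settle
or complete several oscillation periods, short enough to keep a 40-model
corpus cheap. Very stiff or ultraslow systems may need a longer horizon;
it is an argument everywhere.

`extract_features()` computes 18 descriptors per species covering
amplitude (mean, min, max, q05/q50/q80/q99, log10(1+·) variants),
variability (population sd, cv, a Fano-style ratio sd²/(mean+ε)), dynamic
range (range, final/max, fraction of points above half-maximum) and
temporal behaviour (count of strict sign changes of the first differences,
lag-1 autocorrelation of the mean-removed series). Conventions are pinned
so labels are reproducible across implementations: type-7 quantiles,
population (not sample) standard deviation, ε = 10⁻⁹ denominators guards,
autocorrelation defined as 0 for constant series. The exact feature list is
a package design choice; it deliberately includes the two label-defining
quantiles so that the labeling rule is representable by the classifier, and
the remaining features let it generalize beyond a bare threshold.

## Labeling rule, forest, calibration

Ground-truth labels use a conservative abundance rule: a species is
*stochastic* (1) iff $q_{0.80}(y) < 200$ **and** $q_{0.99}(y) < 200$
molecules along its deterministic trajectory, with strict inequalities
exactly at the boundary. The conjunction makes transient-burst species —
low typical abundance but a high 99th percentile — deterministic, which is
where plain mean/median-abundance heuristics err.

`train_partition_model()` fits a probability random forest (`ranger`; 300
trees, unlimited depth, $\sqrt F$ candidate features per split, balanced
class weights, fixed seed, one thread for reproducibility). Probabilities
are calibrated by isotonic regression fitted on *out-of-fold* predictions
from leave-one-model-out (LOMO) folds — holding out whole models, not
species, because the deployment scenario is an unseen model. The calibrated
probability is thresholded at a fixed 0.5; a tie goes to the stochastic
regime, erring toward the higher-fidelity description. Whether published
LOMO summaries of such classifiers average per-fold metrics or pool the
confusion matrix is often unstated, so `evaluate_lomo()` reports both;
folds whose ground truth is single-class contribute balanced accuracy over
the defined class only and are flagged and excluded from the mean MCC.

## The synthetic training corpus

No public corpus ships with the package, so `generate_corpus()` draws one:
by default 40 models over five equally weighted families — linear
birth-death chains (5-6 species), gene-expression cascades with Hill
activation between mRNA/protein tiers (10-12 species), repressilator
variants with randomized repression strength (6 species),
Michaelis-Menten conversion modules (4-5 species) and negatively
autoregulated two-species motifs — roughly 250 species in total. Stationary
target scales are drawn log-uniformly from a *bimodal* abundance
distribution (low-copy 1-120, abundant 400-10⁶ molecules) and the rate
constants are then solved so each species' deterministic stationary value
equals its target; every model carries an exact decomposition and passes
validation. The gap between the scale ranges straddles the 150-300
molecule band deliberately: it reproduces a regime in which relabeling at
thresholds between 150 and 300 flips only a small fraction of species,
which is what makes a fixed 200-molecule rule defensible in the first
place. With probability 0.6 a cascade contains one transient-burst mRNA
(initial spike 2000-6000 copies decaying at rate 0.15-0.3 to a low-copy
baseline): its mean and median sit below 200 while its q99 sits far above,
so the quantile rule and the abundance heuristics provably disagree — these
species are why the forest strictly outperforms the heuristics under LOMO.
Repressilator variants sample their maximal transcription rate from the
low-copy range only, reflecting that low-copy oscillators are the regime
where the stochastic question is interesting.

What the generator does *not* emulate: real kinetic diversity (most
families are stationary by construction rather than transiently excitable),
parameter correlations of curated model repositories, conservation laws,
and models whose abundances concentrate inside the 150-300 band. Passing
classifier tests on this corpus therefore demonstrates rule recovery and
generalization across these synthetic families, not performance on any
specific published model set; the threshold-sensitivity number in
particular is a property of the corpus composition.

## The hybrid engine

With stochastic set $S$ and deterministic set $D$, the engine simulates a
piecewise-deterministic Markov process. Each iteration: evaluate birth and
death propensities $a^\pm_i$, $i \in S$, at the current hybrid state and
local time (so pulsed inputs are seen at the right time); clip negatives to
zero (counted); draw an exponential waiting time $\tau$ with rate
$a_0 = \sum a$; advance by $h = \min(\tau, \Delta t, \text{gap to next
input event}, T - t)$, integrating the $D$ coordinates with lsoda while the
counts stay frozen; if $\tau$ bound, fire one channel chosen by
cumulative-sum inversion over channels in species order with birth before
death (a fixed, documented tie-break), apply ±1 clamped at zero.

Numerical choices worth spelling out:

* **Frozen propensities.** Propensities are re-evaluated after every event
  and at least every $\Delta t$, not integrated continuously. The
  approximation error is controlled by $\Delta t$ (default 0.1 in the
  benchmark's time units): shrinking it tightens the statistics at linear
  cost in ODE restarts. The exact integrated-hazard alternative exists in
  the package as the Haseltine-Rawlings baseline, so the two conventions
  can be compared directly on any network. Note that when *all* species
  are stochastic the frozen-propensity loop is statistically exact anyway
  (re-drawing an exponential clock with an unchanged rate is memoryless),
  which is the basis of the stochastic-limit equivalence test.
* **Initial counts** round half-up; fractional initial conditions for
  discrete species have no canonical treatment, so the convention is fixed
  and documented.
* **Recording.** Counts are recorded on the output grid as right-continuous
  step functions; deterministic coordinates are linearly interpolated
  between segment endpoints, which are at most $\Delta t$ apart, so the
  interpolation error is far below solver tolerance at the default
  settings.
* **RNG.** One R RNG stream per replicate (`withr::with_seed`), consumed in
  a fixed order (waiting time, then channel), so every run is bitwise
  reproducible and ensemble replicate $r$ (seed = base + $r$) is
  independent of execution order.

## Reference solvers

`ssa_direct()` is the Gillespie direct method with exact event timing; zero
total propensity freezes the state until the next declared input event (not
an error). `tau_leap()` fires Poisson counts with frozen propensities over
a fixed leap; a step that would go negative is retried with the leap halved
(up to 20 times) and then falls back to a single exact event — a standard,
testable policy. `hr_hybrid()` partitions *channels*: fast channels form a
deterministic drift $\sum \nu_j a_j$ (deterministic ODE, not Langevin);
slow channels fire exactly via the integrated hazard $\dot g = \sum_{slow}
a_j(x(t),t)$ with the firing time located by lsodar's root-finder on
$g = -\log u$, and the firing channel selected from the propensities at the
located time (not the interval start). On the two-stage benchmark the
natural partition — mRNA channels slow, protein channels fast — reproduces
the published statistics of that method.

## Benchmark statistics

`stationary_stats()` pools grid samples after a burn-in (ergodic averaging;
default burn-in 50, grid step 0.1, horizon 5000) — cheaper than endpoint
ensembles at equal accuracy for these ergodic benchmarks; an `endpoint`
mode exists and is what `compare_methods()` uses for the deterministic ODE
row, so a deterministic method reports its steady state with variance
exactly 0 rather than a numerically-tiny transient variance.
`relative_error()` is defined (the common published tables leave the
formula unstated) as the mean absolute relative deviation of stationary
means across species against the analytic ODE steady state, which
`compare_methods()` computes at run time from the deterministic solve.

The two-stage gene-expression benchmark ($\dot M = k_1 - d_1 M$, $\dot P =
k_2 M - d_2 P$; $k_1 = 5$, $d_1 = 1$, $k_2 = 50$, $d_2 = 0.1$) was pinned
to those round-number rates because they force the steady state
$(M^*, P^*) = (5, 2500)$ exactly and give closed-form stationary moments
under exact stochastic dynamics: $\mathrm{Var}(M) = 5$ (Poisson) and
$\mathrm{Var}(P) = P^*(1 + k_2/(d_1 + d_2)) \approx 1.161\times 10^5$.
Every engine in the package is tested against these oracles.

## Problem sizes and statistical tolerances

The default study protocol integrates the benchmark to $T = 5000$ with
burn-in 50 on a 0.1-spaced grid (≈ 2.5 million SSA events; single
replicate), and evaluates the classifier on the 40-model default corpus
(≈ 260 species) with full inner-calibrated LOMO. At these sizes the
Monte-Carlo standard error of a single-run stationary mean of $M$ is about
1.4% at $T = 2000$ and 0.9% at $T = 5000$, and of a stationary variance
about 3-6%; test tolerances are set at 2-3 standard errors. One
consequence is worth knowing: a mean-based relative error measured from a
single $T = 2000$ run has an *expected* value near 0.011 from sampling
noise alone, so comparisons of such numbers between solvers at equal
protocol are only meaningful to that resolution.

## Known limitations

* The partition is fixed at initialization; species that migrate between
  regimes during a run are not re-classified.
* Drift-derived channels are per-species birth/death pairs; correlated
  multi-species reaction events (e.g. binding) are represented only through
  their net per-species fluxes in the hybrid engine (the explicit
  `reaction_network()` interface retains them for the reference solvers).
* No SBML import/export and no symbolic processing of drift expressions;
  models enter as R closures or as declarative files referencing registered
  families.
* Memory mechanisms (delays, renewal kinetics, cell division) are not
  represented; compartments or explicit intermediate species can emulate
  some of them inside the ODE.
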