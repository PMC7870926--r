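---
title: "Modelling in vivo sRNA target-search kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling in vivo sRNA target-search kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`srnakinetics` quantifies how a bacterial small RNA (sRNA) finds and
destroys its target mRNA in vivo, using the SgrS–*ptsG* system of
*E. coli* as the motivating case. This vignette is the package's own
account of the models it implements, the assumptions behind them, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The kinetic model

Three species are tracked as per-cell copy numbers: free target mRNA $p$,
free sRNA $S$, and the sRNA–mRNA complex $Sp$:

$$\frac{dp}{dt} = \alpha_p - \beta_p\,p - k_{on}\,S\,p + k_{off}\,Sp$$
$$\frac{dS}{dt} = \alpha_S - \beta_{S,p}\,S - k_{on}\,S\,p + k_{off}\,Sp$$
$$\frac{dSp}{dt} = k_{on}\,S\,p - (k_{off} + k_{cat})\,Sp$$

Assumptions worth making explicit:

* **Deterministic mass action.** The model describes population-average
  copy numbers; single-cell stochasticity enters only through the
  measurement noise model, not the dynamics. Hfq is not an explicit
  species, so $k_{on}$ and $k_{off}$ are apparent rate constants that fold
  in chaperone binding and facilitated annealing.
* **Pre-stress steady state.** Before induction the target is at its
  transcription–degradation balance, so $\alpha_p = \beta_p [p]_0$
  (`steady_state_transcription()`) and the fit starts the target at
  $[p]_0 = \alpha_p/\beta_p$. Free sRNA and complex start at their
  measured $t=0$ means (basal expression is small but nonzero).
* **Units.** State is copies per cell. $k_{on}$ is accepted and reported
  in M$^{-1}$s$^{-1}$ and converted internally through the cell volume
  (default 0.7 μm³, Avogadro constant fixed at its exact SI value); the
  conversion is exposed as `copies_to_molar()` / `molar_to_copies()` and
  tested explicitly. At 200 copies and 0.7 μm³ the concentration is
  0.474 μM, conventionally quoted as ~0.48 μM.

### Integration

Rate constants span roughly five orders of magnitude (fastest complex
turnover ~0.5 s$^{-1}$ against a 1200 s horizon), so integration is
adaptive with rtol $10^{-8}$ / atol $10^{-10}$. The default backend is an
embedded Dormand–Prince 5(4) pair implemented in compiled code: the global
fit evaluates tens of thousands of trajectories and an R-level right-hand
side dominated the runtime by two orders of magnitude. The system is at
most mildly stiff at these scales, and `method = "lsoda"` selects the
stiff-capable `deSolve::lsoda` backend; the two agree to better than
$10^{-6}$ relative and both are checked against an independent fixed-step
RK4 oracle in the tests.

## Global fitting

Six curves (three species × wild-type RNase E and a truncation mutant
deficient in co-degradation) are fitted simultaneously. The measured
quantities $\alpha_p$, $\beta_p$ and the two sRNA decay rates
$\beta_{S0} \le \beta_{S,p} \le \beta_{S,\mathrm{total}}$ (RNase E mutant
and wild-type washout measurements) are fixed inputs; the free parameters
default to $\alpha_S$, $\beta_{S,p}$ (box-bounded by the measured decay
rates), $k_{on}$, $k_{off}$ and a co-degradation rate per background.

### Objective

The objective is the global $R^2 = 1 - SS_{res}/SS_{tot}$ with *Poisson
weighting*: both sums of squares are weighted by $1/f_i$, the reciprocal
of the fitted value, since for counting data the variance is approximately
the mean. Weighting $SS_{tot}$ the same way as $SS_{res}$ keeps the two
sums on one scale; an `"unweighted"` switch provides the ordinary $R^2$
for comparison, since either reading of a weighted $R^2$ is defensible.
The group mean entering $SS_{tot}$ is computed per species per background
and the sums pooled, so that no single abundant species dominates the
objective. Where a fitted value can touch zero (the complex at $t=0$), the
weight uses a floor of $10^{-6}$ copies — far below one molecule, so it
only prevents division by zero.

Complex copy numbers sit near the imaging background, which makes their
total variance — and hence their $R^2$ — uninformative; per-curve $\chi^2$
statistics with significance levels are therefore reported alongside
(`chi_squared_gof()`).

### Two co-degradation rates

The truncation mutant cannot co-degrade the duplex efficiently, but minor
degradation routes remain, so by default the fit carries separate
`k_cat_wt` and `k_cat_mut`; `shared_kcat = TRUE` gives the strict
five-parameter variant. The synthetic generator's default
`k_cat_mut = 0.02` s$^{-1}$ encodes the same reading: strongly impaired
but not exactly zero. $\alpha_S$ is shared between backgrounds.

### Optimizer

The search is multi-start Nelder–Mead in log10 parameter space (log scale
because the box bounds span decades), drawn log-uniformly over the bounds
under a fixed seed, with a quadratic penalty outside the box; the best
starts are polished by bounded L-BFGS-B *on the same objective*. A
separate least-squares refinement stage would optimize a subtly different
function, because with weighted $SS_{tot}$ the objective is not a plain
sum of squares. Parameters that finish at a bound are flagged. The default
20 starts make the noise-free fit reproducibly land on the global optimum;
recovery tests in the suite use 4–6 starts as a deliberately harder
setting.

Constrained fits (`pin = c(k_on = ..., k_off = ...)`) re-optimize the
remaining parameters with association and dissociation frozen — the
robustness comparison that shows the data actually constrain those two
rates: on data generated with shifted constants, the pinned fit's global
$R^2$ is strictly lower.

## Sort-Seq intensity moments

Reads are used exactly as base calls (no quality filtering, by design):
bases 23–128 are sliced from each ≥128-nt read to give the 106-nt variable
segment, exact duplicates are grouped, and a variant sequence is kept only
if it has ≥10 reads *in the whole dataset* — the threshold is never
applied per bin, so a variant spread thinly across bins is not discarded.
Classification against the wild-type segment is position-wise; only
single substitutions enter the effect table.

The intensity moment
$$K_{ij} = \frac{\sum_k I_k\, c^k n_{ij}^k / N^k}{\sum_k c^k n_{ij}^k / N^k}$$
is a convex combination of the bin median intensities $I_k$, so it always
lies between the dimmest and brightest bin medians, and it is invariant to
rescaling all read counts in a bin — both properties are tested. Entries
whose weights all vanish are *missing*, rendered as crossed cells in the
heatmap. Standard scores use the population mean and standard deviation
over all non-missing single-substitution entries of the matrix; wild-type
reads do not contribute (the moment is defined for mutants), and a
`per_position` switch offers the narrower normalization because the choice
of normalization set is a convention, not a derivation. Reads are DNA;
heatmaps are emitted in RNA alphabet with segment positions mapped to sRNA
coordinates through an explicit offset.

Duplicate grouping uses hashed tables rather than a search tree — the
contract is the resulting tally, which is tested against a brute-force
count.

## Localization analysis

DBSCAN conventions differ between implementations, so the package states
its own: a core point has at least `nps` neighbours within `eps`
*including itself*; points are visited in index order and border points
reachable from several clusters belong to the first-discovered cluster,
making output deterministic. The kernel is compiled with plain $O(n^2)$
region queries (a few thousand points per cell at most) and is tested for
exact agreement with an exhaustive R implementation. The published
clustering radii for this imaging system — Eps 15 nm / Nps 3 for the sRNA
channel (9 probes), Eps 25 nm / Nps 10 for the mRNA channel (28 probes) —
are defaults, not constants, and `eps` is in the coordinate units of the
input table.

Copy-number estimation calibrates on a low-copy sample where one cluster
can be assumed to be one RNA: the statistic is the median localizations
per cluster. Each cluster then contributes
$\max(1, \mathrm{round}(n_{loc}/\mathrm{statistic}))$ copies, so merged
spots holding several RNAs are counted multiply, and the mean
deletion-strain cluster count is subtracted per cell (floored at zero).
The upstream workflow this emulates described a Bernoulli-trials analysis
whose exact estimator lives in prior work; the median-calibration rule
here is a documented interpretation with the same inputs and intent.

Colocalization counts an mRNA cluster once if any sRNA localization falls
within a 40 nm sphere of its centroid (40 nm being the average measured
mRNA cluster radius). Chance colocalization grows with sRNA copy number;
a negative-control strain provides (copies, raw %) pairs fitted by least
squares through the origin, $y = a x$ — through the origin because zero
sRNA cannot colocalize by chance — and the corrected value is
$\mathrm{raw} - a \times \mathrm{copies}$, clipped at zero with a flag.

## Decay fitting

The log-linear estimator regresses $\ln(\mathrm{value})$ on time by
unweighted OLS — the rate is minus the slope, the lifetime its reciprocal;
shifting the time origin moves only the intercept. A `normalize` flag
divides by the initial value first, which likewise cannot change the rate;
it exists because either convention is common for imaging washout series.
The one-phase model $v(t) = \mathrm{plateau} + \mathrm{span}\,e^{-kt}$
serves RT-qPCR chases that decay to a baseline; it is fitted by
Levenberg–Marquardt with a deterministic initializer (plateau = min,
span = max − min, rate from the first/last log-ratio) that makes
convergence reproducible. Flat series are flagged indeterminate rather
than fitted. `paper_round()` holds the reporting conventions (rates to two
significant figures, lifetimes in minutes to one decimal, fold changes to
integers) and is never used inside a computation.

## What the generators emulate — and what they do not

Each generator reproduces the statistical structure its analysis stage
assumes, and attaches a `truth` attribute that only tests read:

* `sim_timecourses()`: the mass-action dynamics on the standard induction
  grid (0–20 min, eight points), with the reported mean being the average
  of `n_cells` (default 100) Poisson draws per point, with its SEM. The
  default generating constants are the wild-type regime
  ($k_{on} = 1.9\times10^5$ M$^{-1}$s$^{-1}$, $k_{off} = 0.22$ s$^{-1}$,
  $k_{cat} = 0.3$ s$^{-1}$, $\beta_p = 0.005$ s$^{-1}$ with a pre-stress
  steady state of 100 copies, $\beta_{S,p} = 0.001$ s$^{-1}$ inside its
  measured bounds, and $\alpha_S = 0.6$ copies/s so the sRNA accumulates
  into the 100–200 copies-per-cell regime by 20 min).
* `sim_sortseq_library()`: per-variant log-normal single-cell fluorescence
  (σ(log) = 0.35), five log-spaced bins spanning the population, reads
  emitted in proportion to sorted cells, constant adaptor flanks so bases
  23–128 recover the segment, constant quality strings (the analysis
  ignores quality by specification). The wild-type reference segment is a
  fixed *synthetic* 106-mer, not a biological sequence.
* `sim_localizations()`: RNAs uniform in a 1×1×2 μm cell box; probes bound
  as Binomial(9 or 28, 0.6); localizations per bound probe geometric with
  mean 3; Gaussian scatter σ(xy) = 6 nm, σ(z) = 10 nm — an *effective*
  per-localization spread chosen so that a single labelled RNA forms one
  cluster at the published clustering radii, as it does in the real data
  those radii were chosen for; uniform background points model nonspecific
  probe binding as measured in deletion strains.
* `sim_decay_series()`: exponential (optionally with plateau) times
  log-normal multiplicative noise.

Passing recovery tests on these inputs shows the estimators are correct
and well-conditioned *for data matching their assumptions*. It does not
certify performance on real images (no drift, no astigmatism calibration
error, no cell segmentation), real libraries (no PCR bias, no multiple
substitutions beyond what error rates imply), or transcription dynamics
beyond deterministic mass action. Raw-frame peak fitting, drift
correction, channel registration and interaction-energy prediction are
out of scope throughout.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which every estimator's behaviour is comfortably
resolved: 48 fitted points per global fit (eight times × three species ×
two backgrounds), 8–20 fit seeds, tens of cells and $10^4$–$10^5$
localizations per imaging scenario, 25 variants × ~1000 reads for
Sort-Seq. All randomness flows from explicit integer seeds (the
acceptance script derives fixed offsets from its `--seed`), and identical
seeds give bit-identical generator output.

## Known limitations

* $k_{on}$, $k_{off}$ are apparent constants; an explicit Hfq species or
  stochastic/spatial modelling would be needed to decompose them.
* The identifiability of `k_cat_mut` and $\beta_{S,p}$ is data-limited:
  with noisy inputs they are recovered with wider scatter than
  $k_{on}$/$k_{off}$, and bound flags should be inspected.
* The copy-number estimator's median calibration assumes the low-copy
  sample is truly single-RNA; mergers there would bias the statistic.
* Weighted and unweighted $R^2$ can rank parameter sets differently when
  curves include near-zero fitted values; the package defaults to the
  weighted form and exposes the switch.
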