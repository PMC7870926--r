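# srnakinetics

Quantifying how a bacterial small RNA finds and destroys its target mRNA
in living cells.

Bacterial small RNAs (sRNAs) such as *E. coli* SgrS silence target mRNAs
(here *ptsG*, the glucose transporter message) by base-pairing with the
help of the RNA chaperone Hfq, followed by RNase E-mediated co-degradation
of the sRNA–mRNA pair. `srnakinetics` implements the computational side of
an in vivo target-search study of this system:

- **Kinetic modelling.** A deterministic mass-action model of the three
  species — free target mRNA *p*, free sRNA *S*, and the complex *Sp*:

  ```
  dp/dt  = α_p − β_p·p − k_on·S·p + k_off·Sp
  dS/dt  = α_S − β_{S,p}·S − k_on·S·p + k_off·Sp
  dSp/dt = k_on·S·p − (k_off + k_cat)·Sp
  ```

  with copy-number state and `k_on` in conventional M⁻¹s⁻¹ units
  (converted through the cell volume, 0.7 μm³ by default). Six time
  courses (three species × wild-type RNase E and a co-degradation-deficient
  mutant) are fitted **globally** by maximizing a Poisson-weighted R², with
  per-curve χ² diagnostics and a constrained mode (pin `k_on`/`k_off`) for
  robustness comparisons.
- **Derived search kinetics.** `K_D = k_off/k_on`, mean binding events
  before destruction `(k_off + k_cat)/k_cat`, search time `1/(k_on·[S])`,
  and the overall destruction time.
- **Sort-Seq mutational scanning.** From FACS-binned FASTQ reads of an
  error-prone-PCR sRNA library: read slicing (bases 23–128), exact
  duplicate grouping with a ≥10-read filter, single-substitution
  classification, the intensity-moment statistic
  `K_ij = Σ_k I_k c_k n_ij^k/N^k ⁄ Σ_k c_k n_ij^k/N^k`, z-scores, and
  position-by-base heatmaps.
- **Super-resolution copy numbers and colocalization.** DBSCAN clustering
  of 3D smFISH localizations (compiled kernel; Eps = 15/Nps = 3 for the
  sRNA channel, Eps = 25/Nps = 10 for the mRNA channel), single-RNA
  calibration, deletion-strain baseline subtraction, and chance-corrected
  sRNA–mRNA colocalization (40 nm sphere; `y = a·x` control calibration).
- **Decay rates.** Log-linear and one-phase exponential fits for
  washout/rifampicin-chase series, lifetime conversion, and ΔΔCt fold
  changes.
- **Synthetic-data generators** for all four input kinds (ODE dynamics +
  Poisson counting noise; log-normal cell fluorescence + log-spaced FACS
  bins; binomial probe labelling + Gaussian localization scatter + uniform
  background; exponential decay + multiplicative noise), each with a
  machine-readable truth record, so the full pipeline is testable offline.

## Worked example

```r
library(srnakinetics)

# Derived search kinetics from the wild-type rate constants
wt <- rate_constants(k_on = 1.9e5, k_off = 0.22, k_cat = 0.3)
kinetics_report(wt, s_conc = 0.48e-6)
#> # A tibble: 5 × 3
#>   quantity            value unit
#>   <chr>               <dbl> <chr>
#> 1 K_D                  1.16 uM
#> 2 mean_binding_events  1.73 events
#> 3 search_time         11.0  s
#> 4 destruction_time    19.0  s
#> 5 sRNA_concentration   0.48 uM
```

At 0.48 μM sRNA, a wild-type SgrS molecule takes ~11 s to find a *ptsG*
mRNA, needs 1.73 binding attempts on average before one ends in
co-degradation, and destroys the target in ~19 s overall.

```r
# Simulate the six measured time courses and refit the model globally
tc   <- sim_timecourses(seed = 1)                       # 100 cells/point
spec <- fit_spec(alpha_p = 0.5, beta_p = 0.005,         # measured, fixed
                 beta_S0 = 1e-4, beta_S_total = 0.0016, # bounds for beta_Sp
                 n_starts = 6, seed = 2)
fit <- fit_kinetics(tc, spec)
tidy(fit)
#> # A tibble: 6 × 3
#>   parameter     estimate at_bound
#> 1 alpha_S        0.602   FALSE
#> 2 beta_Sp        0.00102 FALSE
#> 3 k_on      191968.      FALSE
#> 4 k_off          0.219   FALSE
#> 5 k_cat_wt       0.298   FALSE
#> 6 k_cat_mut      0.0199  FALSE
glance(fit)
#> # A tibble: 1 × 4
#>   global_r2 n_free n_points n_starts
#> 1     1.000      6       48        6
autoplot(fit)   # data with fitted curves, one panel per species
```

The fit recovers the generating constants (k_on = 1.9e5 M⁻¹s⁻¹,
k_off = 0.22 s⁻¹, k_cat = 0.3 s⁻¹) within a few percent from counting
noise at 100 cells per time point.

```r
# Decay-rate estimation from a noisy washout series
d <- sim_decay_series(rate = 0.0016, noise_sigma = 0.1, seed = 3)
fit_decay(d)
#> <decay_fit: loglinear >
#>   rate 0.001469 s^-1, lifetime 11.3 min (R^2 0.9932)
```

## Layout

- `R/` — kinetics, fitting, sortseq, localization, decay, synthetic
  generators, reporting, I/O, plotting
- `src/` — compiled kernels (DBSCAN, adaptive Dormand–Prince integrator)
- `vignettes/target-search-kinetics.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical details, limitations
- `tests/testthat/` — unit, property and acceptance tests with independent
  oracles (fixed-step RK4 integration, exhaustive DBSCAN, hand arithmetic)
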