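# pipgate

Quantitative tools for studying how the membrane lipid PIP2
(phosphatidylinositol 4,5-bisphosphate) gates the epithelial sodium channel
(ENaC). ENaC requires PIP2 bound to the cytosolic N-termini of its beta and
gamma subunits to open; the local PIP2 supply is controlled electrostatically
by the polybasic effector domain of MARCKS-like protein-1. `pipgate` is for
electrophysiologists and cell biologists who want to analyse (or simulate,
with known ground truth) the measurements this mechanism produces:
single-channel patch-clamp records, PIP2 dose–response curves,
current–voltage relations, two-channel colocalization micrographs, and the
back-of-the-membrane electrostatic arithmetic.

## What the package implements

**Ligand-dependent gating schemes.** Channel gating is modelled as a
continuous-time Markov chain whose opening steps are pseudo-first-order in
[PIP2]. Two schemes are built in:

- `co_scheme(k1, k_1)` — a single binding step,
  C ⇌ O with opening rate k1·[L] and closing rate k−1. Mean open time
  1/k−1 is concentration-independent, equilibrium Hill slope ≡ 1.
- `coo_scheme(k1, k_1, k2, k_2)` — sequential binding,
  C ⇌ O1 ⇌ O2, where the second PIP2 stabilizes the open channel. At
  equilibrium Po = (a + ab)/(1 + a + ab) with a = k1L/k−1, b = k2L/k−2;
  mean closed time 1/(k1L); mean open time (1 + k2L/k−2)/k−1. The local
  Hill slope of this scheme is strictly below 2 — a fitted Hill
  coefficient above 2 cannot come from it at equilibrium.

Exact stationary quantities (`open_probability()`, `sojourn_means()`,
`hill_slope_local()`) sit alongside exact stochastic simulation
(`sample_path()`, `simulate_patch()`) with Gaussian low-pass filtering that
reproduces the half-amplitude dead time ≈ 0.179/f_c.

**Idealization and activity statistics.** `idealize()` performs
half-amplitude multi-level idealization; `compute_npo()` implements
NPo = Σ n·t_n / T; `estimate_channel_count()` reads N off the amplitude
histogram; `dwell_summary()`, `fit_exponential_mixture()` (EM) and
`recover_rates_from_titration()` turn dwell times back into rate constants.

**Curve fits.** `fit_hill()` fits Po = Pmax/(1 + (K0.5/[PIP2])^n);
`fit_ghk()` fits the two-ion Goldman–Hodgkin–Katz current (internal Na+,
external Li+) and reports the reversal potential and `slope_conductance()`;
`linear_rate_fit()` handles rate-versus-concentration lines. All fitted
objects support `tidy()`, `glance()`, `autoplot()` and `predict()`.

**Colocalization.** `coloc_report()` computes the full statistic set for a
registered two-channel image: Pearson correlation, the intensity-ratio
coefficients m1 = Σs1·s2/Σs1² and m2 = Σs1·s2/Σs2², automated
(Costes-style) thresholds from the first non-positive below-threshold
correlation, thresholded overlap coefficients R/k1/k2, and the
colocalized-pixel mask (both channels above threshold and intensity ratio
> 0.1).

**Electrostatics.** `binding_energy()` (ΔG = RT·ln(C°/Kd)),
`enhancement_factor()` (the Boltzmann local-concentration factor C°/Kd), and
`encounter_time()` (a disc-capture model of PIP2–channel encounter by pure
lateral diffusion).

Every generator (`simulate_patch()`, `simulate_dose_response()`,
`simulate_iv()`, `simulate_image_pair()`) records its ground truth and is
bit-reproducible per seed, so estimator-recovery experiments are one-liners.

## Worked example

```r
library(pipgate)

# Sequential two-site scheme at 20 uM PIP2
scheme <- coo_scheme(k1 = 0.001, k_1 = 0.01, k2 = 0.0005, k_2 = 0.005)
open_probability(scheme, L = 20)
#> [1] 0.8571429
sojourn_means(scheme, L = c(10, 20, 50))
#> # A tibble: 3 x 3
#>   concentration mean_open mean_closed
#> 1            10      200.         100
#> 2            20      300.          50
#> 3            50      600.          20

# Simulate a patch recording and analyse it blind
sim <- simulate_patch(scheme, L = 20, duration_ms = 6e4,
                      unit_current = -0.5, noise_sd = 0.1,
                      filter_cutoff = 1000, seed = 42)
channel_activity(sim$trace, unit_current = -0.5)
#> # A tibble: 1 x 4
#>     npo n_channels    po total_time_ms
#> 1 0.851          1 0.851         60000
compute_npo(sim$events)   # ground truth: 0.847

# Dose-response recovery at the published fit values
fit <- fit_hill(simulate_dose_response(seed = 42))
fit
#> <hill_fit> Pmax = 0.413 (se 0.018), K0.5 = 22.46 uM (se 1.08),
#>            n = 2.51 (se 0.22), r^2 = 0.974

# Electrostatic sequestration: a 15 uM well holds PIP2 at
binding_energy(15)$delta_g_kcal    # 6.47 kcal/mol at 20 C
enhancement_factor(binding_energy(15))  # 66667-fold local enrichment
```

The mean open time grows linearly with [PIP2] while the mean closed time
falls as 1/[PIP2] — the signature of the sequential scheme, in which the
first PIP2 opens the channel and a second stabilizes the open state. The
half-activating concentration (~22 uM) sits inside the estimated 5–30 uM
physiological range of membrane PIP2.

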