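---
title: "Models and methods: PIP2-dependent gating, idealization, and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: PIP2-dependent gating, idealization, and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipgate)
```

`pipgate` analyses the gating of the epithelial sodium channel (ENaC) by the
anionic membrane lipid PIP2. This vignette is the package's own account of
the models it implements, the defaults it chooses and why, what the
synthetic-data generators do and do not emulate, and the numerical decisions
that a careful user should know about.

## 1. Gating model

### States and rates

A channel is a continuous-time Markov chain over states labelled `closed` or
`open`. Transition rates either ignore the ligand (order 0, units 1/ms) or
are pseudo-first-order in PIP2 concentration (order 1, units 1/ms/uM):
the effective rate at concentration $L$ is $k \cdot L^{\text{order}}$.
Ligand dependence is deliberately restricted to first order — the model is
mass-action binding, not an allosteric expansion — and cyclic or
voltage-dependent schemes are out of scope.

Two schemes cover the biology:

* **Single site** (`co_scheme`): $C \rightleftharpoons O$ with opening rate
  $k_1 L$ and closing rate $k_{-1}$. Mean open time $1/k_{-1}$ does not
  depend on $L$; the equilibrium dose-response has Hill slope exactly 1.
* **Sequential two-site** (`coo_scheme`): $C \rightleftharpoons O_1
  \rightleftharpoons O_2$; the first PIP2 opens the channel, the second
  stabilizes the open conformation, and both forward rates scale with $L$.
  With $a = k_1 L / k_{-1}$ and $b = k_2 L / k_{-2}$,

  $$P_o = \frac{a + ab}{1 + a + ab}, \qquad
    \bar t_{closed} = \frac{1}{k_1 L}, \qquad
    \bar t_{open} = \frac{1 + k_2 L / k_{-2}}{k_{-1}}.$$

  The growth of the mean open time with $L$, alongside the $1/L$ fall of the
  mean closed time, is the kinetic fingerprint distinguishing the two-site
  scheme from the single-site one.

Stationary quantities are computed from the generator matrix: the stationary
vector solves $\pi Q = 0$, $\sum \pi = 1$ (augmented least-squares solve),
and aggregated class dwell means use the stationary flux identity
$\bar t_{class} = \pi(\text{class}) / \Phi(\text{class} \to \text{other})$.
Both are verified in the test suite against independent oracles (eigenvector
null space; first-step absorption solve) to 1e-10.

### The Hill-slope bound

The local log-log slope of the two-site scheme's dose-response,
$d \ln(P_o/(1-P_o)) / d \ln L = 1 + bL/(1+bL)$, lies strictly in $(1, 2)$ at
every finite concentration. A dose-response whose fitted Hill coefficient
is credibly above 2 therefore cannot be produced by the sequential two-site
scheme at equilibrium. Measured Hill coefficients for PIP2 activation of
ENaC sit around 2.5 with a standard error of about 0.55 — statistically
compatible with 2 at the 1-sigma level but pointing, if taken at face
value, to more than two effective binding steps or to non-equilibrium
steepening. `hill_slope_local()` exists precisely so users can compare a
fitted coefficient against the scheme's attainable range; the package
reports the tension and does not attempt to resolve it.

### Degenerate concentrations

$L = 0$ makes the closed state absorbing in both schemes. Stationary
open probability is defined there as 0 (PIP2 is required to open the
channel); sojourn means raise an error (the closed sojourn is infinite);
`sample_path()` returns a single everlasting closed sojourn.

## 2. Synthetic data

The generators produce every input the analysis pipeline consumes, with
ground truth attached. They emulate:

* **Latent gating** — exact Gillespie simulation: exponential waiting times
  at the total exit rate, jump probabilities proportional to rates. The
  initial state is drawn from the stationary distribution (patch records
  analysed here begin in steady state); `init = "closed"` is available for
  excision-style protocols.
* **Current traces** (`render_trace`, `simulate_patch`) — ideal current =
  unit current x number of open channels, sampled at 4000 Hz by default
  (the digitization rate of the recordings this package targets), filtered
  with an ideal Gaussian response with -3 dB cutoff $f_c$, then overlaid
  with white Gaussian noise. The Gaussian filter gives the textbook
  half-amplitude dead time $t_d \approx 0.179/f_c$: an opening shorter than
  $t_d$ never reaches half amplitude and vanishes from the idealization,
  which is exactly how brief "flickery" events are attenuated in
  low-bandwidth records. Defaults of 0.15 pA r.m.s. noise and a 100 Hz
  display cutoff are fixture choices typical of such recordings, not
  measured values.
* **Dose-response tables** (`simulate_dose_response`) — Hill means plus
  Gaussian noise clipped to [0, 1]. The defaults are the study conditions
  for the recovery experiments: concentrations {0, 10, 20, 30, 50} uM,
  11 replicates, noise sigma 0.02, and generative parameters Pmax 0.411,
  K0.5 22 uM, n 2.5.
* **I-V tables** (`simulate_iv`) — GHK means plus Gaussian noise
  (sigma 0.05 pA) at ten voltages from -120 to +60 mV, for 140 mM external
  Li+ against 3 mM internal Na+ at 295.15 K (22 C room temperature).
* **Two-channel micrographs** (`simulate_image_pair`) — Gaussian puncta
  (PSF sigma 2 px) at 16-bit depth; a chosen fraction share coordinates in
  both channels; background plus Gaussian noise approximates shot noise at
  high count rates. `min_separation` optionally keeps non-colocalized spots
  from overlapping by chance — without it, randomly placed disjoint puncta
  do collide at realistic densities, which is a property of real membranes
  too.

They deliberately do **not** emulate: capacitance transients, leak and
baseline drift, 1/f and correlated noise, multiple conductance sublevels,
Bessel-filter phase response, photobleaching, chromatic misregistration, or
3-D point-spread functions. Passing recovery tests on these fixtures shows
the estimators are correct under the stated noise model; it does not show
robustness to every artefact of real rigs and microscopes.

### Units and conventions

Milliseconds, picoamperes, micromolar, millivolts (membrane convention:
intracellular minus extracellular; inward current negative), kelvin.
Applied-PIP2 concentrations are treated as micromolar throughout;
where source figure axes for such titrations are labelled "mM", that label
is read as a typographical slip for uM, consistent with the ~22 uM
half-activation and the 5-30 uM physiological estimate. Downstream unit
conversion is the caller's responsibility.

The digitization default is 4000 Hz. Recordings in this literature quote
both 4000 Hz and 1000 Hz setups; 4000 Hz is adopted as the default and the
sampling rate is a parameter everywhere.

## 3. Idealization choices

* **Half-amplitude threshold, nearest-level rounding, no hysteresis** —
  standard single-channel practice, and the rule that makes the Gaussian
  dead time exact.
* **Baseline** — mode of the all-points histogram (bin width noise_sd/4
  when known, else Freedman-Diaconis), on the assumption that the closed
  level is the most occupied. When a high-activity record breaks that
  assumption the signal sits at negative normalized levels and the baseline
  is re-anchored by an integer number of unit currents; a sign conflict
  with the trace's recorded unit current is a polarity error.
* **No missed-event correction** — dwell means are reported uncorrected.
  This is intentional: the knockout-phenotype experiments this package
  reproduces report uncorrected means, and applying a correction would
  change the very quantity being recovered.
* **Censoring** — the first and last sojourns of a record are excluded from
  dwell statistics.
* **Multi-channel records** — NPo is always available; per-event dwell
  analysis is restricted to single-channel records (error otherwise), since
  superposed sojourns are not channel sojourns.
* **Channel counting** — N is the highest occupied level among amplitude-
  histogram peaks (occupancy window 0.3 unit currents, prominence 5e-4).
  A warning flags likely undercounting when, at the fitted per-channel Po,
  the next level up had a non-trivial chance (> 5%) of never being visited.

## 4. Fitting choices

* **Hill fit** — unweighted nonlinear least squares on individual
  replicates (not replicate means): per-point weights are unreported in the
  pooled-patch designs this mirrors. Multi-start grid K0.5 in {5, 20, 50} x
  n in {1, 2, 3}; best residual sum wins; standard errors from the Jacobian;
  $L = 0$ evaluated in the limit ($P_o = 0$).
* **GHK fit** — least squares over the absolute permeability scale and the
  Li/Na permeability ratio, with the conditionally-linear scale initialized
  by projection. The reversal potential is computed analytically from the
  fitted ratio, $E_{rev} = (RT/F)\ln(P_{Li}[Li]_o / P_{Na}[Na]_i)$, with a
  delta-method standard error. When the sweep does not bracket the zero
  crossing (the default -120..+60 mV protocol never reaches a +83 mV
  reversal), the fit warns and the reversal is an extrapolation — its
  standard error is then large (tens of mV) and honest. Slope conductance
  is the least-squares slope of the fitted curve on a 1 mV grid over
  [-120, -40] mV, converted to pS.
* **Exponential mixtures** — EM in log space, tolerance 1e-8 on the
  log-likelihood gain, at most 500 iterations, five random restarts with
  quantile-anchored initial time constants. EM never decreases the
  likelihood; ties across restarts resolve to the best likelihood.
* **Titration inversion** — $k_1$ from a through-origin regression of
  opening rate on $L$; $k_{-1}$ from the mean-open-time intercept;
  $k_2/k_{-2}$ from slope x $k_{-1}$. The individual stabilization rates
  $k_2$ and $k_{-2}$ are *not identifiable* from class means alone — only
  their ratio is — and the function says so rather than reporting a fake
  decomposition.

## 5. Colocalization

The statistic set mirrors what threshold-based colocalization plugins
report. Two decisions deserve explanation:

* The printed coefficient definitions $m_1 = \sum s_1 s_2 / \sum s_1^2$,
  $m_2 = \sum s_1 s_2 / \sum s_2^2$ are overlap-style intensity ratios (not
  bounded by 1; they obey exact scaling laws $m_1(a s_1, s_2) = m_1 / a$).
  They are implemented exactly as written over all pixels, while the
  thresholded per-channel overlap coefficients k1/k2 — the quantities
  threshold-aware reports tabulate — are computed over the above-threshold
  region. Both are reported; conflating them would silently change values
  by the background contribution.
* **Automatic thresholds** — ordinary least squares of channel 2 on
  channel 1 (orthogonal regression is a defensible alternative; OLS is the
  common default), then a downward scan of candidate pairs
  $(t, \text{slope}\cdot t + \text{intercept})$ stopping at the *first*
  pair whose below-both-thresholds Pearson correlation is <= 0 — "no
  significant correlation below threshold", not "closest to zero". The scan
  is evaluated in O(n log n) by sorting pixels on the critical threshold
  $\max(s_1, (s_2 - b)/m)$ at which each pixel enters the below-both set;
  this is exactly equivalent to the naive scan at unit intensity steps.
  Fully uncorrelated channels have no such threshold: the scan collapses to
  the minimum intensity with a warning.

A colocalized pixel must exceed both thresholds *and* have a between-channel
intensity ratio above 0.1 (scale-free, hence the mask is invariant under
joint intensity rescaling). Images are assumed single-plane, registered and
background-unsubtracted; numeric values from published micrograph tables
are not reproducible here because the source images are not distributed —
the tests therefore check structure, identities and ground-truth recovery
on simulated pairs only.

## 6. Electrostatics

`binding_energy()` uses $\Delta G = RT \ln(C^\circ/K_d)$ with the 1 mol/L
standard state and $R$ = 1.987e-3 kcal/(mol K). The default temperature is
293.15 K: the often-quoted "6 to 6.5 kcal/mol for a 15 uM site" band is
satisfied at 20 C and exceeded by a few hundredths at 23 C, so the tests
pin 20 C and this sensitivity is the reason why. `enhancement_factor()` is
the exact Boltzmann inverse, $C^\circ/K_d$ — about 6.7e4 for 15 uM, far
above the hundred-fold enrichment needed to explain observed opening rates.

`encounter_time()` answers "how often would a channel meet a PIP2 by pure
diffusion, with no sequestration?" with a deliberately simple capture
model: each channel owns a disc of radius $b = (\pi \rho_{ch})^{-1/2}$; the
mean capture time of one diffuser started uniformly in the disc (absorbing
trap radius $a$, reflecting rim) is $\tau_1 = (b^2/2D)(\ln(b/a) - 3/4)$;
the first arrival among $N$ independent diffusers is $\approx \tau_1/N$.
Defaults: capture radius 1 nm (molecular scale) and lipid density 2e6 per
um^2 per leaflet — package defaults, not measured quantities. With typical
membrane parameters (7 channels/um^2, PIP2 at 1 per 1000 lipids,
D = 4 um^2/s) this model predicts sub-millisecond encounters, orders of
magnitude faster than the ~10-minute interval sometimes quoted from
unstated capture assumptions. The model is validated against a lattice
random-walk Monte Carlo oracle (within 25% at b/a = 10) and is *not*
calibrated toward any published encounter figure; the discrepancy is
reported as-is. All terms ($b$, $\tau_1$, $N$, $\tau_1/N$) are returned so
users can substitute their own capture formula.

## 7. Problem sizes and determinism

Every stochastic function takes a seed and is bit-reproducible given one.
The recovery experiments use: 55 dose-response points (5 concentrations x
11 replicates); 10 I-V voltages; a 200 s model-time patch (~2200 open
events) for dwell recovery; a 600 s patch (~2800 events) for NPo recovery;
1e6 ms paths (~5000 sojourns) for occupancy checks; 1000 Monte Carlo
walkers for the capture-time oracle. These sizes put Monte-Carlo standard
errors in the few-percent range, which is what the 2-s.e. recovery
assertions are calibrated against.

## 8. Known limitations

* Dwell-based rate recovery assumes the sequential scheme; it will fit its
  closed forms to any titration, so model misspecification shows up only as
  trend misfit, not as an error.
* The GHK reversal potential is weakly identified from sweeps that do not
  cross zero current (standard errors of tens of mV); collecting voltages
  beyond the reversal is the fix, not a different estimator.
* Threshold-based colocalization inherits all the usual caveats of
  intensity thresholds: bleed-through, background structure and chromatic
  shift are not modelled, and the Costes stop rule can collapse to the
  minimum for weakly correlated pairs.
* No hidden-Markov idealization, burst analysis, or dead-time-corrected
  maximum-likelihood rate estimation; these are out of scope by design.
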