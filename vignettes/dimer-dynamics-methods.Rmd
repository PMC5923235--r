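---
title: "Models and methods behind gpcrdimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gpcrdimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gpcrdimer)
```

`gpcrdimer` studies the monomer–dimer equilibrium of a membrane receptor
(the neurotensin receptor NTS1 is the motivating system) diffusing in a
planar lipid bilayer. This vignette documents the models implemented, the
parameters that matter, the numerical choices, and the limits of what the
synthetic-data tests demonstrate.

## The reaction–diffusion model

Receptors are point-like particles with a contact (collision) diameter of
5 nm (twice the 2.5 nm receptor radius) diffusing on a periodic square
box whose side is set by `sqrt(n_particles / density)`. Per time step every
particle takes independent per-axis Gaussian steps with standard deviation
`sqrt(2 D dT)` — so the 2D mean squared displacement grows as `4 D t` —
with `D_mon = 1.63` and `D_dim = 1.27` µm² s⁻¹ by default (the measured
donor- and acceptor-channel coefficients). Monomer pairs within the contact
distance (minimum-image metric) dimerise with probability `p` per step of
overlap, closest pairs first and each monomer in at most one event per
step; new dimers sit at the pair midpoint. Dimers dissociate with per-step
probability `1 − exp(−k_off dT)` and re-emit two monomers at contact
separation inflated by a relative tolerance (default `1e-5`) in a random
orientation, so they are created *just outside* contact rather than
overlapping. Higher-order oligomers never form, matching the single-step
photobleaching evidence that excludes them experimentally.

**Time step.** The default step lets a monomer diffuse half a receptor
radius per step (`dT = r²/16D ≈ 2.4e-7 s`). A coarser step is accepted up
to `dT = d²/16D` (rms step equal to half the contact diameter,
`≈ 9.6e-7 s`), the coarsest resolution at which diffusing pairs cannot
step across an encounter; all long simulations in this package use that
bound. Because an encounter then spans several steps, each retrying the
Bernoulli trial, the *effective* second-order association constant depends
on `dT`, which is why the simulator is always calibrated rather than run at
a nominal reaction probability.

**Calibration.** `calibrate_collision_probability()` bisects `p` until
short no-dissociation bursts reproduce a target `k_on`. The effective
constant is measured by the maximum-likelihood estimator
`k̂ = N_events / ∫ M(M−1)/A dt`, the exact MLE for a pure pairing process
and the bin-free analogue of fitting the monomer-loss curve. Bursts run at
10 µm⁻² — dilute (mean spacing ≈ 40 contact diameters) but collision-rich —
and the same seeds are reused across the bisection so the measured curve is
monotone in `p`. For the experimental target `k_on = 0.081` µm² s⁻¹ the
calibrated `p` is ≈ 2×10⁻³ per overlap step; the *per-encounter* reaction
efficiency is far higher (the measured `k_on` is within a factor ~1.2–1.5
of the Hardt diffusion-limited collision estimate, i.e. a ~20–25%
efficiency per encounter).

**Known bias.** A transiently measured `k_on` slightly understates the
association prevailing at equilibrium: during a burst the pair correlation
at contact is depleted by the reactive sink, whereas at equilibrium
dissociation replenishes it. In consequence the simulated equilibrium dimer
fraction at 0.43 µm⁻² runs ~5–15% (relative) above the naive
`k_on/k_off` mass-action value — comparable to its 3-combined-SE
uncertainty once the calibration error (event-count limited, ~5% here) is
propagated. The package therefore reports calibration uncertainty
(`achieved_k_on_se`) and the equilibrium tests compare within combined
errors.

**Oracles.** Two independent well-mixed references validate the particle
model: the closed-form mass-action equilibrium (positive root of
`2(k_on/k_off) M² + M − ρ = 0`) and an exact Gillespie simulation of
`A + A ⇌ A₂` with association propensity `k_on M(M−1)/A`. Equilibrium
dimer fractions are time-weighted means after burn-in with block-averaged
standard errors (default 10 blocks) so autocorrelation does not understate
the uncertainty.

At the measured rate constants the model predicts a strongly
density-tuneable dimer population: ~9.8% of receptors dimeric at
0.43 µm⁻² (`K_d = k_off/k_on ≈ 7.2` µm⁻², half-life `ln2/k_off ≈ 1.2` s)
rising to >86% at 10³ µm⁻².

## Track-based kinetics

`msd_curve()` averages per-track MSDs using all displacement pairs per lag,
weighting tracks by their pair counts — the natural weights when the
averaging is over displacement pairs, and the package's definition of the
track-weighted average. `fit_diffusion()` fits
`MSD = 4Dτ` (optionally `+ 4σ_loc²`) over the first lags — default the
first quarter, and four lags in the acceptance analyses — by weighted least
squares with `1/SE²` weights. Overlapping-window MSDs are strongly
correlated between lags, so the nominal intercept SE is indicative only;
the slope is unbiased (verified to 2% over 50 seeded replicates).

Diffusion contrast between channels uses a two-sided z-test on the fitted
CIs (`SE = width/3.92`). The Saffman–Delbrück relation
`D ∝ ln(L/r) − γ` converts the ratio into an effective radius ratio; the
characteristic length `L` is not identifiable from two coefficients, so it
is an explicit argument (20 nm in the examples, which makes a
`D` ratio of 0.78 correspond to a ~1.4-fold radius increase).

`hardt_collision_frequency()` implements the dilute 2D mean-capture-time
estimate `τ = b²(ln(b/a) − 3/4)/(2 D_rel)` with `b = (πρ)^{−1/2}`,
reporting `ρ/2τ` pairwise collisions per area and time, with
`D_rel = D₁ + D₂` for two mobile particles. With the measured diffusivities
at 0.43 µm⁻² this gives ~0.37–0.43 µm⁻² s⁻¹ depending on whether the
contact radius or diameter is used as the capture radius; the published
~0.31 rests on an unprinted variant and is only bracketed (within ×1.5),
not reproduced.

Dimer-formation rates are estimated by binning new-acceptor-track
appearance times (0.5 s bins), fitting `A·exp(−λt)` by least squares with
one reweighting pass (weights `exposure/fitted`, since bin rates are
counting-noise limited), and extrapolating to `t = 0` where photobleaching
has not yet depleted the visible pool. Only donor–acceptor pairs are
FRET-visible; under random pairing the visible fraction is `2 f_D f_A`
(0.268 at the experimental 100:405:45 donor:acceptor:unlabelled ratio), and
`correct_for_labelling()` divides it out. The pair-visibility factor is the
package's own correction; the original supplementary correction is not
public, so the factor is an explicit, documented choice.

## Ensemble FRET

The correction chain implements: labelling efficiency from absorbances with
the fluorophore's 280-nm contribution removed; donor emission restored for
FRET quenching (`F_D = F_dd + F_fret,cor Φ_D/Φ_A`); the donor-to-acceptor
ratio `r_DA = (F_D/F_A)(Φ_A ε_A)/(Φ_D ε_D)`; and the random-pairing
correction `E_cor = E_app (1 + r_DA)/r_DA`, which accounts for the
invisible donor–donor and acceptor–acceptor dimers. Quantum yields default
to 0.92/0.10 and the Förster radius to 7.0 nm (A488–A555), with κ² fixed
at 2/3 — an assumption, not an estimate. The apparent efficiency itself is
defined here by donor quenching, `E_app = 1 − F_DA/F_D-only` over a
configurable donor band; the upstream estimate is pluggable because the
published definition sits in unavailable supplementary material.

Distances follow `E = R0⁶/(R0⁶ + R⁶)`; the conversion and its inverse are
mutual inverses to 1e-10 across `E ∈ [0.01, 0.99]`.

Apo-vs-agonist comparisons use `delta = mean(apo) − mean(+NT)` and a
Bayesian two-mean model with noninformative priors, whose posterior for the
difference is evaluated as a Welch–Satterthwaite scaled-t:
`Pr(delta > 0) = pt(delta/se, df)`. This is a deterministic simplification
of the BEST model (no explicit outlier accommodation); posterior
probabilities may differ from the published ones by a few hundredths, and
only the strong TM6 effect (Pr ≈ 0.99) is asserted within ±0.05. The sign
convention (apo minus agonist) matches the published per-site differences,
which were evidently computed from unrounded means — the tests therefore
check agreement within the print-rounding slack of the two means.

Spectra are background-subtracted and Savitzky–Golay smoothed (10 nm
window, second-order polynomial; the window is converted to an odd number
of grid points) before peak localisation.

## Single-molecule intensity analytics

Spot intensities are modelled as lognormal mixtures: Gaussian EM on
log-intensities with quantile-split initialisation, 10 restarts (jittered
means), convergence at relative log-likelihood change < 1e-8, and a
component-sd floor of 1e-6 of the data range. Model probability uses
`BIC = 2 lnL − (3k−1) ln n` on the higher-is-better convention. Because
BIC comparisons depend on `n`, datasets of different size are compared via
bootstrap: resample `n = 1000` intensities, refit `k = 1..4`, and report
`BIC_k − max_k BIC_k` per replicate (non-positive by construction). The
EM was cross-checked against an independent mixture implementation
(mclust, fitted to the same log-data) to 1e-4 in log-likelihood.

The conservative high-FRET threshold is the `1 − 0.01` quantile of the
fitted low-state lognormal, `exp(µ_low + z_{0.99} σ_low)`. The published
166.5-count threshold cannot be recomputed (the underlying fit parameters
are unprinted); the package reproduces the construction, not that number.

Dwell analysis binarises a trace at the threshold; runs become dwells of
`n_frames × frame_interval`, classed initial/mid/final by position, with
whole-trajectory runs censored and excluded from the survival curves
(empirical complementary CDFs per state and class). Mean dwells of a
frame-sampled exponential are geometric with mean `1/(1 − e^{−kΔt})`, a
~16% bias at `k = 10 s⁻¹` and 30 ms frames, so `dwell_rates()` inverts
that relation (`k̂ = −ln(1 − 1/m̄)/Δt`, mid-dwells only) rather than using
raw mean durations; this recovers generating rates within 10% at ≥500
dwells. Per-frame efficiencies are `I_A/(I_A + γI_D)` with γ defaulting to
1 (raw counts); frames with non-positive totals are excluded and counted.

## Interface combination fitting

Candidate dimer-interface models enter as per-site efficiency vectors —
means of per-frame `E(R)` over distance samples, because energy transfer
averages over conformations (converting the mean distance instead is
offered but not default). The experimental vector is fitted by a
simplex-constrained least squares (`c_i ≥ 0, Σc_i = 1`), solved exactly by
enumerating active sets: every zero-pattern yields an equality-constrained
candidate, and the feasible candidate of minimal RSS is the global optimum
(exact and fast for ≤ 7 models; verified against a dense simplex grid
search). Fits are unweighted by default, matching plain-RSS fitting, with
an optional SEM-weighted variant. All `2^m − 1` subsets are ranked by
`AIC = n ln(RSS/n) + 2k` with `k` the subset size (`k − 1` free
coefficients plus a variance); only AIC *differences* are meaningful, so
the parameter-count convention is fixed and documented rather than tuned.

With this penalty, an irrelevant extra model is admitted alongside the true
ones with ~8% probability each (the one-sided tail of a χ²₁ past 2, halved
by the non-negativity constraint), so the AIC-best subset *contains* the
generating models essentially always (100/100 seeded replicates at noise
sd 0.05) but equals them exactly only ~73% of the time. The tests encode
both rates; exact-set identification at ≥90% is not achievable under this
criterion and is not claimed.

Condition differences are tested by a nested F-test on pooled vs
per-condition fits sharing a subset:
`F = ((RSS_pooled − RSS_sep)/Δk)/(RSS_sep/(n − k_sep))`. DEER distance
distributions are fitted with the same simplex machinery after linear
interpolation onto a common grid restricted to 1.5–8 nm — the physically
expected inter-label range, and beyond ~5 nm the experimental distributions
are unreliable anyway — and the fitted combination is renormalised to unit
trapezoidal mass.

## Synthetic data: what it does and does not show

Every estimator is exercised on generated data whose truth is known:
Brownian tracks with geometric (bleach-limited) lengths, mean 12 frames at
30 ms; two-channel dimerisation movies rendered from the particle
simulator with per-protomer labels (100:405:45 ratio by default),
single-step exponential photobleaching per fluorophore and lognormal spot
intensities; two-state continuous-time Markov FRET traces with
shot-like Gaussian noise (sd proportional to the square root of intensity,
scale 0.5 by default — the camera noise model is the package's choice);
and simplex mixtures of uniform-random model vectors checked for
conditioning. Generators are byte-deterministic per seed and attach their
truth parameters for assertion-only use.

Passing these tests shows the estimators are correct and calibrated *under
the generating assumptions*: free Brownian motion, flat illumination, no
spot-detection or tracking errors, no gap closing, exponential state
dwells, Gaussian site noise. Real microscopy data violate several of these
(localisation error, blinking, crowding-induced tracking mistakes,
illumination profiles), so quantitative agreement on real data is not
implied — which is also why the raw-data-dependent published numbers
(the z = −14.12 statistic, the 166.5-count threshold, the 20.4%/16%
high-FRET fractions, the specific interface-fraction fits) are bracketed
by property-level checks rather than reproduced digit-for-digit.

## Problem sizes used in the shipped analyses

The acceptance-scale runs use 100 particles at 0.43 µm⁻² (16 s simulated,
4 s burn-in, three seeds), 300 particles at 10³ µm⁻² (2.5 s, three seeds),
calibration bursts of 2 × 300 particles × 1.5 s, 2000 synthetic tracks for
the diffusion fit, and 19 six-second event windows for the formation-rate
pipeline — sizes at which every quantity's Monte-Carlo error is a small
fraction of the tolerance it is compared at, while a full analysis runs on
a laptop core in minutes.
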