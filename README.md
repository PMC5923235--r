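# gpcrdimer

Quantitative machinery for studying transient dimerisation of membrane
receptors in planar lipid bilayers, modelled on single-molecule and
ensemble FRET studies of the neurotensin receptor NTS1.

G protein-coupled receptors diffuse in the membrane, collide, and form
short-lived dimers. Whether a receptor population is mostly monomeric or
mostly dimeric then depends on its surface density: with a two-dimensional
dissociation constant `K_d = k_off / k_on = [M]² / [D]` of a few receptors
per µm², the dimer fraction sweeps from a few percent at single-molecule
imaging densities (~0.4 µm⁻²) to near-saturation at ensemble
reconstitution densities (~10³ µm⁻²). `gpcrdimer` implements the analysis
chain needed to measure and model this behaviour:

* **`mc_sim`** — a lattice-free 2D Monte Carlo of receptor diffusion
  (per-axis Gaussian steps, sd `sqrt(2 D dT)`), collision-driven
  dimerisation (probability `p` per step of pair overlap within a 5 nm
  contact diameter, calibrated so the effective association constant
  matches a target `k_on`) and first-order dissociation
  (`1 − exp(−k_off dT)` per step), on a periodic box, with mass-action and
  Gillespie well-mixed oracles. The step loop is compiled (Rcpp).
* **`kinetics`** — MSD curves and diffusion fits (`MSD = 4Dτ`) from
  single-particle track tables, z-test and Saffman–Delbrück radius ratios,
  the Hardt dilute collision-frequency estimate, photobleaching-corrected
  dimer-formation rates (exponential extrapolation to `t = 0`, divided by
  the FRET-visible pair fraction `2 f_D f_A`), and derived constants
  (`K_d`, `t_½ = ln2/k_off`).
* **`ensemble_fret`** — labelling efficiency from absorbances, the
  donor-to-acceptor-ratio correction `E_cor = E_app (1 + r_DA)/r_DA`,
  efficiency↔distance conversion `E = R0⁶/(R0⁶ + R⁶)`, Savitzky–Golay
  spectrum preprocessing, and Bayesian apo-vs-agonist comparisons per
  labelling site.
* **`smfret`** — lognormal intensity mixtures fitted by EM with bootstrap
  ΔBIC model comparison, conservative high-FRET thresholds (low-state tail
  quantiles), dwell segmentation with survival curves, and per-frame FRET
  efficiencies `I_A/(I_A + γI_D)`.
* **`interface_fit`** — simplex-constrained least squares
  (`c_i ≥ 0, Σc_i = 1`, solved exactly by active-set enumeration) fitting
  experimental per-site FRET efficiency vectors or DEER distance
  distributions as combinations of candidate dimer-interface models, ranked
  across all `2^m − 1` subsets by `AIC = n ln(RSS/n) + 2k`, with nested
  F-tests between conditions.
* **`synthetic_data`** — seed-deterministic generators (Brownian tracks,
  two-channel dimerisation movies with single-step photobleaching,
  two-state FRET traces, model matrices, DEER mixtures) so the whole
  pipeline is testable without the undeposited microscopy data.

## Worked example

Equilibrium composition at the experimentally measured rate constants
(`k_on = 0.081 µm² s⁻¹`, `k_off = 0.58 s⁻¹`), and the derived constants:

```r
library(gpcrdimer)

ma <- mass_action_equilibrium(k_on = 0.081, k_off = 0.58,
                              total_density = 0.43)
round(100 * ma$dimer_receptor_fraction, 1)
#> [1] 9.8

derive_rate_constants(k_on = 0.081, k_off = 0.58)
#> Dimerisation rate set
#>   k_on  = 0.081 um^2/s
#>   k_off = 0.58 /s
#>   K_d   = 7.16 um^-2
#>   t_1/2 = 1.195 s
```

So at a surface density of 0.43 receptors µm⁻² only ~10% of receptors are
dimeric, the 2D dissociation constant (~7 µm⁻²) sits inside the
physiological density range (2–40 µm⁻²), and a dimer lives ~1.2 s. The
same constants drive the particle simulator:

```r
cfg <- sim_config(n_particles = 100, density = 0.43,
                  p_collision = 0.0021,      # calibrated to k_on = 0.081
                  k_off = 0.58, dT = max_timestep(1.63, 0.005),
                  duration = 16, seed = 1)
tr <- run_simulation(cfg)
df <- dimer_fraction(tr, burn_in = which(tr$times >= 4)[1])
round(100 * c(fraction = df$fraction, se = df$se), 1)
#> fraction       se 
#>      7.5      1.1
```

A single 16-second run of 100 particles is noisy — this seed lands about
two standard errors below the closed-form 9.8% — which is why the shipped
analyses average several seeds (see `scripts/acceptance.R`). Converting an
ensemble FRET efficiency into an inter-label distance:

```r
efficiency_distance_conversion(0.77, "to_distance", R0 = 7.0)
#> [1] 5.723182
```

i.e. a corrected TM4–TM4 efficiency of 0.77 corresponds to a 5.7 nm
inter-label distance.

## Analysis workflow

The `analysis/` directory holds numbered drivers, each a thin narrative
script over the package functions, writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_dynamics.R` | calibrates the simulator and maps dimer fraction vs density (0.43–10³ µm⁻²) against both oracles |
| `02_track_kinetics.R` | MSD/diffusion fits on synthetic tracks, z-test, Hardt frequency, formation-rate pipeline |
| `03_ensemble_fret.R` | per-site apo-vs-agonist comparison, TM4–TM4 distance, spectral correction chain |
| `04_smfret_dynamics.R` | mixture/BIC analysis, threshold, dwell and survival analysis, high-FRET fraction |
| `05_interface_models.R` | 127-subset combination fitting, nested F-test, DEER combination fit |

Run any of them from the repository root, e.g.
`Rscript analysis/01_simulate_dynamics.R`.

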