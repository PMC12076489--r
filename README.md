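# suprafiber

Computational toolkit for characterising hapten-functionalized
benzene-1,3,5-tricarboxamide (BTA) supramolecular copolymer fibers —
the water-borne, double-helical, antibody-recruiting kind. It is aimed
at groups combining mass spectrometry, scattering, molecular
simulation and fluorescence microscopy on dynamic supramolecular
materials, and implements the full analysis chain as tested, reusable
functions with a synthetic-data generator (known ground truth) behind
every step.

## What it computes

* **Monomer mass arithmetic** — molecular-formula parsing, average and
  monoisotopic masses, charge-state m/z, natural isotopologue patterns
  by per-element convolution, and labile-hydrogen bookkeeping
  (outer OH/NH that exchange instantly on dilution into D2O vs inner
  amide NH shielded in the stack).
* **HDX-MS exchange kinetics** — deconvolution of isotopic envelopes
  into 0D…nD deuterated-species fractions by non-negative least
  squares, and fitting of the two-process growth model
  y(t) = A_fast(1 − e^(−k_fast t)) + A_slow(1 − e^(−k_slow t)),
  where the fast process reflects solvent penetration and the slow one
  monomer migration; amplitudes need not reach 100% within the window.
* **Scattering** — SLS reduction via the toluene-referenced Rayleigh
  ratio R = ((I_sample − I_solvent)/I_toluene) · R_toluene ·
  (n_solvent/n_toluene)², power-law diagnostics (slope −1 = long
  rods), and an orientation-averaged elliptical-cylinder SANS form
  factor with bounded least-squares fitting; the fitted axis ratio
  rounds to monomers per fiber cross-section.
* **Trajectory metrics** — per-helix core radial distribution
  functions g(r) (stacking order: peaks at multiples of the 3.4 Å
  rise), stacking-order scores, and side-chain extension maps with the
  folded (<20 Å) / extended (>25 Å) back-folding classification.
* **TIRF quantification** — fiber segmentation from the polymer
  channel, background-subtracted antibody-channel contrast, binding
  time courses with saturation times, and condition comparisons.

## Worked example

Exchange kinetics of the trivalent-hapten monomer inside the
2.5:1:96.5 copolymer — simulate spectra, deconvolve, fit:

```r
library(suprafiber)

m   <- study_monomer("BTA-DNP3")          # 9 labile H: 6 outer + 3 inner
row <- exchange_parameter_table()         # fitted copolymer parameters
row <- as.list(row[row$monomer == "BTA-DNP3", ])

cfg <- exchange_sim_config(m, row$k_fast, row$k_slow, row$A_fast,
                           row$A_slow, noise_rel = 0.02, seed = 1)
series  <- simulate_species_fractions(cfg)
pattern <- isotope_pattern(m$formula)
spectra <- spectra_from_fractions(series, pattern, noise_rel = 0.02)
rec     <- deconvolve_series(spectra, pattern, m)
fit     <- fit_biexponential(fully_deuterated_curve(rec))
fit
#> <kinetic_fit> k_fast 0.7521 1/h, k_slow 0.04812 1/h, A_fast 66.1%, A_slow 13.5% (RSS 1.236)
eval_biexponential(row, 70)
#> [1] 79.2712
```

The recovered parameters sit on the generating row (k_fast 0.76/h,
k_slow 0.05/h, A_fast 65.5%, A_slow 14.2%) after the full
spectra-to-fractions-to-fit chain at 2% noise, and the model evaluated
at 70 h gives 79.3% fully deuterated monomers — the ~80% endpoint that
distinguishes the hapten monomer's dynamics from the plain hydroxyl
monomer (60%). Turning on the penetration channel
(`penetration_rate > 0`) additionally populates the intermediate
(n−1)D and (n−2)D species that `intermediate_species_summary()`
quantifies over the first two hours.

The numbered scripts in `analysis/` run the five studies end to end
(masses, exchange kinetics, scattering, fiber structure, TIRF
binding) and write their tables under `results/`:

```sh
Rscript analysis/02_hdx_exchange.R
Rscript analysis/03_scattering.R
```

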