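---
title: "Methods: quantifying structure and dynamics of hapten-functionalized supramolecular copolymers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying structure and dynamics of hapten-functionalized supramolecular copolymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suprafiber)
```

## Scope and model system

Benzene-1,3,5-tricarboxamide (BTA) monomers bearing water-compatible
side chains co-assemble in water into one-dimensional double-helical
fibers. Decorating a small mole fraction of monomers with haptens
(dinitrophenyl, DNP) and membrane anchors (benzoxaborole) turns these
fibers into dynamic, antibody-recruiting materials. `suprafiber`
implements the complete computational layer used to characterise such
multicomponent copolymers:

1. molecular-formula arithmetic and isotope patterns for monomer design
   (`average_mass()`, `monoisotopic_mass()`, `isotope_pattern()`);
2. hydrogen/deuterium-exchange mass spectrometry (HDX-MS): a forward
   simulator of deuterated-species spectra, an envelope deconvolution,
   and the two-process biexponential exchange model
   (`simulate_species_fractions()`, `deconvolve_species()`,
   `fit_biexponential()`);
3. static light scattering (SLS) reduction and small-angle neutron
   scattering (SANS) elliptical-cylinder fitting (`rayleigh_ratio()`,
   `fit_elliptical_cylinder()`);
4. stacking-order and side-chain back-folding metrics on labeled
   double-helix trajectories (`core_rdf()`,
   `side_chain_extension_map()`);
5. segmentation-based quantification of two-channel TIRF image series
   (`segment_fibers()`, `binding_time_course()`).

No instrument data ship with the package: every analysis is validated
against a synthetic-data generator that emits ground truth alongside
each dataset. The numbered scripts under `analysis/` run the five
studies end to end and write their tables under `results/`.

## Exchange kinetics: the two-pathway model

A monomer has `n_labile_total` exchangeable hydrogens split into
`n_outer` outer hydroxyl/amide hydrogens, which exchange effectively
instantaneously upon dilution into D2O, and `n_inner` core-amide
hydrogens shielded inside the hydrophobic stack (six total for the
plain hydroxyl monomer, nine for the trivalent-hapten monomer). The
generative model (`exchange_sim_config()`) distinguishes:

* a **fast** subpopulation (amplitude `A_fast`, percent) whose inner
  hydrogens exchange all at once upon monomer escape at rate `k_fast`
  (1/h) — solvent-penetration-dominated regions;
* a **slow** subpopulation (`A_slow`, `k_slow`) — migration out of
  ordered stack regions;
* an inert-in-window remainder, `100 - A_fast - A_slow`;
* optionally, a **penetration channel** exchanging inner hydrogens one
  at a time at a per-hydrogen rate (1/h) in any not-yet-escaped
  monomer. With equal stage rates the number of exchanged inner
  hydrogens follows the Erlang stage occupation
  \(P(j;t) = (pt)^j e^{-pt}/j!\) with an absorbing final stage; this is
  what populates the intermediate (n−1)D and (n−2)D species summarised
  by `intermediate_species_summary()` over the first two hours.

The fully-deuterated percentage then follows the biexponential growth
law \(y(t) = A_f(1-e^{-k_f t}) + A_s(1-e^{-k_s t})\), exactly when the
penetration channel is off. Parameter-recovery fixtures
(`simulate_biexp_curve()`) are generated directly from this closed
form — not the mechanistic model — so recovery tests measure fitter
quality free of model mismatch.

**Fitting choices.** `fit_biexponential()` uses bounded
Levenberg–Marquardt (minpack.lm) with a five-point multi-start (rate
scales seeded from the early-time slope and from fixed decades),
keeping the best-RSS solution; the larger rate is labelled fast, with
ties broken by amplitude. Amplitudes are bounded in [0, 100] but their
*sum* is deliberately not pinned to 100: the fitted copolymer rows
(35.5 + 28.6 and 65.5 + 14.2) leave an unexchanged remainder within
the 70 h window, so the model must admit a plateau below 100% (a
violation of the soft sum bound only raises a warning). Residuals are
unweighted — no per-point uncertainties are assumed. Biexponentials
are ill-conditioned when the two rates approach each other; recovery
is validated for rate separations of ~15x and ~40x, matching the
study regime. A curve that is identically zero returns zero amplitudes
with rates flagged unidentifiable rather than an arbitrary fit.

**Sampling design.** Default timepoints are t = 0 plus 14 log-spaced
points from 0.25 h to 70 h (`default_hdx_timepoints()`): the fast
process (half-life down to ~12 min) needs dense early sampling while
the slow tail extends to 70 h. The experimental landmarks (100x
dilution, 2 h intermediate window, 70 h endpoint) are retained; exact
instrument timepoints beyond those landmarks are a package choice.

## Envelope deconvolution

Species j (j deuteriums) contributes the monomer's natural isotope
pattern shifted by \(j\,(m_D - m_H)/z\). `deconvolve_species()` builds
that design matrix on a common m/z grid (centroid binning, default
0.005 m/z) and solves the non-negative least-squares problem with
`pracma::lsqnonneg`, renormalizing the fractions to sum to one. On
noiseless stick spectra this inverts the forward model to machine
precision for all species counts used here (n = 6 and n = 9); at 1%
relative intensity noise a 0.3/0.7 binary mixture is recovered within
0.02 absolute. Isotope patterns are element-by-element convolutions of
the embedded isotope table (IUPAC/CIAAW 2021 values), pruned below a
relative-abundance cutoff after each element (bounded memory) and
renormalized once at the end. Back-exchange correction, multi-charge
aggregation, and profile-mode peak picking are out of scope.

## Scattering

**SLS.** Count rates reduce to the excess Rayleigh ratio via
\(R = \frac{I_{sample}-I_{solvent}}{I_{toluene}} R_{toluene}
(n_{solvent}/n_{toluene})^2\) with the toluene reference
\(R_{toluene} = 2.1\times10^{-2}\,m^{-1}\) at 532 nm, water
\(n = 1.333\), toluene \(n = 1.497\); \(q = 4\pi n \sin(\theta/2)/
\lambda\) (1/nm). Negative excess scattering is reported with a
warning, never clipped. A log–log slope of −1 over the measured window
(`fit_power_law()`) is the elongated-scatterer diagnostic.

**SANS.** The elliptical-cylinder form factor is the double
orientation average of
\(F = \mathrm{sinc}(qL\cos\alpha/2)\cdot 2J_1(q r(\varphi)
\sin\alpha)/(q r(\varphi)\sin\alpha)\) with
\(r(\varphi) = r_{minor}\sqrt{\cos^2\varphi + \nu^2\sin^2\varphi}\)
(axis ratio \(\nu \ge 1\)), normalized so intensity tends to scale +
background as \(q \to 0\). Both averages use fixed-order
Gauss–Legendre quadrature (defaults 128 x 64 nodes), a deterministic
and testable choice: halving/doubling the orders changes the intensity
by under 1e-6 for moderate \(qL\); for very long cylinders
(\(qL \gtrsim 10^3\)) the axial sinc oscillates faster than any fixed
grid resolves, which leaves per-point wiggle but does not bias the low-q
slope or the fitted cross-section. At axis ratio 1 the model collapses
onto an independently coded circular-cylinder single integral to 1e-8.

Fits (`fit_elliptical_cylinder()`) run bounded Levenberg–Marquardt on
log intensity (curves span decades). When the lowest measured q never
reaches the Guinier plateau of the fiber (no plateau at low q — fibers
are micron-scale), the length is unidentifiable and is held fixed by
default, fitting the cross-section only; the fit reports a
`length_identifiable` flag. The fitted axis ratio, rounded to the
nearest integer (`cross_section_monomer_count()`), is a documented
heuristic for monomers per cross-section: ~1.87 rounds to 2, the
double-helix signature. q is 1/Å for SANS and 1/nm for SLS, declared
in every output header.

## Trajectory metrics

The generator (`build_double_helix_trajectory()`) emulates the
simulated morphology: two strands of 9 monomers (18 total), cores
stacked at the characteristic 3.4 Å rise along each strand axis
(strand two offset axially by half a rise), each monomer carrying
three labeled side-chain endpoints (OH terminus, linker amide NH,
terminal NH) placed at a folded (15 Å) or extended (28 Å) distance
from its core, with per-frame isotropic Gaussian jitter. The per-step
twist rotates the side-chain arms, not the cores — the intra-strand
nearest-neighbor distance is therefore exactly the rise, which is what
the stacking diagnostics probe.

`core_rdf()` histograms intra-helix core–core distances pooled over
frames. Two conventions matter and are deliberate: bins are *centered*
on multiples of the bin width, so ideal-lattice distances (3.4, 6.8,
10.2 Å at 0.1 Å bins) land on bin centers rather than edges; and
normalization divides by `N_pairs x bin_width / r_max`, the density a
structureless (uniform-distance) reference would give, so flat
backgrounds sit at g = 1. Pair distances here live on a quasi-1D
support, so no 4πr² shell correction applies; peak *positions* are the
robust observable, peak heights depend on this convention. Inter-helix
pairs are excluded, matching the per-helix stacking-order readout.
`stacking_order_score()` counts consecutive neighbor shells resolved
(peak within 0.6 Å of k x rise, height ≥ 1.5, prominence ≥ 0.5);
ideal stacks score 3 within 12 Å, and positional jitter suppresses the
higher shells first. At large jitter all shells dissolve together, so
the score drops from 3 toward 0 without a guaranteed plateau at 1.

`side_chain_extension_map()` reports per-unit, per-label mean
core-to-endpoint distances — invariant under rigid motions of every
frame — and classifies them with the back-folding thresholds: folded
below 20 Å, extended above 25 Å, intermediate between (the
experimental color maps use a continuous scale; the intermediate band
makes the threshold choice explicit). Against generator ground truth
the classifier is ≥ 95% accurate for jitter up to 1 Å.

Trajectories serialize as labeled multi-frame XYZ (full precision) or
a minimal PDB-like format (3-decimal coordinates, labels ≤ 4
characters); both read back into identical analyses.

## TIRF quantification

`render_fiber_image_series()` draws fiber polylines (half-width 4 px)
on a 0.16 µm/px grid, blurs with a Gaussian PSF (σ = 0.8 px,
sub-pixel as a diffraction-limited PSF at this pixel size is), and
adds Poisson-plus-Gaussian noise; the red polymer channel is constant
while the green antibody channel follows a prescribed binding curve.
The pre-PSF rasterized path is the ground-truth mask.

`segment_fibers()` smooths (σ = 0.5 px), thresholds with Otsu (the
policy is pluggable), and drops components under 20 px; a
near-constant image returns an empty mask with a warning.
`masked_intensity_stats()` measures the on-fiber mean on the mask
eroded by 2 px — the PSF dilutes fiber edges, so the erosion reads the
interior plateau (falling back to the full mask if erosion empties
it) — and the background on the complement of the 3-px-dilated mask,
excluding a 5 px border, so PSF bleed-through does not contaminate the
background. The background-subtracted contrast is then accurate to a
few percent on synthetic truth, and invariant under adding a constant
offset to the image (the ratio statistic, also reported, is not).
`binding_time_course()` uses a fixed first-frame mask by default
(fibers are surface-anchored; per-frame masking is available), takes
the plateau as the trailing-frame mean, and interpolates the time to
95% of plateau. The exact masking protocol of the original instrument
analysis is not public; these defaults are documented, pluggable
stand-ins, and all validation is against the generator's ground
truth.

## Synthetic data: what it does and does not emulate

Generators cover: HDX spectrum time series under the two-pathway model
(with instantaneous outer exchange at t = 0+), SLS scans inverted from
a target power law through the Rayleigh equation, SANS curves from the
elliptical-cylinder model, double-helix trajectories with fold ground
truth, and two-channel image series with mask and binding-curve ground
truth. Noise models are simple and documented: multiplicative Gaussian
on spectral/scattering intensities, Poisson + Gaussian on images.
Every generator takes an explicit seed, restores the caller's RNG
state, and is bit-reproducible under a fixed seed. The default
copolymer fixture mirrors the study design: 2.5:1:96.5
trivalent-hapten : anchor : hydroxyl monomer, 500 µM diluted 100x to
5 µM, timepoints to 70 h.

Passing tests on these fixtures demonstrates correctness of the
*computations* — deconvolution inverts its forward model, fitters
recover generating parameters, classifiers match ground truth — not
fidelity to raw instrument physics: there is no detector smearing or
resolution function, no back-exchange, no polydispersity or structure
factor, no fluorophore photophysics, and trajectories are geometric
emulations rather than force-field simulations. Problem sizes in the
tests and scripts (20-replicate recovery studies, 60-point q grids,
96-128 px images, 10-100 frame trajectories) were chosen as the
smallest sizes at which the statistical claims stabilise.

## Known limitations

* The biexponential fit reports asymptotic standard errors; replicate
  simulation is the supported way to get finite-sample spread.
* The elliptical-cylinder fit assumes a fixed, known length when the
  data contain no plateau; joint length/cross-section fitting is only
  meaningful with lower-q coverage.
* The monomers-per-cross-section rounding is a heuristic, not a volume
  calculation.
* Segmentation thresholds (Otsu) assume bimodal intensity histograms;
  densely packed fibers or strong vignetting would need a different
  threshold policy (the argument accepts any function).
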