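---
title: "Methods: densitometry, pressure balance and the synthetic instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: densitometry, pressure balance and the synthetic instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleodensity)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic data do
and do not emulate, and the numerical and design choices that were
genuinely open. Nothing stated here as a number is asserted beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## From refractive index to dry mass

Every quantification rests on one linear relation: the refractive index
of biological material exceeds that of the surrounding medium in
proportion to the dry-mass density of dissolved macromolecules,
$n = n_i + \alpha\rho$. The increment $\alpha$ is remarkably constant
across proteins and nucleic acids; the package default is
0.19 mL/g. (Some sources typeset the increment with concentration units;
that is dimensionally inconsistent — the quantity is a specific refraction
increment, volume per mass — and the package standardises on mL/g. Every
printed RI/density pair is consistent with this reading: a 0.019 RI excess
corresponds to 100 mg/mL.)

The internal unit system is fixed: µm, µm³, pg, mg/mL, mM, with
1 mg/mL = 10⁻³ pg/µm³ and 1 mM = 6.022×10⁵ particles/µm³. All constants
and conversions live in `nd_constants()`; no other file hardcodes a unit.

Compartment quantification is deliberately literal: volume is voxel count
times voxel volume, dry mass is the voxel-wise density integrated over the
label, mean density their quotient. Two policies are worth making
explicit:

* **Sub-background voxels are retained.** Noise can push a voxel's
  apparent density below zero. Clipping would bias every integral upward,
  so negative values are integrated as-is and their count is reported as a
  QC figure (`n_negative_voxels`); a flag exists for the alternative.
* **Nucleoli are excluded by labelling, not detection.** The density of
  the nucleoplasm is computed over label 2 only; the denser nucleolus
  (label 3) never contaminates it. The package does not auto-detect
  nucleoli — masks come from the generator or the user.

ROI-based density estimates (`roi_density_stats()`) reproduce the
small-cube protocol: seeded rejection sampling of axis-aligned cubes fully
inside the label, non-overlapping, at most 10⁴ attempts before a
descriptive error naming the limiting dimension. The cube edge is a
species-level parameter (0.5 µm for yeasts up to several µm for embryo
cells). An optional `z_standoff_um` keeps cubes clear of other labels
along the optical axis; with the default axial blur this matters (see
below), and the scenario layer uses twice the blur sigma. Randomised but
seeded placement is our rendering of "arbitrary and unbiased":
reproducible without being hand-picked.

## The pressure-balance model

The model treats the nuclear envelope as a semipermeable boundary with no
mechanical tension and instantaneous water equilibration, so at every
moment the osmotic pressures balance. The osmotic units are protein
*complexes*: an assembled complex counts once, however many subunits it
has. Three pools matter:

* imported nuclear complexes — mass $M_p$, mean complex mass
  $m_n$ = 131.1 kDa;
* cytoplasmic complexes — concentration $n_c = \rho_c/m_c$ with
  $m_c$ = 155.8 kDa, so 0.64 mM for a 100 mg/mL cytoplasm;
* chromatin — an effective ideal particle count $N_{chr}$, giving a
  confinement pressure $kT\,N_{chr}/V$.

Setting $kT[M_p/(m_n V) + N_{chr}/V] = kT\,n_c$ gives the closed-form,
linear equilibrium volume implemented by `equilibrium_volume()`. The
$P_{chr} = kT\,N_{chr}/V$ form is a deliberate minimal choice: it is
monotone in confinement, keeps the balance closed-form, scales naturally
with genome size, and is observationally indistinguishable from a
counterion-osmosis reading of the same term. The measured data cannot
discriminate those two interpretations, and neither does the model.

Import is a single saturating pool,
$J = J_0 (G/G_{ref})^\beta (1 - M_p/M_{sat})$, zero before the
decondensation time $t_{dec}$ and zero when disabled. The exponent
$\beta$ compresses everything the chromatin → RanGTP → importin axis does
into one number; its default 0.56 is reconstructed so that the
laevis/tropicalis genome ratio maps onto the observed ~1.4-fold nuclear
dry-mass difference, and it is a configurable parameter, not a claim
about mechanism.

The simulated density is $\rho_n = (M_p + M_{chr})/V$: imported complexes
plus chromatin. Passively equilibrating species (<40 kDa) exchange freely
and are treated as part of the solvent on both sides; this lumped
accounting follows the measurement chain the anchors come from.

Two phases complete the trajectory:

1. **Decondensation** ($t < t_{dec}$, default 5 min): the condensed sperm
   state (183 mg/mL at volume $M_{chr}/\rho_{sperm}$) ramps linearly to
   the solvated volume $V_{dec} = M_{chr}/\rho_{dec}$. The decondensed
   chromatin density $\rho_{dec}$ defaults to $\rho_c$: chaperone-driven
   decondensation in buffer plateaus near cytoplasmic density, and a
   chromatin mass at ambient density displaces exactly its own mass of
   fluid — densitometrically invisible.
2. **Growth** ($t \ge t_{dec}$): $M_p$ integrates the flux; the volume is
   $\max(V_{dec}, V_{eq}(M_p))$. The floor encodes the import-off
   phenotype: with no import the nucleus simply holds the decondensed
   chromatin volume and therefore the cytoplasmic density, which is what
   the import-inhibited measurement shows (101.1 ± 1.6 vs 100 ± 2 mg/mL).

### Parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `m_n`, `m_c` | kDa | 131.1, 155.8 | measured mean complex masses |
| `rho_c` | mg/mL | 100 | measured extract density |
| `n_c` | mM | `rho_c/m_c` ≈ 0.642 | definition |
| `M_chr` | pg | 13.38 | 3.1×10⁹ bp × 650 Da/bp × κ/N_A |
| κ (packaging) | – | 4 | see below |
| `N_chr` | – | 4.3×10⁷ | closes the balance at the observed V₆₀ |
| `J0` | pg/min | 1.08 | closed-form: lands M_p(60 min) on 37.6 pg |
| `M_sat` | pg | 60 | saturating pool; 60-min mass sits at ~63% of it |
| `t_dec` | min | 5 | observed decondensation time |
| `beta` | – | 0.56 | genome→import scaling (see above) |
| `rho_sperm` | mg/mL | 183 | measured condensed sperm density |
| `rho_dec` | mg/mL | = `rho_c` | decondensed chromatin ≈ ambient density |
| `temperature_K` | K | 293 | extract work at 16–20 °C |

**The packaging factor κ = 4** deserves its own paragraph. The chromatin
mass subtracted from the measured total is never printed; only the genome
size is. κ multiplies the naked-DNA mass (3.35 pg) to account for
histones, chromatin proteins and RNA. κ = 4 is the round value that makes
the printed numbers mutually consistent: it yields a nuclear complex
concentration of 0.51 mM and a chromatin volume share of 19.9%, both
matching the published figures. It is exposed as a `chromatin_spec()`
parameter, and the calibration errors out with a diagnostic when a κ is
incompatible with the anchors — naked DNA alone (κ = 1) implies a
*negative* chromatin particle count at the observed volume, which is how
the calibration tells you chromatin must be heavier than its DNA.

### Calibration and fitting

`calibrate_xenopus()` is entirely closed-form: volume from mass and
density, chromatin from the genome, protein by subtraction, $n_c$ by
definition, $N_{chr}$ from the volume gap, $J_0$ by inverting the
saturating-pool solution. No optimisation touches these anchors.

`fit_model()` exists for observation tables (synthetic or otherwise):
SEM-weighted least squares over any subset of {V, M, ρ}, a derivative-free
Nelder–Mead search restarted from five seeded uniform draws within box
bounds (one-parameter fits use Brent's bounded method instead), residual
bootstrap for uncertainty. Rows with zero or missing SEM get their
observable's median SEM. Non-convergence is reported in the result rather
than thrown. The reference procedure behind the published simulation bands
is undescribed, so this module defines one and validates it by parameter
recovery: noise-free tables are recovered to optimiser precision,
5%-noise tables (175 nuclei) to within 10%, and bootstrap intervals cover
the generating truth in ≥80% of 50 seeded replicates — sizes chosen as a
deliberately scaled-down but statistically meaningful recovery design.

## The synthetic instrument

`make_cell_phantom()` emulates what the reconstruction *outputs*, not the
physics that produces it: nested analytic solids (ellipsoid cell, sphere
nucleus, sphere nucleoli; labels 0/1/2/3 in plane-major Z,Y,X order),
uniform densities mapped to RI, a Gaussian blur along the optical axis
only (σ default 0.4 µm) as a crude stand-in for the missing-cone
anisotropy of limited-angle tomography, and additive Gaussian RI noise
(default 2×10⁻⁴, small against the 0.019 contrast of 100 mg/mL). Voxels
default to 0.12 µm, the resolution scale of the emulated instrument.
Holography, Fourier-diffraction reconstruction and real PSF physics are
out of scope; consequently the phantoms cannot validate reconstruction
artefacts beyond axial smearing, and tests passing on phantoms say
nothing about, e.g., refractive-index dispersion or coherent noise in
real data.

Ground truth is analytic (sphere and ellipsoid volumes times densities),
so quantification can be scored against exact values: at the default
voxel size, integration over the true mask recovers compartment masses
and volumes within 2% for radii ≥3 µm — the voxelisation error budget the
tests enforce. The axial blur does introduce a real partial-volume band at
compartment boundaries: whole-label means of small compartments are
biased by several percent, which is precisely why the ROI protocol (with
an axial standoff) is the density estimator of record, as it is in the
emulated experiment.

`make_assembly_timecourse()` wraps the deterministic simulation with
per-nucleus multiplicative noise (one factor per nucleus, time and
observable; density recomputed as mass/volume so the three observables
stay internally consistent) and reports mean ± SEM. The default 175
nuclei and 5% noise match the scale of the reference experiment's final
time point.

`make_embryo_lineage()` encodes the cleavage null model. Each division
splits a cell's material pool — volume and dry mass — exactly in half
(optionally asymmetrically, seeded). Within each cell a nucleus condenses
out of the cytoplasm at the fixed nucleoplasmic density: imported mass
`min(M_sat, φ·cell dry mass)`, volume from the pressure balance, and the
cytoplasm surrenders the nuclear mass together with `M_n/ρ_c` of volume so
its density is exactly constant. Consequences, all tested: total dry mass
is conserved bit-for-bit at every stage; the NC density ratio is constant
by construction; the NC volume ratio rises with stage because the
chromatin term of the equilibrium volume does not shrink with the cell.
One bookkeeping subtlety: a daughter's *reported* cell volume (cytoplasm +
nucleus) differs from half the mother's pool by the nuclear osmotic
swelling term, because the nucleus is less dense than the material it
drew in — water follows the imported complexes. Conservation statements
therefore attach to the material pool and to dry mass, which is what the
tests assert. The default φ = 0.02 leaves the 2-cell stage below the
saturation cap, so the material limitation, not the cap, shapes the later
stages.

## Numerical choices

* **Integrator.** Fixed-step explicit Euler, default 0.1 min,
  deterministic. If the fastest possible step would move the pool by more
  than `M_sat`/10, the step is halved (with a message) until it cannot.
  The quasi-static volume makes the ODE one-dimensional and mildly
  nonlinear, so Euler at 0.1 min agrees with 10×-refined stepping to
  <0.1% on all state variables (tested, plus an independent Runge–Kutta
  cross-check).
* **Degenerate states.** `equilibrium_volume(0)` with no chromatin is 0
  and flagged with a warning rather than an error; the simulator reports
  density `NA` at zero volume. `ri_to_density()` never clips.
* **Otsu threshold.** One global threshold on the full-stack histogram
  (256 levels); per-plane thresholding is wrong for 3D objects whose
  cross-section changes with Z. A constant image is a degenerate
  histogram and errors.
* **Tie-breaks and determinism.** Every stochastic step (phantom noise,
  ROI placement, time-course noise, division asymmetry, multi-start
  draws, bootstrap) runs under an explicit seed through an RNG-state-
  preserving wrapper; identical seeds give bit-identical outputs, and the
  scenario layer stamps every report with the MD5 of its config.
* **Problem sizes.** The shipped tests run phantoms at 0.12–0.3 µm voxels
  (up to ~1.7 million voxels), time courses of 30–175 nuclei, 50-replicate
  bootstrap coverage at 19 resamples, and 4-division lineages — sizes
  chosen to exercise every code path at full fidelity while keeping the
  whole suite under a minute.

## Known limitations

* The chromatin pressure term is an effective ideal-gas form; polymer
  elasticity, electrostatics and counterion release are all folded into
  one count. Only the balance point, not the functional form, is
  constrained by the anchors.
* Envelope mechanics, pore-count regulation, lamina elasticity and lipid
  supply are absent; the model is quasi-static by construction and cannot
  describe tension-limited or permeability-limited regimes.
* The import exponent β is phenomenological; the RanGTP gradient has no
  spatial representation.
* The phantom's axial blur is a stand-in, not a PSF; segmentation
  robustness claims transfer to real reconstructions only qualitatively.
* Absolute per-species densities in the panel table are editable
  placeholders at the conserved 0.8 ratio, not measurements.
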