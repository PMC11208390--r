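---
title: "Patch-based Monte Carlo voxel dosimetry: models, layouts and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based Monte Carlo voxel dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchdose)
```

`patchdose` computes 3-D absorbed-dose maps for beta-emitting
radionuclide therapies (the bundled data target ⁹⁰Y liver SIRT) and, in
particular, implements a patch-based Monte Carlo workflow in which the
study volume is cropped into cubic tiles that can be simulated
independently and mosaicked back into a whole-volume dose. This vignette
is the package's own account of the underlying models, the geometry of
the cropping layouts, the synthetic data the tests run on, and the design
decisions taken where more than one reasonable choice existed.

## 1. From counts to time-integrated activity

A quantitative SPECT gives counts per voxel. Self-calibration
(`self_calibrate()`) converts them to Becquerel with one scalar factor:
the administered activity, decay-corrected to the acquisition start, over
the total image counts. The same acquisition interval `T` is used for the
decay correction and for the time integral; the package assumes one shared
interval for both (the alternative — two separate clocks — would only
rescale the map by a constant).

For microspheres that stay trapped in tissue, voxel activity decays purely
physically, so the number of decays over all time is

$$\mathrm{TIA} = \int_0^\infty A(t)\,dt = \frac{A(0)}{\lambda}
  = \frac{A(T)\,e^{\lambda T}}{\lambda},
  \qquad \lambda = \frac{\ln 2}{t_{1/2}},$$

with $t_{1/2} = 64.2\ \mathrm{h}$ for ⁹⁰Y (`tia_map()`,
`decay_params()`). Time is accepted in hours at every interface and
converted to seconds exactly once, internally. No biological clearance or
multi-time-point fitting is modelled; other isotopes are supported by
changing the half-life and spectrum.

## 2. The transport engine

`run_simulation()` is a desk-scale condensed-history β⁻ engine written in
C++ (Rcpp). It is deliberately simple and fully documented rather than a
replica of a general-purpose code:

* **Emission.** Decay positions are sampled proportionally to the TIA map
  and uniformly within a voxel; directions are isotropic. Kinetic energies
  are drawn by inverse CDF from a tabulated spectrum. The bundled ⁹⁰Y
  spectrum is the analytic allowed-transition Fermi shape
  $N(E) \propto pW(W_0-W)^2 F(Z{=}40, W)$ normalised on $(0, 2.28]$ MeV;
  its mean, 0.947 MeV, is within a few percent of evaluated nuclear data,
  adequate for the percent-level benchmarks below. (⁹⁰Y is in reality a
  first-forbidden unique transition; the shape correction it would add is
  not included.)
* **Energy loss.** At each step the electron deposits
  $\Delta E = S_w(E)\,\rho\,\Delta s$ into the voxel containing the step
  midpoint, where $S_w$ is a bundled ICRU-style collision stopping power
  of water (log–log interpolated, power-law extrapolated below 10 keV)
  and $\rho$ the local CT-derived density. All tissues use water stopping
  power scaled by density; at ~10 mm voxels the density term dominates and
  material-specific collision data would change doses by far less than the
  stochastic noise of the runs the package performs. Voxels with
  non-positive density are treated as vacuum (drift, no deposition).
* **Stepping.** $\Delta s$ is the smaller of ¼ of the smallest voxel edge
  and 1/20 of the residual CSDA range (both configurable in
  `transport_config()`), with a 0.1 µm floor. The CSDA range table is the
  integral of $1/S_w$; at 2.28 MeV it gives 11.4 mm in water, matching the
  textbook ⁹⁰Y maximum range of ≈ 11.3 mm that also sizes the patch
  overlap.
* **Multiple scattering.** A Highland-style Gaussian kick per step
  (plane-projected RMS $\theta_0 = \frac{13.6\,\mathrm{MeV}}{p\beta c}
  \sqrt{x/X_0}\,[1 + 0.038 \ln(x/X_0)]$, $X_0 = 36.08\ \mathrm{g\,cm^{-2}}$).
  It can be switched off for straight-track oracle tests.
* **Termination.** A history ends below the energy cutoff (default
  15 keV, the soft-tissue equivalent of a 0.01 mm range cut; kernel
  generation uses 5 keV) with the residual deposited locally, or on grid
  exit with the residual counted as escaped. Deposited plus escaped energy
  equals the sampled energy exactly — the suite asserts this to 1e-9
  relative — and bremsstrahlung photons, δ rays and positrons are not
  transported.
* **Batches and uncertainty.** Primaries are split evenly over batches
  (default 10), each on its own RNG stream derived deterministically from
  `(seed, stream)` with a self-contained xoshiro256+ generator, so results
  are bit-reproducible and independent of R's RNG state, and batches (or
  patches) may run in any order. `merge_batches()` returns the
  primaries-weighted mean and the history-by-history percentage
  uncertainty $U = 100\,s/\bar d$, with $s$ the standard error of the
  batch means; with equal batches this reduces to
  $s = \sqrt{\frac{1}{B-1}\left(\frac{\sum d_i^2}{B} -
  \left(\frac{\sum d_i}{B}\right)^2\right)}$.
* **Absolute scaling.** Per-primary dose maps are multiplied by the total
  simulated-source TIA (`scale_to_absolute()`); each patch uses its own
  patch ΣTIA.

As a physics benchmark, `sphere_s_value()` voxelises a 60 g water sphere
(radius 24.29 mm) in air and returns ≈ 2.31e-12 Gy/decay at 2 mm voxels —
within ~2% of the published reference value 2.2679e-12 Gy/decay. The ~2%
excess is the expected sign of neglecting bremsstrahlung escape and of the
simplified spectrum; the package treats 3% as its engine fidelity band.

## 3. HU to density and materials

`hu_to_density()` interpolates a compact piecewise-linear anchor table
(air −1000 HU → 0.00121, lung −740 → 0.26, adipose-like −98 → 0.93, water
0 → 1.000, liver-like 60 → 1.06, 400 → 1.25, 1500 → 1.90 g/cm³), clamped
at the extremes; `hu_to_material()` bins HU into air / lung / soft tissue
/ bone (< −950 / −950…−200 / −200…200 / > 200). This reproduces the
densities the dosimetry actually depends on with an auditable table; a
full multi-material CT calibration is out of scope because the engine
only consumes density.

## 4. Cropping layouts and mosaicking

All layouts tile the volume with cubic stride cells of edge `source_edge`
after zero-padding to an integer number of cells (stride padding on the
high-index side, overlap halo symmetric; `zero_pad()` records the exact
inverse). Patch order is lexicographic in (z, y, x) origin and recorded,
so reassembly is deterministic.

* **`cl1` (naive).** Source = geometry = stride cell. Emissions near a
  border leave the patch and are discarded — the mosaic strictly
  under-doses voxels within one deposition range of an interior boundary.
* **`cl2` (overlap-average).** Source and geometry are the stride cell
  expanded by OV voxels per face; each mosaic voxel is the mean of the
  N ∈ {1, 2, 4, 8} covering patches (the actual coverage count, not a
  fixed N). Border emissions are retained, but a band voxel near the edge
  of the overlap region is under-estimated by the patch whose source ends
  there, so the average still under-doses band edges.
* **`cl3` (physics-inspired).** Sources tile the volume without overlap
  and are zero-padded into the enlarged geometry patch; mosaic voxels are
  the *sum* of covering patches. Every contribution is counted exactly
  once, and border emissions still deposit inside the enlarged geometry.

"Overlap of OV voxels on each side" is interpreted as: each geometry patch
extends OV voxels beyond its stride cell on every face, so adjacent
patches share a 2·OV-wide band and the canvas carries an OV halo. This is
the only reading consistent with a 40-voxel geometry patch over a
32-voxel stride and with coverage multiplicities {2, 4, 8}; it also puts
the `cl1` borders at the centre of the `cl2` bands, which is what makes a
shared evaluation region possible. Dose deposited outside a patch's
geometry has no canvas address and is discarded — exactly the loss
mechanism the enlarged `cl3` geometry removes.

The overlap is sized from the particle range: `min_overlap_voxels()`
returns the even number closest to $\lceil 2R/v \rceil$. Odd values are
equidistant from two even numbers; the package resolves the tie upward
(never below the minimum), which for ⁹⁰Y (R = 11.3 mm, v = 9.59 mm,
OV_min = 3) gives 4 voxels = 38.36 mm per face.

**The exactness property.** For any *linear* dose operator with a compact
footprint of half-width ≤ OV (a convolution kernel), cropping under `cl3`,
applying the operator per patch with zero boundary, and sum-mosaicking is
algebraically identical to applying the operator to the whole volume:
sources partition, the operator is additive, and no contribution can
escape the geometry patch. The suite verifies this to 1e-12 relative with
toy kernels (`make_toy_kernel()`, delta/uniform/tent shapes) and verifies
the complementary failure modes: `cl1` is strictly low on every band voxel
within the kernel reach of a boundary, `cl2` exactly on the band centre
but strictly low on the band edges. The stochastic MC analogue holds in
expectation; see §7 for what finite desk-scale runs can and cannot show.

`patch_mc_dose()` runs the full stochastic pipeline: homogeneous primaries
split across patches (`allocate_primaries()`, remainder to the first
patches), per-(patch, batch) RNG streams, per-patch absolute scaling,
batch-wise mosaicking, and batch merging for the uncertainty map. Patches
with zero TIA are skipped and contribute zero dose.

## 5. Kernel dosimetry

`generate_vsv()` produces a voxel S-value kernel by simulating decays
uniformly in the central voxel of a homogeneous soft-tissue block
(ρ = 1.03 g/cm³, edge 25, 9.59 mm voxels by default) at the finer 5 keV
cutoff; `convolve_tia()` convolves the TIA map with it (direct sparse
spatial convolution, zero boundary — bit-stable and exact for compact
kernels, which an FFT route would not be); `density_correct()` applies the
first-order heterogeneity correction. The direction of that correction is
genuinely ambiguous in parts of the literature; energy-per-mass reasoning
gives $D' = D\,\rho_{\mathrm{ref}}/\rho$, which is the package default,
with the reciprocal selectable and always recorded. Voxels at or below the
air threshold are zeroed. Kernel generation defaults to 1e6 primaries at
desk scale (a production kernel would use 1e8); kernel noise then enters
any comparison made with it.

## 6. The phantom factory

`make_synthetic_patient()` builds the full study input deterministically:
a 64 × 64 × 42 grid at 9.59 mm (the bremsstrahlung-SPECT geometry the
package is sized for), ellipsoidal body (0 HU), liver (60 HU), two lungs
(−740 HU), an optional bone rod (400 HU); activity confined to the treated
lobe (right by default, as the more common case) with a 3× hot 25 mm
lesion, a 5% lung shunt, multiplicative log-normal texture (σ = 0.4 —
voxel-wise error metrics are uninformative on perfectly uniform sources),
normalised to the administered activity (1.5 GBq default), then blurred
with a 10 mm FWHM Gaussian standing in for SPECT resolution. The blur
kernel is renormalised, so activity is conserved up to edge clipping,
which is reported and negligible for interior organs. The phantom
exercises every density regime the evaluation cares about: air (excluded
by the soft-tissue mask), lung ≈ 0.26, soft tissue ≈ 1.0, liver ≈ 1.06.

What it does **not** emulate: anthropomorphic anatomy, SPECT
projection/reconstruction physics (collimator response, scatter,
attenuation artefacts), registration error, CT noise. Passing tests on
this phantom therefore validate the dosimetry pipeline and the layout
mathematics, not image-formation effects.

`make_benchmark_sphere()` voxelises the 60 g water sphere (centre-inside
rule, ≥ 3-voxel air margin); at 2 mm voxels its mass error is below 2%,
and the S-value denominator uses the voxelised mass so source and target
are self-consistent.

## 7. Numerical choices, evaluation, and honest limits

* **Evaluation region.** All comparisons run on the soft-tissue mask
  ρ > 0.05 g/cm³ (keeps lung, drops air); voxels with zero reference dose
  are excluded from PD maps and counted. Whole-body region statistics use
  this same mask (rather than all body voxels) and the overlap band shared
  by all layouts is the `cl2` band, so `region_statistics()` partitions
  one common region. The mean uncertainty entering the efficiency factor
  `EF = 1/(T·U²)` averages voxel uncertainties over the evaluation mask
  where dose is positive; computation times are recorded but never
  asserted, being hardware-dependent.
* **Problem sizes.** The suite runs the MC engine at 1e4–1e6 histories and
  generates kernels at 2e5–1e6 primaries; these sizes were chosen so the
  whole suite completes on a single CPU in minutes while keeping the
  statistical assertions meaningful (4σ bands for sampling tests, 20%
  bands for 1/√N laws at a few tens of deposits per batch and voxel).
* **Noise regimes.** The layout ordering `cl1 > cl2 > cl3` in band error
  is a statement about *systematic* border losses. It is exact in the
  deterministic kernel form. In stochastic form it emerges only once the
  per-voxel statistical noise falls below the few-percent systematic —
  around 1e8 primaries for this geometry, as in production studies. At
  1e6 histories the band PD of every layout is dominated by counting
  noise (~20% mean voxel uncertainty); in that regime PD/U is close to a
  layout-independent constant (~2, inflated above the Gaussian 1.13 by
  heavy-tailed low-dose voxels), and `cl2`'s band averaging actually gives
  it the *lowest* noise-driven PD. The package reports these quantities
  as measured and leaves the interpretation to the uncertainty analysis
  rather than filtering voxels to force the asymptotic picture.
* **Ties and degenerate inputs.** Even-overlap ties round upward;
  single-batch tallies return `NA` uncertainty with a warning; all-zero
  TIA, empty masks, misaligned grids, non-monotone HU tables and
  under-resolved spheres raise errors rather than guessing.

## 8. Interfaces

Volumes travel as NIfTI with a JSON sidecar carrying the role tag and
origin (`read_volume()`, `write_volume()`); run configurations serialise
to JSON (`run_config()`, `save_config()`, `load_config()`);
`run_comparison()` executes reference MC, kernel dosimetry and the three
patch layouts at matched total primaries and `write_report()` emits
JSON + CSV (+ optional NIfTI) such that every table is reconstructible
from the stored dose maps. A thin command-line wrapper over these
functions ships in `inst/cli/patchdose.R`.
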