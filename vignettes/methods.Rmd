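---
title: "Sorting chaperonin conformers from side views: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting chaperonin conformers from side views}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(conformosort)
```

This vignette is the package's own account of its science: what the
phantom emulates, how each stage models the data, which parameters matter,
where the design was genuinely open, and what the passing tests do and do
not show about real data.

## The problem

A double-ring, seven-fold symmetric chaperonin imaged in the presence of
ATP is a mixture of allosteric states. Each subunit has three rigid-body
domains — equatorial (ATP site, inter-ring contacts), intermediate, and
apical (substrate/cochaperonin binding) — connected by two hinges. The
ATP-driven trajectory runs: en-bloc ~35° sideways tilt of the
intermediate+apical block about hinge 1; additional apical elevation about
hinge 2; radial expansion and further elevation into an "open" state
(about 70% of the final elevation); and a ~100° clockwise apical twist
into the domed, cochaperonin-bound end state. Because side views are the
informative orientation class for double rings, the data are boxed side
views, and the analysis must (i) sort the particle images by conformer,
(ii) reconstruct each class with C7 symmetry, (iii) fit a multi-domain
model into each map, and (iv) quantify the domain motions and the
salt-bridge pattern that fingerprints each state.

## The phantom: exactly known ground truth

`defaultSubunit()` builds a pseudo-atomic caricature — not a crystal
structure — of one subunit: three ellipsoidal blobs of ~110 pseudo-atoms
with helix-like protrusions (H, I, M, the K/L hairpin), a lateral β-sheet
contact group on the equatorial domain, two hinge pivots, and fourteen
marker pseudo-atoms named after the salt-bridge residues (K80, D83, A109,
R197, K207, K242, K245, E255, E257, E386, K327, R452, E461, V464).
`buildStateModel()` applies a per-ring parameter set in the fixed order
tilt → elevation → radial shift → twist (about the carried-along local
axes), an equatorial tilt about the inter-ring contact pivot, and a
whole-ring rotation; the C7 ring and the two-fold-flipped, 360/14°
staggered second ring are then assembled exactly, so C7 closure holds to
machine precision and every downstream measurement can be checked against
truth.

Choices worth knowing about:

* **Canonical parameter values.** The published anchors pin Rs1's tilt
  (35°), the Rs2→Rs_open elevation step (20°), the Rs_open fraction of the
  final elevation (70%), and the final twist (100°). Everything else —
  Rs2's elevation (10°), the open-state radial shift (5 Å), all equatorial
  tilts, and the double-ATP (Rd) ladder — are package defaults, chosen
  once and flagged as stand-ins.
* **Marker calibration.** Marker positions were solved numerically (a
  penalty optimisation over the marker coordinates) so that the canonical
  library reproduces the published contact truth table under the 8 Å rule
  — T holds R197–E386 and E255–K207; the 35° tilt breaks both and forms
  K80–E386 and E255–K245; the open states hold nothing; the Rd ladder
  slips 255–245 → 255/257–245 → 255/257–245/242 — and so that the
  intrasubunit D83–K327 separation tracks 8 / 12.4 / 15.7 / 36 Å over
  T / Rs1 / Rs_open / R_ES. The equatorial tilt (5.8° in the single-ATP
  states) is calibrated so the A109–A109 inter-ring contact lengthens by
  2.0 Å from T to Rs1; the open states tilt more (12°), consistent with
  the progressive weakening of the ring interface.
* **Equatorial tilt scope.** The equatorial tilt moves only the equatorial
  domain (pivot at the outer inter-ring contact). This is what lengthens
  A109–A109 and what keeps K80–E386 unformed in the expanded Rd rings
  while their apical tilt is still large.
* **Rd ladder drivers.** A rigid whole-ring rotation cannot change
  intra-ring intersubunit distances, so the click-stop ladder is driven by
  the per-state tilt/elevation values plus a small negative apical twist
  in Rd2/Rd4; the ring rotation is kept for the inter-ring geometry.

`simulateStack()` emulates the data set: states drawn from the model list,
out-of-plane tilt uniform in 80–100° (side views), azimuth and in-plane
rotation uniform, sub-pixel shifts up to 3 px, defocus uniform in 0.7–3.5
µm at 120 kV, CTF applied in Fourier space, then white Gaussian noise
scaled so that signal variance / noise variance inside the particle-radius
mask (0.4 of the box width ≈ the particle's circumscribed radius) equals
the requested SNR. The generator writes MRC stacks and a TSV ground-truth
table. It does *not* model micrographs, picking, ice gradients, beam
motion or colored noise: passing tests show the statistical sorting logic
works under calibrated white noise, not that it is robust to every
real-data pathology.

## Image processing

The CTF is the standard weak-phase model, `CTF(f) = −(√(1−A²)·sin χ +
A·cos χ)` with `χ = πλΔz f² − (π/2)Cs λ³ f⁴`; correction is phase flipping
only — the minimal, testable-as-involution choice; no Wiener amplitude
restoration, no astigmatism. Band-pass filtering (175–4 Å in the standard
protocol) uses raised-cosine edges two Fourier pixels wide; normalisation
scales to unit background variance outside the particle mask, with the DC
term removed. All cutoffs are in Å and converted through the pixel size.

## Classification

Eigenimages are plain principal components of the aligned stack (the
Gram-matrix route); the classical chi-square-metric variant used by older
packages is deliberately not reproduced — the oracle tests target exact
covariance diagonalisation. Components whose power concentrates in the
apical annulus (default threshold: 0.5 in-mask power fraction) are taken
as "conformational"; this is a stated automated surrogate for what was
historically a visual call. k-means (fixed seed) on the selected
components gives the initial partition.

Competitive alignment then iterates {reproject each 3D reference over the
side-view grid; assign each particle; reconstruct each class} until fewer
than 1% of particles change class. Three design elements matter at low
SNR, and all three are this package's own choices:

* **Paired decisions.** The orientation is chosen once per particle on the
  class-averaged score, and the class comparison is made at that same
  orientation. Maximising orientation independently per class drowns a
  ~1% template difference in selection noise over hundreds of
  orientations.
* **Consensus registration.** In-plane rotation (continuous, golden
  section) and sub-pixel shifts (Fourier cross-correlation) are refined
  every iteration against the *class-averaged* template; refining against
  the chosen class's own template would bias the next decision toward it.
  The 180° side-view flip is re-checked every iteration by exact index
  permutation.
* **Model-regularised references.** At 500 particles/class and SNR 0.1 a
  free-form reconstruction estimates the *between-class difference map*
  very poorly (correlation with truth ≈ 0.2 even with oracle labels and
  registration), which caps raw competitive alignment at ~65–70% on the
  hardest (Rs1/Rs2) pair although oracle references reach 83.5%. Because
  the class difference lives on a one-to-three-parameter hinge manifold,
  the pipeline's final rounds fit each class map with `hingeRefine()`
  (tilt, elevation, radial shift only — freeing nuisance parameters would
  let them invent spurious between-class differences) and synthesise
  noise-free model maps as references. Scoring templates are attenuated
  by each defocus bin's |CTF|.

The per-particle information limit is worth stating plainly: Rs1 and Rs2
projections correlate at ~0.99, so even ideal references give ~84% on that
pair at SNR 0.1; the flagship's ~86% overall accuracy sits close to that
ceiling, and most residual confusion is Rs1↔Rs2 — the same pair whose
separation the original sorting found hardest.

## Reconstruction and resolution

Direct Fourier inversion: each image's DFT is inserted as a central slice
(trilinear gridding, per-voxel weight normalisation, shifts removed by
phase correction), unmeasured voxels (the polar missing cone of
side-view-only geometry) are left at zero, and the map is C7-symmetrised
by real-space averaging of the seven rotated copies. Split-half FSC uses
an even/odd split, soft spherical masks (radius 0.45 box, 5-voxel cosine
edge), one-voxel shells, and linear interpolation of the 0.5 crossing.
The final filter multiplies amplitudes below 1/20 Å⁻¹ by 0.1 and rolls
off beyond 1/8.5 Å⁻¹.

Numerical honesty: with trilinear kernels the discrete rotation operator
has a few-percent resampling error, so "symmetrisation is exactly
idempotent" holds only to ~3–6% band-limited RMS, and reconstruction-based
references score ~1.5% CC below noise-free model references. The tests
assert these operations at their interpolation floors, not at zero.

## Fitting and quantification

`rigidDock()` is a coarse z-rotation/tilt grid plus Nelder–Mead over all
six degrees of freedom. `hingeRefine()` replaces stochastic
flexible-fitting machinery with a deterministic coordinate-wise optimiser:
for each hinge parameter in tree order (equatorial → block → apical), a
coarse scan brackets the optimum and golden-section search polishes it;
only improvements are accepted, so the cross-correlation history is
monotone by construction. The model is rendered with the *same* Gaussian
kernel as the phantom density (1/e Fourier amplitude at 1/resolution,
discretely mass-normalised), so there is no model/map kernel mismatch.
The per-state rigid-group schedules (two-body then all-hinge for Rs1,
etc.) are named presets; helix-level subgroups exist as named groups and
anchor the lateral-sheet restoration in `rebuildRingC7()`, but are not
independent refinement degrees of freedom.

`measureDomainMotion()` is least-squares superposition (Kabsch) reported
as axis/angle/translation — exact for rigidly moved domains, and tested
against an independent quaternion-method oracle. Contact tables pair
subunit *i*'s residue with the counterclockwise neighbour's (viewed from
outside the top ring), average over the seven copies, and apply the 8 Å
in-contact rule everywhere; state assignment is a nearest-Hamming match
against the signature table, returning tied sets (Rs1/Rs2; Rd1/Rd3; the
open family) rather than guessing.

## Problem sizes

The package's default geometry is 64³ voxels at 4 Å (256 Å box) rendered
at 8 Å, with the flagship benchmark at 3 × 500 particles and SNR 0.1
(seed 17) — minutes on one CPU. The unit-test geometry is mostly 48³ at
5 Å; the SNR-monotonicity benchmark runs 3 × 84 particles per replicate.
The acquisition-scale geometry (192² at 2.02 Å/px) is available through
`pipelineConfig(boxVox =, voxelA =)` but is not exercised by the tests.

## Known limitations

* Orientation search is gridded (2° azimuth/tilt in the fine stage);
  there is no local continuous orientation refinement in 3D.
* Phase flipping only; amplitude falloff from |CTF| is matched in the
  scoring templates but never restored in the reconstructions.
* The asymmetric-reconstruction check (`validateAsymmetric()`) tests
  wedge variance against a symmetrised bootstrap null; it flags planted
  2-of-7 apical asymmetry at the tested scales but its power at other
  scales is uncharacterised.
* The D83–K327 numbers are computed from the calibrated phantom, which
  was constructed to honour the published distances; they demonstrate the
  measurement machinery, not an independent re-derivation from deposited
  coordinates.
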