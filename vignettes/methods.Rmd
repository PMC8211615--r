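---
title: "Methods: multimodal fusion and 3-D visualization of neurovascular compression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal fusion and 3-D visualization of neurovascular compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameters and
numerical choices.  It states no empirical result that the test suite and
the worked examples do not themselves compute.

## 1. The processing model

The package re-implements a clinical image-processing chain for judging
neurovascular compression (NVC) at the ventrolateral medulla: a vessel is
considered in contact with the nerve root entry zone (REZ) when no CSF
layer separates them.  The chain has five stages.

**Preprocessing.** Perona–Malik anisotropic diffusion with exponential
conductance $g(s) = e^{-(s/\kappa)^2}$ in flux-conservative form with
Neumann boundaries, followed by grey-value closing with a discrete ball.
Diffusion denoises within tissue classes while keeping the CSF/tissue
edges; closing fills the hypointense specks and thin vessel
cross-sections inside the hyperintense CSF so the cistern can be grown as
one connected body.  Defaults: 5 iterations, $\kappa$ = 1.5 × median
forward-gradient magnitude ("auto"), $dt = 1/7$ (the stability bound for
a 3-D explicit scheme is $1/6$), ball radius 1 voxel.  The sum of
intensities is conserved exactly and the output range never exceeds the
input range; both are tested against a dense loop-based re-implementation.

**Explicit segmentation.** Seeded volume growing: the maximal connected
component containing the seeds with intensity in `[lower, upper]`,
clipped to an optional bounding box; 26-connectivity for CSF (thin
cisternal sheets), 6 for the brainstem.  The CSF window defaults to the
mode of the bright histogram peak ± 2 standard deviations of the bright
class, i.e. "close to the signal intensity of CSF".  The brainstem is
grown with the CSF mask as an impenetrable barrier.  Nerves are imported
as hand annotations (phantom ground truth in tests); automatic nerve
segmentation is out of scope.  The label volume is assembled under a
fixed priority — nerve over CSF(+vessels) over brainstem over rest — so
the result is a partition no matter how the masks overlap.

**Registration.** Landmark pairs give a closed-form rigid initialization
(Kabsch/Umeyama SVD with the reflection branch excluded).  Refinement
maximizes mutual information $MI = H(F)+H(M)-H(F,M)$ (bits, 64 bins)
between the fixed volume and the trilinearly resampled moving volume,
coarse-to-fine over a Gaussian pyramid (3 levels, ×2 stride per level,
smoothing $\sigma = \text{stride}/2$ voxels), with a seeded 25% voxel
sample at the finer levels.  Rotation is parameterized axis-angle about
the fixed-volume center.

Numerical choices that matter here:

* *Optimizer.* A derivative-free simplex (`stats::optim` Nelder–Mead)
  rather than Powell line searches: equivalent class of method, available
  in-stack, robust on 6 parameters.  The simplex scale is set per level
  (wide exploration at the coarse level, sub-voxel steps at the finest).
* *Histogram smoothing.* The contract definition of MI uses a hard joint
  histogram (so `MI(v, v, identity)` equals the binned marginal entropy
  exactly).  A hard histogram is piecewise constant in the transform
  parameters, and a simplex stalls on its plateaus about 1–3° from the
  optimum; the *objective* therefore shares each moving sample linearly
  between its two neighbouring bins (partial-volume binning).  The
  monotone-acceptance guarantee — the returned transform never has lower
  contract-MI than the initializer — is checked with the hard definition.
* *Estimator asymmetry.* MI computed by resampling the moving image is
  exactly symmetric under role swap only when samples land on grid points
  (identity, whole-voxel shifts); under off-grid transforms trilinear
  blur makes the estimate direction-dependent.  The symmetry test covers
  the grid-aligned cases.

**Fusion.** Hyperintense vessels are extracted from the reformatted TOF
volume by volume growing above an Otsu split, seeded at every
supra-threshold voxel.  Their values are mapped by the strictly
decreasing linear inversion onto the CISS dark-vessel range
`[150, 250]` (the display window) and replace — not blend with — the CISS
values at exactly those voxels, which are additionally stamped with a
dedicated VESSEL label.  Replacement follows the source method's wording
("transferred"); the inversion is interpreted as a range remap because
fused vessels must land inside the CISS hypointense display window for a
single transfer function to render them — plain negation would leave
them out of range.  Source range: 1st–99th percentile of the in-mask TOF
intensities (robust to the few partial-volume voxels).

**Rendering and scoring.** Orthographic front-to-back ray casting;
nearest-neighbour label lookup (no label mixing), trilinear intensity,
per-label piecewise-linear opacity with step-length correction
$\alpha' = 1-(1-\alpha)^{\Delta s/s_0}$, early termination at
$A \ge 0.99$.  Default colors follow atlas convention: red vessels,
yellow nerves, light grey brainstem, transparent rest; within the CSF
label, opacity is 0.9 up to intensity 260 and fades to 0 by 450, so dark
(vessel-range) content renders red and CSF itself is invisible.  The
ordinal 0–5 quality scale is operationalized through centerline
display-window coverage $c$: $c=0 \to 0$; $c \ge 0.95 \to 5$; proximal
half $\ge 0.8$ with distal half $< 0.5 \to 3$; otherwise
$c \ge 0.5 \to 4$, $c \ge 0.25 \to 2$, else 1.  These thresholds are this
package's computable reading of the published ordinal prose; clinical
use passes expert scores through unchanged.  Contact detection marks
vessel voxels 26-adjacent to REZ voxels — direct adjacency leaves no
room for an intervening CSF voxel.

**Statistics.** Paired $t$ (differences before − after, $df = n-1$,
symmetric 95% CI), also computable from printed summary means/SDs so the
published 44-patient per-vessel table can be reproduced without raw
data; Pearson χ² on 2×2 tables (Yates correction off by default); classic
Levene on absolute deviations from group means.  Ordinal scores are
treated as interval quantities, exactly as the source analysis did.  The
published χ² of 8.498 for the PICA comparison is documented but not
reproduced: the printed counts do not determine the underlying 2×2 table.

## 2. The phantom: what it emulates and what it does not

No accessions are deposited, so every downstream stage is exercised on a
synthetic posterior fossa with analytic ground truth: a vertical
brainstem column (radius 0.18 × grid extent) in a box-shaped CSF cistern,
a large arterial trunk hugging the anterior brainstem surface within
0.3 mm (the near-brainstem contour-fusion situation), a smaller arterial
loop crossing a radial nerve root at a controlled clearance, on a 96³
grid at 0.4 mm isotropic spacing — a desk-scale stand-in for the
512×512×144 clinical slabs; all geometry scales with the grid.

Stated world (defaults, chosen once):

* CISS class means 1000 (CSF), 400 (brainstem), 250 (nerve), 200
  (vessel), 50 (background); TOF 1000 (vessel) vs ≤ 120 elsewhere; noise
  Gaussian σ = 20 per modality (Rician optional — magnitude MRI noise —
  but Gaussian suffices to exercise diffusion and closing).  Class
  separations are many σ, as in the high-contrast source sequences.
* Flow void: along a configurable arc of a vessel the CISS paint value is
  pulled toward the brainstem mean by a factor (1 ⇒ indistinguishable);
  default: the middle 30% of the trunk.  TOF is unaffected — flowing
  blood is what TOF renders bright.
* Pulsation: vessel-range speckle replacing 2% of CSF voxels in a box
  around the upper trunk (the "cloud of dots" appearance), amplitude 30.
* The TOF frame is displaced by a true rigid transform (default ≈ 4°,
  1.6 mm) and the anatomy is evaluated analytically in the displaced
  frame, so registration has exact ground truth.
* Partial-volume edges: intensities blend over a 1-voxel (0.4 mm) linear
  ramp at every boundary, emulating the scanner point-spread function.
  This is load-bearing: with hard voxel-center rasterization both
  modalities are aliased staircases and the MI optimum genuinely sits
  ~0.5° off the true transform even without noise, which would make
  sub-voxel recovery impossible for any estimator.  Truth *masks* remain
  hard (voxel-center membership); interiors more than half a ramp from a
  boundary keep the exact class mean.

What a green test does **not** establish: realism of vascular anatomy
beyond the topology needed for NVC testing (one trunk, one loop, one
root), MR physics (no k-space, no sequence simulation, no bias fields),
scanner-specific artifact magnitudes (the source describes the artifact
classes qualitatively; magnitudes were chosen so CISS-only
visualization visibly degrades and fusion visibly repairs it), or
rater behaviour (the clinical scores were assigned by experts to rendered
images; the automatic score is a volume-space surrogate).

## 3. Design choices where the design was open

* **File formats.** NIfTI-1 (sform written, qform honoured) with a JSON
  sidecar for label legends; PNG for renders.  Both codecs are
  implemented in-package because the target R stack ships neither, and
  DICOM/PACS plumbing is deliberately out of scope.
* **Coordinates.** 0-based voxel indices with voxel-center sampling in
  the affine (NIfTI convention); R-facing APIs take 1-based indices.
  The on-disk orientation of the clinical slabs is unstated in the
  source; any consistent orientation is acceptable and the phantom uses
  an axis-aligned RAS-style affine.
* **Brainstem growing input.** The preprocessed volume (the source is
  silent on raw vs preprocessed).
* **Processing order.** Diffusion strictly before closing, as listed.
* **Registration acceptance protocol.** The recovery study initializes
  from 4 landmarks with 0.5 mm simulated click jitter before MI
  refinement, mirroring the clinical procedure which always starts from
  hand-picked landmarks; random offsets up to 10°/5 mm are outside the
  MI basin of attraction from an identity start at desk scale.
* **Flow-void arcs in the fusion acceptance study** are drawn from
  42–55% of the trunk centerline: the crossing loop genuinely restores
  about 6% of the trunk path at the junction, so exactly-30% arcs would
  put the before-fusion coverage on the 0.7 boundary the criterion
  separates.
* **Loop types I–III** are accepted as manual annotations only; no
  geometric definition is computable from the published description.

## 4. Degenerate inputs and tie-breaks

Empty seed lists, seeds outside the intensity window (named in the
error), collinear landmark sets, reflection-only correspondences (forced
back to a proper rotation), empty field-of-view overlap, constant TOF
vessel intensities (degenerate inversion range), zero-variance paired
differences, and zero-margin contingency tables all fail fast with
specific messages.  Label-priority overlaps need no tie-break — the
hierarchy is a total order.  The optimizer returns the initializer (with
`converged = FALSE` and a warning) whenever refinement does not improve
the contract MI.

## 5. Known limitations

Registration assumes rigidity and roughly matching fields of view; the
MI estimator uses a fixed 64-bin layout over each volume's global range,
which is appropriate for the phantom's contrast but may need adjustment
for clinical dynamic ranges.  The automatic score requires a truth
centerline and is therefore a phantom/validation instrument, not a
clinical rater.  Rendering is unshaded classification (no gradient
lighting, no perspective), matching the source figures' style.  The
pipeline's nerve mask and brainstem seed come from phantom ground truth,
standing in for the manual interaction the clinical workflow requires.
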