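---
title: "Orthogonal-view 2-D/3-D rigid registration: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal-view 2-D/3-D rigid registration: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(orthoreg)
```

## The problem

Intra-operative pose estimation aligns a pre-operative head CT with
intra-operative biplanar radiographs (anterior-posterior and lateral
fluoroscopy) so that targets annotated in the CT — here the two foramen
ovale, the skull-base openings punctured in radiofrequency ablation for
trigeminal neuralgia — can be located under imaging. Direct 2-D/3-D
registration optimizes a similarity between measured radiographs and
digitally reconstructed radiographs (DRRs) of the CT; the objective is
highly non-convex and each evaluation requires a rendering pass.

`orthoreg` implements the alternative two-stage strategy: a *reconstruction
stage* produces a 3-D target volume from the two radiographs (in the
original method a trained encoder–decoder network; here a pluggable
interface plus a simulator), and a *registration stage* solves an ordinary
3-D/3-D rigid registration between the pre-operative CT and that target.
The similarity is then same-dimensional, smooth enough for gradient
descent, and needs no rendering in the loop.

## Imaging model

The X-ray system is a calibrated pinhole camera. A detector pixel $x$
collects the line integral of the CT $J$ posed at the rigid transform $T$
along the ray $L(x)$ from the source:

$$I(x; T) = \int_{p \in L(x)} J(T^{-1} p)\, \mathrm{d}p .$$

The second view shares the pose and composes a fixed inter-view transform
$V$ (rotation about the cranio-caudal axis; 90° in the orthogonal setup):
the lateral ray points are pulled back through $(V \circ T)^{-1}$. The
renderer marches each source-to-pixel segment in uniform steps (default
half the smallest voxel spacing), accumulating trilinearly interpolated
samples times the step length, with the first/last partial steps weighted
by their true length after clipping the ray to the volume. The integral is
a raw intensity·mm line integral — no Beer–Lambert exponentiation — and an
optional display transform is cosmetic only.

The pose is parameterized by three rotation angles about the fixed x, y, z
axes and a translation, composed extrinsically,
$R = R_z(\gamma) R_y(\beta) R_x(\alpha)$, rotating about a stated center
(by default the moving volume's world center, which keeps rotation and
translation weakly coupled). The rotation order is a declared convention —
it is recorded in every manifest and pose file — and angle recovery at
gimbal lock ($|\beta| = 90°$) deterministically takes the $\gamma = 0$
branch. Angles are radians internally and degrees at every user-facing
boundary; lengths are mm throughout.

## Registration stage

The metric is the mean squared error over the fixed grid,

$$\mathrm{MSE}(T) = \frac{1}{N} \sum_{i} \left[ J_{\mathrm{mov}}(T^{-1} x_i) - J_{\mathrm{fix}}(x_i) \right]^2 ,$$

with $N$ counting, by default, only voxels whose pull-back sample landed
inside the moving volume. This *overlap* policy avoids rewarding transforms
that push the volume out of frame; full-grid counting is available
(`mask = "full"`). Out-of-bounds samples fill with 0, the background value
after bone thresholding. The analytic gradient applies the chain rule
through the pull-back, with the moving image's intensity gradient estimated
by central differences on the grid and sampled trilinearly; rotation
components are made commensurate with translations through an equivalence
radius (default a quarter of the moving volume's mean physical extent).

The optimizer is normalized-direction gradient descent with backtracking:
a step is accepted only if the MSE decreases, so the accepted-iterate MSE
sequence is non-increasing by construction within each resolution level.
Convergence is declared when the pose update falls below 0.01° / 0.01 mm,
the relative MSE change falls below $10^{-7}$, or no decreasing step
exists. The registration contains no randomness: identical inputs give
identical trajectories.

Three robustness mechanisms matter in practice, all on by default and all
disableable:

* **Scale-space pyramid** (`pyramid = c(4, 2, 1)`): volumes are blurred
  (Gaussian, $\sigma = \text{factor}/2$ voxels) before block-mean
  decimation. Plain decimation of a thin skull shell aliases; the blur
  widens the attraction basins that make coarse-to-fine work.
* **Fine-level smoothing** (`fine_sigma = 0.5` voxel): thresholded bone is
  near-binary, and the trilinear-interpolation MSE of binary volumes is
  riddled with sub-voxel kinks that stall any line search even when the
  descent direction is correct. A light common blur of both volumes at the
  finest level smooths the metric without moving its optimum (both inputs
  receive the identical kernel).
* **Initialization search** (`init_search = TRUE`): at the coarsest level a
  translation-only descent is followed by an exhaustive grid over rotation
  offsets (±8°, ±4°, 0 per axis). A thin shell displaced by roughly its own
  thickness re-overlaps itself, creating periodic local minima in rotation
  at a period of about thickness/radius (~6° for a 5 mm shell of ~45 mm
  radius); the grid straddles them deterministically.

## Preprocessing

Clinical head CTs include the scanner bed and soft tissue that does not
move rigidly with the skull. The preprocessing tool mirrors standard
practice: per axial slice, threshold at −200 HU (low enough to keep the
whole head, high enough to drop air), take the largest connected component
and fit an ellipse from its second-order moments (exact for a filled
ellipse in the continuum limit); take the largest fitted ellipse over
slices, expand both semi-axes by 20%, crop to the extruded elliptical
cylinder, and finally remove soft tissue below 100 HU. The boundary is
inclusive — a voxel at exactly 100 HU is kept — and the post-threshold
background is 0 so that it coincides with the resampler's fill value.

## The synthetic benchmark

No external data is required. `make_phantom()` builds a head surrogate: an
ellipsoidal high-HU shell (~1200 HU, 5 mm thick) around ~40 HU soft tissue
in −1000 HU air, with two 2.5 mm-radius low-HU canals carved through the
skull base whose centroids serve as the foramen-ovale landmarks, plus ten
more landmarks sampled on the shell — twelve total, matching the evaluation
convention. The outer semi-axes are 0.34 / 0.44 / 0.38 of the mean grid
extent with ±3% seeded jitter: *distinctly unequal*, as in a real cranium.
That asymmetry is not cosmetic — a shell with two nearly equal semi-axes is
almost rotation-invariant about the third axis, which makes that rotation
unidentifiable for any intensity metric and turns the benchmark into a test
of luck rather than registration. Additive Gaussian HU noise (σ = 10)
keeps thresholding honest. Default grids are 64³ at 2 mm spacing: small
enough that the full experiment suites run in minutes on one CPU, large
enough that the shell is several voxels thick.

Ground-truth poses are sampled uniformly from ±10° per angle and ±20 mm per
translation — the benchmark's augmentation range — and `extreme_pose()`
reproduces the corner cases (all magnitudes at 10° / 20 mm). Manifests
carry every seed, the Euler convention, and a seeded exact 75/25 split.

`pseudo_reconstruct()` stands in for the learned reconstruction: the
ground-truth anatomy is rigidly resampled to the unknown pose, then
degraded by Gaussian blur, a global gain factor, and additive noise scaled
to the clean copy's dynamic range. With all degradations off it is exactly
the clean transformed copy, which separates optimizer failures from
landscape bias in experiments. Real reconstruction networks produce
structured, anatomy-dependent errors (hallucinated bone, depth ambiguity);
this simulator produces none of those, so passing benchmarks here certifies
the geometry, metric and optimizer — not reconstruction quality on real
radiographs.

The view-angle variants model the information loss of non-orthogonal
acquisition: reconstruction from two views degrades as the views approach
each other, so the simulator scales blur and noise by $1/\sin(\text{angle})$
(1.0 at 90°, ≈1.15 at 60°, 2.0 at 30°) — the simplest monotone factor with
the right limits. The contrast ("X-ray energy") variants apply a monotone
gamma remapping after min-max normalization: 0.5 (low contrast), 1.0
(identity), 2.0 (high contrast). Note that with these gammas the *high*
level yields the larger Michelson contrast between bright levels — gamma
below one compresses the upper intensity range.

## Evaluation

Accuracy is the mean target registration error over the landmark set,
$\mathrm{mTRE} = \frac{1}{N}\sum_i \lVert T_{\mathrm{reg}} p_i - T_{\mathrm{gt}} p_i \rVert_2$,
and robustness is the gross failure rate: the percentage of cases with
mTRE strictly above 3 mm, the clinical criterion for this intervention.
Exactly 3.0 mm counts as success; the choice is stated because it changes
the GFR at the boundary. Aggregates use the population (divisor $N$)
standard deviation — the convention under which the shipped ten-case
reference table reproduces its published mean ± SD of 1.65 ± 1.41 mm —
with sample SD available. Per-axis errors are reported in pose space under
the declared Euler convention, not as matrix geodesics, matching the way
benchmark tables decompose errors. The reference table's
optimization-refined tracking method (`point2_opt`) has a published
aggregate GFR that is inconsistent with its own per-case values (7/10
exceed 3 mm); the package therefore asserts only the three internally
consistent methods as metric ground truth and ships the fourth column
for completeness.

## Numerical and interface choices

* Volumes are axis-aligned with positive diagonal spacing; readers reject
  oblique direction matrices loudly rather than misregister silently.
  Voxel centers address the grid (`world = origin + index · spacing`,
  0-based).
* Trilinear interpolation everywhere; outside the voxel-center hull the
  fill value applies and the sample is flagged, feeding the overlap mask.
* Metric, gradient and resampling are pure per-voxel maps plus a sum
  reduction — results are independent of evaluation order and chunking,
  which is the testable contract corresponding to the original method's
  GPU parallelization.
* Default projection geometry (the source papers of such systems rarely
  print one): source–isocenter 1000 mm, source–detector 1500 mm, 256²
  detector at 1 mm pixels, step = half the minimum voxel spacing; all
  recorded in output sidecars.
* Run configuration is YAML (`run_config()` /
  `read_run_config()`); every default is inspectable via the CLI's
  `--dump-config`.
* DRR export writes an 8-bit PNG preview plus a lossless MetaImage raw
  grid and a JSON sidecar with the scaling and geometry, so exact values
  are always recoverable.
* Experiment sizes used by the test suite — 64³ phantoms, 20 seeded runs
  per recovery experiment, 24 seeds per view angle for the trend check —
  are the package's chosen trade-off between statistical resolution and
  desk-scale runtimes.

## Known limitations

* The phantom certifies geometry and optimization, not anatomical realism;
  no scatter, beam hardening, polyenergetic spectra or detector noise are
  modeled, and the renderer is CPU-only.
* Only rigid motion is estimated; deformable anatomy violates the model.
* Oblique CT acquisitions must be resampled to axis-aligned grids upstream.
* Runtime claims of the original GPU pipeline are out of scope; nothing
  here asserts wall-clock performance.
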