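---
title: "Shape biomarkers for three-class differential diagnosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape biomarkers for three-class differential diagnosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Alzheimer's disease (AD) and behavioural-variant frontotemporal dementia
(FTD) overlap clinically and morphometrically; a binary AD-vs-control
classifier is of limited use when the differential includes a second
dementia, because a classifier trained on two classes must assign every
test case to one of them. `shapetriad` implements a *three-class* protocol:
all biomarkers are trained and evaluated simultaneously against AD, FTD and
normal controls (NC), and all are pushed through one fixed pipeline so
their diagnostic value can be compared on a common test set.

The package computes three families of shape biomarkers per subcortical
structure (the intended targets are the hippocampus and lateral ventricle,
left and right):

1. **Normalised volume** — gross atrophy. The structure volume is the
   foreground voxel count of its binary segmentation times the physical
   voxel volume. Head size is removed by the residual method,
   $V_{norm} = V_{abs} - k\,(ICV - \overline{ICV})$, where $k$ is the OLS
   slope of structure volume on intracranial volume (ICV) and
   $\overline{ICV}$ the mean ICV, both estimated in the control group.
2. **Laplacian spectral invariants** — intrinsic global shape. The
   Dirichlet eigenvalues $0 < \lambda_1 < \lambda_2 \le \dots$ of the
   segmentation domain are pose-invariant, and eigenvalue *ratios* are also
   scale-invariant. Three descriptor families are supported:
   $F1 = (\lambda_1/\lambda_i)_{i=2..n}$,
   $F2 = (\lambda_{i-1}/\lambda_i)_{i=2..n}$ (the default, with $n = 100$),
   and $F3 = (\lambda_1/\lambda_i - d_1/d_i)_{i=2..n}$ with $d_i$ the
   unit-ball reference spectrum, so that $F3 \equiv 0$ for a ball and
   measures deviation from sphericity.
3. **Patch-averaged surface displacements** — extrinsic local shape. Given
   a template surface and a target surface in vertex correspondence
   (produced externally by diffeomorphic template injection, or exactly by
   the synthetic generator), the per-vertex Euclidean displacement after
   rigid (Kabsch) pre-alignment is averaged within surface patches obtained
   by k-means clustering of template vertex coordinates ($N = 300$ patches
   by default), yielding local, anatomically indexed features.

## Classification and evaluation protocol

Every biomarker runs through the same protocol. The cohort is split per
class, 75% training / 25% test (floor per class; the 30/34/14 study sizes
give 57 training and 21 test subjects). On the training rows only, features
are ranked by information gain (equal-frequency binning, 10 bins, reduced
when bins would hold fewer than 2 samples) and the top 5 retained — the
rule-of-thumb bound $N_{min} \ge d / (2\,p(e))$ says 5 features at 5% error
need only 50 subjects. An RBF-kernel SVM is then tuned by grid search over
$\log_{10} C = -3..8$, $\log_{10}\gamma = -3..3$ (84 points, unit steps)
using stratified 5-fold cross-validated accuracy *within the training set*,
ties broken toward smaller $C$ then smaller $\gamma$; the winner is refit
on all training rows and scored on the untouched test set. Multi-class
membership scores come from coupling the pairwise SVM decisions (logistic
link on the decision values, then the Wu–Lin iterative coupling, which for
two classes reduces to a complementary pair). We deliberately do not use
libsvm's internal Platt-scaling probabilities: their internal cross-
validation is not seedable from R, and the coupling step is part of the
protocol we want to own and test. Scores are ranks for ROC purposes, so
the missing Platt calibration does not affect AUC; the argmax decision
is equivalent to the coupled-score maximum.

Evaluation: per class, a one-vs-rest ROC summarised by the Mann–Whitney
AUC (ties get half credit), combined as the weighted mean with weights
$w_i = n_i / \sum_j n_j$ proportional to test-set class sizes. The 3×3
confusion matrix is reported with its six off-diagonal row-normalised
rates, drawn as a cobweb (radar) plot — one axis per misclassification
direction "A → B". Two-class runs additionally report sensitivity and
specificity at the classifier's argmax operating point (no ROC-optimised
threshold: the reported numbers are those of the classifier actually
deployed). Robustness is assessed by repeating the hold-out 10 times with
fresh splits (mean ± SD of the weighted AUC), LOOCV re-runs selection and
grid search inside every fold, and a partition sweep
($N = 5, 10, 20, 50, 100, 200, 300$) re-evaluates the displacement
features at each patch resolution.

## Numerical choices

**Dirichlet spectra.** The Laplacian is discretised as the 7-point finite
difference stencil restricted to foreground voxels, with out-of-domain
neighbours held at zero (Dirichlet) and anisotropic spacing entering as
$1/dx^2, 1/dy^2, 1/dz^2$ weights. This differs from spectral constructions
based on a commuting integral operator; absolute eigenvalues depend on the
discretisation, but the descriptors use ratios, which agree across methods
at adequate resolution (the test suite checks the cube ratio
$\lambda_1/\lambda_2 \to 1/2$ and ball sphericity $F3 \to 0$ at $64^3$).
Masks are reduced to their largest 6-connected component first — stray
voxels otherwise contribute spurious near-zero eigenvalue blocks — with a
warning if more than 1% of voxels are dropped, and a 200-voxel minimum
domain size by default. The eigensolver picks its algorithm by size:
dense `eigen` up to 600 voxels; shift-invert Lanczos (ARPACK, $\sigma=0$)
on a CHOLMOD Cholesky factor up to 30,000 voxels; beyond that, Chebyshev-
filtered subspace iteration with Rayleigh–Ritz extraction, which needs
only matrix–vector products (3D stencil Cholesky fill-in becomes the
bottleneck long before memory does). The filter window is re-estimated
each outer iteration from the Ritz values, the spectrum's upper bound from
Gershgorin's theorem, and the start block comes from a private fixed-seed
RNG stream, so spectra are reproducible bit-for-bit per platform. Every
returned pair is checked against the residual contract
$\|Av - \lambda v\|/\|v\| \le 10^{-8}$; non-convergence is an error with
diagnostics, never a silent degradation. The unit-ball reference $d_i$ for
F3 is analytic: squared zeros of the spherical Bessel functions
(located by sign-change scan plus root refinement on $J_{l+1/2}$) with
multiplicity $2l+1$ — not a digitized sphere.

**Rigid alignment** is Procrustes/Kabsch on corresponding vertices without
scaling (size change is signal, pose is nuisance), with the reflection
branch forced to a proper rotation ($\det R = +1$). Alignment on vertices
rather than on segmentation volumes is an equivalent contract here because
correspondence is given; it avoids a registration dependency and is
toggleable.

**Surface parcellation** uses k-means++ seeding, Lloyd iterations
(max 100), 10 restarts keeping the best within-patch variance, fixed
default seed 42; empty patches are re-seeded from the farthest vertices so
every patch is nonempty. The displacement *magnitude* feeds the classifier
(it is the scalar the feature definition prescribes); a signed variant
(projection on the template outward normal) is also computed, because
expansion vs contraction is directional, and it is the default input of
the patch-wise group maps. Group maps use per-patch Welch t tests with
Benjamini–Hochberg FDR at q = 0.05 across patches — a deliberate,
desk-scale replacement for vertex-wise random-field-theory cluster
correction: same question, patch resolution, no external dependency.

**Information gain** has no canonical discretisation; we use
equal-frequency binning (10 bins, reduced to keep ≥ 2 samples per bin).
Tie-breaks everywhere are deterministic (original feature order; smaller
C then smaller gamma), and every loop that draws randomness takes an
explicit seed, so identical seed + data means identical selected features,
hyper-parameters and predictions.

## The synthetic cohort: what it emulates, and what not

No imaging data ship with the package; the generator produces a cohort
with the statistical structure the real study design presumes, so the
whole pipeline is testable end-to-end. One ellipsoidal template mesh
(semi-axes 18 × 11 × 9 mm, ventricle scale; icosphere subdivision 3,
642 vertices) generates every subject, so vertex correspondence is exact
by construction and external diffeomorphic registration is bypassed. Per
subject: (a) a global linear size factor — group means 1.00 (NC) and 1.03
(AD, FTD), SD 0.06, partially coupled to a simulated ICV
(mean 1.5 × 10^6 mm³, SD 1.5 × 10^5, 2% size per ICV SD) — makes volume
distributions overlap heavily across groups, so gross size cannot separate
the dementias; (b) a focal outward bump (amplitude 2 mm, Gaussian angular
falloff, width 0.35 rad ≈ 20°, anatomically focal) at the *posterior* pole
of the long axis for AD-like subjects and the *anterior* pole for FTD-like
subjects, absent in controls — the two dementias differ only in *where*
they deform the surface, and the ellipsoid's mirror symmetry makes the two
bumped shapes nearly isometric, so the pose/scale-invariant spectral
features cannot tell AD-like from FTD-like by construction while the
spatially indexed displacement features can; (c) i.i.d. vertex jitter
(SD 0.05 mm). Masks are produced by the analytic inside test (the deformed
shape is star-shaped, so a voxel centre is inside iff its radius is below
the radial function), on a 1 mm isotropic grid by default. Group sizes
default to NC = 14, AD = 34, FTD = 30 (78 subjects).

What the generator does **not** emulate: real ventricular/hippocampal
anatomy (branched horns, concavities), segmentation error, registration
(correspondence) error, MRI intensities, and site or age covariates.
Passing pipeline tests on this cohort therefore demonstrates that the
machinery recovers planted effects under the study's sampling design —
not that the biomarkers reach any particular performance on clinical data.
Cohort-level empirical checks in the test suite use a reduced problem
size (1.5 mm grid, 25 eigenvalues, 60 patches, one structure) so the full
suite stays in the minutes range; the defaults of the user-facing
functions remain at study scale (1 mm, $n$ = 100, $N$ = 300).

## Known limitations and open choices

* The displacement sign convention depends on template normals; meshes
  with inverted winding would flip signs (magnitudes are unaffected).
* The inner model-selection metric (stratified 5-fold accuracy) and the
  information-gain binning scheme are explicit package choices; the
  protocol's origin leaves both open. Both are configurable.
* The ICV slope $k$ is fitted on controls per structure (configurable to
  pooled fitting); fitting on patients would absorb disease effect into
  the head-size correction.
* Finite-difference spectra at coarse resolution (domains near the
  200-voxel minimum) carry discretisation bias; ratio features cancel most
  but not all of it. Use ≥ 48³ effective resolution when absolute accuracy
  of the first ratios matters.
* LOOCV with the full 84-point grid is expensive ($N$ × 84 × 5 SVM fits);
  the pairwise helpers accept a reduced grid for exploratory runs.
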