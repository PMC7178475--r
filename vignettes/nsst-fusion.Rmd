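---
title: "Shearlet-domain fusion of multimodal brain images: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shearlet-domain fusion of multimodal brain images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsstfuse)
```

## The problem

CT and MRI slices of the same brain carry complementary information: CT
renders bone and dense structure at high contrast but little soft-tissue
detail; MRI renders soft-tissue anatomy but a dim skull. Given a
pre-registered pair, fusion produces one image retaining both. This
package implements a transform-domain pipeline: decompose both images
with a shift-invariant multiscale, multidirectional transform, merge the
coefficients band by band under rules tuned to what each band carries,
and invert.

## The transform

The non-subsampled shearlet transform combines an undecimated (à-trous)
pyramid with directional filtering, all in the frequency domain.

**Pyramid.** Stage $j$ splits the running approximation with a separable
B3-spline low-pass whose 1-D response is $\cos^4(2^{j-1}\omega/2)$ (the
binomial kernel $[1,4,6,4,1]/16$ dilated by $2^{j-1}$) and the
complementary high-pass $1 - H_0$. Because analysis responses sum to one
at every split, synthesis is the plain sum of all bands: reconstruction
is exact to machine precision, and because every operation is a circular
convolution the transform commutes with integer shifts. The DC gains (1
for the low-pass, 0 for every high-pass) mean detail bands are zero-mean.

**Two approximation components.** The fusion rules treat the
low-frequency content as two components. After the $K$ pyramid stages,
one further pyramid stage splits the coarsest approximation: its low
output is `low1` (fused by activity maximum selection), its high output
is `low2` (fused by the spatial-frequency blend). This is one
self-consistent reading of a "first/second component" split of the
low-frequency coefficients — it keeps the whole system perfectly
invertible, since the inverse simply adds the two components back. Other
readings (e.g. splitting between pyramid levels $K$ and $K-1$) would be
defensible; this one was chosen because it leaves the number of detail
levels and their direction counts untouched.

**Directional windows.** Each level's high-pass is split into $d$
directional bands by multiplying its spectrum with $d$ raised-cosine
($\cos^2$, Meyer-style) windows equally spaced in the pseudo-polar angle
coordinate: the slope $\omega_2/\omega_1$ on the horizontal frequency
cone and $2 - \omega_1/\omega_2$ on the vertical one. Equal steps in this
coordinate are exactly the integer shears of the shearlet system's shear
matrix, and adjacent $\cos^2$ bumps overlap as $\cos^2 + \sin^2$, so the
windows tile the frequency plane with deviation at the level of machine
epsilon — the property the round-trip tests assert at `1e-10`. Windows
are symmetric under $\omega \mapsto -\omega$, so all bands are real.

**Defaults.** $K = 4$ levels with $[8, 8, 16, 16]$ directions coarse to
fine — common practice for 256×256 fusion work, and configurable. Images
of any even size ≥ 8 per axis are supported; boundaries are periodic
(FFT-implied), which is what makes reconstruction exact. Symmetric
padding is deliberately not offered inside the transform: it would break
exact invertibility, and the spatial-domain activity measures already use
mirror extension where it matters.

## The weight network

A dual-branch network with shared parameters maps a patch pair to the
probability that the first patch is the sharper one. Architecture: three
3×3 valid convolutions with 16, 32, 64 channels and rectifier
nonlinearity, a 2×2 max-pool after the second, feature concatenation of
the two branches, one fully-connected layer to 2 logits, softmax. For
16×16 patches that is 1024 features per branch. The second
fully-connected layer common in patch-comparison networks is omitted;
the feature extractor feeds the class head directly.

Layer widths, patch size 16, stride 2, the rectifier and the Adam
optimiser (step $10^{-3}$, minibatch 64 pairs) are concretisations — the
layer *counts* are part of the method, the sizes are not prescribed —
chosen as the smallest configuration that reliably solves the
sharp/blurred task on one CPU. Patches are scaled to $[0,1]$ before the
network; determinism is guaranteed by seeding initialisation, sampling
and batch order (the whole stack is plain matrix algebra, single
pass-order).

**Training corpus.** Patches from generated phantoms paired with crops of
the same phantom blurred by a Gaussian with $\sigma \sim U(1, 3)$ —
sharpness discrimination needs no anatomical realism, only texture whose
high-frequency content the blur removes. Pairs alternate orientation so
labels are exactly balanced; near-constant patches (sd ≤ 1 gray level)
are skipped since they carry no sharpness signal. With the default recipe
(5000 pairs, 20 epochs) held-out accuracy on unseen phantoms exceeds
0.95, which the acceptance checks assert.

**Weight map.** The trained pair head slides over both images in lockstep
(stride 2 by default; the last window is pinned to the image edge so
every pixel is covered), writes $p_1$ — the probability that image A's
patch is the high-quality one — over the whole window, and averages
overlaps. The map is *not* assumed to satisfy
$W_S(A,B) = 1 - W_S(B,A)$: the score is computed from the $(A,B)$ order
alone, and no symmetry is enforced.

## The fusion rules

**Coarsest approximation — WLE × WSEML maximum selection.** The weighting
kernel has entries $2^{2R-r}$ with $r$ the city-block (four-neighbourhood
step) distance to the centre — the only reading under which the corner
entries follow the formula — giving $[1\,2\,1;2\,4\,2;1\,2\,1]$ at the
default $R=1$. WLE (window-weighted squared coefficients) measures
energy; WSEML (window-weighted eight-neighbourhood modified Laplacian,
entering *unsquared*) measures detail. The selection takes A's
coefficient where $\mathrm{WLE}_A \cdot \mathrm{WSEML}_A \ge
\mathrm{WLE}_B \cdot \mathrm{WSEML}_B$; ties go to A, following the
printed $\ge$. Activity maps use mirror boundary extension to avoid
spurious edge activity.

**Second component — scalar spatial-frequency blend.** The blend weight
is the spatial frequency of the weight map's (recombined) low band, a
single global scalar: the row/column difference sums run over
$i \le M-1, j \le N-1$ while the normaliser is the full pixel count
$MN$, exactly as conventionally printed. A per-pixel variant is
deliberately not implemented. SF of a near-flat probability map is small
but can in principle exceed 1 on pathological maps, so it is clamped to
$[0,1]$ by default (`clamp_sf`), keeping the blend convex.

**Detail bands — weight-band blend.** Each band uses the weight map's
high-pass band at the same (level, direction) — the only shape-consistent
pairing. Two modes exist because high-pass values of a $[0,1]$ map
straddle zero: `literal` (default) applies the blend with the raw band,
which extrapolates slightly where the weight band is negative; `offset`
first adds 0.5 and clips to $[0,1]$, making the blend convex. Whether the
original method clamped these weights is unknowable from its description;
both are provided and the default follows the formula as written.

All three rules are idempotent — fusing an image with itself returns it
— which composed with exact reconstruction gives the pipeline-level
identity `fuse(A, A) = A` within one gray level after 8-bit quantisation.

## Metrics

* **MI** (bits): joint 256-level gray histogram, log base 2; the fusion
  score is $MI(A,F) + MI(B,F)$.
* **MSSIM**: SSIM with the de-facto standard 11×11 Gaussian window
  ($\sigma = 1.5$) and 8-bit constants $C_1 = (0.01 \cdot 255)^2$,
  $C_2 = (0.03 \cdot 255)^2$, averaged over fully-valid window positions,
  then averaged over the two sources.
* **SD**: population standard deviation ($1/MN$).
* **EI**: backward-difference gradient magnitude, reported as the mean
  over the valid region — the per-pixel field is defined but its scalar
  reduction is not; a mean is the reduction that lands on the scale
  fusion tables report.
* **AG**: forward-difference $\sqrt{(f_x^2+f_y^2)/2}$ summed and divided
  by the full pixel count $MN$, as printed, although the sums have
  $(M-1)(N-1)$ terms.
* **Q_ncie**: the printed pairwise formula mixes symbols (the grid bound
  and base are stated inconsistently), so the implementation follows the
  standard construction the output range pins down: rank both variables
  (ties broken by position), partition the rank plane into a $b \times b$
  grid ($b = 256$), $NCC = 2 + \sum (n_i/N)\log_b(n_i/N)$; assemble the
  3×3 nonlinear correlation matrix of $(A, B, F)$ with unit diagonal and
  aggregate its eigenvalues, $Q = 1 + \sum (\lambda_i/3)
  \log_b(\lambda_i/3)$. Closed forms anchor it: identical variables give
  $NCC = 1$; an identical triple gives $Q = 1$; three independent images
  give $Q \approx 1 - \log_{256} 3 \approx 0.802$. Note the independence
  anchor for a single pair needs $N \gg b^2$: at $N = b^2$ Poisson cell
  occupancy biases $NCC$ up by $\approx 0.1$, which is a property of the
  estimator, not a defect.

Every metric is verified against a naive double-loop transcription of its
formula at `1e-10` on 16×16 inputs.

## The synthetic phantoms

The generator draws a shared geometry per seed — head ellipse, skull
ring, ventricles, tissue blobs, texture-band parameters — and renders it
twice: `ct_like` (bright ring, low-texture interior) and `mri_like` (dim
rim, banded high-texture interior, bright CSF), plus mild Gaussian noise,
clipped and rounded to 8 bits. A pair sharing a seed is co-registered by
construction. The phantoms emulate the *contrast relationships* that
drive the fusion rules — complementary bright structures, disjoint
texture — at the 256×256 size typical of this line of work. They do not
emulate anatomy, partial-volume effects, modality-specific noise
(Rician, streak artefacts) or registration error; a pass on phantoms
therefore demonstrates the machinery (invertibility, rule behaviour,
trainability, metric correctness), not clinical performance on AANLIB or
hospital data. Real registered pairs can be fed directly through
`read_gray()`/`fuse_pipeline()` or the CLI.

## Numerical and scale choices

Pixel values stay floating point on the 0–255 scale through the whole
pipeline; quantisation to 8 bits happens only when writing. Test problem
sizes were chosen to keep the default suite fast while exercising the
stated operating conditions: the transform's round-trip property is
checked on 100 random 128×128 images and the partition of unity on the
256×256 default bank; module tests use 64–96 px images and a lightly
trained network (800 pairs, 5 epochs), while the end-to-end checks train
the full default recipe once and reuse it. The acceptance script mirrors
those computations from scratch under a caller-supplied seed.

## Known limitations

* Periodic boundaries can ring at image borders on images with strong
  edge-to-edge intensity mismatch; fusion inputs (head on dark
  background) rarely trigger this.
* The scalar spatial-frequency weight of the second approximation
  component is typically small on smooth weight maps, so that component
  leans toward source B (the MRI slot by convention); this follows the
  formula as printed.
* In `literal` mode detail-band fusion keeps B's detail where the weight
  map is locally flat (its high-pass is then ~0); pass the MRI — the
  texture-rich modality — as B, or use `offset` mode.
* The network judges *blur*, not modality quality: it transfers to other
  degradation types only insofar as they suppress high frequencies.
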