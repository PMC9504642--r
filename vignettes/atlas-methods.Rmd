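---
title: "Building dynamic vocal-tract atlases: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building dynamic vocal-tract atlases: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtatlas)
```

## The problem

Real-time MRI of speech production yields, per speaker, 2D image series of
the vocal tract at 50 frames/s in five parallel sagittal planes (R2, R1, M,
L1, L2) while the speaker utters consonant-vowel (CV) syllables
(C in f, p, s, t; V in i, a, u).  Speakers differ in anatomy (a buccal
cavity length spread above 20 mm in a typical eight-speaker cohort) and in
timing (each speaker realizes the consonant and vowel with their own
durations).  A *dynamic spatiotemporal atlas* is a synthesized image
sequence for each CV and plane that behaves like an average speaker: the
anatomical and timing idiosyncrasies are removed, and what remains is the
shared articulatory gesture.

`vtatlas` implements the whole chain: groupwise reference-space
construction, anatomical normalization, piecewise-linear temporal
alignment, adaptive Gaussian kernel synthesis, and a cross-validated
similarity evaluation, plus a seeded phantom generator that stands in for
MRI recordings, which are not publicly deposited.

## The transform model

Registration uses a composite backward mapping

$$T(x, y) = T_\mathrm{global}(x, y) + T_\mathrm{local}(x, y),$$

an affine part plus a cubic B-spline free-form deformation evaluated as the
tensor product

$$T_\mathrm{local}(x,y) = \sum_{l=0}^{3}\sum_{m=0}^{3}
  B_l(u)\,B_m(v)\,\phi_{i+l,\,j+m},$$

with $i = \lfloor x/\delta_x\rfloor - 1$, $u = x/\delta_x -
\lfloor x/\delta_x\rfloor$ (and likewise $j$, $v$), control displacements
$\phi$ on a grid with spacing $\delta_x, \delta_y$, and the standard cubic
blending polynomials $B_0,\dots,B_3$ (a partition of unity; the package
asserts this to $10^{-12}$).  Note the two parts *add* as displacements;
they are not composed.  Averaging transforms — the backbone of the
reference-space construction — is therefore a plain parameter-wise mean of
affine entries and control displacements, with no weighting.

Key numerical choices:

* **Similarity criterion.** Every registration in the pipeline is preceded
  by histogram matching, after which intensities of the two images are
  directly comparable.  The optimizer therefore minimizes the mean squared
  intensity difference, which has analytic gradients with respect to both
  the six affine parameters and the full control grid.  This is what makes
  the $N(N-1)$ pairwise registrations of the reference step and the
  per-frame affine normalization tractable, and it is exactly reproducible
  (L-BFGS-B, fixed iteration caps, no stochastic sampling).
* **Control spacing** defaults to 16 px on 136 px images — coarse enough to
  forbid pixel-level warping, fine enough to resolve articulator-scale
  deformation.  A small membrane penalty (first differences of the control
  displacements, weight $10^{-4}$) discourages spurious oscillation.
* **Interpolation** is bilinear for warping (exact for integer shifts,
  zero fill outside) and the exact cubic basis for FFD evaluation.
  The bilinear kernel is compiled code; it is the innermost loop of every
  optimizer iteration.
* **Multi-resolution**: the affine stage runs a 3-level pyramid
  (2x block means), which recovers scale ratios up to ~1.35 and shifts of
  several pixels reliably; the FFD stage refines at full resolution.

On phantom images with known ground truth the affine stage recovers
transforms with mean endpoint error well under 0.5 px and the FFD stage
recovers smooth random deformation fields (control SD 1.2 px) to under
1 px mean endpoint error.

## Histogram matching, and when it bites

`match_histogram()` is a monotone CDF inversion on 256 uniform bins over
the dataset intensity range: each occupied source bin maps to the lowest
reference bin whose cumulative mass reaches the source's cumulative mass;
a bin that maps to itself keeps its exact pixel values.  The construction
makes matching an image to its own histogram an exact no-op and makes the
operation idempotent bit-for-bit, which the tests assert.  "Average
histogram" means the mean of *normalized* (probability) histograms,
rescaled to the mean mass, so images of different sizes contribute equally.

Exact histogram specification has a known failure mode that users should
understand: when two images have different foreground/background area
proportions (a large head fills more of the frame than a small one), the
matching must move intensity mass across levels to equalize the
proportions, which perturbs intensities near region boundaries.  In the
pipeline this slightly biases the affine normalization of strongly scaled
speakers (up to ~10% on the recovered scale in the worst synthetic case)
and blurs the reference image a little; it does not disturb the atlas's
qualitative behavior, and it is the price of the classical matching step
the method prescribes.  The ground-truth recovery diagnostics in the test
suite therefore register raw phantom frames; the pipeline itself always
matches first.

## The four construction steps

1. **Reference space** (per plane, from one silence frame per speaker):
   compute the average histogram and match all frames to it; register every
   frame to every other ($N(N-1)$ non-rigid registrations $T_{i,j}$);
   average each speaker's $N-1$ transforms into $\bar T_i$; warp each
   speaker with its $\bar T_i$; the pixel-wise mean of the warped frames is
   the reference image $\bar I$.  The result is deterministic and
   independent of speaker ordering.  Note a boundary property of the
   formula $\bar T_i = \frac{1}{N-1}\sum_j T_{i,j}$: at $N = 2$ the
   "average" is the single full transform onto the other speaker, so the
   two neutralized images swap positions and only their mean is centered.
2. **Anatomical normalization**: every dynamic frame is matched to the
   reference histogram and registered to $\bar I$ with an *affine only*
   transform, one per frame (warm-started from the previous frame).  Local
   articulator configuration is deliberately not warped: position
   variability is the signal.
3. **Temporal alignment**: per CV, the mean consonant duration
   (`v_onset - c_onset`) and vowel duration (`v_offset - v_onset`) over all
   speakers and planes define reference durations (fractional frames are
   kept; ms = frames x 1000/fps).  Each speaker's consonant and vowel are
   then independently linearly mapped onto those durations: frame $f$ of an
   $n$-frame segment with reference length $r$ frames lands at
   $t_\mathrm{start} + (f/n)\,r/f_s$.  The map is anchored at segment
   starts — the paper fixes only "linearly extended or compressed", so an
   anchor had to be chosen; start-anchoring makes the first consonant frame
   land exactly at 0.  Pooling all speakers yields a global series that may
   hold several samples at one time point; sorting is stabilized by
   (time, speaker, source frame) so the pipeline is deterministic.
4. **Kernel synthesis**: an atlas frame at time $\tau$ is the normalized
   Gaussian-weighted average of the $k = 7$ samples nearest in time.  The
   Gaussian is centered at $\tau$ and its width is *adaptive*: with
   $\tau_f$ the farthest selected sample,
   $\sigma^2 = -(\tau-\tau_f)^2 / (2\ln 0.35)$, so the raw weight at
   $\tau_f$ is exactly 0.35 of the peak.  (The printed form of this rule
   omits a square root — as printed it equals $\sigma^2$; the package
   implements the variance form, which is the one that actually produces
   the stated 0.35 floor, and the tests pin the floor to $10^{-12}$.)
   If $\tau_f = \tau$ the weights degenerate to uniform.  Ties at the
   $k$-th neighbor prefer the smaller time distance, then the earlier
   sample, then the smaller speaker id.  The 20 ms `window` (one frame
   period) is the default atlas time step and a sanity bound: a warning is
   raised when the $k$-th neighbor lies farther away.  Contributors are
   histogram-matched to the contributor nearest $\tau$ before averaging.

```{r kernel}
kw <- adaptive_kernel_weights(c(0.004, 0.008, 0.012), tau = 0.009,
                              kernel_config(k = 3))
round(kw$weights[order(kw$indices)], 3)   # 4, 8, 12 ms samples
kw$raw[length(kw$raw)]                    # exactly 0.35 of the peak
```

## Cross-validated evaluation

`run_validation()` follows a four-fold protocol on a 4 male + 4 female
cohort: each fold trains the reference space and atlas on six speakers and
holds out one speaker of each gender.  Held-out series are piecewise
time-aligned (reference durations are computed from the training speakers
only — the clean protocol; the source cohort's published durations were
computed over all speakers, but the fold protocol does not state which, so
the leakage-free choice is used).  Each atlas frame links to the temporally
closest test frame of each test speaker (frames may be reused or unused;
midpoint ties go to the earlier frame).  Test frames stay anatomically raw
at this point — they are *not* affinely pre-normalized; mapping them to the
atlas is the job of the registration being evaluated.

For every stack (atlas frame A, test frames $O_1, O_2$, registered frames
$R_1, R_2$), similarity is the maximum over all zero-padded integer lags of
the 2D cross-correlation of the two test images, normalized by the maximum
autocorrelation of A:

$$\mathrm{BA} = \frac{\max_{k,l} \sum_{m,w} O_1[m,w]\, O_2[m-k, w-l]}
                     {\max_{f,g} \sum_{m,w} A[m,w]\, A[m-f, w-g]},$$

and AA likewise with $R_1, R_2$.  The prose around the printed formulas
speaks of similarity "between the originals and row A", but the formulas
correlate the two test images with each other and use A only for
normalization; the formulas are implemented as printed.  The maximum is
computed in the frequency domain; a brute-force double-loop oracle verifies
it exactly on small images.  Every image entering the similarity —
including $R_1, R_2$ — is matched to the atlas frame's histogram: warping
perturbs the intensity distribution (interpolation smoothing, zero fill),
and without re-matching the AA score picks up a pure energy artifact
(minifying warps lose high-frequency energy, magnifying warps keep it)
that has nothing to do with articulatory similarity.

Scores are pooled over frames, planes, both test speakers' stacks and
folds into a per-CV mean and SD.  On the seeded eight-speaker phantom
cohort the published qualitative pattern reproduces for every CV: mean
similarity increases after atlas registration while its spread collapses
(typically ~0.98 ± 0.035 before vs ~1.00 ± 0.006 after at the evaluation
scale below).

## The phantom generator

`phantom_cohort()` renders a simplified sagittal head — outline, hard
palate, tongue (body and tip bumps on a jaw baseline), lips, pharynx,
spine — with smooth anti-aliased edges, and animates it with one shared
gesture per CV: the consonant target (lip closure for /p/, labiodental
near-closure for /f/, alveolar tongue-tip contact for /t/, a narrow
tip groove for /s/) is reached over the first 40% of the consonant and
held; the articulators then glide to the vowel target (/i/ high-front,
/a/ low-open, /u/ high-back with rounded lips) over the first 60% of the
vowel.  What varies per speaker:

* **Affine anatomy**: global scale in [0.85, 1.15], head tilt ±4°, shift
  ±3 px — exactly recoverable, and exported as ground-truth transforms.
* **Non-affine anatomy**: palate and jaw offsets (±0.018 head units),
  tongue-body width (±12%), spine position, lip thickness, vertebra count
  (4-6).  These are what affine normalization *cannot* remove — without
  them the validation would have nothing to measure.
* **Timing**: per-speaker consonant/vowel durations are the bundled cohort
  reference durations plus an integer jitter of ±1 frame (minimum 3
  frames), so the piecewise alignment is non-trivially exercised.
* **Intensity**: per-speaker gain/offset, Gaussian noise (SD 0.01), and a
  smooth anatomy-attached shading and texture field.  The shading imitates
  receive-coil falloff and, importantly, spreads the histograms over many
  levels so histogram matching is well conditioned; it is attached to the
  anatomy so speakers remain exactly affine-consistent.
* **Planes**: off-center planes get increasing blur (partial-volume
  imitation), slightly shrunken structures and more closed lips.

All randomness flows through one seed; two calls with the same seed are
bit-identical.  What the phantom does *not* emulate: real MRI noise
statistics and artifacts, soft-tissue deformation detail, head motion
within a series, and genuinely speaker-specific articulatory *strategies*
(the gesture is shared by construction).  Passing tests on phantoms
therefore demonstrate that the pipeline's machinery is correct and that
the validation pattern emerges when anatomy varies and gestures are
shared — not that the method's published effect sizes transfer to real
recordings.

## Problem sizes used by the test and evaluation runs

Unit tests run on 3-speaker cohorts at 48-64 px with control spacing 12 px.
The full cross-validated evaluation in the acceptance suite uses the
complete study conditions — 8 speakers (4M/4F), all 12 CVs, four folds —
rendered at 64 x 64 px on the midsagittal plane with a 40 ms atlas step,
16 px control spacing and 40-iteration optimizer caps; these are the
package's documented evaluation sizes, chosen so a complete run finishes
comfortably on one CPU while every stage still operates in its intended
regime.  The single-target acceptance script needs only the kernel rule
and runs in seconds.

## Known limitations

* Exact histogram specification between images with very different
  foreground proportions perturbs intensities (discussed above).
* The registration is not diffeomorphic and has no inverse-consistency
  constraint; strong deformations can fold.  At the control spacings and
  deformation magnitudes of this problem this does not occur.
* Transform averaging is parameter-wise, per the method's definition;
  averaging rotations through their matrix entries slightly shrinks them
  (second-order effect at the tilt angles involved).
* The BA/AA ratio is not bounded by 1 and depends on the atlas frame's
  energy through its autocorrelation; it is a relative score, meaningful
  in before/after comparison, not an absolute similarity.
* Landmarks for vocal-tract measurements are inputs; no automatic anatomy
  detection is attempted.
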