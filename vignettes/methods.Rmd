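---
title: "Methods: pose-based iconicity analysis of sign languages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-based iconicity analysis of sign languages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes, the
assumptions built into each stage, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. From keypoints to body coordinates

The pipeline consumes the output of a 2D body-pose estimator: per-frame
coordinates and confidences for nose, neck, shoulders, elbows and wrists.
Two assumptions are inherited from that upstream stage and not revisited
here: left/right labels are taken at face value (no anatomical
re-identification), and a confidence at or below a configurable floor
(default 0.1) means "not detected". The floor is configuration rather than
a constant because pose estimators differ and the appropriate cut is an
empirical property of the estimator, not of this analysis.

Hands are not tracked directly. The hand centre is approximated as
`wrist + ½ (wrist − elbow)`: the forearm line extended outwards by half its
length, which puts the point at the lower knuckles under a straight wrist.
Wrist flexion is deliberately ignored — modelling it would require 3D
information the input does not carry. A zero-length forearm (a degenerate
frame) leaves the hand at the wrist rather than failing.

Normalization maps raw pixels to **body units**: the origin is the mean
nose position over the video, *x* is scaled by the mean shoulder distance
and *y* by the mean nose–neck distance; *y* grows downward (image
convention), so the forehead sits near *y* ≈ −0.5 and the hips near
*y* ≈ 3–4. This removes camera distance, framing and body size, and is
exactly invariant under translation and uniform scaling of the raw
coordinates (a property test asserts this to 1e−9).

Two open points were settled as follows. Reference means are computed only
over frames where the reference joints are detected (`reference_frames =
"detected"`), because undetected joints carry meaningless coordinates; the
all-frames variant is available as configuration. When a dialect lacks the
neck joint entirely, the shoulder midpoint stands in for it, with a logged
message — the proxy is geometrically close for typical seated signers.

## 2. Handedness

A hand's **path length** is the sum of Euclidean distances between
consecutive detected frames. Detection dropouts are bridged (each detected
frame pairs with the nearest previous detected one) rather than splitting
the path: dropouts are estimator noise, not articulatory stops, and
bridging preserves total displacement. A sign is **one-handed** when one
path exceeds the other by strictly more than a factor of 3, otherwise
**two-handed**; a still hand against a moving one is one-handed, and two
still hands are two-handed (symmetric stillness). Signs whose hands are
detected in fewer than 10 frames are **discarded**.

The "fewer than 10 frames" rule is ambiguous between "no hand reaches 10"
and "either hand below 10". The permissive reading (discard only when *no*
hand reaches 10 detected frames) is the default, because a tracked dominant
hand is sufficient for classification; the strict both-hands reading is
available via `min_frames_rule = "both"`.

## 3. The plurality model

The model ties three observables together per concept *c*: integer 1–7
plurality ratings `R_{c,i}` from raters *i*, binary two-handedness
outcomes `S_{c,l}` across languages *l*, and a log-frequency `f_c` min–max
scaled to [0,1] over the modeled concept set.

* `R_{c,i} ~ Normal(1 + 6 p_c + r_i, σ_Q)` — the latent plurality
  `p_c ∈ [0,1]` is mapped affinely onto the rating scale (endpoints 1 and
  7), with a per-rater bias `r_i ~ N(0, σ_R)`.
* `S_{c,l} ~ Bernoulli(logit⁻¹(β_p p_c + β_f f_c + α_L[l] + α_C[c] + a))` —
  a hierarchical logistic regression with language and concept random
  effects.
* Priors: `N(0,5)` on `β_p`, `β_f`, `a` (logistic coefficients rarely
  exceed 5 in absolute value); `Exp(1/5)` on all four standard deviations;
  `U(0,1)` on each `p_c`.

Two modelling choices are reproduced deliberately rather than "fixed". The
rating likelihood is a *continuous* normal over integer ratings — no
ordinal link, no truncation at the 1–7 bounds; this is the printed model
and swapping in an ordinal likelihood would change what the parameters
mean. And a single pooled `σ_Q` governs all rating noise. The synthetic
generator, by contrast, rounds and clamps its ratings to the observable
1..7 scale, so the generator/likelihood mismatch present in the real study
design is present in the synthetic one too; parameter-recovery tests
quantify its practical effect (coverage of the 95% interval for `β_p`
remains ≥ 90% at the study's design size).

The rating block has a soft degeneracy: adding a constant to every `r_i`
while shifting the `p_c` by −δ/6 leaves the rating means unchanged. It is
broken softly by the zero-centred prior on `r_i` and hard by the outcome
block, which pins `p_c`; a test verifies the likelihood-level invariance
explicitly.

### Sampling

No Stan-like sampler is available in the target environment, so the
package ships its own Hamiltonian Monte Carlo implementation (Rcpp). The
posterior contract is what matters — split R-hat below the warning
threshold (default 1.01) and adequate effective sample sizes — not the
algorithm. Numerical choices:

* **Parameterization.** Hierarchical effects are non-centred
  (`α = σ·z`, `z ~ N(0,1)`), removing the funnel between scales and
  effects; `p_c` is sampled on the logit scale and the σ's on the log
  scale, each with the appropriate Jacobian.
* **Adaptation.** Dual averaging targets acceptance 0.8; a diagonal mass
  matrix is estimated from the 15–60% warmup window, after which the step
  size re-adapts on the new metric. Leapfrog counts are jittered uniformly
  in `max_leapfrog/2 .. max_leapfrog` (default 24..48) to avoid periodic
  resonances.
* **Determinism.** Each chain runs a private 64-bit Mersenne Twister with
  Box–Muller normals, seeded from the user seed and chain id; a fixed seed
  reproduces every draw bit for bit, independent of R's global RNG.
* **Diagnostics.** Split R-hat (each chain halved; zero-variance chains
  defined as R-hat 1 with a warning) for every parameter; effective sample
  size via per-chain autocovariances combined with the between-chain
  variance and truncated by Geyer's initial monotone positive sequence.
  Percentile summaries use linear interpolation (R type 7).

## 4. Location iconicity

A location rating is a rater-placed axis-aligned rectangle in body units,
mirrored across the body midline (x = 0); the pair counts as one rating.
The score of a sign against a rating is the negative mean distance from the
dominant hand (the hand with the longer path; exact ties go to the right
hand, an arbitrary but fixed convention that cannot affect symmetric signs)
to the nearest rectangle, over the middle frames of the sign: after
removing undetected frames, `floor(0.2·n)` frames are trimmed from each end
to drop transport movements. The trim uses floor, and a one-frame guard
keeps the middle frame when trimming would empty a very short sign — the
guard is this package's own addition for degenerate inputs.

Distance to a rectangle is zero inside it, else the Euclidean distance to
the nearest boundary point; an oracle test checks this against dense
boundary sampling to 1e−3 on 1000 random cases. Scores are therefore in
(−∞, 0], reach 0 exactly when every trimmed frame is inside the rated
region, and are invariant under mirroring the trajectory.

Concept-level scores average the N languages × M ratings matrix. Chance
context comes from scoring the same M ratings against every vocabulary
concept's signs: the reported **percentile** is the concept's rank among
vocabulary concepts ordered from the highest (least negative) score,
`round(100·rank/|vocab|)` — low percentiles mean high similarity. The
original convention behind the published percentile column is not stated
precisely (inclusive vs exclusive rank, exact vocabulary size), so this
definition is documented as ours rather than asserted as the original.

**Heatmaps** accumulate per-frame deposits of time mass per hand on a grid
over x ∈ [−2, 2] shoulder-widths and y ∈ [−1, 5] nose–neck units (head to
waist under the normalization; configurable). Deposits are per-frame
points, not rasterized polylines, because the visual quantity of interest
is *time spent* at a location, not path coverage. By default each sign's
deposits are divided by its detected frame count (equal total mass per
sign — a mean time share); raw counts are a flag away. Grids are blurred
with an isotropic Gaussian of σ = 0.03125 × (horizontal resolution) cells,
truncated at 4σ and normalized to unit kernel sum, so mass is conserved
except within ~4σ of the border (clipped frames and border losses are
warned about, and a conservation test bounds interior loss at 0.1%).
Because convolution is linear, blurring the sign-averaged grid equals
averaging per-sign blurred grids; the implementation does the former.

## 5. The synthetic world

The generator emulates the study design end to end: 23 raters, ~80 modeled
concepts, 27 analysed languages by default; generative truths default to
the reported posterior medians (β_p = 2.25, β_f = 0.18, a = 0.29,
σ_Q = 1.52, σ_R = 0.83, σ_L = 0.41, σ_C = 1.61). Synthetic videos place a
static torso and move hands on jittered circular orbits (radius 0.15 body
units, noise SD 0.05 body units, 40 frames ≈ 1.6 s at 25 fps) around a
per-concept target location; one-handed signs park the left hand at hip
level, and each hand's joints drop out independently per frame (default
probability 0.05). Ratings are rounded and clamped to 1..7 as a real
questionnaire would produce them.

What a green test does establish: the classifier, model and scoring
machinery recover planted truths under the stated noise. What it does not:
robustness to real pose-estimation failure modes (systematic left/right
swaps, partial occlusion, the camera-setup artefacts that made four
languages unreliable in the original data), articulatory phenomena beyond
location (handshape, orientation, non-manuals), or 3D effects such as body
contact — none of which the 2D input can express.

## 6. Known limitations

* The handedness classifier sees only path-length ratios; a two-handed
  sign with a near-still base hand is one-handed to it by design.
* The continuous rating likelihood slightly compresses latent plurality
  near the scale ends (clamping); the recovery tests bound the practical
  effect at design scale but individual `p_c` near 0 or 1 are biased
  inward.
* The HMC sampler uses a diagonal mass matrix; posteriors with strong
  parameter correlations mix more slowly than Stan's dense/NUTS machinery
  would. The convergence warning (R-hat) is the guard rail.
* Heatmap mass is lost at grid borders by construction; widen the bounds
  for signs articulated far outside the default signing space.
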