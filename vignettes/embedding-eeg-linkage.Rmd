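---
title: "Linking contextual-embedding sentence features to EEG band power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking contextual-embedding sentence features to EEG band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embedeeg)
```

## The scientific question

If the brain represents words as context-sensitive vectors — the
vector-based neural coding hypothesis — then geometric summaries of a
sentence's token-embedding trajectory should track the neural effort of
reading it.  `embedeeg` implements the complete analysis pipeline for
that question: it computes fourteen sentence-level (here, "unit"-level)
features from contextual token embeddings, turns event-marked continuous
EEG into one channel-averaged power value per frequency band per reading
epoch, and links the two with linear mixed models.  A synthetic-data
generator with fully known ground truth stands in for real recordings
and live language-model inference, so every stage is testable offline.

## The fourteen features

For a unit whose tokens have embedding rows \(x_1,\dots,x_n \in
\mathbb{R}^d\) (special sequence markers excluded, so a 7-character unit
yields a \(7 \times d\) matrix):

1–4. **Cumulative distances** \(\sum_{i=1}^{n-1}\mathrm{dist}(x_i,
x_{i+1})\) for the Euclidean, cosine, Manhattan and Chebyshev metrics.
Cosine distance is defined as \(1 - \cos\theta\) (range \([0,2]\)); the
source analysis does not write the formula out, and this is the standard
convention consistent with "directional similarity".  For every adjacent
pair, Chebyshev ≤ Euclidean ≤ Manhattan, and the same chain holds for
the totals.

5–10. **Unit-vector norms** — L2, L1 and L∞ — of two unit-level
vectors: the mean of the token rows (the pooled representation), and a
direct unit-level encoding from a separate sentence encoder.

11–13. **Hull geometry.** The unit's token matrix is centered and
projected onto its own top-2 principal components.  We compute the
perimeter and area of the convex hull of the projected points, plus the
sum of distances between *consecutive tokens in reading order* in the
plane ("neighbor sum").

14. **Cumulative surprisal.** Each position in turn is masked, the
masked language model's probability for the true token is read off, and
\(-\log p\) (nats) is summed over positions — exactly \(n\) single-mask
model evaluations per unit.

### Design choices where the procedure was genuinely open

* **PCA per unit, not corpus-wide.**  The hull is described as built
  around "these points" of a single unit; a per-unit fit is the only
  reading that makes hull features intrinsic to the unit.  A corpus-wide
  projection would couple every unit's features to the corpus
  composition.
* **"Neighbor sum" means reading-order neighbors.**  If it meant
  neighboring hull vertices it would duplicate the perimeter feature;
  we therefore sum over consecutive tokens in the projected plane.
  Degenerate cases are pinned down: one point gives (0, 0, 0); two
  distinct points give (d, 2d, 0); collinear points give area 0 and
  perimeter twice the largest pairwise distance.
* **Unit-level vectors are used as the encoder emits them** — no L2
  normalization is applied before the norms, since nothing in the
  source procedure suggests it.
* **Surprisal base.**  Natural log by default (`base = 2` available);
  the choice only rescales the feature by a constant, which the mixed
  model absorbs into \(\beta\).  Probabilities are floored at `1e-12`
  before the log so degenerate mock models cannot emit infinities.
* **Encoders are plug-ins.**  A token encoder maps text to a token ×
  dimension matrix; a unit encoder maps text to one vector; a masked LM
  exposes `predict(tokens, i)` over a vocabulary.  Pretrained models
  can be wrapped by users; the package ships deterministic hash-based
  mocks so that everything builds and tests without network access or
  model weights.

## From EEG to band power

Epochs are cut between ROWS (start) and ROWE (end) markers, 0-based
sample indices, half-open `[start, end)`.  Per epoch and channel the PSD
is estimated by Welch's method: Hann-windowed, mean-detrended segments
with 50% overlap, averaged one-sided periodograms.  The stated segment
length range of 0.5–1 s is realized by the rule *segment length =
clamp(epoch duration, 0.5 s, 1 s)* — epochs shorter than 1 s are
analysed with a single full-epoch segment, longer epochs with 1 s
segments; both stated endpoints are reproduced and the frequency
resolution stays at or below 2 Hz, so every band edge is bracketed.
Epochs shorter than 0.5 s cannot support the minimum window and are
dropped with a logged count rather than zero-padded.

Band power is the trapezoidal integral of the PSD over the grid
frequencies inside each band — delta 1–4, theta 4–8, alpha 8–13, beta
13–30, gamma 30–50 Hz.  A grid point on a shared edge (4 Hz, say)
belongs to both adjacent bands, mirroring inclusive range masks; on an
edge-aligned grid the five band integrals therefore sum exactly to the
1–50 Hz integral.  Per epoch, the unweighted mean over channels of each
band's power is the dependent variable.  The normalization is such that
a pure sinusoid of amplitude \(A\) integrates to \(A^2/2\) over its
band, which the test suite checks directly.

Channel exclusion (electrodes near ears, forehead, back of the head in
the montages this pipeline was designed around) is configuration — a
list of labels — because it is montage-specific.  No filtering,
re-referencing or artifact correction is applied: the pipeline consumes
already-preprocessed releases.

## The linkage models

For each band,
\[
  \mathrm{power}_{pru} = \beta_0 + \textstyle\sum_{f=1}^{14} \beta_f\,
  \mathrm{feature}_{f,u} + b_p + b_r + \varepsilon_{pru},
\]
with crossed random intercepts for participant \(p\) and run \(r\),
fitted by REML via `lme4`.  Inference per fixed effect is Wald:
\(z = \hat\beta / \mathrm{SE}\), \(p = 2\Phi(-|z|)\).  Before each model
the 2.5 SD screen removes rows whose response or any feature deviates
from its column mean by more than 2.5 sample standard deviations; means
and SDs are computed once on the full table, not iteratively, which
makes the screen order-independent.  Which columns the original screen
covered is not stated; screening the response and all features, per
model, is this package's choice and is configurable.

Features enter on their raw scales and no term is dropped for
insignificance.  Significance is flagged at α = 0.05 with an additional
reporting tier at p < 0.1, both strict inequalities.  No
multiple-comparison correction is applied by default (an optional
Benjamini–Hochberg flag exists but is off), mirroring the exploratory
stance of the source analysis.  Because cumulative distance features are
nearly collinear — the generator reproduces correlations around 0.999
between the Euclidean and Manhattan totals, the same magnitude real
encoder-derived features exhibit — every result carries collinearity
diagnostics
(design-matrix condition number, largest absolute pairwise feature
correlation), and individual coefficients among the collinear block
should be read as shared variance.

A combined-materials mode adds material and material × feature fixed
effects and retains the reduced model without them, supporting the
two-text comparison workflow.

## The synthetic world

`sim_config()` states the world once; all generators are pure functions
of (config, seed), and a master seed expands deterministically into
per-stage seeds (`derive_seed()`).

* **Embeddings** are Gaussian random walks, `row[i+1] = row[i] +
  step_scale * g[i]`: the expected adjacent step is `step_scale *
  E||g||` (chi-distribution mean), making cumulative distances
  controllable.  Units have 4–10 tokens, matching presentation segments
  of at most 10 characters; per-unit step scales are uniform on
  [0.5, 1.5] so that distances vary across units.  Dimension defaults
  to 32 — a desk-scale stand-in for 768-dimensional encoders (all
  geometry is dimension-generic); notably the realistic near-collinear
  feature structure already emerges at this dimension.
* **Band powers** follow the linear mixed model above exactly: baseline
  + feature effects (on one configured band; other bands carry no
  feature terms) + participant and run intercepts + residual noise,
  floored at 1e-6.  Baselines (delta 20 … gamma 12, arbitrary squared-
  amplitude units) are set high enough that the linear model stays in
  the positive regime at the default effect sizes — real gamma power is
  smaller than delta power, but the units are arbitrary and positivity
  is what the linear model needs.
* **EEG** realizes those powers as band-limited noise: white Gaussian
  noise shaped in the frequency domain by the squared magnitude
  response of a 4th-order Butterworth bandpass per band (the steady-
  state equivalent of forward–backward filtering; no IIR filter-design
  library is available in this environment, and spectral shaping gives
  the identical transfer magnitude), rescaled to exactly the target
  variance, summed over bands, independently per channel.  Epochs are
  concatenated with silent gaps and ROWS/ROWE markers.  Epoch durations
  default to uniform [1, 4] s, exercising the dynamic Welch window rule
  across its whole range.

What the generator deliberately does *not* emulate: 1/f background
spectra, artifacts, eye movements, volume conduction between channels,
or naturalistic text.  A green round-trip test therefore establishes
that the pipeline's algebra and statistics are correct under its own
model — not that real EEG satisfies that model.

## Validation strategy and the numbers behind it

The acceptance tests assert, among other things:

* all geometry agrees with independently coded brute-force oracles
  (pairwise loops, gift-wrapping + shoelace hull) to 1e-8 on 200 seeded
  instances;
* the alpha-band integral of a 10 Hz, amplitude-2 sinusoid is within 5%
  of \(A^2/2 = 2.0\); five-band additivity holds to 1e-9; scaling the
  signal by c scales powers by c² to 1e-6 relative;
* a uniform mock LM over V gives cumulative surprisal exactly
  \(n \ln V\);
* parameter recovery: at the default 10 × 10 × 30 world, each fixed
  effect lies within 2 estimated SEs of its true value in ≥ 90% of 100
  replicates, and under a feature-free null the per-feature rejection
  rate at α = 0.05 stays within [0.025, 0.075] over 400 replicates
  (type-I error is evaluated conditionally on one fixed design, the
  standard framing, which also keeps the run inside a desk-scale
  budget);
* the full round trip — simulate, synthesize EEG, compute power,
  extract features, fit models — flags the planted gamma effect at
  α = 0.05 in ≥ 90% of 50 replicates while delta and theta stay
  unflagged in ≥ 90% each.

The round-trip world (10 participants × 10 runs × 20 units, 2-4 s
epochs at 128 Hz, two channels, planted `total_euclidean` effect 1.5)
was fixed by an a priori power analysis, not by iterating on test
outcomes.  Two obstacles set the required effect size.  First,
collinearity: the variance inflation factor of the Euclidean total
against the other 13 features is ≈ 1000–1500 in this world, shrinking
the identifiable signal by a factor of 30–40.  Second, spectral
measurement noise: a single 2–4 s epoch carries a Welch estimation error
of roughly 7–10% of the power level, and since the error is
proportional to the (feature-shifted) power it dominates the configured
residual SD.  Working through both terms gives an expected Wald z of
about 4–6 for the planted effect at these settings — detection power
near 1 — while short 1 s epochs or desk-scale designs below ~2000
epochs would leave the effect undetectable at any plausible effect
size.  Sampling at 128 Hz (Nyquist 64 Hz, comfortably above the 50 Hz
gamma edge) halves the synthesis cost without touching the statistics.

## Numerical and degenerate-input conventions

* One-token units: all cumulative distances are 0 and the hull triple
  is (0, 0, 0); the norms are those of the single token vector.
* Rank-deficient projections (fewer than 3 tokens, or token matrices of
  rank < 2 after centering) zero-fill the missing component and flag
  the projection as degenerate rather than erroring.
* A zero-norm embedding row under the cosine metric raises an explicit
  degenerate-input error instead of returning NaN.
* Design matrices are rank-checked before fitting; aliased columns are
  named in the error.  Fewer than 2 participants or runs is an error.
* Cosine values are clamped to \([-1, 1]\) before the distance to
  absorb floating-point excursions.
* Event tables must be strictly increasing in sample index with
  alternating ROWS/ROWE per unit; violations raise a structured error
  (`embedeeg_event_error`) carrying the offending unit ids.

## Limitations

Real contextual embeddings are not random walks: their step
distributions are anisotropic and text-dependent, so absolute feature
scales here are not comparable to encoder-derived ones.  The Wald
normal approximation for mixed-model fixed effects is standard at these
sample sizes but approximate.  The reported per-coefficient p-values
inherit all the usual caveats of highly collinear exploratory
regression, which is why the collinearity diagnostics travel with every
result.  Reproducing published coefficient tables requires the original
recordings and pretrained encoder weights, both outside the scope of
this package.
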