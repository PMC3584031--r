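# distapp

Can knowledge of what things *look like* be learnt from the statistics of
language alone? The Distributional Principle holds that words occurring in
similar contexts tend to have similar meanings; the stronger *Appearance
Hypothesis* holds that they tend to have referents of similar visual
appearance. If true, a learner who already knows the appearance of some
categories, and who tracks word co-occurrence for a word whose referent it
has never seen, can identify and name unfamiliar objects above chance —
zero-shot, with no labelled example of the target category.

`distapp` is an R package for computational cognitive scientists (and the
visually-minded machine learners next door) that implements this test end
to end:

* **Distributional word distances** — COALS-style context vectors:
  windowed co-occurrence counts (±4 tokens, flat or ramped weights)
  transformed to clipped, square-rooted binary correlation coefficients

  `r(a,b) = (T·n(a,b) − n(a)·n(b)) / sqrt(n(a)(T−n(a)) · n(b)(T−n(b)))`,

  with word distance `1 − cor` of the transformed vectors; plus a
  Needleman–Wunsch orthographic control.
* **Appearance distances** — per-image Basic-Colour histograms (11 bins)
  and two-scale oriented-Basic-Image-Feature texton histograms
  (23² = 529 bins), compared by the Bhattacharyya distance
  `1 − Σ√(uᵢvᵢ)`; category appearance = bag of 50 encoded images,
  set distance = symmetric best-match mean.
* **Forced-choice trials** — identification (which appearance goes with
  this word?) and naming (which word goes with this appearance?), decided
  by MIRRORING (cross-domain correlation of distance patterns to known
  items), PROXY(k) or FOIL(k), with colour/texton answers combined by the
  larger decision margin; one rival or many.
* **Evaluation harness** — performance curves over known-set sizes,
  permutation chance baseline, bootstrap CIs over trials/words/images,
  per-word scores with category and semantic-depth stratification,
  multi-rival curves, best-quadruple search.
* **A synthetic world generator** — categories whose linguistic context
  profiles and visual statistics are coupled through a shared latent with
  tunable strength ρ ∈ [0, 1], rendered as small striped/blobbed colour
  images and emitted as a token corpus, so the whole pipeline is testable
  with no external corpus or image collection.

## Worked example

A coupled world (ρ = 1) of 24 categories; corpus → COALS, images →
histograms, then identification/naming curves and the permuted-pairing
chance baseline:

```r
library(distapp)
cfg <- world_config(n_categories = 24, rho = 1, context_rate = 0.9,
                    images_per_category = 8, seed = 42)
models <- synthesize_models(cfg, n_occurrences = 120, seed = 42)
curve <- performance_curve(models, grid = c(2, 8, 22), n_trials = 500,
                           seed = 1)
curve
#>   n_known           task  strategy modality n_trials  rate
#> 1       2 identification mirroring     both      500 0.572
#> 2       8 identification mirroring     both      500 0.814
#> 3      22 identification mirroring     both      500 0.940
#> 4       2         naming mirroring     both      500 0.574
#> 5       8         naming mirroring     both      500 0.784
#> 6      22         naming mirroring     both      500 0.892

pb <- permutation_baseline(models, n_perm = 5, n_trials = 400,
                           n_known = 8, seed = 2)
round(c(mean = pb$mean, sd = pb$sd), 3)
#>  mean    sd
#> 0.499 0.015
```

Reading: with only two known appearances the system is barely above the
50% chance line (many mirroring correlations tie at ±1 with two reference
points); the rate climbs steeply with the number of known appearances —
identification 94% and naming 89% when 22 of the 24 categories are known —
while shuffling the word↔appearance assignment collapses performance to
49.9%, confirming that the signal is the language–appearance coupling and
nothing positional.

In an uncoupled world (`rho = 0`) the same pipeline stays inside the
binomial band of 50% at every known-set size; the test suite checks both
regimes, and checks every computational stage against an independent
brute-force implementation.

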