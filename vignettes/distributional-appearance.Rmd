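---
title: "Distributional learning of appearance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional learning of appearance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distapp)
```

## The question

Children acquire word meanings far faster than direct labelling episodes
can explain. One proposed supplementary route is *distributional*: the
company a word keeps carries information about its meaning, and — the
hypothesis this package operationalises — about the *visual appearance* of
its referents. If words that occur in similar linguistic contexts tend to
have referents that look similar, then a learner who knows what some
categories look like, and who tracks co-occurrence statistics for a word it
has never seen the referent of, can interpolate an approximate idea of that
referent's appearance and use it to identify or name unfamiliar objects.

`distapp` implements a complete computational test of this idea:
distributional word distances from a token corpus, image-based appearance
distances between categories, forced-choice identification and naming
trials decided from the two distance structures, and an evaluation harness
(performance curves, permutation baseline, bootstrap intervals, stratified
analyses). Because the original data sources for such experiments (a
licensed 100M-word corpus; tens of thousands of downloaded photographs)
cannot be shipped, the package also contains a first-class synthetic world
generator in which the strength of the language–appearance coupling is a
known dial, so that every stage is testable end to end.

## Distributional distance

The corpus model follows the COALS family. A target word `a` is
represented by a vector over a context vocabulary (the `size` most common
non-stoplist tokens; `select_context_vocab()`). For each context word `b`,
`count_cooccurrence()` accumulates the weight of `b` within ±4 tokens of
each occurrence of `a` (flat weights by default; the ramped
`window − d + 1` variant used by the original COALS implementation is
available via `weighting = "ramped"` — the choice is exposed because the
method description we follow fixes only the window, not the weighting).
With marginals $n(a)$, $n(b)$ and grand total $T$, each cell is turned
into a binary correlation coefficient

$$r(a,b) = \frac{T\,n(a,b) - n(a)\,n(b)}
  {\sqrt{n(a)\,(T-n(a))\;n(b)\,(T-n(b))}},$$

negative values are clipped to zero (attributed to sampling noise) and the
rest square-rooted (`coals_transform()`). The distance between two words
is one minus the Pearson correlation of their transformed vectors
(`distributional_distance()`), in $[0,2]$, smaller = more similar.

Numerical choices: degenerate marginals ($n = 0$ or $n = T$) give cell
value 0; a context vector with zero variance has no defined correlation,
so its distances are set to the neutral value 1. No dimensionality
reduction is applied, deliberately. An orthographic baseline
(`orthographic_distance()`, a negated Needleman–Wunsch global alignment
score) is included as a control word-distance that carries no semantics.

## Appearance distance

Each category's appearance is a *bag of encoded images*
(`appearance_set()`): a multiple-prototype, view-based representation.
Two per-image encodings are used (`encode_image()`):

* **Basic-Colour histogram** (11 bins): every pixel is classified as one
  of the eleven basic colour terms (black, grey, white, red, orange,
  yellow, green, blue, purple, pink, brown). The partition of the RGB cube
  is implemented as nearest-prototype in CIE Lab; the prototype table is
  an editable TSV shipped with the package, since the exact region
  geometry is a replaceable component.
* **oBIF texton histogram** (529 bins): each pixel is classified into one
  of 23 oriented Basic Image Feature classes — flat, light/dark blob,
  8 slope orientations, 4 light-line, 4 dark-line and 4 saddle
  orientations — from the responses of six derivative-of-Gaussian filters
  (`gaussian_jet()`), at a fine and a coarse scale; the ordered pair of
  classes is the pixel's texton, $23^2 = 529$ possibilities.

The oBIF decision takes the largest of seven scale-normalised scores:
$\varepsilon s$ (flat), $2\sigma|\nabla s|$ (slope), $\pm\lambda$ (dark /
light blob), $(\gamma \pm \lambda)/\sqrt{2}$ (dark / light line) and
$\gamma$ (saddle), where $\lambda = \sigma^2(s_{xx}+s_{yy})$ and
$\gamma = \sigma^2\sqrt{(s_{xx}-s_{yy})^2 + 4s_{xy}^2}$. The $1/\sqrt2$
line normalisation is the standard one from the BIF texture literature; a
$1/2$ normalisation would make the line classes unreachable (their score
could never strictly exceed both $\gamma$ and $|\lambda|$). Line and
saddle orientation is the along-feature direction — perpendicular to the
Hessian eigendirection of largest *magnitude*, which flips between the
signed-principal direction and its perpendicular with the sign of
$\lambda$. Orientation sectors are 45° wide, centred on the axis
directions, boundaries to the lower bin.

Filter kernels are sampled Gaussian derivatives, renormalised so that the
discrete correlation is exact on constants, ramps and quadratics (this
makes the analytic oracle tests exact rather than approximate). Borders
use reflect padding and every pixel is classified. Luminance is Rec. 601.
Defaults $\sigma_{\text{fine}} = 1$ px, scale ratio 4, $\varepsilon =
0.1$: chosen values, exposed in `obif_config()`, since no canonical values
are recoverable for this pipeline.

Histograms are compared with the Bhattacharyya distance
$1 - \sum_i \sqrt{u_i v_i}$ — a cosine distance on square-rooted
histograms, which keeps heavily-populated bins from dominating. The
distance between two appearance *sets* is the symmetric best-match mean

$$S_A(A,B) = \frac{\sum_{a\in A}\min_{b}d(a,b) +
  \sum_{b\in B}\min_{a}d(a,b)}{|A|+|B|}.$$

The one-directional reading ("each image in an appearance set" — which
set?) is possible; the symmetric form is used so that $S_A$ is a genuine
symmetric dissimilarity, and the choice is documented here because it is a
genuine fork.

## Trials and decision strategies

A trial (`trial_spec()`, `run_trial()`) presents candidate
word–appearance pairings: identification fixes the word and varies the
appearance, naming fixes the appearance and varies the word; candidate 1
is internally the correct pairing, but the decision functions never see
the labels.

* **MIRRORING** scores a pairing $(w, a)$ by the Pearson correlation,
  across known items $x$, between $d_W(w, x)$ and $S_A(a, A_x)$ — a
  correct pairing mirrors the word-space structure in appearance space.
  Zero variance in either coordinate gives score 0 (the trial then
  resolves by tie-break) rather than an error, so degenerate worlds
  remain runnable.
* **PROXY(k)** uses only the $k$ *most similar* known items as reference:
  for identification the $k$ distributionally nearest words to the trial
  word; each candidate appearance is scored by its mean appearance
  distance to their appearance sets, smallest wins (naming is the mirror
  image). **FOIL(k)** uses the $k$ *most distant* known items and picks
  the candidate with the *largest* mean distance — what looks least like
  the foils is taken to be the unfamiliar target. The scoring rule
  (mean distance to the reference set) is the simplest reading consistent
  with the k-set construction; no explicit formula exists to follow.
* **Modality combination**: colour-based and texton-based answers are
  computed separately and the modality with the more unequivocal answer —
  the larger top-minus-runner-up margin — is followed. The margin rule is
  stated for two candidates; top-minus-runner-up is its natural
  multi-candidate extension. Equal margins follow textons; residual exact
  ties are broken uniformly at random and flagged.

All exact score ties are broken uniformly at random with the trial RNG.
This matters at tiny known sets: with two known items every mirroring
correlation is ±1 or 0, many trials tie, and the correct rate is pulled
toward 50% — the same compression the curves show at two known
appearances.

## The synthetic world

`world_config()` / `make_world()` draw, per category $c$, a latent
$z_c \sim N(0, I_L)$ and two noisy copies
$u_c = \rho z_c + \sqrt{1-\rho^2}\,\varepsilon_c$,
$v_c = \rho z_c + \sqrt{1-\rho^2}\,\eta_c$ with independent standard
normal noise. The context profile is
$\varphi_c = \mathrm{softmax}(A u_c)$ over the context vocabulary; the
appearance parameters $\theta_c$ — an 11-colour mixture
$\mathrm{softmax}(B v_c)$, stripe orientation in $[0,\pi)$, stripe period
in $(4,16)$ px, stripe contrast, blob density — are fixed maps of $v_c$.
At $\rho = 1$ both modalities are deterministic functions of the shared
latent; at $\rho = 0$ they are independent. The linear-Gaussian-softmax
parameterisation is chosen for analytic control of the coupling, not for
linguistic or photographic realism.

`generate_corpus()` surrounds each of the $n$ occurrences of each
category word with four window slots on each side, each slot holding a
draw from $\varphi_c$ with probability `context_rate` and a uniform
filler word otherwise, with filler runs between occurrences so windows
never overlap — which makes brute-force co-occurrence counting equal
windowed counting by construction, simplifying the oracle tests.
`render_image()` draws a background colour from the colour mixture,
sinusoidal stripes at the category orientation (per-image jitter sd 5°,
random phase) and period, Poisson-placed blobs in mixture colours, and a
multiplicative lighting gain uniform on $[0.85, 1.15]$, clipped to
$[0, 255]$; geometry is axis-aligned, origin top-left, row-major.

What the generator emulates: categories whose linguistic contexts and
visual statistics (colour palette, texture orientation/scale/granularity)
are coupled to a controllable degree; within-category image variation in
"viewpoint, lighting and surrounding context" is stood in for by jitter,
phase, blob placement and gain. What it does not emulate: natural token
frequency distributions (Zipfian structure, polysemy), photographic
content, spatial composition, or object/background segmentation. Passing
tests on these worlds therefore establish that the *pipeline* recovers
coupling when it exists and reports chance when it does not — they say
nothing about whether real language and real images are so coupled, which
only real corpora and image collections can show.

Default conditions (chosen once): 50 images per appearance set, 64×64 px
images, latent dimension 4, context rate 0.5, softmax concentration 2
(language) and 3 (colour). Worlds used by the validation suite use a high
context rate (0.9) as the low-noise condition, 70 categories so that
known sets of 64 fit alongside the trial words, and 8 images per set to
keep rendering time proportionate.

## Evaluation harness

`performance_curve()` samples, per trial, a fresh known set and (C, R)
pair and reports exact correct-rate ratios over a known-set-size grid
(default powers of two up to the vocabulary). `permutation_baseline()`
re-evaluates after shuffling the word→appearance-set assignment: the mean
rate over permutations estimates the empirical chance level (50% for one
rival) whatever structure the world has. `bootstrap_ci()` gives
percentile intervals under resampling of trials, of word identities, and
of images within each appearance set (the image axis rebuilds the
appearance distance matrices per replicate and re-decides the logged
trials). `per_word_scores()` runs the exhaustive rival sweep per word
with the maximal known set; `stratified_summary()` aggregates by category
(t intervals; two-sided t test against the grand mean at α = 0.05,
uncorrected, each flag being of individual interest) and regresses rate
on semantic depth by OLS with a t interval on the slope.
`multi_rival_curve()` reports rates against the $1/(m+1)$ chance line,
and `quadruple_search()` looks for unusually informative four-word known
sets among random candidates.

Problem sizes in the shipped validation suite are scaled to the synthetic
design: 10³ trials per curve point in routine runs, 10⁴ for trend tests,
20 permutations × 10³ trials for the chance recomputation. These are the
package's study conditions; the trial-count parameters accept larger
values unchanged.

## Known limitations

* The Basic-Colour partition is nearest-prototype in Lab with an editable
  prototype table — a stand-in for an exact published RGB-cube partition,
  adequate for synthetic palettes drawn from the same prototypes.
* `distributional_distance()` on tiny synthetic vocabularies is noisier
  than on a 14K-dimensional context space; separation properties are
  therefore tested with point-mass profiles where they are exact.
* FOIL's scoring direction ("choose the candidate most distant from the
  foils") is an interpretation; its poor performance relative to PROXY
  and MIRRORING is expected behaviour, and the structural identity
  between PROXY and FOIL at `k = |known|` (equal scores, opposite
  ordering) is tested instead of any empirical ranking.
* With one latent dimension the softmax map can in principle fold
  distances non-monotonically; rank agreement between modality distances
  at ρ = 1 is near-perfect but not exactly 1, and is tested as such.
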