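---
title: "Adversarial domain adaptation for NIR spectral classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial domain adaptation for NIR spectral classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In-line monitoring of agri-food powders with near-infrared (NIR)
spectroscopy must classify the material moving past the sensor — here into
five allergen classes (gluten, gluten-free, peanut, tree nut, egg) across
25 material-brand units. Collecting labelled calibration spectra on a
running conveyor is disruptive, so the practical route is to train on
spectra acquired from stationary samples (the *source domain*) and deploy
on moving samples (the *target domain*). Motion changes peak intensities
and raises spectral noise, so a classifier trained on stationary spectra
degrades on moving ones. `nirda` implements four training procedures that
address this transfer with no (or one) labelled moving spectrum per
material:

* **TL** — a transfer-learning baseline: cross-entropy training on all
  labelled spectra, ignoring unlabelled target data.
* **DANN** — domain-adversarial training: a domain discriminator learns to
  tell source from target features while the shared feature extractor is
  trained to confuse it, so extracted features become domain-invariant but
  stay class-discriminative.
* **SGAN** — a semisupervised GAN: a generator produces fake spectra, and
  the shared extractor plus a real/fake discriminator learn to separate
  real spectra (labelled *and* unlabelled target) from generated ones,
  shaping features around the target-domain manifold.
* **SGAN+DANN** — both adversarial branches around one shared extractor
  and classifier.

## Architecture

All methods share one fully connected feature extractor
(input → 256 → 128 → 64 → 32, ReLU), with single logistic-regression
heads: a 5-class classifier, a 2-class domain discriminator, and a
2-class real/fake discriminator, each consuming the 32-unit features. The
generator maps a 16-dimensional standard-normal latent vector through
32 → 64 → 128 → 256 → *p* fully connected layers, where *p* is the
spectrum length (401 for the 1550–1950 nm sensor, 451 for 2000–2450 nm,
852 for both concatenated). The generator's output layer is linear —
intensities are unbounded — and generated spectra pass through the shared
extractor before the real/fake head. Weights use fan-in-scaled normal
initialization; `latent_dim = 16` is a design default (nothing in the
protocol pins it).

## Training schedules

Training uses mini-batches of 32, learning rate 0.001, and Adam; the
protocol default is 10,000 epochs, where one epoch is one pass over the
labelled set (the package treats "epoch" as a full pass; examples and
tests use a few hundred epochs at reduced problem sizes). Per labelled
mini-batch:

1. *Classification*: extractor + classifier descend cross-entropy on the
   labelled batch.
2. *DANN step 2*: the domain discriminator is trained on the domain
   labels of the labelled data; the extractor then ascends the
   transformed loss to confuse it.
3. *DANN step 3*: the same pair of updates on unlabelled target data.
4. *SGAN steps 1–3*: extractor + real/fake discriminator learn that
   labelled data are real, that generated spectra are fake (with the
   generator ascending the transformed fake-detection loss), and that
   unlabelled target data are real.

The combined method runs the classification step once, then the DANN
steps, then the SGAN steps. With `adversarial = FALSE` every method
reduces exactly to TL under a matched seed — a property the test suite
asserts on the weights themselves.

### The negative-inverse transform and its sign

The adversarial ("confusing") updates use the transform
$T(L) = -1/(L + \varepsilon)$ of the discriminator loss $L$, with
$\varepsilon = 10^{-6}$. Minimizing $T(L)$ by gradient descent would
*reduce* $L$ — i.e. help the discriminator — so the confused module
performs gradient **ascent** on $T(L)$: its update direction is
$-|T'(L)|\,\partial L/\partial\theta$, with magnitude schedule
$|T'(L)| = 1/(L+\varepsilon)^2$. An accurate discriminator (small $L$)
therefore triggers a large confusing step and a weak one a small step.
A `negation` mode ($T(L) = -L$, constant unit schedule) is retained for
ablation.

Two numerical guards make the schedule usable:

* the schedule is clipped at `adversarial_clip = 100` (reached at
  $L = 0.1$), because an almost-perfect discriminator ($L \to 0$)
  otherwise requests an unbounded step that destroys the shared
  extractor;
* the confusing updates use plain scaled gradient steps
  (`adversarial_lr`), not Adam. Adam's per-coordinate normalization makes
  every step the same size regardless of the gradient, which erases the
  $1/(L+\varepsilon)^2$ schedule entirely and turns saturated,
  near-zero gradients into full-size destructive kicks.

### Optimizer bookkeeping

Each (module, objective) pair owns its optimizer state, mirroring the one
optimizer instance per training step that a framework implementation
would construct. This matters because adversarial gradients are scaled by
up to 100: if they shared Adam moments with the classification gradients,
the inflated second-moment estimates would mute classification updates
for thousands of iterations.

Two further magnitude choices keep the shared extractor's objectives
balanced at the short training lengths used here. The real/fake objective
moves the extractor at `auxiliary_scale = 0.1` of the base rate (its
heads train at the full rate): three real/fake updates per iteration at
full rate systematically outvote the single classification update and
prevent the classifier from converging. And the confusing step size
follows a triangular schedule (`adversarial_ramp`): zero at the start,
peaking mid-training, and relaxing back to zero. The warm-up is the
usual domain-adversarial practice of letting class structure form before
alignment pressure is applied; the cool-down matters at short training
lengths because the returned weights are the *final* ones — ending at
peak adversarial pressure returns a model mid-perturbation, while the
cool-down hands the last epochs back to the classifier to re-converge on
the aligned features, which substantially reduces run-to-run variance in
the combined method's final accuracy.

### Discriminator batches

A domain discriminator trained only on one-class batches (all-source in
step 2 when no labelled target data exist, all-target in step 3) never
learns the domain boundary: its quickest loss reduction is oscillating
its bias term between the alternating batch labels, leaving its weights —
and therefore the confusion gradient through them — uninformative. We
verified this directly: after such training, a freshly fitted logistic
probe separates source from target features perfectly while the
discriminator sits at chance. Each discriminator step therefore
contrasts its named data with a same-size draw from the other domain
(step 2: labelled data versus unlabelled target; step 3: unlabelled
target versus labelled source). The discriminator loss is then a genuine
two-class domain loss, and confusing it aligns the domains.

## The synthetic study

No public dataset accompanies the protocol, so `nirda` ships a generator
that emulates its design: 19 powder materials (wheat, gluten-free white
and almond flours in three brands each) giving 25 material-brand units
over five allergen classes; five samples per unit with ten spectra per
sample (1250 spectra per sensor per condition at full scale); and two
sensor grids at 1 nm resolution.

Templates are Gaussian absorption-band mixtures over a linear baseline.
Class motifs sit at the standard NIR assignments — carbohydrate O–H first
overtone near 1569–1604 nm, long-chain fatty-acid CH~2~ first overtone
near 1725–1750 nm, water O–H near 1931–1951 nm, protein near
2111–2132 nm — plus a C–H combination band in the long-wave sensor's
range so that sensor also carries class information. Units of a class
share its motif amplitudes and differ by seeded perturbations of centers
(±4 nm), widths and amplitudes (±10%) plus one minor unit-specific band.
Sample-level baseline offsets (sd 0.01 a.u.) are shared between the
stationary and moving acquisition of the same physical sample; replicate
noise is i.i.d. Gaussian per grid point.

Motion is modelled per speed as intensity(λ) =
g·(template(λ) + sample offset) + o + ε, ε ~ N(0, (σ₀·m)²) — a
multiplicative gain, an additive offset, and a noise-multiplier that is
nondecreasing with speed. This is the minimal family consistent with the
observed phenomenology (changed peak intensities, increased noise); it
does not model wavelength-dependent scattering, so passing tests show
transfer under affine-plus-noise shift, not under arbitrary real-world
distortion.

### Calibration of the default shift

The defaults were calibrated once and frozen: class separation
(`separation = 0.35`) makes the static task comfortably solvable
(source accuracy ~100%) while keeping class margins tight enough that the
motion shift causes real target-domain errors, and the speed-dependent
gains/offsets put the TL baseline's moving-condition accuracy well below
its stationary accuracy with most of that loss attributable to the
(alignable) affine shift rather than to noise. We deliberately placed the
default medium-speed shift in the regime where the transfer baseline
loses a large fraction of its accuracy: a multi-layer ReLU network is
close to invariant under mild affine perturbations of its input, so
gentle shifts leave the baseline nearly unimpaired and give adaptation
nothing measurable to recover.

## Ensemble confidence and interpretability

Ensembles train `n_models` (default 5) members differing only by seed.
The prediction is the majority class — ties broken alphabetically, a
deterministic documented rule — and the confidence is the vote share, so
3-of-5 agreement scores 0.6 and unanimity 1.0. `confidence_report()`
tabulates correct/incorrect counts per occupied confidence bin with
within-bin percentages, and `misclassification_breakdown()` lists errors
per (material, predicted class) with confidences sorted descending. A
threshold option (default 0.8) reports the share of predictions at or
above an alert level.

Vote-share confidence is informative when ensemble members err on
*different* spectra — the diversity produced by random initialization —
which happens when errors are borderline cases near class boundaries
(noise-driven, high-accuracy regimes). Under a strong uncorrected domain
shift, members make the *same* systematic mistakes and vote share stops
tracking error probability — a unanimous vote then just means the shift
moved a material consistently across a decision boundary. The
confidence-calibration checks therefore run in the noise-dominated
regime (the package's test suite computes the corresponding per-bin
error tables), and a deployed system should treat vote share as
trustworthy only once domain adaptation has brought accuracy into that
regime.

Permutation importance shuffles one wavelength column across spectra
(`n_repeats` fresh permutations, default 10) and reports the drop in
accuracy from the unpermuted baseline, measured against the ensemble's
majority vote when an ensemble is supplied. Contiguous ranges are
extracted by thresholding at mean + 2 sd of the per-wavelength
importances and merging runs of at least 5 nm — a rule chosen to yield a
handful of ranked ranges; the protocol reports ranges but no extraction
rule. Runs cannot bridge the 1950→2000 nm inter-sensor gap because
contiguity requires 1 nm steps. Slightly negative importances are
permutation noise and are left untruncated.

One caveat inherent to per-wavelength permutation: when a model reads a
feature redundantly from many strongly correlated columns — an absorption
band tens of nanometres wide — permuting any single column can leave
every prediction unchanged, and the whole band scores zero importance
despite being the only class signal. The method localizes features whose
information is concentrated in few columns; the package's
interpretability oracle therefore plants a band about one grid point
wide. On real spectra, wide-band importance should be read as a lower
bound.

## Problem sizes and determinism

The package's own tests and the acceptance script run at reduced scale —
typically 25 units with 2 samples × 2–3 replicates per condition
(100–150 spectra per condition) and 300 epochs, with the deep-ensemble
checks at 5 × 8 replicates (1000 spectra, 500 held-out) and 60 epochs —
sizes chosen so a full run completes on one CPU in minutes while leaving
every qualitative property measurable. Adversarial training at these
sizes is genuinely stochastic: single cells vary by tens of percentage
points across seeds, which is why ordering properties are asserted on
means over three seeds.

Every stochastic function takes a seed and restores the caller's RNG
state on exit; training derives all randomness (initialization, batch
shuffling, latent draws) from `control$seed`, so identical inputs give
bit-identical trained weights. The generator derives per-unit sub-seeds
so single units are reproducible in isolation.

## Known limitations

* The synthetic shift family is affine-plus-noise; real conveyor spectra
  also show scattering and path-length effects the generator does not
  emulate.
* Adversarial runs at desk scale are high-variance; single-cell results
  should not be over-interpreted (the grid runner records per-cell seeds
  so any cell can be reproduced).
* The combined schedule inherits both branches' hyperparameters; its
  stability at short training lengths depends on the auxiliary-rate and
  warm-up choices described above.
* Class imbalance across allergen groups (10 gluten units versus 2
  peanut units) is left unweighted, matching the protocol.
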