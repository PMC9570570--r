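# nirda

Domain adaptation for near-infrared (NIR) spectral classification of
agri-food powders.

## The problem

In-line food-safety monitoring classifies the powder moving along a
conveyor — here into five allergen classes (gluten, gluten-free, peanut,
tree nut, egg) across 25 material-brand units — from its NIR spectrum.
Labelled spectra are cheap to collect from stationary samples in a lab
(the *source domain*) but expensive to collect on a running line (the
*target domain*), and motion changes peak intensities and raises noise,
so a classifier trained on stationary spectra degrades on moving ones.

`nirda` implements adversarial domain adaptation for this transfer. One
shared fully connected feature extractor `F` (256–128–64–32 units, ReLU)
feeds a logistic classifier `C` and two logistic discriminators; a
generator `G` maps latent normal noise to spectra. Four training
procedures are available:

* **TL** — transfer learning: minimise cross-entropy
  `L_C(C(F(x)), y)` on labelled spectra only.
* **DANN** — per iteration, after the classification step, a domain
  discriminator `D` descends its source-vs-target loss `L_D` while `F`
  *ascends* the transformed loss `T(L_D) = −1/(L_D + ε)`, whose gradient
  magnitude `1/(L_D + ε)²` grows as `D` gets accurate — an accurate
  discriminator triggers a large confusing step. At equilibrium the
  features are class-discriminative but domain-invariant.
* **SGAN** — a semisupervised GAN: `F` and a real/fake discriminator
  learn that labelled *and unlabelled target* spectra are real and
  generated spectra fake, while `G` ascends the transformed
  fake-detection loss; unlabelled target data thereby shape the features.
* **SGAN+DANN** — both branches around the one shared `F` and `C`.

Ensembles of independently seeded models vote; the vote share is a
confidence score (3 of 5 agreeing = 0.6). Permutation importance
(accuracy drop when one wavelength column is shuffled) with contiguous
range extraction provides global interpretability. A synthetic generator
— Gaussian absorption-band mixtures with class motifs at the standard
carbohydrate/fat/water/protein NIR bands, plus speed-dependent gain,
offset and noise — emulates the two-sensor study design (1550–1950 nm and
2000–2450 nm at 1 nm) so everything is testable without proprietary data.

## Worked example

Simulate a paired stationary/moving study at the frozen default
conditions, build the study's domain split, train the baseline and the
combined adversarial method, and compare on the held-out moving spectra:

```r
library(nirda)

lib  <- material_library(1)                      # 25 units, 5 classes
pair <- simulate_domain_pair(lib, "medium", n_samples = 2,
                             n_replicates = 3, sensor = "both", seed = 1)
split <- make_domain_split(pair$static, pair$moving,
                           n_labelled_per_unit = 0, seed = 1)
split
#> Domain split (seed 1)
#>   source labelled:   150 spectra
#>   target labelled:   0 spectra
#>   target unlabelled: 75 spectra
#>   target test:       75 spectra

ctl  <- da_control(epochs = 300, seed = 1)
tl   <- da_train(split, "tl", ctl)
comb <- da_train(split, "combined", ctl)

truth <- split$target_test$meta$allergen_class
accuracy(predict(tl, split$target_test), truth)
#> [1] 60
accuracy(predict(comb, split$target_test), truth)
#> [1] 92
```

Both models fit their stationary training data perfectly (`accuracy`
100 on `split$source_labelled`); the numbers above are moving-condition
test accuracies, so the combined adversarial training recovers a large
part of what the motion shift costs the plain baseline. Adversarial runs
at this scale are stochastic: single cells move by tens of points across
seeds, which is why the package's own checks compare 3-seed means.

Ensemble confidence and wavelength importance follow the same pattern:

```r
ens   <- da_ensemble(split, "tl", ctl, n_models = 5)
preds <- predict(ens, split$target_test)        # class, vote share, votes
confidence_report(preds, truth)                 # per-bin correct/incorrect
prof  <- permutation_importance(ens, split$target_test, n_repeats = 5,
                                seed = 1)
extract_important_ranges(prof)                  # ranked contiguous ranges
```

`run_experiment_grid()` fills the method × speed × sensor × labelled
accuracy matrix, and `run_pipeline()` drives
simulate → split → train → ensemble → importance → grid from a YAML
config with a checksummed artifact manifest.

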