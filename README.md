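# songform

Form–function analysis of cross-cultural song corpora in R.

Corpora of vocal music annotated with a geographic region, a **glottocode**
(the languoid — language or dialect — a song was sung in) and one of ten
**behavioral contexts** (dance, healing, love, lullaby, play, procession,
mourning, work, story, praise) raise two recurring questions:

1. **Do songs sound like what they are for?** `songform` predicts a song's
   behavioral context from its acoustic features with a class-balanced
   bootstrap ensemble of L1-penalised multinomial (lasso) classifiers:
   the data are split into *k* partitions; for each held-out partition,
   classifiers are trained on bootstrap resamples drawn so that every
   context contributes the same number of songs; across *S* splits and *B*
   bootstraps every song collects *S × B* votes (250 at the defaults), and
   its modal vote is the prediction. Accuracy is compared against chance
   defined as 1/(number of contexts) — never the base rate — and
   significance comes from a permutation test that re-runs the whole
   ensemble on shuffled labels. Reports include row-normalised confusion
   matrices and per-context signal-detection *d′*.
2. **Where does acoustic variance come from?** For each feature,
   `songform` fits Bayesian hierarchical models with random effects for
   behavioral context, culture (glottocode), phylogeny (Brownian-motion
   covariance on a language tree, i.e. shared branch length, in correlation
   form) and geography (a Gaussian process with kernel exp(−d/ρ) on
   great-circle distances, lengthscale estimated), and reports each term's
   **intra-class correlation** — its share of total variance, computed per
   posterior draw. Comparing phylogeny against geography asks whether
   similarity between cultures' songs reflects vertical descent or
   horizontal, neighbour-to-neighbour transmission. All effects are
   integrated out analytically and the scale parameters sampled by a
   collapsed Gibbs/slice scheme; convergence is gated on split-R̂ < 1.05.

A synthetic-corpus generator (Yule language trees, tree-diffused languoid
coordinates, features built from context + culture + phylogenetic +
geographic + residual components with configurable variances) provides
ground truth for end-to-end validation by parameter recovery, so nothing in
the test suite depends on downloading audio or any external archive.

## Worked example

```r
library(songform)

sc <- simulate_corpus(synth_config(
  n_languages = 16, songs_per_language = 10, n_contexts = 4,
  n_features = 8, sigma2_behavior = 1, sigma2_culture = 0.3,
  sigma2_phylo = 0, sigma2_geo = 0, sigma2_resid = 0.7, seed = 1))

labels <- setNames(sc$corpus$context, sc$corpus$song)
cfg <- ensemble_config(k_partitions = 5, n_boot_per_partition = 5,
                       n_splits = 5,
                       contexts_included = context_tokens()[1:4],
                       penalty_selection = "fixed", seed = 1)
votes <- run_ensemble(standardize_features(sc$features), labels, cfg)
pred <- modal_prediction(votes)
evaluate_predictions(as.character(pred), unname(labels), cfg$contexts_included)
#> <classifier_report> accuracy 0.925 (chance 0.250), 4 contexts
#>          n   hit dprime
#> dance   48 0.938  3.464
#> healing 37 0.865  3.073
#> love    35 0.914  3.512
#> lullaby 40 0.975  3.794
```

With half the feature variance planted in behavioral context, the ensemble
recovers context for 92.5% of songs against a chance level of 25%, and
every context's *d′* is large. On feature `f01` of the same corpus, the
two-term variance model attributes the variance shares to behavior and
culture:

```r
y <- setNames(sc$features$values[, 1], sc$features$song)
ps <- fit_variance_model(y, sc$corpus,
                         model_spec("f01", c("behavior", "culture")))
compute_icc(ps)[, c("component", "icc", "lo95", "hi95")]
#>   component       icc       lo95      hi95
#> 1  behavior 0.5705190 0.27485553 0.8622111
#> 2   culture 0.1149995 0.02512793 0.2812247
#> 3     resid 0.3144814 0.10409397 0.5577183
```

The behavior share's posterior mean (≈ 0.57) brackets the generating value
0.5; `ps$rhat` (max 1.001 here) confirms convergence. The methods vignette
(`vignettes/song-form-and-transmission.Rmd`) documents the models, priors,
sampler, generator and their limitations.

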