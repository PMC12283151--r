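test_that("splits partition all songs into near-equal disjoint folds", {
  ids <- sprintf("s%03d", 1:100)
  sch <- make_splits(ids, k = 10, n_splits = 4, seed = 1)
  expect_equal(dim(sch), c(100L, 4L))
  for (s in 1:4) {
    sizes <- table(sch[, s])
    expect_equal(length(sizes), 10L)
    expect_true(all(sizes == 10L))
  }
  expect_identical(make_splits(ids, 10, 4, seed = 1), sch)

  # pigeonhole: 101 songs over 10 folds gives one fold of 11
  sch2 <- make_splits(sprintf("s%03d", 1:101), 10, 1, seed = 2)
  sizes <- sort(as.integer(table(sch2[, 1])))
  expect_equal(sizes, c(rep(10L, 9), 11L))

  expect_error(make_splits(ids[1:5], k = 10, n_splits = 1), "exceed")
})

test_that("balanced bootstraps draw the same count from every class", {
  labels <- c(rep("a", 3), "b")
  idx <- balanced_bootstrap(labels, 1:4, rule = "max-class", seed = 3)
  expect_equal(sum(labels[idx] == "a"), 3L)
  expect_equal(sum(labels[idx] == "b"), 3L)

  # already balanced: per-class draw count equals the class size
  labels2 <- rep(c("a", "b"), each = 5)
  idx2 <- balanced_bootstrap(labels2, 1:10, seed = 4)
  expect_equal(as.integer(table(labels2[idx2])), c(5L, 5L))

  # min-class downsampling
  idx3 <- balanced_bootstrap(labels, 1:4, rule = "min-class", seed = 5)
  expect_equal(as.integer(table(labels[idx3])), c(1L, 1L))

  expect_error(balanced_bootstrap(c("a", "a", "b"), 1:2), "b")

  # balance exactness on every resample, not on average
  set.seed(6)
  labels4 <- sample(c("a", "b", "c"), 60, TRUE)
  for (rep in 1:25) {
    idx <- balanced_bootstrap(labels4, sample(60, 45))
    expect_equal(length(unique(table(labels4[idx]))), 1L)
  }
})

test_that("bootstrap coverage matches the occupancy formula", {
  # expected fraction of distinct training items drawn at least once:
  # 1 - (1 - 1/n_c)^m for class size n_c and m draws per class
  labels <- rep(c("a", "b"), c(12, 20))
  set.seed(8)
  cov_a <- replicate(1000, {
    idx <- balanced_bootstrap(labels, 1:32)
    length(unique(idx[labels[idx] == "a"])) / 12
  })
  m <- 20  # max-class draw count
  expect_equal(mean(cov_a), 1 - (1 - 1 / 12)^m, tolerance = 0.01)
})

test_that("the lasso classifier separates a separable toy problem", {
  set.seed(10)
  n <- 40
  x <- cbind(sig = c(rnorm(n / 2, -3, 0.1), rnorm(n / 2, 3, 0.1)),
             noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rep(c("dance", "lullaby"), each = n / 2)
  clf <- fit_l1_classifier(x, y, penalty_selection = "cv", seed = 1)
  expect_equal(mean(predict(clf, x) == y), 1)

  # exhaustive penalty-path oracle: some penalty on the fitted path achieves
  # perfect training accuracy, and the selected one is among them
  path_acc <- vapply(seq_along(clf$fit$lambda), function(j) {
    o <- clf; o$lambda_index <- j
    mean(predict(o, x) == y)
  }, numeric(1))
  expect_true(any(path_acc == 1))
  expect_equal(path_acc[clf$lambda_index], 1)
})

test_that("degenerate classifier inputs are rejected or neutral", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_l1_classifier(x, rep("dance", 10)), "one class")
  x_bad <- x; x_bad[1, 1] <- NA
  expect_error(fit_l1_classifier(x_bad, rep(c("a", "b"), 5)), "finite")

  # constant features: nothing to learn; intercept-only model whose class
  # probabilities are the training frequencies (uniform on a balanced set)
  x_const <- matrix(1, 12, 2)
  y <- rep(c("dance", "lullaby", "play"), each = 4)
  clf <- fit_l1_classifier(x_const, y, penalty_selection = "fixed",
                           fixed_lambda = 0.1)
  expect_equal(unname(c(clf$class_probs)), rep(1 / 3, 3))
  expect_equal(unique(predict(clf, x_const)), "dance")
})

test_that("label-permuted training yields chance-level held-out accuracy", {
  set.seed(12)
  accs <- replicate(100, {
    x <- matrix(rnorm(60 * 3), 60, 3)
    y_perm <- sample(rep(c("dance", "lullaby"), each = 30))
    # class-balanced training, mirroring the ensemble's balanced bootstraps
    train <- c(sample(which(y_perm == "dance"), 15),
               sample(which(y_perm == "lullaby"), 15))
    test <- setdiff(seq_len(60), train)
    clf <- fit_l1_classifier(x[train, ], y_perm[train],
                             penalty_selection = "fixed", fixed_lambda = 0.1)
    mean(predict(clf, x[test, ]) == y_perm[test])
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 4 * se)
})

test_that("votes are conserved for every song under any configuration", {
  sc <- quick_corpus(n_contexts = 3, seed = 14, n_languages = 8,
                     songs_per_language = 6, n_features = 3)
  labels <- setNames(sc$corpus$context, sc$corpus$song)
  ft <- standardize_features(sc$features)
  for (cfg in list(
    ensemble_config(k_partitions = 2, n_boot_per_partition = 3, n_splits = 2,
                    contexts_included = context_tokens()[1:3],
                    penalty_selection = "fixed", seed = 1),
    ensemble_config(k_partitions = 4, n_boot_per_partition = 2, n_splits = 3,
                    contexts_included = context_tokens()[1:3],
                    penalty_selection = "fixed", seed = 2))) {
    votes <- run_ensemble(ft, labels, cfg)
    expected <- cfg$n_splits * cfg$n_boot_per_partition
    expect_true(all(rowSums(votes) == expected))
    expect_equal(attr(votes, "votes_per_song"), expected)
    expect_true(all(votes >= 0))
  }
})

test_that("modal predictions take the canonical-order argmax with tie flags", {
  votes <- matrix(c(150, 100, 125, 125), 2, 2, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), c("dance", "lullaby")))
  pred <- modal_prediction(votes)
  expect_equal(unname(pred["s1"]), "dance")
  expect_equal(unname(pred["s2"]), "dance")  # tie: first in vocabulary order
  expect_true(attr(pred, "ties")[["s2"]])
  expect_false(attr(pred, "ties")[["s1"]])

  # column order must not matter: canonical order comes from the vocabulary
  votes_swapped <- votes[, c("lullaby", "dance")]
  pred2 <- modal_prediction(votes_swapped)
  expect_equal(unname(pred2), unname(pred))

  expect_error(modal_prediction(votes * 0), "vote")
})

test_that("evaluation reports accuracy, confusion, and d-prime correctly", {
  contexts <- c("dance", "healing", "love", "lullaby")
  truth <- rep(contexts, each = 25)

  perfect <- evaluate_predictions(truth, truth, contexts)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$chance_level, 0.25)
  expect_equal(unname(diag(perfect$confusion)), rep(1, 4))
  # corrected maximum: z(1 - 1/(2*25)) - z(1/(2*75))
  dmax <- qnorm(1 - 1 / 50) - qnorm(1 / 150)
  expect_equal(unname(perfect$per_context_dprime), rep(dmax, 4))

  # uniform random predictions sit at chance
  set.seed(15)
  rand <- sample(contexts, 4000, TRUE)
  rep_rand <- evaluate_predictions(rand, rep(contexts, each = 1000), contexts)
  expect_lt(abs(rep_rand$accuracy - 0.25), 0.03)

  # standard-normal quantile oracle at H = .84, FA = .16: of 25 dance-true
  # songs 21 are called dance; of 75 non-dance songs 12 are called dance
  pred <- c(rep("dance", 21), rep("healing", 4),        # dance-true
            rep("dance", 12), rep("healing", 13),       # healing-true
            rep("love", 25), rep("lullaby", 25))
  truth2 <- rep(contexts, each = 25)
  rep2 <- evaluate_predictions(pred, truth2, contexts)
  expect_equal(rep2$per_context_hit_rate[["dance"]], 0.84)
  expect_equal(rep2$per_context_fa_rate[["dance"]], 0.16)
  d_oracle <- qnorm(0.84) - qnorm(0.16)
  expect_equal(d_oracle, 1.989, tolerance = 1e-3)
  expect_equal(rep2$per_context_dprime[["dance"]], d_oracle)

  # confusion rows are distributions
  expect_true(all(abs(rowSums(rep2$confusion) - 1) < 1e-9))
})

test_that("no test-partition leakage: altering one test song leaves its fold's other predictions unchanged", {
  sc <- quick_corpus(n_contexts = 2, seed = 16, n_languages = 8,
                     songs_per_language = 5, n_features = 3)
  labels <- setNames(sc$corpus$context, sc$corpus$song)
  x <- standardize_features(sc$features)$values
  cfg <- ensemble_config(k_partitions = 2, n_boot_per_partition = 3,
                         n_splits = 1,
                         contexts_included = context_tokens()[1:2],
                         penalty_selection = "fixed", seed = 31)
  # reproduce the fold assignment run_ensemble will draw
  set.seed(cfg$seed)
  folds <- make_splits(rownames(x), cfg$k_partitions, cfg$n_splits)[, 1]
  marked <- rownames(x)[which(folds == 1L)[1L]]
  same_fold_others <- setdiff(rownames(x)[folds == 1L], marked)

  v1 <- run_ensemble(x, labels, cfg)
  x2 <- x
  x2[marked, ] <- x2[marked, ] + 1000  # unique-value marker
  v2 <- run_ensemble(x2, labels, cfg)
  # models for fold 1 are fit on fold 2 only, so every other fold-1 song
  # must receive identical votes; leakage of the marker would change them
  expect_identical(v1[same_fold_others, ], v2[same_fold_others, ])
  # the marker legitimately reaches fold-2 predictions through training
  expect_false(identical(v1, v2))
})

test_that("ensemble accuracy on shuffled labels centers on 1/|contexts|", {
  sc <- quick_corpus(n_contexts = 4, seed = 18, n_languages = 10,
                     songs_per_language = 6, n_features = 3)
  x <- standardize_features(sc$features)
  cfg <- ensemble_config(k_partitions = 2, n_boot_per_partition = 3,
                         n_splits = 2,
                         contexts_included = context_tokens()[1:4],
                         penalty_selection = "fixed", seed = 0)
  set.seed(19)
  devs <- replicate(50, {
    labels <- setNames(sample(sc$corpus$context), sc$corpus$song)
    cfg$seed <- sample.int(1e6, 1)
    votes <- run_ensemble(x, labels, cfg)
    pred <- modal_prediction(votes, cfg$contexts_included)
    mean(pred == labels[names(pred)]) - 0.25
  })
  se <- sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs)), 4 * se + 0.01)
})

test_that("permutation test applies its stated p-value rules", {
  sc <- quick_corpus(n_contexts = 2, seed = 20, n_languages = 8,
                     songs_per_language = 5, n_features = 3)
  labels <- setNames(sc$corpus$context, sc$corpus$song)
  ft <- standardize_features(sc$features)
  cfg <- ensemble_config(k_partitions = 2, n_boot_per_partition = 3,
                         n_splits = 2,
                         contexts_included = context_tokens()[1:2],
                         penalty_selection = "fixed", seed = 3)
  pr <- permutation_test(ft, labels, cfg, n_perm = 19, seed = 4)
  expect_equal(pr$p_overall,
               mean(pr$permuted_accuracies > pr$observed_accuracy))
  expect_equal(pr$n_ties,
               sum(pr$permuted_accuracies == pr$observed_accuracy))
  pr2 <- permutation_test(ft, labels, cfg, n_perm = 19, seed = 4,
                          rule = "add_one")
  expect_equal(pr2$p_overall,
               (1 + sum(pr2$permuted_accuracies >= pr2$observed_accuracy)) /
                 (1 + pr2$n_perm))
  expect_true(all(pr$p_per_context >= 0 & pr$p_per_context <= 1))
  expect_error(permutation_test(ft, labels, cfg, n_perm = 10), "19")
})
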