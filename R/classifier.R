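#' Ensemble classifier configuration
#'
#' Settings for the class-balanced bootstrap ensemble of L1-penalised
#' multinomial models: the data are split into `k_partitions` folds; each
#' fold in turn is held out as a test partition while `n_boot_per_partition`
#' classifiers are trained on class-balanced bootstrap resamples of the
#' remaining folds; the whole procedure repeats for `n_splits` independent
#' random splits, so every song accrues exactly
#' `n_splits * n_boot_per_partition` votes (250 at the defaults).
#'
#' @param k_partitions Number of test-train folds per split. Default 10.
#' @param n_boot_per_partition Bootstrap classifiers per test partition.
#'   Default 10.
#' @param n_splits Number of independent random splits. Default 25.
#' @param contexts_included Contexts to classify (canonical-order subset of
#'   the vocabulary). Default: all ten.
#' @param balance_target `"max-class"` (each context contributes as many
#'   draws as the largest training class; oversampling, default) or
#'   `"min-class"` (downsampling to the smallest class).
#' @param penalty_selection `"cv"` (penalty chosen by `nfolds`-fold
#'   cross-validated deviance within each bootstrap resample, default) or
#'   `"fixed"` (use `fixed_lambda`).
#' @param nfolds Inner cross-validation folds for penalty selection.
#'   Default 5.
#' @param fixed_lambda Penalty used when `penalty_selection = "fixed"`.
#' @param seed Integer seed for the whole ensemble run.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(k_partitions = 10L, n_boot_per_partition = 10L,
                            n_splits = 25L,
                            contexts_included = context_tokens(),
                            balance_target = c("max-class", "min-class"),
                            penalty_selection = c("cv", "fixed"),
                            nfolds = 5L, fixed_lambda = 0.05, seed = 1L) {
  if (k_partitions < 2L) stop("k_partitions must be >= 2")
  structure(list(
    k_partitions = as.integer(k_partitions),
    n_boot_per_partition = as.integer(n_boot_per_partition),
    n_splits = as.integer(n_splits),
    contexts_included = contexts_included,
    balance_target = match.arg(balance_target),
    penalty_selection = match.arg(penalty_selection),
    nfolds = as.integer(nfolds), fixed_lambda = fixed_lambda,
    seed = as.integer(seed)
  ), class = "ensemble_config")
}

#' Random test-train partition schemes
#'
#' For each of `n_splits` independent splits, assigns every song to one of
#' `k` disjoint partitions whose sizes differ by at most one.
#'
#' @param song_ids Character vector of song ids.
#' @param k Number of partitions per split.
#' @param n_splits Number of independent splits.
#' @param seed Optional integer seed.
#' @return Integer matrix `length(song_ids) x n_splits` of fold labels in
#'   1..k, with `song_ids` as rownames.
#' @export
make_splits <- function(song_ids, k, n_splits, seed = NULL) {
  n <- length(song_ids)
  if (k > n) stop("k must not exceed the number of songs")
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0L, n, n_splits, dimnames = list(song_ids, NULL))
  for (s in seq_len(n_splits)) {
    out[, s] <- sample(rep_len(seq_len(k), n))
  }
  out
}

#' Class-balanced bootstrap resample
#'
#' Samples with replacement within each context so that every context
#' contributes exactly `m` draws, where `m` is the largest (rule
#' `"max-class"`) or smallest (`"min-class"`) training class size.
#'
#' @param labels Character vector of context labels for all songs.
#' @param train_indices Indices of the training songs.
#' @param rule Balance rule, `"max-class"` (default) or `"min-class"`.
#' @param seed Optional integer seed.
#' @return Integer vector of resampled training indices of length
#'   `m * n_contexts`, grouped by context.
#' @export
balanced_bootstrap <- function(labels, train_indices,
                               rule = c("max-class", "min-class"),
                               seed = NULL) {
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  tr_labels <- labels[train_indices]
  classes <- unique(labels)
  sizes <- vapply(classes, function(cl) sum(tr_labels == cl), integer(1L))
  if (any(sizes == 0L))
    stop("context(s) with no training examples: ",
         paste(classes[sizes == 0L], collapse = ", "))
  m <- if (rule == "max-class") max(sizes) else min(sizes)
  unlist(lapply(classes, function(cl) {
    pool <- train_indices[tr_labels == cl]
    pool[sample.int(length(pool), m, replace = TRUE)]
  }), use.names = FALSE)
}

#' Fit one L1-penalised multinomial classifier
#'
#' A single multinomial (softmax) logistic model with lasso penalty, fitted
#' with \pkg{glmnet}. Features are standardized internally using the
#' training data only; the penalty is chosen by internal cross-validated
#' deviance (or fixed).
#'
#' @param features Numeric matrix (rows = songs, >= 2 columns).
#' @param labels Character labels; at least two classes must be present.
#' @param penalty_selection `"cv"` or `"fixed"`.
#' @param nfolds Folds for `"cv"`.
#' @param fixed_lambda Penalty for `"fixed"`.
#' @param seed Optional integer seed (affects inner CV fold assignment).
#' @return An `l1_classifier` with a [predict()][predict.l1_classifier()]
#'   method returning labels.
#' @export
fit_l1_classifier <- function(features, labels,
                              penalty_selection = c("cv", "fixed"),
                              nfolds = 5L, fixed_lambda = 0.05,
                              seed = NULL) {
  penalty_selection <- match.arg(penalty_selection)
  if (!is.null(seed)) set.seed(seed)
  if (any(!is.finite(features))) stop("non-finite feature values")
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop("degenerate training set: only one class present")
  y <- factor(labels)
  if (all(apply(features, 2L, var) == 0)) {
    # nothing to learn: intercept-only model predicting class frequencies
    freq <- table(y) / length(y)
    return(structure(list(fit = NULL, lambda = NA_real_,
                          lambda_index = NA_integer_,
                          classes = levels(y), class_probs = c(freq),
                          penalty_selection = "intercept-only"),
                     class = "l1_classifier"))
  }
  # two classes are a binomial special case of the multinomial model
  fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
  # small balanced resamples routinely trip glmnet's small-class warning;
  # it is expected here and would otherwise flood ensemble runs
  quiet_small <- function(expr) withCallingHandlers(
    expr,
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (penalty_selection == "cv") {
    cv <- quiet_small(glmnet::cv.glmnet(features, y, family = fam,
                                        type.measure = "deviance",
                                        nfolds = nfolds,
                                        standardize = TRUE, nlambda = 30L))
    fit <- cv$glmnet.fit
    lambda <- cv$lambda.min
  } else {
    # short warm-started path ending at the requested penalty
    fit <- quiet_small(glmnet::glmnet(features, y, family = fam,
                                      standardize = TRUE,
                                      lambda = fixed_lambda * c(4, 2, 1),
                                      thresh = 1e-5))
    lambda <- fixed_lambda
  }
  structure(list(fit = fit, lambda = lambda,
                 lambda_index = which.min(abs(fit$lambda - lambda)),
                 classes = levels(y),
                 penalty_selection = penalty_selection),
            class = "l1_classifier")
}

#' Predict context labels from a fitted L1 classifier
#'
#' Scores are evaluated at the fitted model's selected point on the penalty
#' path; exact score ties go to the first class in factor-level order.
#'
#' @param object An `l1_classifier`.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Character vector of predicted context labels.
#' @export
predict.l1_classifier <- function(object, newdata, ...) {
  fit <- object$fit
  if (is.null(fit)) {
    # intercept-only fallback: most frequent training class, first-level
    # tie-break
    win <- object$classes[which.max(object$class_probs)]
    return(rep(win, nrow(newdata)))
  }
  j <- object$lambda_index
  if (inherits(fit, "lognet")) {
    sc <- fit$a0[j] + drop(newdata %*% fit$beta[, j])
    # positive linear predictor means the second class
    object$classes[(sc > 0) + 1L]
  } else {
    scores <- vapply(seq_along(object$classes), function(k)
      fit$a0[k, j] + drop(newdata %*% fit$beta[[k]][, j]),
      numeric(nrow(newdata)))
    if (nrow(newdata) == 1L) scores <- matrix(scores, 1L)
    object$classes[apply(scores, 1L, which.max)]
  }
}

#' Run the balanced-bootstrap classifier ensemble
#'
#' For each random split and each held-out test partition, fits
#' `n_boot_per_partition` classifiers on class-balanced bootstrap resamples
#' of the remaining partitions and records each classifier's prediction for
#' every test song. Every song accrues exactly
#' `n_splits * n_boot_per_partition` votes.
#'
#' @param features A `feature_table` or numeric matrix with song-id
#'   rownames.
#' @param labels Named character vector (song id -> context) or unnamed
#'   vector aligned to the feature rows.
#' @param cfg An [ensemble_config()].
#' @return A `vote_matrix`: integer matrix songs x contexts (canonical
#'   context order) with attribute `votes_per_song`.
#' @export
run_ensemble <- function(features, labels, cfg = ensemble_config()) {
  x <- if (inherits(features, "feature_table")) features$values else features
  if (is.null(names(labels))) names(labels) <- rownames(x)
  keep <- names(labels)[labels %in% cfg$contexts_included]
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  n <- nrow(x)
  contexts <- cfg$contexts_included
  set.seed(cfg$seed)
  folds <- make_splits(rownames(x), cfg$k_partitions, cfg$n_splits)
  votes <- matrix(0L, n, length(contexts),
                  dimnames = list(rownames(x), contexts))
  for (s in seq_len(cfg$n_splits)) {
    fold <- folds[, s]
    for (f in seq_len(cfg$k_partitions)) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      for (b in seq_len(cfg$n_boot_per_partition)) {
        bb <- balanced_bootstrap(labels, train_idx,
                                 rule = cfg$balance_target)
        clf <- fit_l1_classifier(x[bb, , drop = FALSE], labels[bb],
                                 penalty_selection = cfg$penalty_selection,
                                 nfolds = cfg$nfolds,
                                 fixed_lambda = cfg$fixed_lambda)
        pred <- predict(clf, x[test_idx, , drop = FALSE])
        for (ci in seq_along(contexts)) {
          hit <- test_idx[pred == contexts[ci]]
          votes[hit, ci] <- votes[hit, ci] + 1L
        }
      }
    }
  }
  structure(votes, votes_per_song = cfg$n_splits * cfg$n_boot_per_partition,
            class = c("vote_matrix", class(votes)))
}

#' Modal prediction from an ensemble vote matrix
#'
#' Per-song argmax of the vote counts; ties are broken deterministically in
#' canonical vocabulary order (the order of the vote-matrix columns is
#' irrelevant) and flagged.
#'
#' @param votes A `vote_matrix` (songs x contexts).
#' @param contexts Canonical context order used for tie-breaking; default:
#'   the vocabulary order restricted to the vote-matrix columns.
#' @return Named character vector of modal labels with attribute `ties`
#'   (logical, per song).
#' @export
modal_prediction <- function(votes, contexts = NULL) {
  if (is.null(contexts)) {
    canon <- c(context_tokens(), setdiff(colnames(votes), context_tokens()))
    contexts <- canon[canon %in% colnames(votes)]
  }
  v <- votes[, contexts, drop = FALSE]
  if (any(rowSums(v) <= 0)) stop("every song must have at least one vote")
  idx <- apply(v, 1L, which.max)  # first max = canonical-order tie-break
  ties <- apply(v, 1L, function(r) sum(r == max(r)) > 1L)
  out <- setNames(contexts[idx], rownames(v))
  attr(out, "ties") <- setNames(ties, rownames(v))
  out
}

z_corrected <- function(rate, n) {
  # keep rates away from 0/1 so the normal quantile is finite
  lo <- 1 / (2 * n)
  qnorm(pmin(pmax(rate, lo), 1 - lo))
}

#' Evaluate ensemble predictions
#'
#' Computes overall accuracy, the row-normalized confusion matrix (rows =
#' true context, columns = predicted), per-context hit rates and
#' false-alarm rates, and per-context d-prime
#' \eqn{d' = z(H) - z(FA)} with rates of 0 or 1 replaced by
#' \eqn{1/(2N)} or \eqn{1 - 1/(2N)}. Chance level is defined as the inverse
#' of the number of contexts, never the empirical base rate.
#'
#' @param predicted Character vector of predicted labels.
#' @param true_labels Character vector of true labels, aligned.
#' @param contexts Contexts to report (canonical order).
#' @return A `classifier_report` list: `accuracy`, `chance_level`,
#'   `confusion`, `per_context_hit_rate`, `per_context_fa_rate`,
#'   `per_context_dprime`, `n_per_context`.
#' @export
evaluate_predictions <- function(predicted, true_labels,
                                 contexts = sort(unique(true_labels))) {
  stopifnot(length(predicted) == length(true_labels))
  canon <- c(context_tokens(), setdiff(contexts, context_tokens()))
  contexts <- canon[canon %in% contexts]
  acc <- mean(predicted == true_labels)
  C <- length(contexts)
  confusion <- matrix(NA_real_, C, C, dimnames = list(contexts, contexts))
  hit <- fa <- dpr <- setNames(rep(NA_real_, C), contexts)
  n_per <- setNames(integer(C), contexts)
  for (ci in seq_len(C)) {
    cl <- contexts[ci]
    in_class <- true_labels == cl
    n_c <- sum(in_class)
    n_per[ci] <- n_c
    if (n_c > 0L) {
      confusion[ci, ] <- vapply(contexts, function(p)
        mean(predicted[in_class] == p), numeric(1L))
      hit[ci] <- confusion[ci, ci]
    }
    n_nc <- sum(!in_class)
    if (n_nc > 0L) fa[ci] <- sum(predicted[!in_class] == cl) / n_nc
    if (n_c > 0L && n_nc > 0L)
      dpr[ci] <- z_corrected(hit[ci], n_c) - z_corrected(fa[ci], n_nc)
  }
  structure(list(
    accuracy = acc, chance_level = 1 / C, confusion = confusion,
    per_context_hit_rate = hit, per_context_fa_rate = fa,
    per_context_dprime = dpr, n_per_context = n_per,
    contexts = contexts
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> accuracy %.3f (chance %.3f), %d contexts\n",
              x$accuracy, x$chance_level, length(x$contexts)))
  tab <- data.frame(n = x$n_per_context, hit = round(x$per_context_hit_rate, 3),
                    dprime = round(x$per_context_dprime, 3))
  print(tab)
  invisible(x)
}

#' Permutation test of ensemble classification accuracy
#'
#' Re-runs the full ensemble on uniformly label-shuffled data `n_perm`
#' times. The overall p-value is the proportion of permutations whose
#' modal-prediction accuracy is strictly higher than the observed accuracy
#' (the literal rule), with an add-one smoothed variant available.
#' Per-context p-values compare per-context hit rates against the same
#' permutation runs.
#'
#' @param features Feature table or matrix with song-id rownames.
#' @param labels Named character vector of true contexts.
#' @param cfg An [ensemble_config()].
#' @param n_perm Number of permutations (>= 19). Default 200.
#' @param seed Integer seed.
#' @param rule `"strict"` (proportion strictly higher, default) or
#'   `"add_one"` ((1 + #higher-or-equal) / (1 + n_perm)).
#' @return A `permutation_result` list: `observed_accuracy`,
#'   `permuted_accuracies`, `p_overall`, `p_per_context`, `n_perm`,
#'   `n_ties` (permutations exactly equal to the observed accuracy),
#'   `observed_report`.
#' @export
permutation_test <- function(features, labels, cfg = ensemble_config(),
                             n_perm = 200L, seed = 1L,
                             rule = c("strict", "add_one")) {
  rule <- match.arg(rule)
  if (n_perm < 19L) stop("n_perm must be >= 19 to resolve alpha = 0.05")
  x <- if (inherits(features, "feature_table")) features$values else features
  if (is.null(names(labels))) names(labels) <- rownames(x)
  keep <- names(labels)[labels %in% cfg$contexts_included]
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  contexts <- cfg$contexts_included

  run_once <- function(lab, run_seed) {
    c2 <- cfg
    c2$seed <- run_seed
    votes <- run_ensemble(x, lab, c2)
    pred <- modal_prediction(votes, contexts)
    evaluate_predictions(as.character(pred), unname(lab), contexts)
  }

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_perm + 1L)
  perm_orders <- replicate(n_perm, sample.int(length(labels)),
                           simplify = FALSE)

  obs <- run_once(labels, run_seeds[1L])
  perm_acc <- numeric(n_perm)
  perm_hits <- matrix(NA_real_, n_perm, length(contexts),
                      dimnames = list(NULL, contexts))
  for (p in seq_len(n_perm)) {
    plab <- setNames(unname(labels)[perm_orders[[p]]], names(labels))
    rep_p <- run_once(plab, run_seeds[p + 1L])
    perm_acc[p] <- rep_p$accuracy
    perm_hits[p, ] <- rep_p$per_context_hit_rate
  }

  p_of <- function(observed, permuted) {
    if (rule == "strict") mean(permuted > observed)
    else (1 + sum(permuted >= observed)) / (1 + length(permuted))
  }
  p_ctx <- vapply(seq_along(contexts), function(ci)
    p_of(obs$per_context_hit_rate[ci], perm_hits[, ci]), numeric(1L))

  structure(list(
    observed_accuracy = obs$accuracy,
    permuted_accuracies = perm_acc,
    p_overall = p_of(obs$accuracy, perm_acc),
    p_per_context = setNames(p_ctx, contexts),
    n_perm = n_perm,
    n_ties = sum(perm_acc == obs$accuracy),
    rule = rule,
    observed_report = obs
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed accuracy %.3f, p = %.4g (%s, %d perms)\n",
              x$observed_accuracy, x$p_overall, x$rule, x$n_perm))
  invisible(x)
}
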