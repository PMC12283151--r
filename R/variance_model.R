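#' MCMC control settings
#'
#' @param chains Number of chains. Default 4.
#' @param iter Post-warmup draws per chain. Default 1000.
#' @param warmup Warmup iterations per chain (discarded). Default 1000.
#' @param seed Integer seed.
#' @return An `mcmc_control` list.
#' @export
mcmc_control <- function(chains = 4L, iter = 1000L, warmup = 1000L,
                         seed = 1L) {
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Specification of one variance-partition model
#'
#' @param feature_name Name of the response feature (bookkeeping).
#' @param terms Non-empty subset of
#'   `c("behavior", "culture", "phylogeny", "geography")`.
#' @param prior_scale Scale of the half-normal priors on component standard
#'   deviations (response is standardized). Default 1.
#' @param mcmc An [mcmc_control()].
#' @return A `model_spec` list.
#' @export
model_spec <- function(feature_name = "feature",
                       terms = c("behavior", "culture"),
                       prior_scale = 1, mcmc = mcmc_control()) {
  allowed <- c("behavior", "culture", "phylogeny", "geography")
  terms <- match.arg(terms, allowed, several.ok = TRUE)
  if (length(terms) == 0L) stop("terms must be non-empty")
  structure(list(feature_name = feature_name, terms = terms,
                 prior_scale = prior_scale, mcmc = mcmc),
            class = "model_spec")
}

# generic 1-d slice sampler (Neal 2003, stepping out + shrinkage)
slice_sample_1d <- function(x0, logf, w = 1, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  logy <- f0 + log(runif(1L))
  lower <- x0 - runif(1L) * w
  upper <- lower + w
  steps <- 0L
  while (steps < max_steps && logf(lower) > logy) {
    lower <- lower - w; steps <- steps + 1L
  }
  steps <- 0L
  while (steps < max_steps && logf(upper) > logy) {
    upper <- upper + w; steps <- steps + 1L
  }
  repeat {
    x1 <- runif(1L, lower, upper)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) lower <- x1 else upper <- x1
    if (upper - lower < 1e-12) return(x0)
  }
}

# truncated-normal draw on [0, Inf) with numeric fallback for extreme means
rtruncnorm_pos <- function(mean, sd) {
  p_lo <- pnorm(0, mean, sd)
  if (p_lo < 1 - 1e-10) {
    u <- runif(1L, p_lo, 1)
    x <- qnorm(u, mean, sd)
    if (is.finite(x) && x > 0) return(x)
  }
  # mass almost entirely below zero: tail is approximately exponential
  rate <- max(-mean, sd) / sd^2
  stats::rexp(1L, rate)
}

# half-normal log prior on a scale parameter
log_halfnormal <- function(s, scale) -s^2 / (2 * scale^2)

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, comparing within- and between-chain variance.
#'
#' @param draws Numeric matrix, iterations x chains.
#' @return Scalar R-hat (NA if fewer than 4 draws per chain).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2L, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Fit a Bayesian hierarchical variance-partition model
#'
#' Fits, per feature, the Gaussian group-effects model
#' \deqn{y_s = \alpha + \beta_{c(s)} + u_{\ell(s)} + p_{\ell(s)} + g_{\ell(s)} + \varepsilon_s}
#' with i.i.d. normal context intercepts (behavior), i.i.d. normal languoid
#' intercepts (culture), a tree-structured effect
#' \eqn{p \sim MVN(0, \sigma^2_{phy} K)} with `K` the unit-diagonal Brownian
#' correlation, and a geographic Gaussian process
#' \eqn{g \sim MVN(0, \sigma^2_{geo} \exp(-d/\rho))} whose lengthscale
#' \eqn{\rho} is estimated. Component standard deviations get half-normal
#' priors; \eqn{\rho} gets an inverse-gamma prior scaled to the observed
#' distance range.
#'
#' Sampling uses a Gibbs scheme with conjugate multivariate-normal updates
#' for the (non-centered) effect vectors, truncated-normal and slice updates
#' for the scales interleaved in both parameterizations
#' (ancillarity-sufficiency interweaving, which mixes well whether a
#' component's variance is large or near zero), and slice updates for
#' \eqn{\log\rho}. Convergence is gated on split R-hat < 1.05 for every
#' retained parameter; non-convergence flags the result rather than
#' discarding it.
#'
#' @param y Numeric response, named by song id (standardized internally
#'   unless `standardize = FALSE`).
#' @param corpus A `corpus_table` covering the songs in `y`.
#' @param spec A [model_spec()].
#' @param K Unit-diagonal Brownian correlation over languoids (required if
#'   `"phylogeny"` is in the terms).
#' @param D Great-circle distance matrix (km) over languoids (required if
#'   `"geography"` is in the terms). Songs whose languoid lacks coordinates
#'   are dropped with a count.
#' @param standardize Center and scale `y` before fitting. Default TRUE.
#' @return A `posterior_summary` list: `draws` (data.frame of per-iteration
#'   `sigma2_<term>`, `sigma2_resid`, `alpha`, and `rho` if geography is
#'   included, with a `.chain` column), `rhat` (named vector), `converged`
#'   (all R-hat < 1.05), `terms`, `n_songs`, `n_dropped_geo`, `spec`.
#' @export
fit_variance_model <- function(y, corpus, spec = model_spec(),
                               K = NULL, D = NULL, standardize = TRUE) {
  stopifnot(inherits(corpus, "corpus_table"), inherits(spec, "model_spec"))
  terms <- spec$terms
  if (is.null(names(y))) stop("y must be named by song id")
  idx <- match(names(y), corpus$song)
  if (anyNA(idx)) stop("song(s) in y absent from corpus")
  context <- corpus$context[idx]
  languoid <- corpus$glottocode[idx]

  n_dropped <- 0L
  if ("geography" %in% terms) {
    if (is.null(D)) stop("geography term requires a distance matrix D")
    covered <- languoid %in% rownames(D)
    n_dropped <- sum(!covered)
    y <- y[covered]; context <- context[covered]; languoid <- languoid[covered]
  }
  if ("phylogeny" %in% terms) {
    if (is.null(K)) stop("phylogeny term requires a Brownian correlation K")
    miss <- setdiff(unique(languoid), rownames(K))
    if (length(miss) > 0L)
      stop("languoid(s) missing from K: ", paste(miss, collapse = ", "))
  }
  n <- length(y)
  if (n < 10L) stop("too few songs to fit a variance model")
  if (standardize) y <- as.numeric(scale(y)) else y <- as.numeric(y)

  ctx_levels <- sort(unique(context))
  lang_levels <- sort(unique(languoid))
  term_info <- list()
  for (tm in terms) {
    gi <- switch(tm,
      behavior = match(context, ctx_levels),
      match(languoid, lang_levels))
    q <- if (tm == "behavior") length(ctx_levels) else length(lang_levels)
    Cmat <- if (tm == "phylogeny") {
      Ksub <- K[lang_levels, lang_levels, drop = FALSE]
      Ksub + diag(1e-8, length(lang_levels))
    } else NULL  # identity for behavior/culture; geography built per rho
    term_info[[tm]] <- list(group = gi, q = q, C = Cmat)
  }
  q_all <- vapply(term_info, function(ti) ti$q, integer(1L))
  offsets <- cumsum(c(0L, q_all))[seq_along(terms)]
  names(offsets) <- terms
  q_tot <- sum(q_all)
  # Gram matrix U'U of the stacked 0/1 incidence blocks
  Gm <- matrix(0, q_tot, q_tot)
  for (j in seq_along(terms)) for (k in seq_len(j)) {
    tab <- unclass(table(
      factor(term_info[[j]]$group, levels = seq_len(q_all[j])),
      factor(term_info[[k]]$group, levels = seq_len(q_all[k]))))
    ij <- offsets[j] + seq_len(q_all[j]); ik <- offsets[k] + seq_len(q_all[k])
    Gm[ij, ik] <- tab
    if (j != k) Gm[ik, ij] <- t(tab)
  }
  group_sums <- function(x) {
    out <- numeric(q_tot)
    for (j in seq_along(terms)) {
      out[offsets[j] + seq_len(q_all[j])] <-
        rowsum(x, term_info[[j]]$group, reorder = TRUE)
    }
    out
  }
  Dsub <- if ("geography" %in% terms)
    D[lang_levels, lang_levels, drop = FALSE] else NULL
  d_pos <- if (!is.null(Dsub)) Dsub[upper.tri(Dsub)][Dsub[upper.tri(Dsub)] > 0]
           else NULL
  rho_med <- if (!is.null(d_pos) && length(d_pos) > 0) median(d_pos) else 1
  # inverse-gamma prior on rho: shape 3, mean = median inter-languoid distance
  rho_shape <- 3; rho_scale <- rho_med * (rho_shape - 1)
  log_rho_prior <- function(rho)
    -(rho_shape + 1) * log(rho) - rho_scale / rho

  mc <- spec$mcmc
  s0 <- spec$prior_scale
  n_keep <- mc$iter
  total <- mc$warmup + mc$iter
  par_names <- c(paste0("sigma2_", sub("phylogeny", "phylo",
                                       sub("geography", "geo", terms))),
                 "sigma2_resid", "alpha",
                 if ("geography" %in% terms) "rho")
  draws_all <- vector("list", mc$chains)
  singular_geo <- FALSE

  has_geo <- "geography" %in% terms
  # per-term transform A_j: C_j = A_j A_j' (lower Cholesky factor; NULL = I)
  A_tr <- lapply(seq_along(terms), function(j) {
    if (terms[j] == "phylogeny") t(chol(term_info[[j]]$C)) else NULL
  })
  geo_j <- match("geography", terms)
  geo_cache <- new.env(parent = emptyenv())
  geo_chol <- function(rho) {
    key <- format(rho, digits = 12)
    Lg <- get0(key, envir = geo_cache)
    if (is.null(Lg)) {
      G <- exponential_kernel(Dsub, rho) + diag(1e-8, nrow(Dsub))
      Lg <- t(chol(G))
      if (length(ls(geo_cache)) > 128L)
        rm(list = ls(geo_cache), envir = geo_cache)
      assign(key, Lg, envir = geo_cache)
    }
    Lg
  }
  # transformed Gram matrix B = A' (U'U) A with A = blockdiag(A_j); only the
  # geography rows/columns depend on rho, so complete B matrices are cached
  # per lengthscale
  blk <- function(j) offsets[j] + seq_len(q_all[j])
  B_base <- Gm
  for (j in seq_along(terms)) {
    if (!is.null(A_tr[[j]]) && terms[j] != "geography") {
      B_base[blk(j), ] <- crossprod(A_tr[[j]], B_base[blk(j), , drop = FALSE])
      B_base[, blk(j)] <- B_base[, blk(j), drop = FALSE] %*% A_tr[[j]]
    }
  }
  geo_B_cache <- new.env(parent = emptyenv())
  B_full <- function(rho) {
    if (!has_geo) return(B_base)
    key <- format(rho, digits = 12)
    B <- get0(key, envir = geo_B_cache)
    if (is.null(B)) {
      Lg <- geo_chol(rho)
      B <- B_base
      ig <- blk(geo_j)
      B[ig, ] <- crossprod(Lg, B[ig, , drop = FALSE])
      B[, ig] <- B[, ig, drop = FALSE] %*% Lg
      if (length(ls(geo_B_cache)) > 128L)
        rm(list = ls(geo_B_cache), envir = geo_B_cache)
      assign(key, B, envir = geo_B_cache)
    }
    B
  }
  s_expand <- rep(seq_along(terms), q_all)

  # Marginal likelihood machinery: with all random effects integrated out,
  # y ~ N(alpha 1, V), V = s2res I + U Ct U', Ct = blockdiag(sigma2_k C_k).
  # Writing W = blockdiag(sqrt(sigma2_k/s2res) A_k),
  #   V^{-1} = s2res^{-1} (I - U W M^{-1} W' U'),  M = I + W' U'U W,
  #   log det V = n log s2res + 2 sum log diag chol(M).
  marginal_eval <- function(sig2, s2res, rho) {
    sc <- sqrt(sig2 / s2res)
    svec <- sc[s_expand]
    M <- B_full(rho) * tcrossprod(svec)
    diag(M) <- diag(M) + 1
    ch <- chol(M)
    wt_apply <- function(tx) {
      # W' tx, blockwise
      out <- numeric(q_tot)
      for (j in seq_along(terms)) {
        v <- tx[blk(j)]
        if (has_geo && j == geo_j) v <- crossprod(geo_chol(rho), v)
        else if (!is.null(A_tr[[j]])) v <- crossprod(A_tr[[j]], v)
        out[blk(j)] <- sc[j] * v
      }
      out
    }
    list(
      logdet = n * log(s2res) + 2 * sum(log(diag(ch))),
      # bilinear form x' V^{-1} z from raw inner product and group sums
      bilin = function(xz, tx, tz) {
        ux <- backsolve(ch, wt_apply(tx), transpose = TRUE)
        uz <- if (identical(tx, tz)) ux
              else backsolve(ch, wt_apply(tz), transpose = TRUE)
        (xz - sum(ux * uz)) / s2res
      })
  }

  t_y <- group_sums(y)
  t_1 <- group_sums(rep(1, n))
  yty <- sum(y * y)

  for (chain in seq_len(mc$chains)) {
    set.seed(mc$seed + 7919L * chain)
    # overdispersed initial values
    state <- list(alpha = rnorm(1L, 0, 0.2),
                  sigma = setNames(runif(length(terms), 0.2, 1.2), terms),
                  sigma_res = runif(1L, 0.5, 1.2),
                  rho = rho_med * exp(runif(1L, -0.7, 0.7)))

    keep <- matrix(NA_real_, n_keep, length(par_names),
                   dimnames = list(NULL, par_names))
    for (it in seq_len(total)) {
      # intercept, integrating over all random effects
      ev <- marginal_eval(state$sigma^2, state$sigma_res^2, state$rho)
      a11 <- ev$bilin(n, t_1, t_1)
      a1y <- ev$bilin(sum(y), t_1, t_y)
      prec <- a11 + 1 / 4
      state$alpha <- rnorm(1L, a1y / prec, sqrt(1 / prec))

      r <- y - state$alpha
      t_r <- t_y - state$alpha * t_1
      rtr <- yty - 2 * state$alpha * sum(y) + n * state$alpha^2

      log_marg <- function(sig2, s2res, rho) {
        ev <- marginal_eval(sig2, s2res, rho)
        -0.5 * ev$logdet - 0.5 * ev$bilin(rtr, t_r, t_r)
      }

      # component scales, collapsed slice updates on log sigma
      for (j in seq_along(terms)) {
        logf <- function(x) {
          s2 <- state$sigma^2; s2[j] <- exp(2 * x)
          log_marg(s2, state$sigma_res^2, state$rho) +
            log_halfnormal(exp(x), s0) + x
        }
        state$sigma[j] <- exp(slice_sample_1d(log(state$sigma[j]), logf))
      }

      # residual scale
      logf_res <- function(x)
        log_marg(state$sigma^2, exp(2 * x), state$rho) +
          log_halfnormal(exp(x), s0) + x
      state$sigma_res <- exp(slice_sample_1d(log(state$sigma_res), logf_res,
                                             w = 0.5))

      # geographic lengthscale; a kernel too degenerate to factor has zero
      # posterior density
      if (has_geo) {
        logf_rho <- function(x)
          tryCatch(
            log_marg(state$sigma^2, state$sigma_res^2, exp(x)) +
              log_rho_prior(exp(x)) + x,
            error = function(e) -Inf)
        state$rho <- exp(slice_sample_1d(log(state$rho), logf_rho, w = 0.5))
        # tiny Cholesky pivots signal a near-singular (all-ones-like) kernel
        ch <- tryCatch(chol(geo_kernel(state$rho)), error = function(e) NULL)
        if (is.null(ch) || min(diag(ch))^2 < 1e-6) singular_geo <- TRUE
      }

      if (it > mc$warmup) {
        keep[it - mc$warmup, ] <- c(state$sigma^2, state$sigma_res^2,
                                    state$alpha,
                                    if (has_geo) state$rho)
      }
    }
    keep <- as.data.frame(keep)
    keep$.chain <- chain
    draws_all[[chain]] <- keep
  }

  draws <- do.call(rbind, draws_all)
  rh <- vapply(par_names, function(p)
    split_rhat(matrix(draws[[p]], ncol = mc$chains)), numeric(1L))
  structure(list(
    draws = draws, rhat = rh, converged = all(rh < 1.05, na.rm = TRUE),
    terms = terms, n_songs = n, n_dropped_geo = n_dropped,
    near_singular_geo_kernel = singular_geo,
    spec = spec
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> terms: %s; n = %d; max R-hat = %.3f%s\n",
              paste(x$terms, collapse = "+"), x$n_songs, max(x$rhat),
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Intra-class correlations from a fitted variance model
#'
#' For every posterior draw, each component's ICC is its variance divided by
#' the total (included components + residual); the per-draw shares,
#' including the residual share, sum to one. The point estimate is the
#' posterior mean of the per-draw shares; the share of posterior-mean
#' variances is reported alongside.
#'
#' @param ps A `posterior_summary` from [fit_variance_model()].
#' @param feature_name Optional label for the output rows.
#' @return An `icc_table` data.frame: `feature`, `model_terms`, `component`,
#'   `icc` (posterior mean share), `icc_of_means`, `lo95`, `hi95`,
#'   `rhat_max`, `converged`.
#' @export
compute_icc <- function(ps, feature_name = ps$spec$feature_name) {
  stopifnot(inherits(ps, "posterior_summary"))
  comp_cols <- grep("^sigma2_", names(ps$draws), value = TRUE)
  mat <- as.matrix(ps$draws[comp_cols])
  shares <- mat / rowSums(mat)
  colnames(shares) <- sub("^sigma2_", "", comp_cols)
  q <- apply(shares, 2L, quantile, probs = c(0.025, 0.975))
  mean_var <- colMeans(mat)
  out <- data.frame(
    feature = feature_name,
    model_terms = paste(ps$terms, collapse = "+"),
    component = colnames(shares),
    icc = colMeans(shares),
    icc_of_means = mean_var / sum(mean_var),
    lo95 = q[1L, ], hi95 = q[2L, ],
    rhat_max = max(ps$rhat),
    converged = ps$converged,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("icc_table", "data.frame")
  out
}

#' Run the variance-partition model battery
#'
#' Fits one model per (feature, term set) and stacks the resulting ICC
#' tables. The default battery mirrors a standard escalation: behavior
#' only; culture only; behavior + culture; then adding phylogeny and/or
#' geography to the behavior + culture base.
#'
#' @param features A `feature_table` (response columns are standardized
#'   per model).
#' @param corpus A `corpus_table` aligned with the features.
#' @param tree Optional `phylo` tree (needed for phylogeny terms).
#' @param coords Optional coordinate table (needed for geography terms).
#' @param term_sets List of character vectors of terms. Default: the
#'   six-set battery described above.
#' @param mcmc An [mcmc_control()].
#' @param feature_names Features to model; default all columns.
#' @param prior_scale Half-normal prior scale for component s.d.s.
#' @return An `icc_table` data.frame covering every
#'   (feature, term set, component), with non-converged fits flagged; the
#'   attribute `n_nonconverged` counts them.
#' @export
run_battery <- function(features, corpus, tree = NULL, coords = NULL,
                        term_sets = default_battery(),
                        mcmc = mcmc_control(),
                        feature_names = colnames(features$values),
                        prior_scale = 1) {
  stopifnot(inherits(features, "feature_table"))
  needs_phylo <- any(vapply(term_sets, function(ts) "phylogeny" %in% ts,
                            logical(1L)))
  needs_geo <- any(vapply(term_sets, function(ts) "geography" %in% ts,
                          logical(1L)))
  K <- if (needs_phylo) {
    if (is.null(tree)) stop("battery includes phylogeny but no tree given")
    tips <- intersect(tree$tip.label, unique(corpus$glottocode))
    brownian_covariance(tree, tips = tips, normalize = TRUE)
  } else NULL
  D <- if (needs_geo) {
    if (is.null(coords)) stop("battery includes geography but no coords")
    geodesic_distance_matrix(coords)
  } else NULL

  rows <- list()
  for (fn in feature_names) {
    yv <- setNames(features$values[, fn], features$song)
    for (ts in term_sets) {
      sp <- model_spec(feature_name = fn, terms = ts,
                       prior_scale = prior_scale, mcmc = mcmc)
      ps <- fit_variance_model(yv, corpus, sp, K = K, D = D)
      rows[[length(rows) + 1L]] <- compute_icc(ps)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_nonconverged") <-
    length(unique(paste(out$feature, out$model_terms)[!out$converged]))
  class(out) <- c("icc_table", "data.frame")
  out
}

#' Default model battery
#'
#' @return List of term sets: behavior; culture; behavior+culture;
#'   behavior+culture+phylogeny; behavior+culture+geography;
#'   behavior+culture+phylogeny+geography.
#' @export
default_battery <- function() {
  list("behavior", "culture", c("behavior", "culture"),
       c("behavior", "culture", "phylogeny"),
       c("behavior", "culture", "geography"),
       c("behavior", "culture", "phylogeny", "geography"))
}
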