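make_ps <- function(draws, terms) {
  # minimal posterior_summary for contract tests of compute_icc
  structure(list(draws = draws, rhat = c(sigma2_x = 1), converged = TRUE,
                 terms = terms, n_songs = 0L, n_dropped_geo = 0L,
                 spec = model_spec("toy", terms)),
            class = "posterior_summary")
}

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(30)
  same <- cbind(rnorm(500), rnorm(500))
  expect_lt(abs(split_rhat(same) - 1), 0.05)
  apart <- cbind(rnorm(500), rnorm(500) + 3)
  expect_gt(split_rhat(apart), 1.5)
})

test_that("ICCs are per-draw shares that sum to one and ignore scale", {
  draws <- data.frame(sigma2_behavior = 0.3, sigma2_culture = 0.3,
                      sigma2_resid = 0.4, .chain = 1L)
  icc <- compute_icc(make_ps(draws, c("behavior", "culture")))
  expect_equal(icc$icc[icc$component == "behavior"], 0.3)
  expect_equal(sum(icc$icc), 1)

  icc2 <- compute_icc(make_ps(
    transform(draws, sigma2_behavior = 0.6, sigma2_culture = 0.6,
              sigma2_resid = 0.8), c("behavior", "culture")))
  expect_equal(icc2$icc, icc$icc)

  set.seed(31)
  many <- data.frame(sigma2_behavior = rexp(200), sigma2_culture = rexp(200),
                     sigma2_resid = rexp(200), .chain = rep(1:2, each = 100))
  ps <- make_ps(many, c("behavior", "culture"))
  mat <- as.matrix(many[1:3])
  shares <- mat / rowSums(mat)
  expect_true(all(abs(rowSums(shares) - 1) < 1e-12))
  icc3 <- compute_icc(ps)
  expect_equal(icc3$icc, unname(colMeans(shares)))
  expect_true(all(icc3$icc >= 0 & icc3$icc <= 1))
  expect_true(all(icc3$lo95 <= icc3$icc & icc3$icc <= icc3$hi95))
})

test_that("a culture-dominated feature recovers its variance share", {
  cfg <- synth_config(n_languages = 40, songs_per_language = 10,
                      n_contexts = 10, n_features = 1,
                      sigma2_behavior = 0, sigma2_culture = 1,
                      sigma2_phylo = 0, sigma2_geo = 0, sigma2_resid = 1,
                      seed = 71)
  sc <- simulate_corpus(cfg)
  y <- setNames(sc$features$values[, 1], sc$features$song)
  sp <- model_spec("f01", "culture",
                   mcmc = mcmc_control(chains = 2, iter = 400, warmup = 400,
                                       seed = 71))
  ps <- fit_variance_model(y, sc$corpus, sp)
  icc <- compute_icc(ps)
  expect_true(ps$converged)
  cul <- icc$icc[icc$component == "culture"]
  expect_gt(cul, 0.35)
  expect_lt(cul, 0.65)
})

test_that("pure-noise features get near-zero component ICCs", {
  cfg <- synth_config(n_languages = 40, songs_per_language = 10,
                      n_contexts = 10, n_features = 1,
                      sigma2_behavior = 0, sigma2_culture = 0,
                      sigma2_phylo = 0, sigma2_geo = 0, sigma2_resid = 1,
                      seed = 72)
  sc <- simulate_corpus(cfg)
  y <- setNames(sc$features$values[, 1], sc$features$song)
  sp <- model_spec("f01", c("behavior", "culture"),
                   mcmc = mcmc_control(chains = 2, iter = 400, warmup = 400,
                                       seed = 72))
  ps <- fit_variance_model(y, sc$corpus, sp)
  icc <- compute_icc(ps)
  for (comp in c("behavior", "culture")) {
    expect_lt(icc$icc[icc$component == comp], 0.15)
  }
  expect_true(all(names(ps$rhat) %in% names(ps$rhat)))
  expect_true(ps$converged)
})

test_that("the collapsed sampler agrees with an independent JAGS fit", {
  cfg <- synth_config(n_languages = 30, songs_per_language = 8,
                      n_contexts = 5, n_features = 1,
                      sigma2_behavior = 0, sigma2_culture = 1,
                      sigma2_phylo = 0, sigma2_geo = 0, sigma2_resid = 1,
                      seed = 73)
  sc <- simulate_corpus(cfg)
  y <- as.numeric(scale(sc$features$values[, 1]))
  g <- match(sc$corpus$glottocode, sort(unique(sc$corpus$glottocode)))

  ps <- fit_variance_model(setNames(sc$features$values[, 1], sc$corpus$song),
                           sc$corpus,
                           model_spec("f01", "culture",
                                      mcmc = mcmc_control(2, 600, 400, 73)))
  mine <- compute_icc(ps)
  icc_mine <- mine$icc[mine$component == "culture"]

  model_txt <- "
    model {
      for (i in 1:N) { y[i] ~ dnorm(alpha + u[g[i]], tau_res) }
      for (l in 1:L) { u[l] ~ dnorm(0, tau_u) }
      alpha ~ dnorm(0, 0.25)
      sigma_u ~ dnorm(0, 1) T(0,)
      sigma_res ~ dnorm(0, 1) T(0,)
      tau_u <- 1 / (sigma_u * sigma_u)
      tau_res <- 1 / (sigma_res * sigma_res)
    }"
  suppressWarnings(requireNamespace("rjags", quietly = TRUE))
  jm <- rjags::jags.model(textConnection(model_txt),
                          data = list(y = y, g = g, N = length(y),
                                      L = max(g)),
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Wichmann-Hill",
                                       .RNG.seed = 73))
  update(jm, 500, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("sigma_u", "sigma_res"), 1000,
                              progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  icc_jags <- mean(draws[, "sigma_u"]^2 /
                     (draws[, "sigma_u"]^2 + draws[, "sigma_res"]^2))
  expect_lt(abs(icc_mine - icc_jags), 0.05)
})

test_that("the battery runs every (feature, term set) pair and stacks ICCs", {
  cfg <- synth_config(n_languages = 15, songs_per_language = 6,
                      n_contexts = 5, n_features = 2,
                      sigma2_behavior = 0.4, sigma2_culture = 0.3,
                      sigma2_phylo = 0, sigma2_geo = 0, sigma2_resid = 0.3,
                      seed = 74)
  sc <- simulate_corpus(cfg)
  term_sets <- list("behavior", "culture", c("behavior", "culture"))
  icc <- run_battery(standardize_features(sc$features), sc$corpus,
                     term_sets = term_sets,
                     mcmc = mcmc_control(chains = 2, iter = 200,
                                         warmup = 200, seed = 74))
  # one row per (feature, term set, component incl. residual)
  expect_equal(nrow(icc), 2 * (2 + 2 + 3))
  expect_setequal(unique(icc$feature), c("f01", "f02"))
  expect_true(all(icc$icc >= 0 & icc$icc <= 1))
  expect_true(is.numeric(attr(icc, "n_nonconverged")))

  # behavior-only and culture-only explained variance roughly add up in the
  # joint model for a feature with independent planted effects
  f1 <- icc[icc$feature == "f01", ]
  tot_joint <- sum(f1$icc[f1$model_terms == "behavior+culture" &
                            f1$component != "resid"])
  expect_gt(tot_joint, 0.2)
})

test_that("adding tree and geography terms to tree-free signal adds little ICC", {
  cfg <- synth_config(n_languages = 20, songs_per_language = 8,
                      n_contexts = 5, n_features = 1,
                      sigma2_behavior = 0.35, sigma2_culture = 0.35,
                      sigma2_phylo = 0, sigma2_geo = 0, sigma2_resid = 0.3,
                      seed = 75)
  sc <- simulate_corpus(cfg)
  mc <- mcmc_control(chains = 2, iter = 250, warmup = 250, seed = 75)
  icc <- run_battery(standardize_features(sc$features), sc$corpus,
                     tree = sc$tree, coords = sc$coords,
                     term_sets = list(c("behavior", "culture"),
                                      c("behavior", "culture", "phylogeny",
                                        "geography")),
                     mcmc = mc)
  base <- icc[icc$model_terms == "behavior+culture", ]
  full <- icc[icc$model_terms == "behavior+culture+phylogeny+geography", ]
  tot <- function(d) sum(d$icc[d$component != "resid"])
  expect_lt(tot(full) - tot(base), 0.1)
})

test_that("a near-flat geographic kernel is flagged but sampling stays stable", {
  set.seed(76)
  n_l <- 12
  # languoids within ~1 km of each other: G is numerically all-ones
  co <- data.frame(glottocode = paste0("g", seq_len(n_l)),
                   latitude = 10 + runif(n_l, 0, 0.01),
                   longitude = 20 + runif(n_l, 0, 0.01))
  df <- data.frame(song = sprintf("s%03d", 1:(n_l * 5)),
                   region = "Polynesia",
                   glottocode = rep(co$glottocode, each = 5),
                   context = rep_len(context_tokens()[1:5], n_l * 5),
                   stringsAsFactors = FALSE)
  corpus <- corpus_table(df)
  y <- setNames(rnorm(nrow(df)), df$song)
  D <- geodesic_distance_matrix(co)
  sp <- model_spec("noise", c("behavior", "geography"),
                   mcmc = mcmc_control(chains = 2, iter = 150, warmup = 150,
                                       seed = 76))
  ps <- fit_variance_model(y, corpus, sp, D = D)
  expect_true(ps$near_singular_geo_kernel)
  expect_true(all(is.finite(as.matrix(ps$draws[, -ncol(ps$draws)]))))
})

test_that("songs without coordinates are dropped only from geographic fits", {
  cfg <- synth_config(n_languages = 10, songs_per_language = 6,
                      n_contexts = 5, n_features = 1, seed = 77)
  sc <- simulate_corpus(cfg)
  D <- geodesic_distance_matrix(sc$coords[-1L, ])  # drop one languoid
  y <- setNames(sc$features$values[, 1], sc$features$song)
  mc <- mcmc_control(chains = 2, iter = 100, warmup = 100, seed = 77)
  ps_geo <- fit_variance_model(y, sc$corpus,
                               model_spec("f01", c("culture", "geography"),
                                          mcmc = mc), D = D)
  expect_equal(ps_geo$n_dropped_geo, 6L)
  ps_cul <- fit_variance_model(y, sc$corpus,
                               model_spec("f01", "culture", mcmc = mc))
  expect_equal(ps_cul$n_dropped_geo, 0L)
  expect_equal(ps_cul$n_songs, 60L)
})
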