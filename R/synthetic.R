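#' Configuration for the synthetic-corpus generator
#'
#' Bundles the generative parameters for [simulate_corpus()]: corpus shape
#' (languages, songs per language, contexts, features) and the ground-truth
#' variance components of each acoustic feature. Feature values are
#' generated as the sum of a behavioral-context effect, an i.i.d. per-culture
#' effect, a tree-structured (Brownian) phylogenetic effect, a geographic
#' Gaussian-process effect with exponential kernel, and residual noise.
#'
#' @param n_languages Number of languoids (tree tips). Default 40.
#' @param songs_per_language Songs per languoid: a scalar, or a length-2
#'   range sampled uniformly per languoid. Default 10.
#' @param n_contexts Number of behavioral contexts (>= 2, <= 10 uses the
#'   canonical vocabulary tokens). Default 10.
#' @param n_features Number of acoustic features. Default 38.
#' @param sigma2_behavior,sigma2_culture,sigma2_phylo,sigma2_geo,sigma2_resid
#'   Non-negative variance components; at least one must be positive.
#'   Defaults 0.2 / 0.2 / 0.1 / 0.1 / 0.4.
#' @param geo_lengthscale Exponential-kernel lengthscale in km. Default 1500.
#' @param birth_rate Yule birth rate for the simulated language tree.
#'   Default 1.
#' @param location_diffusion Variance (degrees^2) of coordinate Brownian
#'   diffusion per unit branch length. Default 250.
#' @param context_weights Optional per-context sampling weights to emulate
#'   the uneven context counts of real corpora; default uniform.
#' @param seed Integer seed; every simulation draw derives from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_languages = 40L, songs_per_language = 10L,
                         n_contexts = 10L, n_features = 38L,
                         sigma2_behavior = 0.2, sigma2_culture = 0.2,
                         sigma2_phylo = 0.1, sigma2_geo = 0.1,
                         sigma2_resid = 0.4,
                         geo_lengthscale = 1500, birth_rate = 1,
                         location_diffusion = 250,
                         context_weights = NULL, seed = 1L) {
  sig <- c(behavior = sigma2_behavior, culture = sigma2_culture,
           phylo = sigma2_phylo, geo = sigma2_geo, resid = sigma2_resid)
  if (any(sig < 0)) stop("variance components must be non-negative")
  if (sum(sig) <= 0) stop("at least one variance component must be positive")
  if (n_contexts < 2L) stop("n_contexts must be >= 2")
  if (!is.null(context_weights) && length(context_weights) != n_contexts)
    stop("context_weights must have length n_contexts")
  structure(list(
    n_languages = as.integer(n_languages),
    songs_per_language = as.integer(songs_per_language),
    n_contexts = as.integer(n_contexts), n_features = as.integer(n_features),
    sigma2 = sig, geo_lengthscale = geo_lengthscale,
    birth_rate = birth_rate, location_diffusion = location_diffusion,
    context_weights = context_weights, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Theoretical variance shares of a generator configuration
#'
#' @param cfg A [synth_config()].
#' @return Named numeric vector of shares
#'   (behavior, culture, phylo, geo, resid) summing to 1.
#' @export
theoretical_variance <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  tot <- sum(cfg$sigma2)
  if (tot <= 0) stop("all variance components are zero")
  cfg$sigma2 / tot
}

#' Simulate a pure-birth (Yule) language tree
#'
#' Starts from two lineages at the root; with k extant lineages the next
#' split arrives after an Exponential(k * birth_rate) wait and hits a
#' uniformly chosen lineage. Simulation stops one Exponential(n * birth_rate)
#' wait after the n-th tip appears, so the expected root-to-tip depth is
#' \eqn{\sum_{k=2}^{n} 1/(k\,\lambda)}. The tree is ultrametric by
#' construction.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Birth rate lambda (> 0).
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @return An ultrametric `phylo` tree with tips `L01`, `L02`, ...
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_tips <- as.integer(n_tips)
  n_node <- n_tips - 1L
  # active lineages: parent node id and start time
  parent <- c(n_tips + 1L, n_tips + 1L)
  start <- c(0, 0)
  next_node <- n_tips + 2L
  t <- 0
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  while (length(parent) < n_tips) {
    k <- length(parent)
    t <- t + stats::rexp(1L, rate = k * birth_rate)
    i <- sample.int(k, 1L)
    edges <- rbind(edges, c(parent[i], next_node))
    lens <- c(lens, t - start[i])
    parent <- c(parent[-i], next_node, next_node)
    start <- c(start[-i], t, t)
    next_node <- next_node + 1L
  }
  t_end <- t + stats::rexp(1L, rate = n_tips * birth_rate)
  for (i in seq_along(parent)) {
    edges <- rbind(edges, c(parent[i], i))
    lens <- c(lens, t_end - start[i])
  }
  tree <- list(
    edge = edges, edge.length = lens, Nnode = n_node,
    tip.label = sprintf("L%0*d", max(2L, nchar(n_tips)), seq_len(n_tips)))
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate languoid coordinates by Brownian diffusion on a tree
#'
#' Diffuses (latitude, longitude) independently along branches from a root
#' location, giving tip locations whose spatial autocorrelation mirrors the
#' phylogeny, as real languoid coordinates do. Latitudes are clamped to
#' [-90, 90] and longitudes wrapped into [-180, 180].
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param location_diffusion Variance (degrees^2) per unit branch length.
#' @param seed Optional integer seed.
#' @param root_location Numeric `(latitude, longitude)` of the root.
#' @return Coordinate data.frame (`glottocode`, `latitude`, `longitude`),
#'   one row per tip.
#' @export
simulate_locations <- function(tree, location_diffusion = 250, seed = NULL,
                               root_location = c(0, 0)) {
  validate_language_tree(tree)
  if (location_diffusion < 0) stop("location_diffusion must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  lat <- lon <- numeric(n_all)
  root <- n_tip + 1L
  lat[root] <- root_location[1L]
  lon[root] <- root_location[2L]
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    s <- sqrt(location_diffusion * tree$edge.length[e])
    lat[child] <- lat[par] + rnorm(1L, 0, s)
    lon[child] <- lon[par] + rnorm(1L, 0, s)
  }
  lat_t <- pmin(pmax(lat[seq_len(n_tip)], -90), 90)
  lon_t <- ((lon[seq_len(n_tip)] + 180) %% 360) - 180
  coordinate_table(data.frame(
    glottocode = tree$tip.label, latitude = lat_t, longitude = lon_t,
    stringsAsFactors = FALSE))
}

#' Simulate a full synthetic corpus with known variance components
#'
#' Generates a language tree, coordinates, per-song metadata and an acoustic
#' feature table in which each feature value is
#' \deqn{y = \beta_{c(s)} + u_{\ell(s)} + p_{\ell(s)} + g_{\ell(s)} + \varepsilon_s}
#' with context effects \eqn{\beta_c \sim N(0, \sigma^2_{behavior})},
#' i.i.d. culture effects \eqn{u_\ell \sim N(0, \sigma^2_{culture})},
#' phylogenetic effects \eqn{p \sim MVN(0, \sigma^2_{phylo} K)} (unit-diagonal
#' Brownian correlation), geographic effects
#' \eqn{g \sim MVN(0, \sigma^2_{geo} \exp(-d/\rho))} on great-circle
#' distances, and residual noise. Features are drawn independently given the
#' design; contexts are assigned uniformly at random unless
#' `context_weights` is set.
#'
#' @param cfg A [synth_config()].
#' @return A `synthetic_corpus` list: `corpus` (corpus_table), `features`
#'   (feature_table), `tree`, `coords`, and `truth` (config echo, theoretical
#'   shares, realized per-feature effect vectors).
#' @export
simulate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  tree <- simulate_tree(cfg$n_languages, cfg$birth_rate)
  coords <- simulate_locations(tree, cfg$location_diffusion)
  langs <- tree$tip.label
  L <- length(langs)

  nspl <- cfg$songs_per_language
  songs_per <- if (length(nspl) == 2L) {
    sample(seq(nspl[1L], nspl[2L]), L, replace = TRUE)
  } else rep(nspl, L)
  song_lang <- rep(langs, songs_per)
  n <- length(song_lang)
  song_ids <- sprintf("S%0*d", max(4L, nchar(n)), seq_len(n))

  ctx_tokens <- if (cfg$n_contexts <= 10L) {
    context_tokens()[seq_len(cfg$n_contexts)]
  } else {
    c(context_tokens(), sprintf("context%02d", seq_len(cfg$n_contexts - 10L)))
  }
  w <- cfg$context_weights
  song_ctx <- sample(ctx_tokens, n, replace = TRUE, prob = w)

  # one region per language, arbitrary but valid
  regions <- region_tokens()
  lang_region <- setNames(sample(regions, L, replace = TRUE), langs)

  corpus <- corpus_table(data.frame(
    song = song_ids, region = unname(lang_region[song_lang]),
    glottocode = song_lang, context = song_ctx, stringsAsFactors = FALSE),
    contexts = ctx_tokens)

  sig <- cfg$sigma2
  K <- brownian_covariance(tree, tips = langs, normalize = TRUE)
  D <- geodesic_distance_matrix(coords)
  G <- exponential_kernel(D, cfg$geo_lengthscale)
  chK <- jittered_chol(K)
  chG <- jittered_chol(G)
  lang_idx <- match(song_lang, langs)
  ctx_idx <- match(song_ctx, ctx_tokens)

  vals <- matrix(0, n, cfg$n_features,
                 dimnames = list(song_ids,
                                 sprintf("f%02d", seq_len(cfg$n_features))))
  effects <- vector("list", cfg$n_features)
  for (f in seq_len(cfg$n_features)) {
    beta <- rnorm(cfg$n_contexts, 0, sqrt(sig["behavior"]))
    u <- rnorm(L, 0, sqrt(sig["culture"]))
    p <- sqrt(sig["phylo"]) * drop(crossprod(chK, rnorm(L)))
    g <- sqrt(sig["geo"]) * drop(crossprod(chG, rnorm(L)))
    eps <- rnorm(n, 0, sqrt(sig["resid"]))
    vals[, f] <- beta[ctx_idx] + u[lang_idx] + p[lang_idx] +
      g[lang_idx] + eps
    effects[[f]] <- list(behavior = setNames(beta, ctx_tokens),
                         culture = setNames(u, langs),
                         phylo = setNames(p, langs),
                         geo = setNames(g, langs))
  }

  structure(list(
    corpus = corpus,
    features = feature_table(vals),
    tree = tree,
    coords = coords,
    truth = list(
      note = paste("synthetic stand-in corpus: all generative choices are",
                   "package inventions for validation, not estimates from",
                   "any real corpus"),
      config = unclass(cfg),
      shares = theoretical_variance(cfg),
      effects = effects)
  ), class = "synthetic_corpus")
}

#' Write a synthetic corpus to disk
#'
#' Emits the same CSV/newick formats the loaders read
#' (`metadata.csv`, `features.csv`, `tree.nwk`, `coords.csv`) plus
#' `truth.json` with the generator configuration and true variance shares.
#'
#' @param sc A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_corpus <- function(sc, dir) {
  stopifnot(inherits(sc, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metadata(sc$corpus, file.path(dir, "metadata.csv"))
  write_feature_table(sc$features, file.path(dir, "features.csv"))
  ape::write.tree(sc$tree, file.path(dir, "tree.nwk"))
  write.csv(sc$coords, file.path(dir, "coords.csv"), row.names = FALSE)
  truth <- sc$truth
  truth$effects <- NULL  # realized effects are bulky; keep truth.json small
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
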