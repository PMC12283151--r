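# 32-bit FNV-1a hash of a string; used to fingerprint configs and inputs.
# Arithmetic is done in 16-bit halves so every intermediate stays exactly
# representable in a double.
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (h_lo * p + ((h_hi * p) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

stage_seed <- function(global_seed, stage) {
  # deterministic per-stage substream, keyed by stage name
  (global_seed + sum(utf8ToInt(stage)) * 10007L) %% .Machine$integer.max
}

#' Per-group summaries of one acoustic feature
#'
#' The data behind feature-by-group comparison plots: per-group mean,
#' median, standard deviation and count of a named feature, grouped by
#' behavioral context, language family, or their crossing.
#'
#' @param features A `feature_table`.
#' @param corpus A `corpus_table` covering the feature songs.
#' @param grouping `"context"`, `"family"` or `"context_family"`.
#' @param feature_name Feature column to summarize.
#' @param family_map Named glottocode -> family vector (needed for family
#'   groupings).
#' @return Long data.frame: group column(s), `n`, `mean`, `median`, `sd`.
#' @export
feature_by_group_summary <- function(features, corpus,
                                     grouping = c("context", "family",
                                                  "context_family"),
                                     feature_name,
                                     family_map = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(features, "feature_table"))
  if (!feature_name %in% colnames(features$values))
    stop("unknown feature name: ", feature_name)
  idx <- match(features$song, corpus$song)
  df <- data.frame(value = features$values[, feature_name],
                   context = corpus$context[idx],
                   glottocode = corpus$glottocode[idx],
                   stringsAsFactors = FALSE)
  if (grouping %in% c("family", "context_family")) {
    if (is.null(family_map)) stop("family grouping requires family_map")
    if (is.data.frame(family_map))
      family_map <- setNames(as.character(family_map$family),
                             family_map$glottocode)
    df$family <- unname(family_map[df$glottocode])
    df$family[is.na(df$family)] <- "unknown"
  }
  keys <- switch(grouping,
                 context = "context",
                 family = "family",
                 context_family = c("context", "family"))
  split_key <- interaction(df[keys], drop = TRUE, lex.order = TRUE)
  parts <- split(df, split_key)
  out <- do.call(rbind, lapply(parts, function(p) {
    row <- p[1L, keys, drop = FALSE]
    row$n <- nrow(p)
    row$mean <- mean(p$value)
    row$median <- median(p$value)
    row$sd <- if (nrow(p) > 1L) sd(p$value) else NA_real_
    row
  }))
  rownames(out) <- NULL
  out$feature <- feature_name
  out
}

#' Run the analysis pipeline from a single configuration
#'
#' Executes the requested stages in dependency order
#' (io -> simulate -> summarize / classify / partition -> report) and writes
#' a machine-readable bundle (JSON + CSV) into `out_dir`, stamped with the
#' configuration hash, seed and package version. Identical config + seed
#' reproduce an identical bundle.
#'
#' @param config A named list or path to a JSON config file. Recognised
#'   entries: `stages` (subset of "simulate", "validate", "summarize",
#'   "classify", "partition"), `seed`, `out_dir`, `inputs` (paths:
#'   `metadata`, `features`, `tree`, `coords`, `family_map`), `simulate`
#'   (arguments to [synth_config()]), `classify` (contexts, k_partitions,
#'   n_boot_per_partition, n_splits, n_perm, penalty_selection,
#'   fixed_lambda), `partition` (term_sets or "default", chains, iter,
#'   warmup, feature_names).
#' @return A `report_bundle` list with the per-stage results and
#'   provenance, invisibly also written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  stages <- config$stages %||% "summarize"
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL  # output location is not part of the identity
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA)
  cfg_hash <- fnv1a32(cfg_json)
  t0 <- Sys.time()
  log_lines <- character()
  logit <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS2"),
                    sprintf(...))
    log_lines <<- c(log_lines, line)
  }

  bundle <- list(provenance = list(
    config = config, config_hash = cfg_hash, seed = seed,
    package_version = as.character(utils::packageVersion("songform"))))

  corpus <- features <- tree <- coords <- truth <- NULL
  mark_incomplete <- function(err, stage) {
    if (!is.null(out_dir)) {
      writeLines(c(sprintf("stage: %s", stage), conditionMessage(err)),
                 file.path(out_dir, "INCOMPLETE"))
    }
    stop(sprintf("[stage %s] %s", stage, conditionMessage(err)), call. = FALSE)
  }

  if ("simulate" %in% stages) {
    tryCatch({
      sim_args <- config$simulate %||% list()
      sim_args$seed <- stage_seed(seed, "simulate")
      sc <- do.call(synth_config, sim_args)
      sim <- simulate_corpus(sc)
      corpus <- sim$corpus; features <- sim$features
      tree <- sim$tree; coords <- sim$coords; truth <- sim$truth
      if (!is.null(out_dir)) write_synthetic_corpus(sim, out_dir)
      logit("simulate: %d songs, %d languoids, seed %d",
            nrow(corpus), length(unique(corpus$glottocode)), sim_args$seed)
    }, error = function(e) mark_incomplete(e, "simulate"))
  } else {
    tryCatch({
      inp <- config$inputs %||% list()
      if (!is.null(inp$metadata)) corpus <- load_metadata(inp$metadata)
      if (!is.null(inp$features))
        features <- load_feature_table(inp$features, corpus)
      if (!is.null(inp$tree)) tree <- load_language_tree(inp$tree)
      if (!is.null(inp$coords)) coords <- load_coordinates(inp$coords)
      logit("io: loaded %s", paste(names(inp), collapse = ", "))
    }, error = function(e) mark_incomplete(e, "io"))
  }

  if ("validate" %in% stages && !is.null(features)) {
    bundle$validation <- list(
      n_songs = nrow(corpus),
      n_features = ncol(features$values),
      zero_variance = features$zero_variance,
      missing_feature_rows = features$missing_songs)
    logit("validate: %d zero-variance feature(s)",
          length(features$zero_variance))
  }

  if ("summarize" %in% stages) {
    tryCatch({
      fam <- config$inputs$family_map
      fam_map <- if (!is.null(fam)) {
        fdf <- read.csv(fam, stringsAsFactors = FALSE)
        setNames(fdf$family, fdf$glottocode)
      } else NULL
      bundle$summary <- unclass(summarize_corpus(corpus, fam_map))
      logit("summarize: %d songs", bundle$summary$n_songs)
    }, error = function(e) mark_incomplete(e, "summarize"))
  }

  if ("classify" %in% stages) {
    tryCatch({
      cc <- config$classify %||% list()
      ec <- ensemble_config(
        k_partitions = cc$k_partitions %||% 10L,
        n_boot_per_partition = cc$n_boot_per_partition %||% 10L,
        n_splits = cc$n_splits %||% 25L,
        contexts_included = cc$contexts %||%
          intersect(context_tokens(), unique(corpus$context)),
        penalty_selection = cc$penalty_selection %||% "cv",
        fixed_lambda = cc$fixed_lambda %||% 0.05,
        seed = stage_seed(seed, "classify"))
      labels <- setNames(corpus$context, corpus$song)
      ft <- standardize_features(features)
      n_perm <- cc$n_perm %||% 0L
      if (n_perm >= 19L) {
        pr <- permutation_test(ft, labels, ec, n_perm = n_perm,
                               seed = stage_seed(seed, "permute"))
        report <- pr$observed_report
        bundle$classification <- list(
          accuracy = report$accuracy, chance_level = report$chance_level,
          p_overall = pr$p_overall, p_per_context = pr$p_per_context,
          n_perm = n_perm, per_context_dprime = report$per_context_dprime,
          seed = ec$seed)
      } else {
        votes <- run_ensemble(ft, labels, ec)
        pred <- modal_prediction(votes, ec$contexts_included)
        report <- evaluate_predictions(as.character(pred),
                                       unname(labels[names(pred)]),
                                       ec$contexts_included)
        bundle$classification <- list(
          accuracy = report$accuracy, chance_level = report$chance_level,
          per_context_dprime = report$per_context_dprime, seed = ec$seed)
        if (!is.null(out_dir)) {
          write.csv(data.frame(song = rownames(votes), unclass(votes),
                               check.names = FALSE),
                    file.path(out_dir, "votes.csv"), row.names = FALSE)
        }
      }
      if (!is.null(out_dir)) {
        write.csv(round(report$confusion, 6),
                  file.path(out_dir, "confusion.csv"))
      }
      logit("classify: accuracy %.3f (chance %.3f), seed %d",
            report$accuracy, report$chance_level, ec$seed)
    }, error = function(e) mark_incomplete(e, "classify"))
  }

  if ("partition" %in% stages) {
    tryCatch({
      pc <- config$partition %||% list()
      ts <- pc$term_sets
      if (is.null(ts) || identical(ts, "default")) ts <- default_battery()
      mc <- mcmc_control(chains = pc$chains %||% 4L,
                         iter = pc$iter %||% 1000L,
                         warmup = pc$warmup %||% 1000L,
                         seed = stage_seed(seed, "partition"))
      fns <- pc$feature_names %||% colnames(features$values)
      icc <- run_battery(standardize_features(features), corpus,
                         tree = tree, coords = coords, term_sets = ts,
                         mcmc = mc, feature_names = fns)
      bundle$icc <- icc
      if (!is.null(out_dir))
        write.csv(icc, file.path(out_dir, "icc.csv"), row.names = FALSE)
      logit("partition: %d fits, %d non-converged",
            length(fns) * length(ts), attr(icc, "n_nonconverged"))
    }, error = function(e) mark_incomplete(e, "partition"))
  }

  bundle$truth <- if (!is.null(truth)) truth[c("config", "shares")] else NULL
  bundle$log <- log_lines
  bundle$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(out_dir)) {
    out <- bundle
    out$icc <- NULL  # icc.csv carries the table
    out$log <- NULL  # run.log carries timestamps; report.json stays
    out$elapsed_sec <- NULL  # byte-identical across reruns
    jsonlite::write_json(out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  class(bundle) <- "report_bundle"
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
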