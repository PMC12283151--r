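#' @importFrom stats median sd var quantile rnorm runif qnorm pnorm setNames
#' @importFrom utils read.csv write.csv
NULL

lower_median <- function(x) {
  # lower of the two middle values for even n, so integer counts stay integer
  if (length(x) == 0L) return(NA_real_)
  sort(x)[floor((length(x) + 1L) / 2L)]
}

#' Load and validate corpus metadata
#'
#' Reads a per-song metadata table (CSV, one row per song) with required
#' columns `song`, `region`, `glottocode`, `type` and validates each field
#' against its controlled vocabulary. Unknown columns are preserved.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param regions Character vector of permitted region tokens
#'   (default [region_tokens()]).
#' @param contexts Character vector of permitted behavioral-context tokens
#'   (default [context_tokens()]).
#' @return A `corpus_table`: a data.frame with columns `song`, `region`,
#'   `glottocode`, `context` plus any extra columns from the file.
#' @export
load_metadata <- function(path, regions = region_tokens(),
                          contexts = context_tokens()) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 fileEncoding = "UTF-8")
  required <- c("song", "region", "glottocode", "type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("metadata schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  names(df)[names(df) == "type"] <- "context"
  corpus_table(df, regions = regions, contexts = contexts)
}

#' Construct a validated corpus table
#'
#' @param df data.frame with columns `song`, `region`, `glottocode`,
#'   `context`; extra columns are preserved.
#' @inheritParams load_metadata
#' @return A `corpus_table` data.frame.
#' @export
corpus_table <- function(df, regions = region_tokens(),
                         contexts = context_tokens()) {
  stopifnot(is.data.frame(df))
  required <- c("song", "region", "glottocode", "context")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("corpus table missing column(s): ", paste(missing, collapse = ", "))
  }
  df$song <- as.character(df$song)
  dup <- unique(df$song[duplicated(df$song)])
  if (length(dup) > 0L) {
    stop("corpus integrity error: duplicate song id(s): ",
         paste(dup, collapse = ", "))
  }
  if (any(!nzchar(df$glottocode) | is.na(df$glottocode))) {
    bad <- which(!nzchar(df$glottocode) | is.na(df$glottocode))
    stop("corpus integrity error: empty glottocode in row(s): ",
         paste(bad, collapse = ", "))
  }
  bad_ctx <- which(!(df$context %in% contexts))
  if (length(bad_ctx) > 0L) {
    stop("vocabulary error: unknown context token(s) ",
         paste(sprintf("'%s' (row %d)", df$context[bad_ctx], bad_ctx),
               collapse = ", "))
  }
  bad_reg <- which(!(df$region %in% regions))
  if (length(bad_reg) > 0L) {
    stop("vocabulary error: unknown region token(s) ",
         paste(sprintf("'%s' (row %d)", df$region[bad_reg], bad_reg),
               collapse = ", "))
  }
  attr(df, "contexts") <- contexts
  attr(df, "regions") <- regions
  class(df) <- c("corpus_table", "data.frame")
  df
}

#' Write corpus metadata to CSV
#'
#' Inverse of [load_metadata()]: round-trips a corpus table bit-exactly.
#'
#' @param corpus A `corpus_table`.
#' @param path Output CSV path.
#' @export
write_metadata <- function(corpus, path) {
  df <- as.data.frame(corpus)
  names(df)[names(df) == "context"] <- "type"
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load an acoustic feature table aligned to a corpus
#'
#' Reads a CSV whose first column is the song id and whose remaining columns
#' are numeric acoustic features, and aligns its rows to the corpus order.
#'
#' @param path Path to the feature CSV (header row mandatory).
#' @param corpus A `corpus_table` the features must align with.
#' @param expected_features Expected number of feature columns; a mismatch
#'   raises a warning, not an error. Default 38.
#' @return A `feature_table`: list with `song` (ids, corpus order),
#'   `values` (songs x features numeric matrix with dimnames),
#'   `standardized` (flag), `zero_variance` (feature names with zero sample
#'   variance), and `missing_songs` (corpus songs absent from the file).
#' @export
load_feature_table <- function(path, corpus, expected_features = 38L) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("feature table needs a song column plus features")
  ids <- as.character(df[[1L]])
  feat <- df[, -1L, drop = FALSE]
  for (j in seq_along(feat)) {
    col <- feat[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(col))
      if (length(bad) > 0L) {
        stop(sprintf(
          "feature parse error: non-numeric value '%s' at row %d, column '%s'",
          col[bad[1L]], bad[1L], names(feat)[j]))
      }
      feat[[j]] <- num
    }
  }
  extra <- setdiff(ids, corpus$song)
  if (length(extra) > 0L) {
    stop("feature alignment error: song(s) not in corpus: ",
         paste(extra, collapse = ", "))
  }
  if (length(expected_features) == 1L && ncol(feat) != expected_features) {
    warning(sprintf("feature table has %d feature columns (expected %d)",
                    ncol(feat), expected_features))
  }
  mat <- as.matrix(feat)
  rownames(mat) <- ids
  present <- corpus$song[corpus$song %in% ids]
  mat <- mat[present, , drop = FALSE]
  missing_songs <- setdiff(corpus$song, ids)
  feature_table(mat, standardized = FALSE, missing_songs = missing_songs)
}

#' Construct a feature table from a numeric matrix
#'
#' @param values Numeric matrix, songs x features, with song ids as rownames
#'   and feature names as colnames.
#' @param standardized Whether columns are already centered/scaled.
#' @param missing_songs Song ids known to lack feature rows.
#' @return A `feature_table` object.
#' @export
feature_table <- function(values, standardized = FALSE,
                          missing_songs = character()) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("feature matrix needs song-id rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate song ids in features")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  zv <- colnames(values)[apply(values, 2L, function(x) var(x) == 0)]
  structure(
    list(song = rownames(values), values = values,
         standardized = standardized, zero_variance = zv,
         missing_songs = missing_songs),
    class = "feature_table")
}

#' Write a feature table to CSV
#'
#' @param ft A `feature_table`.
#' @param path Output CSV path.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(song = ft$song, ft$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d songs x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  if (length(x$zero_variance) > 0L)
    cat("  zero-variance:", paste(x$zero_variance, collapse = ", "), "\n")
  invisible(x)
}

#' Center and scale feature columns
#'
#' Standardizes each feature column to mean 0 and unit sample variance.
#' Zero-variance columns are centered to 0 and flagged rather than divided
#' by zero. Idempotent on an already standardized table.
#'
#' @param ft A `feature_table`.
#' @return A standardized `feature_table` with the `zero_variance` field
#'   listing flagged columns.
#' @export
standardize_features <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (nrow(ft$values) < 2L)
    stop("cannot standardize a single-row feature table (variance undefined)")
  if (any(!is.finite(ft$values))) stop("non-finite feature values")
  vals <- ft$values
  mu <- colMeans(vals)
  s <- apply(vals, 2L, sd)
  zero <- s == 0
  s[zero] <- 1
  out <- sweep(sweep(vals, 2L, mu, "-"), 2L, s, "/")
  res <- feature_table(out, standardized = TRUE,
                       missing_songs = ft$missing_songs)
  res$zero_variance <- colnames(vals)[zero]
  res
}

#' Load a language phylogeny
#'
#' Parses a newick file into an [ape::read.tree()] `phylo` object with tip
#' labels interpreted as glottocodes, and validates branch lengths.
#'
#' @param path Path to a newick file with branch lengths.
#' @return A rooted `phylo` tree.
#' @export
load_language_tree <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("newick format error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick format error: could not parse tree")
  validate_language_tree(tree)
}

validate_language_tree <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree integrity error: branch lengths required")
  if (any(tree$edge.length < 0))
    stop("tree integrity error: negative branch length")
  if (anyDuplicated(tree$tip.label))
    stop("tree integrity error: duplicate tip labels")
  tree
}

#' Load languoid coordinates
#'
#' @param path CSV with columns `glottocode`, `latitude`, `longitude`
#'   (decimal degrees).
#' @return A data.frame with one validated row per glottocode.
#' @export
load_coordinates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("glottocode", "latitude", "longitude")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("coordinate schema error: missing column(s): ",
         paste(missing, collapse = ", "))
  coordinate_table(df)
}

#' Validate a coordinate table
#'
#' @param df data.frame with `glottocode`, `latitude`, `longitude`.
#' @return The validated data.frame.
#' @export
coordinate_table <- function(df) {
  if (anyDuplicated(df$glottocode))
    stop("coordinate integrity error: duplicate glottocode entries")
  if (any(!is.finite(df$latitude)) || any(!is.finite(df$longitude)) ||
      any(df$latitude < -90 | df$latitude > 90) ||
      any(df$longitude < -180 | df$longitude > 180)) {
    stop("coordinate range error: latitude must be in [-90, 90], ",
         "longitude in [-180, 180]")
  }
  df
}

count_summary <- function(tab) {
  counts <- as.integer(tab)
  data.frame(group = names(tab), n = counts, stringsAsFactors = FALSE)
}

#' Summarize a corpus
#'
#' Computes the breadth-and-depth summary of a corpus: song, languoid and
#' language-family counts; per-context and per-region count distributions
#' (medians use the lower-median convention so integer counts give integer
#' medians); deep-sample sizes for named families; and the number of
#' non-empty region-by-context cells.
#'
#' @param corpus A `corpus_table`.
#' @param family_map Named character vector or data.frame
#'   (`glottocode`, `family`) mapping glottocodes to language families.
#'   Unmapped glottocodes are counted under family "unknown" with a warning.
#' @param deep_families Families whose per-family song counts are reported
#'   individually (the deeply sampled families).
#' @return A `corpus_summary` list; see Details.
#' @details Fields: `n_songs`, `n_languoids`, `n_families`, `per_context`
#'   and `per_region` (data.frames of counts plus `median`/`range`
#'   attributes), `deep_sample` (per named family count and their total),
#'   `region_context_coverage` (non-empty cells of the region x context
#'   contingency table), `n_regions_used`, `n_possible_cells`.
#' @export
summarize_corpus <- function(corpus, family_map = NULL,
                             deep_families = c("Indo-European",
                                               "Austronesian",
                                               "Atlantic-Congo")) {
  stopifnot(inherits(corpus, "corpus_table"))
  if (is.data.frame(family_map)) {
    fm <- setNames(as.character(family_map$family), family_map$glottocode)
  } else {
    fm <- family_map
  }
  n_songs <- nrow(corpus)
  languoids <- unique(corpus$glottocode)

  if (is.null(fm)) {
    fam <- rep(NA_character_, n_songs)
  } else {
    fam <- unname(fm[corpus$glottocode])
    if (anyNA(fam) && n_songs > 0L) {
      warning(sprintf("%d glottocode(s) missing from family map, counted as 'unknown'",
                      length(unique(corpus$glottocode[is.na(fam)]))))
      fam[is.na(fam)] <- "unknown"
    }
  }

  ctx_tab <- table(corpus$context)
  reg_tab <- table(corpus$region)
  per_context <- count_summary(ctx_tab)
  per_region <- count_summary(reg_tab)

  cover <- if (n_songs > 0L) {
    sum(table(corpus$region, corpus$context) > 0L)
  } else 0L

  deep <- setNames(integer(length(deep_families)), deep_families)
  if (!is.null(fm)) for (f in deep_families) deep[f] <- sum(fam == f)

  lang_tab <- table(corpus$glottocode)

  structure(list(
    n_songs = n_songs,
    n_languoids = length(languoids),
    n_families = if (is.null(fm) || n_songs == 0L) 0L
                 else length(unique(fam)),
    per_context = per_context,
    context_median = lower_median(per_context$n),
    context_range = if (n_songs > 0L) range(per_context$n) else c(0L, 0L),
    per_region = per_region,
    region_median = lower_median(per_region$n),
    region_range = if (n_songs > 0L) range(per_region$n) else c(0L, 0L),
    languoid_median = lower_median(as.integer(lang_tab)),
    languoid_range = if (n_songs > 0L) range(as.integer(lang_tab)) else c(0L, 0L),
    deep_sample = deep,
    deep_sample_total = sum(deep),
    region_context_coverage = cover,
    n_possible_cells = length(attr(corpus, "regions")) *
      length(attr(corpus, "contexts"))
  ), class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("<corpus_summary> %d songs, %d languoids, %d families\n",
              x$n_songs, x$n_languoids, x$n_families))
  cat(sprintf("  songs per context: median %s, range %s-%s\n",
              x$context_median, x$context_range[1], x$context_range[2]))
  cat(sprintf("  songs per region:  median %s, range %s-%s\n",
              x$region_median, x$region_range[1], x$region_range[2]))
  if (x$deep_sample_total > 0) {
    cat("  deep sample:",
        paste(sprintf("%s %d", names(x$deep_sample), x$deep_sample),
              collapse = ", "),
        sprintf("(total %d)\n", x$deep_sample_total))
  }
  cat(sprintf("  region x context coverage: %d of %d cells\n",
              x$region_context_coverage, x$n_possible_cells))
  invisible(x)
}
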