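# Small fixtures built in code; all tests read/write under tempdir().

fixture_metadata_df <- function() {
  data.frame(
    song = c("NHS2-0001", "NHS2-0002", "NHS2-0003"),
    region = c("Western Africa", "Polynesia", "Scandinavia"),
    glottocode = c("yoru1245", "samo1305", "swed1254"),
    type = c("dance", "lullaby", "work"),
    stringsAsFactors = FALSE)
}

write_fixture_metadata <- function(df = fixture_metadata_df(),
                                   path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

fixture_corpus <- function(df = fixture_metadata_df()) {
  names(df)[names(df) == "type"] <- "context"
  corpus_table(df)
}

write_fixture_features <- function(corpus, n_features = 38L,
                                   path = tempfile(fileext = ".csv"),
                                   seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(nrow(corpus) * n_features), nrow(corpus), n_features)
  df <- data.frame(song = corpus$song, m)
  names(df)[-1L] <- sprintf("f%02d", seq_len(n_features))
  write.csv(df, path, row.names = FALSE)
  path
}

# brute-force shared root-to-MRCA path length between two tips, used as the
# independent oracle for the Brownian covariance
brute_shared_path <- function(tree, tip_a, tip_b) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  path_to_root <- function(tip) {
    node <- which(tree$tip.label == tip)
    edges <- integer(0)
    while (node != root) {
      e <- which(tree$edge[, 2L] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1L]
    }
    edges
  }
  shared <- intersect(path_to_root(tip_a), path_to_root(tip_b))
  sum(tree$edge.length[shared])
}

# quick synthetic corpus for classifier tests
quick_corpus <- function(n_contexts = 4L, seed = 1L, share_behavior = 0.5,
                         n_languages = 16L, songs_per_language = 10L,
                         n_features = 8L) {
  stopifnot(share_behavior <= 1)
  s_b <- share_behavior
  rest <- 1 - share_behavior
  simulate_corpus(synth_config(
    n_languages = n_languages, songs_per_language = songs_per_language,
    n_contexts = n_contexts, n_features = n_features,
    sigma2_behavior = s_b, sigma2_culture = rest * 0.3,
    sigma2_phylo = 0, sigma2_geo = 0, sigma2_resid = rest * 0.7,
    seed = seed))
}
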