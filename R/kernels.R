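#' Brownian-motion covariance from a language tree
#'
#' Under Brownian trait diffusion on a rooted tree, the covariance between
#' two tips equals their shared root-to-MRCA path length. Returns that
#' matrix either raw or normalized to correlation form
#' (\eqn{K_{norm} = D^{-1/2} K D^{-1/2}} with \eqn{D = diag(K)}), which puts
#' the phylogenetic variance component on the same unit scale as the other
#' components of a variance-partition model.
#'
#' @param tree A `phylo` tree with branch lengths (tips = glottocodes).
#' @param tips Tip labels to include, in the desired order. Default: all
#'   tips in tree order.
#' @param normalize If `TRUE` (default) return the unit-diagonal
#'   correlation form; otherwise raw shared path lengths.
#' @return Symmetric covariance matrix with dimnames = tips.
#' @export
brownian_covariance <- function(tree, tips = tree$tip.label,
                                normalize = TRUE) {
  validate_language_tree(tree)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0L)
    stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  K <- ape::vcv.phylo(tree)
  K <- K[tips, tips, drop = FALSE]
  if (normalize) {
    d <- diag(K)
    if (any(d <= 0))
      stop("cannot normalize: tip(s) with zero root-to-tip depth")
    s <- 1 / sqrt(d)
    K <- K * tcrossprod(s)
    diag(K) <- 1
  }
  K
}

#' Great-circle distance matrix between languoids
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param coords Coordinate table (data.frame with `glottocode`,
#'   `latitude`, `longitude`).
#' @return Symmetric distance matrix in kilometres, zero diagonal,
#'   dimnames = glottocodes.
#' @export
geodesic_distance_matrix <- function(coords) {
  coords <- coordinate_table(coords)
  p <- cbind(coords$longitude, coords$latitude)
  D <- geosphere::distm(p, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(D) <- list(coords$glottocode, coords$glottocode)
  diag(D) <- 0
  D
}

#' Exponential geographic covariance kernel
#'
#' \eqn{G = \exp(-D / \rho)}: covariance decays exponentially with
#' great-circle distance, with unit diagonal.
#'
#' @param D Symmetric non-negative distance matrix (km), zero diagonal.
#' @param rho Lengthscale in km; must be positive.
#' @return Covariance matrix of the same dimension as `D`.
#' @export
exponential_kernel <- function(D, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("rho must be a positive scalar (km)")
  if (any(D < 0)) stop("distances must be non-negative")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  G <- exp(-D / rho)
  diag(G) <- 1
  G
}

#' Expand a languoid-level covariance to the song level
#'
#' Each song inherits its languoid's random effect exactly, so the song-level
#' covariance is \eqn{Z K Z^T} with `Z` the 0/1 song-by-languoid incidence
#' matrix.
#'
#' @param K Covariance matrix over languoids (dimnames required).
#' @param song_languoid Named character vector: song id -> languoid.
#' @return Song-level covariance matrix with song ids as dimnames.
#' @export
expand_to_songs <- function(K, song_languoid) {
  langs <- colnames(K)
  unmapped <- setdiff(unique(song_languoid), langs)
  if (length(unmapped) > 0L)
    stop("song(s) map to languoid(s) not covered by the kernel: ",
         paste(unmapped, collapse = ", "))
  idx <- match(song_languoid, langs)
  out <- K[idx, idx, drop = FALSE]
  dimnames(out) <- list(names(song_languoid), names(song_languoid))
  out
}

# Cholesky with small diagonal jitter; errors if still not PSD.
jittered_chol <- function(S, jitter = 1e-8) {
  ch <- tryCatch(chol(S + diag(jitter, nrow(S))), error = function(e) NULL)
  if (is.null(ch))
    stop("kernel is not positive semi-definite even after diagonal jitter")
  ch
}
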