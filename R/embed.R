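#' Convert a similarity matrix to dissimilarities
#'
#' Order-reversing affine map `D(i, j) = max(S) - S(i, j)` for i != j,
#' zero diagonal. This preserves the similarity ordering exactly, which
#' is all the neighbor distributions of the embedding consume.
#'
#' @param S Symmetric `similarity_matrix` (or plain symmetric matrix).
#' @return Symmetric non-negative dissimilarity matrix with zero
#'   diagonal; the `keys` attribute of `S`, if any, is carried over.
#' @export
to_dissimilarity <- function(S) {
  v <- unclass(S)
  attr(v, "keys") <- NULL
  if (!isSymmetric(unname(v), tol = 1e-8))
    stop("similarity matrix must be symmetric", call. = FALSE)
  if (any(!is.finite(v))) stop("non-finite similarity values", call. = FALSE)
  d <- max(v) - v
  diag(d) <- 0
  attr(d, "keys") <- attr(S, "keys")
  d
}

embedding_table <- function(D, Y, method, seed) {
  keys <- attr(D, "keys")
  if (is.null(keys)) {
    nm <- rownames(D)
    keys <- data.frame(key = if (is.null(nm)) as.character(seq_len(nrow(D)))
                             else nm,
                       stringsAsFactors = FALSE)
  }
  out <- cbind(keys, data.frame(dim1 = Y[, 1], dim2 = Y[, 2]))
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  out
}

#' t-SNE embedding of a precomputed dissimilarity matrix
#'
#' Maps each scanpath to a point in the plane so that the pairwise
#' neighbor distributions of the dissimilarities are preserved, by
#' minimizing the Kullback-Leibler divergence between input and embedded
#' neighbor probabilities (Student-t kernel in the embedding). Input
#' affinities are Gaussian kernels on squared dissimilarities with
#' perplexity-calibrated bandwidths; optimization is gradient descent
#' with momentum (0.5 then 0.8 after iteration 250), gain adaptation,
#' learning rate `eta` and early exaggeration (factor 12 for the first
#' quarter of the iterations, at most 250).
#'
#' @param D Dissimilarity matrix, e.g. from [to_dissimilarity()].
#' @param perplexity Target perplexity (effective neighbor count);
#'   requires `nrow(D) > 3 * perplexity`. Default 30.
#' @param iterations Gradient-descent iterations, default 1000.
#' @param seed Integer seed for the random initial configuration
#'   (`N(0, 1e-4)` coordinates); the embedding is deterministic given the
#'   seed.
#' @param eta Learning rate, default 200.
#' @return An embedding data.frame (key columns plus `dim1`, `dim2`) with
#'   attributes `method = "tsne"`, `seed`, `kl_initial`, `kl_final`.
#' @export
tsne_embed <- function(D, perplexity = 30, iterations = 1000, seed = 1,
                       eta = 200) {
  v <- unclass(D)
  n <- nrow(v)
  if (n <= 3 * perplexity)
    stop("perplexity ", perplexity, " too large for ", n,
         " items; choose a smaller perplexity (need N > 3 * perplexity)",
         call. = FALSE)
  set.seed(seed)
  Y0 <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  exagg_iter <- min(250L, as.integer(iterations / 4))
  res <- .tsne_cpp(v, Y0, perplexity, as.integer(iterations), eta,
                   12, exagg_iter)
  out <- embedding_table(D, res$Y, "tsne", seed)
  attr(out, "kl_initial") <- res$kl_initial
  attr(out, "kl_final") <- res$kl_final
  out
}

#' Non-metric MDS embedding (benchmark pathway)
#'
#' Kruskal's non-metric multidimensional scaling into the plane
#' (minimizing stress-1 over monotone transformations of the input
#' dissimilarities), via [MASS::isoMDS()] initialized from classical
#' scaling. Zero dissimilarities between distinct items (which isoMDS
#' rejects) are nudged to a negligible positive value so duplicate items
#' may coincide without error.
#'
#' @param D Dissimilarity matrix.
#' @param seed Integer seed (kept for interface symmetry; the optimizer
#'   itself is deterministic from the classical-scaling start).
#' @return An embedding data.frame with attributes `method = "nmds"`,
#'   `seed` and `stress` (Kruskal stress-1, in percent as returned by
#'   isoMDS).
#' @export
nmds_embed <- function(D, seed = 1) {
  v <- unclass(D)
  attr(v, "keys") <- NULL
  n <- nrow(v)
  eps <- max(v) * 1e-9
  if (eps == 0) eps <- 1e-9
  v[v <= 0] <- eps
  diag(v) <- 0
  set.seed(seed)
  fit <- MASS::isoMDS(stats::as.dist(v), k = 2, trace = FALSE)
  out <- embedding_table(D, fit$points, "nmds", seed)
  attr(out, "stress") <- fit$stress
  out
}
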