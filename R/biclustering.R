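# Bipartite spectral co-clustering of samples and genes.
#
# The expression matrix is viewed as the biadjacency of a bipartite graph
# (samples on one side, genes on the other).  The normalized-cut relaxation
# of that graph is solved either
#   * via the SVD of the degree-normalized matrix Xn = R^{-1/2} X C^{-1/2}
#     (spectral_cocluster, the production path), or
#   * via the generalized eigenproblem L z = lambda D z of the full graph
#     Laplacian (laplacian_cocluster_oracle, an independent small-scale
#     cross-check of the same relaxation).
# Both embed samples and genes jointly in p = ceiling(log2 k) dimensions
# and partition the embedding with k-means.

#' Degree-normalize a nonnegative matrix for bipartite spectral clustering
#'
#' Computes `Xn = R^{-1/2} X C^{-1/2}` where R and C are the diagonal
#' matrices of row and column sums.  The leading singular value of Xn is 1,
#' attained by the trivial pair proportional to the square-rooted degrees.
#'
#' @param X nonnegative numeric matrix with no all-zero row or column.
#' @return list with `Xn`, `r` (row sums) and `c` (column sums).
#' @export
normalize_bipartite <- function(X) {
  X <- as.matrix(X)
  if (any(X < 0)) {
    stop("matrix has negative entries; shift it to be nonnegative first",
         call. = FALSE)
  }
  r <- rowSums(X); cs <- colSums(X)
  if (any(r == 0)) {
    id <- if (!is.null(rownames(X))) rownames(X)[which(r == 0)[1]] else which(r == 0)[1]
    stop("all-zero row: ", id, call. = FALSE)
  }
  if (any(cs == 0)) {
    id <- if (!is.null(colnames(X))) colnames(X)[which(cs == 0)[1]] else which(cs == 0)[1]
    stop("all-zero column: ", id, call. = FALSE)
  }
  Xn <- X / sqrt(r) / rep(sqrt(cs), each = nrow(X))
  list(Xn = Xn, r = r, c = cs)
}

# seeded k-means with restarts; returns stats::kmeans fit
.seeded_kmeans <- function(Z, k, seed, n_init = 50, iter_max = 300) {
  with_stream_seed(seed, "kmeans", {
    stats::kmeans(Z, centers = k, nstart = n_init, iter.max = iter_max)
  })
}

#' Spectral co-clustering of an expression matrix (SVD path)
#'
#' @param expr genes x samples numeric matrix (the on-disk orientation;
#'   internally samples become the rows of X).  Log2 matrices with negative
#'   entries are min-shifted to zero first; the shift is recorded.
#' @param k number of biclusters (>= 2); default 3.
#' @param seed integer seed driving the k-means restarts.
#' @param n_init number of k-means restarts (the reported partition is the
#'   one with minimum within-cluster inertia).
#' @param shift automatically shift negative matrices to be nonnegative.
#' @return an object of class `bicluster_model`: `sample_labels` and
#'   `gene_labels` (named integer vectors in 1..k), `k`, `p`, `Z`, `U`, `V`,
#'   `d` (singular values of Xn), `r`, `c`, `shift`, `inertia`.
#' @export
spectral_cocluster <- function(expr, k = 3, seed = 1L, n_init = 50,
                               shift = TRUE) {
  k <- stopifnot_count(k, "k", min = 2)
  X <- t(as.matrix(expr))  # m samples x n genes
  m <- nrow(X); n <- ncol(X)
  if (k > min(m, n)) stop("k exceeds min(samples, genes)", call. = FALSE)
  offset <- 0
  if (min(X) < 0) {
    if (!shift) stop("matrix has negative entries; shift it first", call. = FALSE)
    offset <- -min(X)
    X <- X + offset
  }
  nb <- normalize_bipartite(X)
  p <- as.integer(ceiling(log2(k)))
  sv <- svd(nb$Xn, nu = p + 1, nv = p + 1)
  U <- sv$u[, 2:(p + 1), drop = FALSE]
  V <- sv$v[, 2:(p + 1), drop = FALSE]
  Z <- rbind(U / sqrt(nb$r), V / sqrt(nb$c))
  km <- .seeded_kmeans(Z, k, seed, n_init = n_init)
  sample_labels <- stats::setNames(km$cluster[seq_len(m)], rownames(X))
  gene_labels <- stats::setNames(km$cluster[m + seq_len(n)], colnames(X))
  structure(list(
    k = k, p = p, sample_labels = sample_labels, gene_labels = gene_labels,
    Z = Z, U = U, V = V, d = sv$d, r = nb$r, c = nb$c, shift = offset,
    inertia = km$tot.withinss, seed = seed, method = "svd"
  ), class = "bicluster_model")
}

#' Co-clustering via the graph-Laplacian generalized eigenproblem (oracle)
#'
#' Independent solution path for cross-validation on small instances: build
#' the (m+n) x (m+n) bipartite adjacency A with X in the off-diagonal
#' blocks, solve `L z = lambda D z` with `L = D - A` (equivalently the
#' eigenproblem of the symmetric normalized Laplacian), keep the p
#' eigenvectors after the constant one, back-transform by D^{-1/2} and
#' cluster with k-means.  Refuses matrices with more than `max_nodes`
#' total rows+columns.
#'
#' @inheritParams spectral_cocluster
#' @param max_nodes refusal bound on m + n (default 400).
#' @export
laplacian_cocluster_oracle <- function(expr, k = 3, seed = 1L, n_init = 50,
                                       shift = TRUE, max_nodes = 400) {
  k <- stopifnot_count(k, "k", min = 2)
  X <- t(as.matrix(expr))
  m <- nrow(X); n <- ncol(X)
  if (m + n > max_nodes) {
    stop("oracle path refuses instances with m + n > ", max_nodes, call. = FALSE)
  }
  if (k > min(m, n)) stop("k exceeds min(samples, genes)", call. = FALSE)
  offset <- 0
  if (min(X) < 0) {
    if (!shift) stop("matrix has negative entries; shift it first", call. = FALSE)
    offset <- -min(X)
    X <- X + offset
  }
  A <- rbind(cbind(matrix(0, m, m), X),
             cbind(t(X), matrix(0, n, n)))
  d <- rowSums(A)
  if (any(d == 0)) stop("isolated node: zero total degree", call. = FALSE)
  # symmetric normalized Laplacian shares eigenvectors (up to D^{1/2}) with
  # the generalized problem L z = lambda D z
  S <- A / sqrt(d) / rep(sqrt(d), each = m + n)
  Lsym <- diag(m + n) - S
  eg <- eigen(Lsym, symmetric = TRUE)
  p <- as.integer(ceiling(log2(k)))
  ord <- order(eg$values)           # ascending: constant vector first
  W <- eg$vectors[, ord[2:(p + 1)], drop = FALSE]
  Z <- W / sqrt(d)
  km <- .seeded_kmeans(Z, k, seed, n_init = n_init)
  sample_labels <- stats::setNames(km$cluster[seq_len(m)], rownames(X))
  gene_labels <- stats::setNames(km$cluster[m + seq_len(n)], colnames(X))
  structure(list(
    k = k, p = p, sample_labels = sample_labels, gene_labels = gene_labels,
    Z = Z, d = eg$values, shift = offset, inertia = km$tot.withinss,
    seed = seed, method = "laplacian"
  ), class = "bicluster_model")
}

#' Reorder a matrix into contiguous checkerboard blocks
#'
#' Sorts samples by their cluster label (ties by original position) and
#' genes likewise, so the planted or fitted biclusters appear as contiguous
#' blocks.  Values are untouched.
#'
#' @param expr the genes x samples matrix the model was fitted on.
#' @param model a `bicluster_model`.
#' @return list with `expr` (permuted matrix), `gene_order`, `sample_order`
#'   (integer permutations such that `expr[gene_order, sample_order]`
#'   reproduces the output).
#' @export
reorder_checkerboard <- function(expr, model) {
  expr <- as.matrix(expr)
  if (nrow(expr) != length(model$gene_labels) ||
      ncol(expr) != length(model$sample_labels)) {
    stop("model dimensions do not match the matrix", call. = FALSE)
  }
  gene_order <- order(model$gene_labels, seq_along(model$gene_labels))
  sample_order <- order(model$sample_labels, seq_along(model$sample_labels))
  list(expr = expr[gene_order, sample_order, drop = FALSE],
       gene_order = gene_order, sample_order = sample_order)
}

#' @export
print.bicluster_model <- function(x, ...) {
  cat(sprintf("bicluster_model (%s path): k = %d, p = %d, %d samples x %d genes\n",
              x$method, x$k, x$p, length(x$sample_labels), length(x$gene_labels)))
  cat("sample cluster sizes:",
      paste(tabulate(x$sample_labels, x$k), collapse = ", "), "\n")
  cat("gene cluster sizes:  ",
      paste(tabulate(x$gene_labels, x$k), collapse = ", "), "\n")
  invisible(x)
}
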