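#' k-nearest-neighbor sets of the samples
#'
#' For each sample (column of `X`) finds the `k_neighbors` other samples at
#' smallest Euclidean distance. Ties in distance are broken by the lower
#' sample index, so the result is deterministic.
#'
#' @param X numeric matrix with samples in columns.
#' @param k_neighbors number of neighbors per sample; must be < ncol(X).
#' @return Integer matrix of dimension n x k_neighbors; row i holds the
#'   indices of sample i's neighbors in order of increasing distance.
#' @export
knn_neighbors <- function(X, k_neighbors) {
  if (any(!is.finite(X))) stop("`X` contains non-finite entries", call. = FALSE)
  n <- ncol(X)
  if (!is.numeric(k_neighbors) || length(k_neighbors) != 1 ||
      k_neighbors < 1 || k_neighbors >= n) {
    stop("`k_neighbors` must be a positive integer smaller than the number of samples",
         call. = FALSE)
  }
  k_neighbors <- as.integer(k_neighbors)
  D2 <- as.matrix(stats::dist(t(X)))^2
  nb <- matrix(0L, n, k_neighbors)
  for (i in seq_len(n)) {
    ord <- order(D2[i, ], seq_len(n))   # secondary key: sample index
    ord <- ord[ord != i]
    nb[i, ] <- ord[seq_len(k_neighbors)]
  }
  nb
}

#' Weight matrix of the sample graph
#'
#' Assigns edge weights to the directed kNN sets under one of three schemes
#' and symmetrizes by the union of directed edges (an edge is kept if i is a
#' neighbor of j or j of i):
#' * `heat_kernel`: \eqn{w_{ij} = \exp(-\|x_i - x_j\|^2 / \sigma)};
#' * `binary`: \eqn{w_{ij} = 1} (0-1 weighting);
#' * `dot_product`: \eqn{w_{ij} = x_i^\top x_j}, clipped at 0 from below
#'   (a Laplacian needs nonnegative weights; a warning is emitted when
#'   clipping occurs).
#'
#' @param neighbors integer matrix from [knn_neighbors()].
#' @param X the matrix the neighbors were computed on (samples in columns).
#' @param scheme one of "heat_kernel", "binary", "dot_product".
#' @param sigma heat-kernel bandwidth; if `NULL` (default) it is set to the
#'   mean squared distance over the kNN edges.
#' @return n x n symmetric nonnegative weight matrix with zero diagonal.
#' @export
weight_matrix <- function(neighbors, X, scheme = c("binary", "heat_kernel", "dot_product"),
                          sigma = NULL) {
  scheme <- match.arg(scheme)
  n <- ncol(X)
  stopifnot(nrow(neighbors) == n)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) A[i, neighbors[i, ]] <- TRUE
  A <- A | t(A)                     # union symmetrization
  diag(A) <- FALSE
  W <- matrix(0, n, n)
  if (scheme == "binary") {
    W[A] <- 1
  } else if (scheme == "heat_kernel") {
    D2 <- as.matrix(stats::dist(t(X)))^2
    if (is.null(sigma)) sigma <- mean(D2[A])
    if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
      stop("`sigma` must be a single positive number", call. = FALSE)
    }
    W[A] <- exp(-D2[A] / sigma)
  } else {
    G <- crossprod(X)
    if (any(G[A] < 0)) {
      warning("dot-product weights below 0 clipped to 0 (Laplacian requires nonnegative weights)")
    }
    W[A] <- pmax(G[A], 0)
  }
  W
}

#' Degree matrix and graph Laplacian
#'
#' Computes the diagonal degree matrix D with \eqn{d_i = \sum_j w_{ij}} and
#' the (unnormalized) Laplacian \eqn{L = D - W}. Row sums of L are zero and L
#' is positive semidefinite for any symmetric nonnegative W.
#'
#' @param W symmetric nonnegative weight matrix.
#' @return List with elements `D` and `L` (both n x n matrices).
#' @export
laplacian <- function(W) {
  if (!isSymmetric(unname(W), tol = 1e-10)) {
    stop("`W` must be symmetric", call. = FALSE)
  }
  if (any(W < 0)) stop("`W` must be nonnegative", call. = FALSE)
  d <- rowSums(W)
  D <- diag(d, nrow = nrow(W))
  list(D = D, L = D - W)
}

#' Build the kNN sample graph model
#'
#' Convenience constructor running [knn_neighbors()], [weight_matrix()] and
#' [laplacian()] and bundling the result. The default neighbor count follows
#' the square-root-of-n rule, \eqn{k' = \mathrm{round}(\sqrt{n})}, and the
#' default weighting is binary (0-1), the least parameter-sensitive scheme.
#'
#' @inheritParams weight_matrix
#' @param X numeric matrix with samples in columns.
#' @param k_neighbors neighbor count k'; default `round(sqrt(ncol(X)))`.
#' @return Object of class `sample_graph`: a list with `n_nodes`,
#'   `k_neighbors`, `scheme`, `sigma`, `W`, `D`, `L`.
#' @export
sample_graph <- function(X, k_neighbors = NULL,
                         scheme = c("binary", "heat_kernel", "dot_product"),
                         sigma = NULL) {
  scheme <- match.arg(scheme)
  n <- ncol(X)
  if (is.null(k_neighbors)) k_neighbors <- max(1L, round(sqrt(n)))
  nb <- knn_neighbors(X, k_neighbors)
  if (scheme == "heat_kernel" && is.null(sigma)) {
    d2 <- vapply(seq_len(n), function(i) {
      colSums((X[, nb[i, ], drop = FALSE] - X[, i])^2)
    }, numeric(ncol(nb)))
    sigma <- mean(d2)
  }
  W <- weight_matrix(nb, X, scheme, sigma)
  DL <- laplacian(W)
  structure(
    list(n_nodes = n, k_neighbors = as.integer(k_neighbors), scheme = scheme,
         sigma = sigma, W = W, D = DL$D, L = DL$L),
    class = "sample_graph"
  )
}

#' @export
print.sample_graph <- function(x, ...) {
  cat(sprintf("sample_graph: %d nodes, k' = %d, %s weighting, %d undirected edges\n",
              x$n_nodes, x$k_neighbors, x$scheme, sum(x$W > 0) / 2))
  invisible(x)
}

#' Write a weighted edge list
#'
#' Exports the upper triangle of a weight (or adjacency) matrix as a
#' tab-separated edge list with columns node_i, node_j, weight.
#'
#' @param W symmetric weight matrix; dimnames, if present, are used as node
#'   identifiers.
#' @param path output file path.
#' @return Invisibly, the data frame that was written.
#' @export
write_edge_list <- function(W, path) {
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  df <- data.frame(node_i = ids[idx[, 1]], node_j = ids[idx[, 2]],
                   weight = W[idx], stringsAsFactors = FALSE)
  df <- df[order(idx[, 1], idx[, 2]), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
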