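#' Rank genes by loading magnitude
#'
#' Scores each gene by the sum of absolute values of its row of the fitted
#' loading matrix U: positive loadings correspond to up-regulated and
#' negative to down-regulated genes, so the absolute values are summed and a
#' larger score marks a more strongly differentially expressed gene. Ties are
#' broken by gene index.
#'
#' @param U genes x k loading matrix from a fit; rownames, if present, are
#'   carried through as gene identifiers.
#' @return Object of class `gene_ranking`: list with `scores` (named by
#'   gene), `order` (gene indices by descending score), `ids`.
#' @examples
#' r <- rank_genes(rbind(g1 = c(1, -2), g2 = c(0.5, 0.5)))
#' r$scores  # g1 = 3, g2 = 1
#' @export
rank_genes <- function(U) {
  if (is.null(dim(U))) U <- matrix(U, ncol = 1)
  ids <- rownames(U)
  if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(U)))
  scores <- rowSums(abs(U))
  names(scores) <- ids
  ord <- order(-scores, seq_along(scores))
  structure(list(scores = scores, order = ord, ids = ids),
            class = "gene_ranking")
}

#' Thresholded absolute-Pearson adjacency
#'
#' Computes the absolute Pearson correlation between all pairs of gene rows
#' and keeps \eqn{a_{ij} = |r_{ij}|} when \eqn{|r_{ij}| \ge \tau} (i != j),
#' zero otherwise. Genes with zero variance across samples cannot be
#' correlated; they are isolated (all-zero row/column) with a warning.
#'
#' @param R l x n matrix: expression of the l selected genes over n samples
#'   (n >= 2).
#' @param threshold edge-inclusion cutoff tau in \[0, 1\] (default 0.8).
#' @return l x l symmetric adjacency matrix with zero diagonal.
#' @export
pcc_adjacency <- function(R, threshold = 0.8) {
  if (ncol(R) < 2) stop("at least 2 samples are required", call. = FALSE)
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  }
  sds <- apply(R, 1, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sprintf("%d zero-variance gene row(s) isolated in the network",
                    sum(flat)))
  }
  A <- matrix(0, nrow(R), nrow(R), dimnames = list(rownames(R), rownames(R)))
  ok <- which(!flat)
  if (length(ok) >= 2) {
    cc <- abs(stats::cor(t(R[ok, , drop = FALSE])))
    cc[cc < threshold] <- 0
    diag(cc) <- 0
    A[ok, ok] <- cc
  }
  A
}

#' Modules and degrees of a thresholded gene network
#'
#' Modules are the connected components of the thresholded co-expression
#' graph, listed by decreasing node count (ties by smallest member index);
#' isolated nodes (degree 0) belong to no module. Degrees count incident
#' edges per node.
#'
#' @param adjacency symmetric adjacency matrix (e.g. from
#'   [pcc_adjacency()]); any nonzero entry is an edge.
#' @return Object of class `gene_network`: list with `modules` (list of
#'   integer index vectors), `module_ids` (same, as identifiers),
#'   `degrees` (named integer vector), `n_edges`.
#' @export
extract_modules <- function(adjacency) {
  ids <- rownames(adjacency)
  if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(adjacency)))
  deg <- as.integer(rowSums(adjacency > 0))
  names(deg) <- ids
  g <- igraph::graph_from_adjacency_matrix(adjacency > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  keep <- which(comp$csize[comp$membership] >= 2)   # drop isolated nodes
  mods <- split(keep, comp$membership[keep])
  if (length(mods)) {
    sizes <- lengths(mods)
    firsts <- vapply(mods, min, integer(1))
    mods <- mods[order(-sizes, firsts)]
    mods <- lapply(mods, unname)
  }
  names(mods) <- NULL
  structure(
    list(modules = mods,
         module_ids = lapply(mods, function(ix) ids[ix]),
         degrees = deg,
         n_edges = sum(adjacency > 0) / 2),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes (%d in modules), %d edges, %d modules\n",
              length(x$degrees), length(unlist(x$modules)), x$n_edges,
              length(x$modules)))
  invisible(x)
}

#' Hub genes per module
#'
#' The highest-degree genes of each module, a common shortlist of candidate
#' key genes.
#'
#' @param network a [extract_modules()] result.
#' @param top number of genes per module (default 10).
#' @return List (one element per module) of named degree vectors, decreasing.
#' @export
hub_genes <- function(network, top = 10) {
  lapply(network$modules, function(ix) {
    d <- network$degrees[ix]
    d <- d[order(-d, ix)]
    utils::head(d, top)
  })
}

#' Choose the number of genes by clustering performance
#'
#' For each candidate count l, refits the model on the submatrix of the
#' currently top-l ranked genes, reruns the K-means harness, and returns the
#' l with the best mean accuracy (ties broken by the smaller l). This is how
#' the size of the co-expression network is chosen when prior labels are
#' available.
#'
#' @param X genes x samples matrix.
#' @param labels prior class labels for the samples.
#' @param ranking a [rank_genes()] result for X's genes.
#' @param candidates integer vector of candidate gene counts (e.g.
#'   seq(500, 2000, by = 100)).
#' @param config a [pl21gpca_config()] used for the refits.
#' @param n_runs,seed passed to [kmeans_harness()].
#' @return List with `l` (chosen count), `acc_mean` (named vector over
#'   candidates).
#' @export
select_gene_count <- function(X, labels, ranking, candidates, config,
                              n_runs = 50, seed = 0) {
  if (length(candidates) == 0) {
    stop("`candidates` must not be empty", call. = FALSE)
  }
  if (any(candidates < 1 | candidates > nrow(X))) {
    stop("`candidates` must lie in 1..nrow(X)", call. = FALSE)
  }
  accs <- vapply(candidates, function(l) {
    sub <- X[ranking$order[seq_len(l)], , drop = FALSE]
    fit <- pl21gpca_fit(sub, config)
    kmeans_harness(fit$V, config$k, labels, n_runs = n_runs, seed = seed)$acc_mean
  }, numeric(1))
  names(accs) <- candidates
  best <- candidates[order(-accs, candidates)][1]
  list(l = best, acc_mean = accs)
}
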