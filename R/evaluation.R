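#' Clustering accuracy with optimal label mapping
#'
#' Fraction of samples whose predicted cluster, after the cluster-to-class
#' assignment that maximizes the total number of matches, equals the prior
#' class. The assignment is the maximum-weight bipartite matching (Hungarian
#' assignment) on the confusion matrix, so the score is invariant to any
#' bijective relabeling of either argument.
#'
#' @param prior vector of prior class labels (any atomic type).
#' @param predicted vector of predicted cluster labels, same length.
#' @return Accuracy as a fraction in \[0, 1\].
#' @examples
#' cluster_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: bijective relabeling
#' cluster_accuracy(c(1, 1, 2, 2), c(1, 2, 2, 2))  # 0.75
#' @export
cluster_accuracy <- function(prior, predicted) {
  if (length(prior) != length(predicted)) {
    stop("`prior` and `predicted` must have the same length", call. = FALSE)
  }
  tab <- table(factor(predicted), factor(prior))
  k1 <- nrow(tab); k2 <- ncol(tab)
  g <- igraph::make_empty_graph(n = k1 + k2, directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, k1), rep(TRUE, k2))
  edges <- rbind(rep(seq_len(k1), each = k2), rep(k1 + seq_len(k2), k1))
  g <- igraph::add_edges(g, as.vector(edges))
  igraph::E(g)$weight <- as.vector(t(tab))
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  m$matching_weight / length(prior)
}

#' Normalized mutual information of two partitions
#'
#' Mutual information of the empirical joint cluster distribution (log base
#' 2) divided by the larger of the two empirical entropies. Equals 1 for
#' identical partitions with at least two clusters and 0 for empirically
#' independent ones; when both partitions have a single cluster the 0/0 case
#' is defined as 0.
#'
#' @param C,Cp label vectors of the same length (partitions of the same
#'   items).
#' @return NMI in \[0, 1\].
#' @examples
#' cluster_nmi(c(1, 1, 2, 2), c(1, 1, 2, 2))  # 1
#' cluster_nmi(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0: independent
#' @export
cluster_nmi <- function(C, Cp) {
  if (length(C) != length(Cp)) {
    stop("`C` and `Cp` must have the same length", call. = FALSE)
  }
  n <- length(C)
  joint <- table(factor(C), factor(Cp)) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hmax <- max(ent(px), ent(py))
  if (hmax == 0) return(0)
  mi / hmax
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- colSums((t(X) - X[idx[1], ])^2)
  for (j in seq_len(k)[-1]) {
    idx[j] <- if (sum(d2) == 0) {
      sample(setdiff(seq_len(n), idx[seq_len(j - 1)]), 1)
    } else {
      sample.int(n, 1, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, colSums((t(X) - X[idx[j], ])^2))
  }
  X[idx, , drop = FALSE]
}

#' K-means evaluation harness
#'
#' Runs K-means on the rows of an embedding `n_runs` times, each run with a
#' fresh k-means++ initialization seeded by `seed + run - 1`, and scores each
#' run against the prior labels with [cluster_accuracy()] and
#' [cluster_nmi()]. Because K-means may converge to different local optima
#' across random starts, the mean over restarts is the headline statistic and
#' the max is reported for reference.
#'
#' @param V numeric matrix; rows are sample embeddings.
#' @param k number of clusters.
#' @param prior vector of prior class labels, length nrow(V).
#' @param n_runs number of restarts (default 50).
#' @param seed base seed; run i uses seed + i - 1.
#' @return Object of class `clustering_report`: list with `acc_max`,
#'   `acc_mean`, `nmi_max`, `nmi_mean` (percentages), `n_runs`, and
#'   `per_run`, a data frame with one row per restart (acc, nmi, seed).
#' @export
kmeans_harness <- function(V, k, prior, n_runs = 50, seed = 0) {
  n <- nrow(V)
  if (k > n) stop("`k` must not exceed the number of samples", call. = FALSE)
  if (length(prior) != n) {
    stop("`prior` must have one label per row of `V`", call. = FALSE)
  }
  acc <- nmi <- numeric(n_runs)
  seeds <- seed + seq_len(n_runs) - 1
  for (i in seq_len(n_runs)) {
    set.seed(seeds[i])
    centers <- kmeanspp_centers(V, k)
    km <- suppressWarnings(stats::kmeans(V, centers = centers, iter.max = 100))
    acc[i] <- cluster_accuracy(prior, km$cluster)
    nmi[i] <- cluster_nmi(prior, km$cluster)
  }
  structure(
    list(acc_max = 100 * max(acc), acc_mean = 100 * mean(acc),
         nmi_max = 100 * max(nmi), nmi_mean = 100 * mean(nmi),
         n_runs = n_runs,
         per_run = data.frame(acc = acc, nmi = nmi, seed = seeds)),
    class = "clustering_report"
  )
}

#' @export
print.clustering_report <- function(x, ...) {
  cat(sprintf(paste0("clustering_report over %d K-means restarts\n",
                     "  ACC  mean %.2f%%  max %.2f%%\n",
                     "  NMI  mean %.2f%%  max %.2f%%\n"),
              x$n_runs, x$acc_mean, x$acc_max, x$nmi_mean, x$nmi_max))
  invisible(x)
}
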