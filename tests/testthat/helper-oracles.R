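# Independent brute-force oracles and small fixture builders shared by the
# tests. Oracles deliberately use naive loops/enumeration, not the package's
# code paths.

# all permutations of a vector (tiny k only)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(perms(v[-i]), function(p) c(v[i], p))
  }))
}

# accuracy by exhaustive maximization over cluster-to-class bijections
bf_accuracy <- function(prior, predicted) {
  pl <- sort(unique(prior)); rl <- sort(unique(predicted))
  m <- max(length(pl), length(rl))
  best <- 0
  for (pp in perms(seq_len(m))) {
    s <- 0
    for (i in seq_along(rl)) {
      j <- pp[i]
      if (j <= length(pl)) s <- s + sum(predicted == rl[i] & prior == pl[j])
    }
    best <- max(best, s)
  }
  best / length(prior)
}

# NMI from the definition: explicit loops over the joint table, log base 2,
# normalized by the larger marginal entropy
bf_nmi <- function(C, Cp) {
  n <- length(C)
  mi <- 0
  for (a in unique(C)) {
    for (b in unique(Cp)) {
      pab <- sum(C == a & Cp == b) / n
      if (pab > 0) {
        mi <- mi + pab * log2(pab / ((sum(C == a) / n) * (sum(Cp == b) / n)))
      }
    }
  }
  H <- function(z) {
    ps <- as.vector(table(z)) / length(z)
    -sum(ps * log2(ps))
  }
  hm <- max(H(C), H(Cp))
  if (hm == 0) 0 else mi / hm
}

# scalar proximal objective delta*|e|^p + (e - t)^2 / 2 minimized numerically
bf_prox_min <- function(t, p, delta) {
  f <- function(e) delta * abs(e)^p + 0.5 * (e - t)^2
  lo <- -abs(t) - 1; hi <- abs(t) + 1
  cand <- stats::optimize(f, c(lo, hi), tol = 1e-12)$minimum
  # 0 is always a candidate (the objective is non-smooth there)
  if (f(0) <= f(cand)) 0 else cand
}

# exact rank-k genes x samples fixture
rank_k_matrix <- function(p, n, k, seed = 1) {
  set.seed(seed)
  matrix(rnorm(p * k), p, k) %*% t(matrix(rnorm(n * k), n, k))
}

# well-scaled block fixture: 3 gene blocks elevated in 3 sample classes;
# values O(5) so the reweighted U-step keeps nonzero rows
block_fixture <- function(seed = 3) {
  set.seed(seed)
  blk <- rep(1:3, each = 10)
  X <- matrix(rnorm(120 * 30, 5, 1), 120, 30)
  for (b in 1:3) {
    rows <- ((b - 1) * 40 + 1):(b * 40)
    X[rows, blk == b] <- X[rows, blk == b] + 4
  }
  list(X = X, labels = blk)
}

# two planted correlation blocks: genes are noisy copies of one of two
# independent latent factors
correlated_blocks <- function(n_genes = 50, n_samples = 100, seed = 5,
                              noise = 0.15) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  half <- n_genes / 2
  R <- rbind(
    t(replicate(half, f1 + rnorm(n_samples, 0, noise))),
    t(replicate(half, f2 + rnorm(n_samples, 0, noise)))
  )
  rownames(R) <- paste0("g", seq_len(n_genes))
  R
}
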