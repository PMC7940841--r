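test_that("rank_genes scores absolute row sums with index tie-breaks", {
  U <- rbind(g1 = c(0, 0), g2 = c(0.5, 0), g3 = c(0, 0))
  r <- rank_genes(U)
  expect_equal(r$order[1], 2L)

  expect_equal(unname(rank_genes(rbind(c(1, -2)))$scores), 3)

  r0 <- rank_genes(matrix(0, 4, 2))
  expect_equal(r0$order, 1:4)
  expect_true(all(r0$scores == 0))

  # invariant to column permutation of U
  set.seed(1)
  U2 <- matrix(rnorm(20), 5, 4)
  expect_identical(rank_genes(U2)$order, rank_genes(U2[, c(3, 1, 4, 2)])$order)
})

test_that("pcc_adjacency thresholds absolute Pearson correlation", {
  R <- rbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4) + 3, c = c(1, 2, 3, 5))
  A <- pcc_adjacency(R, threshold = 0.8)
  expect_equal(A["a", "b"], 1)                       # perfect linear relation
  r_ac <- abs(stats::cor(R["a", ], R["c", ]))        # approx 0.9827
  expect_equal(A["a", "c"], r_ac)
  expect_equal(pcc_adjacency(R, threshold = 0.99)["a", "c"], 0)
  expect_true(all(diag(A) == 0))
  expect_equal(A, t(A))

  # centered-orthogonal rows are uncorrelated
  R2 <- rbind(c(-1, 0, 1, 0), c(0, -1, 0, 1))
  expect_equal(pcc_adjacency(R2, 0.1)[1, 2], 0)

  # anticorrelation enters through the absolute value
  R3 <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(pcc_adjacency(R3, 0.9)[1, 2], 1)

  # affine per-gene rescaling does not change the adjacency
  R4 <- correlated_blocks(10, 30, seed = 2)
  sc <- diag(runif(10, 0.5, 4)) %*% R4 + matrix(rnorm(10), 10, 30)[, 1]
  expect_equal(unname(pcc_adjacency(R4, 0.6)), unname(pcc_adjacency(sc, 0.6)),
               tolerance = 1e-12)

  # zero-variance gene is isolated with a warning
  R5 <- rbind(c(1, 2, 3, 4), c(2, 2, 2, 2), c(1, 2, 3, 5))
  expect_warning(A5 <- pcc_adjacency(R5, 0.5), "zero-variance")
  expect_true(all(A5[2, ] == 0) && all(A5[, 2] == 0))

  expect_error(pcc_adjacency(matrix(1, 2, 1), 0.5), "2 samples")
  expect_error(pcc_adjacency(R, 1.5), "0, 1")
})

test_that("extract_modules finds components, sizes and degrees", {
  # two disjoint triangles
  A <- matrix(0, 6, 6)
  tri <- function(i, j) A[i, j] <<- A[j, i] <<- 1
  tri(1, 2); tri(2, 3); tri(1, 3); tri(4, 5); tri(5, 6); tri(4, 6)
  net <- extract_modules(A)
  expect_length(net$modules, 2)
  expect_equal(net$modules[[1]], 1:3)   # size tie broken by smallest member
  expect_equal(net$modules[[2]], 4:6)
  expect_true(all(net$degrees == 2))
  expect_equal(net$n_edges, 6)

  # empty graph: no modules
  expect_length(extract_modules(matrix(0, 4, 4))$modules, 0)

  # path of 4 nodes
  P <- matrix(0, 4, 4)
  P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- P[3, 4] <- P[4, 3] <- 1
  netp <- extract_modules(P)
  expect_length(netp$modules, 1)
  expect_equal(unname(netp$degrees), c(1L, 2L, 2L, 1L))

  # isolated nodes are excluded from modules but keep degree 0
  I5 <- matrix(0, 5, 5); I5[1, 2] <- I5[2, 1] <- 1
  neti <- extract_modules(I5)
  expect_equal(neti$modules, list(1:2))
  expect_equal(unname(neti$degrees), c(1L, 1L, 0L, 0L, 0L))
})

test_that("raising the threshold never adds edges, modules or degree", {
  R <- correlated_blocks(20, 60, seed = 4, noise = 0.5)
  taus <- c(0.2, 0.5, 0.8, 0.95)
  stats <- lapply(taus, function(tau) {
    A <- pcc_adjacency(R, tau)
    net <- extract_modules(A)
    list(edges = net$n_edges, deg = net$degrees,
         big = sum(lengths(net$modules) >= 2))
  })
  for (i in seq_along(taus)[-1]) {
    expect_lte(stats[[i]]$edges, stats[[i - 1]]$edges)
    expect_true(all(stats[[i]]$deg <= stats[[i - 1]]$deg))
  }
})

test_that("hub_genes lists the highest-degree members per module", {
  R <- correlated_blocks(12, 50, seed = 6)
  net <- extract_modules(pcc_adjacency(R, 0.8))
  hubs <- hub_genes(net, top = 3)
  expect_length(hubs, length(net$modules))
  for (h in hubs) {
    expect_lte(length(h), 3)
    expect_true(all(diff(unname(h)) <= 0))
  }
})

test_that("select_gene_count picks the best-clustering gene count", {
  fx <- block_fixture()
  cfg <- pl21gpca_config(k = 3, lambda = 1, alpha = 10, max_iter = 200)
  fit <- pl21gpca_fit(fx$X, cfg)
  ranking <- rank_genes(fit$U)

  # single candidate comes straight back
  one <- select_gene_count(fx$X, fx$labels, ranking, 60, cfg,
                           n_runs = 5, seed = 1)
  expect_equal(one$l, 60)

  # informative-rows check: the chosen subset clusters at least as well as
  # using every gene
  sel <- select_gene_count(fx$X, fx$labels, ranking, c(60, 120), cfg,
                           n_runs = 5, seed = 1)
  expect_gte(max(sel$acc_mean), sel$acc_mean[["120"]])
  # ties resolve to the smaller count
  if (length(unique(sel$acc_mean)) == 1) expect_equal(sel$l, 60)

  expect_error(select_gene_count(fx$X, fx$labels, ranking, integer(0), cfg),
               "empty")
  expect_error(select_gene_count(fx$X, fx$labels, ranking, 1e6, cfg),
               "1..nrow")
})
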