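#' Solver configuration
#'
#' Collects and validates every hyperparameter of the robust sparse
#' graph-regularized PCA fit.
#'
#' @param k embedding dimension; usually the number of prior sample classes.
#' @param p Lp-loss exponent, strictly in (0, 1). Default 0.5.
#' @param lambda weight of the L2,1 penalty on the loading matrix U
#'   (row/gene sparsity). Default 100; performance is stable over roughly
#'   10..1000.
#' @param alpha weight of the graph-Laplacian penalty Tr(V'LV) on the sample
#'   embedding. Default 100; same stable range as `lambda`.
#' @param mu0 initial augmented-Lagrangian penalty, default 1e-2.
#' @param rho geometric growth factor of the penalty, default 1.2.
#' @param k_neighbors neighbor count for the sample graph; `NULL` (default)
#'   means round(sqrt(n)).
#' @param scheme graph weighting scheme, see [weight_matrix()].
#' @param max_iter iteration cap, default 500.
#' @param tol convergence tolerance on the relative constraint residual
#'   ||E - X + UV'||_F / ||X||_F, default 1e-7.
#' @param mu_max cap on the penalty to avoid numeric overflow under
#'   geometric growth, default 1e7.
#' @param v_update `"with_A"` (default) forms the V-step matrix as
#'   (alpha/mu) L - H'AH with the diagonal A of the U-step; `"without_A"`
#'   uses H'H instead.
#' @param seed integer seed for any stochastic initialization (the default
#'   initialization is deterministic; the seed is recorded for provenance).
#' @return Object of class `pl21gpca_config` (a validated list).
#' @export
pl21gpca_config <- function(k, p = 0.5, lambda = 100, alpha = 100,
                            mu0 = 1e-2, rho = 1.2, k_neighbors = NULL,
                            scheme = c("binary", "heat_kernel", "dot_product"),
                            max_iter = 500, tol = 1e-7, mu_max = 1e7,
                            v_update = c("with_A", "without_A"), seed = 0L) {
  scheme <- match.arg(scheme)
  v_update <- match.arg(v_update)
  stopifnot(length(k) == 1, k >= 1,
            length(p) == 1, length(lambda) == 1, length(alpha) == 1)
  if (p <= 0 || p >= 1) stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (mu0 <= 0) stop("`mu0` must be > 0", call. = FALSE)
  if (rho <= 1) stop("`rho` must be > 1", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  structure(
    list(k = as.integer(k), p = as.numeric(p), lambda = as.numeric(lambda),
         alpha = as.numeric(alpha), mu0 = as.numeric(mu0),
         rho = as.numeric(rho),
         k_neighbors = if (!is.null(k_neighbors)) as.integer(k_neighbors),
         scheme = scheme,
         max_iter = as.integer(max_iter), tol = as.numeric(tol),
         mu_max = as.numeric(mu_max),
         v_update = v_update, seed = as.integer(seed)),
    class = "pl21gpca_config"
  )
}

#' Residual update (E-step)
#'
#' Applies the generalized p-shrinkage to the current constraint slack:
#' \eqn{E = \mathrm{shrink}_p(X - UV' - Y/\mu,\; 1/\mu)} elementwise.
#'
#' @param X data matrix (genes x samples).
#' @param U loading matrix (genes x k).
#' @param V embedding matrix (samples x k).
#' @param Y Lagrange multiplier (genes x samples).
#' @param mu current penalty, > 0.
#' @param p Lp exponent in (0, 1].
#' @return Updated residual matrix E.
#' @export
update_E <- function(X, U, V, Y, mu, p) {
  stopifnot(mu > 0)
  shrink_p(X - U %*% t(V) - Y / mu, p, 1 / mu)
}

#' Loading update (U-step)
#'
#' Closed-form reweighted ridge solution
#' \eqn{U = (I + (2\lambda/\mu) Q)^{-1} H V}. Since Q is diagonal the
#' inverse is the diagonal matrix A with
#' \eqn{a_{ii} = 1 / (1 + (2\lambda/\mu) q_{ii})}, applied as a row scaling
#' of HV.
#'
#' @param H working matrix X - E - Y/mu (genes x samples).
#' @param V embedding matrix (samples x k).
#' @param q diagonal of the reweighting matrix Q, from [reweight_q()].
#' @param lambda L2,1 penalty weight.
#' @param mu current penalty.
#' @return List with `U` (genes x k) and `a`, the diagonal of A.
#' @export
update_U <- function(H, V, q, lambda, mu) {
  stopifnot(mu > 0, all(q > 0), length(q) == nrow(H))
  a <- 1 / (1 + (2 * lambda / mu) * q)
  list(U = a * (H %*% V), a = a)
}

#' Embedding update (V-step)
#'
#' The columns of V are the k orthonormal eigenvectors with smallest
#' eigenvalues of the symmetric matrix
#' \eqn{M = (\alpha/\mu) L - H^\top A H} (or \eqn{H^\top H} when
#' `with_A = FALSE`). Each column's sign is fixed so that its
#' largest-magnitude entry is positive, for run-to-run determinism.
#'
#' @param H working matrix (genes x samples).
#' @param a diagonal of A from [update_U()] (recycled to 1s when
#'   `with_A = FALSE`).
#' @param L graph Laplacian (samples x samples); may be `NULL` when
#'   `alpha = 0`.
#' @param alpha Laplacian penalty weight.
#' @param mu current penalty.
#' @param k number of eigenvectors.
#' @param with_A logical; include the diagonal A in the quadratic term.
#' @return samples x k matrix with orthonormal columns.
#' @export
update_V <- function(H, a, L, alpha, mu, k, with_A = TRUE) {
  n <- ncol(H)
  if (k > n) stop("`k` must not exceed the number of samples", call. = FALSE)
  M <- if (with_A) -crossprod(H, a * H) else -crossprod(H)
  if (alpha != 0) {
    if (is.null(L)) stop("`L` is required when `alpha` != 0", call. = FALSE)
    M <- M + (alpha / mu) * L
  }
  ee <- eigen(M, symmetric = TRUE)        # eigenvalues in decreasing order
  V <- ee$vectors[, seq(n, n - k + 1), drop = FALSE]
  fix_signs(V)
}

# Deterministic eigenvector sign convention: largest-magnitude entry positive.
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Fit the robust sparse graph-regularized PCA model
#'
#' Minimizes \deqn{\|X - UV^\top\|_p + \lambda \|U\|_{2,1} +
#' \alpha\,\mathrm{Tr}(V^\top L V) \quad \mathrm{s.t.}\; V^\top V = I}
#' by an augmented-Lagrangian alternating-direction scheme. The constraint
#' E = X - UV' splits the non-smooth loss from the factorization; each sweep
#' updates U (reweighted ridge), V (smallest-k eigenvectors), E (generalized
#' p-shrinkage), then the multiplier Y and the penalty mu <- min(rho*mu,
#' mu_max), until the relative constraint residual
#' ||E - X + UV'||_F / ||X||_F falls below `tol` or `max_iter` sweeps.
#'
#' Initialization is deterministic: Y = 0, E = 0, V = top-k right singular
#' vectors of X (signs fixed), U = XV.
#'
#' @param X numeric matrix, genes in rows, samples in columns, all finite.
#' @param config a [pl21gpca_config()].
#' @param graph a [sample_graph()] built on the columns of X, or a bare
#'   Laplacian matrix; `NULL` is allowed when `config$alpha == 0` and
#'   otherwise builds the graph from X with the config's `k_neighbors` and
#'   `scheme`.
#' @return Object of class `pl21gpca_fit`: list with `U` (genes x k), `V`
#'   (samples x k, orthonormal columns), `E`, `Y`, `objective_trace`,
#'   `residual_trace`, `ortho_trace` (per-sweep max |V'V - I|), `n_iter`,
#'   `converged`, `config`.
#' @examples
#' X <- matrix(rnorm(50 * 12), 50, 12)
#' cfg <- pl21gpca_config(k = 2, lambda = 1, alpha = 1, max_iter = 60)
#' fit <- pl21gpca_fit(X, cfg)
#' @export
pl21gpca_fit <- function(X, config, graph = NULL) {
  stopifnot(inherits(config, "pl21gpca_config"))
  if (any(!is.finite(X))) stop("`X` contains non-finite entries", call. = FALSE)
  n <- ncol(X); p_genes <- nrow(X)
  k <- config$k
  if (k >= n) stop("`k` must be smaller than the number of samples", call. = FALSE)

  L <- NULL
  if (config$alpha != 0) {
    if (is.null(graph)) {
      graph <- sample_graph(X, k_neighbors = config$k_neighbors,
                            scheme = config$scheme)
    }
    L <- if (inherits(graph, "sample_graph")) graph$L else graph
    if (!is.matrix(L) || nrow(L) != n || ncol(L) != n) {
      stop("graph Laplacian must be n x n for the n samples of `X`", call. = FALSE)
    }
  }

  # deterministic warm start: top-k right singular vectors of X itself (the
  # model factorizes X without centering, so the uncentered subspace is the
  # consistent warm start; see the methods vignette)
  V <- fix_signs(svd(X, nu = 0, nv = k)$v)
  U <- X %*% V
  E <- matrix(0, p_genes, n)
  Y <- matrix(0, p_genes, n)
  mu <- config$mu0
  normX <- norm(X, "F")

  obj_trace <- res_trace <- orth_trace <- numeric(config$max_iter)
  converged <- FALSE
  n_iter <- 0L
  for (r in seq_len(config$max_iter)) {
    H <- X - E - Y / mu
    q <- reweight_q(U)
    up <- update_U(H, V, q, config$lambda, mu)
    U <- up$U
    V <- update_V(H, up$a, L, config$alpha, mu, k,
                  with_A = (config$v_update == "with_A"))
    E <- update_E(X, U, V, Y, mu, config$p)
    C <- E - X + U %*% t(V)
    Y <- Y + mu * C
    mu <- min(config$rho * mu, config$mu_max)

    if (!all(is.finite(U)) || !all(is.finite(V)) || !all(is.finite(E))) {
      stop(sprintf("solver diverged: non-finite values at iteration %d", r),
           call. = FALSE)
    }
    n_iter <- r
    res_trace[r] <- norm(C, "F") / normX
    orth_trace[r] <- max(abs(crossprod(V) - diag(k)))
    obj <- lp_norm(X - U %*% t(V), config$p) + config$lambda * l21_norm(U)
    if (config$alpha != 0) obj <- obj + config$alpha * sum(V * (L %*% V))
    obj_trace[r] <- obj
    if (res_trace[r] <= config$tol) { converged <- TRUE; break }
  }

  structure(
    list(U = U, V = V, E = E, Y = Y,
         objective_trace = obj_trace[seq_len(n_iter)],
         residual_trace = res_trace[seq_len(n_iter)],
         ortho_trace = orth_trace[seq_len(n_iter)],
         n_iter = n_iter, converged = converged, config = config),
    class = "pl21gpca_fit"
  )
}

#' @export
print.pl21gpca_fit <- function(x, ...) {
  cat(sprintf(paste0("pl21gpca_fit: %d genes x %d samples, k = %d\n",
                     "  %d sweeps, %s (final relative residual %.3g)\n"),
              nrow(x$U), nrow(x$V), ncol(x$U), x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              utils::tail(x$residual_trace, 1)))
  invisible(x)
}

# Augmented-Lagrangian value with the separable sum |E|^p surrogate that the
# shrink step targets; used by diagnostics and the E-step monotonicity test.
augmented_lagrangian <- function(X, E, U, V, Y, mu, p, lambda, alpha, L = NULL) {
  val <- sum(abs(E)^p) +
    (mu / 2) * norm(E - X + U %*% t(V) + Y / mu, "F")^2 +
    lambda * l21_norm(U)
  if (alpha != 0) val <- val + alpha * sum(V * (L %*% V))
  val
}
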