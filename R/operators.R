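#' Lp quasi-norm of a matrix
#'
#' Computes \eqn{\|M\|_p = (\sum_{ij} |m_{ij}|^p)^{1/p}} for an exponent
#' \eqn{0 < p < 1}. For p in this range the quantity is a quasi-norm: it is
#' non-convex and non-smooth, promotes sparser solutions than the L1 norm,
#' and penalizes large entries less steeply than a squared loss, which is why
#' it is used as a robust reconstruction loss.
#'
#' @param M numeric matrix (or vector, treated as a one-row matrix).
#' @param p exponent, strictly between 0 and 1.
#' @return A single nonnegative number.
#' @examples
#' lp_norm(matrix(c(1, 1), 1), p = 0.5)  # (1 + 1)^2 = 4
#' @export
lp_norm <- function(M, p) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
    stop("`p` must be a single number strictly between 0 and 1", call. = FALSE)
  }
  s <- sum(abs(M)^p)
  s^(1 / p)
}

#' L2,1 norm of a matrix
#'
#' Sum of the Euclidean norms of the rows: \eqn{\|M\|_{2,1} = \sum_i
#' \|m_{i\cdot}\|_2}. As a penalty it drives entire rows to zero, which on a
#' genes-by-components loading matrix performs gene selection.
#'
#' @param M numeric matrix (a vector is treated as a single-column matrix,
#'   i.e. each entry is its own row).
#' @return A single nonnegative number.
#' @examples
#' l21_norm(rbind(c(3, 4), c(0, 0)))  # 5
#' @export
l21_norm <- function(M) {
  if (is.null(dim(M))) M <- matrix(M, ncol = 1)
  sum(sqrt(rowSums(M^2)))
}

#' Generalized p-shrinkage operator
#'
#' Elementwise thresholding
#' \eqn{\mathrm{shrink}_p(t, \delta) = \mathrm{sign}(t)\,
#' \max\{0, |t| - \delta |t|^{p-1}\}}, the generalized shrinkage
#' approximation to the proximal operator of the Lp quasi-norm. At
#' \eqn{p = 1} it reduces exactly to classical soft thresholding
#' \eqn{\mathrm{sign}(t)\max\{0, |t| - \delta\}}. The operator is odd,
#' never increases magnitude, and maps t = 0 to 0 (the \eqn{t/|t|} factor is
#' taken as 0 there). Entries with \eqn{|t|^{2-p} \le \delta} are annihilated.
#'
#' @param t numeric vector or matrix of inputs.
#' @param p exponent in (0, 1]; values below 1 give the non-convex
#'   p-shrinkage, p = 1 gives soft thresholding.
#' @param delta nonnegative threshold (the solver uses \eqn{1/\mu}).
#' @return Object of the same shape as `t`.
#' @examples
#' shrink_p(4, p = 0.5, delta = 1)   # 4 - 4^(-0.5) = 3.5
#' shrink_p(-4, p = 0.5, delta = 1)  # -3.5
#' @export
shrink_p <- function(t, p, delta) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    stop("`p` must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0) {
    stop("`delta` must be a single nonnegative number", call. = FALSE)
  }
  a <- abs(t)
  # a^(p-1) is Inf at a = 0; the max() would give -Inf there, so patch after
  mag <- pmax(0, a - delta * a^(p - 1))
  mag[a == 0] <- 0
  out <- sign(t) * mag
  if (!is.null(dim(t))) dim(out) <- dim(t)
  out
}

#' Diagonal of the L2,1 reweighting matrix
#'
#' The L2,1-penalized least-squares subproblem for the loading matrix U is
#' solved by iterative reweighting with the diagonal matrix Q,
#' \eqn{q_{ii} = 1 / \|u_{i\cdot}\|_2}. Exactly-zero rows would make
#' \eqn{q_{ii}} infinite, so the row norm is floored at `eps`; this is the
#' standard smoothing of iteratively reweighted least squares and keeps the
#' row-sparsity pressure on (a zero row gets weight 1/eps, i.e. is pinned
#' near zero).
#'
#' @param U numeric matrix (genes by components).
#' @param eps positive stabilizer flooring the row norms (default 1e-8).
#' @return Numeric vector of length `nrow(U)`: the diagonal entries of Q.
#' @examples
#' reweight_q(rbind(c(3, 4)))  # 1/5
#' @export
reweight_q <- function(U, eps = 1e-8) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0) {
    stop("`eps` must be a single positive number", call. = FALSE)
  }
  if (is.null(dim(U))) U <- matrix(U, nrow = 1)
  1 / pmax(sqrt(rowSums(U^2)), eps)
}
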