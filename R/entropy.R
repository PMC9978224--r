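# Entropy estimators and their analytic gradients. Two kinds of entropy
# drive the particle optimization:
#   * configuration-space (sampling) entropy, a Parzen estimate over one
#     organ's particles on one subject, whose gradient repels particles
#     into a uniform surface covering;
#   * subspace (shape-space) entropy, the Gaussian log-determinant of a
#     data matrix's sample covariance, estimated through the N x N Gram
#     matrix so the ambient-dimension covariance is never materialized.

#' Gaussian subspace entropy via the Gram matrix
#'
#' For a data matrix `Y` (rows: coordinates, columns: the N samples),
#' returns \eqn{\frac12 \sum_i \log(\lambda_i + \alpha)} over all
#' `nrow(Y)` dimensions, where \eqn{\lambda_i} are eigenvalues of the
#' sample covariance \eqn{Y_c Y_c^\top/(N-1)} (with `Y_c` the
#' column-mean-centered matrix) and \eqn{\alpha} a regularization floor.
#' Eigenvalues are obtained from the dual `N x N` Gram matrix
#' \eqn{Y_c^\top Y_c/(N-1)}, whose nonzero spectrum equals the primal
#' covariance spectrum, so the cost is independent of the ambient
#' dimension.
#'
#' @param Y numeric matrix, `D x N`, `N >= 2`. Centering across columns is
#'   applied internally (idempotent if `Y` is already centered).
#' @param alpha_reg positive regularization added to every eigenvalue.
#' @return the entropy value (scalar).
#' @export
subspace_entropy <- function(Y, alpha_reg) {
  Y <- as.matrix(Y)
  N <- ncol(Y)
  if (N < 2L) stop("subspace entropy needs at least 2 samples")
  stopifnot(alpha_reg > 0)
  D <- nrow(Y)
  Yc <- Y - rowMeans(Y)
  ev <- eigen(crossprod(Yc) / (N - 1), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  lam <- numeric(D)
  top <- seq_len(min(D, length(ev)))
  lam[top] <- ev[top]
  0.5 * sum(log(lam + alpha_reg))
}

#' Shape-space correspondence gradient (dual form)
#'
#' Returns \eqn{Y_c (Y_c^\top Y_c + \alpha I)^{-1}}, the derivative of
#' \eqn{\frac12 \log|Y_c Y_c^\top + \alpha I|} with respect to the raw
#' entries of `Y` (the column-centering coupling cancels exactly because
#' the all-ones vector is an \eqn{\alpha^{-1}} eigenvector of the
#' regularized Gram inverse). To obtain the derivative of
#' [subspace_entropy()] with covariance normalization `1/(N-1)` and
#' regularization `a`, call this with `alpha = a * (N - 1)`; optimizer call
#' sites do exactly that. Updates map to per-particle moves through the
#' centering Jacobians of the caller's subspace and are *subtracted* for
#' entropy descent.
#'
#' @param Y numeric matrix, `D x N`, `N >= 2` (centered internally).
#' @param alpha positive ridge added to the Gram matrix.
#' @return a `D x N` matrix, the per-sample gradient of the subspace
#'   entropy.
#' @export
correspondence_gradient <- function(Y, alpha) {
  Y <- as.matrix(Y)
  N <- ncol(Y)
  if (N < 2L) stop("correspondence gradient needs at least 2 samples")
  stopifnot(alpha > 0)
  Yc <- Y - rowMeans(Y)
  G <- crossprod(Yc)
  diag(G) <- diag(G) + alpha
  Yc %*% solve(G)
}

# Adaptive Parzen kernel width: per particle, the median distance to its 6
# nearest same-organ neighbours (all others when M <= 6), floored at
# 1e-3 * the organ's bounding-box diagonal. Scale-aware and parameter-free.
adaptive_sigma <- function(P, floor_scale) {
  M <- nrow(P)
  if (M < 2L) return(rep(floor_scale, M))
  d2 <- pairwise_sq_dists(P)
  diag(d2) <- Inf
  k <- min(6L, M - 1L)
  sig <- apply(d2, 1L, function(row) {
    median(sqrt(sort(row, partial = k)[seq_len(k)]))
  })
  pmax(sig, floor_scale)
}

pairwise_sq_dists <- function(P) {
  s <- rowSums(P^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0
  d2
}

#' Sampling (configuration-space) entropy and its gradient
#'
#' Parzen estimate of the differential entropy of one organ's particle
#' positions on one subject,
#' \eqn{H(X) \approx -\frac1M \sum_m \log p(x_m)}, with
#' \eqn{p(x_m) = \frac{1}{M-1}\sum_{j \ne m} K_{\sigma_m}(x_m - x_j)} and
#' an isotropic 3-D Gaussian kernel of per-particle width \eqn{\sigma_m}.
#' The returned gradient is \eqn{\partial H/\partial x_i} — the net
#' repulsion direction that *increases* entropy (spreads particles); the
#' optimization objective contains \eqn{-H(X)}, so callers add this
#' direction. The kernel widths are treated as constants within one
#' gradient evaluation (lagged statistics), which makes the gradient exact
#' for fixed `sigma` and verifiable by finite differences.
#'
#' Densities are evaluated in log space (log-sum-exp), so widely separated
#' particles do not underflow.
#'
#' @param P `M x 3` matrix of particle positions (mm), `M >= 2`.
#' @param sigma kernel width(s): a scalar or length-M vector (mm).
#' @return list with `entropy` (scalar) and `gradient` (`M x 3` matrix).
#' @export
sampling_entropy <- function(P, sigma) {
  P <- as.matrix(P)
  M <- nrow(P)
  if (M < 2L) stop("sampling entropy needs at least 2 particles")
  sigma <- rep_len(sigma, M)
  stopifnot(all(sigma > 0))
  d2 <- pairwise_sq_dists(P)
  # logK[m, j] = log K_{sigma_m}(x_m - x_j): row kernel width
  logK <- -d2 / (2 * sigma^2) - 1.5 * log(2 * pi * sigma^2)
  diag(logK) <- -Inf
  # log p_m = logsumexp_j(logK[m, j]) - log(M - 1)
  rmax <- apply(logK, 1L, max)
  logp <- rmax + log(rowSums(exp(logK - rmax))) - log(M - 1)
  entropy <- -mean(logp)

  # W[m, j] = K_{sigma_m}(d_mj) / (sigma_m^2 (M-1) p_m); the gradient at i
  # combines its own-density term (row i) and the cross terms (column i).
  W <- exp(logK - logp) / (sigma^2 * (M - 1))
  A <- W + t(W)
  grad <- -(A %*% P - rowSums(A) * P) / M
  list(entropy = entropy, gradient = grad)
}

#' Sampling entropy gradient for one subject/organ of a particle system
#'
#' Convenience wrapper around [sampling_entropy()] that extracts the
#' particles of subject `n`, organ `k`. If any two particles coincide
#' (distance < 1e-12), they are jittered apart deterministically and the
#' estimate retried, with a message.
#'
#' @param ps a [particle_system].
#' @param n subject index.
#' @param k organ index.
#' @param sigma `"adaptive"` (default: per-particle median 6-NN distance,
#'   floored) or numeric width(s) in mm.
#' @param floor_scale lower bound for adaptive widths (mm).
#' @return list with `entropy`, `gradient` (`M_k x 3`) and `sigma` used.
#' @export
sampling_entropy_gradient <- function(ps, n, k, sigma = "adaptive",
                                      floor_scale = 1e-3) {
  P <- get_particles(ps, n, k)
  if (nrow(P) >= 2L) {
    d2 <- pairwise_sq_dists(P)
    diag(d2) <- Inf
    if (min(d2) < 1e-24) {
      message("coincident particles for subject ", n, " organ ", k,
              "; applying deterministic jitter")
      set.seed(subject_seed(7919L, n * 1000L + k))
      P <- P + matrix(rnorm(length(P), sd = 1e-9), nrow(P))
    }
  }
  if (identical(sigma, "adaptive")) sigma <- adaptive_sigma(P, floor_scale)
  res <- sampling_entropy(P, sigma)
  res$sigma <- sigma
  res
}
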