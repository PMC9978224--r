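# Multilevel decomposition of a particle ensemble and the disentangled
# (within/between) correspondence objective. Each flattened particle vector
# splits exactly into
#   offset (global centroid) + within (deviation from the organ centroid)
#                            + between (organ centroid - global centroid),
# and the two non-offset parts are orthogonal by construction. Shape
# statistics are then taken per subspace: one covariance per organ over the
# within vectors (3*M_k dimensional) and one 3K-dimensional covariance over
# the stacked centroid deviations, which is what makes the approach
# scalable in the particle count.

#' Multilevel (within/between) decomposition of a particle system
#'
#' @param ps a [particle_system].
#' @return an object of class `mlca_decomposition` with elements:
#'   `offset` (`3 x N`, per-subject global particle centroid), `within`
#'   (list over organs of `(3*M_k) x N` matrices of particle deviations
#'   from the organ centroid), `between` (`(3*K) x N` matrix of organ
#'   centroid deviations from the global centroid, stacked over organs),
#'   and `organ_sizes`.
#' @export
mlca_decompose <- function(ps) {
  stopifnot(inherits(ps, "particle_system"))
  N <- n_subjects(ps)
  K <- n_organs(ps)
  sizes <- ps$organ_sizes
  M <- sum(sizes)
  offset <- matrix(0, 3L, N)
  centroids <- array(0, dim = c(3L, K, N))
  within <- vector("list", K)
  for (k in seq_len(K)) {
    block <- ps$coords[organ_rows(ps, k), , drop = FALSE]
    # organ centroid per subject: mean over the M_k particle 3-vectors
    arr <- array(block, dim = c(3L, sizes[k], N))
    cent <- apply(arr, c(1L, 3L), mean)          # 3 x N
    centroids[, k, ] <- cent
    within[[k]] <- block - cent[rep(seq_len(3L), sizes[k]), , drop = FALSE]
    offset <- offset + sizes[k] * cent
  }
  offset <- offset / M
  between <- matrix(0, 3L * K, N)
  for (k in seq_len(K))
    between[3L * (k - 1L) + 1:3, ] <- centroids[, k, ] - offset
  names(within) <- names(sizes)
  structure(list(offset = offset, within = within, between = between,
                 organ_sizes = sizes),
            class = "mlca_decomposition")
}

#' Reassemble particle coordinates from a decomposition
#'
#' Inverse of [mlca_decompose()]: offset + within + between reproduces the
#' original flattened coordinates exactly (floating-point rounding only).
#'
#' @param dec an `mlca_decomposition`.
#' @return the `(3*M) x N` coordinate matrix.
#' @export
mlca_reassemble <- function(dec) {
  sizes <- dec$organ_sizes
  N <- ncol(dec$offset)
  blocks <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    cent <- dec$offset + dec$between[3L * (k - 1L) + 1:3, , drop = FALSE]
    blocks[[k]] <- dec$within[[k]] +
      cent[rep(seq_len(3L), sizes[k]), , drop = FALSE]
  }
  do.call(rbind, blocks)
}

#' Sum-of-squares split of a decomposition
#'
#' ANOVA-style conservation: with totals taken after offset (global
#' centroid) removal and the between term expanded per particle (each
#' organ's centroid deviation counted once per particle, i.e. weighted by
#' `M_k`), the identity `ssq_total = ssq_within + ssq_between` holds
#' exactly.
#'
#' @param dec an `mlca_decomposition` (or a [particle_system], which is
#'   decomposed first).
#' @return list with `total`, `within`, `between` (mm^2).
#' @export
ssq_components <- function(dec) {
  if (inherits(dec, "particle_system")) dec <- mlca_decompose(dec)
  sizes <- dec$organ_sizes
  ssq_w <- sum(vapply(dec$within, function(m) sum(m^2), numeric(1)))
  b2 <- colSums(matrix(dec$between^2, nrow = 3L))  # per (k, n), k fast
  K <- length(sizes)
  N <- ncol(dec$between)
  ssq_b <- sum(rep(sizes, times = N) * b2)
  list(total = ssq_w + ssq_b, within = ssq_w, between = ssq_b)
}

# --- gradient mappings through the centering Jacobians -------------------

# Map a within-subspace gradient (w.r.t. the entries of Y_k^W) to raw
# particle coordinates: d(x_m - zbar_k)/dx_j = delta_mj I - (1/M_k) I, so
# each particle's 3-vector gradient is reduced by the organ-mean gradient.
map_within_gradient <- function(Gk, Mk) {
  arr <- array(Gk, dim = c(3L, Mk, ncol(Gk)))
  mean_g <- apply(arr, c(1L, 3L), mean)  # 3 x N
  Gk - mean_g[rep(seq_len(3L), Mk), , drop = FALSE]
}

# Map a between-subspace gradient (w.r.t. the 3K x N centroid-deviation
# matrix) to raw particle coordinates: for a particle of organ k,
# d(zbar_k' - zbar)/dx_m = delta_kk' (1/M_k) I - (1/M) I, giving
# (1/M_k) g_k - (1/M) sum_k' g_k' for every particle of organ k.
map_between_gradient <- function(GB, sizes) {
  K <- length(sizes)
  M <- sum(sizes)
  N <- ncol(GB)
  gsum <- matrix(0, 3L, N)
  for (k in seq_len(K))
    gsum <- gsum + GB[3L * (k - 1L) + 1:3, , drop = FALSE]
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    per_part <- GB[3L * (k - 1L) + 1:3, , drop = FALSE] / sizes[k] -
      gsum / M
    blocks[[k]] <- per_part[rep(seq_len(3L), sizes[k]), , drop = FALSE]
  }
  do.call(rbind, blocks)
}

#' Disentangled multi-organ objective
#'
#' \deqn{Q = \alpha_W \sum_k H(Z_k^W) + \alpha_B H(Z^B)
#'       - \sum_k \sum_n H(X_{n,k}),}
#' the within/between subspace entropies (computed from the decomposition's
#' `(3 M_k)`- and `3K`-dimensional covariances) minus the per-surface
#' sampling entropies.
#'
#' @param ps a [particle_system] with at least 2 subjects.
#' @param alpha_within,alpha_between nonnegative subspace weights.
#' @param alpha_reg covariance regularization: scalar, or list with
#'   elements `within` (length K) and `between`.
#' @param sigma sampling-kernel rule passed to
#'   [sampling_entropy_gradient()]: `"adaptive"` or a list (per subject) of
#'   lists (per organ) of widths.
#' @param floor_scale adaptive-width floor (mm).
#' @return list with `Q` and a `terms` breakdown (`within` per organ,
#'   `between`, `sampling` total).
#' @export
mlmo_objective <- function(ps, alpha_within = 1, alpha_between = 1,
                           alpha_reg = 1e-2, sigma = "adaptive",
                           floor_scale = 1e-3) {
  N <- n_subjects(ps)
  if (N < 2L) stop("objective needs at least 2 subjects")
  K <- n_organs(ps)
  dec <- mlca_decompose(ps)
  areg <- normalize_alpha_reg(alpha_reg, K)
  h_w <- vapply(seq_len(K), function(k)
    subspace_entropy(dec$within[[k]], areg$within[k]), numeric(1))
  h_b <- subspace_entropy(dec$between, areg$between)
  h_s <- 0
  for (n in seq_len(N)) for (k in seq_len(K)) {
    if (ps$organ_sizes[k] < 2L) next
    sg <- if (is.list(sigma)) sigma[[n]][[k]] else sigma
    h_s <- h_s + sampling_entropy_gradient(ps, n, k, sigma = sg,
                                           floor_scale = floor_scale)$entropy
  }
  Q <- alpha_within * sum(h_w) + alpha_between * h_b - h_s
  list(Q = Q, terms = list(within = h_w, between = h_b, sampling = h_s))
}

normalize_alpha_reg <- function(alpha_reg, K) {
  if (is.list(alpha_reg)) {
    list(within = rep_len(alpha_reg$within, K),
         between = alpha_reg$between)
  } else {
    list(within = rep_len(alpha_reg, K), between = alpha_reg)
  }
}

# Raw-coordinate gradients of the within and between entropy terms
# (alpha-weighted sums), used by the optimizer and by finite-difference
# validation. Returns (3M) x N matrices.
within_entropy_gradient <- function(ps, alpha_reg) {
  dec <- mlca_decompose(ps)
  K <- n_organs(ps)
  N <- n_subjects(ps)
  areg <- normalize_alpha_reg(alpha_reg, K)
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    Gk <- correspondence_gradient(dec$within[[k]],
                                  areg$within[k] * (N - 1))
    blocks[[k]] <- map_within_gradient(Gk, ps$organ_sizes[k])
  }
  do.call(rbind, blocks)
}

between_entropy_gradient <- function(ps, alpha_reg) {
  dec <- mlca_decompose(ps)
  N <- n_subjects(ps)
  areg <- normalize_alpha_reg(alpha_reg, n_organs(ps))
  GB <- correspondence_gradient(dec$between, areg$between * (N - 1))
  map_between_gradient(GB, ps$organ_sizes)
}

# Shared-space (global) entropy gradient w.r.t. raw coordinates.
shared_entropy_gradient <- function(ps, alpha_reg) {
  N <- n_subjects(ps)
  correspondence_gradient(ps$coords, alpha_reg * (N - 1))
}
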