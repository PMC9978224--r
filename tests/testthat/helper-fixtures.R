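# Fixtures built in code: small meshes, random particle systems, and
# independent (naive) reimplementations used as oracles.

unit_tetrahedron <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(1L, 4L, 3L),
                     c(2L, 3L, 4L)))
}

# A unit square in the z = z0 plane, two triangles, wound so the normals
# point along `normal_sign` * z.
unit_square <- function(z0 = 0, normal_sign = 1, x0 = 0, y0 = 0) {
  v <- cbind(c(0, 1, 1, 0) + x0, c(0, 0, 1, 1) + y0, z0)
  f <- if (normal_sign > 0) rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  else rbind(c(1L, 3L, 2L), c(1L, 4L, 3L))
  surface_mesh(v, f)
}

sphere_mesh <- function(radius = 1, resolution = 32) {
  sp <- supershape_spec()
  build_supershape_mesh(sp, sp, resolution = resolution, scale = radius)
}

random_particle_system <- function(n_subjects = 4, organ_sizes = c(a = 3L, b = 2L),
                                   sd = 5, seed = 1) {
  set.seed(seed)
  M <- sum(organ_sizes)
  particle_system(matrix(rnorm(3 * M * n_subjects, sd = sd), 3L * M),
                  organ_sizes, sprintf("s%d", seq_len(n_subjects)))
}

# Small multi-organ ensemble of supershapes (coarse meshes, fast).
tiny_ensemble <- function(n_subjects = 4, n_objects = 2, seed = 3,
                          resolution = 16) {
  cfg <- ensemble_config(n_subjects = n_subjects, n_objects = n_objects,
                         mesh_resolution = resolution, seed = seed)
  generate_synthetic_ensemble(cfg)
}

# One-organ ensemble (for single-mode tests): unit spheres scaled per
# subject so there is real shape variation.
one_organ_ensemble <- function(n_subjects = 3, resolution = 12) {
  sp <- supershape_spec()
  lapply(seq_len(n_subjects), function(n) {
    mesh <- build_supershape_mesh(sp, sp, resolution = resolution,
                                  scale = 10 + n)
    multi_organ_subject(sprintf("s%d", n), list(organ = mesh))
  })
}

# ---- independent oracles ------------------------------------------------

# Point-to-triangle distance by a different route than the compiled kernel:
# clamp the plane projection via barycentric coordinates, else take the
# minimum over the three edge segments.
point_triangle_distance_r <- function(p, a, b, c) {
  seg_dist <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d * d)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (u + t * d))^2))
  }
  n <- pracma_cross(b - a, c - a)
  n2 <- sum(n * n)
  if (n2 > 0) {
    q <- p - sum((p - a) * n) / n2 * n
    # barycentric test
    v0 <- b - a; v1 <- c - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1) return(sqrt(sum((p - q)^2)))
  }
  min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, a, c))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

brute_nearest_r <- function(mesh, p) {
  d <- vapply(seq_len(nrow(mesh$faces)), function(f) {
    tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
    point_triangle_distance_r(p, tri[1, ], tri[2, ], tri[3, ])
  }, numeric(1))
  list(distance = min(d), face = which.min(d))
}

# Dense-covariance PCA oracle (materializes the D x D covariance).
dense_pca_oracle <- function(Y) {
  mu <- rowMeans(Y)
  Yc <- Y - mu
  C <- Yc %*% t(Yc) / (ncol(Y) - 1)
  e <- eigen(C, symmetric = TRUE)
  list(mean = mu, values = pmax(e$values, 0), vectors = e$vectors)
}

# Central finite differences of a scalar function of a matrix.
fd_gradient <- function(f, X, eps = 1e-6) {
  G <- X * 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    Xp <- X; Xp[i, j] <- Xp[i, j] + eps
    Xm <- X; Xm[i, j] <- Xm[i, j] - eps
    G[i, j] <- (f(Xp) - f(Xm)) / (2 * eps)
  }
  G
}

rel_err <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-300)

# Naive leave-one-out generalization: explicit loops and dense PCA.
naive_generalization <- function(ps, subspace, P, organ = NULL) {
  Y <- mlmoshape:::subspace_data(ps, subspace, organ)
  N <- ncol(Y)
  vapply(P, function(p) {
    errs <- vapply(seq_len(N), function(n) {
      tr <- Y[, -n, drop = FALSE]
      o <- dense_pca_oracle(tr)
      keep <- which(o$values > 1e-12 * max(o$values, 0))
      keep <- head(keep, min(p, ncol(tr) - 1))
      U <- o$vectors[, keep, drop = FALSE]
      yc <- Y[, n] - o$mean
      rec <- o$mean + U %*% crossprod(U, yc)
      sqrt(sum((Y[, n] - rec)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
}


# Naive specificity: identical RNG protocol, explicit loops.
naive_specificity <- function(ps, subspace, P, T, seed, organ = NULL) {
  Y <- mlmoshape:::subspace_data(ps, subspace, organ)
  fit <- fit_subspace_model(Y)
  r <- length(fit$values)
  set.seed(seed)
  Z <- matrix(rnorm(T * r), T, r)
  vapply(P, function(p) {
    d <- vapply(seq_len(T), function(t) {
      s <- fit$mean
      for (q in seq_len(p))
        s <- s + Z[t, q] * sqrt(fit$values[q]) * fit$vectors[, q]
      min(sqrt(colSums((Y - s)^2)))
    }, numeric(1))
    mean(d)
  }, numeric(1))
}

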