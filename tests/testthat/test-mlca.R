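# Subspace PCA models, projection/reconstruction, and mode sweeps.

# single-sample decomposition via the package internals
decompose_sample_t <- function(z, sizes) {
  mlmoshape:::decompose_sample(z, sizes)
}

test_that("shared PCA matches the dense-covariance oracle", {
  ps <- random_particle_system(n_subjects = 5,
                               organ_sizes = c(a = 3L, b = 2L), seed = 41)
  model <- fit_shared_pca(ps)
  oracle <- dense_pca_oracle(ps$coords)
  r <- length(model$values)
  expect_lte(r, 4L)  # at most N - 1 nonzero eigenvalues
  expect_equal(model$values, oracle$values[seq_len(r)], tolerance = 1e-9)
  # eigenvectors equal up to sign
  for (j in seq_len(r))
    expect_equal(abs(sum(model$vectors[, j] * oracle$vectors[, j])), 1,
                 tolerance = 1e-8)
  # orthonormality and variance bookkeeping
  expect_equal(crossprod(model$vectors), diag(r), tolerance = 1e-9)
  expect_equal(sum(model$values), model$total_variance, tolerance = 1e-9)
})

test_that("degenerate spectra behave as expected", {
  # identical samples: no modes
  X <- matrix(rep(rnorm(9), 4), 9, 4)
  ps <- particle_system(X, c(o = 3L), paste0("s", 1:4))
  expect_length(fit_shared_pca(ps)$values, 0L)
  # samples on a line: exactly one nonzero eigenvalue
  dir <- rnorm(9)
  X2 <- outer(dir, seq(-2, 2, length.out = 5))
  ps2 <- particle_system(X2, c(o = 3L), paste0("s", 1:5))
  expect_length(fit_shared_pca(ps2)$values, 1L)
})

test_that("MLCA subspaces are mutually orthogonal and conserve SSQ", {
  ps <- random_particle_system(n_subjects = 6,
                               organ_sizes = c(a = 4L, b = 2L, c = 3L),
                               seed = 42)
  fit <- fit_mlca(ps)
  sizes <- ps$organ_sizes
  # expand basis vectors to the full particle space and test pairwise
  expand_between <- function(u) unlist(lapply(seq_along(sizes),
    function(k) rep(u[3 * (k - 1) + 1:3], sizes[k])))
  embed_within <- function(k, u) {
    out <- numeric(3 * sum(sizes))
    out[mlmoshape:::organ_rows(ps, k)] <- u
    out
  }
  B <- apply(fit$between$vectors, 2, expand_between)
  for (k in seq_along(sizes)) {
    Wk <- apply(fit$within[[k]]$vectors, 2, embed_within, k = k)
    expect_lt(max(abs(crossprod(Wk, B))), 1e-9)
    for (k2 in seq_along(sizes)) if (k2 != k) {
      W2 <- apply(fit$within[[k2]]$vectors, 2, embed_within, k = k2)
      expect_lt(max(abs(crossprod(Wk, W2))), 1e-9)
    }
  }
  # variance split agrees with the SSQ decomposition (1/(N-1) scaled)
  ss <- ssq_components(ps)
  tot_w <- sum(vapply(fit$within, `[[`, numeric(1), "total_variance"))
  dec <- mlca_decompose(ps)
  wc <- sum(vapply(dec$within,
                   function(m) sum((m - rowMeans(m))^2), numeric(1)))
  expect_equal(tot_w, wc / 5, tolerance = 1e-9)
})

test_that("K = 1 leaves the between model empty", {
  ps <- random_particle_system(organ_sizes = c(solo = 4L))
  fit <- fit_mlca(ps)
  expect_length(fit$between$values, 0L)
})

test_that("projection and reconstruction are mutually inverse", {
  ps <- random_particle_system(n_subjects = 6,
                               organ_sizes = c(a = 3L, b = 4L), seed = 43)
  fit <- fit_mlca(ps)
  # consolidated mean projects to zero coefficients
  co0 <- project_sample(fit, fit$mean_full)
  expect_lt(max(abs(unlist(co0$alpha_within))), 1e-9)
  expect_lt(max(abs(co0$alpha_between)), 1e-9)
  # training samples reconstruct exactly with all modes
  for (n in c(1, 4)) {
    z <- ps$coords[, n]
    co <- project_sample(fit, z)
    zr <- reconstruct_shape(fit, co)
    expect_lt(max(abs(zr - z)) / max(abs(z)), 1e-8)
  }
  # zero coefficients reproduce the consolidated mean, also with P = 0
  zeros <- list(alpha_within = lapply(fit$within, function(m)
    numeric(length(m$values))),
    alpha_between = numeric(length(fit$between$values)))
  expect_equal(reconstruct_shape(fit, zeros), fit$mean_full,
               tolerance = 1e-10)
  expect_equal(reconstruct_shape(fit, zeros, p_within = 0, p_between = 0),
               fit$mean_full, tolerance = 1e-10)
  expect_error(reconstruct_shape(fit, zeros, p_within = 99), "modes")
})

test_that("projection minimizes reconstruction error", {
  ps <- random_particle_system(n_subjects = 5,
                               organ_sizes = c(a = 3L, b = 2L), seed = 44)
  fit <- fit_mlca(ps)
  set.seed(45)
  z <- rnorm(nrow(ps$coords), sd = 4)
  co <- project_sample(fit, z)
  base_err <- sum((reconstruct_shape(fit, co) - z)^2)
  for (t in 1:200) {
    pert <- co
    pert$alpha_within <- lapply(pert$alpha_within, function(a)
      a + rnorm(length(a), sd = 0.5))
    pert$alpha_between <- pert$alpha_between +
      rnorm(length(pert$alpha_between), sd = 0.5)
    expect_gte(sum((reconstruct_shape(fit, pert) - z)^2),
               base_err - 1e-10)
  }
})

test_that("mode sweeps are linear, symmetric and disentangled", {
  ps <- random_particle_system(n_subjects = 6,
                               organ_sizes = c(a = 3L, b = 4L), seed = 46)
  fit <- fit_mlca(ps)
  sizes <- ps$organ_sizes
  sweep_b <- mode_sweep(fit, "between", mode = 1, sigmas = c(-2, 0, 2))
  # c = 0 gives the mean; +c and -c mirror about it
  expect_equal(sweep_b[, 2], fit$mean_full, tolerance = 1e-10)
  expect_equal(sweep_b[, 1] + sweep_b[, 3], 2 * fit$mean_full,
               tolerance = 1e-9)
  # between sweep: per-organ centered within-shape unchanged
  scale_ref <- max(abs(ps$coords))
  for (j in c(1, 3)) {
    d <- decompose_sample_t(sweep_b[, j], sizes)
    d0 <- decompose_sample_t(fit$mean_full, sizes)
    for (k in 1:2)
      expect_lt(max(abs(d$within[[k]] - d0$within[[k]])),
                1e-9 * scale_ref)
  }
  # within sweep: organ centroids unchanged
  sweep_w <- mode_sweep(fit, "within", mode = 1, sigmas = c(-2, 2),
                        organ = "b")
  for (j in 1:2) {
    d <- decompose_sample_t(sweep_w[, j], sizes)
    d0 <- decompose_sample_t(fit$mean_full, sizes)
    expect_lt(max(abs(d$between - d0$between)), 1e-9 * scale_ref)
    expect_lt(max(abs(d$offset - d0$offset)), 1e-9 * scale_ref)
  }
  # shared sweep on the PCA model
  g <- fit_shared_pca(ps)
  sweep_g <- mode_sweep(g, "shared", mode = 1, sigmas = 0)
  expect_equal(sweep_g[, 1], g$mean, tolerance = 1e-10)
  expect_error(mode_sweep(fit, "within", mode = 1), "organ")
  expect_error(mode_sweep(fit, "between", mode = 99), "rank")
})
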