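# Model-quality metrics against naive reimplementations, and the
# coverage-area ray-casting oracles.

test_that("compactness is the cumulative eigenvalue sum", {
  model <- structure(list(tag = "G", mean = numeric(3),
                          vectors = diag(3), values = c(3, 2, 1),
                          total_variance = 6, n = 4),
                     class = "subspace_model")
  expect_equal(compactness(model, 2), 5)
  expect_equal(compactness(model, 3), 6)  # P = rank: total variance
  expect_equal(compactness(model, 1:3), c(3, 5, 6))
  expect_error(compactness(model, 4), "out of range")
  # agrees with the dense oracle on a random fit
  ps <- random_particle_system(n_subjects = 5,
                               organ_sizes = c(a = 3L, b = 2L), seed = 51)
  fit <- fit_shared_pca(ps)
  oracle <- dense_pca_oracle(ps$coords)
  P <- seq_along(fit$values)
  expect_equal(compactness(fit, P), cumsum(oracle$values[P]),
               tolerance = 1e-9)
  # normalized compactness is a nondecreasing fraction in [0, 1]
  frac <- compactness(fit, P) / compactness(fit, max(P))
  expect_true(all(diff(frac) >= -1e-12))
  expect_true(all(frac >= 0 & frac <= 1 + 1e-12))
})

test_that("generalization equals the naive reimplementation", {
  ps <- random_particle_system(n_subjects = 6,
                               organ_sizes = c(a = 3L, b = 2L), seed = 52)
  for (sub in c("shared", "between")) {
    got <- generalization(ps, sub, P = 1:3)
    expect_equal(got$value, naive_generalization(ps, sub, 1:3),
                 tolerance = 1e-9, label = sub)
  }
  got_w <- generalization(ps, "within", P = 1:2, organ = "b")
  expect_equal(got_w$value, naive_generalization(ps, "within", 1:2, "b"),
               tolerance = 1e-9)
  expect_error(generalization(random_particle_system(n_subjects = 2),
                              "shared", 1), "3 subjects")
})

test_that("generalization vanishes for degenerate ensembles", {
  # identical subjects: zero error at every P
  X <- matrix(rep(rnorm(12), 5), 12, 5)
  ps <- particle_system(X, c(o = 4L), paste0("s", 1:5))
  expect_equal(generalization(ps, "shared", 1:2)$value, c(0, 0),
               tolerance = 1e-9)
  # rank-1 data: one mode reconstructs held-out subjects exactly
  dir <- rnorm(12)
  X2 <- outer(dir, seq(1, 2, length.out = 5))
  ps2 <- particle_system(X2, c(o = 4L), paste0("s", 1:5))
  scale_ref <- sqrt(mean(X2^2))
  expect_lt(generalization(ps2, "shared", 1)$value, 1e-6 * scale_ref)
})

test_that("specificity equals the naive reimplementation (T = 1000)", {
  ps <- random_particle_system(n_subjects = 5,
                               organ_sizes = c(a = 2L, b = 2L), seed = 53)
  got <- specificity(ps, "shared", P = 1:2, T = 1000, seed = 9)
  expect_equal(got$value, naive_specificity(ps, "shared", 1:2, 1000, 9),
               tolerance = 1e-9)
  got_b <- specificity(ps, "between", P = 1:2, T = 1000, seed = 9)
  expect_equal(got_b$value,
               naive_specificity(ps, "between", 1:2, 1000, 9),
               tolerance = 1e-9)
  # reproducible under a fixed seed
  expect_identical(specificity(ps, "shared", 1:2, T = 200, seed = 4),
                   specificity(ps, "shared", 1:2, T = 200, seed = 4))
})

test_that("specificity is a consistent Monte-Carlo estimate", {
  ps <- random_particle_system(n_subjects = 5,
                               organ_sizes = c(a = 2L, b = 2L), seed = 54)
  v1 <- specificity(ps, "shared", P = 2, T = 1000, seed = 1)$value
  v2 <- specificity(ps, "shared", P = 2, T = 10000, seed = 2)$value
  # crude scale of the Monte-Carlo standard error
  set.seed(99)
  se <- sd(vapply(sample.int(1e6, 30), function(s)
    specificity(ps, "shared", P = 2, T = 100, seed = s)$value,
    numeric(1))) / sqrt(10)
  expect_lt(abs(v1 - v2), 3 * se + 1e-9)
})

test_that("specificity of a zero-variance model centered on a sample is 0", {
  X <- matrix(rep(rnorm(9), 4), 9, 4)
  ps <- particle_system(X, c(o = 3L), paste0("s", 1:4))
  got <- specificity(ps, "shared", P = 0, T = 10, seed = 1)
  expect_equal(got$value, 0, tolerance = 1e-12)
})

test_that("coverage area reproduces the plane and sphere oracles", {
  a <- unit_square(z0 = 0, normal_sign = 1)
  b <- unit_square(z0 = 1, normal_sign = -1)
  # facing squares: fully covered
  expect_equal(coverage_area(a, b), 1, tolerance = 1e-12)
  # offset by half a side: half covered (verified by exhaustive
  # ray-triangle reasoning: centroids with x < 0.5 still hit)
  b_off <- unit_square(z0 = 1, normal_sign = -1, x0 = 0.5)
  expect_equal(coverage_area(a, b_off), 0.5, tolerance = 1e-12)
  # disjoint: nothing covered
  expect_equal(coverage_area(a, unit_square(z0 = 1, x0 = 5)), 0)
  # concentric spheres: the whole inner sphere is covered
  inner <- sphere_mesh(1, 64)
  outer <- sphere_mesh(2, 64)
  cov <- coverage_area(inner, outer)
  expect_lt(abs(cov - 4 * pi) / (4 * pi), 0.02)
  # coverage never exceeds the mesh's own area
  expect_lte(cov, mesh_area(inner) + 1e-12)
  # a convex mesh casting outward never covers itself
  expect_equal(coverage_area(inner, inner), 0)
})

test_that("relative error follows its definition", {
  expect_equal(relative_error(100, 100), 0)
  expect_equal(relative_error(104, 100), 0.04)
  expect_equal(relative_error(0, 57), 1)
  expect_error(relative_error(1, 0), "positive")
})

test_that("dominant mode counting applies the share threshold", {
  expect_equal(dominant_mode_count(c(0.98, 0.01, 0.01), 0.05), 1L)
  expect_equal(dominant_mode_count(rep(1, 4), 0.05), 4L)
  expect_equal(dominant_mode_count(c(9, 0.9, 0.05, 0.05), 0.05), 2L)
  expect_error(dominant_mode_count(c(0, 0)), "positive")
})
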