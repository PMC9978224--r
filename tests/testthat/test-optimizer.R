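# Particle initialization, splitting, and the optimization loop.

test_that("initialization places one particle per organ on the surface", {
  ens <- tiny_ensemble(n_subjects = 3, resolution = 12)
  ps <- initialize_particles(ens$subjects, c(8, 16))
  expect_equal(unname(ps$organ_sizes), c(1L, 1L))
  expect_equal(unname(attr(ps, "target_particles")), c(8L, 16L))
  for (n in 1:3) for (k in 1:2) {
    p <- get_particles(ps, n, k)
    d <- nearest_point_on_surface(ens$subjects[[n]]$organs[[k]], p)
    expect_lt(d$distance, 1e-9)
  }
  expect_error(initialize_particles(ens$subjects, c(8, 3)),
               "powers of two")
  # determinism
  ps2 <- initialize_particles(ens$subjects, c(8, 16))
  expect_identical(ps$coords, ps2$coords)
})

test_that("splitting doubles counts, keeps parents, stays on-surface", {
  ens <- tiny_ensemble(n_subjects = 3, resolution = 12)
  ps <- initialize_particles(ens$subjects, 8)
  ps2 <- split_particles(ps, ens$subjects, seed = 5)
  expect_equal(unname(ps2$organ_sizes), c(2L, 2L))
  # parents keep their coordinates and their ordering (children appended)
  for (k in 1:2)
    expect_equal(get_particles(ps2, 1, k)[1, ],
                 get_particles(ps, 1, k)[1, ], tolerance = 1e-12)
  # children lie on the surface
  for (n in 1:3) for (k in 1:2) {
    d <- nearest_point_on_surface(ens$subjects[[n]]$organs[[k]],
                                  get_particles(ps2, n, k))
    expect_lt(max(d$distance), 1e-9)
  }
  # per-organ splitting is independent
  ps3 <- split_particles(ps2, ens$subjects, seed = 6, organs = 2L)
  expect_equal(unname(ps3$organ_sizes), c(2L, 4L))
  # same seed reproduces the same children
  ps2b <- split_particles(ps, ens$subjects, seed = 5)
  expect_identical(ps2$coords, ps2b$coords)
})

test_that("repeated splitting and relaxation separates all particles", {
  subj <- one_organ_ensemble(n_subjects = 3, resolution = 16)
  cfg <- optimizer_config(particles_per_organ = 64, mode = "single",
                          iterations_per_split_level = 8, seed = 2)
  fit <- optimize_particles(subj, cfg)
  for (n in 1:3) {
    P <- get_particles(fit$particles, n, 1)
    d2 <- as.matrix(dist(P))
    diag(d2) <- Inf
    expect_gt(min(d2), 0)
  }
})

test_that("global mode with one organ reproduces single-organ runs exactly", {
  subj <- one_organ_ensemble(n_subjects = 3, resolution = 12)
  base <- list(particles_per_organ = 8, iterations_per_split_level = 6,
               seed = 4)
  f1 <- optimize_particles(subj, do.call(optimizer_config,
                                         c(base, mode = "single")))
  f2 <- optimize_particles(subj, do.call(optimizer_config,
                                         c(base, mode = "global")))
  expect_identical(f1$particles$coords, f2$particles$coords)
  expect_equal(f1$trace$q_after, f2$trace$q_after, tolerance = 1e-12)
  # single mode refuses multi-organ input
  ens <- tiny_ensemble(n_subjects = 3, resolution = 12)
  expect_error(optimize_particles(ens$subjects,
                                  do.call(optimizer_config,
                                          c(base, mode = "single"))),
               "one organ")
})

test_that("optimization keeps particles on the surface and energy monotone", {
  ens <- tiny_ensemble(n_subjects = 4, resolution = 14)
  subjects <- center_ensemble(ens$subjects)$subjects
  cfg <- optimizer_config(particles_per_organ = 16, mode = "mlmo",
                          iterations_per_split_level = 10, seed = 1)
  fit <- optimize_particles(subjects, cfg)
  for (n in 1:4) for (k in 1:2) {
    d <- nearest_point_on_surface(subjects[[n]]$organs[[k]],
                                  get_particles(fit$particles, n, k))
    expect_lt(max(d$distance), cfg$tau_surf)
  }
  tr <- fit$trace
  expect_true(all(tr$q_after <= tr$q_before + 1e-8 * (1 + abs(tr$q_before))))
  # determinism of the whole loop
  fit2 <- optimize_particles(subjects, cfg)
  expect_identical(fit$particles$coords, fit2$particles$coords)
})

test_that("identical subjects converge to identical particle sets", {
  sp <- supershape_spec()
  mesh <- build_supershape_mesh(sp, sp, resolution = 14, scale = 10)
  subjects <- lapply(1:3, function(n)
    multi_organ_subject(sprintf("s%d", n), list(organ = mesh)))
  cfg <- optimizer_config(particles_per_organ = 16, mode = "global",
                          iterations_per_split_level = 25, seed = 3)
  fit <- optimize_particles(subjects, cfg)
  # identical geometry + identical split directions: the shape-space term
  # vanishes and subjects stay in perfect correspondence
  expect_lt(max(abs(fit$particles$coords[, 1] -
                      fit$particles$coords[, 2])), 1e-6)
  expect_lt(max(abs(fit$particles$coords[, 1] -
                      fit$particles$coords[, 3])), 1e-6)
})

test_that("mlmo_step with one organ applies no between update", {
  subj <- one_organ_ensemble(n_subjects = 3, resolution = 12)
  ps <- initialize_particles(subj, 4)
  for (l in 1:2) ps <- split_particles(ps, subj, seed = l)
  cfg <- optimizer_config(particles_per_organ = 4, mode = "mlmo", seed = 1)
  # with sampling and within weights zeroed, a K = 1 step is a no-op
  cfg0 <- cfg
  cfg0$alpha_within <- 0
  ps2 <- mlmoshape:::apply_moves(
    ps, mlmoshape:::build_mesh_cache(subj),
    mlmoshape:::between_entropy_gradient(ps, 0.1),
    mlmoshape:::compute_sigma_list(ps, mlmoshape:::build_mesh_cache(subj)),
    eta = 1, with_sampling = FALSE)
  expect_equal(ps2$coords, ps$coords, tolerance = 1e-12)
})

test_that("optimizer configuration is validated", {
  expect_error(optimizer_config(particles_per_organ = 12),
               "powers of two")
  expect_error(optimizer_config(alpha_within = -1), "alpha_within")
  expect_error(optimizer_config(alpha_reg_start = 0), "alpha_reg_start")
  expect_error(optimize_particles(one_organ_ensemble(2),
                                  optimizer_config(mode = "single")),
               "3 subjects")
})
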