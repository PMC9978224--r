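# Multilevel decomposition: exactness, SSQ conservation, orthogonality,
# and the Jacobian-mapped subspace gradients.

test_that("decomposition of degenerate systems is exact", {
  # all particles at one point: offset = p, within = between = 0
  p <- c(3, -2, 7)
  ps <- particle_system(matrix(rep(p, 5 * 3), 15, 3), c(a = 3L, b = 2L),
                        c("s1", "s2", "s3"))
  dec <- mlca_decompose(ps)
  expect_equal(dec$offset, matrix(p, 3, 3), tolerance = 1e-12)
  expect_equal(max(abs(dec$within[[1]])), 0, tolerance = 1e-12)
  expect_equal(max(abs(dec$between)), 0, tolerance = 1e-12)
  # K = 1: between is identically zero
  ps1 <- random_particle_system(organ_sizes = c(solo = 4L))
  expect_equal(max(abs(mlca_decompose(ps1)$between)), 0,
               tolerance = 1e-12)
})

test_that("reassembly reproduces coordinates bit-for-bit", {
  ps <- random_particle_system(n_subjects = 5,
                               organ_sizes = c(a = 3L, b = 5L, c = 2L))
  dec <- mlca_decompose(ps)
  expect_equal(mlca_reassemble(dec), ps$coords, tolerance = 1e-12)
})

test_that("decomposition invariants hold on random systems", {
  set.seed(31)
  for (rep in 1:20) {
    sizes <- setNames(sample(1:6, 3), c("a", "b", "c"))
    ps <- random_particle_system(n_subjects = 4, organ_sizes = sizes,
                                 seed = rep)
    dec <- mlca_decompose(ps)
    # within components sum to zero per (subject, organ)
    for (k in 1:3) {
      arr <- array(dec$within[[k]], dim = c(3, sizes[k], 4))
      expect_lt(max(abs(apply(arr, c(1, 3), sum))), 1e-9)
    }
    # particle-weighted between blocks sum to zero per subject
    wsum <- matrix(0, 3, 4)
    for (k in 1:3)
      wsum <- wsum + sizes[k] * dec$between[3 * (k - 1) + 1:3, ]
    expect_lt(max(abs(wsum)), 1e-9)
    # orthogonality of the expanded within and between vectors
    for (n in 1:4) {
      w_vec <- unlist(lapply(dec$within, function(m) m[, n]))
      b_vec <- unlist(lapply(1:3, function(k)
        rep(dec$between[3 * (k - 1) + 1:3, n], sizes[k])))
      expect_lt(abs(sum(w_vec * b_vec)),
                1e-9 * sqrt(sum(w_vec^2) * sum(b_vec^2)))
    }
  }
})

test_that("sum-of-squares conservation holds on 100 random systems", {
  set.seed(32)
  for (rep in 1:100) {
    K <- sample(2:4, 1)
    sizes <- setNames(sample(1:5, K, replace = TRUE),
                      paste0("o", seq_len(K)))
    N <- sample(2:6, 1)
    ps <- random_particle_system(n_subjects = N, organ_sizes = sizes,
                                 sd = runif(1, 0.1, 50), seed = 1000 + rep)
    dec <- mlca_decompose(ps)
    ss <- ssq_components(dec)
    # independent direct summation
    tot <- w <- b <- 0
    for (n in seq_len(N)) {
      z <- matrix(ps$coords[, n], nrow = 3)
      off <- rowMeans(z)  # global particle centroid
      idx <- 0
      for (k in seq_len(K)) {
        cols <- idx + seq_len(sizes[k])
        cent <- rowMeans(z[, cols, drop = FALSE])
        tot <- tot + sum((z[, cols] - off)^2)
        w <- w + sum((z[, cols] - cent)^2)
        b <- b + sizes[k] * sum((cent - off)^2)
        idx <- idx + sizes[k]
      }
    }
    expect_lt(abs(ss$total - tot) / tot, 1e-9)
    expect_lt(abs(ss$within - w) / max(w, 1e-12), 1e-9)
    expect_lt(abs(ss$between - b) / max(b, 1e-12), 1e-9)
    expect_lt(abs(ss$total - ss$within - ss$between) / ss$total, 1e-9)
  }
})

test_that("within/between gradients match finite differences of their entropies", {
  set.seed(33)
  # toy: 2 organs x 2 particles, 3 subjects (and a 8-particle variant)
  for (sizes in list(c(a = 2L, b = 2L), c(a = 5L, b = 3L))) {
    ps <- random_particle_system(n_subjects = 3, organ_sizes = sizes,
                                 sd = 2, seed = 99)
    areg <- 0.3
    gw <- mlmoshape:::within_entropy_gradient(ps, areg)
    gb <- mlmoshape:::between_entropy_gradient(ps, areg)
    hw <- function(X) {
      ps$coords <- X
      d <- mlca_decompose(ps)
      sum(vapply(d$within, subspace_entropy, numeric(1),
                 alpha_reg = areg))
    }
    hb <- function(X) {
      ps$coords <- X
      subspace_entropy(mlca_decompose(ps)$between, areg)
    }
    expect_lt(rel_err(gw, fd_gradient(hw, ps$coords)), 1e-4)
    expect_lt(rel_err(gb, fd_gradient(hb, ps$coords)), 1e-4)
  }
})

test_that("mlmo objective reduces correctly in its degenerate cases", {
  ps <- random_particle_system(n_subjects = 4,
                               organ_sizes = c(a = 3L, b = 3L), seed = 7)
  # zero subspace weights: pure negative sampling entropy
  res <- mlmo_objective(ps, alpha_within = 0, alpha_between = 0,
                        alpha_reg = 0.1, sigma = "adaptive")
  expect_equal(res$Q, -res$terms$sampling, tolerance = 1e-12)
  # identical subjects: entropies at the regularization floor
  ps2 <- ps
  ps2$coords <- matrix(rep(ps$coords[, 1], 4), ncol = 4)
  res2 <- mlmo_objective(ps2, alpha_reg = 0.25)
  expect_equal(res2$terms$within,
               rep(0.5 * 9 * log(0.25), 2), tolerance = 1e-10)
  expect_equal(res2$terms$between, 0.5 * 6 * log(0.25),
               tolerance = 1e-10)
  # full Q equals an independent dense-covariance recomputation
  dec <- mlca_decompose(ps)
  dense_h <- function(Y, a) {
    lam <- dense_pca_oracle(Y)$values
    0.5 * sum(log(lam + a))
  }
  res3 <- mlmo_objective(ps, alpha_reg = 0.1, sigma = 0.9)
  hs <- sum(vapply(1:4, function(n) sum(vapply(1:2, function(k)
    sampling_entropy(get_particles(ps, n, k), 0.9)$entropy,
    numeric(1))), numeric(1)))
  expect_equal(res3$Q,
               dense_h(dec$within[[1]], 0.1) + dense_h(dec$within[[2]], 0.1) +
                 dense_h(dec$between, 0.1) - hs,
               tolerance = 1e-9)
})

test_that("between machinery vanishes for a single organ", {
  ps <- random_particle_system(organ_sizes = c(solo = 4L))
  gb <- mlmoshape:::between_entropy_gradient(ps, 0.2)
  expect_equal(max(abs(gb)), 0, tolerance = 1e-12)
})
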