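# Particle optimization loop shared by the single-organ, global
# (shared-space) and multi-level (MLMO) modes. Particles are initialized
# one per organ and repeatedly split (each particle spawns a nearby child,
# with the same random split direction across subjects so correspondence
# order is preserved), and at every scale the combined objective
#   shape-statistics entropy  -  surface sampling entropy
# is descended with lagged statistics: covariance-based gradients are
# computed once per iteration, particle moves are tangent-projected and
# snapped back to the surface, and a backtracking step rule (halve on
# energy increase and revert; grow 1.1x on success) keeps the recorded
# energy non-increasing within every iteration.

#' Optimizer configuration
#'
#' @param particles_per_organ target particle counts, one per organ (powers
#'   of two); recycled across organs if scalar.
#' @param iterations_per_split_level iterations of the full objective at
#'   each particle-count level.
#' @param init_iterations_per_split_level sampling-only iterations run at
#'   each level before the full objective (the spreading/initialization
#'   phase; shape terms off).
#' @param mode `"mlmo"` (disentangled within/between objective),
#'   `"global"` (shared shape space) or `"single"` (one organ; identical to
#'   global with K = 1).
#' @param alpha_global weight of the shared-space entropy (global mode).
#' @param alpha_within,alpha_between subspace weights (mlmo mode).
#' @param alpha_reg_start,alpha_reg_end covariance regularization schedule,
#'   as multiples of the subspace's mean eigenvalue at the start of each
#'   level; decays geometrically over the level's iterations.
#' @param step_size initial gradient step; adapted multiplicatively.
#' @param backtrack_factor step shrink factor on energy increase.
#' @param grow_factor step growth factor on success.
#' @param max_backtracks retries per iteration before stalling.
#' @param tau_surf surface tolerance (mm); particles are snapped exactly,
#'   this bounds acceptable numerical drift.
#' @param seed RNG seed (particle splitting).
#' @param convergence_tol relative energy-change tolerance.
#' @param convergence_window iterations over which the tolerance applies.
#' @return an object of class `optimizer_config`.
#' @export
optimizer_config <- function(particles_per_organ = 128,
                             iterations_per_split_level = 250,
                             init_iterations_per_split_level = 0,
                             mode = c("mlmo", "global", "single"),
                             alpha_global = 1,
                             alpha_within = 1, alpha_between = 1,
                             alpha_reg_start = 10, alpha_reg_end = 1e-2,
                             step_size = 1, backtrack_factor = 0.5,
                             grow_factor = 1.5, max_backtracks = 10,
                             tau_surf = 1e-6, seed = 1,
                             convergence_tol = 1e-6,
                             convergence_window = 10) {
  mode <- match.arg(mode)
  ppo <- as.integer(particles_per_organ)
  if (any(ppo < 1L) || any(bitwAnd(ppo, ppo - 1L) != 0L))
    stop("particles_per_organ must be powers of two")
  stopifnot(alpha_global >= 0, alpha_within >= 0, alpha_between >= 0,
            alpha_reg_start > 0, alpha_reg_end > 0, step_size > 0,
            tau_surf > 0)
  structure(list(particles_per_organ = ppo,
                 iterations_per_split_level =
                   as.integer(iterations_per_split_level),
                 init_iterations_per_split_level =
                   as.integer(init_iterations_per_split_level),
                 mode = mode, alpha_global = alpha_global,
                 alpha_within = alpha_within,
                 alpha_between = alpha_between,
                 alpha_reg_start = alpha_reg_start,
                 alpha_reg_end = alpha_reg_end,
                 step_size = step_size,
                 backtrack_factor = backtrack_factor,
                 grow_factor = grow_factor,
                 max_backtracks = as.integer(max_backtracks),
                 tau_surf = tau_surf, seed = as.integer(seed),
                 convergence_tol = convergence_tol,
                 convergence_window = as.integer(convergence_window)),
            class = "optimizer_config")
}

# Precompute per-(subject, organ) mesh arrays for the compiled kernels.
build_mesh_cache <- function(subjects) {
  lapply(subjects, function(s)
    lapply(s$organs, function(m)
      list(V = m$vertices, F = m$faces, mesh = m,
           bbox = bbox_diagonal(m), area = mesh_area(m))))
}

# Snap all particles of a system onto their surfaces; refreshes face ids.
snap_system <- function(ps, cache) {
  N <- n_subjects(ps)
  K <- n_organs(ps)
  if (is.null(ps$face_ids))
    ps$face_ids <- matrix(NA_integer_, total_particles(ps), N)
  for (n in seq_len(N)) for (k in seq_len(K)) {
    ck <- cache[[n]][[k]]
    idx <- organ_particles(ps, k)
    hint <- ps$face_ids[idx, n]
    hint[is.na(hint)] <- 0L
    res <- closest_points_hint_cpp(get_particles(ps, n, k), ck$V, ck$F,
                                   hint)
    ps <- set_particles(ps, n, k, res$point)
    ps$face_ids[idx, n] <- res$face
  }
  ps
}

#' Initialize a particle system (one particle per organ)
#'
#' Starting point of the multiscale particle-splitting strategy: each organ
#' receives a single particle at the surface point nearest the organ's
#' vertex centroid. [split_particles()] then doubles counts per call until
#' the requested (power-of-two) counts are reached.
#'
#' @param subjects list of [multi_organ_subject].
#' @param particles_per_organ target counts (powers of two), recycled.
#' @param seed RNG seed recorded for the later splits.
#' @return a [particle_system] with `M_k = 1` for every organ and an
#'   attribute `target_particles`.
#' @export
initialize_particles <- function(subjects, particles_per_organ, seed = 1) {
  labs <- check_ensemble(subjects)
  K <- length(labs)
  ppo <- as.integer(rep_len(particles_per_organ, K))
  if (any(ppo < 1L) || any(bitwAnd(ppo, ppo - 1L) != 0L))
    stop("particles_per_organ must be powers of two")
  cache <- build_mesh_cache(subjects)
  N <- length(subjects)
  cols <- vapply(seq_len(N), function(n) {
    unlist(lapply(seq_len(K), function(k) {
      m <- subjects[[n]]$organs[[k]]
      np <- nearest_point_on_surface(m, mesh_centroid(m))
      as.numeric(np$point)
    }))
  }, numeric(3L * K))
  ps <- particle_system(cols, setNames(rep(1L, K), labs),
                        vapply(subjects, `[[`, "", "subject_id"))
  ps <- snap_system(ps, cache)
  attr(ps, "target_particles") <- setNames(ppo, labs)
  ps
}

#' Split particles (double per-organ counts)
#'
#' Every particle spawns a child at a small random tangential offset,
#' reprojected to the surface. The split direction for particle m of organ
#' k is shared across subjects, so the correspondence ordering is
#' preserved; children are appended after the parents (child of parent m
#' lands at index `M_k + m`).
#'
#' @param ps a [particle_system].
#' @param subjects the ensemble the particles live on.
#' @param seed RNG seed for the split directions.
#' @param organs indices of organs to split (default all).
#' @return the system with doubled counts for the selected organs.
#' @export
split_particles <- function(ps, subjects, seed = 1, organs = NULL) {
  cache <- build_mesh_cache(subjects)
  K <- n_organs(ps)
  N <- n_subjects(ps)
  if (is.null(organs)) organs <- seq_len(K)
  sizes <- ps$organ_sizes
  set.seed(as.integer(seed))
  dirs <- lapply(seq_len(K), function(k)
    if (k %in% organs)
      matrix(rnorm(3L * sizes[k]), sizes[k], 3L) else NULL)

  new_sizes <- sizes
  new_sizes[organs] <- 2L * sizes[organs]
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    old <- ps$coords[organ_rows(ps, k), , drop = FALSE]
    if (!(k %in% organs)) {
      blocks[[k]] <- old
      next
    }
    kids <- matrix(0, 3L * sizes[k], N)
    for (n in seq_len(N)) {
      ck <- cache[[n]][[k]]
      P <- get_particles(ps, n, k)
      fid <- ps$face_ids[organ_particles(ps, k), n]
      nrm <- face_normals(ck$mesh)[fid, , drop = FALSE]
      tang <- dirs[[k]] - rowSums(dirs[[k]] * nrm) * nrm
      tl <- sqrt(rowSums(tang^2))
      degen <- tl < 1e-8
      if (any(degen)) {  # split direction parallel to the normal: rotate
        alt <- cbind(-dirs[[k]][degen, 2], dirs[[k]][degen, 1],
                     dirs[[k]][degen, 3])
        tang[degen, ] <- alt - rowSums(alt * nrm[degen, , drop = FALSE]) *
          nrm[degen, , drop = FALSE]
        tl <- sqrt(rowSums(tang^2))
        tl[tl < 1e-12] <- 1
      }
      len <- split_offset_length(P, ck$area)
      child <- P + tang / tl * len
      res <- closest_points_hint_cpp(child, ck$V, ck$F, fid)
      kids[, n] <- as.vector(t(res$point))
    }
    blocks[[k]] <- rbind(old, kids)
  }
  out <- particle_system(do.call(rbind, blocks), new_sizes,
                         ps$subject_ids)
  out <- snap_system(out, cache)
  attr(out, "target_particles") <- attr(ps, "target_particles")
  out
}

# Offset used when spawning a child particle: the spacing a uniform
# covering of the surface would have at the doubled count, so coverage
# expands across split levels instead of staying clumped near the seed.
split_offset_length <- function(P, area) {
  sqrt(area / (2 * nrow(P)))
}

# ---- energies and gradients --------------------------------------------

# Frozen per-(subject, organ) kernel widths for one iteration: a single
# covering-scale width per organ, 0.7 * sqrt(area / M) (the spacing of a
# uniform covering). A shared width keeps the density estimate sensitive
# to density differences across the surface, which is what drives global
# spreading; per-particle adaptive widths equalize local scales and let
# clumped configurations stall.
compute_sigma_list <- function(ps, cache) {
  N <- n_subjects(ps)
  K <- n_organs(ps)
  lapply(seq_len(N), function(n) lapply(seq_len(K), function(k) {
    Mk <- ps$organ_sizes[k]
    rep(0.7 * sqrt(cache[[n]][[k]]$area / Mk), Mk)
  }))
}

total_sampling_entropy <- function(ps, sigma_list) {
  h <- 0
  for (n in seq_len(n_subjects(ps))) for (k in seq_len(n_organs(ps))) {
    if (ps$organ_sizes[k] < 2L) next
    h <- h + sampling_entropy(get_particles(ps, n, k),
                              sigma_list[[n]][[k]])$entropy
  }
  h
}

# Combined objective for the current mode, with frozen kernel widths and
# regularization. For mlmo, alpha_reg is a list (within per organ,
# between); for global a scalar.
total_energy <- function(ps, config, sigma_list, alpha_reg) {
  hs <- total_sampling_entropy(ps, sigma_list)
  shape_off <- (config$mode == "mlmo" && config$alpha_within == 0 &&
                  config$alpha_between == 0) ||
    (config$mode != "mlmo" && config$alpha_global == 0)
  if (shape_off)
    return(list(Q = -hs, shape = 0, sampling = hs))
  if (config$mode == "mlmo") {
    dec <- mlca_decompose(ps)
    areg <- normalize_alpha_reg(alpha_reg, n_organs(ps))
    hw <- vapply(seq_len(n_organs(ps)), function(k)
      subspace_entropy(dec$within[[k]], areg$within[k]), numeric(1))
    hb <- subspace_entropy(dec$between, areg$between)
    q <- config$alpha_within * sum(hw) + config$alpha_between * hb - hs
    list(Q = q, shape = config$alpha_within * sum(hw) +
           config$alpha_between * hb, sampling = hs)
  } else {
    hz <- subspace_entropy(ps$coords, alpha_reg)
    list(Q = config$alpha_global * hz - hs,
         shape = config$alpha_global * hz, sampling = hs)
  }
}

# Apply one tangential, capped, surface-snapped move to every particle.
# shape_grad is the (3M) x N entropy gradient to descend (may be zero);
# sampling gradients (entropy ascent = repulsion) are added when
# `with_sampling` is TRUE.
apply_moves <- function(ps, cache, shape_grad, sigma_list, eta,
                        with_sampling) {
  N <- n_subjects(ps)
  K <- n_organs(ps)
  for (n in seq_len(N)) for (k in seq_len(K)) {
    ck <- cache[[n]][[k]]
    P <- get_particles(ps, n, k)
    Mk <- nrow(P)
    g <- matrix(shape_grad[organ_rows(ps, k), n], ncol = 3L, byrow = TRUE)
    dir <- -g
    if (with_sampling && Mk >= 2L)
      dir <- dir + sampling_entropy(P, sigma_list[[n]][[k]])$gradient
    fid <- ps$face_ids[organ_particles(ps, k), n]
    nrm <- face_normals(ck$mesh)[fid, , drop = FALSE]
    dir <- dir - rowSums(dir * nrm) * nrm       # tangent projection
    step <- eta * dir
    cap <- if (Mk >= 2L) sigma_list[[n]][[k]] else ck$bbox / 20
    sl <- sqrt(rowSums(step^2))
    over <- sl > cap
    if (any(over)) step[over, ] <- step[over, , drop = FALSE] *
      (cap[over] / sl[over])
    res <- closest_points_hint_cpp(P + step, ck$V, ck$F, fid)
    ps <- set_particles(ps, n, k, res$point)
    ps$face_ids[organ_particles(ps, k), n] <- res$face
  }
  ps
}

#' One alternating MLMO iteration
#'
#' With statistics lagged (decomposition, subspace gradients and kernel
#' widths computed once at entry), applies the within-subspace phase
#' (within-entropy descent plus sampling repulsion, tangent-projected and
#' snapped per particle) and then the between-subspace phase (between-
#' entropy descent mapped through the centroid Jacobians), sequentially.
#' Organ surfaces never move; only particle placement changes.
#'
#' @param ps a [particle_system].
#' @param subjects the ensemble.
#' @param config an [optimizer_config] with `mode = "mlmo"`.
#' @param eta step size (defaults to `config$step_size`).
#' @param cache,sigma_list,alpha_reg optional precomputed state (internal
#'   use by the optimization loop).
#' @return the updated [particle_system].
#' @export
mlmo_step <- function(ps, subjects, config, eta = config$step_size,
                      cache = NULL, sigma_list = NULL, alpha_reg = NULL) {
  if (is.null(cache)) cache <- build_mesh_cache(subjects)
  if (is.null(ps$face_ids)) ps <- snap_system(ps, cache)
  if (is.null(sigma_list)) sigma_list <- compute_sigma_list(ps, cache)
  if (is.null(alpha_reg))
    alpha_reg <- default_alpha_reg(ps, "mlmo", 1e-2)
  zero <- matrix(0, nrow(ps$coords), ncol(ps$coords))
  gw <- if (config$alpha_within > 0)
    config$alpha_within * within_entropy_gradient(ps, alpha_reg) else zero
  ps <- apply_moves(ps, cache, gw, sigma_list, eta, with_sampling = TRUE)
  if (config$alpha_between > 0) {
    gb <- config$alpha_between * between_entropy_gradient(ps, alpha_reg)
    ps <- apply_moves(ps, cache, gb, sigma_list, eta,
                      with_sampling = FALSE)
  }
  ps
}

# One global-mode iteration (shared shape space), same mechanics.
global_step <- function(ps, cache, config, eta, sigma_list, alpha_reg) {
  g <- if (config$alpha_global > 0)
    config$alpha_global * shared_entropy_gradient(ps, alpha_reg)
  else matrix(0, nrow(ps$coords), ncol(ps$coords))
  apply_moves(ps, cache, g, sigma_list, eta, with_sampling = TRUE)
}

# Regularization anchored at the subspace's mean covariance eigenvalue
# (trace / dimension), floored to stay positive for degenerate data.
mean_eigenvalue <- function(Y) {
  N <- ncol(Y)
  Yc <- Y - rowMeans(Y)
  max(sum(Yc^2) / ((N - 1) * nrow(Y)), 1e-10)
}

default_alpha_reg <- function(ps, mode, factor) {
  if (mode == "mlmo") {
    dec <- mlca_decompose(ps)
    list(within = factor * vapply(dec$within, mean_eigenvalue, numeric(1)),
         between = factor * mean_eigenvalue(dec$between))
  } else {
    factor * mean_eigenvalue(ps$coords)
  }
}

scale_alpha_reg <- function(base, s) {
  if (is.list(base)) list(within = base$within * s, between = base$between * s)
  else base * s
}

#' Optimize correspondence particles across an ensemble
#'
#' Runs the multiscale particle-splitting optimization: particles start one
#' per organ, are doubled level by level up to
#' `config$particles_per_organ`, and at each level the mode's objective is
#' descended with lagged statistics and a backtracking step rule. Every
#' accepted iteration satisfies `q_after <= q_before` (up to the
#' backtracking tolerance) under that iteration's frozen kernel widths and
#' regularization; all particles lie exactly on their surfaces after every
#' iteration. Deterministic given `config$seed`.
#'
#' @param subjects list of [multi_organ_subject] (at least 3).
#' @param config an [optimizer_config].
#' @return list with `particles` (the final [particle_system]) and `trace`
#'   (data frame: level, iteration, q_before, q_after, shape and sampling
#'   terms, step size, backtracks).
#' @export
optimize_particles <- function(subjects, config) {
  stopifnot(inherits(config, "optimizer_config"))
  labs <- check_ensemble(subjects)
  if (length(subjects) < 3L) stop("need at least 3 subjects")
  if (config$mode == "single" && length(labs) != 1L)
    stop("mode 'single' requires exactly one organ")
  run_mode <- if (config$mode == "single") "global" else config$mode
  cfg <- config
  cfg$mode <- run_mode
  targets <- setNames(as.integer(rep_len(config$particles_per_organ,
                                         length(labs))), labs)

  cache <- build_mesh_cache(subjects)
  ps <- initialize_particles(subjects, targets, seed = config$seed)
  trace <- list()
  level <- 0L
  init_cfg <- cfg
  init_cfg$alpha_global <- 0
  init_cfg$alpha_within <- 0
  init_cfg$alpha_between <- 0
  while (any(ps$organ_sizes < targets)) {
    level <- level + 1L
    grow <- which(ps$organ_sizes < targets)
    ps <- split_particles(ps, subjects, seed = config$seed + level,
                          organs = grow)
    pieces <- list()
    if (config$init_iterations_per_split_level > 0L) {
      res <- run_level(ps, cache, init_cfg, level, phase = "init",
                       iters = config$init_iterations_per_split_level)
      ps <- res$ps
      pieces$init <- res$trace
    }
    res <- run_level(ps, cache, cfg, level, phase = "opt",
                     iters = config$iterations_per_split_level)
    ps <- res$ps
    pieces$opt <- res$trace
    trace[[level]] <- do.call(rbind, pieces)
  }
  list(particles = ps,
       trace = do.call(rbind, trace))
}

run_level <- function(ps, cache, config, level, phase = "opt",
                      iters = config$iterations_per_split_level) {
  base_reg <- default_alpha_reg(ps, config$mode, 1)
  decay <- (config$alpha_reg_end / config$alpha_reg_start)^
    (1 / max(iters - 1L, 1L))
  eta <- config$step_size
  rows <- vector("list", iters)
  q_hist <- rep(NA_real_, iters)
  for (it in seq_len(iters)) {
    sigma_list <- compute_sigma_list(ps, cache)
    areg <- scale_alpha_reg(base_reg,
                            config$alpha_reg_start * decay^(it - 1L))
    e0 <- total_energy(ps, config, sigma_list, areg)
    if (!is.finite(e0$Q))
      stop("non-finite energy at level ", level, " iteration ", it)
    qb <- e0$Q
    accepted <- FALSE
    tries <- 0L
    cand <- ps
    qa <- qb
    while (tries <= config$max_backtracks) {
      cand <- if (config$mode == "mlmo") {
        mlmo_step(ps, NULL, config, eta = eta, cache = cache,
                  sigma_list = sigma_list, alpha_reg = areg)
      } else {
        global_step(ps, cache, config, eta, sigma_list, areg)
      }
      e1 <- total_energy(cand, config, sigma_list, areg)
      qa <- e1$Q
      if (is.finite(qa) && qa <= qb + 1e-10 * (1 + abs(qb))) {
        accepted <- TRUE
        break
      }
      eta <- eta * config$backtrack_factor
      tries <- tries + 1L
    }
    if (accepted) {
      ps <- cand
      eta <- eta * config$grow_factor
    } else {
      qa <- qb  # stalled: keep the previous particle set
    }
    rows[[it]] <- data.frame(level = level, phase = phase,
                             iteration = it,
                             q_before = qb, q_after = qa,
                             shape = e0$shape, sampling = e0$sampling,
                             eta = eta, backtracks = tries,
                             accepted = accepted)
    q_hist[it] <- qa
    w <- config$convergence_window
    if (it > w) {
      rel <- abs(q_hist[it] - q_hist[it - w]) /
        max(abs(q_hist[it]), 1e-12)
      if (rel < config$convergence_tol) break
    }
  }
  list(ps = ps, trace = do.call(rbind, rows[!vapply(rows, is.null,
                                                    logical(1))]))
}
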