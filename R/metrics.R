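# Subspace-aware model-quality metrics (compactness, generalization,
# specificity) and the joint coverage-area measurement. Generalization and
# specificity accept the shared subspace or any MLCA subspace; both are
# computed in the subspace's own coordinates, and errors are Euclidean
# distances in mm.

# Pull one subspace's data matrix (D x N) out of a particle system.
subspace_data <- function(ps, subspace, organ = NULL) {
  if (subspace == "shared") return(ps$coords)
  dec <- mlca_decompose(ps)
  if (subspace == "between") return(dec$between)
  if (is.null(organ)) stop("within-subspace metrics require an organ")
  k <- if (is.character(organ)) match(organ, names(ps$organ_sizes))
  else as.integer(organ)
  if (is.na(k) || k < 1L || k > n_organs(ps))
    stop("unknown organ: ", organ)
  dec$within[[k]]
}

#' Compactness of a subspace model
#'
#' Cumulative variance retained by the leading modes:
#' \eqn{C(P) = \sum_{p \le P} \lambda_p}. Higher at fixed `P` means fewer
#' modes are needed to explain the data.
#'
#' @param model a [fit_subspace_model()] result.
#' @param P number of modes, `1 <= P <= rank`; may be a vector.
#' @return variance sum(s), same length as `P`.
#' @export
compactness <- function(model, P) {
  stopifnot(inherits(model, "subspace_model"))
  P <- as.integer(P)
  if (any(P < 1L) || any(P > length(model$values)))
    stop("P out of range: model has ", length(model$values), " modes")
  cumsum(model$values)[P]
}

#' Generalization error (leave-one-out)
#'
#' For every subject, the model is refit on the other N - 1 subjects, the
#' held-out subject's subspace vector is projected onto the leading `P`
#' modes and reconstructed, and the Euclidean distance (mm) between the
#' vector and its reconstruction is recorded; the metric is the mean over
#' subjects. For the within/between subspaces the held-out vector is the
#' subject's own decomposed component (its offset is kept, not modeled).
#' All `P` are evaluated from one eigendecomposition per fold.
#'
#' @param ps a [particle_system] with at least 3 subjects.
#' @param subspace `"shared"`, `"within"` or `"between"`.
#' @param P mode counts to evaluate (vector allowed).
#' @param organ organ label or index, for `subspace = "within"`.
#' @return data frame with columns `P` and `value` (mm).
#' @export
generalization <- function(ps, subspace = c("shared", "within", "between"),
                           P = 1L, organ = NULL) {
  subspace <- match.arg(subspace)
  N <- n_subjects(ps)
  if (N < 3L) stop("generalization needs at least 3 subjects")
  Y <- subspace_data(ps, subspace, organ)
  P <- as.integer(P)
  errs <- matrix(NA_real_, N, length(P))
  for (n in seq_len(N)) {
    fit <- fit_subspace_model(Y[, -n, drop = FALSE])
    yc <- Y[, n] - fit$mean
    a <- as.numeric(crossprod(fit$vectors, yc))
    # ||resid_P||^2 = ||yc||^2 - sum_{p<=P} a_p^2 (orthonormal basis)
    tot <- sum(yc^2)
    if (length(a) == 0L) {
      errs[n, ] <- sqrt(tot)
    } else {
      cums <- cumsum(a^2)
      pn <- pmin(P, length(a))
      got <- ifelse(pn >= 1L, cums[pmax(pn, 1L)], 0)
      errs[n, ] <- sqrt(pmax(tot - got, 0))
    }
  }
  data.frame(P = P, value = colMeans(errs))
}

#' Specificity of a subspace model
#'
#' Draws `T` random coefficient vectors with independent components
#' \eqn{\alpha_p \sim N(0, \lambda_p)} for the leading `P` modes,
#' reconstructs each sample in the subspace, and averages the Euclidean
#' distance (mm) to the nearest training sample. Sampling and the distance
#' are both computed in the subspace's own coordinates. Deterministic
#' given `seed`.
#'
#' @param ps a [particle_system] (the training data).
#' @param subspace `"shared"`, `"within"` or `"between"`.
#' @param P mode counts to evaluate (vector allowed).
#' @param T number of random samples (default 1000).
#' @param seed RNG seed.
#' @param organ organ label or index, for `subspace = "within"`.
#' @return data frame with columns `P` and `value` (mm).
#' @export
specificity <- function(ps, subspace = c("shared", "within", "between"),
                        P = 1L, T = 1000L, seed = 1L, organ = NULL) {
  subspace <- match.arg(subspace)
  Y <- subspace_data(ps, subspace, organ)
  fit <- fit_subspace_model(Y)
  P <- as.integer(P)
  if (any(P < 0L) || any(P > length(fit$values)))
    stop("P out of range: model has ", length(fit$values), " modes")
  r <- length(fit$values)
  set.seed(as.integer(seed))
  Z <- matrix(rnorm(T * r), T, r)  # one draw, reused across P
  vals <- vapply(P, function(p) {
    coef <- if (p > 0L)
      Z[, seq_len(p), drop = FALSE] *
        rep(sqrt(fit$values[seq_len(p)]), each = T)
    else matrix(0, T, 0L)
    S <- fit$mean +
      (if (p > 0L) fit$vectors[, seq_len(p), drop = FALSE] %*% t(coef)
       else matrix(0, length(fit$mean), T))
    # T x N cross distances to the training columns
    d2 <- outer(colSums(S^2), colSums(Y^2), "+") - 2 * crossprod(S, Y)
    mean(sqrt(pmax(apply(d2, 1L, min), 0)))
  }, numeric(1))
  data.frame(P = P, value = vals)
}

#' Joint coverage area by face-normal ray casting
#'
#' For every face of `mesh_a`, a ray is cast from the face centroid along
#' the face normal; the face counts as covered if the ray intersects any
#' face of `mesh_b` (forward direction only). The returned value is the
#' summed area (mm^2) of the covered faces. Normal orientation follows the
#' face winding: for a meaningful result, `mesh_a`'s normals must point
#' toward the opposing surface (outward winding for a bone facing its
#' articulation partner). Self-intersections with `mesh_a` are ignored.
#'
#' @param mesh_a the mesh whose covered area is measured.
#' @param mesh_b the opposing mesh.
#' @return covered area (mm^2).
#' @export
coverage_area <- function(mesh_a, mesh_b) {
  stopifnot(inherits(mesh_a, "surface_mesh"),
            inherits(mesh_b, "surface_mesh"))
  if (nrow(mesh_a$faces) == 0L || nrow(mesh_b$faces) == 0L)
    stop("both meshes must be nonempty")
  hits <- ray_hits_cpp(face_centroids(mesh_a), face_normals(mesh_a),
                       mesh_b$vertices, mesh_b$faces, 1e-9)
  sum(face_areas(mesh_a)[hits[, 1L] > 0])
}

#' Relative error of an area estimate
#'
#' \eqn{\epsilon = |\hat a - a| / a}, dimensionless.
#'
#' @param a_hat estimated area (mm^2).
#' @param a reference area (mm^2), must be positive.
#' @return relative error.
#' @export
relative_error <- function(a_hat, a) {
  if (any(a <= 0)) stop("reference area must be positive")
  abs(a_hat - a) / a
}

#' Number of dominant modes of a spectrum
#'
#' Counts the eigenvalues whose share of the total variance is at least
#' `fraction_threshold`. A well-recovered single-factor subspace has
#' exactly one dominant mode.
#'
#' @param eigenvalues nonnegative spectrum with positive sum.
#' @param fraction_threshold share cutoff (default 0.05).
#' @return integer count.
#' @export
dominant_mode_count <- function(eigenvalues, fraction_threshold = 0.05) {
  tot <- sum(eigenvalues)
  if (!is.finite(tot) || tot <= 0)
    stop("spectrum must have a positive sum")
  sum(eigenvalues / tot >= fraction_threshold)
}

#' Write metric curves as CSV
#'
#' One file per metric/subspace: `metrics_<name>_<subspace>.csv` with
#' columns `P, value`.
#'
#' @param curve data frame from [generalization()] or [specificity()], or
#'   a compactness curve built with [compactness()].
#' @param name metric name.
#' @param subspace subspace label.
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
write_metric_csv <- function(curve, name, subspace, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, sprintf("metrics_%s_%s.csv", name, subspace))
  write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
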