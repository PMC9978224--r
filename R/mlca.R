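# Post-optimization statistics: PCA in the shared shape space and
# multilevel component analysis in the within/between subspaces. All PCA is
# done through the N x N Gram matrix, so fitting cost is independent of the
# particle count; eigenvector signs follow a fixed convention
# (largest-magnitude component positive) so mode signs are reproducible.

#' Fit a PCA model of one subspace
#'
#' @param Y data matrix, rows = coordinates, columns = N samples.
#' @param tag subspace tag (`"G"`, `"W_<organ>"`, `"B"`), bookkeeping only.
#' @return an object of class `subspace_model`: `mean` (length-D vector),
#'   `vectors` (`D x r` orthonormal columns), `values` (nonincreasing
#'   eigenvalues of the `1/(N-1)` sample covariance; eigenvalues below
#'   `1e-12 * lambda_max` are truncated), `total_variance` (trace of the
#'   covariance), `n` (samples).
#' @export
fit_subspace_model <- function(Y, tag = "G") {
  Y <- as.matrix(Y)
  N <- ncol(Y)
  if (N < 2L) stop("subspace model needs at least 2 samples")
  mu <- rowMeans(Y)
  Yc <- Y - mu
  G <- crossprod(Yc) / (N - 1)
  e <- eigen(G, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  keep <- which(lam > 1e-12 * max(lam, 0) & lam > 0 &
                  seq_along(lam) <= N - 1L)
  U <- if (length(keep)) {
    u <- Yc %*% e$vectors[, keep, drop = FALSE]
    u <- sweep(u, 2L, sqrt((N - 1) * lam[keep]), "/")
    # sign convention: largest-magnitude component positive
    for (j in seq_len(ncol(u))) {
      i <- which.max(abs(u[, j]))
      if (u[i, j] < 0) u[, j] <- -u[, j]
    }
    u
  } else {
    matrix(0, nrow(Y), 0L)
  }
  structure(list(tag = tag, mean = mu, vectors = U,
                 values = lam[keep], total_variance = sum(Yc^2) / (N - 1),
                 n = N),
            class = "subspace_model")
}

#' @export
print.subspace_model <- function(x, ...) {
  cat("subspace_model", x$tag, ":", length(x$mean), "dims,",
      length(x$values), "modes, total variance",
      format(x$total_variance, digits = 4), "\n")
  invisible(x)
}

#' Shared-space PCA of a particle system
#'
#' The baseline point distribution model: PCA of the flattened `3M`-vectors
#' of all organs concatenated, where shape and pose variation remain
#' entangled.
#'
#' @param ps a [particle_system] with at least 2 subjects.
#' @return a [fit_subspace_model()] result with tag `"G"`.
#' @export
fit_shared_pca <- function(ps) {
  stopifnot(inherits(ps, "particle_system"))
  fit_subspace_model(ps$coords, tag = "G")
}

#' Fit the multilevel component model
#'
#' PCA independently on each organ's within matrix and on the between
#' (centroid-deviation) matrix of the decomposition, yielding K + 1
#' mutually orthogonal subspaces, plus the consolidated mean (offset mean +
#' between mean broadcast per organ + within mean) in the full particle
#' space.
#'
#' @param ps a [particle_system] with at least 2 subjects.
#' @return an object of class `mlca_model`: `within` (list of
#'   `subspace_model`), `between` (`subspace_model` over the `3K`
#'   centroid deviations), `offset_mean` (length 3), `mean_full` (length
#'   `3M` consolidated mean), `organ_sizes`.
#' @export
fit_mlca <- function(ps) {
  stopifnot(inherits(ps, "particle_system"))
  dec <- mlca_decompose(ps)
  labs <- names(ps$organ_sizes)
  within <- lapply(seq_along(labs), function(k)
    fit_subspace_model(dec$within[[k]], tag = paste0("W_", labs[k])))
  names(within) <- labs
  between <- fit_subspace_model(dec$between, tag = "B")
  offset_mean <- rowMeans(dec$offset)
  sizes <- ps$organ_sizes
  mean_full <- unlist(lapply(seq_along(labs), function(k) {
    cent <- offset_mean + between$mean[3L * (k - 1L) + 1:3]
    within[[k]]$mean + rep(cent, sizes[k])
  }), use.names = FALSE)
  structure(list(within = within, between = between,
                 offset_mean = offset_mean, mean_full = mean_full,
                 organ_sizes = sizes),
            class = "mlca_model")
}

#' @export
print.mlca_model <- function(x, ...) {
  cat("mlca_model:", length(x$within), "within subspaces +",
      "between subspace (", length(x$between$mean), "dims )\n")
  invisible(x)
}

# Decompose a single flattened sample vector (length 3M) into offset,
# per-organ within vectors, and the 3K between vector.
decompose_sample <- function(z, organ_sizes) {
  ps1 <- particle_system(matrix(z, ncol = 1L), organ_sizes, "sample")
  dec <- mlca_decompose(ps1)
  list(offset = dec$offset[, 1L],
       within = lapply(dec$within, function(m) m[, 1L]),
       between = dec$between[, 1L])
}

#' Project a sample onto the MLCA subspaces
#'
#' Orthogonal projections of the sample's within and between components
#' onto the fitted bases. The sample's own offset (global centroid) is
#' returned as-is; it is not modeled.
#'
#' @param model an [fit_mlca()] model.
#' @param z flattened sample vector (length `3M`, same organ partition).
#' @return list with `alpha_within` (list of coefficient vectors, one per
#'   organ), `alpha_between`, `offset`.
#' @export
project_sample <- function(model, z) {
  stopifnot(inherits(model, "mlca_model"))
  if (length(z) != length(model$mean_full))
    stop("sample dimension mismatch: expected ", length(model$mean_full),
         ", got ", length(z))
  d <- decompose_sample(z, model$organ_sizes)
  aw <- lapply(seq_along(model$within), function(k)
    as.numeric(crossprod(model$within[[k]]$vectors,
                         d$within[[k]] - model$within[[k]]$mean)))
  names(aw) <- names(model$within)
  ab <- as.numeric(crossprod(model$between$vectors,
                             d$between - model$between$mean))
  list(alpha_within = aw, alpha_between = ab, offset = d$offset)
}

#' Reconstruct a flattened shape vector from MLCA coefficients
#'
#' Linear generative reconstruction: per organ, consolidated mean plus the
#' within modes plus the between modes, where each organ's between
#' eigenvector block (a 3-vector per organ) is broadcast uniformly to all
#' of that organ's particles. Coefficients beyond the retained mode counts
#' are dropped.
#'
#' @param model an [fit_mlca()] model.
#' @param coefficients list as returned by [project_sample()]; `offset`,
#'   if present, replaces the model's mean offset.
#' @param p_within number of within modes to retain (scalar or per-organ
#'   vector; `Inf` = all).
#' @param p_between number of between modes to retain.
#' @return the reconstructed flattened vector (length `3M`).
#' @export
reconstruct_shape <- function(model, coefficients, p_within = Inf,
                              p_between = Inf) {
  stopifnot(inherits(model, "mlca_model"))
  K <- length(model$within)
  sizes <- model$organ_sizes
  pw <- rep_len(p_within, K)
  if (any(pw < 0) || p_between < 0) stop("mode counts must be >= 0")
  if (any(is.finite(pw) & pw > vapply(model$within, function(m)
    length(m$values), numeric(1))) ||
    (is.finite(p_between) && p_between > length(model$between$values)))
    stop("requested more modes than the model holds")

  # between reconstruction in the 3K space
  nb <- min(p_between, length(model$between$values))
  yb <- model$between$mean
  if (nb > 0) {
    ab <- coefficients$alpha_between[seq_len(nb)]
    yb <- yb + model$between$vectors[, seq_len(nb), drop = FALSE] %*% ab
  }
  offset <- if (!is.null(coefficients$offset)) coefficients$offset
  else model$offset_mean

  out <- unlist(lapply(seq_len(K), function(k) {
    mw <- model$within[[k]]
    nwk <- min(pw[k], length(mw$values))
    yw <- mw$mean
    if (nwk > 0) {
      awk <- coefficients$alpha_within[[k]][seq_len(nwk)]
      yw <- yw + mw$vectors[, seq_len(nwk), drop = FALSE] %*% awk
    }
    cent <- offset + yb[3L * (k - 1L) + 1:3]
    as.numeric(yw) + rep(cent, sizes[k])
  }), use.names = FALSE)
  out
}

#' Sweep a mode of variation
#'
#' Returns the flattened shape vectors `mean + c * sqrt(lambda) * u` for
#' each requested multiple `c`. Sweeping a between mode moves organ
#' centroids while leaving every organ's centered within-shape untouched,
#' and vice versa — the disentanglement property of the multilevel model.
#'
#' @param model an [fit_mlca()] model, or a shared-space
#'   [fit_subspace_model()] (tag `"G"`).
#' @param subspace `"within"`, `"between"` or `"shared"`.
#' @param mode 1-based mode index.
#' @param sigmas multiples of the mode standard deviation (default
#'   `c(-2, -1, 0, 1, 2)`).
#' @param organ organ label or index (required for `subspace = "within"`).
#' @return a `D x length(sigmas)` matrix of flattened shape vectors, with
#'   column names from `sigmas`.
#' @export
mode_sweep <- function(model, subspace = c("within", "between", "shared"),
                       mode = 1L, sigmas = c(-2, -1, 0, 1, 2),
                       organ = NULL) {
  subspace <- match.arg(subspace)
  if (subspace == "shared") {
    stopifnot(inherits(model, "subspace_model"))
    if (mode > length(model$values)) stop("mode index exceeds model rank")
    step <- sqrt(model$values[mode]) * model$vectors[, mode]
    out <- vapply(sigmas, function(s) model$mean + s * step,
                  numeric(length(model$mean)))
  } else {
    stopifnot(inherits(model, "mlca_model"))
    K <- length(model$within)
    zeros <- list(alpha_within = lapply(model$within, function(m)
      numeric(length(m$values))),
      alpha_between = numeric(length(model$between$values)))
    if (subspace == "within") {
      if (is.null(organ)) stop("within-subspace sweep requires an organ")
      k <- if (is.character(organ)) match(organ, names(model$within))
      else as.integer(organ)
      if (is.na(k) || k < 1L || k > K) stop("unknown organ: ", organ)
      mw <- model$within[[k]]
      if (mode > length(mw$values)) stop("mode index exceeds model rank")
      sd_m <- sqrt(mw$values[mode])
      out <- vapply(sigmas, function(s) {
        co <- zeros
        co$alpha_within[[k]][mode] <- s * sd_m
        reconstruct_shape(model, co)
      }, numeric(length(model$mean_full)))
    } else {
      if (mode > length(model$between$values))
        stop("mode index exceeds model rank")
      sd_m <- sqrt(model$between$values[mode])
      out <- vapply(sigmas, function(s) {
        co <- zeros
        co$alpha_between[mode] <- s * sd_m
        reconstruct_shape(model, co)
      }, numeric(length(model$mean_full)))
    }
  }
  colnames(out) <- as.character(sigmas)
  out
}

#' Write eigenvalue CSVs for all subspaces
#'
#' `eigen_G.csv` (shared), `eigen_W_<organ>.csv` per organ, and
#' `eigen_B.csv` (between), each with columns `mode, eigenvalue`.
#'
#' @param mlca an [fit_mlca()] model.
#' @param shared a [fit_shared_pca()] model (optional).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_eigen_csvs <- function(mlca, shared = NULL, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eig_df <- function(m) data.frame(mode = seq_along(m$values),
                                   eigenvalue = m$values)
  if (!is.null(shared))
    write.csv(eig_df(shared), file.path(dir, "eigen_G.csv"),
              row.names = FALSE)
  for (lab in names(mlca$within))
    write.csv(eig_df(mlca$within[[lab]]),
              file.path(dir, sprintf("eigen_W_%s.csv", lab)),
              row.names = FALSE)
  write.csv(eig_df(mlca$between), file.path(dir, "eigen_B.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Export a decomposition as CSV matrices
#'
#' `within_<organ>.csv`, `between.csv` and `offsets.csv`: rows are
#' flattened coordinates, columns are subjects (header = subject ids).
#'
#' @param ps a [particle_system].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_decomposition_csvs <- function(ps, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dec <- mlca_decompose(ps)
  as_df <- function(m) {
    d <- as.data.frame(m)
    names(d) <- ps$subject_ids
    d
  }
  for (lab in names(dec$within))
    write.csv(as_df(dec$within[[lab]]),
              file.path(dir, sprintf("within_%s.csv", lab)),
              row.names = FALSE)
  write.csv(as_df(dec$between), file.path(dir, "between.csv"),
            row.names = FALSE)
  write.csv(as_df(dec$offset), file.path(dir, "offsets.csv"),
            row.names = FALSE)
  invisible(dir)
}
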