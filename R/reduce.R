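pool_features <- function(trajs) {
  if (inherits(trajs, "feature_trajectory") || is.matrix(trajs))
    trajs <- list(trajs)
  mats <- lapply(trajs, function(x) {
    m <- ft_matrix(as.matrix(x))
    if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
    m
  })
  nm <- colnames(mats[[1]])
  for (m in mats) if (!identical(colnames(m), nm))
    stop_("all trajectories must share the same feature set")
  list(mats = mats, names = nm)
}

#' Joint principal component analysis across ensembles
#'
#' Eigendecomposition of the pooled covariance of the mean-centred features
#' of all supplied trajectories. Fitting one PCA on the pooled frames of
#' several ensembles yields a single, directly comparable projection space
#' for all of them. Rank-deficient input keeps only the
#' nonzero-eigenvalue components, with a warning.
#'
#' @param trajs a [feature_trajectory()]/matrix or a list of them (e.g. the
#'   replicas of two protonation-state ensembles together).
#' @return object of class `linear_projection` with `kind = "pca"`: `mean`,
#'   `components` (features x components), `eigenvalues` (variances),
#'   `explained` (fractions summing to 1 over all components of the full
#'   trace), `feature_names`.
#' @export
fit_pca <- function(trajs) {
  p <- pool_features(trajs)
  X <- do.call(rbind, p$mats)
  if (nrow(X) < 2L) stop_("need at least 2 frames")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  keep <- ev > max(ev) * 1e-12
  if (!all(keep)) {
    warn_("rank-deficient covariance: keeping %d of %d components",
          sum(keep), length(keep))
  }
  structure(list(kind = "pca", mean = pc$center,
                 components = pc$rotation[, keep, drop = FALSE],
                 eigenvalues = ev[keep], total_variance = total,
                 explained = ev[keep] / total, lag_ns = NA_real_,
                 feature_names = p$names),
            class = "linear_projection")
}

#' Time-lagged independent component analysis
#'
#' Solves the generalized eigenproblem `C(tau) v = lambda C(0) v` with the
#' symmetrized (forward+backward) time-lagged covariance estimator, which
#' enforces a real spectrum on finite data. `C(0)` is regularized by adding
#' `eps * I` with `eps = 1e-6 * trace/dim`, so perfectly collinear features
#' are handled. Components (tICs) maximize autocovariance at lag `tau`
#' rather than instantaneous variance and are sorted by decreasing
#' eigenvalue; they are normalized to unit variance under `C(0)`.
#'
#' @param trajs a [feature_trajectory()] or list of them; lagged pairs are
#'   never formed across replica boundaries.
#' @param lag_ns lag time tau in ns; must be a positive multiple of the
#'   frame interval and shorter than every trajectory.
#' @param reg_scale regularization scale for `C(0)` (default `1e-6`).
#' @return object of class `linear_projection` with `kind = "tica"`,
#'   eigenvalues in `[-1, 1]` (up to numerical tolerance) and `lag_ns`.
#'   The implied timescale of component i is `-tau/log(lambda_i)`.
#' @export
fit_tica <- function(trajs, lag_ns, reg_scale = 1e-6) {
  p <- pool_features(trajs)
  dt <- ft_dt(if (is.list(trajs) && !is.data.frame(trajs)) trajs[[1]] else trajs)
  lag <- lag_ns / dt
  if (abs(lag - round(lag)) > 1e-8 || lag < 1)
    stop_("lag must be a positive multiple of the frame interval (%g ns)", dt)
  lag <- as.integer(round(lag))
  short <- vapply(p$mats, nrow, 1L) <= lag
  if (any(short))
    stop_("lag (%d frames) is not shorter than trajectories: %s", lag,
          paste(which(short), collapse = ", "))
  d <- length(p$names)
  # pooled mean over all frames participating in lagged pairs
  Xall <- do.call(rbind, p$mats)
  mu <- colMeans(Xall)
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d); npairs <- 0
  for (m in p$mats) {
    n <- nrow(m)
    A <- sweep(m[seq_len(n - lag), , drop = FALSE], 2, mu)
    B <- sweep(m[(lag + 1):n, , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(A) + crossprod(B)
    Ct <- Ct + crossprod(A, B) + crossprod(B, A)
    npairs <- npairs + (n - lag)
  }
  C0 <- C0 / (2 * npairs)
  Ct <- Ct / (2 * npairs)
  eps <- reg_scale * sum(diag(C0)) / d
  C0r <- C0 + diag(eps, d)
  L <- chol(C0r)                    # C0r = L'L
  Linv <- backsolve(L, diag(d))
  M <- t(Linv) %*% Ct %*% Linv
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  lambda <- e$values[ord]
  V <- Linv %*% e$vectors[, ord, drop = FALSE]   # C0-orthonormal
  rownames(V) <- p$names
  colnames(V) <- paste0("tIC", seq_len(ncol(V)))
  structure(list(kind = "tica", mean = mu, components = V,
                 eigenvalues = lambda, lag_ns = lag * dt,
                 n_pairs = npairs, feature_names = p$names),
            class = "linear_projection")
}

#' @export
print.linear_projection <- function(x, ...) {
  cat(sprintf("<linear_projection> %s, %d features -> %d components%s\n",
              x$kind, length(x$feature_names), ncol(x$components),
              if (x$kind == "tica") sprintf(", lag = %g ns", x$lag_ns) else ""))
  cat("leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  if (x$kind == "tica") {
    ts <- -x$lag_ns / log(pmax(pmin(x$eigenvalues, 1 - 1e-12), 1e-12))
    cat("implied timescales (ns):",
        paste(signif(utils::head(ts[x$eigenvalues > 0 & x$eigenvalues < 1], 5), 4),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Project features into a fitted component space
#'
#' `(x - mean) %*% components`, preserving frame order. Feature names must
#' match the model.
#'
#' @param object a `linear_projection` from [fit_pca()] or [fit_tica()].
#' @param newdata a [feature_trajectory()] or matrix with the model's
#'   features.
#' @param n_components keep the first k components (default all).
#' @param ... unused.
#' @return matrix of projected coordinates (or a [feature_trajectory()] if
#'   the input was one).
#' @export
predict.linear_projection <- function(object, newdata, n_components = NULL,
                                      ...) {
  m <- ft_matrix(as.matrix(newdata))
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  missing <- setdiff(object$feature_names, colnames(m))
  if (length(missing) > 0)
    stop_("features missing from input: %s", paste(missing, collapse = ", "))
  m <- m[, object$feature_names, drop = FALSE]
  W <- object$components
  if (!is.null(n_components)) W <- W[, seq_len(n_components), drop = FALSE]
  Y <- sweep(m, 2, object$mean) %*% W
  if (inherits(newdata, "feature_trajectory"))
    feature_trajectory(Y, dt_ns = ft_dt(newdata),
                       replica = attr(newdata, "replica"),
                       ensemble = attr(newdata, "ensemble"))
  else Y
}

#' Free-energy surface on a 2D projection
#'
#' Bins the first two projected coordinates, normalizes bin counts to a
#' population, and reports `F = -kT * log(p)` shifted so that the global
#' minimum is zero. Empty bins are flagged (`NA` free energy, masked in
#' plots), never interpolated.
#'
#' @param xy matrix (or [feature_trajectory()]) whose first two columns are
#'   the projected coordinates; a list is pooled.
#' @param bins number of bins per axis, or a list of two break vectors.
#' @param kT energy scale of the output (default 1: surfaces in units of kT).
#' @param ensemble label stored with the surface.
#' @return object of class `energy_surface`: `breaks_x`, `breaks_y`,
#'   `population` (sums to 1), `free_energy`, `kT`, `ensemble`.
#' @export
energy_surface <- function(xy, bins = 50, kT = 1, ensemble = "default") {
  if (is.list(xy) && !is.data.frame(xy))
    xy <- do.call(rbind, lapply(xy, function(m) ft_matrix(as.matrix(m))[, 1:2]))
  xy <- ft_matrix(as.matrix(xy))[, 1:2, drop = FALSE]
  if (is.list(bins)) {
    bx <- bins[[1]]; by <- bins[[2]]
  } else {
    bx <- seq(min(xy[, 1]), max(xy[, 1]), length.out = bins + 1)
    by <- seq(min(xy[, 2]), max(xy[, 2]), length.out = bins + 1)
  }
  ix <- findInterval(xy[, 1], bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(xy[, 2], by, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, length(bx) - 1, length(by) - 1)
  for (k in seq_len(nrow(xy)))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  p <- counts / sum(counts)
  f <- -kT * log(p)
  f[!is.finite(f)] <- NA_real_
  f <- f - min(f, na.rm = TRUE)
  structure(list(breaks_x = bx, breaks_y = by, population = p,
                 free_energy = f, kT = kT, ensemble = ensemble),
            class = "energy_surface")
}

#' @export
print.energy_surface <- function(x, ...) {
  cat(sprintf("<energy_surface> %d x %d bins, ensemble %s, %d empty bins\n",
              nrow(x$population), ncol(x$population), x$ensemble,
              sum(is.na(x$free_energy))))
  invisible(x)
}

#' @export
plot.energy_surface <- function(x, ...) {
  mx <- (x$breaks_x[-1] + x$breaks_x[-length(x$breaks_x)]) / 2
  my <- (x$breaks_y[-1] + x$breaks_y[-length(x$breaks_y)]) / 2
  image(mx, my, x$free_energy, xlab = "component 1", ylab = "component 2", ...)
  invisible(x)
}

#' Difference of two probability densities on a shared grid
#'
#' Returns `pA - pB` per bin. Surfaces with different (but equally spaced
#' and mutually aligned) bins are rebinned onto the union grid with a
#' warning; populations outside a surface's support count as zero. The
#' difference integrates to zero since both inputs are normalized.
#'
#' @param a,b `energy_surface` objects.
#' @return list with `breaks_x`, `breaks_y` and `difference` (matrix).
#' @export
difference_density <- function(a, b) {
  stopifnot(inherits(a, "energy_surface"), inherits(b, "energy_surface"))
  same <- isTRUE(all.equal(a$breaks_x, b$breaks_x)) &&
    isTRUE(all.equal(a$breaks_y, b$breaks_y))
  if (same) {
    return(list(breaks_x = a$breaks_x, breaks_y = a$breaks_y,
                difference = a$population - b$population))
  }
  hx <- diff(a$breaks_x)[1]; hy <- diff(a$breaks_y)[1]
  aligned <- isTRUE(all.equal(hx, diff(b$breaks_x)[1])) &&
    isTRUE(all.equal(hy, diff(b$breaks_y)[1])) &&
    isTRUE(all.equal((a$breaks_x[1] - b$breaks_x[1]) / hx,
                     round((a$breaks_x[1] - b$breaks_x[1]) / hx))) &&
    isTRUE(all.equal((a$breaks_y[1] - b$breaks_y[1]) / hy,
                     round((a$breaks_y[1] - b$breaks_y[1]) / hy)))
  if (!aligned)
    stop_("bin grids are incompatible; recompute both surfaces on shared breaks")
  warn_("surfaces have different supports; rebinning to the union grid")
  ux <- seq(min(a$breaks_x[1], b$breaks_x[1]),
            max(max(a$breaks_x), max(b$breaks_x)) + hx / 2, by = hx)
  uy <- seq(min(a$breaks_y[1], b$breaks_y[1]),
            max(max(a$breaks_y), max(b$breaks_y)) + hy / 2, by = hy)
  place <- function(s) {
    m <- matrix(0, length(ux) - 1, length(uy) - 1)
    ox <- round((s$breaks_x[1] - ux[1]) / hx)
    oy <- round((s$breaks_y[1] - uy[1]) / hy)
    m[ox + seq_len(nrow(s$population)), oy + seq_len(ncol(s$population))] <-
      s$population
    m
  }
  list(breaks_x = ux, breaks_y = uy, difference = place(a) - place(b))
}
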