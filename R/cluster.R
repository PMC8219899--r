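# neighbor lists within radius r; exact. Uses a uniform cell grid in low
# dimension (cells of edge r, 3^d neighbor cells) and falls back to chunked
# brute force otherwise. Self is never a neighbor.
neighbor_lists <- function(X, r) {
  n <- nrow(X); d <- ncol(X)
  nb <- vector("list", n)
  if (d <= 3L && n > 200L) {
    cell <- floor(sweep(X, 2, apply(X, 2, min)) / r)
    key <- apply(cell, 1, paste, collapse = ",")
    buckets <- split(seq_len(n), key)
    offs <- as.matrix(expand.grid(rep(list(-1:1), d)))
    for (i in seq_len(n)) {
      cand <- integer(0)
      for (o in seq_len(nrow(offs))) {
        k <- paste(cell[i, ] + offs[o, ], collapse = ",")
        b <- buckets[[k]]
        if (!is.null(b)) cand <- c(cand, b)
      }
      cand <- cand[cand != i]
      if (length(cand)) {
        d2 <- rowSums((X[cand, , drop = FALSE] -
                         matrix(X[i, ], length(cand), d, byrow = TRUE))^2)
        nb[[i]] <- sort(cand[d2 <= r^2])
      } else nb[[i]] <- integer(0)
    }
  } else {
    r2 <- r^2
    chunk <- max(1L, 2e6 %/% n)
    for (s in seq(1L, n, by = chunk)) {
      e <- min(s + chunk - 1L, n)
      block <- X[s:e, , drop = FALSE]
      d2 <- outer(rowSums(block^2), rowSums(X^2), "+") -
        2 * tcrossprod(block, X)
      for (ii in seq_len(e - s + 1L)) {
        i <- s + ii - 1L
        w <- which(d2[ii, ] <= r2 + 1e-12)
        nb[[i]] <- w[w != i]
      }
    }
  }
  nb
}

#' Common-nearest-neighbours density-based clustering
#'
#' Two points `a`, `b` are density-connected iff they lie within `r` of each
#' other *and* their `r`-neighbourhoods share at least `n_c` other points;
#' clusters are the connected components of the density-connected graph.
#' Components smaller than `min_members`, and isolated points (no
#' density-connected partner at all), are noise. The algorithm is fully
#' deterministic and its partition is invariant to point order; labels are
#' `0..K-1` by decreasing cluster size (ties broken by smallest member
#' index), with `-1` marking noise.
#'
#' Neighbour search is exact (uniform cell grid in up to 3 dimensions,
#' chunked brute force otherwise); no approximate search is used.
#'
#' @param points numeric matrix of observations x coordinates (e.g. frames
#'   in a PCA or tICA space).
#' @param r neighbourhood radius (component-space units); > 0.
#' @param n_c required number of shared neighbours; >= 0.
#' @param min_members minimum cluster size; >= 1.
#' @return object of class `cnn_labels`: `labels` (per-point integer),
#'   `sizes` (named by label), `params`, `n_noise`.
#' @export
fit_commonnn <- function(points, r, n_c, min_members = 1L) {
  X <- as.matrix(points)
  if (!is.numeric(X) || any(!is.finite(X))) stop_("points must be finite numeric")
  if (r <= 0) stop_("r must be > 0")
  if (n_c < 0) stop_("n_c must be >= 0")
  if (min_members < 1) stop_("min_members must be >= 1")
  n <- nrow(X)
  nb <- neighbor_lists(X, r)
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (i in seq_len(n)) {
    ni <- nb[[i]]
    for (j in ni[ni > i]) {
      # shared neighbours; i, j are excluded automatically since a point is
      # never in its own neighbour list
      shared <- sum(match(ni, nb[[j]], nomatch = 0L) > 0L)
      if (shared >= n_c) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[min(ri, rj)] <- parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  # points with no density-connected partner are noise regardless of
  # min_members: a cluster needs at least one edge
  isolated <- root == seq_len(n) & tabulate(root, n) == 1L
  comp <- match(root, unique(root))
  sizes <- tabulate(comp)
  sizes[unique(comp[isolated])] <- 0L
  labels <- rep(-1L, n)
  good <- which(sizes >= min_members)
  if (length(good)) {
    first_member <- vapply(good, function(g) which(comp == g)[1], 1L)
    ord <- good[order(-sizes[good], first_member)]
    for (k in seq_along(ord)) labels[comp == ord[k]] <- k - 1L
  }
  sz <- if (any(labels >= 0)) table(labels[labels >= 0]) else table(integer(0))
  structure(list(labels = labels,
                 sizes = as.integer(sz),
                 params = list(r = r, n_c = n_c, min_members = min_members),
                 n_noise = sum(labels == -1L), n = n),
            class = "cnn_labels")
}

#' @export
print.cnn_labels <- function(x, ...) {
  cat(sprintf("<cnn_labels> %d points, %d clusters, %d noise (r = %g, n_c = %d, min %d)\n",
              x$n, length(x$sizes), x$n_noise, x$params$r, x$params$n_c,
              x$params$min_members))
  if (length(x$sizes))
    cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cnn_labels <- function(object, ...) {
  data.frame(label = seq_along(object$sizes) - 1L, size = object$sizes,
             fraction = object$sizes / object$n)
}

#' Turn clusters into core sets for a core-set Markov model
#'
#' Each non-noise cluster becomes one core set, stored with its member
#' coordinates and the clustering radius; noise frames remain unassigned
#' (they are filled by milestoning downstream). An all-noise labelling is
#' rejected with advice to loosen the clustering parameters.
#'
#' @param labels a `cnn_labels` object.
#' @param points the clustered coordinates (same order as the labels).
#' @return object of class `core_set`: list of per-core member coordinate
#'   matrices, `r`, `dim`, 1D member intervals.
#' @export
select_cores <- function(labels, points) {
  stopifnot(inherits(labels, "cnn_labels"))
  X <- as.matrix(points)
  if (nrow(X) != labels$n) stop_("points and labels disagree in length")
  K <- length(labels$sizes)
  if (K == 0L)
    stop_("all points are noise; decrease n_c or increase r before defining cores")
  members <- lapply(seq_len(K) - 1L, function(k)
    X[labels$labels == k, , drop = FALSE])
  intervals <- if (ncol(X) == 1L)
    lapply(members, function(m) range(m[, 1])) else NULL
  structure(list(members = members, r = labels$params$r, dim = ncol(X),
                 intervals = intervals, n_cores = K),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> %d cores in %dD (r = %g); sizes %s\n", x$n_cores,
              x$dim, x$r, paste(vapply(x$members, nrow, 1L), collapse = ", ")))
  invisible(x)
}

#' Assign points to core sets
#'
#' A point belongs to core `k` if it falls inside that core's region: in 1D
#' the member interval `[min, max]`; in higher dimension within the
#' clustering radius `r` of any core member. Points in no core get `NA`.
#'
#' @param points matrix of coordinates.
#' @param cores a `core_set` from [select_cores()].
#' @return integer vector of core ids (1-based) with `NA` for unassigned
#'   points.
#' @export
assign_cores <- function(points, cores) {
  stopifnot(inherits(cores, "core_set"))
  X <- as.matrix(points)
  if (ncol(X) != cores$dim) stop_("dimension mismatch with core definition")
  n <- nrow(X)
  out <- rep(NA_integer_, n)
  if (cores$dim == 1L) {
    for (k in seq_len(cores$n_cores)) {
      iv <- cores$intervals[[k]]
      out[is.na(out) & X[, 1] >= iv[1] & X[, 1] <= iv[2]] <- k
    }
  } else {
    r2 <- cores$r^2
    chunk <- 4096L
    for (s in seq(1L, n, by = chunk)) {
      e <- min(s + chunk - 1L, n)
      blk <- X[s:e, , drop = FALSE]
      idx <- s:e
      for (k in seq_len(cores$n_cores)) {
        un <- which(is.na(out[idx]))
        if (!length(un)) break
        M <- cores$members[[k]]
        d2 <- outer(rowSums(blk[un, , drop = FALSE]^2), rowSums(M^2), "+") -
          2 * tcrossprod(blk[un, , drop = FALSE], M)
        hit <- apply(d2 <= r2 + 1e-12, 1, any)
        out[idx[un[hit]]] <- k
      }
    }
  }
  out
}

#' Per-cluster hydrogen-bond occupancy table
#'
#' For every bond label, the occupancy inside each cluster and in the full
#' ensemble, plus the cluster weights -- the per-cluster fingerprint used to
#' characterize conformational states.
#'
#' @param labels a `cnn_labels` object (or an integer label vector with
#'   `-1` = noise).
#' @param presence 0/1 matrix or [feature_trajectory()] of per-frame bond
#'   presence, one column per bond; same frame count as the labels.
#' @return data.frame with columns `bond`, `cluster` (label or
#'   `"ensemble"`), `occupancy`, `weight`.
#' @export
cluster_report <- function(labels, presence) {
  lab <- if (inherits(labels, "cnn_labels")) labels$labels else as.integer(labels)
  P <- ft_matrix(as.matrix(presence))
  if (nrow(P) != length(lab))
    stop_("label count (%d) does not match frame count (%d)", length(lab), nrow(P))
  ks <- sort(unique(lab[lab >= 0]))
  rows <- list()
  for (b in colnames(P)) {
    rows[[length(rows) + 1L]] <- data.frame(
      bond = b, cluster = "ensemble", occupancy = mean(P[, b]), weight = 1)
    for (k in ks) {
      in_k <- lab == k
      rows[[length(rows) + 1L]] <- data.frame(
        bond = b, cluster = as.character(k), occupancy = mean(P[in_k, b]),
        weight = mean(in_k))
    }
  }
  do.call(rbind, rows)
}
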