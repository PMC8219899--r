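#' Milestoning assignment of frames to core sets
#'
#' Frames inside a core keep that core's id; frames outside every core are
#' assigned to the last core visited (the milestoning rule that approximates
#' committor-based assignment between free-energy minima). Frames before the
#' first core visit have no causal antecedent and stay unassigned (`NA`);
#' they are excluded from transition counting. A trajectory that never
#' enters any core is excluded entirely, with a warning naming the replica.
#'
#' @param projected a matrix / [feature_trajectory()] of projected
#'   coordinates, or a list of them (one per replica); alternatively a
#'   vector (or list of vectors) of precomputed core ids with `NA` for
#'   frames outside all cores.
#' @param cores a `core_set` from [select_cores()]; ignored when core ids
#'   are supplied directly.
#' @return list of integer vectors (class `core_trajectory` each): per-frame
#'   core ids after the milestoning fill.
#' @export
milestone_assign <- function(projected, cores = NULL) {
  as_list <- if (is.list(projected) && !is.data.frame(projected) &&
                 !is.matrix(projected)) projected else list(projected)
  out <- vector("list", length(as_list))
  keep <- logical(length(as_list))
  for (i in seq_along(as_list)) {
    x <- as_list[[i]]
    ids <- if (is.null(dim(x)) && !inherits(x, "feature_trajectory"))
      as.integer(x) else assign_cores(ft_matrix(as.matrix(x)), cores)
    filled <- forward_fill(ids)
    if (all(is.na(filled))) {
      warn_("replica %d never enters any core; excluded", i)
      keep[i] <- FALSE
    } else {
      keep[i] <- TRUE
    }
    class(filled) <- c("core_trajectory", class(filled))
    out[[i]] <- filled
  }
  out[keep]
}

forward_fill <- function(ids) {
  ok <- !is.na(ids)
  if (!any(ok)) return(ids)
  idx <- cummax(ifelse(ok, seq_along(ids), 0L))
  out <- rep(NA_integer_, length(ids))
  out[idx > 0L] <- ids[idx[idx > 0L]]
  out
}

#' Sliding-window transition counts at a lag
#'
#' `C[i, j] = #\{t : s(t) = i, s(t + tau) = j\}` summed over replicas, never
#' across replica boundaries. Pairs with an unassigned end (leading `NA`s
#' from milestoning) are skipped.
#'
#' @param core_trajs list of per-frame core-id vectors (from
#'   [milestone_assign()]).
#' @param lag lag in frames (>= 1).
#' @param n_states number of states (defaults to the largest id seen).
#' @return integer count matrix (states x states).
#' @export
count_transitions <- function(core_trajs, lag, n_states = NULL) {
  if (!is.list(core_trajs)) core_trajs <- list(core_trajs)
  lag <- as.integer(lag)
  if (lag < 1) stop_("lag must be >= 1 frame")
  if (all(vapply(core_trajs, length, 1L) <= lag))
    stop_("lag (%d frames) is not shorter than any trajectory", lag)
  K <- n_states %||% max(unlist(lapply(core_trajs, max, na.rm = TRUE)))
  C <- matrix(0L, K, K)
  for (s in core_trajs) {
    n <- length(s)
    if (n <= lag) next
    a <- s[seq_len(n - lag)]
    b <- s[(lag + 1):n]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = seq_len(K)),
                 factor(b[ok], levels = seq_len(K)))
    C <- C + as.integer(tab)
  }
  matrix(C, K, K)
}

# strongly connected component containing the most counts, by boolean
# transitive closure on the directed count graph
largest_strong_component <- function(C) {
  K <- nrow(C)
  A <- (C > 0) | diag(TRUE, K)
  R <- A
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  mutual <- R & t(R)
  comp <- match(apply(mutual, 1, paste, collapse = ""),
                unique(apply(mutual, 1, paste, collapse = "")))
  weight <- vapply(seq_len(max(comp)), function(g) {
    m <- comp == g
    sum(C[m, m, drop = FALSE])
  }, 1)
  which(comp == which.max(weight))
}

#' Estimate a core-set Markov model from transition counts
#'
#' Reversible estimation by count symmetrisation: the counts restricted to
#' the largest strongly connected component are symmetrised,
#' `C' = (C + t(C))/2`, and row-normalised, which guarantees a real spectrum
#' and detailed balance. The stationary distribution is the (normalised) row
#' sum of the symmetrised counts. Implied timescales are
#' `t_i = -tau / log(lambda_{i+1})` for eigenvalues in (0, 1).
#'
#' @param counts count matrix from [count_transitions()].
#' @param lag_ns the lag time tau in ns corresponding to the counts.
#' @param reversible logical; only the reversible symmetrised estimator is
#'   implemented (an iterative reversible MLE is an extension hook).
#' @return object of class `coreset_msm`: `T` (row-stochastic), `pi`,
#'   `eigenvalues` (descending, `lambda_1 = 1`), `timescales_ns`,
#'   `active_set`, `counts`, `lag_ns`.
#' @export
estimate_msm <- function(counts, lag_ns = 1, reversible = TRUE) {
  C <- as.matrix(counts)
  if (any(C < 0)) stop_("counts must be non-negative")
  if (!reversible)
    stop_("only the reversible (symmetrised) estimator is implemented")
  active <- largest_strong_component(C)
  if (length(active) == 0L || sum(C[active, active]) == 0)
    stop_("empty active set: no connected transitions")
  Cs <- (C[active, active, drop = FALSE] +
           t(C[active, active, drop = FALSE])) / 2
  rs <- rowSums(Cs)
  if (any(rs == 0)) stop_("state with no counts inside the active set")
  T_ <- Cs / rs
  pi_ <- rs / sum(rs)
  # similarity transform to a symmetric matrix: real spectrum, stable eigen
  s <- sqrt(pi_)
  S <- diag(s) %*% T_ %*% diag(1 / s)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lambda <- e$values
  ts <- rep(NA_real_, length(lambda) - 1)
  valid <- lambda[-1] > 0 & lambda[-1] < 1
  ts[valid] <- -lag_ns / log(lambda[-1][valid])
  structure(list(T = T_, pi = pi_, eigenvalues = lambda,
                 timescales_ns = ts, active_set = active,
                 counts = C, lag_ns = lag_ns),
            class = "coreset_msm")
}

#' @export
print.coreset_msm <- function(x, ...) {
  cat(sprintf("<coreset_msm> %d states (of %d), lag = %g ns\n",
              length(x$active_set), nrow(x$counts), x$lag_ns))
  cat("implied timescales (ns):",
      paste(signif(utils::head(x$timescales_ns, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.coreset_msm <- function(object, ...) {
  list(n_states = length(object$active_set), lag_ns = object$lag_ns,
       stationary = object$pi, timescales_ns = object$timescales_ns)
}

#' Implied-timescale test over a ladder of lag times
#'
#' Estimates a Markov model at each lag and reports the implied timescales
#' `t_i(tau)`. For a Markovian discretisation the timescales are independent
#' of the lag; each process is flagged converged when its maximum relative
#' spread over the upper half of the lag ladder is at most `tol`.
#'
#' @param core_trajs list of core-id vectors (from [milestone_assign()]).
#' @param lags integer lags in frames (>= 2 values).
#' @param dt_ns frame interval in ns.
#' @param n_processes how many slow processes to tabulate.
#' @param tol relative-spread tolerance for the convergence flag.
#' @return object of class `implied_timescales`: data.frame `table`
#'   (lag_ns, t1_ns, t2_ns, ...), logical `converged` per process, `tol`.
#' @export
implied_timescales <- function(core_trajs, lags, dt_ns = 1, n_processes = 2,
                               tol = 0.2) {
  lags <- sort(unique(as.integer(lags)))
  if (length(lags) < 2L) stop_("need at least 2 lags")
  K <- max(unlist(lapply(core_trajs, max, na.rm = TRUE)))
  n_processes <- min(n_processes, K - 1L)
  tab <- matrix(NA_real_, length(lags), n_processes)
  for (i in seq_along(lags)) {
    C <- count_transitions(core_trajs, lags[i], n_states = K)
    m <- estimate_msm(C, lag_ns = lags[i] * dt_ns)
    k <- min(n_processes, length(m$timescales_ns))
    tab[i, seq_len(k)] <- m$timescales_ns[seq_len(k)]
  }
  upper <- seq.int(ceiling(length(lags) / 2), length(lags))
  converged <- vapply(seq_len(n_processes), function(j) {
    v <- tab[upper, j]
    if (any(is.na(v))) return(FALSE)
    (max(v) - min(v)) / mean(v) <= tol
  }, TRUE)
  out <- data.frame(lag_ns = lags * dt_ns, tab)
  names(out)[-1] <- paste0("t", seq_len(n_processes), "_ns")
  structure(list(table = out, converged = converged, tol = tol),
            class = "implied_timescales")
}

#' @export
print.implied_timescales <- function(x, ...) {
  cat("<implied_timescales>\n")
  print(x$table, row.names = FALSE)
  cat("converged (tol", x$tol, "):", paste(x$converged, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.implied_timescales <- function(x, log = "y", ...) {
  tab <- x$table
  matplot_cols <- seq(2, ncol(tab))
  plot(range(tab$lag_ns), range(tab[, -1], na.rm = TRUE), type = "n",
       xlab = "lag (ns)", ylab = "implied timescale (ns)", log = log, ...)
  for (j in matplot_cols) lines(tab$lag_ns, tab[, j], type = "b", col = j - 1)
  abline(0, 1, lty = 2)
  invisible(x)
}
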