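#' Assemble survival records
#'
#' @param time_ns event or censoring time, ns (> 0).
#' @param censored 0/1 or logical; censored records carry the cap time.
#' @param condition,criterion labels.
#' @return a `survival_data` data.frame.
#' @export
survival_data <- function(time_ns, censored, condition = "default",
                          criterion = "rmsd") {
  if (any(time_ns <= 0)) stop_("times must be > 0")
  out <- data.frame(time_ns = time_ns, censored = as.integer(censored),
                    condition = condition, criterion = criterion)
  class(out) <- c("survival_data", "data.frame")
  out
}

#' Classify unfolding events from feature time series
#'
#' Operationalises the unfolding criteria: with `criterion = "rmsd"` the
#' event is the first time the RMSD exceeds `threshold` (default 0.2 nm) and
#' stays above it for at least `persistence`; with an `"hbond"` criterion the
#' event is the first time the named bond is continuously broken for at
#' least `persistence`. Brief excursions shorter than the persistence window
#' are filtered out. A trajectory with no event is right-censored at its
#' end. Visual criteria cannot be automated and are accepted only as
#' externally supplied annotations via [survival_data()].
#'
#' @param trajs a [feature_trajectory()] or list of them, each containing
#'   the required feature column.
#' @param criterion `"rmsd"` or the name of a 0/1 hydrogen-bond column.
#' @param threshold RMSD threshold, nm (ignored for hbond criteria).
#' @param persistence minimum duration of the exceedance/breakage, ns.
#' @param condition label stored in the output.
#' @return a `survival_data` data.frame, one row per trajectory.
#' @export
classify_unfolding <- function(trajs, criterion = "rmsd", threshold = 0.2,
                               persistence = 1, condition = "default") {
  if (inherits(trajs, "feature_trajectory")) trajs <- list(trajs)
  rows <- lapply(seq_along(trajs), function(i) {
    x <- trajs[[i]]
    m <- ft_matrix(as.matrix(x))
    dt <- ft_dt(x)
    col <- if (criterion == "rmsd") "rmsd" else criterion
    if (!col %in% colnames(m))
      stop_("required feature '%s' missing from trajectory %d", col, i)
    v <- m[, col]
    flag <- if (criterion == "rmsd") v > threshold else v < 0.5  # bond broken
    n_persist <- max(1L, as.integer(ceiling(persistence / dt)))
    ev <- first_sustained(flag, n_persist)
    t_end <- length(v) * dt
    if (is.na(ev)) data.frame(time_ns = t_end, censored = 1L)
    else data.frame(time_ns = (ev - 1L) * dt, censored = 0L)
  })
  out <- do.call(rbind, rows)
  # an event in the very first frame would give time 0; clamp to half a frame
  out$time_ns[out$time_ns <= 0] <- ft_dt(trajs[[1]]) / 2
  out$condition <- condition
  out$criterion <- if (criterion == "rmsd") "rmsd" else paste0("hbond_", criterion)
  class(out) <- c("survival_data", "data.frame")
  out
}

# index of the first TRUE that starts a run of >= n TRUEs, else NA
first_sustained <- function(flag, n) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= n)
  if (length(hit) == 0L) NA_integer_ else starts[hit[1]]
}

#' Fraction of trajectories still folded as a function of time
#'
#' Right-continuous step function `S(t) = #\{event time > t or censored\}/n`.
#'
#' @param data a `survival_data` data.frame.
#' @return object of class `survival_curve`: `time_ns` (sorted event times,
#'   0 prepended), `folded_fraction`.
#' @export
survival_curve <- function(data) {
  if (nrow(data) == 0L) stop_("no records")
  ev <- sort(data$time_ns[data$censored == 0L])
  n <- nrow(data)
  tt <- c(0, unique(ev))
  frac <- vapply(tt, function(t0)
    sum(data$time_ns > t0 | data$censored == 1L) / n, 1)
  structure(list(time_ns = tt, folded_fraction = frac, n = n),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> n = %d, %d event times, final fraction %.3f\n",
              x$n, length(x$time_ns) - 1L, x$folded_fraction[length(x$folded_fraction)]))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, xlab = "time (ns)",
                                ylab = "folded fraction", ...) {
  plot(x$time_ns, x$folded_fraction, type = "s", ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Exponential decay fit with right-censoring
#'
#' Maximum-likelihood rate for exponentially distributed unfolding times
#' under right-censoring: `k = n_events / (sum of all observed times,
#' events and censoring alike)` -- the standard censored-exponential MLE,
#' which reduces to `1/mean` for fully observed data. The half-life is
#' `t_1/2 = log(2)/k`; its standard error follows from the Fisher
#' information (`sigma_k = k/sqrt(n_events)`, delta method for `t_1/2`).
#' A Kolmogorov--Smirnov distance of the event times to the fitted
#' (censoring-truncated) exponential is reported as a
#' deviation-from-single-exponential diagnostic. A least-squares fit of the
#' decay curve is available as an alternative method for comparison.
#'
#' @param data a `survival_data` data.frame with at least one event.
#' @param method `"mle"` (default) or `"ls"` (nonlinear least squares of
#'   `exp(-k t)` to the survival curve).
#' @return object of class `decay_fit`: `k` (1/ns), `t_half`, `sigma_k`,
#'   `sigma_t_half`, `n_events`, `n_censored`, `ks_distance`, `method`.
#' @export
fit_exponential <- function(data, method = c("mle", "ls")) {
  method <- match.arg(method)
  d <- sum(data$censored == 0L)
  if (d == 0L)
    return(structure(list(k = NA_real_, t_half = NA_real_,
                          sigma_k = NA_real_, sigma_t_half = NA_real_,
                          n_events = 0L, n_censored = nrow(data),
                          ks_distance = NA_real_, method = method,
                          no_events = TRUE),
                     class = "decay_fit"))
  if (method == "mle") {
    k <- d / sum(data$time_ns)
  } else {
    sc <- survival_curve(data)
    fit <- stats::nls(frac ~ exp(-k * t),
                      data = data.frame(t = sc$time_ns, frac = sc$folded_fraction),
                      start = list(k = d / sum(data$time_ns)))
    k <- coef(fit)[["k"]]
  }
  sigma_k <- k / sqrt(d)
  t_half <- log(2) / k
  sigma_t_half <- t_half / sqrt(d)        # delta method: |dt/dk| * sigma_k
  ev <- sort(data$time_ns[data$censored == 0L])
  t_cap <- max(data$time_ns)
  # event times conditioned on occurring before the cap
  cdf <- function(t) (1 - exp(-k * t)) / (1 - exp(-k * t_cap))
  emp <- ecdf(ev)
  grid <- sort(c(ev, ev - 1e-9))
  ks <- max(abs(emp(grid) - cdf(grid)))
  structure(list(k = k, t_half = t_half, sigma_k = sigma_k,
                 sigma_t_half = sigma_t_half, n_events = d,
                 n_censored = sum(data$censored == 1L),
                 ks_distance = ks, method = method, no_events = FALSE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (isTRUE(x$no_events)) {
    cat("<decay_fit> no events: rate undefined\n")
    return(invisible(x))
  }
  cat(sprintf("<decay_fit> k = %.4g /ns, t_1/2 = %.4g +/- %.2g ns (%d events, %d censored, %s)\n",
              x$k, x$t_half, x$sigma_t_half, x$n_events, x$n_censored,
              x$method))
  cat(sprintf("KS distance to single exponential: %.3f\n", x$ks_distance))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(k = object$k, t_half = object$t_half)
}

#' Percentage of trajectories unfolded by a time point
#'
#' `100 * #\{events with time <= t\} / n`, per condition and criterion.
#'
#' @param data a `survival_data` data.frame.
#' @param t evaluation time, ns (must not exceed the largest censoring time
#'   when censored records exist).
#' @return data.frame (`condition`, `criterion`, `percent_unfolded`) or a
#'   single percentage when only one group is present.
#' @export
percent_unfolded <- function(data, t = 220) {
  if (any(data$censored == 1L) && t > max(data$time_ns[data$censored == 1L]))
    stop_("t exceeds the censoring horizon")
  groups <- unique(data[, c("condition", "criterion")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- data[data$condition == groups$condition[i] &
                data$criterion == groups$criterion[i], ]
    data.frame(condition = groups$condition[i],
               criterion = groups$criterion[i],
               percent_unfolded = 100 * sum(g$censored == 0L & g$time_ns <= t) /
                 nrow(g))
  }))
  if (nrow(out) == 1L) out$percent_unfolded else out
}
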