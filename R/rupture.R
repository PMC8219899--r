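#' Read a force trace from a two-column CSV
#'
#' @param path CSV with columns `time_ns`, `force`.
#' @param condition condition label attached to the trace.
#' @return a `force_trace` data.frame.
#' @export
read_force_trace <- function(path, condition = "default") {
  d <- utils::read.csv(path)
  if (!all(c("time_ns", "force") %in% names(d)))
    stop_("force trace must have columns time_ns, force: %s", path)
  tr <- data.frame(time_ns = d$time_ns, force = d$force)
  attr(tr, "condition") <- condition
  class(tr) <- c("force_trace", "data.frame")
  tr
}

#' Detect the rupture event in a constant-velocity pulling trace
#'
#' The trace is smoothed with a centred moving average of width `window`;
#' the candidate rupture time is the argmax of the smoothed force, and the
#' event is accepted only if the smoothed force subsequently stays below
#' `drop_fraction * max` for at least `sustain` -- the operational version of
#' the "sudden drop in the opposing force" that marks the ionic bonds
#' breaking. A monotone, never-dropping trace yields `detected = FALSE`
#' rather than an error.
#'
#' @param trace a `force_trace` (data.frame with `time_ns`, `force`; strictly
#'   increasing times, >= 2 samples).
#' @param window smoothing window, ns (>= 0; 0 disables smoothing).
#' @param drop_fraction fraction of the maximum the force must fall below,
#'   in (0, 1).
#' @param sustain minimum duration of the post-rupture drop, ns.
#' @return object of class `rupture_result`: `detected`, `force`
#'   (smoothed maximum, kJ/(mol nm)), `time_ns`, `window`, `drop_fraction`,
#'   `sustain`, `condition`.
#' @export
detect_rupture <- function(trace, window = 0.1, drop_fraction = 0.5,
                           sustain = 0.5) {
  if (nrow(trace) < 2L) stop_("trace needs at least 2 samples")
  tt <- trace$time_ns; f <- trace$force
  if (any(diff(tt) <= 0)) stop_("times must be strictly increasing")
  if (window < 0) stop_("window must be >= 0")
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop_("drop_fraction must be in (0, 1)")
  dt <- stats::median(diff(tt))
  w <- max(1L, as.integer(round(window / dt)))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- if (w > 1L) stats::filter(f, rep(1 / w, w), sides = 2) else f
  sm <- as.numeric(sm)
  # the centred filter leaves NA at the edges; ignore those for the argmax
  valid <- which(!is.na(sm))
  imax <- valid[which.max(sm[valid])]
  fmax <- sm[imax]
  thresh <- drop_fraction * fmax
  n_sust <- max(1L, as.integer(round(sustain / dt)))
  below <- !is.na(sm) & sm < thresh
  below[seq_len(imax)] <- FALSE
  detected <- FALSE
  if (any(below)) {
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= n_sust)
    # accept a terminal shorter run too if the trace simply ends below
    terminal_ok <- length(r$values) > 0 && r$values[length(r$values)] &&
      starts[length(r$values)] > imax
    detected <- length(runs) > 0 || terminal_ok &&
      (tt[length(tt)] - tt[starts[length(r$values)]]) >= sustain - dt
  }
  structure(list(detected = detected,
                 force = if (detected) fmax else NA_real_,
                 time_ns = if (detected) tt[imax] else NA_real_,
                 window = window, drop_fraction = drop_fraction,
                 sustain = sustain,
                 condition = attr(trace, "condition") %||% "default"),
            class = "rupture_result")
}

#' @export
print.rupture_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<rupture_result> force %.1f kJ/(mol nm) at %.2f ns (window %g ns)\n",
                x$force, x$time_ns, x$window))
  else cat("<rupture_result> no rupture detected\n")
  invisible(x)
}

#' Notched-box statistics of a sample
#'
#' Median and quartiles (linear-interpolation quantiles, R type 7 -- the
#' convention is stated in the output since it differs across tools), the
#' notch half-width `1.57 * IQR / sqrt(n)` approximating a 95% confidence
#' interval on the median, outliers beyond `quartile +/- 1.5 * IQR`, and
#' whiskers at the extreme non-outlier points.
#'
#' @param x numeric sample.
#' @return object of class `notched_box`: `n`, `median`, `q1`, `q3`, `iqr`,
#'   `notch`, `whisker_lo`, `whisker_hi`, `outliers`, `quartile_method`.
#' @export
notched_box_stats <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L)
    return(structure(list(n = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_, iqr = NA_real_, notch = NA_real_,
                          whisker_lo = NA_real_, whisker_hi = NA_real_,
                          outliers = numeric(0),
                          quartile_method = "linear interpolation (type 7)"),
                     class = "notched_box"))
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  out <- x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr]
  inl <- x[!(x %in% out)]
  structure(list(n = n, median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 notch = 1.57 * iqr / sqrt(n),
                 whisker_lo = min(inl), whisker_hi = max(inl),
                 outliers = sort(out),
                 quartile_method = "linear interpolation (type 7)"),
            class = "notched_box")
}

#' @export
print.notched_box <- function(x, ...) {
  cat(sprintf("<notched_box> n = %d, median %.3g [%.3g, %.3g], notch +/- %.3g, %d outliers\n",
              x$n, x$median, x$q1, x$q3, x$notch, length(x$outliers)))
  invisible(x)
}

#' Summarise rupture cohorts per condition
#'
#' Notched-box statistics per condition plus the table of pairwise median
#' differences with percentile-bootstrap confidence intervals. Traces in
#' which no rupture was detected are counted and reported separately;
#' conditions with zero detections are reported with `n = 0` and no
#' statistics.
#'
#' @param results list of `rupture_result`s (e.g. from [detect_rupture()]
#'   applied to every trace).
#' @param n_boot bootstrap resamples for the median-difference CI.
#' @param ci confidence level of that interval.
#' @param seed seed for the bootstrap.
#' @return object of class `rupture_summary`: `stats` (named list of
#'   `notched_box` per condition), `n_undetected` (named), `differences`
#'   (data.frame: condition_a, condition_b, median_diff, ci_lo, ci_hi).
#' @export
summarize_ruptures <- function(results, n_boot = 2000, ci = 0.95, seed = 1) {
  conds <- vapply(results, function(r) r$condition, "")
  det <- vapply(results, function(r) r$detected, TRUE)
  forces <- vapply(results, function(r) if (r$detected) r$force else NA_real_, 1)
  ucond <- unique(conds)
  stats <- lapply(ucond, function(cc) notched_box_stats(forces[conds == cc & det]))
  names(stats) <- ucond
  n_undet <- vapply(ucond, function(cc) sum(conds == cc & !det), 1L)
  diffs <- NULL
  if (length(ucond) >= 2L) {
    set.seed(seed)
    alpha <- (1 - ci) / 2
    pairs <- utils::combn(ucond, 2, simplify = FALSE)
    diffs <- do.call(rbind, lapply(pairs, function(p) {
      a <- forces[conds == p[1] & det]; b <- forces[conds == p[2] & det]
      if (length(a) == 0L || length(b) == 0L)
        return(data.frame(condition_a = p[1], condition_b = p[2],
                          median_diff = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_))
      bd <- replicate(n_boot, median(sample(a, replace = TRUE)) -
                        median(sample(b, replace = TRUE)))
      data.frame(condition_a = p[1], condition_b = p[2],
                 median_diff = median(a) - median(b),
                 ci_lo = quantile(bd, alpha, names = FALSE),
                 ci_hi = quantile(bd, 1 - alpha, names = FALSE))
    }))
  }
  structure(list(stats = stats, n_undetected = n_undet, differences = diffs,
                 ci = ci),
            class = "rupture_summary")
}

#' @export
print.rupture_summary <- function(x, ...) {
  cat("<rupture_summary>\n")
  for (cc in names(x$stats)) {
    s <- x$stats[[cc]]
    cat(sprintf("  %s: n = %d, median = %.4g (undetected: %d)\n", cc, s$n,
                s$median, x$n_undetected[[cc]]))
  }
  if (!is.null(x$differences)) {
    cat("median differences:\n")
    print(x$differences, row.names = FALSE)
  }
  invisible(x)
}
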