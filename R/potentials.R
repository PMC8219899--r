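#' Model potentials for synthetic conformational dynamics
#'
#' Constructors for the model free-energy landscapes sampled by
#' [generate_langevin()]: a harmonic well, a symmetric 1D double well and a
#' 2D three-well surface. Together with a temperature and a friction
#' coefficient they fully specify an overdamped Langevin system whose
#' stationary density is proportional to `exp(-U/kT)`.
#'
#' Units are fixed package-wide: positions in nm, energies in kJ/mol,
#' temperature in K, time in ns. The friction coefficient `gamma` is
#' expressed in kJ ns/(mol nm^2), so the diffusion coefficient is
#' `D = kT/gamma` in nm^2/ns.
#'
#' The double well is `U(x) = barrier * ((x/a)^2 - 1)^2` with minima at
#' `x = +/- a` and a barrier of height `barrier` at `x = 0`.
#'
#' @param stiffness harmonic force constant, kJ/(mol nm^2); > 0.
#' @param center position of the harmonic minimum, nm.
#' @param barrier barrier height, kJ/mol; > 0.
#' @param well_pos half-separation `a` of the double-well minima, nm.
#' @param temperature temperature in K; > 0.
#' @param friction friction coefficient gamma, kJ ns/(mol nm^2); > 0.
#' @return an object of class `md_potential` with elements `kind`, `U`,
#'   `grad`, `dim`, `params`, `temperature`, `friction`, `kT` and
#'   `max_curvature` (used for the integrator stability check).
#' @seealso [generate_langevin()], [grid_relaxation_time()]
#' @export
harmonic_potential <- function(stiffness, center = 0, temperature = 300,
                               friction = 1) {
  check_pot_common(temperature, friction)
  if (stiffness <= 0) stop_("stiffness must be > 0")
  new_potential(
    kind = "harmonic",
    U = function(x) 0.5 * stiffness * (x - center)^2,
    grad = function(x) stiffness * (x - center),
    dim = 1L,
    params = list(stiffness = stiffness, center = center),
    temperature = temperature, friction = friction,
    max_curvature = stiffness,
    range = center + c(-1, 1) * 6 * sqrt(.kB * temperature / stiffness))
}

#' @rdname harmonic_potential
#' @export
double_well_potential <- function(barrier, well_pos = 1, temperature = 300,
                                  friction = 1) {
  check_pot_common(temperature, friction)
  if (barrier <= 0) stop_("barrier must be > 0")
  if (well_pos <= 0) stop_("well_pos must be > 0")
  a <- well_pos
  new_potential(
    kind = "double_well_1d",
    U = function(x) barrier * ((x / a)^2 - 1)^2,
    grad = function(x) 4 * barrier * x * ((x / a)^2 - 1) / a^2,
    dim = 1L,
    params = list(barrier = barrier, well_pos = a),
    temperature = temperature, friction = friction,
    max_curvature = 8 * barrier / a^2,
    range = c(-1, 1) * (a + 4 * a * sqrt(.kB * temperature / (8 * barrier))))
}

#' @rdname harmonic_potential
#' @param depths,centers,widths for the 2D triple well: per-well Gaussian
#'   depths (kJ/mol, > 0), a 3 x 2 matrix of well centres (nm) and Gaussian
#'   widths (nm). A weak harmonic confinement (`confine`, kJ/(mol nm^2))
#'   keeps the walker bounded.
#' @param confine confinement stiffness of the triple-well surface.
#' @export
triple_well_potential <- function(depths = c(10, 10, 10),
                                  centers = rbind(c(-1, 0), c(1, 0), c(0, 1.2)),
                                  widths = c(0.4, 0.4, 0.4),
                                  confine = 2,
                                  temperature = 300, friction = 1) {
  check_pot_common(temperature, friction)
  if (any(depths <= 0)) stop_("well depths must be > 0")
  centers <- as.matrix(centers)
  U <- function(x) {
    # x: length-2 vector or n x 2 matrix
    xm <- if (is.null(dim(x))) matrix(x, ncol = 2) else x
    g <- 0
    for (k in seq_along(depths)) {
      d2 <- (xm[, 1] - centers[k, 1])^2 + (xm[, 2] - centers[k, 2])^2
      g <- g + depths[k] * exp(-d2 / (2 * widths[k]^2))
    }
    -g + 0.5 * confine * (xm[, 1]^2 + xm[, 2]^2)
  }
  grad <- function(x) {
    xm <- if (is.null(dim(x))) matrix(x, ncol = 2) else x
    gx <- confine * xm[, 1]; gy <- confine * xm[, 2]
    for (k in seq_along(depths)) {
      dx <- xm[, 1] - centers[k, 1]; dy <- xm[, 2] - centers[k, 2]
      e <- depths[k] * exp(-(dx^2 + dy^2) / (2 * widths[k]^2)) / widths[k]^2
      gx <- gx + e * dx; gy <- gy + e * dy
    }
    cbind(gx, gy)
  }
  new_potential(
    kind = "triple_well_2d", U = U, grad = grad, dim = 2L,
    params = list(depths = depths, centers = centers, widths = widths,
                  confine = confine),
    temperature = temperature, friction = friction,
    max_curvature = max(depths / widths^2) + confine,
    range = c(-1, 1) * (max(abs(centers)) + 3 * max(widths)))
}

new_potential <- function(kind, U, grad, dim, params, temperature, friction,
                          max_curvature, range) {
  structure(list(kind = kind, U = U, grad = grad, dim = dim, params = params,
                 temperature = temperature, friction = friction,
                 kT = .kB * temperature, max_curvature = max_curvature,
                 range = range),
            class = "md_potential")
}

check_pot_common <- function(temperature, friction) {
  if (temperature < 0) stop_("temperature must be >= 0")
  if (friction <= 0) stop_("friction must be > 0")
}

#' @export
print.md_potential <- function(x, ...) {
  cat(sprintf("<md_potential> %s (%dD), T = %g K, gamma = %g kJ ns/(mol nm^2)\n",
              x$kind, x$dim, x$temperature, x$friction))
  invisible(x)
}

#' Slowest relaxation time of a 1D potential from a grid transfer operator
#'
#' Independent oracle for the slowest timescale of overdamped diffusion in a
#' 1D potential: the domain is discretised into `n_bins` uniform bins and the
#' continuous dynamics replaced by a nearest-neighbour jump process whose
#' rates satisfy detailed balance with respect to `exp(-U/kT)`,
#' `q(i -> i+-1) = D/h^2 * exp(-(U(i+-1) - U(i)) / (2 kT))`.
#' The slowest relaxation time is `-1/lambda_2` of the rate matrix,
#' equivalently `-tau/log lambda_2` of its propagator at any lag `tau`.
#' This routine shares no code with the Markov-model estimators it validates.
#'
#' @param potential an `md_potential` of dimension 1.
#' @param n_bins number of grid bins (>= 500 recommended).
#' @param range optional domain `c(lo, hi)`; defaults to the potential's
#'   sampling range.
#' @return slowest relaxation time in ns.
#' @export
grid_relaxation_time <- function(potential, n_bins = 500, range = NULL) {
  stopifnot(inherits(potential, "md_potential"))
  if (potential$dim != 1L) stop_("grid oracle implemented for 1D potentials")
  if (n_bins < 10) stop_("n_bins too small")
  rng <- range %||% potential$range
  h <- diff(rng) / n_bins
  xc <- rng[1] + (seq_len(n_bins) - 0.5) * h
  u <- potential$U(xc)
  kT <- potential$kT
  D <- kT / potential$friction
  up <- (D / h^2) * exp(-(u[-1] - u[-n_bins]) / (2 * kT))    # i -> i+1
  dn <- (D / h^2) * exp(-(u[-n_bins] - u[-1]) / (2 * kT))    # i+1 -> i
  Q <- matrix(0, n_bins, n_bins)
  Q[cbind(seq_len(n_bins - 1), seq_len(n_bins - 1) + 1)] <- up
  Q[cbind(seq_len(n_bins - 1) + 1, seq_len(n_bins - 1))] <- dn
  diag(Q) <- -rowSums(Q)
  # symmetrize with the stationary weights for a stable real spectrum
  w <- exp(-(u - min(u)) / (2 * kT))
  S <- diag(w) %*% Q %*% diag(1 / w)
  S <- (S + t(S)) / 2
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  lambda2 <- ev[2]
  if (lambda2 >= -.Machine$double.eps) stop_("degenerate spectrum on grid")
  -1 / lambda2
}
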