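#' Sample an overdamped Langevin trajectory from a model potential
#'
#' Euler--Maruyama integration of the overdamped Langevin equation
#' `dx = -grad U / gamma dt + sqrt(2 kT / gamma) dW`, whose stationary
#' density is proportional to `exp(-U/kT)`. Used to emulate metastable
#' conformational dynamics with known exchange timescales.
#'
#' The integrator refuses step sizes that violate the stability bound
#' `dt * max|U''| / gamma < 0.1` and aborts explicitly (rather than silently
#' diverging) if the walker leaves a generous bounding box.
#'
#' For 1D potentials the returned ground truth includes the slowest
#' relaxation timescale computed by the independent grid oracle
#' [grid_relaxation_time()] (for a harmonic well the exact value
#' `gamma/stiffness` is used).
#'
#' @param potential an [harmonic_potential()], [double_well_potential()] or
#'   [triple_well_potential()].
#' @param n_steps number of integration steps.
#' @param dt time step in ns.
#' @param seed integer seed; the same seed reproduces the trajectory bit for
#'   bit.
#' @param x0 optional start position (defaults to a potential minimum).
#' @param stride keep every `stride`-th frame (frame interval `dt * stride`).
#' @param replica,ensemble labels attached to the output.
#' @return a [feature_trajectory()] with columns `x` (and `y` in 2D) and an
#'   attribute `ground_truth`: list with the seed, the potential parameters
#'   and (1D) `timescale_ns`.
#' @export
generate_langevin <- function(potential, n_steps, dt, seed, x0 = NULL,
                              stride = 1L, replica = "r1", ensemble = "default") {
  stopifnot(inherits(potential, "md_potential"))
  if (n_steps < 1) stop_("n_steps must be >= 1")
  if (dt <= 0) stop_("dt must be > 0")
  if (dt * potential$max_curvature / potential$friction >= 0.1)
    stop_("unstable time step: dt * stiffness / friction = %.3g >= 0.1",
          dt * potential$max_curvature / potential$friction)
  set.seed(seed)
  d <- potential$dim
  mob <- dt / potential$friction
  sig <- sqrt(2 * potential$kT * dt / potential$friction)
  bound <- 10 * max(abs(potential$range))
  if (is.null(x0)) {
    x0 <- switch(potential$kind,
                 harmonic = potential$params$center,
                 double_well_1d = -potential$params$well_pos,
                 triple_well_2d = potential$params$centers[1, ])
  }
  n_keep <- n_steps %/% stride
  out <- matrix(NA_real_, n_keep, d)
  x <- as.numeric(x0)
  gradf <- potential$grad
  noise <- NULL
  block <- 100000L
  ptr <- block + 1L   # force refill on first use
  k <- 0L
  for (i in seq_len(n_steps)) {
    if (ptr > block) {   # draw noise in blocks: fast and still seed-stable
      noise <- matrix(rnorm(block * d), block, d)
      ptr <- 1L
    }
    x <- x - mob * as.numeric(gradf(x)) + sig * noise[ptr, ]
    ptr <- ptr + 1L
    if (i %% stride == 0L) {
      k <- k + 1L
      out[k, ] <- x
    }
    if (i %% 10000L == 0L && (any(!is.finite(x)) || max(abs(x)) > bound))
      stop_("integration diverged at step %d; reduce dt", i)
  }
  if (any(!is.finite(out)) || max(abs(out)) > bound)
    stop_("integration diverged; reduce dt")
  colnames(out) <- c("x", "y")[seq_len(d)]
  gt <- list(seed = seed, kind = potential$kind, params = potential$params,
             temperature = potential$temperature, friction = potential$friction)
  if (d == 1L) {
    gt$timescale_ns <- if (potential$kind == "harmonic")
      potential$friction / potential$params$stiffness
    else grid_relaxation_time(potential)
  }
  ft <- feature_trajectory(out, dt_ns = dt * stride, replica = replica,
                           ensemble = ensemble)
  attr(ft, "ground_truth") <- gt
  ft
}

#' Synthetic constant-velocity pulling traces with planted rupture events
#'
#' Each trace rises linearly at `loading_rate` with additive Gaussian noise
#' until its planted rupture force (drawn from a normal cohort distribution),
#' then relaxes exponentially to a low plateau -- the signature of the ionic
#' bonds between the pulled ion and its coordinating residues breaking.
#'
#' @param loading_rate force ramp slope, kJ/(mol nm ns); > 0.
#' @param f_rupture_mean,f_rupture_sd cohort mean and spread of the planted
#'   rupture forces, kJ/(mol nm).
#' @param noise_sd additive force noise, kJ/(mol nm).
#' @param n number of traces.
#' @param seed integer seed.
#' @param dt sampling interval, ns.
#' @param t_tail extra simulated time after rupture, ns.
#' @param condition label attached to each trace.
#' @return a list of `force_trace` data.frames (`time_ns`, `force`) with an
#'   attribute `ground_truth` carrying the planted forces and times.
#' @export
generate_rupture_traces <- function(loading_rate, f_rupture_mean,
                                    f_rupture_sd = 0, noise_sd = 0, n = 1,
                                    seed = 1, dt = 0.01, t_tail = 5,
                                    condition = "default") {
  if (loading_rate <= 0) stop_("loading_rate must be > 0")
  if (n < 1) stop_("n must be >= 1")
  set.seed(seed)
  f_rup <- rnorm(n, f_rupture_mean, f_rupture_sd)
  f_rup[f_rup < 0.1 * f_rupture_mean] <- 0.1 * f_rupture_mean
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    t_rup <- f_rup[i] / loading_rate
    tt <- seq(0, t_rup + t_tail, by = dt)
    ramp <- ifelse(tt <= t_rup, loading_rate * tt,
                   f_rup[i] * 0.05 +
                     (f_rup[i] - f_rup[i] * 0.05) * exp(-(tt - t_rup) / 0.2))
    f <- ramp + if (noise_sd > 0) rnorm(length(tt), 0, noise_sd) else 0
    # the planted maximum itself is noise-free so that the noiseless case
    # reproduces the planted force exactly
    f[which.min(abs(tt - t_rup))] <- f_rup[i]
    tr <- data.frame(time_ns = tt, force = f)
    attr(tr, "condition") <- condition
    class(tr) <- c("force_trace", "data.frame")
    traces[[i]] <- tr
  }
  attr(traces, "ground_truth") <- list(seed = seed, rupture_force = f_rup,
                                       rupture_time = f_rup / loading_rate,
                                       loading_rate = loading_rate,
                                       condition = condition)
  traces
}

#' Synthetic unfolding times with right-censoring
#'
#' Draws `n` event times from an exponential distribution with rate `k` and
#' censors every draw beyond the simulation cap `t_max`: a fixed-length
#' simulation protocol truncates each trajectory, so unfolding events later
#' than the cap are only known to exceed it.
#'
#' @param k unfolding rate, 1/ns; `k = 0` gives all-censored data.
#' @param t_max censoring time, ns; > 0.
#' @param n number of trajectories.
#' @param seed integer seed.
#' @param condition,criterion labels stored in the output.
#' @return a `survival_data` data.frame (`time_ns`, `censored`, `condition`,
#'   `criterion`) with attribute `ground_truth` (`k`, `t_half`, seed).
#' @export
generate_unfolding_times <- function(k, t_max, n, seed = 1,
                                     condition = "default",
                                     criterion = "rmsd") {
  if (k < 0) stop_("k must be >= 0")
  if (t_max <= 0) stop_("t_max must be > 0")
  set.seed(seed)
  tt <- if (k > 0) rexp(n, rate = k) else rep(Inf, n)
  cens <- tt > t_max
  out <- data.frame(time_ns = pmin(tt, t_max), censored = as.integer(cens),
                    condition = condition, criterion = criterion)
  class(out) <- c("survival_data", "data.frame")
  attr(out, "ground_truth") <- list(seed = seed, k = k,
                                    t_half = if (k > 0) log(2) / k else Inf,
                                    t_max = t_max)
  out
}

# Exact single-site binding isotherm with cell-displacement correction.
# Concentrations mol/l, volumes ul, dH kJ/mol; returns heats in ucal.
itc_heats_ucal <- function(Kd, dH, n_sites, cell_conc, syringe_conc,
                           volumes_ul, cell_volume_ul = 200) {
  V0 <- cell_volume_ul * 1e-6          # l
  M <- cell_conc; X <- 0; B_prev <- 0
  q <- numeric(length(volumes_ul))
  for (j in seq_along(volumes_ul)) {
    dV <- volumes_ul[j] * 1e-6
    f <- dV / V0
    M <- M * (1 - f)
    X <- X * (1 - f) + syringe_conc * f
    s <- n_sites * M + X + Kd
    B <- (s - sqrt(s^2 - 4 * n_sites * M * X)) / 2     # bound ligand, mol/l
    dB_mol <- V0 * (B - B_prev * (1 - f))
    q[j] <- dH * 1000 * dB_mol / 4.184 * 1e6           # kJ/mol -> ucal
    B_prev <- B
  }
  q
}

#' Synthetic one-site ITC thermogram
#'
#' Per-injection heats from the exact single-site binding isotherm (ligand
#' conservation solved by the quadratic formula, with the standard
#' displacement correction for the overfill cell), plus Gaussian noise.
#' The Wiseman c-value `n * cell_conc / Kd` is reported and a low-c warning
#' flag is set when `c < 5`, the regime in which the fitted enthalpy is
#' unreliable.
#'
#' @param Kd dissociation constant, mol/l.
#' @param dH binding enthalpy, kJ/mol.
#' @param n_sites stoichiometry.
#' @param cell_conc cell (macromolecule) concentration, mol/l.
#' @param syringe_conc titrant concentration, mol/l.
#' @param injections injection volumes, ul.
#' @param noise_sd heat noise, ucal.
#' @param seed integer seed.
#' @param cell_volume_ul calorimeter cell volume, ul; must be > 0.
#' @return a `titration` data.frame (`injection`, `volume_ul`, `heat_ucal`)
#'   with attributes `ground_truth` and `geometry`.
#' @export
generate_itc_thermogram <- function(Kd, dH, n_sites = 1, cell_conc,
                                    syringe_conc, injections = rep(2, 19),
                                    noise_sd = 0, seed = 1,
                                    cell_volume_ul = 200) {
  if (Kd <= 0 || cell_conc <= 0 || syringe_conc <= 0)
    stop_("Kd and concentrations must be > 0")
  if (cell_volume_ul <= 0) stop_("cell volume must be > 0")
  set.seed(seed)
  q <- itc_heats_ucal(Kd, dH, n_sites, cell_conc, syringe_conc, injections,
                      cell_volume_ul)
  if (noise_sd > 0) q <- q + rnorm(length(q), 0, noise_sd)
  c_value <- n_sites * cell_conc / Kd
  out <- data.frame(injection = seq_along(injections),
                    volume_ul = injections, heat_ucal = q)
  class(out) <- c("titration", "data.frame")
  attr(out, "geometry") <- list(cell_conc = cell_conc,
                                syringe_conc = syringe_conc,
                                cell_volume_ul = cell_volume_ul)
  attr(out, "ground_truth") <- list(seed = seed, Kd = Kd, dH = dH,
                                    n_sites = n_sites, c_value = c_value,
                                    low_c = c_value < 5)
  out
}

#' Toy coordinate trajectory with scheduled hydrogen-bond occupancies
#'
#' A hidden three-state Markov chain emits a miniature donor/hydrogen/
#' acceptor system per scheduled bond: in a frame where a bond is "on" the
#' acceptor sits 0.28 nm from the donor with the hydrogen on the axis
#' (satisfying the geometric criterion); "off" frames place the acceptor at
#' 0.60 nm. Two additional reporter atoms move between state-specific
#' emission centres so that clustering in coordinate space can recover the
#' hidden states. True labels and the occupancy schedule are recorded.
#'
#' @param schedule numeric matrix states x bonds of occupancies in `[0, 1]`;
#'   column names become bond labels.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param stay self-transition probability of the hidden chain.
#' @param emission_sd positional noise of the reporter atoms, nm.
#' @param dt_ns frame interval.
#' @return a [coord_trajectory()] with attribute `ground_truth` (hidden
#'   `labels`, `schedule`, bond atom indices, reporter emission centres).
#' @export
generate_hbond_toy <- function(schedule, n_frames, seed = 1, stay = 0.95,
                               emission_sd = 0.05, dt_ns = 1) {
  schedule <- as.matrix(schedule)
  if (any(schedule < 0 | schedule > 1)) stop_("occupancies must be in [0, 1]")
  n_states <- nrow(schedule)
  n_bonds <- ncol(schedule)
  if (is.null(colnames(schedule)))
    colnames(schedule) <- paste0("bond", seq_len(n_bonds))
  set.seed(seed)
  # hidden chain: symmetric, uniform off-diagonal
  P <- matrix((1 - stay) / (n_states - 1), n_states, n_states)
  diag(P) <- stay
  z <- integer(n_frames); z[1] <- 1L
  for (t in 2:n_frames) z[t] <- sample.int(n_states, 1L, prob = P[z[t - 1], ])

  # atoms: per bond D (N), H, A (O); then 2 reporter CA atoms
  n_at <- 3L * n_bonds + 2L
  atoms <- data.frame(
    eleno = seq_len(n_at),
    elety = c(rep(c("N", "H", "O"), n_bonds), "CA", "CA"),
    resno = c(rep(seq_len(n_bonds) * 2 - 1, each = 3) ,
              n_bonds * 2 + 1, n_bonds * 2 + 2),
    resid = c(rep("ASN", 3 * n_bonds), "GLY", "GLY"))
  # emission centres for the reporter atoms, one pair per hidden state
  centers <- matrix(rnorm(n_states * 6, sd = 2), n_states, 6)
  xyz <- array(0, c(n_frames, n_at, 3))
  base <- (seq_len(n_bonds) - 1) * 3
  for (t in seq_len(n_frames)) {
    on <- runif(n_bonds) < schedule[z[t], ]
    for (b in seq_len(n_bonds)) {
      o <- c(5 * b, 0, 0)                       # donor origin per bond
      xyz[t, base[b] + 1, ] <- o                # donor N
      xyz[t, base[b] + 2, ] <- o + c(0.10, 0, 0)  # hydrogen on the axis
      xyz[t, base[b] + 3, ] <- o + c(if (on[b]) 0.28 else 0.60, 0, 0)
    }
    xyz[t, n_at - 1L, ] <- centers[z[t], 1:3] + rnorm(3, sd = emission_sd)
    xyz[t, n_at, ] <- centers[z[t], 4:6] + rnorm(3, sd = emission_sd)
  }
  traj <- coord_trajectory(xyz, atoms, dt_ns = dt_ns)
  attr(traj, "ground_truth") <- list(
    seed = seed, labels = z, schedule = schedule, stay = stay,
    bonds = lapply(seq_len(n_bonds), function(b)
      list(donor = base[b] + 1L, hydrogen = base[b] + 2L,
           acceptor = base[b] + 3L, label = colnames(schedule)[b])),
    reporter_atoms = c(n_at - 1L, n_at), centers = centers)
  traj
}

#' Synthetic per-frame pKa records with planted carboxyl--carboxyl coupling
#'
#' Emulates an ensemble of per-frame pKa predictions for one titratable
#' residue: values are drawn from `N(mean_pka, sd)`; a Bernoulli flag with
#' probability `coupling_fraction` marks frames in which the residue couples
#' to a nearby carboxyl group, and those frames carry the two alternative
#' values returned by a coupling-aware predictor (alternative a: this group
#' protonated first; alternative b: the partner first).
#'
#' @param n_frames number of frames.
#' @param mean_pka,sd base distribution of the per-frame pKa.
#' @param coupling_fraction probability that a frame is coupled, in `[0, 1]`.
#' @param seed integer seed.
#' @param residue,partner residue identifiers (e.g. `"D308"`, `"E285"`).
#' @param alt_shift separation of the alternative-a/-b means from the base
#'   mean (a above, b below).
#' @return a data.frame of `pka_record`s (`frame`, `residue`, `pka`,
#'   `coupled`, `partner`, `alt_a`, `alt_b`) with attribute `ground_truth`.
#' @export
generate_pka_records <- function(n_frames, mean_pka, sd, coupling_fraction,
                                 seed = 1, residue = "D308",
                                 partner = "E285", alt_shift = 0.8) {
  if (coupling_fraction < 0 || coupling_fraction > 1)
    stop_("coupling_fraction must be in [0, 1]")
  if (sd < 0) stop_("sd must be >= 0")
  set.seed(seed)
  pka <- rnorm(n_frames, mean_pka, sd)
  coupled <- runif(n_frames) < coupling_fraction
  alt_a <- ifelse(coupled, pka + alt_shift, NA_real_)
  alt_b <- ifelse(coupled, pka - alt_shift, NA_real_)
  out <- data.frame(frame = seq_len(n_frames) - 1L, residue = residue,
                    pka = pka, coupled = coupled,
                    partner = ifelse(coupled, partner, NA_character_),
                    alt_a = alt_a, alt_b = alt_b)
  attr(out, "ground_truth") <- list(seed = seed, mean_pka = mean_pka, sd = sd,
                                    coupling_fraction = coupling_fraction,
                                    alt_shift = alt_shift)
  out
}

#' Write pKa records as PROPKA 3.1-style summary files
#'
#' One file per frame in the summary layout of PROPKA 3.1 (a
#' `SUMMARY OF THIS PREDICTION` table plus a coupled-residues block with the
#' two alternative pKa values). The files are synthetic stand-ins generated
#' from [generate_pka_records()]; they carry the subset of the format that
#' [parse_propka()] consumes.
#'
#' @param records data.frame from [generate_pka_records()] (possibly several
#'   residues row-bound; one file is written per distinct frame).
#' @param dir output directory.
#' @param prefix file name prefix; files are `<prefix>_<frame>.pka`.
#' @return character vector of file paths, invisibly ordered by frame.
#' @export
write_propka <- function(records, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frames <- sort(unique(records$frame))
  paths <- character(length(frames))
  res_parts <- function(id) {
    list(aa = .aa3[[substr(id, 1, 1)]], num = substr(id, 2, nchar(id)))
  }
  for (i in seq_along(frames)) {
    fr <- records[records$frame == frames[i], , drop = FALSE]
    p <- file.path(dir, sprintf("%s_%05d.pka", prefix, frames[i]))
    con <- file(p, "w")
    writeLines("propka3.1", con)
    writeLines(strrep("-", 80), con)
    writeLines("SUMMARY OF THIS PREDICTION", con)
    writeLines("     Group      pKa  model-pKa", con)
    for (j in seq_len(nrow(fr))) {
      rp <- res_parts(fr$residue[j])
      writeLines(sprintf("   %-3s %4s A %8.2f %10.2f", rp$aa, rp$num,
                         fr$pka[j], 4.0), con)
    }
    writeLines(strrep("-", 80), con)
    cp <- fr[fr$coupled, , drop = FALSE]
    if (nrow(cp) > 0) {
      writeLines("Detecting coupled residues", con)
      for (j in seq_len(nrow(cp))) {
        rp <- res_parts(cp$residue[j]); pp <- res_parts(cp$partner[j])
        writeLines(sprintf("  %s %s A is coupled to %s %s A", rp$aa, rp$num,
                           pp$aa, pp$num), con)
        writeLines(sprintf("    Alternative a pKa %s %s A %8.2f", rp$aa,
                           rp$num, cp$alt_a[j]), con)
        writeLines(sprintf("    Alternative b pKa %s %s A %8.2f", rp$aa,
                           rp$num, cp$alt_b[j]), con)
      }
    }
    close(con)
    paths[i] <- p
  }
  invisible(paths)
}
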