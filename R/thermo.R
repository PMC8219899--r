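#' Binding free energy from a dissociation constant
#'
#' Standard binding free energy `dG = R T log(Kd)` (equivalently
#' `-R T log(Ka)`) with `R = 8.314` J/(K mol) and `Kd` dimensionless under
#' the 1 M standard state (i.e. entered in mol/l), so that sub-molar
#' dissociation constants give the negative free energies of favourable
#' binding. The value is returned in kJ/mol at full precision; the field
#' convention of reporting one decimal (half-away-from-zero) is applied in
#' [binding_energy_table()].
#'
#' @param Kd dissociation constant, mol/l (> 0); vectorised.
#' @param temperature temperature, K.
#' @return free energy in kJ/mol.
#' @export
delta_g <- function(Kd, temperature = 300) {
  if (any(Kd <= 0)) stop_("Kd must be > 0")
  if (any(temperature <= 0)) stop_("temperature must be > 0")
  .R_GAS * temperature * log(Kd) / 1000
}

#' pH sensitivity from a pair of binding measurements
#'
#' `ddG = dG(pH 6) - dG(pH 7)` for the same variant and temperature, with
#' the measurement errors propagated to first order
#' (`sigma_dG = R T sigma_Kd / Kd / 1000`) and combined in quadrature.
#' The result is antisymmetric under swapping the pair.
#'
#' @param m_ph6,m_ph7 lists or one-row data.frames with fields `variant`,
#'   `pH`, `Kd` (mol/l), `Kd_err` (mol/l), `temperature` (K).
#' @return object of class `free_energy_result`: `ddG` (kJ/mol),
#'   `ddG_err`, `dG_ph6`, `dG_ph7`, per-measurement errors, `variant`.
#' @export
delta_delta_g <- function(m_ph6, m_ph7) {
  m6 <- as.list(m_ph6); m7 <- as.list(m_ph7)
  if (!identical(m6$variant, m7$variant))
    stop_("measurements are for different variants: %s vs %s",
          m6$variant, m7$variant)
  T6 <- m6$temperature %||% 300; T7 <- m7$temperature %||% 300
  if (!isTRUE(all.equal(T6, T7)))
    stop_("measurements at different temperatures")
  g6 <- delta_g(m6$Kd, T6)
  g7 <- delta_g(m7$Kd, T7)
  e6 <- if (is.null(m6$Kd_err)) 0 else .R_GAS * T6 * m6$Kd_err / m6$Kd / 1000
  e7 <- if (is.null(m7$Kd_err)) 0 else .R_GAS * T7 * m7$Kd_err / m7$Kd / 1000
  structure(list(variant = m6$variant, ddG = g6 - g7,
                 ddG_err = sqrt(e6^2 + e7^2),
                 dG_ph6 = g6, dG_ph7 = g7, dG_ph6_err = e6, dG_ph7_err = e7,
                 temperature = T6),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("<free_energy_result> %s: dG(pH6) = %.1f, dG(pH7) = %.1f, ddG = %.1f kJ/mol\n",
              x$variant, round_half_up(x$dG_ph6), round_half_up(x$dG_ph7),
              round_half_up(x$ddG)))
  invisible(x)
}

#' Bundled calcium-binding dissociation constants
#'
#' The ITC-determined dissociation constants of the wildtype langerin
#' carbohydrate-recognition domain and its H294A and E261D variants at pH 6
#' and pH 7 (including an independent remeasurement of the wildtype),
#' shipped as a plain-text table.
#'
#' @return data.frame with columns `variant`, `pH`, `Kd` (mol/l), `Kd_err`
#'   (mol/l), `temperature` (K).
#' @export
binding_measurements <- function() {
  path <- system.file("extdata", "ca_binding_kd.csv", package = "phrelay")
  d <- utils::read.csv(path)
  d$Kd <- d$Kd_uM * 1e-6
  d$Kd_err <- d$Kd_err_uM * 1e-6
  d$temperature <- d$T_K
  d[, c("variant", "pH", "Kd", "Kd_err", "temperature")]
}

#' Free energies and pH sensitivities for a measurement table
#'
#' Computes `dG` for every measurement and `ddG` for every variant with
#' both a pH 6 and a pH 7 entry; values are displayed at one decimal
#' (half-away-from-zero), the printing convention for these quantities.
#'
#' @param measurements data.frame as returned by [binding_measurements()].
#' @param digits decimals for the displayed columns.
#' @return data.frame `variant`, `pH`, `Kd_uM`, `dG`, `ddG` (ddG on the
#'   pH 6 rows).
#' @export
binding_energy_table <- function(measurements = binding_measurements(),
                                 digits = 1) {
  m <- measurements
  m$dG <- round_half_up(delta_g(m$Kd, m$temperature), digits)
  m$ddG <- NA_real_
  for (v in unique(m$variant)) {
    i6 <- which(m$variant == v & m$pH == 6)
    i7 <- which(m$variant == v & m$pH == 7)
    if (length(i6) == 1L && length(i7) == 1L) {
      r <- delta_delta_g(m[i6, ], m[i7, ])
      m$ddG[i6] <- round_half_up(r$ddG, digits)
    }
  }
  data.frame(variant = m$variant, pH = m$pH, Kd_uM = m$Kd * 1e6,
             dG = m$dG, ddG = m$ddG)
}

#' Fit a one-set-of-sites binding isotherm to an ITC thermogram
#'
#' Nonlinear least squares of the per-injection heats against the exact
#' single-site conservation model (quadratic solution with the cell-
#' displacement correction; Hill coefficient 1), the model used by standard
#' ITC software. The stoichiometry can be fixed (`fix_n = 1` is the usual
#' choice) or fitted. The Wiseman c-value `n * cell_conc / Kd` is reported;
#' when `c < 5` the low-c flag is set and the fitted enthalpy carries a
#' reliability note, since shallow isotherms leave `dH` poorly determined.
#'
#' @param thermogram a `titration` data.frame (columns `injection`,
#'   `volume_ul`, `heat_ucal`), e.g. from [generate_itc_thermogram()] or
#'   read from CSV.
#' @param cell_conc cell (macromolecule) concentration, mol/l.
#' @param syringe_conc titrant concentration, mol/l.
#' @param cell_volume_ul calorimeter cell volume, ul.
#' @param fix_n fixed stoichiometry, or `NULL` to fit it.
#' @param start optional named start values (`Kd`, `dH`, `n`).
#' @return object of class `one_site_fit`: `Kd` (mol/l), `dH` (kJ/mol),
#'   `n`, `c_value`, `low_c`, `dH_unreliable`, `residuals`, `fitted`.
#' @export
fit_one_site <- function(thermogram, cell_conc, syringe_conc,
                         cell_volume_ul = NULL, fix_n = 1, start = NULL) {
  if (nrow(thermogram) < 5L) stop_("need at least 5 injections")
  geom <- attr(thermogram, "geometry")
  cell_conc <- if (missing(cell_conc)) geom$cell_conc else cell_conc
  syringe_conc <- if (missing(syringe_conc)) geom$syringe_conc else syringe_conc
  cell_volume_ul <- cell_volume_ul %||% geom$cell_volume_ul %||% 200
  if (cell_conc <= 0 || syringe_conc <= 0) stop_("concentrations must be > 0")
  q <- thermogram$heat_ucal
  vols <- thermogram$volume_ul
  # flat thermogram: dH unidentifiable
  if (max(abs(q)) < 1e-9 || sd(q) < 1e-9 * max(abs(q), 1)) {
    return(structure(list(Kd = NA_real_, dH = 0, n = fix_n %||% 1,
                          c_value = NA_real_, low_c = NA, dH_unreliable = TRUE,
                          flat = TRUE, residuals = q * 0, fitted = q * 0),
                     class = "one_site_fit"))
  }
  # heuristic starts: half-saturation near the inflection, dH from total heat
  dH0 <- sum(q) * 4.184 * 1e-6 / 1000 / (cell_conc * cell_volume_ul * 1e-6)
  st <- list(logKd = log(start$Kd %||% (cell_conc / 2)),
             dH = start$dH %||% dH0)
  if (is.null(fix_n)) st$n <- start$n %||% 1
  model <- function(logKd, dH, n) {
    itc_heats_ucal(exp(logKd), dH, n, cell_conc, syringe_conc, vols,
                   cell_volume_ul)
  }
  dat <- data.frame(q = q)
  fit <- if (is.null(fix_n)) {
    minpack.lm::nlsLM(q ~ model(logKd, dH, n), data = dat, start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    n_fixed <- fix_n
    minpack.lm::nlsLM(q ~ model(logKd, dH, n_fixed), data = dat, start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- coef(fit)
  Kd <- exp(cf[["logKd"]])
  n <- if (is.null(fix_n)) cf[["n"]] else fix_n
  cv <- n * cell_conc / Kd
  structure(list(Kd = Kd, dH = cf[["dH"]], n = n, c_value = cv,
                 low_c = cv < 5, dH_unreliable = cv < 5, flat = FALSE,
                 residuals = as.numeric(resid(fit)),
                 fitted = as.numeric(stats::fitted(fit)),
                 convergence = fit$convInfo %||% NULL),
            class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  if (isTRUE(x$flat)) {
    cat("<one_site_fit> flat thermogram: dH = 0, Kd unidentifiable\n")
    return(invisible(x))
  }
  cat(sprintf("<one_site_fit> Kd = %.3g mol/l, dH = %.3g kJ/mol, n = %.3g, c = %.3g%s\n",
              x$Kd, x$dH, x$n, x$c_value,
              if (x$low_c) " [low c: enthalpy unreliable]" else ""))
  invisible(x)
}

#' @export
coef.one_site_fit <- function(object, ...) {
  c(Kd = object$Kd, dH = object$dH, n = object$n)
}
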