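# Closed-form and numeric binding/protonation models.
#
# The probe (F-neo) binds equivalent RNA sites tightly enough that free and
# total concentrations cannot be identified, so the forward model is the
# ligand-depletion ("tight-binding") quadratic isotherm, and competition with
# an unlabelled compound is solved by mass balance on the free-site
# concentration. All concentrations are in nM throughout the package.

# Paper-style physical constants (used as printed alongside the potential
# equation; R deliberately 8.312, not CODATA).
.R_GAS <- 8.312        # J mol^-1 K^-1
.N_AVOGADRO <- 6.023e23
.E_CHARGE <- 1.602e-19 # C

#' Tight-binding quadratic isotherm model
#'
#' Container for the forward fluorescence model of probe binding under ligand
#' depletion: total probe `probe_total` (nM) distributed over a single class of
#' equivalent sites with dissociation constant `kd` (nM), reading out
#' fluorescence between `f0` (free probe) and `fb` (fully bound probe).
#'
#' @param f0 Fluorescence of the free probe (arbitrary units).
#' @param fb Fluorescence of the fully bound probe (same units). Quenching
#'   assays have `fb < f0`, but `fb >= f0` is accepted.
#' @param kd Dissociation constant, nM (> 0).
#' @param probe_total Total probe concentration, nM (> 0).
#' @return An object of class `quadratic_binding_model`.
#' @seealso [eq1_fluorescence()], [fit_kd()]
#' @export
quadratic_binding_model <- function(f0, fb, kd, probe_total) {
  check_scalar_finite(f0, "f0")
  check_scalar_finite(fb, "fb")
  check_scalar_finite(kd, "kd")
  check_scalar_finite(probe_total, "probe_total")
  if (kd <= 0) validation_error("'kd' must be > 0")
  if (probe_total <= 0) validation_error("'probe_total' must be > 0")
  structure(list(f0 = f0, fb = fb, kd = kd, probe_total = probe_total),
            class = "quadratic_binding_model")
}

#' @export
print.quadratic_binding_model <- function(x, ...) {
  cat("Tight-binding quadratic model\n")
  cat(sprintf("  F0 = %g, Fb = %g, K_D = %g nM, [probe]_total = %g nM\n",
              x$f0, x$fb, x$kd, x$probe_total))
  invisible(x)
}

#' Forward fluorescence of the quadratic isotherm
#'
#' Computes `F = F0 + (Fb - F0)/(2 P) * (S - sqrt(S^2 - 4 psi P))` with
#' `P = probe_total` and `S = psi + P + kd`, i.e. the fraction of probe bound
#' to a total site concentration `psi` under ligand depletion, mapped onto the
#' fluorescence axis. `psi` is the concentration of *binding sites* (RNA
#' concentration times site multiplicity), in nM.
#'
#' A tiny negative discriminant (|disc| < 1e-9 * S^2) is clamped to zero —
#' titrations near stoichiometric equivalence hit it through round-off; larger
#' negatives raise a domain error.
#'
#' @param model A [quadratic_binding_model()].
#' @param psi Site concentrations, nM (vectorized, >= 0).
#' @return Numeric vector of fluorescence values.
#' @export
eq1_fluorescence <- function(model, psi) {
  if (!inherits(model, "quadratic_binding_model"))
    validation_error("'model' must be a quadratic_binding_model")
  check_numeric_finite(psi, "psi")
  if (any(psi < 0)) domain_error("'psi' must be >= 0")
  p <- model$probe_total
  s <- psi + p + model$kd
  disc <- s^2 - 4 * psi * p
  neg <- disc < 0
  if (any(neg)) {
    hard <- neg & (abs(disc) >= 1e-9 * s^2)
    if (any(hard))
      domain_error("discriminant < 0 beyond round-off: invalid parameters")
    disc[neg] <- 0
  }
  bound <- (s - sqrt(disc)) / 2
  bound[psi == 0] <- 0  # exact free-probe limit
  model$f0 + (model$fb - model$f0) * bound / p
}

# Vectorized safeguarded bisection + Newton polish for the free-site
# concentration s in [0, site_total] of the two-ligand one-site mass balance
#   s + P s/(s + KdP) + C s/(s + KdC) = S_total.
# The left side is strictly increasing in s, so the root is unique.
.solve_free_sites <- function(site_total, probe_total, kd_probe,
                              competitor_total, kd_competitor) {
  comp_term <- function(s) {
    out <- rep(0, length(s))
    fin <- is.finite(kd_competitor) & competitor_total > 0
    if (any(fin))
      out[fin] <- competitor_total[fin] * s[fin] / (s[fin] + kd_competitor[fin])
    out
  }
  g <- function(s) s + probe_total * s / (s + kd_probe) + comp_term(s) - site_total
  lo <- rep(0, length(site_total))
  hi <- site_total
  for (i in seq_len(64L)) {
    mid <- (lo + hi) / 2
    up <- g(mid) > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  s <- (lo + hi) / 2
  # Newton polish to machine precision (derivative of g is >= 1).
  for (i in seq_len(4L)) {
    dcomp <- rep(0, length(s))
    fin <- is.finite(kd_competitor) & competitor_total > 0
    if (any(fin))
      dcomp[fin] <- competitor_total[fin] * kd_competitor[fin] /
        (s[fin] + kd_competitor[fin])^2
    dg <- 1 + probe_total * kd_probe / (s + kd_probe)^2 + dcomp
    s <- pmin(pmax(s - g(s) / dg, 0), site_total)
  }
  resid <- abs(g(s))
  scale <- pmax(site_total, 1)
  if (any(resid > 1e-6 * scale))
    numeric_error(sprintf(
      "competitive equilibrium failed to converge (max relative residual %.3g)",
      max(resid / scale)))
  s
}

#' Competitive two-ligand one-site equilibrium
#'
#' Solves the mass-balance system for a labelled probe and an unlabelled
#' competitor binding a single class of equivalent sites. The free-site
#' concentration is found by a bracketing root search on `[0, site_total]`
#' (the mass-balance function is strictly monotone there, so the physical root
#' is unique), followed by a Newton polish.
#'
#' All arguments are in nM and vectorized (recycled to a common length);
#' `kd_competitor = Inf` encodes an inert or absent competitor.
#'
#' @param site_total Total binding-site concentration, nM (>= 0).
#' @param probe_total Total probe concentration, nM (>= 0).
#' @param kd_probe Probe dissociation constant, nM (> 0).
#' @param competitor_total Total competitor concentration, nM (>= 0).
#' @param kd_competitor Competitor dissociation constant, nM (> 0 or `Inf`).
#' @return An `equilibrium_state`: list of numeric vectors `free_sites`,
#'   `bound_probe`, `free_probe`, `bound_competitor`, `free_competitor`
#'   (all nM), plus the totals used.
#' @export
solve_competitive_equilibrium <- function(site_total, probe_total, kd_probe,
                                          competitor_total = 0,
                                          kd_competitor = Inf) {
  for (nm in c("site_total", "probe_total", "competitor_total")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      validation_error(sprintf("'%s' must be finite and >= 0", nm))
  }
  if (!is.numeric(kd_probe) || any(!is.finite(kd_probe)) || any(kd_probe <= 0))
    validation_error("'kd_probe' must be finite and > 0")
  if (!is.numeric(kd_competitor) || any(is.na(kd_competitor)) ||
      any(kd_competitor <= 0))
    validation_error("'kd_competitor' must be > 0 (Inf allowed)")
  n <- max(length(site_total), length(probe_total), length(kd_probe),
           length(competitor_total), length(kd_competitor))
  site_total <- rep_len(site_total, n)
  probe_total <- rep_len(probe_total, n)
  kd_probe <- rep_len(kd_probe, n)
  competitor_total <- rep_len(competitor_total, n)
  kd_competitor <- rep_len(kd_competitor, n)

  s <- .solve_free_sites(site_total, probe_total, kd_probe,
                         competitor_total, kd_competitor)
  bound_probe <- probe_total * s / (s + kd_probe)
  bound_comp <- ifelse(is.finite(kd_competitor),
                       competitor_total * s / (s + kd_competitor), 0)
  structure(list(
    free_sites = s,
    bound_probe = bound_probe,
    free_probe = probe_total - bound_probe,
    bound_competitor = bound_comp,
    free_competitor = competitor_total - bound_comp,
    site_total = site_total,
    probe_total = probe_total,
    competitor_total = competitor_total
  ), class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("Equilibrium state (%d condition%s)\n", length(x$free_sites),
              if (length(x$free_sites) == 1L) "" else "s"))
  print(data.frame(free_sites = x$free_sites, bound_probe = x$bound_probe,
                   bound_competitor = x$bound_competitor), ...)
  invisible(x)
}

#' Fluorescein protonation model
#'
#' Two-state (monoanion/dianion) ionization of the probe's fluorescein: a
#' single-proton Henderson-Hasselbalch equilibrium with distinct optical
#' signals for the two species.
#'
#' @param pka Apparent pKa, in (0, 14).
#' @param signal_mono Signal (absorbance or fluorescence) of the monoanion.
#' @param signal_di Signal of the dianion; must differ from `signal_mono` for
#'   identifiability.
#' @return An object of class `protonation_model`.
#' @export
protonation_model <- function(pka, signal_mono, signal_di) {
  check_scalar_finite(pka, "pka")
  check_scalar_finite(signal_mono, "signal_mono")
  check_scalar_finite(signal_di, "signal_di")
  if (pka <= 0 || pka >= 14) validation_error("'pka' must be in (0, 14)")
  if (signal_di == signal_mono)
    validation_error("'signal_di' must differ from 'signal_mono'")
  structure(list(pka = pka, signal_mono = signal_mono, signal_di = signal_di),
            class = "protonation_model")
}

#' Dianion fraction at a given pH
#'
#' `fraction = 1 / (1 + 10^(pka - ph))`: the fraction of fluorescein in the
#' strongly absorbing/emitting dianion state.
#'
#' @param ph pH values (vectorized, finite).
#' @param pka Apparent pKa (scalar) or a [protonation_model()].
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
dianion_fraction <- function(ph, pka) {
  if (inherits(pka, "protonation_model")) pka <- pka$pka
  check_numeric_finite(ph, "ph")
  check_scalar_finite(pka, "pka")
  1 / (1 + 10^(pka - ph))
}

#' Predicted optical signal of the protonation model
#'
#' @param model A [protonation_model()].
#' @param ph pH values.
#' @return A list with components `fraction` (dianion fraction) and `signal`
#'   (`signal_mono + (signal_di - signal_mono) * fraction`).
#' @export
protonation_signal <- function(model, ph) {
  if (!inherits(model, "protonation_model"))
    validation_error("'model' must be a protonation_model")
  f <- dianion_fraction(ph, model$pka)
  list(fraction = f,
       signal = model$signal_mono + (model$signal_di - model$signal_mono) * f)
}

#' Apparent electrostatic potential from a pKa shift
#'
#' Converts the shift in the probe fluorescein's pKa between free and bound
#' states into an apparent electrostatic potential of the binding site:
#' `phi = -2.303 * (pKa_bound - pKa_free)` in units of kT/e, also reported in
#' volts at `temperature_k` using the gas-constant/Avogadro/elementary-charge
#' values conventional for this assay (R = 8.312 J/mol/K, N_A = 6.023e23,
#' e = 1.602e-19 C). A pKa increase on binding (stabilized monoanion) gives a
#' negative potential, as expected for a nucleic-acid groove.
#'
#' @param pka_free pKa of the free probe, in (0, 14).
#' @param pka_bound pKa of the bound probe, in (0, 14).
#' @param temperature_k Temperature in kelvin (default 298.2).
#' @return An `electrostatic_result` with `delta_pka`, `phi_kt_per_e`,
#'   `phi_volts` and `temperature_k`.
#' @export
electrostatic_potential <- function(pka_free, pka_bound, temperature_k = 298.2) {
  check_scalar_finite(pka_free, "pka_free")
  check_scalar_finite(pka_bound, "pka_bound")
  check_scalar_finite(temperature_k, "temperature_k")
  if (pka_free <= 0 || pka_free >= 14 || pka_bound <= 0 || pka_bound >= 14)
    validation_error("pKa values must be in (0, 14)")
  if (temperature_k <= 0) validation_error("'temperature_k' must be > 0")
  delta <- pka_bound - pka_free
  phi_kt <- -2.303 * delta
  kt_over_e_volts <- .R_GAS * temperature_k / (.N_AVOGADRO * .E_CHARGE)
  structure(list(
    delta_pka = delta,
    phi_kt_per_e = phi_kt,
    phi_volts = phi_kt * kt_over_e_volts,
    temperature_k = temperature_k
  ), class = "electrostatic_result")
}

#' @export
print.electrostatic_result <- function(x, ...) {
  cat(sprintf("delta pKa = %+.4g; phi = %.4g kT/e = %.4g mV (T = %g K)\n",
              x$delta_pka, x$phi_kt_per_e, 1e3 * x$phi_volts, x$temperature_k))
  invisible(x)
}
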