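# Nonlinear least-squares estimation: K_D via the quadratic isotherm, site
# multiplicity by candidate scan, pKa from pH titrations, IC50 from
# displacement titrations. Fits run stats::nls (port, bounded) with
# data-driven starting values; an optim() fallback keeps pathological series
# from dying in the line search.

#' Titration series container
#'
#' Paired (x, y) observations for any titration experiment: `x` is a
#' concentration in nM (or a pH for [fit_pka()]), `y` the optical signal.
#'
#' @param x Numeric vector of concentrations (nM) or pH values.
#' @param y Numeric signal vector, same length as `x`.
#' @param meta Optional named list describing the titrated species and fixed
#'   assay components.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(x, y, meta = list()) {
  check_numeric_finite(x, "x")
  if (!is.numeric(y) || length(y) != length(x) || any(!is.finite(y)))
    validation_error("'y' must be finite numeric of the same length as 'x'")
  structure(list(x = as.numeric(x), y = as.numeric(y), meta = meta),
            class = "titration_series")
}

#' @export
as.data.frame.titration_series <- function(x, ...) {
  data.frame(x = x$x, y = x$y)
}

#' @export
print.titration_series <- function(x, ...) {
  lab <- if (!is.null(x$meta$label)) paste0(" [", x$meta$label, "]") else ""
  cat(sprintf("Titration series%s: %d points, x in [%g, %g]\n",
              lab, length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

.as_series <- function(series) {
  if (inherits(series, "titration_series")) return(series)
  if (is.data.frame(series) && ncol(series) >= 2L)
    return(titration_series(series[[1L]], series[[2L]]))
  validation_error("expected a titration_series or a two-column data frame")
}

# Shared nls-with-fallback driver. `fn(pars, x)` is the forward model,
# `start` a named list; `lower` named bounds (port). Returns list(pars, se,
# rss, fitted, converged).
.ls_fit <- function(x, y, fn, start, lower) {
  par_names <- names(start)
  env <- new.env(parent = environment())
  assign("x", x, envir = env)
  assign("y", y, envir = env)
  assign("fn", fn, envir = env)
  form <- stats::as.formula(
    paste0("y ~ fn(c(", paste(sprintf("%s = %s", par_names, par_names),
                              collapse = ", "), "), x)"),
    env = env)
  fit <- tryCatch(
    stats::nls(form, start = start, algorithm = "port",
               lower = lower[par_names],
               control = stats::nls.control(maxiter = 200L, tol = 1e-10,
                                            minFactor = 1e-12,
                                            warnOnly = FALSE)),
    error = function(e) e)
  if (!inherits(fit, "error")) {
    pars <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) stats::setNames(rep(NA_real_, length(pars)),
                                                       names(pars)))
    fitted <- fn(pars, x)
    return(list(pars = pars, se = se[par_names],
                rss = sum((y - fitted)^2), fitted = fitted, converged = TRUE))
  }
  # Fallback: Nelder-Mead on the SSE with a log-barrier-free reparametrization
  # is overkill here; plain bounded SSE via optim(L-BFGS-B) is enough.
  obj <- function(p) {
    names(p) <- par_names
    sum((y - fn(p, x))^2)
  }
  op <- tryCatch(
    stats::optim(unlist(start), obj, method = "L-BFGS-B",
                 lower = lower[par_names],
                 control = list(maxit = 2000L, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(op))
    fit_error(sprintf("nonlinear fit failed: %s", conditionMessage(fit)))
  pars <- stats::setNames(op$par, par_names)
  fitted <- fn(pars, x)
  list(pars = pars,
       se = stats::setNames(rep(NA_real_, length(pars)), par_names),
       rss = op$value, fitted = fitted, converged = op$convergence == 0L)
}

.check_not_flat <- function(y) {
  if (diff(range(y)) <= 1e-8 * max(abs(y), 1))
    identifiability_error("series has no transition (flat signal)")
}

# x-coordinate where the observed signal crosses the half-range, by linear
# interpolation on the sorted series. Used for starting values only.
.half_crossing <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  half <- (max(y) + min(y)) / 2
  s <- sign(y - half)
  idx <- which(s[-1] * s[-length(s)] <= 0)
  if (length(idx) == 0L) return(stats::median(x))
  i <- idx[1L]
  if (y[i + 1L] == y[i]) return(x[i])
  x[i] + (half - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
}

#' Fit the probe dissociation constant (quadratic isotherm)
#'
#' Least-squares fit of [eq1_fluorescence()] to an RNA-into-probe titration:
#' `x` is the RNA concentration (nM) and the site concentration used in the
#' model is `psi = psi_multiplier * x`. Estimates `f0`, `fb` and `kd`.
#'
#' Starting values follow the data (f0 from max(y), fb from min(y), kd from
#' the half-signal crossing corrected for probe depletion), so no per-dataset
#' tuning is needed; the fit is deterministic given identical inputs.
#'
#' @param series A [titration_series()] (x = RNA concentration, nM).
#' @param psi_multiplier Integer number of probe sites per RNA molecule.
#' @param probe_total Total probe concentration, nM.
#' @return A `kd_fit`: `kd`, `f0`, `fb` (estimates), `se` (named standard
#'   errors), `rss`, `psi_multiplier`, `probe_total`, `fitted`, `converged`.
#' @export
fit_kd <- function(series, psi_multiplier = 1L, probe_total) {
  series <- .as_series(series)
  check_scalar_finite(probe_total, "probe_total")
  if (probe_total <= 0) validation_error("'probe_total' must be > 0")
  if (!is.numeric(psi_multiplier) || length(psi_multiplier) != 1L ||
      psi_multiplier < 1 || psi_multiplier != round(psi_multiplier))
    validation_error("'psi_multiplier' must be a positive integer")
  x <- series$x; y <- series$y
  if (length(x) < 4L) validation_error("need >= 4 titration points")
  if (any(x < 0)) validation_error("concentrations must be >= 0")
  .check_not_flat(y)

  psi <- psi_multiplier * x
  # At half-saturation of the probe, psi ~ probe/2 + kd (depletion-corrected).
  kd0 <- max(.half_crossing(psi, y) - probe_total / 2, 1e-3)
  start <- list(f0 = max(y), fb = min(y), kd = kd0)
  fn <- function(p, x) {
    m <- list(f0 = p[["f0"]], fb = p[["fb"]], kd = max(p[["kd"]], 1e-12),
              probe_total = probe_total)
    s <- x + probe_total + m$kd
    disc <- pmax(s^2 - 4 * x * probe_total, 0)
    m$f0 + (m$fb - m$f0) * (s - sqrt(disc)) / (2 * probe_total)
  }
  res <- .ls_fit(psi, y, fn, start,
                 lower = c(f0 = -Inf, fb = -Inf, kd = 1e-9))
  structure(list(
    kd = unname(res$pars[["kd"]]),
    f0 = unname(res$pars[["f0"]]),
    fb = unname(res$pars[["fb"]]),
    psi_multiplier = as.integer(psi_multiplier),
    probe_total = probe_total,
    se = res$se, rss = res$rss, fitted = res$fitted,
    converged = res$converged
  ), class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("K_D fit: kd = %.4g nM (se %.2g), f0 = %.4g, fb = %.4g, rss = %.4g, %d sites/RNA\n",
              x$kd, x$se[["kd"]], x$f0, x$fb, x$rss, x$psi_multiplier))
  invisible(x)
}

#' Estimate binding-site multiplicity from a saturation titration
#'
#' Fits the quadratic isotherm once per candidate site multiplicity
#' (`psi = n * [RNA]`) and selects the candidate with the smallest residual
#' sum of squares; ties break toward the smallest `n` (parsimony). If even the
#' best candidate leaves a large residual (R^2 < 0.995) the estimate carries a
#' `large_residual` flag — typically the generating multiplicity was outside
#' the candidate set.
#'
#' @param series A [titration_series()] (x = RNA concentration, nM).
#' @param probe_total Total probe concentration, nM.
#' @param candidates Integer candidate multiplicities (default `1:8`).
#' @return A `multiplicity_estimate`: `n_sites`, `fit` (the selected
#'   [fit_kd()] result), `table` (candidate / rss / converged), and
#'   `large_residual`.
#' @export
estimate_site_multiplicity <- function(series, probe_total, candidates = 1:8) {
  series <- .as_series(series)
  if (length(candidates) == 0L ||
      any(candidates < 1 | candidates != round(candidates)))
    validation_error("'candidates' must be positive integers")
  candidates <- sort(unique(as.integer(candidates)))
  fits <- lapply(candidates, function(n)
    tryCatch(fit_kd(series, n, probe_total), error = function(e) e))
  rss <- vapply(fits, function(f)
    if (inherits(f, "error")) NA_real_ else f$rss, numeric(1))
  if (all(is.na(rss)))
    fit_error("all candidate multiplicity fits failed")
  best <- min(rss, na.rm = TRUE)
  sel <- which(!is.na(rss) & rss <= best * (1 + 1e-9))[1L]
  tss <- sum((series$y - mean(series$y))^2)
  r2 <- if (tss > 0) 1 - rss[sel] / tss else NA_real_
  structure(list(
    n_sites = candidates[sel],
    fit = fits[[sel]],
    table = data.frame(n_sites = candidates, rss = rss,
                       converged = !vapply(fits, inherits, logical(1), "error")),
    large_residual = isTRUE(r2 < 0.995)
  ), class = "multiplicity_estimate")
}

#' @export
print.multiplicity_estimate <- function(x, ...) {
  cat(sprintf("Site multiplicity: n = %d (kd = %.4g nM)%s\n", x$n_sites,
              x$fit$kd, if (x$large_residual) " [large residual]" else ""))
  invisible(x)
}

#' Fit a single-proton pKa from a pH titration
#'
#' Least-squares fit of the two-state ionization model
#' `y = mono + (di - mono) / (1 + 10^(pka - pH))` to signal-vs-pH data. Works
#' for increasing or decreasing series (the asymptotes swap, the pKa does
#' not). The fitted pKa must lie inside the observed pH range; otherwise the
#' transition was not sampled and an identifiability error is raised.
#'
#' @param series A [titration_series()] with `x` = pH. The observed range must
#'   span at least 1.5 pH units.
#' @return A `pka_fit`: `pka`, `signal_mono`, `signal_di`, `se`, `rss`,
#'   `fitted`, `converged`.
#' @export
fit_pka <- function(series) {
  series <- .as_series(series)
  x <- series$x; y <- series$y
  if (length(x) < 4L) validation_error("need >= 4 titration points")
  if (diff(range(x)) < 1.5)
    validation_error("pH range must span >= 1.5 units")
  .check_not_flat(y)
  y_lo <- mean(y[x <= stats::quantile(x, 0.25)])
  y_hi <- mean(y[x >= stats::quantile(x, 0.75)])
  start <- list(pka = .half_crossing(x, y), mono = y_lo, di = y_hi)
  fn <- function(p, x)
    p[["mono"]] + (p[["di"]] - p[["mono"]]) / (1 + 10^(p[["pka"]] - x))
  res <- .ls_fit(x, y, fn, start,
                 lower = c(pka = -Inf, mono = -Inf, di = -Inf))
  pka <- unname(res$pars[["pka"]])
  if (pka < min(x) || pka > max(x))
    identifiability_error(sprintf(
      "fitted pKa (%.3g) outside the observed pH range [%.3g, %.3g]",
      pka, min(x), max(x)))
  structure(list(
    pka = pka,
    signal_mono = unname(res$pars[["mono"]]),
    signal_di = unname(res$pars[["di"]]),
    se = stats::setNames(res$se, c("pka", "signal_mono", "signal_di")),
    rss = res$rss, fitted = res$fitted, converged = res$converged
  ), class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("pKa fit: pKa = %.4g (se %.2g), mono = %.4g, di = %.4g, rss = %.4g\n",
              x$pka, x$se[["pka"]], x$signal_mono, x$signal_di, x$rss))
  invisible(x)
}

#' Fit an IC50 from a displacement titration
#'
#' Four-parameter logistic in log10 concentration:
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(IC50) - log10(x))))`.
#' The IC50 is the inflection of the sigmoid — the competitor concentration at
#' 50% displacement. The data must bracket the transition.
#'
#' @param series A [titration_series()] with `x` = competitor concentration
#'   (nM, > 0); at least 5 points over at least 4 distinct concentrations.
#' @return An `ic50_fit`: `ic50` (nM), `hill`, `top`, `bottom`, `se`, `rss`,
#'   `fitted`, `converged`.
#' @export
fit_ic50 <- function(series) {
  series <- .as_series(series)
  x <- series$x; y <- series$y
  if (length(x) < 5L) validation_error("need >= 5 titration points")
  if (length(unique(x)) < 4L)
    identifiability_error("need >= 4 distinct concentrations")
  if (any(x <= 0)) validation_error("concentrations must be > 0 (log scale)")
  .check_not_flat(y)
  lx <- log10(x)
  half <- (max(y) + min(y)) / 2
  if (!any(y < half) || !any(y > half))
    identifiability_error("data do not bracket the transition midpoint")
  start <- list(logi = .half_crossing(lx, y), hill = 1,
                top = max(y), bottom = min(y))
  fn <- function(p, lx)
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + 10^(p[["hill"]] * (p[["logi"]] - lx)))
  res <- .ls_fit(lx, y, fn, start,
                 lower = c(logi = -Inf, hill = -Inf, top = -Inf, bottom = -Inf))
  logi <- unname(res$pars[["logi"]])
  if (logi < min(lx) - 2 || logi > max(lx) + 2)
    identifiability_error("fitted IC50 far outside the titrated range")
  # the data must traverse most of the fitted window, else the transition was
  # extrapolated rather than observed
  window <- abs(res$pars[["top"]] - res$pars[["bottom"]])
  if (is.finite(window) && window > 0 && diff(range(y)) < 0.5 * window)
    identifiability_error("data do not bracket the transition (observed signal span covers < 50% of the fitted window)")
  structure(list(
    ic50 = 10^logi,
    hill = unname(res$pars[["hill"]]),
    top = unname(res$pars[["top"]]),
    bottom = unname(res$pars[["bottom"]]),
    se = stats::setNames(res$se, c("log10_ic50", "hill", "top", "bottom")),
    rss = res$rss, fitted = res$fitted, converged = res$converged
  ), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 fit: IC50 = %.4g nM, hill = %.3g, top = %.4g, bottom = %.4g, rss = %.4g\n",
              x$ic50, x$hill, x$top, x$bottom, x$rss))
  invisible(x)
}
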