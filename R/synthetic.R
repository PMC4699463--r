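# Seeded generators for every input the pipeline consumes: probe titrations,
# displacement titrations, pH titrations, and full multi-plate screens driven
# by a ground-truth positional-effect library. The zero-noise output of every
# generator is exactly the corresponding closed-form/solver model, so the
# generators double as oracles for the fitting layer.

#' Assay condition
#'
#' The fixed concentrations of one screening configuration. Presets carry the
#' four published configurations (see [assay_preset()]).
#'
#' @param probe_total Total probe concentration, nM.
#' @param rna_total Total RNA concentration, nM.
#' @param compound_conc Single-point screening concentration of each compound,
#'   nM.
#' @param n_sites_per_rna Integer probe sites per RNA molecule.
#' @param kd_probe Probe dissociation constant, nM.
#' @return An `assay_condition`.
#' @export
assay_condition <- function(probe_total, rna_total, compound_conc,
                            n_sites_per_rna, kd_probe) {
  for (nm in c("probe_total", "rna_total", "compound_conc", "kd_probe")) {
    v <- get(nm)
    check_scalar_finite(v, nm)
    if (v <= 0) validation_error(sprintf("'%s' must be > 0", nm))
  }
  if (!is.numeric(n_sites_per_rna) || length(n_sites_per_rna) != 1L ||
      n_sites_per_rna < 1 || n_sites_per_rna != round(n_sites_per_rna))
    validation_error("'n_sites_per_rna' must be a positive integer")
  structure(list(probe_total = probe_total, rna_total = rna_total,
                 compound_conc = compound_conc,
                 n_sites_per_rna = as.integer(n_sites_per_rna),
                 kd_probe = kd_probe),
            class = "assay_condition")
}

#' Published assay presets
#'
#' The four screening configurations: mature hsa-miR 504 (100 nM probe,
#' 50 nM RNA, 300 nM compound, 2 sites, probe K_D 1.5 nM), pre-hsa-miR 504
#' (100 / 16.7 / 300, 6 sites, 0.5 nM), hsa-miR 142 (100 / 100 / 500, 1 site,
#' 2.0 nM) and hsa-miR 335 (100 / 100 / 500, 1 site, 2.2 nM). Each preset
#' also carries the neomycin IC50 (nM) measured under that configuration
#' (`ic50_neomycin`) and a default titration grid for the competitor
#' (`titration_concs`) and the RNA (`rna_concs`).
#'
#' @param name One of `"mir504"`, `"premir504"`, `"mir142"`, `"mir335"`
#'   (hyphen/case-insensitive variants accepted).
#' @return An `assay_condition` with extra fields `preset`, `ic50_neomycin`,
#'   `rna_concs`, `titration_concs`.
#' @export
assay_preset <- function(name) {
  key <- gsub("[^a-z0-9]", "", tolower(name))
  specs <- list(
    mir504    = list(c(100, 50, 300, 2, 1.5), 70.3,
                     seq(10, 150, length.out = 15L)),
    premir504 = list(c(100, 16.7, 300, 6, 0.5), 56.2,
                     seq(5, 80, length.out = 16L)),
    mir142    = list(c(100, 100, 500, 1, 2.0),  95.7,
                     10^seq(log10(0.5), 3, length.out = 24L)),
    mir335    = list(c(100, 100, 500, 1, 2.2), 117.4,
                     10^seq(log10(0.5), 3, length.out = 24L))
  )
  key <- switch(key, prehsamir504 = "premir504", premir504 = "premir504",
                hsamir504 = "mir504", hsamir142 = "mir142",
                hsamir335 = "mir335", key)
  if (!key %in% names(specs))
    validation_error(sprintf("unknown preset '%s'; expected one of %s", name,
                             paste(names(specs), collapse = ", ")))
  v <- specs[[key]][[1L]]
  cond <- assay_condition(v[1L], v[2L], v[3L], v[4L], v[5L])
  cond$preset <- key
  cond$ic50_neomycin <- specs[[key]][[2L]]
  cond$rna_concs <- specs[[key]][[3L]]
  cond$titration_concs <- 10^seq(0, 3.2, length.out = 16L)
  cond
}

#' Well-noise model
#'
#' Multiplicative Gaussian noise per well: observed = expected * N(1, cv).
#' Plate-position effects (edge, drift) are deliberately not modelled.
#'
#' @param cv Coefficient of variation of well signals (default 0.02).
#' @param seed Optional integer seed for reproducibility (`NULL` uses the
#'   ambient RNG stream).
#' @return A `noise_model`.
#' @export
noise_model <- function(cv = 0.02, seed = NULL) {
  check_scalar_finite(cv, "cv")
  if (cv < 0) validation_error("'cv' must be >= 0")
  structure(list(cv = cv, seed = seed), class = "noise_model")
}

.apply_noise <- function(mu, noise) {
  if (!inherits(noise, "noise_model"))
    validation_error("'noise' must be a noise_model")
  if (noise$cv == 0) return(mu)
  with_seed(noise$seed, mu * stats::rnorm(length(mu), mean = 1, sd = noise$cv))
}

#' Simulate a probe saturation titration
#'
#' RNA titrated into the probe: expected signals from [eq1_fluorescence()] at
#' `psi = n_sites * conc`, multiplied by per-well Gaussian noise factors.
#'
#' @param model A [quadratic_binding_model()].
#' @param rna_concs RNA concentrations, nM (>= 0).
#' @param n_sites Probe sites per RNA molecule.
#' @param noise A [noise_model()].
#' @return A [titration_series()] (x = RNA concentration).
#' @export
simulate_fneo_titration <- function(model, rna_concs, n_sites = 1L,
                                    noise = noise_model()) {
  check_numeric_finite(rna_concs, "rna_concs")
  if (any(rna_concs < 0)) validation_error("'rna_concs' must be >= 0")
  mu <- eq1_fluorescence(model, n_sites * rna_concs)
  titration_series(rna_concs, .apply_noise(mu, noise),
                   meta = list(label = "F-neo saturation titration",
                               n_sites = n_sites,
                               probe_total = model$probe_total))
}

#' Simulate a displacement titration
#'
#' Competitor titrated into the pre-formed probe:RNA complex. Expected signal
#' at each concentration is `f0 + (fb - f0) * bound_probe / probe_total` with
#' `bound_probe` from [solve_competitive_equilibrium()].
#'
#' @param cond An [assay_condition()].
#' @param kd_competitor Competitor dissociation constant, nM (`Inf` = inert).
#' @param competitor_concs Competitor concentrations, nM (>= 0).
#' @param f0,fb Free/bound probe fluorescence (defaults 1000 / 250 AU).
#' @param noise A [noise_model()].
#' @return A [titration_series()] (x = competitor concentration).
#' @export
simulate_displacement_titration <- function(cond, kd_competitor,
                                            competitor_concs,
                                            f0 = 1000, fb = 250,
                                            noise = noise_model()) {
  if (!inherits(cond, "assay_condition"))
    validation_error("'cond' must be an assay_condition")
  check_numeric_finite(competitor_concs, "competitor_concs")
  if (any(competitor_concs < 0))
    validation_error("'competitor_concs' must be >= 0")
  eq <- solve_competitive_equilibrium(
    site_total = cond$n_sites_per_rna * cond$rna_total,
    probe_total = cond$probe_total,
    kd_probe = cond$kd_probe,
    competitor_total = competitor_concs,
    kd_competitor = kd_competitor)
  mu <- f0 + (fb - f0) * eq$bound_probe / cond$probe_total
  titration_series(competitor_concs, .apply_noise(mu, noise),
                   meta = list(label = "displacement titration",
                               kd_competitor = kd_competitor))
}

#' Simulate a pH titration of the probe
#'
#' @param pka True apparent pKa.
#' @param signal_mono,signal_di Monoanion/dianion signals.
#' @param ph_grid pH values.
#' @param noise A [noise_model()].
#' @return A [titration_series()] (x = pH).
#' @export
simulate_ph_titration <- function(pka, signal_mono, signal_di, ph_grid,
                                  noise = noise_model()) {
  model <- protonation_model(pka, signal_mono, signal_di)
  check_numeric_finite(ph_grid, "ph_grid")
  mu <- protonation_signal(model, ph_grid)$signal
  titration_series(ph_grid, .apply_noise(mu, noise),
                   meta = list(label = "pH titration", pka = pka))
}

#' Calibrate a competitor K_D from a target IC50
#'
#' The competitor affinities behind published IC50s are not stated, so
#' simulations anchor them to the IC50: this solves (on log10 K_D) for the
#' competitor dissociation constant whose *noiseless* displacement curve under
#' `cond` crosses 50% of the zero-competitor bound probe exactly at
#' `ic50` nM.
#'
#' @param cond An [assay_condition()].
#' @param ic50 Target IC50, nM (> 0).
#' @return Competitor K_D in nM.
#' @export
calibrate_competitor_kd <- function(cond, ic50) {
  if (!inherits(cond, "assay_condition"))
    validation_error("'cond' must be an assay_condition")
  check_scalar_finite(ic50, "ic50")
  if (ic50 <= 0) validation_error("'ic50' must be > 0")
  site_total <- cond$n_sites_per_rna * cond$rna_total
  b0 <- solve_competitive_equilibrium(site_total, cond$probe_total,
                                      cond$kd_probe)$bound_probe
  fr <- function(log_kd) {
    b <- solve_competitive_equilibrium(site_total, cond$probe_total,
                                       cond$kd_probe, ic50,
                                       10^log_kd)$bound_probe
    b / b0 - 0.5
  }
  # bound fraction at the IC50 increases with kd (weaker competitor). If even
  # an infinitely tight competitor cannot halve the bound probe at this
  # concentration, the target is below the stoichiometric floor of the
  # one-site competitive model (possible when site and probe totals are
  # comparable and the IC50 is close to them).
  if (fr(-6) > 0)
    domain_error(sprintf(
      "target IC50 (%g nM) is below the stoichiometric floor of this assay condition: no competitor K_D can reach it",
      ic50))
  root <- stats::uniroot(fr, lower = -6, upper = 8, tol = 1e-12)
  10^root$root
}

#' Default positional effect tables
#'
#' Additive shifts of log10(K_D) for the conjugated amino acid at each
#' position. Signs follow the published preference directions: arginine at
#' position 1 stabilizes (alpha < 0), aspartate destabilizes at either
#' position, tryptophan destabilizes, serine at position 2 stabilizes; most
#' conjugations carry a net steric penalty, so the library as a whole binds
#' more weakly than the parent.
#'
#' Magnitudes are chosen once so that a simulated single-point screen under
#' the mature hsa-miR 504 preset lands in the published regime (library mean
#' percent binding in the low 70s with a spread of roughly 20 percentage
#' points, and the weakest aspartate conjugates nearly inactive).
#'
#' @return A list with named numeric vectors `alpha` (position 1, 15 codes)
#'   and `beta` (position 2, 14 amino acids + `"bA"` beta-alanine).
#' @export
default_positional_effects <- function() {
  list(
    alpha = c(A = 0.54, R = -0.30, N = 0.45, D = 1.35, C = 0.60, H = 0.24,
              L = 0.54, K = 0.06, F = 0.66, P = 0.75, S = 0.36, T = 0.42,
              W = 0.90, Y = 0.48, V = 0.54),
    beta = c(S = -0.54, T = -0.36, Y = -0.24, V = -0.15, D = 1.20, W = 0.66,
             bA = 0.30, H = 0.18, R = -0.06, L = 0.36, F = 0.30, C = 0.45,
             A = 0.15, N = 0.06)
  )
}

#' Default 215-compound conjugate roster
#'
#' 15 mono-conjugates (14 variable amino acids plus lysine); di-conjugates
#' with position 2 in S, T, Y, V over all 15 position-1 codes (60) and
#' position 2 in D, W, beta-alanine, H, R, L, F, C, A, N over the 14 codes
#' without lysine (140).
#'
#' @return Character vector of 215 compound names (beta-alanine as `"bA"`).
#' @export
default_roster <- function() {
  aa14 <- setdiff(.AA_CODES, "K")
  mono <- paste0("Neo", .AA_CODES)
  di_k <- as.vector(outer(.AA_CODES, c("S", "T", "Y", "V"), paste0))
  di_nok <- as.vector(outer(aa14, c("D", "W", "bA", "H", "R", "L", "F", "C",
                                    "A", "N"), paste0))
  c(mono, paste0("Neo", di_k), paste0("Neo", di_nok))
}

#' Generate a ground-truth compound library
#'
#' Draws a deterministic table of true dissociation constants:
#' `log10(kd) = log10(kd_neo) + alpha(pos1) + beta(pos2) + eps`,
#' `eps ~ N(0, noise_sd)`, seeded. Mono-conjugates take no beta term.
#'
#' @param kd_neo Neomycin (parent) dissociation constant under the assay
#'   condition, nM.
#' @param effects Positional effect tables ([default_positional_effects()]).
#' @param roster Compound names ([default_roster()]).
#' @param noise_sd SD of the idiosyncratic log10(K_D) term (default 0.15).
#' @param seed Integer seed.
#' @return A `library_truth` data frame: `compound`, `pos1`, `pos2`,
#'   `log10_kd`, `kd`; attributes `kd_neo`, `effects`, `seed`.
#' @export
generate_ground_truth_library <- function(kd_neo,
                                          effects = default_positional_effects(),
                                          roster = default_roster(),
                                          noise_sd = 0.15, seed = 1L) {
  check_scalar_finite(kd_neo, "kd_neo")
  if (kd_neo <= 0) validation_error("'kd_neo' must be > 0")
  check_scalar_finite(noise_sd, "noise_sd")
  if (noise_sd < 0) validation_error("'noise_sd' must be >= 0")
  if (length(roster) == 0L) validation_error("'roster' must be non-empty")
  parsed <- lapply(roster, parse_compound_name)
  pos1 <- vapply(parsed, `[[`, character(1), "pos1")
  pos2 <- vapply(parsed, `[[`, character(1), "pos2")
  lookup <- function(tab, code, pos) {
    if (is.na(code)) return(0)
    if (!code %in% names(tab))
      validation_error(sprintf("no %s effect defined for code '%s'", pos, code))
    tab[[code]]
  }
  a <- vapply(pos1, lookup, numeric(1), tab = effects$alpha, pos = "position-1")
  b <- vapply(pos2, lookup, numeric(1), tab = effects$beta, pos = "position-2")
  eps <- with_seed(seed, stats::rnorm(length(roster), 0, noise_sd))
  lk <- log10(kd_neo) + a + b + eps
  out <- data.frame(compound = roster, pos1 = pos1, pos2 = pos2,
                    log10_kd = lk, kd = 10^lk, stringsAsFactors = FALSE)
  attr(out, "kd_neo") <- kd_neo
  attr(out, "effects") <- effects
  attr(out, "seed") <- seed
  class(out) <- c("library_truth", "data.frame")
  out
}

#' Simulate a multi-plate single-point screen
#'
#' Lays the ground-truth library out on 96-well plates and generates well
#' fluorescence through the competitive solver. Each plate carries two
#' probe-only wells, two negative (probe + RNA) wells and two positive
#' (probe + RNA + neomycin) wells; the remaining 90 wells hold compounds at
#' `cond$compound_conc` in `duplicates` adjacent wells each.
#'
#' @param truth A `library_truth` from [generate_ground_truth_library()].
#' @param cond An [assay_condition()].
#' @param noise A [noise_model()]; its seed makes the whole plate set
#'   reproducible.
#' @param f0,fb Free/bound probe fluorescence (defaults 1000 / 250 AU).
#' @param duplicates Replicate wells per compound (default 2).
#' @return A [plate_set()].
#' @export
simulate_screen_plates <- function(truth, cond, noise = noise_model(),
                                   f0 = 1000, fb = 250, duplicates = 2L) {
  if (!inherits(truth, "library_truth"))
    validation_error("'truth' must come from generate_ground_truth_library()")
  if (!inherits(cond, "assay_condition"))
    validation_error("'cond' must be an assay_condition")
  if (duplicates < 1 || duplicates != round(duplicates))
    validation_error("'duplicates' must be a positive integer")
  duplicates <- as.integer(duplicates)
  site_total <- cond$n_sites_per_rna * cond$rna_total
  kd_neo <- attr(truth, "kd_neo")
  signal_of <- function(comp_total, kd_comp) {
    b <- solve_competitive_equilibrium(site_total, cond$probe_total,
                                       cond$kd_probe, comp_total,
                                       kd_comp)$bound_probe
    f0 + (fb - f0) * b / cond$probe_total
  }
  wells_96 <- paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, times = 8L))
  n_control <- 6L
  per_plate <- (96L - n_control) %/% duplicates

  rows <- list()
  idx <- seq_len(nrow(truth))
  plate_no <- 0L
  while (length(idx) > 0L) {
    plate_no <- plate_no + 1L
    take <- idx[seq_len(min(per_plate, length(idx)))]
    idx <- setdiff(idx, take)
    role <- c("probe_only", "probe_only", "negative", "negative",
              "positive", "positive",
              rep("compound", duplicates * length(take)))
    compound <- c(rep("", 4L), rep("Neomycin", 2L),
                  rep(truth$compound[take], each = duplicates))
    mu <- c(rep(f0, 2L),
            rep(signal_of(0, Inf), 2L),
            rep(signal_of(cond$compound_conc, kd_neo), 2L),
            rep(signal_of(cond$compound_conc, truth$kd[take]),
                each = duplicates))
    rows[[plate_no]] <- data.frame(
      plate_id = sprintf("plate%02d", plate_no),
      well = wells_96[seq_along(role)],
      role = role, compound = compound, signal = mu,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$signal <- .apply_noise(df$signal, noise)
  df$signal <- pmax(df$signal, 0)
  plate_set(df)
}
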