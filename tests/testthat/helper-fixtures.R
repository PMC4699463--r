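# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# A toy single plate with known control and compound signals.
toy_plate <- function(baseline = c(200, 202), neomycin = c(400, 402),
                      compounds = list(NeoRS = c(350, 360)),
                      plate_id = "p1", probe_only = c(990, 1010)) {
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  sig <- c(probe_only, baseline, neomycin, unlist(compounds, use.names = FALSE))
  role <- c(rep("probe_only", length(probe_only)),
            rep("negative", length(baseline)),
            rep("positive", length(neomycin)),
            rep("compound", length(unlist(compounds))))
  comp <- c(rep("", length(probe_only) + length(baseline) + length(neomycin)),
            rep(names(compounds), vapply(compounds, length, integer(1))))
  plate_set(data.frame(plate_id = plate_id, well = wells[seq_along(sig)],
                       role = role, compound = comp, signal = sig,
                       stringsAsFactors = FALSE))
}

# A 48+48 control plate under an assay condition, for Z'-factor properties.
# Noise uses one seed so different cv values share the same standard-normal
# draws (common random numbers).
control_plate <- function(cond, kd_neo, cv, seed, f0 = 1000, fb = 250,
                          n_each = 48L) {
  site_total <- cond$n_sites_per_rna * cond$rna_total
  sig <- function(comp, kd) {
    b <- solve_competitive_equilibrium(site_total, cond$probe_total,
                                       cond$kd_probe, comp, kd)$bound_probe
    f0 + (fb - f0) * b / cond$probe_total
  }
  mu <- c(rep(sig(cond$compound_conc, kd_neo), n_each), rep(sig(0, Inf), n_each))
  noisy <- fneoscreen:::with_seed(seed,
    mu * (1 + cv * stats::rnorm(length(mu))))
  list(positive = noisy[seq_len(n_each)],
       negative = noisy[n_each + seq_len(n_each)])
}

# Noiseless saturation titration from known truth.
make_kd_series <- function(f0 = 1000, fb = 250, kd = 1.5, probe = 100,
                           n_sites = 1, concs = 10^seq(log10(0.5), 3,
                                                       length.out = 24),
                           cv = 0, seed = NULL) {
  m <- quadratic_binding_model(f0, fb, kd, probe)
  simulate_fneo_titration(m, concs, n_sites, noise_model(cv, seed))
}
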