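# Synthetic-data generators and the dot-bracket bulge counter.

test_that("generators are exact at zero noise and bit-reproducible", {
  m <- quadratic_binding_model(1000, 250, 1.5, 100)
  concs <- seq(10, 150, length.out = 15)
  s0 <- simulate_fneo_titration(m, concs, 2, noise_model(0))
  expect_identical(s0$y, eq1_fluorescence(m, 2 * concs))

  s1 <- simulate_fneo_titration(m, concs, 2, noise_model(0.02, seed = 33))
  s2 <- simulate_fneo_titration(m, concs, 2, noise_model(0.02, seed = 33))
  expect_identical(s1$y, s2$y)
  expect_false(identical(s1$y, s0$y))

  cond <- assay_preset("mir504")
  d0 <- simulate_displacement_titration(cond, 0.4, c(0, 10, 100),
                                        noise = noise_model(0))
  b <- solve_competitive_equilibrium(100, 100, 1.5, c(0, 10, 100), 0.4)
  expect_identical(d0$y, 1000 + (250 - 1000) * b$bound_probe / 100)

  p0 <- simulate_ph_titration(6.37, 0.1, 1, seq(4.5, 9, 0.25), noise_model(0))
  expect_identical(p0$y,
                   protonation_signal(protonation_model(6.37, 0.1, 1),
                                      seq(4.5, 9, 0.25))$signal)
  # midpoint hits the mean of the asymptotes
  expect_equal(simulate_ph_titration(6.37, 0.1, 1, 6.37, noise_model(0))$y,
               0.55)
})

test_that("noisy replicate means converge on the noiseless curve", {
  m <- quadratic_binding_model(1000, 250, 1.5, 100)
  concs <- c(10, 50, 100, 150)
  mu <- eq1_fluorescence(m, 2 * concs)
  seeds <- fneoscreen:::derive_seeds(88, 1000)
  ys <- vapply(seeds, function(sd)
    simulate_fneo_titration(m, concs, 2, noise_model(0.02, sd))$y,
    numeric(length(concs)))
  se <- apply(ys, 1, sd) / sqrt(ncol(ys))
  expect_true(all(abs(rowMeans(ys) - mu) < 3 * se + 1e-9))
})

test_that("displacement series behave physically", {
  cond <- assay_preset("mir142")
  flat0 <- simulate_displacement_titration(cond, 50, rep(0, 6),
                                           noise = noise_model(0))
  expect_equal(diff(range(flat0$y)), 0)
  inert <- simulate_displacement_titration(cond, Inf, 10^(0:5),
                                           noise = noise_model(0))
  expect_equal(inert$y, rep(flat0$y[1], 6), tolerance = 1e-9)

  # fitted IC50 of noiseless curves is monotone in the competitor kd
  kds <- 10^seq(-1, 2, length.out = 7)
  ic <- vapply(kds, function(kd) {
    s <- simulate_displacement_titration(cond, kd,
                                         10^seq(-1, 4.2, length.out = 18),
                                         noise = noise_model(0))
    fit_ic50(s)$ic50
  }, numeric(1))
  expect_true(all(diff(ic) > 0))
})

test_that("calibrated competitor kd reproduces its target IC50 midpoint", {
  for (preset in c("mir142", "mir335", "mir504", "premir504")) {
    cond <- assay_preset(preset)
    kd <- calibrate_competitor_kd(cond, cond$ic50_neomycin)
    site <- cond$n_sites_per_rna * cond$rna_total
    b0 <- solve_competitive_equilibrium(site, cond$probe_total,
                                        cond$kd_probe)$bound_probe
    b_half <- solve_competitive_equilibrium(site, cond$probe_total,
                                            cond$kd_probe,
                                            cond$ic50_neomycin, kd)$bound_probe
    expect_equal(b_half / b0, 0.5, tolerance = 1e-8)
  }
})

test_that("ground-truth library honors roster, seed and effect tables", {
  truth <- generate_ground_truth_library(0.34, seed = 5)
  expect_identical(nrow(truth), 215L)
  expect_identical(truth$kd,
                   generate_ground_truth_library(0.34, seed = 5)$kd)
  expect_false(identical(truth$kd,
                         generate_ground_truth_library(0.34, seed = 6)$kd))

  zero <- list(alpha = sapply(fneoscreen:::.AA_CODES, function(x) 0),
               beta = sapply(c(fneoscreen:::.AA_CODES, "bA"), function(x) 0))
  flat <- generate_ground_truth_library(0.34, effects = zero, noise_sd = 0)
  expect_equal(flat$kd, rep(0.34, 215))

  # default effect signs follow the published preference directions
  eff <- default_positional_effects()
  expect_lt(eff$alpha[["R"]], 0)
  expect_gt(eff$alpha[["D"]], 0)
  expect_lt(eff$beta[["S"]], 0)
  expect_gt(eff$beta[["D"]], 0)
  expect_gt(eff$beta[["W"]], 0)

  expect_error(generate_ground_truth_library(0.34, roster = "NeoQQ"),
               class = "fneo_parse_error")
  expect_error(
    generate_ground_truth_library(
      0.34, effects = list(alpha = c(R = -0.1), beta = c(S = -0.1)),
      roster = c("NeoR", "NeoRS", "NeoA")),
    "A", class = "fneo_validation_error")
})

test_that("simulated plates satisfy the layout contract", {
  cond <- assay_preset("mir504")
  truth <- generate_ground_truth_library(0.34, seed = 2)
  plates <- simulate_screen_plates(truth, cond, noise_model(0.02, seed = 3))
  for (pid in unique(plates$plate_id)) {
    pl <- plates[plates$plate_id == pid, ]
    expect_gte(sum(pl$role == "positive"), 2L)
    expect_gte(sum(pl$role == "negative"), 2L)
    expect_lte(nrow(pl), 96L)
  }
  counts <- table(plates$compound[plates$role == "compound"])
  expect_true(all(counts == 2L))
  expect_identical(length(counts), 215L)
})

test_that("a compound as potent as neomycin reads out 100% without noise", {
  cond <- assay_preset("mir504")
  truth <- generate_ground_truth_library(
    0.34, effects = list(alpha = sapply(fneoscreen:::.AA_CODES, function(x) 0),
                         beta = sapply(c(fneoscreen:::.AA_CODES, "bA"),
                                       function(x) 0)),
    noise_sd = 0, seed = 1)
  tab <- summarize_screen(simulate_screen_plates(truth, cond, noise_model(0)))
  expect_equal(tab$percent_binding, rep(100, nrow(tab)), tolerance = 1e-6)
})

test_that("screens at the published conditions clear Z' > 0.5 at 2% CV", {
  for (preset in c("mir142", "mir335", "mir504", "premir504")) {
    cond <- assay_preset(preset)
    kd_neo <- calibrate_competitor_kd(cond, cond$ic50_neomycin)
    cp <- control_plate(cond, kd_neo, cv = 0.02, seed = 500 + cond$n_sites_per_rna)
    expect_gt(zfactor(cp$positive, cp$negative)$z, 0.5)
  }
})

test_that("ledger sign recovery holds on simulated screens (quick check)", {
  cond <- assay_preset("mir504")
  kd_neo <- calibrate_competitor_kd(cond, cond$ic50_neomycin)
  seeds <- fneoscreen:::derive_seeds(1234, 10)
  ok <- vapply(seeds, function(sd) {
    truth <- generate_ground_truth_library(kd_neo, seed = sd)
    plates <- simulate_screen_plates(truth, cond,
                                     noise_model(0.02, seed = sd + 1L))
    sc <- library_zscores(summarize_screen(plates), "mir504")
    sgn <- function(cs) sign(class_average(sc, cs)$mean_sigma)
    all(sgn("NeoRX") > 0, sgn("NeoXS") > 0,
        sgn("NeoDX") < 0, sgn("NeoXD") < 0, sgn("NeoXW") < 0)
  }, logical(1))
  expect_true(all(ok))
})

test_that("bulge counting matches manual enumeration", {
  expect_identical(count_bulge_regions("((((....))))"), 0L)
  expect_identical(count_bulge_regions("(((.(((....))).)))"), 1L)
  expect_identical(count_bulge_regions("((((((....)).))))"), 1L)  # 3' bulge
  # two separated internal loops (each two-sided loop counts once)
  expect_identical(count_bulge_regions("((.((.((...))..)).))"), 2L)
  # multibranch spacer counts once; hairpins don't
  expect_identical(count_bulge_regions("((..((...))((...))..))"), 1L)
  # duplex: dangling ends and the strand break are not bulges
  expect_identical(count_bulge_regions("..((((&)))).."), 0L)
  expect_identical(count_bulge_regions("((((.(((&))).))))"), 1L)
  expect_identical(count_bulge_regions(""), 0L)
})

test_that("bulge counting rejects malformed structures with a position", {
  expect_error(count_bulge_regions("((..)"), "position 1",
               class = "fneo_parse_error")
  expect_error(count_bulge_regions("(..))"), "position 5",
               class = "fneo_parse_error")
  expect_error(count_bulge_regions("((a))"), "position 3",
               class = "fneo_parse_error")
})

test_that("synthetic supplementary tables are pinned to published summaries", {
  for (id in c("mir142", "mir504")) {
    tab <- synthetic_supplementary_table(id, seed = 9)
    expect_true(isTRUE(attr(tab, "synthetic")))
    sc <- library_zscores(tab, id)
    anch <- attr(tab, "anchors")
    expect_equal(attr(sc, "library_mean"), anch$mean, tolerance = 1e-9)
    expect_equal(attr(sc, "library_sd"), anch$sd, tolerance = 1e-9)
  }
  expect_error(synthetic_supplementary_table("mir9000"),
               class = "fneo_validation_error")
})
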