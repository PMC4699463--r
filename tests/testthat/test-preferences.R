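# Compound-name grammar and the sigma-preference ledger.

test_that("compound names parse and round-trip", {
  cn <- parse_compound_name("NeoRS")
  expect_identical(cn$pos1, "R")
  expect_identical(cn$pos2, "S")

  cn1 <- parse_compound_name("NeoR")
  expect_identical(cn1$pos1, "R")
  expect_true(is.na(cn1$pos2))

  # beta-alanine is one token, in either spelling
  for (nm in c("NeoRβA", "NeoRbA")) {
    cn2 <- parse_compound_name(nm)
    expect_identical(cn2$pos1, "R")
    expect_identical(cn2$pos2, "bA")
  }
  expect_identical(format(parse_compound_name("NeoRβA"), ascii = FALSE),
                   "NeoRβA")
  expect_identical(format(parse_compound_name("NeobAS")), "NeobAS")

  parent <- parse_compound_name("Neomycin")
  expect_true(is.na(parent$pos1) && is.na(parent$pos2))
  expect_identical(format(parent), "Neomycin")

  for (nm in c("NeoAS", "NeoVP", "NeoHD", "NeoK", "NeoβAβA"))
    expect_identical(format(parse_compound_name(nm), ascii = FALSE), nm)
})

test_that("bad compound names fail with the offending token named", {
  expect_error(parse_compound_name("NeoZ"), "Z", class = "fneo_parse_error")
  expect_error(parse_compound_name("Xyz"), class = "fneo_parse_error")
  expect_error(parse_compound_name("NeoRST"), class = "fneo_parse_error")
  expect_error(parse_compound_name(""), class = "fneo_parse_error")
})

test_that("library z-scores match hand arithmetic and exclude neomycin", {
  tab <- data.frame(compound = c("NeoA", "NeoR", "NeoN", "NeoD", "Neomycin"),
                    percent_binding = c(100, 80, 60, 40, 100))
  sc <- library_zscores(tab, "m1")
  expect_false("Neomycin" %in% sc$compound)
  expect_equal(sc$sigma_dev, c(1.162, 0.387, -0.387, -1.162), tolerance = 1e-3)
  expect_equal(attr(sc, "library_mean"), 70)
  expect_equal(attr(sc, "library_sd"), sqrt(2000 / 3))

  # sigma ledger is standardized: mean 0, sd 1
  expect_equal(mean(sc$sigma_dev), 0, tolerance = 1e-9)
  expect_equal(sd(sc$sigma_dev), 1, tolerance = 1e-9)
})

test_that("degenerate libraries warn and zero out", {
  tab <- data.frame(compound = c("NeoA", "NeoR", "NeoN"),
                    percent_binding = c(50, 50, 50))
  expect_warning(sc <- library_zscores(tab, "m1"), "degenerate")
  expect_identical(sc$sigma_dev, c(0, 0, 0))
  expect_error(library_zscores(tab[1:2, ], "m1"),
               class = "fneo_validation_error")
})

test_that("standardization holds over random libraries", {
  set.seed(77)
  for (i in 1:10) {
    roster <- sample(default_roster(), 40)
    tab <- data.frame(compound = roster,
                      percent_binding = rnorm(40, 70, 20))
    sc <- library_zscores(tab, "mX")
    expect_equal(mean(sc$sigma_dev), 0, tolerance = 1e-9)
    expect_equal(sd(sc$sigma_dev), 1, tolerance = 1e-9)
  }
})

test_that("class averages aggregate the right members", {
  tab <- data.frame(compound = c("NeoA", "NeoR", "NeoN", "NeoD"),
                    percent_binding = c(100, 80, 60, 40))
  sc <- library_zscores(tab, "m1")
  expect_equal(class_average(sc, "NeoR")$mean_sigma, sc$sigma_dev[2])
  # mean of the first two compounds' sigmas
  ca <- class_average(sc, "NeoX")
  expect_identical(ca$n_members, 4L)
  first_two <- mean(sc$sigma_dev[1:2])
  expect_equal(first_two, 0.775, tolerance = 1e-3)
  expect_error(class_average(sc, "NeoXS"), "NeoXS",
               class = "fneo_validation_error")
})

test_that("positional X matches 'any or no amino acid' at position 2", {
  tab <- data.frame(compound = c("NeoR", "NeoRS", "NeoRD", "NeoAS", "NeoA"),
                    percent_binding = c(90, 120, 40, 80, 70))
  sc <- library_zscores(tab, "m1")
  rx <- class_average(sc, "NeoRX")
  expect_setequal(rx$members, c("NeoR", "NeoRS", "NeoRD"))
  xs <- class_average(sc, "NeoXS")
  expect_setequal(xs$members, c("NeoRS", "NeoAS"))
  mono <- class_average(sc, "NeoX")
  expect_setequal(mono$members, c("NeoR", "NeoA"))
})

test_that("size-weighted disjoint pos1 classes reconstruct the library mean", {
  tab <- synthetic_supplementary_table("mir142", seed = 11)
  sc <- library_zscores(tab, "mir142")
  specs <- paste0("Neo", c("A", "R", "N", "D", "C", "H", "L", "K", "F", "P",
                           "S", "T", "W", "Y", "V"), "X")
  cas <- lapply(specs, class_average, scores = sc)
  w <- vapply(cas, `[[`, integer(1), "n_members")
  m <- vapply(cas, `[[`, numeric(1), "mean_sigma")
  expect_equal(sum(w), nrow(sc))
  expect_equal(sum(w * m) / sum(w), 0, tolerance = 1e-9)
})

test_that("specificity deltas are antisymmetric and match the ledger", {
  mk <- function(sig) {
    out <- data.frame(compound = c("NeoHS", "NeoA", "NeoR"),
                      mirna_id = "x", percent_binding = 0,
                      sigma_dev = c(sig, -0.1, 0.2))
    class(out) <- c("preference_scores", "data.frame")
    out
  }
  sets <- list(mir504 = mk(0.24), mir142 = mk(0.15))
  d <- specificity_delta(sets, "NeoHS")
  expect_equal(d["mir504", "mir142"], 0.09, tolerance = 1e-12)
  expect_equal(d, -t(d))
  expect_identical(specificity_delta(list(a = mk(0.5), b = mk(0.5)),
                                     "NeoHS")[1, 2], 0)
  expect_error(specificity_delta(sets, "NeoWW"), "searched",
               class = "fneo_validation_error")
})

test_that("preference_table lays classes out by miRNA", {
  sets <- list(m142 = library_zscores(synthetic_supplementary_table("mir142"),
                                      "m142"),
               m504 = library_zscores(synthetic_supplementary_table("mir504"),
                                      "m504"))
  t4 <- preference_table(sets, c("NeoX", "NeoRX", "NeoXS"))
  expect_identical(dim(t4), c(3L, 3L))
  expect_identical(names(t4), c("class_spec", "m142", "m504"))
  expect_equal(t4$m142[t4$class_spec == "NeoXS"], 1.21, tolerance = 0.01)
})
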