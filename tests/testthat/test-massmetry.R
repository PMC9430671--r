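test_that("partition coefficient spans its limits", {
  expect_equal(kav(7.2, 7.2, 24), 0)
  expect_equal(kav(24, 7.2, 24), 1)
  expect_equal(kav((7.2 + 24) / 2, 7.2, 24), 0.5)
  expect_error(kav(25, 7.2, 24), "fractionation")
  expect_error(kav(5, 7.2, 24), "fractionation")
})

test_that("calibration recovers an exact linear law", {
  # standards planted on log10(M) = -2 * Kav + 3
  k <- c(0.1, 0.25, 0.4, 0.6, 0.8)
  std <- data.frame(name = paste0("s", 1:5), mass_kda = 10^(-2 * k + 3),
                    rs_nm = c(8, 6, 4.5, 3, 2),
                    ve_ml = 7.2 + k * (24 - 7.2))
  curve <- gfCalibrate(std, 7.2, 24)
  expect_equal(curve@mass_fit[["slope"]], -2, tolerance = 1e-9)
  expect_equal(curve@mass_fit[["intercept"]], 3, tolerance = 1e-9)
  expect_equal(curve@r2_mass, 1, tolerance = 1e-9)

  # duplicated standard changes nothing
  curve2 <- gfCalibrate(rbind(std, std[2, ]), 7.2, 24)
  expect_equal(curve2@mass_fit, curve@mass_fit, tolerance = 1e-9)

  # out-of-range standard excluded with a warning
  std3 <- rbind(std, data.frame(name = "late", mass_kda = 0.5,
                                rs_nm = 0.5, ve_ml = 30))
  expect_warning(curve3 <- gfCalibrate(std3, 7.2, 24), "excluded")
  expect_equal(curve3@mass_fit, curve@mass_fit, tolerance = 1e-9)

  expect_error(gfCalibrate(std[1:2, ], 7.2, 24), "at least 3")
})

test_that("mass estimation inverts the calibration exactly", {
  k <- c(0.1, 0.25, 0.4, 0.6, 0.8)
  std <- data.frame(name = paste0("s", 1:5), mass_kda = 10^(-2 * k + 3),
                    rs_nm = c(8, 6, 4.5, 3, 2),
                    ve_ml = 7.2 + k * (24 - 7.2))
  curve <- gfCalibrate(std, 7.2, 24)
  ve_half <- 7.2 + 0.5 * (24 - 7.2)
  expect_equal(estimateMass(ve_half, curve), 100, tolerance = 1e-9)
  # round trip: mass -> ve -> mass
  for (m in c(15, 50, 500)) {
    kk <- (log10(m) - curve@mass_fit[["intercept"]]) /
      curve@mass_fit[["slope"]]
    ve <- curve@v0 + kk * (curve@vt - curve@v0)
    expect_equal(estimateMass(ve, curve), m, tolerance = 1e-9)
  }
  # monotone: larger elution volume, smaller mass
  ves <- seq(8, 23, by = 0.5)
  expect_true(all(diff(vapply(ves, estimateMass, numeric(1),
                              curve = curve)) < 0))
  # Stokes radius route present and monotone too
  expect_true(is.finite(estimateRs(ve_half, curve)))
})

test_that("the packaged synthetic standards calibrate cleanly", {
  std <- readGfStandards(system.file("extdata",
                                     "gf_standards_synthetic.tsv",
                                     package = "lysinITSS"))
  curve <- gfCalibrate(std, 7.2, 24)
  expect_equal(curve@n_standards, 6L)
  expect_gt(curve@r2_mass, 0.999)
  expect_gt(curve@r2_rs, 0.9)
})

test_that("sequence masses match the residue tables", {
  expect_equal(sequenceMass("G"), 75.03203, tolerance = 1e-5)
  expect_equal(sequenceMass("GG"), 132.05349, tolerance = 1e-5)
  expect_error(sequenceMass(""), "empty")
  expect_error(sequenceMass("GXG"), "position 2")
})

test_that("monoisotopic masses agree with an elemental-composition oracle", {
  set.seed(8)
  aas <- strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]]
  for (i in 1:100) {
    pep <- paste(sample(aas, sample(5:60, 1), replace = TRUE),
                 collapse = "")
    expect_equal(sequenceMass(pep, "monoisotopic"),
                 unname(oracle_peptide_mass(pep)), tolerance = 1e-4)
  }
})

test_that("mass deviation is a plain absolute difference", {
  expect_equal(massDeviation(34063.70, 34064.28), 0.58, tolerance = 1e-9)
  expect_equal(massDeviation(10790.40, 10790.20), 0.20, tolerance = 1e-9)
  expect_equal(massDeviation(123.4, 123.4), 0)
  expect_error(massDeviation(-1, 5), "positive")
})

test_that("extinction coefficients follow the Trp/Tyr/cystine convention", {
  expect_equal(extinctionCoefficient("W"), 5500)
  expect_equal(extinctionCoefficient("WYY"), 8480)
  expect_equal(extinctionCoefficient("AAAA"), 0)
  expect_equal(extinctionCoefficient("WCC", cystines = TRUE), 5625)
  expect_equal(extinctionCoefficient("WCC", cystines = FALSE), 5500)
  expect_equal(extinctionCoefficient("WCCC", cystines = TRUE), 5625)
})

test_that("charge-state series invert to a consistent neutral mass", {
  one <- massFromCsd(4412.457, 20)
  expect_equal(one$mass, 88229, tolerance = 1e-3)
  expect_equal(one$sd, 0)
  # peaks synthesized from one mass at z = 18..23 agree exactly
  M <- 88229
  z <- 18:23
  mz <- (M + z * 1.00728) / z
  res <- massFromCsd(mz, z)
  expect_equal(res$mass, M, tolerance = 1e-9)
  expect_equal(res$sd, 0, tolerance = 1e-9)
  expect_error(massFromCsd(numeric(0), integer(0)), "at least one")
  expect_error(massFromCsd(100, 0), "positive")
})

test_that("complex masses are linear in the composition", {
  expect_equal(complexMass(1, 5, 34.1, 10.8), 88.1)
  expect_equal(complexMass(0, 7, 34.1, 10.8), 75.6)
  expect_equal(complexMass(2, 2, 34.1, 10.8), 89.8)
  expect_error(complexMass(0, 0, 34.1, 10.8), "not a complex")
  set.seed(2)
  for (i in 1:20) {
    a <- sample(0:3, 2, replace = TRUE); b <- sample(0:6, 2, replace = TRUE)
    if (any(a + b == 0) || sum(a) + sum(b) == 0) next
    if (a[1] + b[1] == 0 || a[2] + b[2] == 0) next
    expect_equal(complexMass(a[1] + a[2], b[1] + b[2], 34.1, 10.8),
                 complexMass(a[1], b[1], 34.1, 10.8) +
                   complexMass(a[2], b[2], 34.1, 10.8),
                 tolerance = 1e-12)
  }
})

test_that("stoichiometry enumeration finds the documented compositions", {
  expect_equal(bestComposition(bestStoichiometry(88.229, 34.1, 10.8)),
               c(flp = 1L, ctp = 5L))
  expect_equal(bestComposition(bestStoichiometry(75.7, 34.1, 10.8)),
               c(flp = 0L, ctp = 7L))
  fit <- bestStoichiometry(34.1, 34.1, 10.8)
  expect_equal(bestComposition(fit), c(flp = 1L, ctp = 0L))
  expect_equal(fit@residual, 0)
  # tie-break: equal residuals resolve to smaller a, then smaller b
  tie <- bestStoichiometry(2, 2, 1, a_max = 3, b_max = 10)
  expect_equal(unname(bestComposition(tie)), c(0L, 2L))
})

test_that("enumeration agrees with an independent oracle", {
  set.seed(12)
  for (i in 1:1000) {
    m1 <- runif(1, 5, 60)
    m2 <- runif(1, 2, 30)
    amax <- sample(1:4, 1)
    bmax <- sample(1:12, 1)
    obs <- runif(1, 1, amax * m1 + bmax * m2)
    fit <- bestStoichiometry(obs, m1, m2, amax, bmax)
    expect_identical(unname(bestComposition(fit)),
                     as.integer(oracle_stoichiometry(obs, m1, m2,
                                                     amax, bmax)))
  }
})
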