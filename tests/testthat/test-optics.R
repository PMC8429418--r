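# Threshold-dose model and tissue library.

test_that("photon energy follows h*c0/lambda", {
  # hand evaluation: 6.626e-34 * 2.998e8 / 690e-9
  expect_equal(photon_energy(690e-9), 2.879e-19, tolerance = 1e-3)
  # inverse proportionality and the 565/690 ratio identity
  lams <- c(400, 565, 690, 800) * 1e-9
  expect_equal(photon_energy(2 * lams), photon_energy(lams) / 2)
  expect_equal(photon_energy(565e-9), (690 / 565) * photon_energy(690e-9))
  expect_error(photon_energy(0), "positive")
  expect_error(photon_energy(-1e-9), "positive")
})

test_that("threshold fluence reproduces the reference tissue values", {
  phi_cord <- threshold_fluence(0.1e18, 0.13, 33000, wavelength = 690e-9)
  phi_met <- threshold_fluence(10e18, 0.7, 33000, wavelength = 690e-9)
  phi_bone <- threshold_fluence(1e18, 0.3, 33000, wavelength = 690e-9)
  expect_equal(round(phi_cord, 2), 0.02)
  expect_equal(round(phi_met, 1), 0.4)
  # bone computes to 0.09 J/mm^2 (the library reference value is 0.1)
  expect_equal(round(phi_bone, 2), 0.09)
  expect_error(threshold_fluence(0, 0.13, 33000, wavelength = 690e-9))
  expect_error(threshold_fluence(1e18, -1, 33000, wavelength = 690e-9))
})

test_that("threshold fluence scales linearly in T and inversely in C", {
  set.seed(101)
  for (i in 1:20) {
    T0 <- runif(1, 0.01, 20) * 1e18
    C0 <- runif(1, 0.05, 2)
    s <- runif(1, 0.1, 10)
    base <- threshold_fluence(T0, C0, 33000, wavelength = 690e-9)
    expect_equal(threshold_fluence(s * T0, C0, 33000, wavelength = 690e-9),
                 s * base)
    expect_equal(threshold_fluence(T0, s * C0, 33000, wavelength = 690e-9),
                 base / s)
  }
})

test_that("same-tissue threshold ratio between wavelengths is eps*lambda", {
  # (33000 * 690) / (6724 * 565)
  expected <- (33000 * 690) / (6724 * 565)
  r <- threshold_fluence(1e18, 0.3, 6724, wavelength = 565e-9) /
    threshold_fluence(1e18, 0.3, 33000, wavelength = 690e-9)
  expect_equal(r, expected, tolerance = 1e-12)
  expect_equal(expected, 5.99, tolerance = 1e-3)
  lib565 <- tissue_library(565)
  lib690 <- tissue_library(690)
  for (tis in c("spinal_cord", "bone", "metastasis", "muscle")) {
    expect_equal(tl_threshold(lib565, tis) / tl_threshold(lib690, tis),
                 expected)
  }
})

test_that("tissue library round-trips the optical-property table", {
  # frozen reference entries: (tissue, wavelength) -> mu_s, mu_a, g, n
  ref <- list(
    list("spinal_cord", 690, 15.47, 0.0216, 0.9, 1.41),
    list("bone",        690, 15.23, 0.01,   0.9, 1.56),
    list("muscle",      690, 7.356, 0.052,  0.93, 1.41),
    list("spinal_cord", 565, 22.48, 0.108,  0.9, 1.41),
    list("bone",        565, 32.09, 0.04,   0.9, 1.56),
    list("muscle",      565, 11.61, 0.36,   0.93, 1.41)
  )
  for (e in ref) {
    o <- tl_optics(tissue_library(e[[2]], "lytic"), e[[1]])
    expect_identical(c(o$mu_s, o$mu_a, o$g, o$n),
                     c(e[[3]], e[[4]], e[[5]], e[[6]]))
  }
  # lytic metastasis has its own optics; sclerotic duplicates bone
  lyt <- tl_optics(tissue_library(690, "lytic"), "metastasis")
  expect_identical(c(lyt$mu_s, lyt$mu_a), c(16, 0.009))
  lyt565 <- tl_optics(tissue_library(565, "lytic"), "metastasis")
  expect_identical(c(lyt565$mu_s, lyt565$mu_a), c(10.22, 0.09))
  for (wl in c(690, 565)) {
    scl <- tissue_library(wl, "sclerotic")
    expect_identical(tl_optics(scl, "metastasis"), tl_optics(scl, "bone"))
  }
  expect_error(tissue_library(800), "wavelength")
  expect_error(tl_optics(tissue_library(690), "fat"), "unknown tissue")
})

test_that("library thresholds: reference values at 690, computed mode", {
  lib <- tissue_library(690)
  expect_equal(tl_threshold(lib, "spinal_cord"), 0.02)
  expect_equal(tl_threshold(lib, "bone"), 0.1)
  expect_equal(tl_threshold(lib, "metastasis"), 0.4)
  expect_equal(tl_threshold(lib, "muscle"), 0.1)
  comp <- tissue_library(690, thresholds = "computed")
  expect_equal(tl_threshold(comp, "spinal_cord"),
               threshold_fluence(0.1e18, 0.13, 33000, wavelength = 690e-9))
})

test_that("tissue library YAML serialization round-trips", {
  lib <- tissue_library(565, "lytic")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tissue_library(lib, path)
  back <- read_tissue_library(path)
  expect_equal(back$wavelength, lib$wavelength)
  for (tis in names(lib$tissues)) {
    expect_equal(back$tissues[[tis]]$optics, lib$tissues[[tis]]$optics)
    expect_equal(back$tissues[[tis]]$threshold$phi,
                 lib$tissues[[tis]]$threshold$phi)
  }
})

test_that("packaged default library file matches the in-code defaults", {
  path <- system.file("extdata", "tissue_defaults_690.yaml",
                      package = "pdtplanr")
  expect_true(nzchar(path))
  back <- read_tissue_library(path)
  lib <- tissue_library(690, "sclerotic")
  for (tis in names(lib$tissues)) {
    expect_equal(back$tissues[[tis]]$optics, lib$tissues[[tis]]$optics)
    expect_equal(back$tissues[[tis]]$threshold$phi,
                 lib$tissues[[tis]]$threshold$phi)
  }
})
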