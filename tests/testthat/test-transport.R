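# Monte Carlo building blocks and kernel-level physics checks.

test_that("Henyey-Greenstein sampling matches the closed form", {
  # isotropic limit: g = 0 maps u to 2u - 1
  u <- seq(0, 0.999, length.out = 101)
  expect_equal(hg_sample(0, u), 2 * u - 1)
  # hand evaluation at g = 0.9, u = 0.5
  expect_equal(hg_sample(0.9, 0.5), 0.98550, tolerance = 1e-5)
  expect_error(hg_sample(1, 0.5), "\\|g\\| < 1")
  expect_error(hg_sample(0.5, 1), "\\[0, 1\\)")
})

test_that("mean Henyey-Greenstein cosine converges to g", {
  set.seed(7)
  for (g in c(0.3, 0.9)) {
    u <- stats::runif(2e5)
    x <- hg_sample(g, u)
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - g), 4 * se)
  }
})

test_that("Fresnel reflectance: matched media, normal incidence, TIR", {
  expect_equal(fresnel_reflectance(1.41, 1.41, c(0.2, 0.7, 1)), rep(0, 3))
  # ((n2 - n1)/(n2 + n1))^2 at normal incidence
  expect_equal(fresnel_reflectance(1.41, 1.56, 1), (0.15 / 2.97)^2,
               tolerance = 1e-12)
  # beyond the critical angle for 1.56 -> 1.41
  cos_crit <- sqrt(1 - (1.41 / 1.56)^2)
  expect_equal(fresnel_reflectance(1.56, 1.41, cos_crit * 0.5), 1)
  r <- fresnel_reflectance(1.41, 1.56, seq(0.05, 1, by = 0.05))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("diffusion point-source oracle evaluates the closed form", {
  bone <- optical_properties(0.01, 15.23, 0.9, 1.56)
  # D = 0.2174 mm, mu_eff = 0.2145 /mm -> 0.0250 mm^-2 at r = 5
  expect_equal(diffusion_point_source(bone, 5), 0.0250, tolerance = 2e-3)
  r <- seq(1, 10, by = 0.5)
  expect_true(all(diff(diffusion_point_source(bone, r)) < 0))
  # mu_a -> 0 limit approaches 1/(4 pi D r)
  thin <- optical_properties(1e-9, 15.23, 0.9, 1.56)
  D <- 1 / (3 * (1e-9 + 15.23 * 0.1))
  expect_equal(diffusion_point_source(thin, 5), 1 / (4 * pi * D * 5),
               tolerance = 1e-3)
  expect_error(diffusion_point_source(bone, 0), "r must be")
  expect_warning(diffusion_point_source(
    optical_properties(0.36, 11.61, 0.93, 1.41), 5), "inaccurate")
})

test_that("energy bookkeeping balances exactly including roulette", {
  vol <- homogeneous_box(31, 1, "muscle")
  lib <- tissue_library(565, "lytic")
  k <- simulate_kernel(vol, lib, point_source(c(0, 0, 0)),
                       n_packets = 2e4, seed = 13)
  expect_equal(k$absorbed + k$escaped - k$roulette_net, 1,
               tolerance = 1e-9)
  expect_true(all(is.finite(k$fluence)) && all(k$fluence >= 0))
  expect_true(all(is.finite(k$rel_se)))
})

test_that("kernels are bit-reproducible for a fixed seed and stream", {
  vol <- homogeneous_box(21, 1, "muscle")
  lib <- tissue_library(565, "lytic")
  src <- point_source(c(0, 0, 0))
  k1 <- simulate_kernel(vol, lib, src, n_packets = 5e3, seed = 21, stream = 2)
  k2 <- simulate_kernel(vol, lib, src, n_packets = 5e3, seed = 21, stream = 2)
  expect_identical(k1$fluence, k2$fluence)
  k3 <- simulate_kernel(vol, lib, src, n_packets = 5e3, seed = 21, stream = 3)
  expect_false(identical(k3$fluence, k1$fluence))
})

test_that("MC kernel matches diffusion theory in diffusive media", {
  # media with mu_s' >> mu_a; shell-averaged comparison removes the voxel
  # discretization bias. muscle at 565 nm is excluded here: mu_a/mu_s' is
  # ~0.44 there and the diffusion closed form itself is invalid.
  vol <- homogeneous_box(41, 1, "bone")
  r <- box_radii(vol)
  cases <- list(list(690, "bone", 3e4), list(690, "muscle", 3e4))
  for (cs in cases) {
    lib <- tissue_library(cs[[1]], "lytic")
    vol$labels[] <- label_codes()[[cs[[2]]]]
    opt <- tl_optics(lib, cs[[2]])
    k <- simulate_kernel(vol, lib, point_source(c(0, 0, 0)),
                         n_packets = cs[[3]], seed = 17,
                         n_outside = opt$n)
    for (rr in c(3, 5, 8)) {
      sel <- abs(r - rr) < 0.5
      mc <- mean(k$fluence[sel])
      th <- mean(suppressWarnings(diffusion_point_source(opt, r[sel])))
      expect_lt(abs(mc / th - 1), 0.15)
    }
  }
})

test_that("565 nm kernels decay faster with distance than 690 nm", {
  vol <- homogeneous_box(41, 1, "bone")
  r <- box_radii(vol)
  ratio_at <- function(wl) {
    lib <- tissue_library(wl, "lytic")
    opt <- tl_optics(lib, "bone")
    k <- simulate_kernel(vol, lib, point_source(c(0, 0, 0)),
                         n_packets = 2e4, seed = 19, n_outside = opt$n)
    near <- mean(k$fluence[abs(r - 3) < 0.5])
    far <- mean(k$fluence[abs(r - 10) < 0.5])
    far / near
  }
  expect_lt(ratio_at(565), ratio_at(690))
})

test_that("averaging two streams agrees with one longer run (linearity)", {
  vol <- homogeneous_box(31, 1, "muscle")
  lib <- tissue_library(565, "lytic")
  src <- point_source(c(0, 0, 0))
  ka <- simulate_kernel(vol, lib, src, n_packets = 2e4, seed = 23, stream = 0)
  kb <- simulate_kernel(vol, lib, src, n_packets = 2e4, seed = 23, stream = 1)
  kc <- simulate_kernel(vol, lib, src, n_packets = 4e4, seed = 29, stream = 0)
  avg <- (ka$fluence + kb$fluence) / 2
  r <- box_radii(vol)
  sel <- r > 1 & r < 6
  expect_equal(mean(avg[sel]), mean(kc$fluence[sel]), tolerance = 0.03)
})

test_that("sources outside the tissue volume are rejected", {
  vol <- homogeneous_box(21, 1, "muscle")
  lib <- tissue_library(690, "lytic")
  expect_error(simulate_kernel(vol, lib, point_source(c(100, 0, 0)),
                               n_packets = 1e3),
               "outside the tissue volume")
  expect_error(simulate_kernel(vol, lib, point_source(c(0, 0, 0)),
                               n_packets = 10), "n_packets")
})
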