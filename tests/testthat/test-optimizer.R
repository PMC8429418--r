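# Energy-allocation optimizer: superposition, toy-problem oracle checks,
# symmetry, and the two planning modes.

# Hand-held fixture: a 3-voxel "volume" encoded directly as kernel
# matrices, bypassing transport. Voxels 1-2 are tumour, voxel 3 is cord.
toy_kernels <- function(K, vol) {
  lapply(seq_len(ncol(K)), function(j) {
    arr <- array(K[, j], dim = dim(vol$labels))
    structure(list(fluence = arr, rel_se = array(0, dim(vol$labels)),
                   wavelength = 690, spacing = vol$spacing,
                   origin = vol$origin,
                   source = point_source(c(0, 0, 0))),
              class = "fluence_kernel")
  })
}

toy_volume <- function(labels) {
  lab <- array(as.integer(labels), dim = c(length(labels), 1, 1))
  structure(list(labels = lab, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                 meta = list()), class = "label_volume")
}

test_that("superpose_dose is the energy-weighted kernel sum", {
  set.seed(31)
  K <- matrix(stats::runif(125 * 2), nrow = 125)
  vol <- homogeneous_box(5, 1, "metastasis")
  kernels <- toy_kernels(K, vol)
  E <- c(2.5, 4)
  dose <- superpose_dose(kernels, E)
  # brute-force per-voxel loop oracle
  expected <- array(0, dim = c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    for (s in 1:2) {
      expected[i, j, k] <- expected[i, j, k] +
        E[s] * kernels[[s]]$fluence[i, j, k]
    }
  }
  expect_equal(dose$fluence, expected)
  # homogeneity and the zero plan
  expect_equal(superpose_dose(kernels, 3 * E)$fluence, 3 * dose$fluence)
  expect_true(all(superpose_dose(kernels, c(0, 0))$fluence == 0))
  expect_error(superpose_dose(kernels, c(1, -1)), ">= 0")
})

test_that("coverage plan matches exhaustive search on a 3-voxel toy", {
  # 2 tumour voxels + 1 cord voxel, 2 kernels (mm^-2)
  vol <- toy_volume(c(3, 3, 4))
  K <- matrix(c(0.010, 0.002, 0.004,
                0.003, 0.012, 0.001), nrow = 3)
  kernels <- toy_kernels(K, vol)
  lib <- tissue_library(690, "lytic")
  cfg <- plan_config(target_coverage = 1, coverage_tol = 0.01,
                     oar_weights = c(spinal_cord = 1))
  plan <- optimize_coverage(kernels, vol, lib, cfg)
  t_tum <- tl_threshold(lib, "metastasis")
  # oracle: full coverage needs K[1:2,] %*% E >= t_tum; minimal cord dose
  # then minimal energy; exhaustive grid over the energy box
  grid <- seq(0, 200, by = 0.05)
  best <- NULL
  for (e1 in grid) {
    # e2 needed for both tumour voxels given e1 (linear algebra per row)
    e2 <- max((t_tum - K[1, 1] * e1) / K[1, 2],
              (t_tum - K[2, 1] * e1) / K[2, 2], 0)
    cord <- K[3, 1] * e1 + K[3, 2] * e2
    cand <- c(e1, e2, cord, e1 + e2)
    if (is.null(best) || cord < best[3] - 1e-12 ||
        (cord < best[3] + 1e-12 && e1 + e2 < best[4])) best <- cand
  }
  expect_equal(plan$coverage, 1)
  expect_equal(sum(plan$energies), best[4], tolerance = 1e-2)
  dose_cord <- sum(K[3, ] * plan$energies)
  expect_equal(dose_cord, best[3], tolerance = 1e-2)
})

test_that("single-kernel coverage plan equals the percentile closed form", {
  # homogeneous tumour-only phantom: minimal E such that the voxel at the
  # coverage-defining percentile reaches threshold
  vol <- homogeneous_box(15, 1, "metastasis")
  lib <- fast_lib()
  k <- simulate_kernels(vol, lib, list(point_source(c(0, 0, 0))),
                        n_packets = 3e4, seed = 37)
  cfg <- plan_config(target_coverage = 0.9,
                     oar_weights = c(spinal_cord = 1))
  plan <- optimize_coverage(k, vol, lib, cfg)
  kv <- as.vector(k[[1]]$fluence)
  n <- length(kv)
  d_k <- sort(kv, decreasing = TRUE)[ceiling(0.9 * n)]
  E_closed <- tl_threshold(lib, "metastasis") / d_k
  expect_equal(unname(plan$energies[1]), E_closed, tolerance = 1e-6)
  expect_gte(plan$coverage, 0.9)
  expect_lte(plan$coverage, 0.9 + 2 / n)
})

test_that("mirror-symmetric sources receive near-equal energies", {
  sp <- symmetric_pair()
  cfg <- plan_config(target_coverage = 0.9,
                     oar_weights = c(spinal_cord = 1))
  plan <- optimize_coverage(sp$kernels, sp$vol, sp$lib, cfg)
  expect_gte(plan$coverage, 0.9)
  expect_lt(abs(diff(plan$energies)) / plan$total_energy, 0.02)
})

test_that("tumour-weight bisection trace is monotone in coverage", {
  sp <- symmetric_pair()
  cfg <- plan_config(target_coverage = 0.999,
                     oar_weights = c(spinal_cord = 1))
  plan <- optimize_coverage(sp$kernels, sp$vol, sp$lib, cfg)
  tr <- plan$diagnostics$trace
  w <- vapply(tr, function(t) t$w_t, numeric(1))
  cov <- vapply(tr, function(t) t$coverage, numeric(1))
  o <- order(w)
  expect_true(all(diff(cov[o]) > -0.02))
})

test_that("plan dose round-trips through superpose_dose", {
  sp <- symmetric_pair()
  cfg <- plan_config(target_coverage = 0.9,
                     oar_weights = c(spinal_cord = 1))
  plan <- optimize_coverage(sp$kernels, sp$vol, sp$lib, cfg)
  dose <- superpose_dose(sp$kernels, plan$energies)
  cov <- mean(dose$fluence[sp$vol$labels == 3L] >=
                tl_threshold(sp$lib, "metastasis"))
  expect_equal(cov, plan$coverage)
})

test_that("sparing mode: hard cord constraint, toy oracle, dominance", {
  # toy with a cord voxel that binds: maximizing coverage surrogate under
  # d_cord <= t_cord
  vol <- toy_volume(c(3, 3, 4))
  K <- matrix(c(0.010, 0.002, 0.004,
                0.003, 0.012, 0.001), nrow = 3)
  kernels <- toy_kernels(K, vol)
  lib <- tissue_library(690, "lytic")
  t_cord <- tl_threshold(lib, "spinal_cord")
  plan <- optimize_sparing(kernels, vol, lib)
  d <- as.vector(K %*% plan$energies)
  expect_lt(d[3], t_cord)           # strictly feasible
  expect_identical(unname(plan$damage_cm3[["spinal_cord"]]), 0)
  # oracle: exhaustive search over the feasible box
  t_tum <- tl_threshold(lib, "metastasis")
  grid <- seq(0, t_cord / min(K[3, ]), length.out = 400)
  best <- -Inf
  for (e1 in grid) for (e2 in grid) {
    if (K[3, 1] * e1 + K[3, 2] * e2 > t_cord) next
    val <- min(K[1, 1] * e1 + K[1, 2] * e2, t_tum) +
      min(K[2, 1] * e1 + K[2, 2] * e2, t_tum)
    if (val > best) best <- val
  }
  achieved <- sum(pmin(d[1:2], t_tum))
  expect_gt(achieved, 0)
  expect_equal(achieved, best, tolerance = 0.01 * best)
})

test_that("relaxing the cord threshold recovers coverage maximization", {
  sp <- symmetric_pair()
  lib_inf <- sp$lib
  lib_inf$tissues$spinal_cord$threshold$phi <- Inf
  plan_inf <- optimize_sparing(sp$kernels, sp$vol, lib_inf)
  cfg <- plan_config(target_coverage = 0.999, coverage_tol = 0.01,
                     oar_weights = c(spinal_cord = 0.001))
  plan_cov <- optimize_coverage(sp$kernels, sp$vol, sp$lib, cfg)
  # with no binding constraint the sparing plan reaches the same coverage
  expect_gte(plan_inf$coverage + 0.005, plan_cov$coverage)
})

test_that("sparing never exceeds coverage-mode tumour damage", {
  sp <- symmetric_pair()
  # make the central region "cord" so the constraint binds
  vol <- sp$vol
  r <- box_radii(vol)
  vol$labels[r < 3] <- label_codes()[["spinal_cord"]]
  cfg <- plan_config(target_coverage = 0.9,
                     oar_weights = c(spinal_cord = 1))
  plan_cov <- optimize_coverage(sp$kernels, vol, sp$lib, cfg)
  plan_sp <- optimize_sparing(sp$kernels, vol, sp$lib)
  expect_lte(plan_sp$coverage, plan_cov$coverage + 1e-9)
  expect_identical(unname(plan_sp$damage_cm3[["spinal_cord"]]), 0)
})
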