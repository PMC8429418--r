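# Per-source energy allocation under the PDT threshold-dose model. Dose is
# linear in the source energies (dose = sum_j E_j * kernel_j), so both
# planning scenarios are convex programs in at most a handful of variables:
#
#   coverage mode: minimize sum_OAR w_oar * max(0, d_i - Phi_oar)
#                         + w_t * sum_tum max(0, Phi_tum - d_i),  E >= 0,
#   with an outer monotone bisection on the tumour weight w_t until the
#   tumour coverage reaches the target, then a uniform energy trim down to
#   the target (minimal-total-energy tie-break);
#
#   sparing mode: maximize sum_tum min(d_i, Phi_tum) subject to
#   d_i <= Phi_cord on every cord voxel, E >= 0 (hard feasibility enforced
#   by a final uniform down-scaling, exact because the objective is
#   nondecreasing in E).
#
# The piecewise-linear objectives are minimized by softplus smoothing with
# a decreasing smoothing width (continuation) and L-BFGS-B; tests verify
# the solutions against exhaustive search.

#' Planning configuration
#'
#' @param mode `"coverage"` (reach a target tumour coverage with minimal
#'   organ-at-risk damage) or `"sparing"` (maximize tumour coverage under a
#'   hard spinal-cord constraint).
#' @param target_coverage Tumour coverage target, fraction (coverage mode).
#' @param tumour_weight Fixed tumour weight; `NULL` (default) lets coverage
#'   mode adjust it automatically by bisection.
#' @param oar_weights Named per-voxel penalty weights for doses above
#'   threshold in organs at risk.
#' @param coverage_tol Acceptance window above the coverage target.
#' @param max_iter Maximum bisection iterations on the tumour weight.
#' @param solver_max_voxels Per-tissue voxel cap inside the solver (uniform
#'   stride subsampling); final metrics are always computed on the full
#'   grid.
#' @param sparing_hard Enforce the cord constraint exactly by rescaling
#'   (default); `FALSE` keeps the soft-penalty solution.
#' @param sparing_penalty Penalty weight per cord voxel in sparing mode.
#' @return A `plan_config` object.
#' @export
plan_config <- function(mode = c("coverage", "sparing"),
                        target_coverage = 0.9,
                        tumour_weight = NULL,
                        oar_weights = c(spinal_cord = 1, bone = 0.05,
                                        muscle = 0.05),
                        coverage_tol = 0.002,
                        max_iter = 40L,
                        solver_max_voxels = 30000L,
                        sparing_hard = TRUE,
                        sparing_penalty = 1e6) {
  mode <- match.arg(mode)
  stopifnot(target_coverage > 0, target_coverage <= 1, coverage_tol > 0,
            all(oar_weights >= 0), max_iter >= 1)
  structure(list(mode = mode, target_coverage = target_coverage,
                 tumour_weight = tumour_weight, oar_weights = oar_weights,
                 coverage_tol = coverage_tol, max_iter = as.integer(max_iter),
                 solver_max_voxels = as.integer(solver_max_voxels),
                 sparing_hard = sparing_hard,
                 sparing_penalty = sparing_penalty),
            class = "plan_config")
}

#' Superpose per-source kernels into a dose map
#'
#' @param kernels List of `fluence_kernel` objects on a common grid and
#'   wavelength.
#' @param energies Per-source emitted energies, J (same length, >= 0).
#' @return A `dose_map`: `fluence` (J/mm^2 array), grid metadata and
#'   provenance (energies, wavelength).
#' @export
superpose_dose <- function(kernels, energies) {
  stopifnot(length(kernels) >= 1, length(energies) == length(kernels))
  if (any(energies < 0)) stop("energies must be >= 0", call. = FALSE)
  d <- dim(kernels[[1]]$fluence)
  wl <- kernels[[1]]$wavelength
  for (k in kernels) {
    if (!identical(dim(k$fluence), d) || !identical(k$wavelength, wl)) {
      stop("kernels are incompatible (grid or wavelength mismatch)",
           call. = FALSE)
    }
  }
  dose <- array(0, dim = d)
  for (j in seq_along(kernels)) {
    dose <- dose + energies[j] * kernels[[j]]$fluence
  }
  structure(list(fluence = dose, spacing = kernels[[1]]$spacing,
                 origin = kernels[[1]]$origin,
                 provenance = list(energies = energies, wavelength = wl)),
            class = "dose_map")
}

# Kernel matrix (n_vox x n_sources) restricted to one tissue label,
# optionally stride-subsampled for the solver.
.kernel_matrix <- function(kernels, vol, tissue, max_voxels = Inf) {
  idx <- which(vol$labels == label_codes()[[tissue]])
  if (!length(idx)) return(NULL)
  if (length(idx) > max_voxels) {
    stride <- ceiling(length(idx) / max_voxels)
    idx <- idx[seq(1, length(idx), by = stride)]
  }
  K <- vapply(kernels, function(k) k$fluence[idx], numeric(length(idx)))
  if (is.null(dim(K))) K <- matrix(K, ncol = length(kernels))
  K
}

.softplus <- function(x, beta) {
  y <- beta * x
  out <- ifelse(y > 30, x, log1p(exp(pmin(y, 30))) / beta)
  out
}
.sigmoid <- function(x, beta) 1 / (1 + exp(-pmin(pmax(beta * x, -500), 500)))

# Minimize sum_k c_k * hinge(s_k * (K_k E - t_k)) over E >= 0 by softplus
# continuation + L-BFGS-B. `terms` is a list of lists(K, t, sign, weight):
# sign +1 penalizes dose above t, -1 penalizes dose below t. A generous
# upper box keeps the solver finite when the objective saturates (e.g. no
# organ-at-risk term).
.solve_hinge <- function(terms, E0, t_scale, maxit = 300, lin = 0) {
  nj <- length(E0)
  widths <- t_scale * c(0.3, 0.03, 0.003, 3e-4)
  E <- pmax(E0, 0)
  E_cap <- max(E0, t_scale) * 1e8
  lin <- rep_len(lin, nj)
  # strictly convex tie-break at the same (tiny) scale as the linear
  # energy cost: selects the balanced point on an otherwise flat optimal
  # face instead of an arbitrary vertex
  quad_of <- function(E) {
    if (all(lin == 0)) return(0)
    mean(lin) / max(mean(abs(E)), .Machine$double.eps)
  }
  for (wd in widths) {
    beta <- 1 / wd
    qc <- quad_of(E)
    fn <- function(E) {
      tot <- sum(lin * E) + 0.5 * qc * sum(E^2)
      for (tm in terms) {
        r <- tm$sign * (as.vector(tm$K %*% E) - tm$t)
        tot <- tot + tm$weight * sum(.softplus(r, beta))
      }
      tot
    }
    gr <- function(E) {
      g <- lin + qc * E
      for (tm in terms) {
        r <- tm$sign * (as.vector(tm$K %*% E) - tm$t)
        g <- g + tm$weight * tm$sign *
          as.vector(crossprod(tm$K, .sigmoid(r, beta)))
      }
      g
    }
    sc <- max(E, t_scale / max(vapply(terms, function(tm) max(tm$K),
                                      numeric(1)), 1e-300))
    res <- stats::optim(E, fn, gr, method = "L-BFGS-B", lower = 0,
                        upper = E_cap,
                        control = list(maxit = maxit, factr = 1e7,
                                       parscale = rep(sc, nj)))
    E <- pmax(res$par, 0)
  }
  E
}

# Full-grid coverage and per-tissue damage for energies E.
.plan_metrics <- function(kernels, vol, lib, E) {
  dose <- superpose_dose(kernels, E)
  voxvol <- prod(vol$spacing)
  codes <- label_codes()
  tissues <- setdiff(names(codes), "outside")
  damaged <- vapply(tissues, function(tis) {
    idx <- vol$labels == codes[[tis]]
    sum(dose$fluence[idx] >= tl_threshold(lib, tis)) * voxvol / 1000
  }, numeric(1))
  totals <- tissue_volumes(vol)
  coverage <- if (totals[["metastasis"]] > 0) {
    damaged[["metastasis"]] / totals[["metastasis"]]
  } else NA_real_
  list(dose = dose, damaged_cm3 = damaged, total_cm3 = totals,
       coverage = coverage)
}

.new_plan <- function(E, metrics, mode, wavelength, diagnostics) {
  structure(list(energies = E, total_energy = sum(E),
                 coverage = metrics$coverage,
                 damage_cm3 = metrics$damaged_cm3,
                 tissue_cm3 = metrics$total_cm3,
                 mode = mode, wavelength = wavelength,
                 diagnostics = diagnostics),
            class = "pdt_plan")
}

#' @export
print.pdt_plan <- function(x, ...) {
  cat(sprintf("pdt_plan (%s mode, %d nm)\n", x$mode, x$wavelength))
  cat(sprintf("  energies (J): %s  [total %.4g J]\n",
              paste(signif(x$energies, 4), collapse = ", "), x$total_energy))
  cat(sprintf("  tumour coverage: %.1f%%\n", 100 * x$coverage))
  cat(sprintf("  spinal cord damage: %.3g cm^3\n",
              x$damage_cm3[["spinal_cord"]]))
  if (isTRUE(x$diagnostics$infeasible)) {
    cat("  NOTE: coverage target not reached at the tumour-weight bound\n")
  }
  invisible(x)
}

#' Optimize per-source energies for a tumour-coverage target
#'
#' Runs the weighted one-sided-penalty convex program with an outer
#' monotone bisection on the tumour weight until the full-grid tumour
#' coverage lands in `[target, target + tol]`, then trims all energies by a
#' common factor to the smallest plan still meeting the target. Among
#' bisection iterates that meet the target the one with least spinal-cord
#' damage is kept.
#'
#' @param kernels List of `fluence_kernel` objects (one per source).
#' @param vol The `label_volume` the kernels were computed on.
#' @param lib The matching [tissue_library()].
#' @param cfg A [plan_config()] with `mode = "coverage"`.
#' @return A `pdt_plan`; if the target is unreachable even at the upper
#'   tumour-weight bound the best plan is returned with
#'   `diagnostics$infeasible = TRUE` and a warning.
#' @export
optimize_coverage <- function(kernels, vol, lib, cfg = plan_config()) {
  stopifnot(cfg$mode == "coverage", length(kernels) >= 1)
  t_tum <- tl_threshold(lib, "metastasis")
  Ktum_s <- .kernel_matrix(kernels, vol, "metastasis",
                           cfg$solver_max_voxels)
  if (is.null(Ktum_s)) stop("volume contains no metastasis voxels",
                            call. = FALSE)
  oar_terms <- list()
  for (tis in names(cfg$oar_weights)) {
    if (cfg$oar_weights[[tis]] <= 0) next
    K <- .kernel_matrix(kernels, vol, tis, cfg$solver_max_voxels)
    if (is.null(K)) next
    oar_terms[[tis]] <- list(K = K, t = tl_threshold(lib, tis), sign = 1,
                             weight = cfg$oar_weights[[tis]])
  }
  Ktum_full <- .kernel_matrix(kernels, vol, "metastasis")
  n_tum <- nrow(Ktum_full)

  kmean <- mean(Ktum_s[Ktum_s > 0])
  E0 <- rep(t_tum / max(kmean * ncol(Ktum_s), 1e-300), ncol(Ktum_s))

  solve_at <- function(w_t, E_start) {
    terms <- c(oar_terms,
               list(tum = list(K = Ktum_s, t = t_tum, sign = -1,
                               weight = w_t)))
    # small linear energy cost, independent of w_t: besides acting as the
    # minimal-total-energy tie-break it gives the tumour-weight bisection
    # traction even when no organ-at-risk voxels oppose coverage
    lin <- 1e-4 * colMeans(Ktum_s)
    .solve_hinge(terms, E_start, t_tum, lin = lin)
  }
  coverage_of <- function(E) mean(as.vector(Ktum_full %*% E) >= t_tum)

  trace <- list()
  record <- function(w, E) {
    cov <- coverage_of(E)
    trace[[length(trace) + 1]] <<- list(w_t = w, E = E, coverage = cov)
    cov
  }

  if (!is.null(cfg$tumour_weight)) {
    E <- solve_at(cfg$tumour_weight, E0)
    record(cfg$tumour_weight, E)
  } else {
    target <- cfg$target_coverage
    w <- 1
    E <- solve_at(w, E0)
    cov <- record(w, E)
    w_lo <- w_hi <- NULL
    tries <- 0
    if (cov < target) {
      # raise the tumour weight until the target is met
      while (cov < target && tries < 40) {
        w_lo <- w
        w <- w * 4
        E <- solve_at(w, E)
        cov <- record(w, E)
        tries <- tries + 1
      }
      if (cov >= target) w_hi <- w
    } else {
      # lower the tumour weight until coverage drops below the target, so
      # the bracketing iterate sits just above it
      w_hi <- w
      while (cov >= target && tries < 40) {
        w_hi <- w
        w <- w / 4
        E <- solve_at(w, E)
        cov <- record(w, E)
        tries <- tries + 1
      }
      if (cov < target) w_lo <- w
    }
    if (!is.null(w_lo) && !is.null(w_hi)) {
      cov_hi <- max(vapply(trace, function(tr)
        if (tr$w_t == w_hi) tr$coverage else -Inf, numeric(1)))
      for (it in seq_len(cfg$max_iter)) {
        if (cov_hi <= target + cfg$coverage_tol) break
        wm <- sqrt(w_lo * w_hi)
        Em <- solve_at(wm, E)
        cm <- record(wm, Em)
        if (cm >= target) {
          w_hi <- wm
          cov_hi <- cm
        } else {
          w_lo <- wm
        }
      }
    }
  }

  ok <- Filter(function(tr) !is.na(tr$coverage) &&
                 tr$coverage >= cfg$target_coverage, trace)
  infeasible <- length(ok) == 0
  if (infeasible) {
    warning("coverage target unreachable at the tumour-weight bound; ",
            "returning the highest-coverage plan", call. = FALSE)
    covs <- vapply(trace, function(tr) tr$coverage, numeric(1))
    best <- trace[[which.max(covs)]]
  } else {
    t_cord <- tl_threshold(lib, "spinal_cord")
    Kcord <- .kernel_matrix(kernels, vol, "spinal_cord")
    cord_dam <- vapply(ok, function(tr) {
      if (is.null(Kcord)) 0 else sum(as.vector(Kcord %*% tr$E) >= t_cord)
    }, numeric(1))
    en <- vapply(ok, function(tr) sum(tr$E), numeric(1))
    best <- ok[[order(cord_dam, en)[1]]]
    # uniform trim to the smallest energy still meeting the target
    d <- as.vector(Ktum_full %*% best$E)
    k_need <- ceiling(cfg$target_coverage * n_tum)
    d_k <- sort(d, decreasing = TRUE)[k_need]
    if (is.finite(d_k) && d_k > 0) {
      best$E <- best$E * (t_tum / d_k) * (1 + 1e-9)
    }
  }
  metrics <- .plan_metrics(kernels, vol, lib, best$E)
  .new_plan(best$E, metrics, "coverage", lib$wavelength,
            list(w_t = best$w_t, infeasible = infeasible,
                 iterations = length(trace),
                 trace = lapply(trace, function(tr)
                   list(w_t = tr$w_t, coverage = tr$coverage,
                        total_energy = sum(tr$E)))))
}

#' Maximize tumour coverage under a hard spinal-cord constraint
#'
#' Maximizes the coverage surrogate `sum_tum min(d_i, Phi_tum)` subject to
#' `d_i <= Phi_cord` on every spinal-cord voxel. The constraint is enforced
#' by a large one-sided penalty during the solve and then made exact by a
#' final uniform down-scaling of the energies against the full-grid cord
#' dose (optimal along the scaling ray because the surrogate is
#' nondecreasing in the energies).
#'
#' @inheritParams optimize_coverage
#' @param cfg A [plan_config()] with `mode = "sparing"`.
#' @return A `pdt_plan`; with `sparing_hard = TRUE` the returned plan has
#'   zero cord voxels at or above threshold by construction.
#' @export
optimize_sparing <- function(kernels, vol, lib,
                             cfg = plan_config(mode = "sparing")) {
  stopifnot(cfg$mode == "sparing", length(kernels) >= 1)
  t_tum <- tl_threshold(lib, "metastasis")
  t_cord <- tl_threshold(lib, "spinal_cord")
  Ktum_s <- .kernel_matrix(kernels, vol, "metastasis",
                           cfg$solver_max_voxels)
  if (is.null(Ktum_s)) stop("volume contains no metastasis voxels",
                            call. = FALSE)
  Kcord_s <- .kernel_matrix(kernels, vol, "spinal_cord",
                            cfg$solver_max_voxels)
  terms <- list(tum = list(K = Ktum_s, t = t_tum, sign = -1, weight = 1))
  if (!is.null(Kcord_s) && is.finite(t_cord)) {
    terms$cord <- list(K = Kcord_s, t = t_cord, sign = 1,
                       weight = cfg$sparing_penalty)
  }
  kmean <- mean(Ktum_s[Ktum_s > 0])
  E0 <- rep(t_tum / max(kmean * ncol(Ktum_s), 1e-300), ncol(Ktum_s))
  E <- .solve_hinge(terms, E0, min(t_tum, t_cord))

  rescaled <- FALSE
  if (cfg$sparing_hard && is.finite(t_cord)) {
    Kcord_full <- .kernel_matrix(kernels, vol, "spinal_cord")
    if (!is.null(Kcord_full)) {
      dmax <- max(as.vector(Kcord_full %*% E))
      if (dmax > 0 && t_cord / dmax < 1e8) {
        # move exactly onto the binding cord constraint (up or down):
        # the coverage surrogate is nondecreasing in E, so the boundary
        # point on this ray dominates the smoothed interior solution,
        # and scaling strictly below threshold leaves no cord voxel
        # counted as damaged
        E <- E * (t_cord / dmax) * (1 - 1e-9)
        rescaled <- TRUE
      }
    }
  }
  metrics <- .plan_metrics(kernels, vol, lib, E)
  .new_plan(E, metrics, "sparing", lib$wavelength,
            list(rescaled = rescaled, hard = cfg$sparing_hard))
}
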