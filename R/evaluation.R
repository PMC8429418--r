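# Plan-quality evaluation: dose-volume histograms, damage volumes under the
# binary threshold model, energy bookkeeping, and treatment-time estimates.

#' Cumulative dose-volume histogram of one tissue
#'
#' @param dose A `dose_map`.
#' @param vol The matching `label_volume`.
#' @param tissue Tissue role name.
#' @param n_bins Number of linear dose bins between 0 and the maximum
#'   tissue dose (one extra point beyond the maximum closes the curve at 0).
#' @return A `dvh_curve`: data.frame with `dose` (J/mm^2) and `fraction`
#'   (volume fraction receiving at least that dose), plus attributes
#'   `tissue` and `wavelength`.
#' @export
compute_dvh <- function(dose, vol, tissue, n_bins = 512L) {
  stopifnot(inherits(dose, "dose_map"), inherits(vol, "label_volume"),
            n_bins >= 2)
  code <- label_codes()
  if (!tissue %in% names(code)) {
    stop("unknown tissue '", tissue, "'", call. = FALSE)
  }
  d <- dose$fluence[vol$labels == code[[tissue]]]
  if (!length(d)) stop("tissue '", tissue, "' absent from the volume",
                       call. = FALSE)
  dmax <- max(d)
  grid <- if (dmax > 0) {
    c(seq(0, dmax, length.out = n_bins), dmax * (1 + 1 / n_bins))
  } else {
    c(0, 1e-12)
  }
  ds <- sort(d)
  n <- length(ds)
  # fraction of voxels with dose >= g
  frac <- (n - findInterval(grid, ds, left.open = TRUE)) / n
  out <- data.frame(dose = grid, fraction = frac)
  attr(out, "tissue") <- tissue
  attr(out, "wavelength") <- dose$provenance$wavelength
  class(out) <- c("dvh_curve", "data.frame")
  out
}

#' Write a DVH curve as a two-column CSV
#' @param dvh A `dvh_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(dvh, path) {
  utils::write.csv(as.data.frame(dvh)[, c("dose", "fraction")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Damage report under the binary threshold-dose model
#'
#' For each tissue: total volume, volume at or above its threshold fluence
#' (the predicted necrotic volume), and the damage fraction. Tumour
#' coverage is the damaged metastasis fraction. Energies are copied from
#' the plan when supplied.
#'
#' @param dose A `dose_map`.
#' @param vol The matching `label_volume`.
#' @param lib The [tissue_library()] providing the thresholds.
#' @param plan Optional `pdt_plan` whose energies are reported.
#' @return A `damage_report`: `table` (data.frame with tissue,
#'   `volume_cm3`, `damaged_cm3`, `damage_pct`), `coverage_pct`,
#'   `energies_J`, `total_energy_J`, `wavelength`.
#' @export
damage_report <- function(dose, vol, lib, plan = NULL) {
  stopifnot(inherits(dose, "dose_map"), inherits(vol, "label_volume"),
            inherits(lib, "tissue_library"))
  if (!identical(dim(dose$fluence), dim(vol$labels))) {
    stop("dose and label grids differ", call. = FALSE)
  }
  codes <- label_codes()
  tissues <- setdiff(names(codes), "outside")
  voxvol <- prod(vol$spacing)
  rows <- lapply(tissues, function(tis) {
    idx <- vol$labels == codes[[tis]]
    n_tot <- sum(idx)
    thr <- tl_threshold(lib, tis)
    if (is.null(thr)) stop("missing threshold for ", tis, call. = FALSE)
    n_dam <- if (n_tot > 0) sum(dose$fluence[idx] >= thr) else 0
    data.frame(tissue = tis,
               volume_cm3 = n_tot * voxvol / 1000,
               damaged_cm3 = n_dam * voxvol / 1000,
               damage_pct = if (n_tot > 0) 100 * n_dam / n_tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  cov <- tab$damage_pct[tab$tissue == "metastasis"]
  energies <- if (!is.null(plan)) plan$energies else
    dose$provenance$energies
  structure(list(table = tab, coverage_pct = cov,
                 energies_J = energies,
                 total_energy_J = if (is.null(energies)) NA_real_ else
                   sum(energies),
                 wavelength = lib$wavelength),
            class = "damage_report")
}

#' @export
print.damage_report <- function(x, ...) {
  cat(sprintf("damage_report (%d nm)\n", x$wavelength))
  print(x$table, row.names = FALSE)
  if (!is.null(x$energies_J)) {
    cat(sprintf("  energies (J): %s  [total %.4g J]\n",
                paste(signif(x$energies_J, 5), collapse = ", "),
                x$total_energy_J))
  }
  invisible(x)
}

#' Total-energy ratio between two plans or reports
#'
#' @param report_a,report_b `damage_report`s, `pdt_plan`s, or bare total
#'   energies in J.
#' @return `total_a / total_b` (dimensionless).
#' @export
energy_ratio <- function(report_a, report_b) {
  total_of <- function(x) {
    if (is.numeric(x) && length(x) == 1) return(x)
    if (inherits(x, "damage_report")) return(x$total_energy_J)
    if (inherits(x, "pdt_plan")) return(x$total_energy)
    stop("cannot extract a total energy from the given object",
         call. = FALSE)
  }
  ta <- total_of(report_a)
  tb <- total_of(report_b)
  if (!is.finite(tb) || tb == 0) stop("denominator energy must be nonzero",
                                      call. = FALSE)
  if (!is.finite(ta) || ta <= 0) stop("numerator energy must be positive",
                                      call. = FALSE)
  ta / tb
}

#' Treatment-time estimate for diffuser delivery
#'
#' Assumes a fixed linear power density along the total emitting length,
#' so time = energy / (power density x length).
#'
#' @param total_energy Total delivered energy, J.
#' @param linear_power_density Power per unit diffuser length, W/cm.
#' @param total_diffuser_length Total emitting length, cm.
#' @return Treatment time in seconds.
#' @examples
#' treatment_time(2914, 0.2, 6) / 60  # about 40 minutes
#' @export
treatment_time <- function(total_energy, linear_power_density,
                           total_diffuser_length) {
  args <- c(total_energy, linear_power_density, total_diffuser_length)
  if (any(!is.finite(args)) || any(args <= 0)) {
    stop("all treatment_time() arguments must be positive", call. = FALSE)
  }
  total_energy / (linear_power_density * total_diffuser_length)
}

#' Serialize a plan and its damage report to JSON
#'
#' @param plan A `pdt_plan`.
#' @param report A `damage_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan_report <- function(plan, report, path) {
  out <- list(
    mode = plan$mode, wavelength = plan$wavelength,
    energies_J = plan$energies, total_energy_J = plan$total_energy,
    coverage_pct = 100 * plan$coverage,
    damage = report$table, diagnostics = plan$diagnostics
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
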