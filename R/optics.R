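# Physical constants, tissue optical properties and the PDT threshold-dose
# model. Canonical internal units: mm, mm^-1, J, J/mm^2; conversions happen
# at the boundary of each function.

.PLANCK_H <- 6.626e-34      # J s
.LIGHT_SPEED_C0 <- 2.998e8  # m/s
.BPD_MA_MOLAR_MASS <- 718.8 # g/mol

# Molar extinction coefficients of BPD-MA at its two activation bands,
# M^-1 cm^-1.
.EPS_MOLAR <- c("690" = 33000, "565" = 6724)

.TISSUES <- c("spinal_cord", "bone", "metastasis", "muscle")

# Optical properties (mu_a, mu_s in mm^-1; g, n dimensionless) for each
# tissue role at the two activation wavelengths. Sclerotic metastases share
# bone optics; osteolytic metastases have their own row.
.OPTICS_TABLE <- data.frame(
  tissue = rep(c("spinal_cord", "bone", "metastasis_sclerotic",
                 "metastasis_lytic", "muscle"), times = 2),
  wavelength = rep(c(690, 565), each = 5),
  mu_s = c(15.47, 15.23, 15.23, 16.00, 7.356,
           22.48, 32.09, 32.09, 10.22, 11.61),
  mu_a = c(0.0216, 0.01, 0.01, 0.009, 0.052,
           0.108,  0.04, 0.04, 0.09,  0.36),
  g    = c(0.9, 0.9, 0.9, 0.9, 0.93,
           0.9, 0.9, 0.9, 0.9, 0.93),
  n    = c(1.41, 1.56, 1.56, 1.56, 1.41,
           1.41, 1.56, 1.56, 1.56, 1.41),
  stringsAsFactors = FALSE
)

# Necrosis thresholds: T in photons/cm^3, photosensitizer uptake in ug/g,
# and the reference threshold fluence at 690 nm in J/mm^2. The reference
# fluences are the library defaults; computed values from the threshold
# formula differ slightly for bone (0.09) and muscle (0.21), see vignette.
.THRESH_TABLE <- data.frame(
  tissue   = .TISSUES,
  T_photons = c(0.1e18, 1e18, 10e18, 1e18),
  uptake_C  = c(0.13, 0.3, 0.7, 0.13),
  phi_690   = c(0.02, 0.1, 0.4, 0.1),
  stringsAsFactors = FALSE
)

#' Physical constants used by the threshold-dose model
#'
#' @return A named list with `planck_h` (J s) and `light_speed_c0` (m/s).
#' @export
physical_constants <- function() {
  list(planck_h = .PLANCK_H, light_speed_c0 = .LIGHT_SPEED_C0)
}

#' Integer label codes of the phantom tissues
#'
#' @return Named integer vector mapping tissue role to voxel label code.
#' @export
label_codes <- function() {
  c(outside = 0L, muscle = 1L, bone = 2L, metastasis = 3L, spinal_cord = 4L)
}

#' Photon energy at a given wavelength
#'
#' @param wavelength Vacuum wavelength in metres (e.g. `690e-9`).
#' @return Photon energy in joules, `h * c0 / wavelength`.
#' @examples
#' photon_energy(690e-9)
#' @export
photon_energy <- function(wavelength) {
  if (!is.numeric(wavelength) || any(!is.finite(wavelength)) ||
      any(wavelength <= 0)) {
    stop("`wavelength` must be a positive finite length in metres",
         call. = FALSE)
  }
  .PLANCK_H * .LIGHT_SPEED_C0 / wavelength
}

#' Threshold fluence of the PDT threshold-dose model
#'
#' Converts a necrosis threshold expressed as an absorbed photon density into
#' the fluence at the boundary of necrosis, given the photosensitizer uptake
#' and its molar extinction coefficient. The uptake (ug of drug per g of
#' tissue) is converted to molarity assuming the given tissue density, the
#' photosensitizer absorption is `ln(10) * eps * c` (cm^-1), and the
#' threshold fluence is `photon_energy * T / mu_a_ps`, returned in J/mm^2.
#'
#' @param T_photons Necrosis threshold, photons/cm^3.
#' @param uptake_C Photosensitizer uptake, ug/g.
#' @param eps_molar Molar extinction coefficient, M^-1 cm^-1.
#' @param molar_mass Photosensitizer molar mass, g/mol (BPD-MA default).
#' @param wavelength Activation wavelength in metres.
#' @param tissue_density Tissue density, g/cm^3.
#' @return Threshold fluence in J/mm^2.
#' @examples
#' # spinal cord at 690 nm rounds to 0.02 J/mm^2
#' threshold_fluence(0.1e18, 0.13, 33000, wavelength = 690e-9)
#' @export
threshold_fluence <- function(T_photons, uptake_C, eps_molar,
                              molar_mass = .BPD_MA_MOLAR_MASS,
                              wavelength, tissue_density = 1) {
  args <- c(T_photons = T_photons, uptake_C = uptake_C,
            eps_molar = eps_molar, molar_mass = molar_mass,
            wavelength = wavelength, tissue_density = tissue_density)
  if (any(!is.finite(args)) || any(args <= 0)) {
    stop("all threshold_fluence() arguments must be strictly positive",
         call. = FALSE)
  }
  # uptake ug/g -> mol/L: C * 1e-6 g/cm^3 * 1e3 cm^3/L / M
  c_molar <- uptake_C * 1e-3 * tissue_density / molar_mass
  mu_a_ps_cm <- log(10) * eps_molar * c_molar          # cm^-1
  phi_cm2 <- photon_energy(wavelength) * T_photons / mu_a_ps_cm  # J/cm^2
  phi_cm2 / 100                                        # J/mm^2
}

#' Optical properties of a tissue
#'
#' @param mu_a Absorption coefficient, mm^-1.
#' @param mu_s Scattering coefficient, mm^-1.
#' @param g Scattering anisotropy, in (-1, 1).
#' @param n Refractive index, >= 1.
#' @return An `optical_properties` object (named list).
#' @export
optical_properties <- function(mu_a, mu_s, g, n) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g), is.numeric(n))
  if (mu_a < 0 || mu_s < 0) stop("mu_a and mu_s must be >= 0", call. = FALSE)
  if (mu_a + mu_s <= 0) stop("mu_a + mu_s must be > 0", call. = FALSE)
  if (abs(g) > 1) stop("anisotropy g must lie in [-1, 1]", call. = FALSE)
  if (n < 1) stop("refractive index n must be >= 1", call. = FALSE)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

# Scale factor between same-tissue threshold fluences at two wavelengths,
# from the threshold formula: phi(l2)/phi(l1) = (eps1 * l1)/(eps2 * l2).
.threshold_wavelength_ratio <- function(to_nm, from_nm = 690) {
  (.EPS_MOLAR[[as.character(from_nm)]] * from_nm) /
    (.EPS_MOLAR[[as.character(to_nm)]] * to_nm)
}

#' Tissue library: optical properties and thresholds for one wavelength
#'
#' Returns the per-tissue optical properties and threshold-dose parameters
#' for the four anatomical roles of the vertebra model (spinal cord, bone,
#' metastasis, muscle) at one activation wavelength. Sclerotic metastases
#' take bone optics. Threshold fluences default to the reference values at
#' 690 nm; at 565 nm they are rescaled by the threshold formula using the
#' BPD-MA extinction coefficients (a factor of about 5.99), since no
#' measured 565 nm thresholds exist. Pass `thresholds = "computed"` to use
#' the threshold formula for every tissue at either wavelength.
#'
#' @param wavelength Activation wavelength in nm, 690 or 565.
#' @param lesion_type `"sclerotic"` or `"lytic"`.
#' @param thresholds `"reference"` (default) or `"computed"`.
#' @return A `tissue_library` object: list with `wavelength` (nm),
#'   `lesion_type`, and `tissues`, a named list of
#'   `list(optics = optical_properties, threshold = list(T_photons,
#'   uptake_C, phi))` entries, `phi` in J/mm^2.
#' @export
tissue_library <- function(wavelength = 690,
                           lesion_type = c("sclerotic", "lytic"),
                           thresholds = c("reference", "computed")) {
  lesion_type <- match.arg(lesion_type)
  thresholds <- match.arg(thresholds)
  if (!wavelength %in% c(690, 565)) {
    stop("no tissue data for wavelength ", wavelength,
         " nm (supported: 690, 565)", call. = FALSE)
  }
  met_row <- paste0("metastasis_", lesion_type)
  tissues <- lapply(.TISSUES, function(tis) {
    opt_name <- if (tis == "metastasis") met_row else tis
    row <- .OPTICS_TABLE[.OPTICS_TABLE$tissue == opt_name &
                           .OPTICS_TABLE$wavelength == wavelength, ]
    th <- .THRESH_TABLE[.THRESH_TABLE$tissue == tis, ]
    phi <- if (thresholds == "computed") {
      threshold_fluence(th$T_photons, th$uptake_C,
                        .EPS_MOLAR[[as.character(wavelength)]],
                        wavelength = wavelength * 1e-9)
    } else if (wavelength == 690) {
      th$phi_690
    } else {
      th$phi_690 * .threshold_wavelength_ratio(wavelength)
    }
    list(
      optics = optical_properties(row$mu_a, row$mu_s, row$g, row$n),
      threshold = list(T_photons = th$T_photons, uptake_C = th$uptake_C,
                       phi = unname(phi))
    )
  })
  names(tissues) <- .TISSUES
  structure(list(wavelength = wavelength, lesion_type = lesion_type,
                 thresholds = thresholds, tissues = tissues),
            class = "tissue_library")
}

#' @export
print.tissue_library <- function(x, ...) {
  cat(sprintf("tissue_library: %d nm, %s lesion (%s thresholds)\n",
              x$wavelength, x$lesion_type, x$thresholds))
  for (tis in names(x$tissues)) {
    o <- x$tissues[[tis]]$optics
    cat(sprintf("  %-12s mu_a %-7.4g mu_s %-7.4g g %-5.3g n %-5.3g  Phi_thr %.4g J/mm2\n",
                tis, o$mu_a, o$mu_s, o$g, o$n, x$tissues[[tis]]$threshold$phi))
  }
  invisible(x)
}

#' Optical properties of one tissue in a library
#' @param lib A `tissue_library`.
#' @param tissue Tissue role name.
#' @return An `optical_properties` object.
#' @export
tl_optics <- function(lib, tissue) {
  stopifnot(inherits(lib, "tissue_library"))
  if (!tissue %in% names(lib$tissues)) {
    stop("unknown tissue '", tissue, "'", call. = FALSE)
  }
  lib$tissues[[tissue]]$optics
}

#' Threshold fluence of one tissue in a library
#' @inheritParams tl_optics
#' @return Threshold fluence, J/mm^2.
#' @export
tl_threshold <- function(lib, tissue) {
  stopifnot(inherits(lib, "tissue_library"))
  if (!tissue %in% names(lib$tissues)) {
    stop("unknown tissue '", tissue, "'", call. = FALSE)
  }
  lib$tissues[[tissue]]$threshold$phi
}

# Per-label optics matrix consumed by the transport core: one row per label
# code 0..4, columns mu_a, mu_s, g, n. Label 0 is the non-tissue exterior
# (mu = 0); its refractive index sets the outer boundary condition.
.optics_matrix <- function(lib, n_outside = 1.0) {
  codes <- label_codes()
  m <- matrix(0, nrow = length(codes), ncol = 4,
              dimnames = list(names(codes), c("mu_a", "mu_s", "g", "n")))
  m["outside", ] <- c(0, 0, 0, n_outside)
  for (tis in .TISSUES) {
    o <- lib$tissues[[tis]]$optics
    m[tis, ] <- c(o$mu_a, o$mu_s, o$g, o$n)
  }
  m
}

#' Serialize a tissue library to YAML
#'
#' The schema mirrors the `tissue_library` structure: top-level `wavelength`,
#' `lesion_type`, `thresholds`, and a `tissues` map with `optics`
#' (`mu_a`, `mu_s`, `g`, `n`) and `threshold` (`T_photons`, `uptake_C`,
#' `phi`) blocks per tissue.
#'
#' @param lib A `tissue_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tissue_library <- function(lib, path) {
  stopifnot(inherits(lib, "tissue_library"))
  yaml::write_yaml(unclass(lib), path, precision = 15)
  invisible(path)
}

#' Read a tissue library from YAML
#'
#' @param path YAML file following the [write_tissue_library()] schema.
#' @return A validated `tissue_library`.
#' @export
read_tissue_library <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("wavelength", "lesion_type", "tissues")
  if (!all(need %in% names(raw))) {
    stop("tissue library file missing fields: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  if (!all(.TISSUES %in% names(raw$tissues))) {
    stop("tissue library must define all of: ",
         paste(.TISSUES, collapse = ", "), call. = FALSE)
  }
  tissues <- lapply(raw$tissues[.TISSUES], function(entry) {
    o <- entry$optics
    list(optics = optical_properties(o$mu_a, o$mu_s, o$g, o$n),
         threshold = list(T_photons = entry$threshold$T_photons,
                          uptake_C = entry$threshold$uptake_C,
                          phi = entry$threshold$phi))
  })
  structure(list(wavelength = raw$wavelength, lesion_type = raw$lesion_type,
                 thresholds = raw$thresholds %||% "reference",
                 tissues = tissues),
            class = "tissue_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
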