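# Synthetic labelled voxel phantom of a metastatically involved vertebra:
# an elliptic-cylinder vertebral body of bone containing an ellipsoidal
# metastasis, a cylindrical spinal cord centred in a posterior canal, and
# muscle filling the rest of an outer elliptic boundary. Geometry primitives
# are scaled by monotone (quantile-exact) searches so the per-tissue volumes
# hit their targets to within voxel quantization.
#
# Coordinate convention: right-handed, +y = posterior (toward the cord),
# z = cranio-caudal; voxel centres at origin + (i - 0.5) * spacing.

#' Phantom specification
#'
#' Defaults emulate the segmented anatomy of a T8 vertebra with a large
#' sclerotic metastasis: target volumes are the reference case values
#' (metastasis 23.21, spinal cord 4.72, bone 31.14, muscle 171.84 cm^3).
#'
#' @param volumes_cm3 Named target volumes in cm^3 for `metastasis`,
#'   `spinal_cord`, `bone`, `muscle`.
#' @param pitch Voxel pitch in mm (isotropic).
#' @param height Phantom (and vertebral body) height in mm.
#' @param body_semiaxes Base in-plane semi-axes (x, y) of the vertebral
#'   body, mm; rescaled to meet the bone volume.
#' @param lesion_semiaxes Base semi-axes (x, y, z) of the metastasis
#'   ellipsoid, mm; in-plane axes rescaled to meet the lesion volume.
#' @param lesion_offset Lesion centroid offset from the body centre, mm;
#'   the default shifts the lesion posteriorly toward the spinal canal
#'   (posterior vertebral-body involvement, the configuration that puts
#'   the cord at risk).
#' @param outer_semiaxes Base in-plane semi-axes of the outer soft-tissue
#'   boundary, mm; rescaled to meet the muscle volume.
#' @param canal_wall Radial gap between cord surface and canal wall, mm.
#' @param canal_gap Gap between vertebral body surface and canal, mm.
#' @param lesion_type `"sclerotic"` or `"lytic"` (metadata used when pairing
#'   the phantom with a tissue library).
#' @param jitter_sd Standard deviation of optional Gaussian boundary jitter
#'   applied to the primitive level-set values (dimensionless, 0 = smooth
#'   deterministic boundaries).
#' @param rng_seed Seed used only for boundary jitter.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(volumes_cm3 = c(metastasis = 23.21,
                                         spinal_cord = 4.72,
                                         bone = 31.14,
                                         muscle = 171.84),
                         pitch = 1,
                         height = 30,
                         body_semiaxes = c(28, 20.6),
                         lesion_semiaxes = c(25.5, 15.5, 14),
                         lesion_offset = c(0, 4, 0),
                         outer_semiaxes = c(57.7, 43),
                         canal_wall = 2,
                         canal_gap = 1,
                         lesion_type = c("sclerotic", "lytic"),
                         jitter_sd = 0,
                         rng_seed = 1L) {
  lesion_type <- match.arg(lesion_type)
  need <- c("metastasis", "spinal_cord", "bone", "muscle")
  if (!all(need %in% names(volumes_cm3))) {
    stop("volumes_cm3 must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(volumes_cm3 < 0) || any(volumes_cm3[c("spinal_cord", "bone",
                                                "muscle")] <= 0)) {
    stop("tissue volumes must be positive (metastasis may be zero)",
         call. = FALSE)
  }
  stopifnot(pitch > 0, height > 0, all(body_semiaxes > 0),
            all(lesion_semiaxes > 0), all(outer_semiaxes > 0),
            canal_wall >= 0, canal_gap >= 0, jitter_sd >= 0)
  structure(list(volumes_cm3 = volumes_cm3[need], pitch = pitch,
                 height = height, body_semiaxes = body_semiaxes,
                 lesion_semiaxes = lesion_semiaxes,
                 lesion_offset = lesion_offset,
                 outer_semiaxes = outer_semiaxes,
                 canal_wall = canal_wall, canal_gap = canal_gap,
                 lesion_type = lesion_type, jitter_sd = jitter_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Threshold a level-set vector so that exactly n_target voxels fall inside.
# Values are made unique by an index-based perturbation far below geometric
# scale, so ties on symmetric shells cannot overshoot the count.
.level_threshold <- function(values, n_target) {
  if (n_target <= 0) return(-Inf)
  if (n_target > length(values)) return(NA_real_)
  sort(values, partial = n_target)[n_target]
}

.tiebreak <- function(values, idx) {
  values + (idx %% 9973L) * 1e-12
}

#' Build a labelled vertebra phantom
#'
#' Rasterizes the phantom described by `spec` onto a regular voxel grid and
#' scales each geometric primitive (cord radius, lesion in-plane axes,
#' vertebral-body axes, outer boundary) by a monotone search so each
#' tissue's voxel count matches its target volume to within half a voxel.
#'
#' @param spec A [phantom_spec()].
#' @return A `label_volume`: list with `labels` (integer 3D array using
#'   [label_codes()]), `spacing` (mm), `origin` (mm, corner of voxel
#'   (1,1,1)), and `meta` (achieved scales and the spec).
#' @export
build_vertebra_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  p <- spec$pitch
  vox <- p^3                                   # mm^3
  targets <- spec$volumes_cm3 * 1000           # mm^3
  n_tar <- round(targets / vox)                # voxel counts

  # cord radius estimate fixes the canal axis position
  r_cord0 <- sqrt(targets[["spinal_cord"]] / (pi * spec$height))
  r_canal0 <- r_cord0 + spec$canal_wall
  y_canal <- spec$body_semiaxes[2] + spec$canal_gap + r_canal0

  half_x <- max(1.15 * spec$outer_semiaxes[1], spec$lesion_semiaxes[1] + 4)
  half_y <- max(1.15 * spec$outer_semiaxes[2], y_canal + r_canal0 + 3)
  nx <- as.integer(ceiling(2 * half_x / p))
  ny <- as.integer(ceiling(2 * half_y / p))
  nz <- as.integer(round(spec$height / p))
  if (nz < 1) stop("pitch exceeds phantom height", call. = FALSE)
  origin <- -c(nx, ny, nz) * p / 2
  xc <- origin[1] + (seq_len(nx) - 0.5) * p
  yc <- origin[2] + (seq_len(ny) - 0.5) * p
  zc <- origin[3] + (seq_len(nz) - 0.5) * p

  nvox <- nx * ny * nz
  idx <- seq_len(nvox)
  X <- rep(xc, times = ny * nz)
  Y <- rep(rep(yc, each = nx), times = nz)
  Z <- rep(zc, each = nx * ny)

  jit <- if (spec$jitter_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$rng_seed)
    stats::rnorm(nvox, sd = spec$jitter_sd)
  } else 0

  # --- spinal cord: cylinder about the canal axis (full height)
  r2_canal <- X^2 + (Y - y_canal)^2
  lv_cord <- .tiebreak(r2_canal / r_cord0^2 + jit, idx)
  th_cord <- .level_threshold(lv_cord, n_tar[["spinal_cord"]])
  if (is.na(th_cord)) stop("infeasible spec: grid too small for spinal cord",
                           call. = FALSE)
  cord <- lv_cord <= th_cord
  r_cord <- r_cord0 * sqrt(max(th_cord, 0))
  canal <- !cord & (r2_canal <= (r_cord + spec$canal_wall)^2)

  # --- metastasis: ellipsoid, in-plane axes scaled
  a <- spec$lesion_semiaxes
  off <- spec$lesion_offset
  lesion <- rep(FALSE, nvox)
  if (n_tar[["metastasis"]] > 0) {
    les_n <- ((X - off[1]) / a[1])^2 + ((Y - off[2]) / a[2])^2 +
      ((Z - off[3]) / a[3])^2
    elig <- !cord & !canal
    lv_les <- .tiebreak(les_n + jit, idx)
    pool <- lv_les[elig]
    th_les <- .level_threshold(pool, n_tar[["metastasis"]])
    if (is.na(th_les)) {
      stop("infeasible spec: lesion volume exceeds space inside the grid ",
           "(limiting dimension: lesion semi-axes)", call. = FALSE)
    }
    lesion <- elig & (lv_les <= th_les)
  }

  # --- vertebral body: elliptic cylinder; bone = body minus lesion/canal
  b <- spec$body_semiaxes
  body_n <- (X / b[1])^2 + (Y / b[2])^2
  elig_bone <- !cord & !canal & !lesion
  lv_body <- .tiebreak(body_n + jit, idx)
  th_body <- .level_threshold(lv_body[elig_bone], n_tar[["bone"]])
  if (is.na(th_body)) {
    stop("infeasible spec: bone volume exceeds space inside the grid ",
         "(limiting dimension: body semi-axes)", call. = FALSE)
  }
  bone <- elig_bone & (lv_body <= th_body)
  # the lesion must not poke out of the vertebral body into muscle
  if (any(lesion & (body_n > max(th_body, 1e-12) * 1.0001))) {
    stop("infeasible spec: lesion breaches the vertebral body ",
         "(limiting dimension: bone volume vs lesion semi-axes)",
         call. = FALSE)
  }

  # --- muscle: outer elliptic boundary; canal space counts as muscle
  o <- spec$outer_semiaxes
  outer_n <- (X / o[1])^2 + (Y / o[2])^2
  forced <- canal                      # soft tissue inside the canal
  n_musc_free <- n_tar[["muscle"]] - sum(forced)
  if (n_musc_free < 0) {
    stop("infeasible spec: canal space alone exceeds the muscle volume",
         call. = FALSE)
  }
  elig_musc <- !cord & !canal & !lesion & !bone
  lv_out <- .tiebreak(outer_n + jit, idx)
  th_out <- .level_threshold(lv_out[elig_musc], n_musc_free)
  if (is.na(th_out)) {
    stop("infeasible spec: muscle volume exceeds the grid ",
         "(limiting dimension: outer semi-axes)", call. = FALSE)
  }
  muscle <- forced | (elig_musc & (lv_out <= th_out))

  codes <- label_codes()
  labels <- integer(nvox)
  labels[muscle] <- codes[["muscle"]]
  labels[bone] <- codes[["bone"]]
  labels[lesion] <- codes[["metastasis"]]
  labels[cord] <- codes[["spinal_cord"]]
  dim(labels) <- c(nx, ny, nz)

  structure(list(labels = labels, spacing = c(p, p, p), origin = origin,
                 meta = list(spec = spec, r_cord = r_cord,
                             y_canal = y_canal,
                             lesion_scale = if (n_tar[["metastasis"]] > 0)
                               sqrt(max(th_les, 0)) else 0,
                             body_scale = sqrt(max(th_body, 0)),
                             outer_scale = sqrt(max(th_out, 0)))),
            class = "label_volume")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Per-tissue volumes of a label volume
#'
#' @param vol A `label_volume`.
#' @return Named numeric vector of volumes in cm^3 (one entry per tissue
#'   role present in [label_codes()], excluding `outside`).
#' @export
tissue_volumes <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  codes <- label_codes()
  voxvol <- prod(vol$spacing)
  counts <- tabulate(vol$labels + 1L, nbins = length(codes))
  v <- counts * voxvol / 1000
  names(v) <- names(codes)
  v[setdiff(names(codes), "outside")]
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d voxels, %.3g mm pitch\n",
              d[1], d[2], d[3], x$spacing[1]))
  v <- tissue_volumes(x)
  for (tis in names(v)) cat(sprintf("  %-12s %8.2f cm^3\n", tis, v[[tis]]))
  invisible(x)
}

# Voxel-centre coordinates of a label volume along each axis (mm).
.grid_axes <- function(vol) {
  d <- dim(vol$labels)
  lapply(1:3, function(k) vol$origin[k] + (seq_len(d[k]) - 0.5) * vol$spacing[k])
}

# Centroid (mm) of a tissue label; NULL if absent.
.label_centroid <- function(vol, tissue) {
  code <- label_codes()[[tissue]]
  w <- which(vol$labels == code, arr.ind = TRUE)
  if (nrow(w) == 0) return(NULL)
  ax <- .grid_axes(vol)
  c(mean(ax[[1]][w[, 1]]), mean(ax[[2]][w[, 2]]), mean(ax[[3]][w[, 3]]))
}
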