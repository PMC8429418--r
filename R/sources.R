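# Interstitial light-source models: cut-end fibres emitting a forward cone
# set by their numerical aperture, and cylindrical diffusers emitting
# radially along their length. Sources are placed in lesion-centred
# coordinates (mm) and sampled as emission distributions by the transport
# core.

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized", call. = FALSE)
  v / n
}

#' Cut-end fibre source
#'
#' Emits from a flat fibre tip: positions uniform on the core disc,
#' directions uniform in solid angle within the acceptance cone of
#' half-angle `asin(NA / n_medium)` about the fibre axis (NA is specified
#' in air; the in-tissue half-angle uses the local refractive index).
#'
#' @param tip_position Tip centre, mm (length-3).
#' @param axis Emission axis (normalized internally).
#' @param core_radius Core radius, mm (default 0.2, i.e. 400 um diameter).
#' @param na Numerical aperture (default 0.22).
#' @return A `cut_end_fibre` / `pdt_source` object.
#' @export
cut_end_fibre <- function(tip_position, axis, core_radius = 0.2, na = 0.22) {
  stopifnot(length(tip_position) == 3, length(axis) == 3,
            core_radius > 0, na > 0)
  structure(list(type = "cut_end", tip_position = as.numeric(tip_position),
                 axis = .normalize(as.numeric(axis)),
                 core_radius = core_radius, na = na),
            class = c("cut_end_fibre", "pdt_source"))
}

#' Cylindrical diffuser source
#'
#' Emits from the lateral surface of a cylinder: positions uniform along
#' the axis (uniform linear power density), directions cosine-weighted
#' (Lambertian) about the outward radial normal. End caps do not emit.
#'
#' @param endpoint_a,endpoint_b Cylinder axis endpoints, mm.
#' @param radius Diffuser radius, mm (default 0.5).
#' @return A `cylindrical_diffuser` / `pdt_source` object.
#' @export
cylindrical_diffuser <- function(endpoint_a, endpoint_b, radius = 0.5) {
  stopifnot(length(endpoint_a) == 3, length(endpoint_b) == 3, radius > 0)
  if (sqrt(sum((endpoint_a - endpoint_b)^2)) <= 0) {
    stop("diffuser endpoints must be distinct", call. = FALSE)
  }
  structure(list(type = "diffuser", endpoint_a = as.numeric(endpoint_a),
                 endpoint_b = as.numeric(endpoint_b), radius = radius),
            class = c("cylindrical_diffuser", "pdt_source"))
}

#' Isotropic point source (validation geometry)
#'
#' @param position Source position, mm.
#' @return A `point_source` / `pdt_source` object.
#' @export
point_source <- function(position) {
  stopifnot(length(position) == 3)
  structure(list(type = "point", position = as.numeric(position)),
            class = c("point_source", "pdt_source"))
}

# Internal: translate a source to the list consumed by the C++ core.
# n_medium is the refractive index at the emission site (cut-end cone only).
.source_cpp <- function(source, n_medium = 1.4) {
  switch(source$type,
    point = list(kind = 0L, position = source$position),
    cut_end = {
      if (source$na >= n_medium) {
        stop("numerical aperture must be smaller than the medium index",
             call. = FALSE)
      }
      list(kind = 1L, position = source$tip_position, axis = source$axis,
           radius = source$core_radius,
           cos_max = cos(asin(source$na / n_medium)))
    },
    diffuser = list(kind = 2L, position = source$endpoint_a,
                    endpoint_b = source$endpoint_b, radius = source$radius),
    stop("unknown source type", call. = FALSE)
  )
}

#' Sample emission positions and directions from a source
#'
#' @param source A `pdt_source`.
#' @param n Number of samples.
#' @param n_medium Refractive index of the medium at the emission site
#'   (sets the in-tissue acceptance cone of a cut-end fibre).
#' @param seed,stream RNG seed and stream (deterministic).
#' @return List with `positions` (n x 3, mm), `directions` (n x 3, unit
#'   vectors), `weights` (all 1 at launch).
#' @export
sample_emission <- function(source, n = 1000L, n_medium = 1.4,
                            seed = 1L, stream = 0L) {
  stopifnot(inherits(source, "pdt_source"), n >= 1)
  .sample_emission_cpp(.source_cpp(source, n_medium), as.integer(n),
                       as.integer(seed), as.integer(stream))
}

# Geometry summary of the lesion used for default source placement.
.lesion_geometry <- function(vol) {
  codes <- label_codes()
  w <- which(vol$labels == codes[["metastasis"]], arr.ind = TRUE)
  if (nrow(w) == 0) stop("phantom contains no metastasis voxels",
                         call. = FALSE)
  ax <- .grid_axes(vol)
  pts <- cbind(ax[[1]][w[, 1]], ax[[2]][w[, 2]], ax[[3]][w[, 3]])
  centroid <- colMeans(pts)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  half_extents <- apply(pts, 2, function(c) diff(range(c)) / 2)
  cord_centroid <- .label_centroid(vol, "spinal_cord")
  list(centroid = centroid, axes = ev$vectors, half_extents = half_extents,
       points = pts, cord_centroid = cord_centroid)
}

.inside_label <- function(vol, pos, tissue) {
  d <- dim(vol$labels)
  i <- floor((pos - vol$origin) / vol$spacing) + 1
  if (any(i < 1) || any(i > d)) return(FALSE)
  vol$labels[i[1], i[2], i[3]] == label_codes()[[tissue]]
}

#' Default source configurations of the planning study
#'
#' `cut_end_4`: four cut-end fibres around the lesion centroid, each axis
#' tilted 45 degrees away from the direction of the spinal cord.
#' `diffuser_2`: two parallel cylindrical diffusers spanning the lesion's
#' long axis, symmetric about the centroid, with length equal to the local
#' lesion chord minus a margin.
#'
#' @param kind `"cut_end_4"` or `"diffuser_2"`.
#' @param vol A `label_volume` containing a metastasis.
#' @param tip_spread Fraction of the in-plane lesion half-extent at which
#'   cut-end tips are placed.
#' @param diffuser_offset_frac Fraction of the lesion half-extent (third
#'   axis) at which the two diffusers are offset from the centroid.
#' @param length_margin Shortening of each diffuser relative to the lesion
#'   chord at its position, mm.
#' @param ... Passed to the source constructors (`core_radius`, `na`,
#'   `radius`).
#' @return List of `pdt_source` objects, all inside the metastasis label.
#' @export
default_configuration <- function(kind = c("cut_end_4", "diffuser_2"), vol,
                                  tip_spread = 0.3,
                                  diffuser_offset_frac = 0.25,
                                  length_margin = 4, ...) {
  kind <- match.arg(kind)
  geo <- .lesion_geometry(vol)
  ctr <- geo$centroid
  if (is.null(geo$cord_centroid)) {
    stop("phantom contains no spinal cord; cannot orient sources",
         call. = FALSE)
  }
  cord_dir <- .normalize(geo$cord_centroid - ctr)
  sources <- if (kind == "cut_end_4") {
    # two in-plane directions perpendicular to the cord direction
    u1 <- .perp_unit(cord_dir)
    u2 <- .normalize(cross3(cord_dir, u1))
    dirs <- list(u1, -u1, u2, -u2)
    lapply(dirs, function(u) {
      tip <- ctr + tip_spread * sum(abs(u) * geo$half_extents) * u
      cut_end_fibre(tip, .normalize(u - cord_dir), ...)
    })
  } else {
    long <- geo$axes[, 1]
    if (abs(sum(long * cord_dir)) > 0.7) long <- geo$axes[, 2]
    third <- .normalize(cross3(long, cord_dir))
    off <- diffuser_offset_frac * sum(abs(third) * geo$half_extents)
    lapply(c(-1, 1), function(s) {
      base <- ctr + s * off * third
      # lesion chord along `long` through `base`
      rel <- sweep(geo$points, 2, base)
      near <- rowSums((rel - outer(rel %*% long, long)[, , 1])^2) < 4
      tproj <- (rel %*% long)[near]
      if (!length(tproj)) stop("diffuser line misses the lesion",
                               call. = FALSE)
      half <- (max(tproj) - min(tproj)) / 2 - length_margin / 2
      mid <- base + long * (max(tproj) + min(tproj)) / 2
      cylindrical_diffuser(mid - half * long, mid + half * long, ...)
    })
  }
  for (s in sources) {
    anchor <- if (s$type == "cut_end") s$tip_position
              else (s$endpoint_a + s$endpoint_b) / 2
    ends_ok <- if (s$type == "diffuser") {
      .inside_label(vol, s$endpoint_a, "metastasis") &&
        .inside_label(vol, s$endpoint_b, "metastasis")
    } else TRUE
    if (!.inside_label(vol, anchor, "metastasis") || !ends_ok) {
      stop("source placement outside the metastasis label", call. = FALSE)
    }
  }
  sources
}

# First convenient unit vector perpendicular to v.
.perp_unit <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  .normalize(cross3(v, ref))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
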