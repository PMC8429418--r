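# R surface of the voxel Monte Carlo transport core: per-source fluence
# kernels (fluence per unit emitted energy, mm^-2), Henyey-Greenstein
# sampling, Fresnel reflectance, and the diffusion-theory point-source
# oracle used for validation.

#' Henyey-Greenstein scattering-angle cosine (inverse-CDF sample)
#'
#' @param g Anisotropy, |g| < 1.
#' @param u Uniform variates in \[0, 1).
#' @return cos(theta) samples; uniform on \[-1, 1) when `g = 0`.
#' @export
hg_sample <- function(g, u) {
  if (!is.finite(g) || abs(g) >= 1) {
    stop("anisotropy g must satisfy |g| < 1", call. = FALSE)
  }
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)", call. = FALSE)
  .hg_sample_cpp(g, as.numeric(u))
}

#' Unpolarized Fresnel reflectance at a planar interface
#'
#' @param n1,n2 Refractive indices of the incident and transmitting media.
#' @param cos_incident Cosine of the incidence angle, in (0, 1].
#' @return Reflection probability; 1 beyond the critical angle.
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (any(cos_incident <= 0 | cos_incident > 1)) {
    stop("cos_incident must lie in (0, 1]", call. = FALSE)
  }
  .fresnel_cpp(n1, n2, as.numeric(cos_incident))
}

#' Diffusion-approximation fluence of an isotropic point source
#'
#' Closed form `1/(4 pi D r) * exp(-mu_eff r)` with
#' `D = 1 / (3 (mu_a + mu_s (1 - g)))` and
#' `mu_eff = sqrt(3 mu_a (mu_a + mu_s (1 - g)))`, per unit emitted energy in
#' an infinite homogeneous medium. Used as an independent oracle for the
#' Monte Carlo kernels; accurate when `mu_s (1 - g) >> mu_a` (a warning is
#' issued otherwise).
#'
#' @param optics An [optical_properties()] object.
#' @param r Distance from the source, mm (> 0).
#' @return Fluence per unit energy, mm^-2.
#' @export
diffusion_point_source <- function(optics, r) {
  stopifnot(inherits(optics, "optical_properties"))
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  mus_p <- optics$mu_s * (1 - optics$g)
  if (mus_p < 10 * optics$mu_a) {
    warning("diffusion approximation is inaccurate: mu_s' is not >> mu_a",
            call. = FALSE)
  }
  D <- 1 / (3 * (optics$mu_a + mus_p))
  mu_eff <- sqrt(3 * optics$mu_a * (optics$mu_a + mus_p))
  exp(-mu_eff * r) / (4 * pi * D * r)
}

#' Simulate a per-source fluence kernel by voxel Monte Carlo
#'
#' Launches photon packets from `source`, propagates them through the
#' labelled voxel grid with free paths sampled from the local interaction
#' coefficient, attenuates packet weight by the single-scatter albedo at
#' each collision, scores fluence with the track-length estimator, applies
#' Fresnel reflection/refraction at voxel faces where the refractive index
#' changes, and terminates packets by Russian roulette or on leaving the
#' tissue (escape). The returned kernel is fluence per unit emitted energy
#' (mm^-2): multiplying by a source energy in J gives J/mm^2.
#'
#' @param vol A `label_volume`.
#' @param lib A [tissue_library()] at the desired wavelength.
#' @param source A `pdt_source`.
#' @param n_packets Number of photon packets (>= 1000).
#' @param seed,stream RNG master seed and per-source stream index; the pair
#'   makes the kernel bit-reproducible.
#' @param roulette_weight Weight below which Russian roulette is played.
#' @param roulette_survive Survival probability of the roulette.
#' @param n_batches Batches used for the per-voxel relative standard error.
#' @param n_outside Refractive index of the non-tissue exterior (1 = air;
#'   set equal to the tissue index for matched-boundary validation runs).
#' @param max_events Safety cap on interactions per packet.
#' @return A `fluence_kernel`: `fluence` and `rel_se` arrays, energy
#'   bookkeeping (`absorbed`, `escaped`, `roulette_net`, all per unit
#'   launched energy), and provenance fields.
#' @export
simulate_kernel <- function(vol, lib, source, n_packets = 1e5,
                            seed = 1L, stream = 0L,
                            roulette_weight = 1e-4, roulette_survive = 0.1,
                            n_batches = 16L, n_outside = 1.0,
                            max_events = 2e6) {
  stopifnot(inherits(vol, "label_volume"), inherits(lib, "tissue_library"),
            inherits(source, "pdt_source"))
  if (n_packets < 1e3) stop("n_packets must be >= 1000", call. = FALSE)
  anchor <- switch(source$type, point = source$position,
                   cut_end = source$tip_position,
                   diffuser = (source$endpoint_a + source$endpoint_b) / 2)
  d <- dim(vol$labels)
  i <- floor((anchor - vol$origin) / vol$spacing) + 1
  if (any(i < 1) || any(i > d) || vol$labels[i[1], i[2], i[3]] == 0) {
    stop("source lies outside the tissue volume", call. = FALSE)
  }
  n_medium <- {
    code <- vol$labels[i[1], i[2], i[3]]
    tis <- names(which(label_codes() == code))
    tl_optics(lib, tis)$n
  }
  om <- .optics_matrix(lib, n_outside = n_outside)
  res <- .mc_kernel_cpp(vol$labels, as.integer(d), as.numeric(vol$spacing),
                        as.numeric(vol$origin), om,
                        .source_cpp(source, n_medium),
                        as.integer(n_packets), as.integer(seed),
                        as.integer(stream), roulette_weight,
                        roulette_survive, as.integer(n_batches),
                        as.integer(max_events))
  structure(list(fluence = res$fluence, rel_se = res$rel_se,
                 absorbed = res$absorbed, escaped = res$escaped,
                 roulette_net = res$roulette_net,
                 n_packets = as.integer(n_packets),
                 seed = as.integer(seed), stream = as.integer(stream),
                 wavelength = lib$wavelength, source = source,
                 spacing = vol$spacing, origin = vol$origin),
            class = "fluence_kernel")
}

#' Simulate kernels for a list of sources
#'
#' Each source gets its own RNG stream derived from its index, so the set
#' is reproducible from one master seed.
#'
#' @inheritParams simulate_kernel
#' @param sources List of `pdt_source` objects.
#' @param ... Passed to [simulate_kernel()].
#' @return List of `fluence_kernel` objects.
#' @export
simulate_kernels <- function(vol, lib, sources, n_packets = 1e5,
                             seed = 1L, ...) {
  stopifnot(length(sources) >= 1)
  lapply(seq_along(sources), function(j) {
    simulate_kernel(vol, lib, sources[[j]], n_packets = n_packets,
                    seed = seed, stream = j - 1L, ...)
  })
}

#' @export
print.fluence_kernel <- function(x, ...) {
  cat(sprintf(
    "fluence_kernel: %s source, %d nm, %g packets (seed %d / stream %d)\n",
    x$source$type, x$wavelength, x$n_packets, x$seed, x$stream))
  cat(sprintf("  absorbed %.4f  escaped %.4f per unit energy\n",
              x$absorbed, x$escaped))
  invisible(x)
}
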