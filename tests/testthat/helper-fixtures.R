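# Shared fixtures: small homogeneous boxes and cached phantoms. Everything
# is generated in code; expensive objects are built once per test run.

# Homogeneous cubic volume of one tissue label, centred at the origin.
homogeneous_box <- function(n = 41, pitch = 1, tissue = "muscle") {
  lab <- array(label_codes()[[tissue]], dim = c(n, n, n))
  structure(list(labels = lab, spacing = rep(pitch, 3),
                 origin = rep(-n * pitch / 2, 3), meta = list()),
            class = "label_volume")
}

# Radial distance of every voxel centre from the origin.
box_radii <- function(vol) {
  ax <- lapply(1:3, function(k) {
    vol$origin[k] + (seq_len(dim(vol$labels)[k]) - 0.5) * vol$spacing[k]
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  sqrt(g$x^2 + g$y^2 + g$z^2)
}

# A tissue library with fast metastasis optics (moderate absorption, low
# scattering), used where transport speed matters more than tissue realism.
fast_lib <- function(wavelength = 690) {
  lib <- tissue_library(wavelength, "lytic")
  lib$tissues$metastasis$optics <- optical_properties(0.1, 10, 0.9, 1.41)
  lib
}

# Cache: the reference-case phantom at coarse pitch (shared by optimizer
# and evaluation tests).
.cache <- new.env(parent = emptyenv())
coarse_phantom <- function() {
  if (is.null(.cache$phantom)) {
    .cache$phantom <- build_vertebra_phantom(phantom_spec(pitch = 2.5))
  }
  .cache$phantom
}

# A tiny all-metastasis slab with two mirror-symmetric cut-end fibres and
# precomputed kernels (fast optics); shared by optimizer tests.
symmetric_pair <- function(n_packets = 1.5e5) {
  if (is.null(.cache$sympair)) {
    vol <- homogeneous_box(31, 1, "metastasis")
    lib <- fast_lib()
    s1 <- cut_end_fibre(c(-5, 0, 0), c(-1, 0, 0))
    s2 <- cut_end_fibre(c(5, 0, 0), c(1, 0, 0))
    kernels <- simulate_kernels(vol, lib, list(s1, s2),
                                n_packets = n_packets, seed = 42)
    .cache$sympair <- list(vol = vol, lib = lib, kernels = kernels)
  }
  .cache$sympair
}
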