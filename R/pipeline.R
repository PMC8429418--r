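# One-call pipeline: phantom -> sources -> kernels -> plan -> report.

#' Run the full planning pipeline on a phantom
#'
#' Builds (or accepts) a labelled phantom, places the default source
#' configuration, simulates per-source fluence kernels, optimizes the
#' per-source energies, and evaluates the resulting dose.
#'
#' @param spec A [phantom_spec()] (ignored when `vol` is given).
#' @param vol Optional pre-built `label_volume`.
#' @param wavelength 690 or 565 (nm).
#' @param source_kind `"cut_end_4"` or `"diffuser_2"`.
#' @param mode Planning mode, `"coverage"` or `"sparing"`.
#' @param n_packets Packets per source.
#' @param seed Master RNG seed.
#' @param cfg Optional [plan_config()]; defaults to the mode's defaults.
#' @param ... Passed to [simulate_kernel()].
#' @return List with `phantom`, `lib`, `sources`, `kernels`, `plan`,
#'   `dose`, `report`.
#' @export
plan_case <- function(spec = phantom_spec(), vol = NULL, wavelength = 690,
                      source_kind = c("cut_end_4", "diffuser_2"),
                      mode = c("coverage", "sparing"),
                      n_packets = 1e5, seed = 1L, cfg = NULL, ...) {
  source_kind <- match.arg(source_kind)
  mode <- match.arg(mode)
  if (is.null(vol)) vol <- build_vertebra_phantom(spec)
  lesion_type <- vol$meta$spec$lesion_type %||% "sclerotic"
  lib <- tissue_library(wavelength, lesion_type)
  sources <- default_configuration(source_kind, vol)
  kernels <- simulate_kernels(vol, lib, sources, n_packets = n_packets,
                              seed = seed, ...)
  cfg <- cfg %||% plan_config(mode = mode)
  plan <- if (mode == "coverage") {
    optimize_coverage(kernels, vol, lib, cfg)
  } else {
    optimize_sparing(kernels, vol, lib, cfg)
  }
  dose <- superpose_dose(kernels, plan$energies)
  report <- damage_report(dose, vol, lib, plan)
  list(phantom = vol, lib = lib, sources = sources, kernels = kernels,
       plan = plan, dose = dose, report = report)
}
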