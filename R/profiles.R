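#' Construct a per-condition effect profile for the image generator
#'
#' An effect profile encodes the condition-level means that the synthetic
#' microscopy generator renders and that the image pipeline must recover:
#' nuclear geometry (radius, axis ratio, centroid displacement), nuclear and
#' cytoplasmic target-protein intensity, and the actin stress-fiber regime.
#' Intensities are arbitrary units; condition effects are therefore encoded
#' as ratios of channel means between profiles, not absolute values.
#'
#' @param condition_name condition label.
#' @param cells_per_image cells placed per image (>= 1).
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus equivalent radius
#'   (pixels; geometric mean of the semi-axes).
#' @param nucleus_axis_ratio_mean target minor/major axis ratio in (0, 1].
#' @param nucleus_displacement_frac_mean nuclear centroid offset as a
#'   fraction of the cell radius (>= 0, < 0.7).
#' @param yap_nuclear_mean,yap_cyto_mean protein-channel intensity inside
#'   the nucleus / in the cytoplasm (a.u.).
#' @param fiber_count_mean Poisson mean of stress fibers per cell.
#' @param fiber_length_mean,fiber_length_sd fiber length (pixels).
#' @param background_level,noise_sd background intensity and additive
#'   Gaussian noise s.d. (a.u., all channels).
#' @return a validated `hq_profile` list.
#' @export
effect_profile <- function(condition_name,
                           cells_per_image = 9,
                           nucleus_radius_mean = 16,
                           nucleus_radius_sd = 1.5,
                           nucleus_axis_ratio_mean = 0.85,
                           nucleus_displacement_frac_mean = 0.05,
                           yap_nuclear_mean = 180,
                           yap_cyto_mean = 80,
                           fiber_count_mean = 4,
                           fiber_length_mean = 45,
                           fiber_length_sd = 8,
                           background_level = 20,
                           noise_sd = 6) {
  p <- list(
    condition_name = as.character(condition_name),
    cells_per_image = as.integer(cells_per_image),
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    nucleus_axis_ratio_mean = nucleus_axis_ratio_mean,
    nucleus_displacement_frac_mean = nucleus_displacement_frac_mean,
    yap_nuclear_mean = yap_nuclear_mean,
    yap_cyto_mean = yap_cyto_mean,
    fiber_count_mean = fiber_count_mean,
    fiber_length_mean = fiber_length_mean,
    fiber_length_sd = fiber_length_sd,
    background_level = background_level,
    noise_sd = noise_sd
  )
  validate_profile(p)
  class(p) <- "hq_profile"
  p
}

validate_profile <- function(p) {
  num <- c("nucleus_radius_mean", "nucleus_radius_sd",
           "nucleus_axis_ratio_mean", "nucleus_displacement_frac_mean",
           "yap_nuclear_mean", "yap_cyto_mean", "fiber_count_mean",
           "fiber_length_mean", "fiber_length_sd", "background_level",
           "noise_sd")
  for (f in num) {
    assert_that(is.numeric(p[[f]]) && length(p[[f]]) == 1 && is.finite(p[[f]]),
                paste0("profile field '", f, "' must be a finite number"))
    assert_that(p[[f]] >= 0, paste0("profile field '", f, "' must be >= 0"))
  }
  assert_that(p$cells_per_image >= 1, "cells_per_image must be >= 1")
  assert_that(p$nucleus_axis_ratio_mean > 0 && p$nucleus_axis_ratio_mean <= 1,
              "nucleus_axis_ratio_mean must be in (0, 1]")
  assert_that(p$nucleus_displacement_frac_mean < 0.7,
              "nucleus_displacement_frac_mean must be < 0.7 so the nucleus stays inside the cell")
  assert_that(p$nucleus_radius_mean >= 4, "nucleus_radius_mean must be >= 4 px")
  invisible(p)
}

#' Read an effect profile from a YAML file
#'
#' The packaged fixtures `profiles/wt.yaml`, `profiles/ksr1_null.yaml` and
#' `profiles/ksr1_oe.yaml` transcribe the condition effects of the wild-type,
#' scaffold-knockout and scaffold-overexpressing cells as channel-mean ratios
#' (e.g. nuclear protein intensity in the knockout = 0.62 x wild type).
#'
#' @param path YAML file with the fields of [effect_profile()].
#' @export
read_profile <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(effect_profile, y)
}
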