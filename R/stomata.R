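#' Physical constants for anatomical conductance
#'
#' Container for the two gas-exchange constants entering the anatomical
#' maximum stomatal conductance: the diffusivity of water vapour in air and
#' the molar volume of air. Defaults are the 25 degC values.
#'
#' @param dw Diffusivity of water in air, m^2 s^-1. Default `2.49e-5`.
#' @param v Molar volume of air, m^3 mol^-1. Default `0.0224`.
#' @return A named list of class `gas_exchange_constants`.
#' @export
#' @examples
#' gas_exchange_constants()
gas_exchange_constants <- function(dw = 2.49e-5, v = 0.0224) {
  check_scalar(dw, "dw", lower = 0, allow_lower = FALSE)
  check_scalar(v, "v", lower = 0, allow_lower = FALSE)
  structure(list(dw = dw, v = v), class = "gas_exchange_constants")
}

#' Effective stomatal count per image
#'
#' Weighted count of detected stomata: complete objects count 1, incomplete
#' objects 0.5. Blurry detections and trichomes are excluded: they indicate
#' an object was seen but not measurable, so they contribute neither to
#' density nor to dimensions.
#'
#' @param counts Data frame with integer columns `n_complete` and
#'   `n_incomplete` (one row per image; further columns such as
#'   `n_blurry_complete` or `n_trichome` are ignored).
#' @return Numeric vector of effective counts, one per row of `counts`.
#' @export
#' @examples
#' effective_stomatal_count(data.frame(n_complete = 4, n_incomplete = 2))
effective_stomatal_count <- function(counts) {
  check_columns(counts, c("n_complete", "n_incomplete"), "counts")
  if (any(counts$n_complete < 0 | counts$n_incomplete < 0, na.rm = TRUE)) {
    abort("Stomatal counts must be non-negative.")
  }
  counts$n_complete + 0.5 * counts$n_incomplete
}

#' Stomatal density from effective counts
#'
#' @param effective_count Numeric vector of effective stomata per image.
#' @param image_area_mm2 Imaged leaf area in mm^2; default 0.806, the field
#'   of view of the acquisition setup.
#' @return Density in m^-2 (multiply by `1e-6` for mm^-2).
#' @export
stomatal_density <- function(effective_count, image_area_mm2 = 0.806) {
  check_scalar(image_area_mm2, "image_area_mm2", lower = 0,
               allow_lower = FALSE)
  if (any(effective_count < 0, na.rm = TRUE)) {
    abort("`effective_count` must be non-negative.")
  }
  effective_count / (image_area_mm2 * 1e-6)
}

#' Maximum stomatal pore area
#'
#' The fully open pore is modelled as an ellipse whose major axis is the
#' pore length and whose minor axis is half the pore length. With pore
#' length taken as half the stomatal length (`pore_length = "half"`, the
#' default convention) this gives `pa_max = pi * SL^2 / 32`. The stricter
#' quarter-length reading is available as `pore_length = "quarter"`
#' (`pa_max = pi * SL^2 / 128`).
#'
#' @param sl_m Stomatal length (guard-cell long axis) in metres.
#' @param pore_length Either `"half"` (pore length = SL/2) or `"quarter"`
#'   (SL/4).
#' @return Maximum pore area in m^2.
#' @export
max_pore_area <- function(sl_m, pore_length = c("half", "quarter")) {
  pore_length <- match.arg(pore_length)
  if (any(sl_m < 0, na.rm = TRUE)) abort("`sl_m` must be non-negative.")
  pl <- if (pore_length == "half") sl_m / 2 else sl_m / 4
  # ellipse: semi-major pl/2, semi-minor pl/4 => area = pi * pl^2 / 8
  pi * pl^2 / 8
}

#' Anatomical maximum stomatal conductance
#'
#' Diffusion-limited upper bound on stomatal conductance to water vapour
#' computed from anatomy alone:
#'
#' \deqn{g_{max} = \frac{(d_w / v)\, SD \, pa_{max}}
#'                      {pd + (\pi/2)\sqrt{pa_{max}/\pi}}}
#'
#' with stomatal density \eqn{SD} (m^-2), maximum pore area
#' \eqn{pa_{max}} (m^2, see [max_pore_area()]) and pore depth \eqn{pd}
#' taken equal to the stomatal width. gmax is linear in density and zero
#' when no stomata are present.
#'
#' @param sd_m2 Stomatal density, m^-2.
#' @param sl_m Stomatal length, m.
#' @param sw_m Stomatal width, m (used as pore depth).
#' @param constants A [gas_exchange_constants()] object.
#' @param pore_length Passed to [max_pore_area()].
#' @return Conductance in mol m^-2 s^-1.
#' @export
#' @examples
#' gmax(sd_m2 = 5e7, sl_m = 50e-6, sw_m = 25e-6)
gmax <- function(sd_m2, sl_m, sw_m, constants = gas_exchange_constants(),
                 pore_length = c("half", "quarter")) {
  if (!inherits(constants, "gas_exchange_constants")) {
    abort("`constants` must come from gas_exchange_constants().")
  }
  if (any(sd_m2 < 0, na.rm = TRUE)) abort("`sd_m2` must be non-negative.")
  if (any(sw_m > sl_m, na.rm = TRUE)) {
    warn("Some stomatal widths exceed lengths; check unit conventions.")
  }
  pa <- max_pore_area(sl_m, pore_length)
  denom <- sw_m + (pi / 2) * sqrt(pa / pi)
  if (any(denom <= 0, na.rm = TRUE)) {
    abort("Pore depth and pore area are both zero: gmax undefined.")
  }
  (constants$dw / constants$v) * sd_m2 * pa / denom
}

#' Per-image stomatal traits
#'
#' Turns object-detection counts and mean guard-cell dimensions into the
#' derived anatomy: effective count, density (mm^-2 and m^-2), stomatal
#' size, maximum pore area and anatomical gmax.
#'
#' @param detections Data frame with one row per image: `image_id`,
#'   `n_complete`, `n_incomplete`, mean `sl_um` and `sw_um` (micrometres);
#'   optional `image_area_mm2` column overrides the default area.
#' @param image_area_mm2 Default image area when no per-image column given.
#' @inheritParams gmax
#' @return A tibble, one row per image, with columns `effective_count`,
#'   `sd_mm2`, `sd_m2`, `ss_m2`, `pa_max_m2`, `gmax_mol_m2_s`.
#' @export
stomatal_traits <- function(detections, image_area_mm2 = 0.806,
                            constants = gas_exchange_constants(),
                            pore_length = c("half", "quarter")) {
  check_columns(detections, c("image_id", "n_complete", "n_incomplete",
                              "sl_um", "sw_um"), "detections")
  pore_length <- match.arg(pore_length)
  area <- detections$image_area_mm2 %||% rep(image_area_mm2,
                                             nrow(detections))
  eff <- effective_stomatal_count(detections)
  sd_m2 <- mapply(stomatal_density, eff, area)
  sl_m <- detections$sl_um * 1e-6
  sw_m <- detections$sw_um * 1e-6
  tibble::tibble(
    image_id = detections$image_id,
    effective_count = eff,
    sd_mm2 = sd_m2 * 1e-6,
    sd_m2 = sd_m2,
    ss_m2 = sl_m * sw_m,
    pa_max_m2 = max_pore_area(sl_m, pore_length),
    gmax_mol_m2_s = gmax(sd_m2, sl_m, sw_m, constants, pore_length)
  )
}

#' Combine abaxial and adaxial surfaces into leaf-level gmax
#'
#' For amphistomatous leaves gmax is computed per surface and the leaf value
#' is the sum of the two surface conductances (parallel diffusion paths).
#' The alternative of pooling anatomy first -- summing densities and
#' averaging dimensions across surfaces before applying the conductance
#' formula -- is reported alongside for comparison; the two differ whenever
#' surfaces differ in anatomy, and `gmax_surface_sum` is the value the
#' pipeline treats as the leaf conductance.
#'
#' @param surface_traits Data frame with columns `genotype`, `surface`
#'   (`"abaxial"`/`"adaxial"`), `sd_m2`, `sl_um`, `sw_um`.
#' @inheritParams gmax
#' @return Tibble with one row per genotype: `gmax_surface_sum` and
#'   `gmax_pooled` (mol m^-2 s^-1).
#' @export
leaf_gmax <- function(surface_traits, constants = gas_exchange_constants(),
                      pore_length = c("half", "quarter")) {
  check_columns(surface_traits, c("genotype", "surface", "sd_m2",
                                  "sl_um", "sw_um"), "surface_traits")
  pore_length <- match.arg(pore_length)
  surface_traits |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      gmax_surface_sum = sum(gmax(.data$sd_m2, .data$sl_um * 1e-6,
                                  .data$sw_um * 1e-6, constants,
                                  pore_length)),
      gmax_pooled = gmax(sum(.data$sd_m2), mean(.data$sl_um) * 1e-6,
                         mean(.data$sw_um) * 1e-6, constants, pore_length),
      .groups = "drop"
    )
}
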