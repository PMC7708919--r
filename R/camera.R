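#' Thermal camera model
#'
#' Geometry and noise characteristics of the thermal imager used by the
#' phantom generator: an 80x60 px microbolometer sensor resolving 0.1 deg C
#' with a scene range of -20 to 120 deg C.
#'
#' @param width_px,height_px sensor resolution in pixels (> 0).
#' @param noise_sd i.i.d. Gaussian sensor noise SD, deg C (>= 0).
#' @param scene_min,scene_max measurable scene range, deg C.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(width_px = 80L, height_px = 60L, noise_sd = 0.1,
                         scene_min = -20, scene_max = 120) {
  width_px <- check_count(width_px, "width_px", lower = 1L)
  height_px <- check_count(height_px, "height_px", lower = 1L)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(scene_min, "scene_min")
  check_number(scene_max, "scene_max")
  if (scene_min >= scene_max)
    stop("`scene_min` must be below `scene_max`", call. = FALSE)
  structure(list(width_px = width_px, height_px = height_px,
                 noise_sd = noise_sd,
                 scene_min = scene_min, scene_max = scene_max),
            class = "camera_model")
}

#' True surface-temperature state of one imaged mouse
#'
#' Holds the ground-truth temperatures behind a phantom frame: the four paw
#' (wrist/ankle joint) surface temperatures, the back reference temperature,
#' and the temperature of the heated plate the animal lies on.
#'
#' @param paw_temps named numeric vector with elements FL, FR, HL, HR (deg C).
#' @param back_temp back (fur) surface temperature, deg C.
#' @param plate_temp background plate/pad temperature, deg C (default 34).
#' @param latent_severity four non-negative unitless latent severities
#'   (the disease state driving temperature, swelling and clinical score).
#' @return object of class `mouse_state`.
#' @export
mouse_state <- function(paw_temps, back_temp, plate_temp = 34,
                        latent_severity = c(FL = 0, FR = 0, HL = 0, HR = 0)) {
  paws <- c("FL", "FR", "HL", "HR")
  if (!is.numeric(paw_temps) || length(paw_temps) != 4L)
    stop("`paw_temps` must be four temperatures (FL, FR, HL, HR)", call. = FALSE)
  if (is.null(names(paw_temps))) names(paw_temps) <- paws
  if (!setequal(names(paw_temps), paws))
    stop("`paw_temps` must be named FL, FR, HL, HR", call. = FALSE)
  check_number(back_temp, "back_temp")
  check_number(plate_temp, "plate_temp")
  if (!is.numeric(latent_severity) || length(latent_severity) != 4L ||
      any(!is.finite(latent_severity)) || any(latent_severity < 0))
    stop("`latent_severity` must be four finite values >= 0", call. = FALSE)
  if (is.null(names(latent_severity))) names(latent_severity) <- paws
  structure(list(paw_temps = paw_temps[paws], back_temp = back_temp,
                 plate_temp = plate_temp,
                 latent_severity = latent_severity[paws]),
            class = "mouse_state")
}
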