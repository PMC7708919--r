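#' Generate a phantom thermogram of a prone mouse
#'
#' Paints a piecewise-constant scene -- background plate, elliptical body
#' mask at the back temperature, and four paw ellipses at the paw
#' temperatures -- then adds i.i.d. Gaussian sensor noise. The paw and back
#' reference ellipses coincide with [default_roi_layout()], so with zero
#' noise the ROI mean over each region reproduces the ground-truth
#' temperature exactly.
#'
#' @param state a [mouse_state()] with the ground-truth temperatures.
#' @param camera a [camera_model()].
#' @param seed optional integer seed for the sensor noise.
#' @param emit_apparent if TRUE the frame holds *apparent* radiance
#'   temperatures: each region is pushed through the forward radiometric
#'   model with its tissue emissivity (skin for paws, fur for body/back;
#'   the plate background is treated as a perfect emitter). ROI extraction
#'   then undoes the transform per ROI. Default FALSE (surface
#'   temperatures).
#' @param reflected_temp reflected ambient temperature used when
#'   `emit_apparent = TRUE`, deg C.
#' @return list with elements `frame` (a [thermal_frame()]), `layout` (the
#'   ground-truth [default_roi_layout()]) and `truth` (the `state`).
#' @examples
#' st <- mouse_state(c(FL = 31.9, FR = 28.6, HL = 28.6, HR = 28.6), 34)
#' ph <- generate_phantom_frame(st, camera_model(noise_sd = 0), seed = 1)
#' roi_stats(ph$frame, ph$layout$FL)$mean # exactly 31.9
#' @export
generate_phantom_frame <- function(state, camera = camera_model(), seed = NULL,
                                   emit_apparent = FALSE, reflected_temp = 24) {
  stopifnot(inherits(state, "mouse_state"), inherits(camera, "camera_model"))
  temps <- c(state$paw_temps, back = state$back_temp, plate = state$plate_temp)
  if (any(temps < camera$scene_min | temps > camera$scene_max))
    stop(sprintf("state temperature outside camera scene range [%g, %g] degC",
                 camera$scene_min, camera$scene_max), call. = FALSE)

  shp <- c(camera$height_px, camera$width_px)
  layout <- default_roi_layout(shp)

  img <- matrix(state$plate_temp, shp[1L], shp[2L])
  sy <- shp[1L] / 60; sx <- shp[2L] / 80
  body <- ellipse_roi("body", .BASE_BODY$x * sx, .BASE_BODY$y * sy,
                      .BASE_BODY$a * sx, .BASE_BODY$b * sy,
                      emissivity_role = "fur")
  img[ellipse_mask(body, shp)] <- state$back_temp
  for (paw in c("FL", "FR", "HL", "HR"))
    img[ellipse_mask(layout[[paw]], shp)] <- state$paw_temps[[paw]]

  if (emit_apparent) {
    skin <- emissivity_spec(roi_emissivity("skin"), reflected_temp)
    fur <- emissivity_spec(roi_emissivity("fur"), reflected_temp)
    body_m <- ellipse_mask(body, shp)
    paw_m <- Reduce(`|`, lapply(c("FL", "FR", "HL", "HR"),
                                function(p) ellipse_mask(layout[[p]], shp)))
    img[body_m & !paw_m] <- simulate_apparent_temperature(img[body_m & !paw_m], fur)
    img[paw_m] <- simulate_apparent_temperature(img[paw_m], skin)
  }

  if (camera$noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), sd = camera$noise_sd),
                                        nrow(img), ncol(img)))
  img <- pmin(pmax(img, camera$scene_min), camera$scene_max)

  frame <- thermal_frame(img, metadata = list(
    seed = seed, radiometric = emit_apparent, reflected_temp = reflected_temp,
    scene_min = camera$scene_min, scene_max = camera$scene_max))
  list(frame = frame, layout = layout, truth = state)
}
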