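## Thermal frames, elliptical ROIs and per-ROI pixel statistics.
##
## Conventions (the discretization is not dictated by the imaging software,
## so it is fixed here once): pixels are indexed 0-based, x runs along
## columns (left to right), y along rows (top to bottom), and a pixel is
## inside an ellipse iff its *center* satisfies the rotated-ellipse
## inequality <= 1. ROI standard deviations are population SDs.

#' Construct a thermal frame
#'
#' @param temperatures numeric matrix of temperatures (deg C), row 0 = top.
#' @param metadata named list of acquisition metadata. Recognised fields:
#'   `subject`, `day`, `seed`, `radiometric` (TRUE if values are apparent
#'   radiance temperatures still needing emissivity correction),
#'   `reflected_temp`, `scene_min`, `scene_max`.
#' @return object of class `thermal_frame`.
#' @export
thermal_frame <- function(temperatures, metadata = list()) {
  if (!is.matrix(temperatures) || !is.numeric(temperatures))
    stop("`temperatures` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(temperatures))) {
    bad <- which(!is.finite(temperatures), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite temperature at cell (%d,%d)", bad[1L], bad[2L]),
         call. = FALSE)
  }
  scene_min <- metadata$scene_min %||% -20
  scene_max <- metadata$scene_max %||% 120
  if (any(temperatures < scene_min | temperatures > scene_max))
    stop(sprintf("temperatures outside scene range [%g, %g] degC",
                 scene_min, scene_max), call. = FALSE)
  structure(list(temperatures = temperatures,
                 width = ncol(temperatures),
                 height = nrow(temperatures),
                 metadata = metadata),
            class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf("thermal_frame %dx%d px, %.2f-%.2f degC%s\n",
              x$width, x$height, min(x$temperatures), max(x$temperatures),
              if (isTRUE(x$metadata$radiometric)) " (apparent/radiometric)" else ""))
  invisible(x)
}

#' Construct an elliptical region of interest
#'
#' One of the seven ellipses (El1-El7) of the standardized layout: four over
#' the wrist/ankle joints of the paws (bare skin) and three along the upper
#' back (fur) used as the reference region.
#'
#' @param label ROI label, e.g. "FL", "FR", "HL", "HR", "back1".
#' @param center_x,center_y ellipse center in pixels (0-based pixel-center
#'   coordinates; y increases downward).
#' @param semi_axis_a,semi_axis_b semi-axes in pixels (> 0); `a` lies along
#'   the rotated x axis.
#' @param rotation rotation in radians (counter-clockwise in pixel coords).
#' @param emissivity_role "skin" (eps 0.98) or "fur" (eps 0.94); selects the
#'   emissivity used when correcting radiometric frames per ROI.
#' @return object of class `ellipse_roi`.
#' @export
ellipse_roi <- function(label, center_x, center_y, semi_axis_a, semi_axis_b,
                        rotation = 0, emissivity_role = c("skin", "fur")) {
  emissivity_role <- match.arg(emissivity_role)
  check_number(center_x, "center_x")
  check_number(center_y, "center_y")
  check_number(semi_axis_a, "semi_axis_a", lower = 1e-9)
  check_number(semi_axis_b, "semi_axis_b", lower = 1e-9)
  check_number(rotation, "rotation")
  structure(list(label = as.character(label),
                 center_x = center_x, center_y = center_y,
                 semi_axis_a = semi_axis_a, semi_axis_b = semi_axis_b,
                 rotation = rotation, emissivity_role = emissivity_role),
            class = "ellipse_roi")
}

.frame_shape <- function(frame_shape) {
  if (inherits(frame_shape, "thermal_frame"))
    return(c(frame_shape$height, frame_shape$width))
  if (!is.numeric(frame_shape) || length(frame_shape) != 2L ||
      any(frame_shape < 1) || any(frame_shape != round(frame_shape)))
    stop("`frame_shape` must be c(rows, cols) of positive integers", call. = FALSE)
  as.integer(frame_shape)
}

#' Boolean pixel mask of an elliptical ROI
#'
#' A pixel belongs to the mask iff its center satisfies the rotated-ellipse
#' inequality; pixels falling outside the frame are silently clipped.
#'
#' @param roi an [ellipse_roi()].
#' @param frame_shape `c(rows, cols)` or a `thermal_frame`.
#' @return logical matrix of dimension `frame_shape`.
#' @export
ellipse_mask <- function(roi, frame_shape) {
  stopifnot(inherits(roi, "ellipse_roi"))
  shp <- .frame_shape(frame_shape)
  nr <- shp[1L]; nc <- shp[2L]
  dx <- matrix(rep(0:(nc - 1L), each = nr), nr, nc) - roi$center_x
  dy <- matrix(rep(0:(nr - 1L), times = nc), nr, nc) - roi$center_y
  ct <- cos(roi$rotation); st <- sin(roi$rotation)
  u <- (dx * ct + dy * st) / roi$semi_axis_a
  v <- (-dx * st + dy * ct) / roi$semi_axis_b
  m <- u * u + v * v <= 1
  if (!any(m))
    stop(sprintf("ROI '%s' covers no pixel inside a %dx%d frame",
                 roi$label, nc, nr), call. = FALSE)
  m
}

#' Pixel statistics inside an elliptical ROI
#'
#' Computes min / max / mean / population SD of the temperatures under the
#' ROI mask. If the frame holds apparent radiance temperatures
#' (`metadata$radiometric` is TRUE) the masked pixels are first corrected
#' using the emissivity of the ROI's tissue role (0.98 skin, 0.94 fur) and
#' the frame's reflected temperature (default 24 deg C).
#'
#' @param frame a [thermal_frame()].
#' @param roi an [ellipse_roi()].
#' @return list of class `roi_stats`: `label`, `min`, `max`, `mean`, `sd`
#'   (population), `n_pixels`.
#' @export
roi_stats <- function(frame, roi) {
  stopifnot(inherits(frame, "thermal_frame"))
  m <- ellipse_mask(roi, frame)
  px <- frame$temperatures[m]
  if (isTRUE(frame$metadata$radiometric)) {
    eps <- roi_emissivity(roi$emissivity_role)
    spec <- emissivity_spec(eps, frame$metadata$reflected_temp %||% 24)
    px <- correct_apparent_temperature(px, spec)
  }
  mu <- mean(px)
  structure(list(label = roi$label,
                 min = min(px), max = max(px), mean = mu,
                 sd = sqrt(mean((px - mu)^2)),
                 n_pixels = length(px)),
            class = "roi_stats")
}

#' Emissivity value associated with a tissue role
#'
#' @param role "skin" or "fur".
#' @return emissivity (0.98 for bare skin, 0.94 for fur).
#' @export
roi_emissivity <- function(role) {
  switch(match.arg(role, c("skin", "fur")), skin = 0.98, fur = 0.94)
}

## Fixed layout constant for the reference 80x60 frame, mimicking the
## standardized placement: a prone mouse with legs extended, four paw
## ellipses at the corners of the body mask and three reference ellipses
## along the midline of the upper back. El1..El4 map to FL, FR, HL, HR;
## El5..El7 to back1..back3. Head side is at low x; the animal's left side
## is at low y (viewed from above).
.BASE_LAYOUT <- list(
  FL    = list(x = 20, y = 12, a = 4.0, b = 3.0, role = "skin"),
  FR    = list(x = 20, y = 48, a = 4.0, b = 3.0, role = "skin"),
  HL    = list(x = 58, y = 12, a = 4.0, b = 3.0, role = "skin"),
  HR    = list(x = 58, y = 48, a = 4.0, b = 3.0, role = "skin"),
  back1 = list(x = 34, y = 30, a = 4.5, b = 3.5, role = "fur"),
  back2 = list(x = 41, y = 30, a = 4.5, b = 3.5, role = "fur"),
  back3 = list(x = 48, y = 30, a = 4.5, b = 3.5, role = "fur"))

## body ellipse of the phantom (same coordinate frame)
.BASE_BODY <- list(x = 40, y = 30, a = 24, b = 13)

#' The standardized seven-ellipse ROI layout
#'
#' Deterministic layout constant for the reference 80x60 frame; for larger
#' frames every geometric field scales linearly with the frame size.
#' Paw ROIs carry the skin emissivity role, back ROIs the fur role.
#'
#' @param frame_shape `c(rows, cols)`; must be at least 60x80.
#' @return object of class `roi_layout`: a named list of 7 [ellipse_roi()]s
#'   (FL, FR, HL, HR, back1, back2, back3).
#' @export
default_roi_layout <- function(frame_shape = c(60, 80)) {
  shp <- .frame_shape(frame_shape)
  if (shp[1L] < 60 || shp[2L] < 80)
    stop("frame too small for the standardized layout: need at least 80x60",
         call. = FALSE)
  sy <- shp[1L] / 60
  sx <- shp[2L] / 80
  rois <- lapply(names(.BASE_LAYOUT), function(nm) {
    g <- .BASE_LAYOUT[[nm]]
    ellipse_roi(nm, g$x * sx, g$y * sy, g$a * sx, g$b * sy,
                rotation = 0, emissivity_role = g$role)
  })
  names(rois) <- names(.BASE_LAYOUT)
  structure(rois, class = "roi_layout")
}

#' @export
print.roi_layout <- function(x, ...) {
  cat(sprintf("roi_layout with %d ellipses: %s\n", length(x),
              paste(vapply(x, `[[`, "", "label"), collapse = ", ")))
  invisible(x)
}

#' Serialize / read an ROI layout as JSON
#'
#' @param layout a `roi_layout`.
#' @param path file path.
#' @return `read_roi_layout` returns a `roi_layout`; `write_roi_layout`
#'   returns `path` invisibly.
#' @export
write_roi_layout <- function(layout, path) {
  stopifnot(inherits(layout, "roi_layout"))
  jsonlite::write_json(lapply(unclass(layout), unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_layout
#' @export
read_roi_layout <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- lapply(raw, function(g)
    ellipse_roi(g$label, g$center_x, g$center_y, g$semi_axis_a, g$semi_axis_b,
                g$rotation, g$emissivity_role))
  names(rois) <- vapply(rois, `[[`, "", "label")
  structure(rois, class = "roi_layout")
}
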