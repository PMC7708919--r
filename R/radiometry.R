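## Radiometric model and camera calibration QC.
##
## Apparent (radiance) temperatures reported by an uncorrected microbolometer
## are related to the true surface temperature through the surface emissivity
## and the reflected ambient radiation. We use the band-integrated
## Stefan-Boltzmann model, W(T) proportional to T^4 with T in Kelvin:
##
##   W_app = eps * W(T_surface) + (1 - eps) * W(T_reflected)
##
## Atmospheric transmittance is taken as 1: at a ~20 cm camera-object path
## the atmosphere absorbs a negligible fraction of long-wave IR.

.ZERO_C <- 273.15

.t4 <- function(t_c) (t_c + .ZERO_C)^4

#' Emissivity specification for radiometric correction
#'
#' @param emissivity surface emissivity in (0, 1]. Mouse skin is typically
#'   0.98 and fur 0.94.
#' @param reflected_temp apparent temperature (deg C) of the radiation
#'   reflected by the surface, usually the ambient temperature.
#' @param atmospheric_transmittance in (0, 1]; fixed default 1 (short path).
#' @return an object of class `emissivity_spec`.
#' @examples
#' emissivity_spec(0.98, reflected_temp = 24)
#' @export
emissivity_spec <- function(emissivity, reflected_temp = 24,
                            atmospheric_transmittance = 1) {
  check_number(emissivity, "emissivity", lower = 1e-6, upper = 1)
  if (emissivity <= 0) stop("`emissivity` must be > 0", call. = FALSE)
  check_number(reflected_temp, "reflected_temp", lower = -.ZERO_C)
  check_number(atmospheric_transmittance, "atmospheric_transmittance",
               lower = 1e-6, upper = 1)
  structure(list(emissivity = emissivity,
                 reflected_temp = reflected_temp,
                 atmospheric_transmittance = atmospheric_transmittance),
            class = "emissivity_spec")
}

#' Apparent temperature seen by the camera for a known surface temperature
#'
#' Forward radiometric model: mixes surface and reflected radiance according
#' to the emissivity. Exact algebraic inverse of
#' [correct_apparent_temperature()]; with emissivity 1 it is the identity.
#'
#' @param surface surface temperature(s), deg C.
#' @param spec an [emissivity_spec()].
#' @return apparent temperature(s), deg C.
#' @examples
#' simulate_apparent_temperature(34, emissivity_spec(0.98, 24)) # ~33.81
#' @export
simulate_apparent_temperature <- function(surface, spec) {
  stopifnot(inherits(spec, "emissivity_spec"))
  if (!is.numeric(surface) || any(!is.finite(surface)))
    stop("`surface` must be finite numeric", call. = FALSE)
  if (any(surface < -.ZERO_C)) stop("`surface` below absolute zero", call. = FALSE)
  e <- spec$emissivity
  w <- e * .t4(surface) + (1 - e) * .t4(spec$reflected_temp)
  w^0.25 - .ZERO_C
}

#' Correct an apparent temperature for emissivity and reflected radiation
#'
#' Inverts the band-integrated fourth-power radiance model to recover the
#' true surface temperature from the camera's apparent reading.
#'
#' @param apparent apparent temperature(s), deg C.
#' @param spec an [emissivity_spec()].
#' @return surface temperature(s), deg C.
#' @examples
#' correct_apparent_temperature(33.81, emissivity_spec(0.98, 24)) # ~34.0
#' @export
correct_apparent_temperature <- function(apparent, spec) {
  stopifnot(inherits(spec, "emissivity_spec"))
  if (!is.numeric(apparent) || any(!is.finite(apparent)))
    stop("`apparent` must be finite numeric", call. = FALSE)
  if (any(apparent < -.ZERO_C)) stop("`apparent` below absolute zero", call. = FALSE)
  e <- spec$emissivity
  radicand <- (.t4(apparent) - (1 - e) * .t4(spec$reflected_temp)) / e
  if (any(radicand <= 0))
    stop("radiometric correction impossible: apparent radiance does not ",
         "exceed the reflected component (check emissivity/reflected_temp)",
         call. = FALSE)
  radicand^0.25 - .ZERO_C
}

#' Simulate a blackbody calibration series
#'
#' Emulates repeated camera readings against blackbody reference sources of
#' known temperature; ground truth is slope 1, intercept 0.
#'
#' @param ref_temps reference temperatures, deg C (at least one).
#' @param reps replicate readings per reference (>= 1).
#' @param noise_sd Gaussian sensor noise SD, deg C.
#' @param seed optional integer seed.
#' @return a data.frame of class `calibration_series` with columns
#'   `reference_c`, `replicate`, `reading_c`.
#' @examples
#' s <- generate_calibration_series(35:40, reps = 3, noise_sd = 0.1, seed = 1)
#' fit_calibration(s)
#' @export
generate_calibration_series <- function(ref_temps, reps = 3, noise_sd = 0.1,
                                        seed = NULL) {
  if (!is.numeric(ref_temps) || length(ref_temps) == 0L || any(!is.finite(ref_temps)))
    stop("`ref_temps` must be a non-empty finite numeric vector", call. = FALSE)
  reps <- check_count(reps, "reps", lower = 1L)
  check_number(noise_sd, "noise_sd", lower = 0)
  df <- with_seed(seed, {
    ref <- rep(ref_temps, each = reps)
    data.frame(reference_c = ref,
               replicate = rep(seq_len(reps), times = length(ref_temps)),
               reading_c = ref + stats::rnorm(length(ref), sd = noise_sd))
  })
  class(df) <- c("calibration_series", "data.frame")
  df
}

#' Fit the camera calibration regression against blackbody references
#'
#' Replicate readings are averaged per reference temperature and the mean
#' reading is regressed on the reference by ordinary least squares. The
#' maximum absolute deviation of mean readings from their references
#' quantifies absolute accuracy.
#'
#' @param series a `calibration_series` or data.frame with columns
#'   `reference_c` and `reading_c`.
#' @return an object of class `calibration_result` with fields `slope`,
#'   `intercept`, `r_squared`, `max_abs_dev`, `n_points`.
#' @export
fit_calibration <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("reference_c", "reading_c") %in% names(series)))
    stop("`series` must have columns reference_c and reading_c", call. = FALSE)
  means <- tapply(series$reading_c, series$reference_c, mean)
  ref <- as.numeric(names(means))
  y <- as.numeric(means)
  if (length(ref) < 2L || stats::var(ref) == 0)
    stop("degenerate calibration design: need >= 2 distinct reference ",
         "temperatures", call. = FALSE)
  ## direct OLS normal equations: exact (slope 1, intercept 0, R^2 1) on a
  ## perfect line, where lm() would leave ~1e-16 rounding residue
  xc <- ref - mean(ref)
  yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc * xc)
  intercept <- mean(y) - slope * mean(ref)
  sstot <- sum(yc^2)
  ssres <- sum((y - (intercept + slope * ref))^2)
  structure(list(slope = slope,
                 intercept = intercept,
                 r_squared = if (sstot > 0) 1 - ssres / sstot else 1,
                 max_abs_dev = max(abs(y - ref)),
                 n_points = length(ref)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration fit (%d reference points)\n  slope %.4f  intercept %.4f degC\n  R-squared %.4f  max |deviation| %.3f degC\n",
    x$n_points, x$slope, x$intercept, x$r_squared, x$max_abs_dev))
  invisible(x)
}

#' Pass/fail accuracy check of a calibration result
#'
#' @param result a `calibration_result` from [fit_calibration()].
#' @param tolerance accuracy tolerance in deg C (> 0); 0.2 deg C is the
#'   accuracy established for the 35-40 deg C range.
#' @return list with `pass`, `max_abs_dev`, `tolerance` and a `message`.
#' @export
accuracy_check <- function(result, tolerance = 0.2) {
  stopifnot(inherits(result, "calibration_result"))
  check_number(tolerance, "tolerance", lower = 1e-12)
  ## comparison at 1e-9 degC resolution so that e.g. a deviation of exactly
  ## 0.2 degC passes a 0.2 degC tolerance despite binary rounding
  pass <- result$max_abs_dev <= tolerance + 1e-9
  list(pass = pass,
       max_abs_dev = result$max_abs_dev,
       tolerance = tolerance,
       message = sprintf("max |deviation| %.3f degC %s tolerance %.3f degC: %s",
                         result$max_abs_dev, if (pass) "<=" else ">",
                         tolerance, if (pass) "PASS" else "FAIL"))
}
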