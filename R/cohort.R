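## Synthetic CIA cohort generator.
##
## Measurement model: each diseased (responder) paw carries a latent
## severity s >= 0 that ramps from 0 at baseline to ~1 at the day-28
## LPS-synchronized flare, scaled by a per-mouse severity multiplier
## u ~ N(1, severity_sd) (CIA is a symmetric polyarthritis, so the flare is
## shared by all four paws of a mouse). The three endpoints read the same
## latent state through independent noise:
##
##   temperature: T = T0(group) + (T_flare - T0_cia) * s
##                    + (B - 34) + mouse offset + paw noise
##     (paw surface temperature tracks the core/back temperature B, so the
##      temperature index is robust to whole-body temperature shifts)
##   thickness:   THK = THK0 + (THK_flare - THK0) * s + heteroscedastic noise
##     (caliper noise grows with swelling)
##   clinical:    CS = ordinal bin of (s + noise) via fixed thresholds
##
## Controls and non-responders keep s = 0 throughout. `cross_modality_noise`
## scales every modality-specific noise source; as it approaches 0 all
## endpoints become deterministic functions of the shared latent severity
## and the day-28 correlation between TI_total and total thickness
## approaches 1.

#' Default parameters of the synthetic measurement model
#'
#' Group-level distribution parameters of [generate_cohort()]. Temperature
#' means reproduce the canonical group summaries (baseline TI_total about
#' 3.37 CIA / 3.31 control, day-28 flare about 3.71); the noise partition
#' (mouse-level vs paw-level vs back-coupled) and the flare-dependent
#' thickness noise were fixed once by replicate simulation so that the
#' generated cohorts also reproduce the downstream selection counts (12 of
#' 14 mice with all four joints TI >= 0.9) and the day-28 cross-modality
#' correlation r(TI_total, total thickness) of about 0.615. See the package
#' vignette for the calibration rationale.
#'
#' @return named list of parameters (all deg C, mm, or unitless):
#' \describe{
#'   \item{back_mean, back_sd}{back (core) temperature distribution.}
#'   \item{back_reading_sd}{per-back-ROI reading noise.}
#'   \item{cia_baseline_temp, control_baseline_temp}{baseline paw means.}
#'   \item{flare_temp}{day-28 responder paw mean.}
#'   \item{mouse_temp_sd, paw_temp_sd}{mouse-level and paw-level temperature
#'     noise; together with `back_sd` they compose the baseline per-paw SD
#'     sqrt(back_sd^2 + mouse_temp_sd^2 + paw_temp_sd^2) = 0.35.}
#'   \item{severity_sd}{SD of the per-mouse flare multiplier; brings the
#'     day-28 responder per-paw SD to 0.5.}
#'   \item{baseline_thickness, thickness_sd, flare_thickness}{caliper model.}
#'   \item{thickness_flare_sd}{extra per-paw caliper noise at full flare
#'     (scales with latent severity); calibrated to the day-28
#'     cross-modality correlation.}
#'   \item{cs_thresholds, cs_noise_sd}{ordinal clinical-score model: score k
#'     when the noisy latent severity falls between thresholds k and k+1;
#'     tuned so the day-28 responder total score has median 10.}
#'   \item{ramp_days, ramp_values}{piecewise-linear disease ramp knots
#'     (subclinical until week 3, flare after day-25 LPS).}
#'   \item{cross_modality_noise}{global scale on all modality-specific
#'     noise sources.}
#' }
#' @export
cohort_params <- function() {
  list(
    back_mean = 34, back_sd = 0.2, back_reading_sd = 0.1,
    cia_baseline_temp = 28.65, control_baseline_temp = 28.14,
    flare_temp = 31.9,
    mouse_temp_sd = 0.2061553, paw_temp_sd = 0.20,
    severity_sd = 0.109868,
    baseline_thickness = 1.79, thickness_sd = 0.13,
    flare_thickness = 2.65, thickness_flare_sd = 0.885,
    cs_thresholds = c(0.50, 0.60, 0.95, 1.40), cs_noise_sd = 0.25,
    ramp_days = c(0, 21, 25, 28), ramp_values = c(0, 0.10, 0.25, 1),
    cross_modality_noise = 1)
}

#' Configuration of a synthetic CIA/control cohort
#'
#' @param n_cia number of immunized (CIA) mice (default 14).
#' @param n_control number of healthy control mice (default 4).
#' @param n_nonresponders number of CIA mice that fail to develop arthritis
#'   and stay at baseline (default 2; must be <= `n_cia`).
#' @param days strictly increasing study days (default 0, 7, 14, 21, 28).
#' @param seed integer seed; a fixed seed reproduces the cohort table
#'   byte-for-byte.
#' @param params measurement-model parameters, see [cohort_params()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_cia = 14L, n_control = 4L, n_nonresponders = 2L,
                          days = c(0, 7, 14, 21, 28), seed = NULL,
                          params = cohort_params()) {
  n_cia <- check_count(n_cia, "n_cia")
  n_control <- check_count(n_control, "n_control")
  n_nonresponders <- check_count(n_nonresponders, "n_nonresponders")
  if (n_nonresponders > n_cia)
    stop("`n_nonresponders` must be <= `n_cia`", call. = FALSE)
  if (!is.numeric(days) || length(days) < 1L || any(!is.finite(days)) ||
      is.unsorted(days, strictly = TRUE))
    stop("`days` must be strictly increasing", call. = FALSE)
  defaults <- cohort_params()
  if (!all(names(params) %in% names(defaults)))
    stop("unknown parameter(s): ",
         paste(setdiff(names(params), names(defaults)), collapse = ", "),
         call. = FALSE)
  params <- utils::modifyList(defaults, params)
  sds <- c("back_sd", "back_reading_sd", "mouse_temp_sd", "paw_temp_sd",
           "severity_sd", "thickness_sd", "thickness_flare_sd", "cs_noise_sd",
           "cross_modality_noise")
  for (s in sds) check_number(params[[s]], s, lower = 0)
  if (is.unsorted(params$cs_thresholds, strictly = TRUE))
    stop("`cs_thresholds` must be strictly increasing", call. = FALSE)
  structure(list(n_cia = n_cia, n_control = n_control,
                 n_nonresponders = n_nonresponders,
                 days = as.numeric(days), seed = seed, params = params),
            class = "cohort_config")
}

## piecewise-linear disease ramp (clamped at the ends)
severity_ramp <- function(day, params = cohort_params()) {
  stats::approx(params$ramp_days, params$ramp_values, xout = day, rule = 2)$y
}

#' Expected endpoint values at a given latent severity
#'
#' Noise-free measurement model: expected paw surface temperature, caliper
#' thickness, and clinical score for a paw with latent severity `s`.
#' All three are strictly increasing in `s`.
#'
#' @param s latent severity (>= 0; 0 healthy, ~1 full day-28 flare).
#' @param params see [cohort_params()].
#' @param group "CIA" or "control" (baseline differs slightly).
#' @return data.frame with columns `severity`, `temp_c`, `thickness_mm`,
#'   `clinical_score` (expected ordinal score, continuous).
#' @export
expected_endpoints <- function(s, params = cohort_params(), group = "CIA") {
  if (any(s < 0)) stop("`s` must be >= 0", call. = FALSE)
  t0 <- if (group == "CIA") params$cia_baseline_temp else params$control_baseline_temp
  d_t <- params$flare_temp - params$cia_baseline_temp
  d_k <- params$flare_thickness - params$baseline_thickness
  sd_cs <- max(params$cs_noise_sd * params$cross_modality_noise, 1e-12)
  ecs <- vapply(s, function(si)
    sum(1 - stats::pnorm(params$cs_thresholds, mean = si, sd = sd_cs)), 0)
  data.frame(severity = s,
             temp_c = t0 + d_t * s,
             thickness_mm = params$baseline_thickness + d_k * s,
             clinical_score = ecs)
}

#' Generate a synthetic longitudinal CIA/control cohort
#'
#' Simulates the full longitudinal study: per mouse and study day, the four
#' paw surface temperatures, three back-reference readings, per-paw caliper
#' thickness and per-paw ordinal clinical score, all driven by a shared
#' latent severity (see [cohort_params()]). CIA responders ramp to a day-28
#' flare; non-responders and controls stay at baseline.
#'
#' @param config a [cohort_config()].
#' @return tidy data.frame of class `cia_cohort`, one row per mouse x day x
#'   region with columns `mouse_id`, `group` ("CIA"/"control"), `day`,
#'   `paw` (FL/FR/HL/HR/back1..back3), `surface_temp_c`, `thickness_mm`,
#'   `clinical_score` (NA for back rows), `latent_severity`, `responder`.
#'   Attributes `seed` and `config_hash` record provenance.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' scores <- score_cohort(cohort)
#' mean(scores$ti_total[scores$group == "CIA" & scores$day == 0]) # ~3.37
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  p <- config$params
  knob <- p$cross_modality_noise
  with_seed(config$seed, {
    n_mice <- config$n_cia + config$n_control
    ids <- c(if (config$n_cia) paste0("M", seq_len(config$n_cia)),
             if (config$n_control) paste0("Ctl", seq_len(config$n_control)))
    group <- rep(c("CIA", "control"), c(config$n_cia, config$n_control))
    responder <- rep(FALSE, n_mice)
    if (config$n_cia > 0) {
      responder[seq_len(config$n_cia)] <- TRUE
      if (config$n_nonresponders > 0)
        responder[sample.int(config$n_cia, config$n_nonresponders)] <- FALSE
    }

    ## mouse-level draws
    u <- pmax(stats::rnorm(n_mice, 1, p$severity_sd), 0)   # flare multiplier
    b <- stats::rnorm(n_mice, 0, p$mouse_temp_sd * knob)   # temp offset

    days <- config$days
    nd <- length(days)
    ## mouse x day grid
    mi <- rep(seq_len(n_mice), each = nd)
    dd <- rep(days, times = n_mice)
    back <- stats::rnorm(n_mice * nd, p$back_mean, p$back_sd * knob)
    ramp <- severity_ramp(dd, p)
    sev <- ifelse(group[mi] == "CIA" & responder[mi], u[mi] * ramp, 0)

    ## paw rows: 4 per mouse-day
    paw <- rep(.PAWS, times = n_mice * nd)
    pmi <- rep(mi, each = 4L)
    pdd <- rep(dd, each = 4L)
    psev <- rep(sev, each = 4L)
    pback <- rep(back, each = 4L)
    t0 <- ifelse(group[pmi] == "CIA", p$cia_baseline_temp, p$control_baseline_temp)
    d_t <- p$flare_temp - p$cia_baseline_temp
    temp <- t0 + d_t * psev + (pback - p$back_mean) + b[pmi] +
      stats::rnorm(length(pmi), 0, p$paw_temp_sd * knob)
    d_k <- p$flare_thickness - p$baseline_thickness
    thk_sd <- knob * sqrt(p$thickness_sd^2 + (p$thickness_flare_sd * psev)^2)
    thk <- pmax(p$baseline_thickness + d_k * psev +
                  stats::rnorm(length(pmi), 0, thk_sd), 0.4)
    cs_lat <- psev + stats::rnorm(length(pmi), 0, p$cs_noise_sd * knob)
    cs <- pmin(pmax(findInterval(cs_lat, p$cs_thresholds), 0L), 4L)

    paw_rows <- data.frame(
      mouse_id = ids[pmi], group = group[pmi], day = pdd, paw = paw,
      surface_temp_c = temp, thickness_mm = thk, clinical_score = cs,
      latent_severity = psev, responder = responder[pmi],
      stringsAsFactors = FALSE)

    ## back reference rows: 3 readings per mouse-day
    bmi <- rep(mi, each = 3L)
    bdd <- rep(dd, each = 3L)
    bread <- rep(back, each = 3L) +
      stats::rnorm(3L * length(mi), 0, p$back_reading_sd * knob)
    back_rows <- data.frame(
      mouse_id = ids[bmi], group = group[bmi], day = bdd,
      paw = rep(.BACKS, times = length(mi)),
      surface_temp_c = bread, thickness_mm = NA_real_,
      clinical_score = NA_integer_, latent_severity = NA_real_,
      responder = responder[bmi], stringsAsFactors = FALSE)

    out <- rbind(paw_rows, back_rows)
    out <- out[order(out$day, match(out$mouse_id, ids),
                     match(out$paw, c(.PAWS, .BACKS))), ]
    rownames(out) <- NULL
    attr(out, "seed") <- config$seed
    attr(out, "config_hash") <- config_hash(unclass(config))
    class(out) <- c("cia_cohort", "data.frame")
    out
  })
}

#' Generate a synthetic four-arm treatment study
#'
#' Simulates the efficacy-trial design: flared CIA mice randomized to
#' nanoparticle-formulated methotrexate (NP-MTX), free MTX or vehicle
#' (Ctl+), plus healthy vehicle controls (Ctl-), measured every 3-4 days
#' over four weeks of treatment. All CIA-derived arms start at full flare
#' (latent severity ~1); the latent severity then follows a per-group
#' linear trend to `end_severity` at the last day, through the same
#' measurement model as [generate_cohort()].
#'
#' @param n_per_group mice per arm (default 4).
#' @param days measurement days (default every 3-4 days over 28 days).
#' @param end_severity named end-of-study latent severities per arm.
#' @param seed integer seed.
#' @param params see [cohort_params()].
#' @return tidy data.frame in the same format as [generate_cohort()], with
#'   groups "NP-MTX", "MTX", "Ctl+", "Ctl-".
#' @export
generate_treatment_cohort <- function(n_per_group = 4L,
                                      days = c(0, 3, 7, 10, 14, 17, 21, 24, 28),
                                      end_severity = c("NP-MTX" = 0.10,
                                                       "MTX" = 0.55,
                                                       "Ctl+" = 1.15,
                                                       "Ctl-" = 0),
                                      seed = NULL, params = cohort_params()) {
  n_per_group <- check_count(n_per_group, "n_per_group", lower = 1L)
  if (is.unsorted(days, strictly = TRUE))
    stop("`days` must be strictly increasing", call. = FALSE)
  p <- utils::modifyList(cohort_params(), params)
  knob <- p$cross_modality_noise
  groups <- names(end_severity)
  with_seed(seed, {
    n_mice <- n_per_group * length(groups)
    g <- rep(groups, each = n_per_group)
    ids <- paste0(rep(groups, each = n_per_group), "_", seq_len(n_per_group))
    u <- pmax(stats::rnorm(n_mice, 1, p$severity_sd), 0)
    b <- stats::rnorm(n_mice, 0, p$mouse_temp_sd * knob)
    frac <- (days - days[1L]) / (days[length(days)] - days[1L])

    rows <- vector("list", n_mice * length(days))
    k <- 0L
    for (i in seq_len(n_mice)) {
      start <- if (g[i] == "Ctl-") 0 else 1
      target <- end_severity[[g[i]]]
      for (j in seq_along(days)) {
        s <- u[i] * (start + (target - start) * frac[j])
        s <- max(s, 0)
        back <- stats::rnorm(1L, p$back_mean, p$back_sd * knob)
        t0 <- if (g[i] == "Ctl-") p$control_baseline_temp else p$cia_baseline_temp
        d_t <- p$flare_temp - p$cia_baseline_temp
        temp <- t0 + d_t * s + (back - p$back_mean) + b[i] +
          stats::rnorm(4L, 0, p$paw_temp_sd * knob)
        d_k <- p$flare_thickness - p$baseline_thickness
        thk_sd <- knob * sqrt(p$thickness_sd^2 + (p$thickness_flare_sd * s)^2)
        thk <- pmax(p$baseline_thickness + d_k * s + stats::rnorm(4L, 0, thk_sd), 0.4)
        cs <- pmin(pmax(findInterval(
          s + stats::rnorm(4L, 0, p$cs_noise_sd * knob), p$cs_thresholds), 0L), 4L)
        k <- k + 1L
        rows[[k]] <- data.frame(
          mouse_id = ids[i], group = g[i], day = days[j],
          paw = c(.PAWS, .BACKS),
          surface_temp_c = c(temp, back + stats::rnorm(3L, 0, p$back_reading_sd * knob)),
          thickness_mm = c(thk, rep(NA_real_, 3L)),
          clinical_score = c(cs, rep(NA_integer_, 3L)),
          latent_severity = c(rep(s, 4L), rep(NA_real_, 3L)),
          responder = g[i] != "Ctl-", stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "seed") <- seed
    class(out) <- c("cia_cohort", "data.frame")
    out
  })
}
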