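## Temperature-index scoring, severity classification, cohort selection.

.PAWS <- c("FL", "FR", "HL", "HR")
.BACKS <- c("back1", "back2", "back3")
.SEVERITY_LEVELS <- c("absent", "mild", "moderate", "severe")

#' Back reference temperature from the three back ROIs
#'
#' Unweighted arithmetic mean of the three back ROI mean temperatures.
#'
#' @param back_means three ROI mean temperatures (deg C), or a list of three
#'   [roi_stats()] objects.
#' @return T_back in deg C.
#' @export
back_reference <- function(back_means) {
  if (is.list(back_means) && all(vapply(back_means, inherits, TRUE, "roi_stats")))
    back_means <- vapply(back_means, `[[`, 0, "mean")
  if (!is.numeric(back_means) || length(back_means) != 3L || any(!is.finite(back_means)))
    stop("`back_means` must be three finite back ROI mean temperatures",
         call. = FALSE)
  mean(back_means)
}

#' Per-paw temperature index (TI)
#'
#' TI = T_paw / T_back, the mean paw ROI temperature normalized to the
#' averaged back reference temperature of the same animal. Computed on the
#' Celsius scale: the canonical TI values (about 0.8-1.0 for paw
#' temperatures of 28-34 deg C against a 34 deg C back) are only consistent
#' with a Celsius ratio. A Kelvin variant is available via `scale`.
#'
#' The index is returned unclamped; values above 1 (paw hotter than the
#' back) are legitimate inputs to [classify_severity()], which flags them.
#'
#' @param t_paw paw ROI mean temperature(s), deg C.
#' @param t_back back reference temperature(s), deg C (> 0 for the Celsius
#'   scale).
#' @param scale "celsius" (default) or "kelvin".
#' @return temperature index (unitless).
#' @examples
#' temperature_index(30.6, 34) # 0.9
#' @export
temperature_index <- function(t_paw, t_back, scale = c("celsius", "kelvin")) {
  scale <- match.arg(scale)
  if (!is.numeric(t_paw) || !is.numeric(t_back) ||
      any(!is.finite(t_paw)) || any(!is.finite(t_back)))
    stop("temperatures must be finite numeric", call. = FALSE)
  if (any(t_paw <= -273.15) || any(t_back <= -273.15))
    stop("temperatures below absolute zero", call. = FALSE)
  if (scale == "celsius") {
    if (any(t_back <= 0))
      stop("`t_back` must be > 0 degC for the Celsius-scale index", call. = FALSE)
    t_paw / t_back
  } else {
    (t_paw + 273.15) / (t_back + 273.15)
  }
}

#' Total temperature index (TI_total)
#'
#' Sum of the four per-paw temperature indices (front wrists and hind
#' ankles); nominal maximum 4 when every paw matches the back reference.
#'
#' @param tis four finite per-paw TIs.
#' @return TI_total (unitless).
#' @export
ti_total <- function(tis) {
  if (!is.numeric(tis) || length(tis) != 4L || any(!is.finite(tis)))
    stop("`tis` must be four finite temperature indices", call. = FALSE)
  sum(tis)
}

#' Total clinical arthritis score
#'
#' Sum of the four per-paw ordinal redness/swelling grades (0-4 each),
#' maximum 16.
#'
#' @param scores four integer scores in 0..4.
#' @return integer total in 0..16.
#' @export
total_clinical_score <- function(scores) {
  if (!is.numeric(scores) || length(scores) != 4L || any(!is.finite(scores)) ||
      any(scores != round(scores)) || any(scores < 0) || any(scores > 4))
    stop("`scores` must be four integers in 0..4", call. = FALSE)
  as.integer(sum(scores))
}

#' Total paw thickness
#'
#' Sum of the four caliper thicknesses (mm).
#'
#' @param thicknesses four positive thicknesses, mm.
#' @return total thickness, mm.
#' @export
total_thickness <- function(thicknesses) {
  if (!is.numeric(thicknesses) || length(thicknesses) != 4L ||
      any(!is.finite(thicknesses)) || any(thicknesses <= 0))
    stop("`thicknesses` must be four positive values (mm)", call. = FALSE)
  sum(thicknesses)
}

#' Classify arthritis severity from TI, thickness or clinical score
#'
#' Bins follow the standardized framework: TI absent < 0.85, mild
#' \[0.85, 0.90), moderate \[0.90, 0.95), severe >= 0.95; thickness (mm)
#' absent < 2, mild \[2, 2.5), moderate \[2.5, 3), severe >= 3; clinical
#' score 0 absent, 1 mild, 2-3 moderate, 4 severe. Bins are left-closed /
#' right-open except the open-ended severe bin. Values below the nominal
#' lower edge of the absent bin (TI 0.80, THK 1.5 mm) map to absent with a
#' warning, and TI above the nominal maximum of 1 maps to severe with a
#' warning.
#'
#' @param value numeric vector of values (CS must be integer 0..4).
#' @param modality "TI", "THK" or "CS".
#' @return ordered factor with levels absent < mild < moderate < severe.
#' @examples
#' classify_severity(c(0.82, 0.92, 0.96), "TI")
#' @export
classify_severity <- function(value, modality = c("TI", "THK", "CS")) {
  modality <- match.arg(modality)
  if (!is.numeric(value) || any(!is.finite(value)))
    stop("`value` must be finite numeric", call. = FALSE)
  lab <- switch(modality,
    TI = {
      if (any(value < 0.80))
        warning("TI value(s) below the nominal absent bin (0.80); classified absent")
      if (any(value > 1))
        warning("TI value(s) above the nominal maximum of 1; classified severe")
      cut(value, breaks = c(-Inf, 0.85, 0.90, 0.95, Inf),
          labels = .SEVERITY_LEVELS, right = FALSE)
    },
    THK = {
      if (any(value < 1.5))
        warning("thickness value(s) below the nominal absent bin (1.5 mm); classified absent")
      if (any(value > 3.5))
        warning("thickness value(s) above the nominal severe bin (3.5 mm); classified severe")
      cut(value, breaks = c(-Inf, 2, 2.5, 3, Inf),
          labels = .SEVERITY_LEVELS, right = FALSE)
    },
    CS = {
      if (any(value != round(value)) || any(value < 0) || any(value > 4))
        stop("clinical scores must be integers in 0..4", call. = FALSE)
      factor(.SEVERITY_LEVELS[c(1L, 2L, 3L, 3L, 4L)[value + 1L]],
             levels = .SEVERITY_LEVELS)
    })
  factor(as.character(lab), levels = .SEVERITY_LEVELS, ordered = TRUE)
}

#' Cohort inclusion rule for the therapeutic study
#'
#' A mouse enters the efficacy trial only if *all four* joints (front wrists
#' and hind ankles) score TI >= 0.9, i.e. fully developed, moderate-to-severe
#' arthritis; the boundary is inclusive (0.9 <= TI <= 1).
#'
#' @param tis four per-paw TIs (or a one-row scores data.frame from
#'   [score_cohort()]).
#' @return logical: TRUE if included.
#' @export
mouse_inclusion <- function(tis) {
  if (is.data.frame(tis)) {
    cols <- c("ti_fl", "ti_fr", "ti_hl", "ti_hr")
    if (!all(cols %in% names(tis)) || nrow(tis) != 1L)
      stop("data.frame input must be one row with columns ti_fl..ti_hr",
           call. = FALSE)
    tis <- as.numeric(tis[1L, cols])
  }
  if (!is.numeric(tis) || length(tis) != 4L || any(is.na(tis)))
    stop("all four paw TIs must be present", call. = FALSE)
  all(tis >= 0.9)
}

#' Score a tidy cohort table into per-mouse per-day endpoints
#'
#' Takes the tidy long table produced by [generate_cohort()] (one row per
#' mouse x day x region; regions FL/FR/HL/HR carry temperature, thickness
#' and clinical score, regions back1..back3 carry the back reference
#' temperatures) and computes, per mouse and day: the four paw TIs,
#' TI_total, total thickness, total clinical score, and the back reference.
#'
#' @param cohort data.frame with columns `mouse_id`, `group`, `day`, `paw`,
#'   `surface_temp_c` and (for paw rows) `thickness_mm`, `clinical_score`.
#' @return data.frame with one row per mouse x day: `mouse_id`, `group`,
#'   `day`, `t_back`, `ti_fl`, `ti_fr`, `ti_hl`, `ti_hr`, `ti_total`,
#'   `thk_fl`..`thk_hr`, `total_thickness`, `cs_fl`..`cs_hr`,
#'   `total_clinical`, `included` (the all-paws TI >= 0.9 rule).
#' @export
score_cohort <- function(cohort) {
  need <- c("mouse_id", "group", "day", "paw", "surface_temp_c",
            "thickness_mm", "clinical_score")
  if (!is.data.frame(cohort) || !all(need %in% names(cohort)))
    stop("`cohort` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  backs <- cohort[cohort$paw %in% .BACKS, ]
  paws <- cohort[cohort$paw %in% .PAWS, ]
  if (nrow(backs) == 0L || nrow(paws) == 0L)
    stop("cohort table must contain paw rows (FL/FR/HL/HR) and back rows ",
         "(back1..back3)", call. = FALSE)

  bk <- stats::aggregate(list(t_back = backs$surface_temp_c),
                         by = list(mouse_id = backs$mouse_id, day = backs$day),
                         FUN = mean)
  key <- function(m, d) paste(m, d, sep = "\r")
  paws$t_back <- bk$t_back[match(key(paws$mouse_id, paws$day),
                                 key(bk$mouse_id, bk$day))]
  if (any(is.na(paws$t_back)))
    stop("missing back reference rows for some mouse/day", call. = FALSE)
  paws$ti <- temperature_index(paws$surface_temp_c, paws$t_back)

  ids <- unique(paws[, c("mouse_id", "group", "day")])
  k <- key(paws$mouse_id, paws$day)
  pick <- function(col, paw) {
    v <- paws[paws$paw == paw, ]
    v[[col]][match(key(ids$mouse_id, ids$day), key(v$mouse_id, v$day))]
  }
  out <- ids
  out$t_back <- pick("t_back", "FL")
  for (p in .PAWS) out[[paste0("ti_", tolower(p))]] <- pick("ti", p)
  for (p in .PAWS) out[[paste0("thk_", tolower(p))]] <- pick("thickness_mm", p)
  for (p in .PAWS) out[[paste0("cs_", tolower(p))]] <- pick("clinical_score", p)
  ti_cols <- paste0("ti_", tolower(.PAWS))
  if (any(is.na(out[ti_cols])))
    stop("incomplete paw measurements: every mouse/day needs all four paws",
         call. = FALSE)
  out$ti_total <- rowSums(out[ti_cols])
  out$total_thickness <- rowSums(out[paste0("thk_", tolower(.PAWS))])
  out$total_clinical <- as.integer(rowSums(out[paste0("cs_", tolower(.PAWS))]))
  out$included <- apply(out[ti_cols] >= 0.9, 1L, all)
  rownames(out) <- NULL
  out[order(out$day, out$mouse_id), ]
}

#' Severity heatmap and per-mouse severity counts at one timepoint
#'
#' Builds the per-mouse x per-paw severity label matrix for one modality at
#' one study day, plus per-mouse summary flags. A mouse's overall level for
#' a modality is the level that *all four* joints reach (the minimum over
#' paws), matching the framework's rule that moderate-to-severe disease
#' requires all four joints at or above the moderate cut-off; the
#' mild-to-severe incidence count uses the same all-joints rule at the mild
#' cut-off.
#'
#' @param scores scores data.frame from [score_cohort()].
#' @param day study day to tabulate (default: the last day present).
#' @param modality "TI", "THK" or "CS".
#' @param group optional group label filter (e.g. "CIA").
#' @return list of class `severity_heatmap`: `labels` (mice x 4 character
#'   matrix), `mouse_level` (named factor, min level across paws),
#'   `moderate_severe` (named logical), `n_moderate_severe`,
#'   `n_mild_severe`, `n_mice`, `modality`, `day`.
#' @export
severity_heatmap <- function(scores, day = NULL, modality = c("TI", "THK", "CS"),
                             group = NULL) {
  modality <- match.arg(modality)
  if (is.null(day)) day <- max(scores$day)
  sub <- scores[scores$day == day, ]
  if (!is.null(group)) sub <- sub[sub$group %in% group, ]
  if (nrow(sub) == 0L) stop("no rows at the requested day/group", call. = FALSE)
  cols <- switch(modality,
                 TI = paste0("ti_", tolower(.PAWS)),
                 THK = paste0("thk_", tolower(.PAWS)),
                 CS = paste0("cs_", tolower(.PAWS)))
  vals <- as.matrix(sub[, cols])
  lv <- suppressWarnings(classify_severity(as.numeric(vals), modality))
  labels <- matrix(as.character(lv), nrow(vals), 4L,
                   dimnames = list(sub$mouse_id, .PAWS))
  idx <- matrix(as.integer(lv), nrow(vals), 4L)
  mouse_min <- apply(idx, 1L, min)
  mouse_level <- factor(.SEVERITY_LEVELS[mouse_min],
                        levels = .SEVERITY_LEVELS, ordered = TRUE)
  names(mouse_level) <- sub$mouse_id
  moderate_severe <- mouse_min >= 3L
  names(moderate_severe) <- sub$mouse_id
  structure(list(labels = labels,
                 mouse_level = mouse_level,
                 moderate_severe = moderate_severe,
                 n_moderate_severe = sum(moderate_severe),
                 n_mild_severe = sum(mouse_min >= 2L),
                 n_mice = nrow(sub),
                 modality = modality, day = day),
            class = "severity_heatmap")
}

#' @export
print.severity_heatmap <- function(x, ...) {
  cat(sprintf("severity heatmap (%s, day %s): %d mice, %d moderate-severe, %d mild-severe\n",
              x$modality, format(x$day), x$n_mice, x$n_moderate_severe,
              x$n_mild_severe))
  print(x$labels)
  invisible(x)
}

#' Score a single phantom frame
#'
#' Runs [roi_stats()] over the seven-ellipse layout and computes the four
#' paw TIs and TI_total for one frame.
#'
#' @param frame a [thermal_frame()].
#' @param layout a `roi_layout` (default [default_roi_layout()] for the
#'   frame's shape).
#' @return list with `roi` (list of [roi_stats()]), `t_back`, `ti` (named
#'   four-vector) and `ti_total`.
#' @export
score_frame <- function(frame, layout = NULL) {
  stopifnot(inherits(frame, "thermal_frame"))
  if (is.null(layout)) layout <- default_roi_layout(c(frame$height, frame$width))
  stats <- lapply(layout, function(r) roi_stats(frame, r))
  t_back <- back_reference(vapply(stats[.BACKS], `[[`, 0, "mean"))
  ti <- vapply(.PAWS, function(p) temperature_index(stats[[p]]$mean, t_back), 0)
  list(roi = stats, t_back = t_back, ti = ti, ti_total = ti_total(ti))
}
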