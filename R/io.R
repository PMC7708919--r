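## Frame and table I/O, run configuration, pipeline orchestration.
##
## Frame formats:
##  * CSV: plain comma-separated matrix of deg C values, no header, "."
##    decimal, UTF-8; written with 17 significant digits so a write/read
##    round trip is bit-exact.
##  * raster: 16-bit unsigned TIFF with the common radiometric linear
##    scale  value = (T_c + 273.15) / 0.01  (centikelvin), i.e. round
##    trips are exact to 0.01 K.

.RASTER_SCALE <- 0.01   # K per digital number

#' Read / write a thermal frame
#'
#' @param path file path.
#' @param format "csv" (plain matrix of deg C values) or "raster" (16-bit
#'   centikelvin TIFF). `read_frame` infers the format from the file
#'   extension when `format` is NULL.
#' @param frame a [thermal_frame()].
#' @param metadata optional metadata list attached to the frame on read.
#' @return `read_frame` returns a [thermal_frame()]; `write_frame` returns
#'   `path` invisibly.
#' @export
read_frame <- function(path, format = NULL, metadata = list()) {
  if (is.null(format))
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "raster" else "csv"
  format <- match.arg(format, c("csv", "raster"))
  if (format == "csv") {
    lines <- readLines(path)
    if (length(lines) == 0L) stop("empty frame file: ", path, call. = FALSE)
    cells <- strsplit(lines, ",", fixed = TRUE)
    widths <- lengths(cells)
    if (length(unique(widths)) != 1L)
      stop(sprintf("non-rectangular matrix in %s: row %d has %d cells, row 1 has %d",
                   path, which(widths != widths[1L])[1L],
                   widths[which(widths != widths[1L])[1L]], widths[1L]),
           call. = FALSE)
    m <- matrix(suppressWarnings(as.numeric(unlist(cells))),
                nrow = length(lines), byrow = TRUE)
    if (any(!is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("invalid or NaN temperature at cell (%d,%d) of %s",
                   bad[1L], bad[2L], path), call. = FALSE)
    }
  } else {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (is.array(raw) && length(dim(raw)) == 3L) raw <- raw[, , 1L]
    m <- raw * .RASTER_SCALE - 273.15
  }
  thermal_frame(m, metadata = metadata)
}

#' @rdname read_frame
#' @export
write_frame <- function(frame, path, format = NULL) {
  stopifnot(inherits(frame, "thermal_frame"))
  if (is.null(format))
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "raster" else "csv"
  format <- match.arg(format, c("csv", "raster"))
  m <- frame$temperatures
  if (format == "csv") {
    writeLines(apply(m, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = ",")), path)
  } else {
    dn <- round((m + 273.15) / .RASTER_SCALE)
    if (any(dn < 0 | dn > 65535))
      stop("temperature outside the 16-bit raster range", call. = FALSE)
    tiff::writeTIFF(dn / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(path)
}

#' Read / write a tidy cohort table
#'
#' CSV dialect: comma separators, "." decimal, UTF-8, mandatory header row;
#' days written as integers, temperatures and thicknesses rounded to 2
#' decimals on output (0.01 degC / 0.01 mm, the instrument resolution).
#'
#' @param cohort a cohort data.frame ([generate_cohort()] format).
#' @param path file path.
#' @return `read_cohort` returns the cohort data.frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$surface_temp_c <- round(out$surface_temp_c, 2L)
  if ("thickness_mm" %in% names(out)) out$thickness_mm <- round(out$thickness_mm, 2L)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("mouse_id", "group", "day", "paw", "surface_temp_c")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Assemble and validate a pipeline run configuration
#'
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir output directory (created if missing).
#' @param cohort a [cohort_config()] (its seed is overridden by `seed`).
#' @param analysis_day day used for classification/correlation (default:
#'   last study day).
#' @param verbose logical; INFO-level progress messages.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "pawtherm-results",
                       cohort = cohort_config(), analysis_day = NULL,
                       verbose = TRUE) {
  stopifnot(inherits(cohort, "cohort_config"))
  cohort$seed <- check_count(seed, "seed")
  structure(list(seed = cohort$seed, out_dir = out_dir, cohort = cohort,
                 analysis_day = analysis_day %||% max(cohort$days),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full simulate / score / classify / analyze pipeline
#'
#' Deterministic end-to-end run: generates a synthetic cohort, scores it,
#' classifies severity at the analysis day, and computes the longitudinal
#' summaries and cross-modality correlations. Every written artifact is
#' stamped with the configuration hash and seed.
#'
#' @param config a [run_config()], or a path to a YAML file with fields
#'   `seed`, `out_dir` and optional cohort overrides (`n_cia`,
#'   `n_control`, `n_nonresponders`, `days`, `params`).
#' @return (invisibly) list with elements `cohort`, `scores`, `heatmaps`,
#'   `inclusion`, `summaries`, `correlations`, `paths`, `hash`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- .config_from_yaml(config)
  stopifnot(inherits(config, "run_config"))
  ## hash the scientific configuration only, not output locations/verbosity
  hash <- config_hash(list(seed = config$seed,
                           cohort = unclass(config$cohort),
                           analysis_day = config$analysis_day))
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(paste0("[INFO] ", fmt), ...)
    log_lines <<- c(log_lines, msg)
    if (config$verbose) message(msg)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("simulate: cohort seed %d (config %s)", config$seed, hash)
  cohort <- generate_cohort(config$cohort)
  say("score: %d measurement rows", nrow(cohort))
  scores <- score_cohort(cohort)

  day <- config$analysis_day
  say("classify: severity heatmaps at day %s", format(day))
  heatmaps <- lapply(c(TI = "TI", THK = "THK", CS = "CS"), function(m)
    suppressWarnings(severity_heatmap(scores, day = day, modality = m)))
  day_scores <- scores[scores$day == day, ]
  inclusion <- data.frame(mouse_id = day_scores$mouse_id,
                          group = day_scores$group,
                          included = day_scores$included)

  say("analyze: interval summaries and cross-modality correlation")
  summaries <- lapply(c(ti_total = "ti_total",
                        total_thickness = "total_thickness",
                        total_clinical = "total_clinical"),
                      function(ep) interval_summary(scores, ep))
  cia <- day_scores[day_scores$group == "CIA", ]
  correlations <- if (nrow(cia) >= 3L) list(
    ti_vs_thickness = correlate(cia$ti_total, cia$total_thickness),
    ti_vs_clinical = correlate(cia$ti_total, cia$total_clinical,
                               y_ordinal = TRUE)) else list()

  paths <- list(
    cohort = file.path(config$out_dir, "cohort.csv"),
    scores = file.path(config$out_dir, "scores.csv"),
    analysis = file.path(config$out_dir, "analysis.json"),
    log = file.path(config$out_dir, "log.txt"))
  write_cohort(cohort, paths$cohort)
  utils::write.csv(cbind(scores, config_hash = hash, seed = config$seed),
                   paths$scores, row.names = FALSE, quote = FALSE)
  for (m in names(heatmaps)) {
    paths[[paste0("heatmap_", m)]] <-
      file.path(config$out_dir, sprintf("heatmap_%s.csv", m))
    utils::write.csv(heatmaps[[m]]$labels, paths[[paste0("heatmap_", m)]],
                     quote = FALSE)
  }
  jsonlite::write_json(
    list(seed = config$seed, config_hash = hash, analysis_day = day,
         inclusion = inclusion,
         n_moderate_severe_TI = heatmaps$TI$n_moderate_severe,
         n_mild_severe_TI = heatmaps$TI$n_mild_severe,
         summaries = summaries,
         correlations = correlations),
    paths$analysis, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  say("report: artifacts in %s", config$out_dir)
  writeLines(c(sprintf("pawtherm run  seed=%d  config=%s", config$seed, hash),
               log_lines), paths$log)

  invisible(list(cohort = cohort, scores = scores, heatmaps = heatmaps,
                 inclusion = inclusion, summaries = summaries,
                 correlations = correlations, paths = paths, hash = hash))
}

.config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cc_args <- y[intersect(names(y), c("n_cia", "n_control", "n_nonresponders",
                                     "days", "params"))]
  run_config(seed = y$seed %||% 1L,
             out_dir = y$out_dir %||% "pawtherm-results",
             cohort = do.call(cohort_config, cc_args),
             analysis_day = y$analysis_day,
             verbose = y$verbose %||% TRUE)
}
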