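## Longitudinal group summaries, AUC-based efficacy quantification,
## normality-gated two-group tests, cross-modality correlation.

#' Trapezoid area under a longitudinal endpoint curve
#'
#' Composite trapezoid rule over the observed (possibly unequally spaced)
#' study days; no baseline subtraction is applied, so the area summarizes
#' the cumulative disease burden over the whole observation period in
#' endpoint-units x days.
#'
#' @param days strictly increasing measurement days (>= 2).
#' @param values endpoint values at those days.
#' @return area (endpoint-units x days).
#' @examples
#' auc_trapezoid(c(0, 3, 7), c(0, 3, 7)) # 24.5
#' @export
auc_trapezoid <- function(days, values) {
  if (!is.numeric(days) || !is.numeric(values) || length(days) < 2L ||
      length(days) != length(values) || any(!is.finite(days)) ||
      any(!is.finite(values)))
    stop("`days` and `values` must be finite vectors of equal length >= 2",
         call. = FALSE)
  if (is.unsorted(days, strictly = TRUE))
    stop("`days` must be strictly increasing", call. = FALSE)
  pracma::trapz(days, values)
}

#' Two-group comparison with a Shapiro-Wilk normality gate
#'
#' Implements the gated testing policy: ordinal endpoints go straight to
#' the two-sided Mann-Whitney (Wilcoxon rank-sum) test; continuous
#' endpoints are first checked per group with the Shapiro-Wilk test at
#' alpha = 0.05 and compared by the two-sided Student t test (pooled
#' variance) only if both groups pass, otherwise by Mann-Whitney. A group
#' whose normality cannot be assessed (fewer than 3 values, or zero
#' variance) routes to the nonparametric branch.
#'
#' @param a,b numeric endpoint values of the two groups (>= 2 each).
#' @param ordinal TRUE for ordinal endpoints (skips the gate).
#' @param alpha significance level recorded in the report (default 0.05).
#' @return list of class `test_report`: `test_name` ("t" or
#'   "Mann-Whitney"), `statistic`, `p_value`, `normality_p` (named, NA when
#'   not assessed), `alpha`, `significant`, `route` (human-readable gating
#'   decision).
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6), ordinal = TRUE)$p_value # 0.1
#' @export
compare_groups <- function(a, b, ordinal = FALSE, alpha = 0.05) {
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) || any(!is.finite(b)))
    stop("group values must be finite numeric", call. = FALSE)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  shapiro_p <- function(x) {
    if (length(x) < 3L || stats::var(x) == 0) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  normality_p <- c(a = NA_real_, b = NA_real_)
  if (ordinal) {
    route <- "ordinal endpoint -> Mann-Whitney"
    use_t <- FALSE
  } else {
    normality_p <- c(a = shapiro_p(a), b = shapiro_p(b))
    use_t <- all(!is.na(normality_p)) && all(normality_p > alpha)
    route <- if (use_t)
      "both groups normal (Shapiro-Wilk p > alpha) -> Student t"
    else
      "normality not established in both groups -> Mann-Whitney"
  }
  if (use_t) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test_name <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    test_name <- "Mann-Whitney"
  }
  p_value <- ht$p.value
  ## completely tied samples make the normal approximation 0/0; there is no
  ## evidence against the null, so report p = 1
  if (is.nan(p_value)) p_value <- 1
  structure(list(test_name = test_name,
                 statistic = unname(ht$statistic),
                 p_value = p_value,
                 normality_p = normality_p,
                 alpha = alpha,
                 significant = p_value < alpha,
                 route = route),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s test: statistic %.4g, p = %.4g (%s)\n  %s\n",
              x$test_name, x$statistic, x$p_value,
              if (x$significant) "significant" else "ns", x$route))
  invisible(x)
}

#' Correlation between a continuous and a continuous or ordinal endpoint
#'
#' Pearson's r for continuous-continuous pairs, tie-corrected Kendall's
#' tau (tau-b) for continuous-ordinal pairs.
#'
#' @param x continuous values.
#' @param y continuous or ordinal values.
#' @param y_ordinal TRUE if `y` is ordinal (selects Kendall).
#' @return list with `method` ("pearson"/"kendall"), `estimate`, `p_value`,
#'   `n`.
#' @examples
#' correlate(c(1, 2, 3), c(1, 3, 2), y_ordinal = TRUE)$estimate # 1/3
#' @export
correlate <- function(x, y, y_ordinal = FALSE) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("`x` and `y` must be numeric vectors of equal length", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  method <- if (y_ordinal) "kendall" else "pearson"
  est <- stats::cor(x, y, method = method)
  p <- suppressWarnings(stats::cor.test(x, y, method = method)$p.value)
  list(method = method, estimate = unname(est), p_value = p, n = length(x))
}

#' Per-group per-day endpoint summaries
#'
#' Mean, SD, range and n of an endpoint for every group x day cell
#' (interval-plot style summaries). The SD of a single observation is
#' reported as 0.
#'
#' @param scores scores data.frame from [score_cohort()] (or any data.frame
#'   with `group`, `day` and the endpoint column).
#' @param endpoint endpoint column name, e.g. "ti_total".
#' @return data.frame with columns `group`, `day`, `mean`, `sd`, `min`,
#'   `max`, `n`.
#' @export
interval_summary <- function(scores, endpoint) {
  if (!endpoint %in% names(scores))
    stop(sprintf("endpoint '%s' not found", endpoint), call. = FALSE)
  if (nrow(scores) == 0L) stop("empty input", call. = FALSE)
  v <- scores[[endpoint]]
  out <- do.call(rbind, lapply(
    split(seq_len(nrow(scores)), list(scores$group, scores$day), drop = TRUE),
    function(idx) data.frame(
      group = scores$group[idx[1L]], day = scores$day[idx[1L]],
      mean = mean(v[idx]),
      sd = if (length(idx) > 1L) stats::sd(v[idx]) else 0,
      min = min(v[idx]), max = max(v[idx]), n = length(idx))))
  rownames(out) <- NULL
  out[order(out$group, out$day), ]
}

#' AUC-based treatment-efficacy analysis
#'
#' Computes a per-mouse trapezoid AUC over the study period for each
#' endpoint, then compares the per-mouse AUC distributions pairwise between
#' groups with [compare_groups()]. Clinical-score AUCs are routed as
#' ordinal (Mann-Whitney); the other endpoints pass through the normality
#' gate. Significance stars: * p < 0.05, ** p < 0.01, *** p < 0.001.
#'
#' @param scores scores data.frame from [score_cohort()] covering >= 2 days
#'   and >= 2 groups.
#' @param endpoints endpoint columns to analyze.
#' @param ordinal_endpoints endpoints whose AUCs are compared as ordinal.
#' @return list of class `efficacy_analysis`: `auc` (data.frame mouse x
#'   endpoint AUCs with group), `comparisons` (data.frame with endpoint,
#'   group pair, test, p, stars), `summaries` (per-group mean/SD of AUC).
#' @export
efficacy_analysis <- function(scores,
                              endpoints = c("ti_total", "total_thickness",
                                            "total_clinical"),
                              ordinal_endpoints = "total_clinical") {
  if (length(unique(scores$group)) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  missing_ep <- setdiff(endpoints, names(scores))
  if (length(missing_ep))
    stop("endpoint(s) not found: ", paste(missing_ep, collapse = ", "),
         call. = FALSE)

  auc <- do.call(rbind, lapply(split(scores, scores$mouse_id), function(d) {
    d <- d[order(d$day), ]
    row <- data.frame(mouse_id = d$mouse_id[1L], group = d$group[1L])
    for (ep in endpoints)
      row[[paste0("auc_", ep)]] <- auc_trapezoid(d$day, d[[ep]])
    row
  }))
  rownames(auc) <- NULL

  groups <- sort(unique(auc$group))
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  star <- function(p) if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else "ns"
  comparisons <- do.call(rbind, lapply(endpoints, function(ep) {
    do.call(rbind, lapply(pairs, function(pr) {
      va <- auc[[paste0("auc_", ep)]][auc$group == pr[1L]]
      vb <- auc[[paste0("auc_", ep)]][auc$group == pr[2L]]
      rep_ <- compare_groups(va, vb, ordinal = ep %in% ordinal_endpoints)
      data.frame(endpoint = ep, group_a = pr[1L], group_b = pr[2L],
                 test = rep_$test_name, statistic = rep_$statistic,
                 p_value = rep_$p_value, stars = star(rep_$p_value))
    }))
  }))
  rownames(comparisons) <- NULL

  summaries <- do.call(rbind, lapply(endpoints, function(ep) {
    agg <- stats::aggregate(auc[[paste0("auc_", ep)]],
                            by = list(group = auc$group),
                            FUN = function(x) c(mean = mean(x),
                                                sd = if (length(x) > 1) stats::sd(x) else 0,
                                                n = length(x)))
    data.frame(endpoint = ep, group = agg$group,
               mean_auc = agg$x[, "mean"], sd_auc = agg$x[, "sd"],
               n = agg$x[, "n"])
  }))
  rownames(summaries) <- NULL

  structure(list(auc = auc, comparisons = comparisons, summaries = summaries),
            class = "efficacy_analysis")
}

#' @export
print.efficacy_analysis <- function(x, ...) {
  cat("Per-mouse AUC treatment-efficacy analysis\n")
  print(x$summaries)
  cat("\nPairwise comparisons:\n")
  print(x$comparisons[, c("endpoint", "group_a", "group_b", "test",
                          "p_value", "stars")])
  invisible(x)
}
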