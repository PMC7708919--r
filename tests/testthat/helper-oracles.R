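# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and library calls) they verify.

# exhaustive pixel-center count/collection for a rotated ellipse
oracle_ellipse_pixels <- function(cx, cy, a, b, rot, nrow, ncol) {
  hits <- matrix(FALSE, nrow, ncol)
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      dx <- (c - 1) - cx
      dy <- (r - 1) - cy
      u <- (dx * cos(rot) + dy * sin(rot)) / a
      v <- (-dx * sin(rot) + dy * cos(rot)) / b
      hits[r, c] <- u^2 + v^2 <= 1
    }
  }
  hits
}

# per-pixel loop statistics (population SD)
oracle_stats <- function(values) {
  n <- length(values)
  mu <- sum(values) / n
  list(min = min(values), max = max(values), mean = mu,
       sd = sqrt(sum((values - mu)^2) / n), n = n)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled)) # exact only without ties
  n1 <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">"))
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2L, function(i) u_stat(pooled[i], pooled[-i]))
  u_obs <- u_stat(a, b)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# tie-corrected Kendall tau-b by explicit pair counting
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_count(x)) * (n0 - tie_count(y)))
}

tie_count <- function(v) {
  tt <- table(v)
  sum(tt * (tt - 1) / 2)
}

# textbook Pearson r
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# composite trapezoid by explicit loop
oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

# coefficient of determination from its definition
oracle_r2 <- function(x, y) {
  fit <- stats::lsfit(x, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

# hand-built tidy cohort table for one or more mice at one day
make_cohort_table <- function(mouse_id, group, day, paw_temps, back_temps,
                              thickness = rep(1.8, 4), clinical = rep(0L, 4)) {
  rbind(
    data.frame(mouse_id = mouse_id, group = group, day = day,
               paw = c("FL", "FR", "HL", "HR"),
               surface_temp_c = paw_temps, thickness_mm = thickness,
               clinical_score = clinical, stringsAsFactors = FALSE),
    data.frame(mouse_id = mouse_id, group = group, day = day,
               paw = c("back1", "back2", "back3"),
               surface_temp_c = back_temps, thickness_mm = NA_real_,
               clinical_score = NA_integer_, stringsAsFactors = FALSE))
}
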