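test_that("trapezoid AUC matches hand-computed areas", {
  expect_equal(auc_trapezoid(c(0, 28), c(5, 5)), 140)      # constant -> 28*v
  expect_equal(auc_trapezoid(c(0, 3, 7), c(0, 3, 7)), 24.5) # 4.5 + 20
  expect_equal(auc_trapezoid(c(0, 28), c(4, 3)), 98)        # 14*(v1+v2)
  expect_error(auc_trapezoid(c(0, 7, 3), c(1, 2, 3)), "strictly increasing")
  expect_error(auc_trapezoid(c(0), c(1)), "length >= 2")
})

test_that("trapezoid AUC equals the loop oracle, is additive and linear", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(3:9, 1)
    d <- sort(sample(0:40, n))
    v <- rnorm(n, 5, 2)
    expect_equal(auc_trapezoid(d, v), oracle_trapz(d, v), tolerance = 1e-9)
    ## additivity over a split at an interior knot
    k <- if (n == 3) 2L else sample(2:(n - 1), 1)
    expect_equal(auc_trapezoid(d, v),
                 auc_trapezoid(d[1:k], v[1:k]) + auc_trapezoid(d[k:n], v[k:n]),
                 tolerance = 1e-9)
    ## linearity in the values
    w <- rnorm(n)
    expect_equal(auc_trapezoid(d, 2 * v + 3 * w),
                 2 * auc_trapezoid(d, v) + 3 * auc_trapezoid(d, w),
                 tolerance = 1e-9)
  }
})

test_that("ordinal endpoints route to the exact Mann-Whitney test", {
  rep_ <- compare_groups(c(1, 2, 3), c(4, 5, 6), ordinal = TRUE)
  expect_identical(rep_$test_name, "Mann-Whitney")
  expect_equal(rep_$statistic, 0) # U = 0
  expect_equal(rep_$p_value, 0.1) # exact two-sided over C(6,3) = 20 splits
  expect_true(all(is.na(rep_$normality_p)))
})

test_that("Mann-Whitney p-values match the exhaustive permutation oracle for n <= 4", {
  set.seed(42)
  for (i in 1:100) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    a <- round(runif(n1, 0, 100), 6)
    b <- round(runif(n2, 0, 100) + runif(1, -20, 20), 6)
    rep_ <- compare_groups(a, b, ordinal = TRUE)
    expect_equal(rep_$p_value, oracle_mw_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("the normality gate selects t for normal data and Mann-Whitney otherwise", {
  set.seed(43)
  a <- rnorm(10); b <- rnorm(10, 1)
  rep_n <- compare_groups(a, b)
  expect_identical(rep_n$test_name, "t")
  expect_true(all(rep_n$normality_p > 0.05))
  ## grossly lognormal data fails the gate
  x <- exp(rnorm(20, 0, 2)); y <- exp(rnorm(20, 0.5, 2))
  rep_l <- compare_groups(x, y)
  expect_identical(rep_l$test_name, "Mann-Whitney")
  ## zero-variance groups cannot be assessed and route nonparametric
  rep_c <- compare_groups(rep(1, 5), rep(1, 5))
  expect_identical(rep_c$test_name, "Mann-Whitney")
  expect_gte(rep_c$p_value, 0.99)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("identical normally-distributed groups give p near 1", {
  g <- c(3.5, 3.6, 3.7, 3.8)
  rep_ <- compare_groups(g, g)
  expect_gte(rep_$p_value, 0.99)
})

test_that("a 3-sigma shift at n = 4 is detected in most replicates", {
  hits <- vapply(1:100, function(s) {
    set.seed(5000 + s)
    a <- rnorm(4, 0, 1); b <- rnorm(4, 3, 1)
    compare_groups(a, b)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("the gated procedure holds its nominal type-I error under the null", {
  hits <- vapply(1:2000, function(s) {
    set.seed(20000 + s)
    compare_groups(rnorm(8), rnorm(8))$p_value < 0.05
  }, TRUE)
  expect_lt(abs(mean(hits) - 0.05), 0.015) # binomial CI at 2000 replicates
})

test_that("Pearson and Kendall estimates match their brute-force definitions", {
  expect_equal(correlate(1:5, 2 * (1:5) + 3)$estimate, 1)
  expect_equal(correlate(c(1, 2, 3), c(1, 3, 2), y_ordinal = TRUE)$estimate,
               1 / 3, tolerance = 1e-12)
  set.seed(44)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(correlate(x, y)$estimate, oracle_pearson(x, y),
                 tolerance = 1e-12)
    yo <- sample(0:4, n, replace = TRUE)
    if (var(yo) == 0) yo[1] <- yo[1] + 1
    expect_equal(correlate(x, yo, y_ordinal = TRUE)$estimate,
                 oracle_kendall_tau_b(x, yo), tolerance = 1e-12)
  }
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate(1:2, 1:2), "n >= 3")
})

test_that("interval summaries equal a brute-force recomputation", {
  tbl <- data.frame(group = c("A", "A", "A", "B"), day = c(0, 0, 0, 0),
                    v = c(3.5, 3.6, 3.7, 9.9))
  s <- interval_summary(tbl, "v")
  a <- s[s$group == "A", ]
  expect_equal(a$mean, 3.6)
  expect_equal(a$min, 3.5)
  expect_equal(a$max, 3.7)
  expect_equal(a$n, 3)
  b <- s[s$group == "B", ]
  expect_identical(b$sd, 0) # single-observation convention
  set.seed(45)
  co <- score_cohort(generate_cohort(cohort_config(seed = 46)))
  s2 <- interval_summary(co, "ti_total")
  for (r in seq_len(nrow(s2))) {
    v <- co$ti_total[co$group == s2$group[r] & co$day == s2$day[r]]
    expect_equal(s2$mean[r], mean(v), tolerance = 1e-12)
    expect_equal(s2$sd[r], sd(v), tolerance = 1e-12)
  }
})

test_that("efficacy analysis: identical constant trajectories are non-significant", {
  tbl <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(mouse_id = paste0("m", i),
               group = ifelse(i <= 4, "A", "B"),
               day = c(0, 14, 28), ti_total = 3.4,
               total_thickness = 7.2, total_clinical = 0L)
  }))
  ## add negligible jitter so variances are defined but groups stay identical
  set.seed(47)
  jit <- rep(rnorm(4, 0, 1e-9), each = 3)
  tbl$ti_total <- tbl$ti_total + c(jit, jit)
  tbl$total_thickness <- tbl$total_thickness + c(jit, jit)
  ea <- efficacy_analysis(tbl)
  expect_true(all(ea$comparisons$p_value > 0.9))
})

test_that("efficacy analysis computes hand-checkable AUCs and stars", {
  tbl <- do.call(rbind, lapply(1:4, function(i) {
    v <- if (i <= 2) 4 else c(4, 3.5, 3)
    data.frame(mouse_id = paste0("m", i),
               group = ifelse(i <= 2, "vehicle", "treated"),
               day = c(0, 14, 28), ti_total = v,
               total_thickness = 8, total_clinical = 2L)
  }))
  ea <- efficacy_analysis(tbl, endpoints = "ti_total")
  auc <- stats::setNames(ea$auc$auc_ti_total, ea$auc$mouse_id)
  expect_equal(unname(auc["m1"]), 112)   # 28 * 4
  expect_equal(unname(auc["m3"]), 98)    # trapezoid of 4 -> 3.5 -> 3
  expect_true(all(c("endpoint", "p_value", "stars") %in% names(ea$comparisons)))
})
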