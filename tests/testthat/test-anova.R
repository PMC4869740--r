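test_that("one-way ANOVA matches the squared pooled t statistic and aov", {
  set.seed(11)
  d <- data.frame(
    g = rep(c("a", "b"), c(12, 9)),
    y = c(rnorm(12, 5, 2), rnorm(9, 6.2, 2))
  )
  res <- one_way_anova(d, y, g)
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(tidy(res)$statistic, unname(tt$statistic^2), tolerance = 1e-9)
  expect_equal(tidy(res)$p.value, tt$p.value, tolerance = 1e-9)

  # three groups against the stats::aov oracle
  d3 <- data.frame(g = rep(c("a", "b", "c"), c(8, 10, 7)),
                   y = rnorm(25, rep(c(0, 1, 0.5), c(8, 10, 7))))
  res3 <- one_way_anova(d3, y, g)
  ref <- summary(aov(y ~ g, data = d3))[[1]]
  expect_equal(tidy(res3)$statistic, ref[1, "F value"], tolerance = 1e-9)
  expect_equal(res3$df_den, ref[2, "Df"])
})

test_that("one-way ANOVA degenerates and errors are as defined", {
  d <- data.frame(g = rep(c("a", "b"), each = 4), y = rep(c(1, 2, 3, 4), 2))
  res <- one_way_anova(d, y, g)
  expect_equal(tidy(res)$statistic, 0)
  expect_equal(tidy(res)$p.value, 1)
  expect_error(one_way_anova(data.frame(g = "a", y = 1), y, g), "2 groups")
  expect_error(one_way_anova(data.frame(g = c("a", "a", "b"), y = 1:3), y, g),
               "at least 2 observations")
})

test_that("summary-path two-way ANOVA equals the raw path and, when balanced, lm", {
  set.seed(21)
  d <- tidyr::expand_grid(a = c("x", "y"), b = c("p", "q"), rep = 1:8)
  d$v <- rnorm(nrow(d), ifelse(d$a == "x", 0, 1) + ifelse(d$b == "p", 0, 0.5))
  raw <- two_way_anova(d, v, a, b)

  cells <- dplyr::summarise(
    dplyr::group_by(d, a, b),
    mean = mean(v), sem = sd(v) / sqrt(dplyr::n()), n = dplyr::n(),
    .groups = "drop"
  )
  summ <- two_way_anova_summary(cells, a, b, mean, sem, n)
  expect_equal(tidy(raw)$statistic, tidy(summ)$statistic, tolerance = 1e-9)
  expect_equal(raw$ms_within, summ$ms_within, tolerance = 1e-9)

  # balanced design: matches the regression (design-matrix) decomposition
  fit <- anova(lm(v ~ a * b, data = d))
  expect_equal(tidy(raw)$statistic, fit[1:3, "F value"], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(raw$df_den, fit["Residuals", "Df"])
})

test_that("balanced two-way sums of squares are additive and affine-invariant", {
  set.seed(22)
  d <- tidyr::expand_grid(a = c("x", "y"), b = c("p", "q"), rep = 1:6)
  d$v <- rnorm(nrow(d))
  res <- two_way_anova(d, v, a, b)
  ss_total <- sum((d$v - mean(d$v))^2)
  ss_within <- res$ms_within * res$df_den
  expect_equal(sum(tidy(res)$sumsq) + ss_within, ss_total,
               tolerance = 1e-9 * ss_total)

  d2 <- d; d2$v <- 3.7 * d$v - 11
  res2 <- two_way_anova(d2, v, a, b)
  expect_equal(tidy(res)$statistic, tidy(res2)$statistic, tolerance = 1e-9)

  # all cells equal -> all F zero
  d3 <- d; d3$v <- rep(c(1, 2, 1.5), length.out = nrow(d))
  d3$v <- ave(d3$v, d3$a, d3$b)  # force equal values within cells? no: equal means
  d0 <- tidyr::expand_grid(a = c("x", "y"), b = c("p", "q"), rep = 1:3)
  d0$v <- rep(c(1, 2, 3), times = 4)
  expect_true(all(tidy(two_way_anova(d0, v, a, b))$statistic == 0))
})

test_that("unbalanced summary ANOVA input validation holds", {
  cells <- gabazine_reference_summaries()
  expect_error(two_way_anova_summary(cells[-1, ], genotype, treatment, mean, sem, n),
               "one row per design cell")
  bad <- cells; bad$n[1] <- 1
  expect_error(two_way_anova_summary(bad, genotype, treatment, mean, sem, n),
               "n >= 2")
  degen <- cells; degen$sem[2] <- 0
  expect_warning(two_way_anova_summary(degen, genotype, treatment, mean, sem, n),
                 "SEM = 0")
})

test_that("mixed ANOVA matches aov and the difference-score t identity", {
  set.seed(31)
  d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:12), w = c("w1", "w2", "w3"))
  d$g <- ifelse(d$subject %in% sprintf("s%02d", 1:6), "WT", "DF")
  d$y <- rnorm(nrow(d)) + ifelse(d$g == "WT", 0, 0.8) + ifelse(d$w == "w3", 0.5, 0)
  res <- mixed_anova(d, y, g, w, subject)
  ref <- summary(aov(y ~ g * w + Error(subject), data = d))
  f_between <- ref[["Error: subject"]][[1]]["g", "F value"]
  f_within <- ref[["Error: Within"]][[1]][c("w", "g:w"), "F value"]
  expect_equal(tidy(res)$statistic, c(f_between, f_within), tolerance = 1e-9,
               ignore_attr = TRUE)

  # 2 groups x 2 levels: interaction F = squared t on difference scores
  d2 <- tidyr::expand_grid(subject = sprintf("s%02d", 1:10), w = c("w1", "w2"))
  d2$g <- ifelse(d2$subject %in% sprintf("s%02d", 1:5), "WT", "DF")
  set.seed(32)
  d2$y <- rnorm(nrow(d2)) + ifelse(d2$g == "DF" & d2$w == "w2", 1, 0)
  res2 <- mixed_anova(d2, y, g, w, subject)
  diffs <- tidyr::pivot_wider(d2, names_from = w, values_from = y)
  diffs$d <- diffs$w2 - diffs$w1
  tt <- t.test(d ~ g, data = diffs, var.equal = TRUE)
  f_int <- tidy(res2)$statistic[tidy(res2)$term == "g:w"]
  expect_equal(f_int, unname(tt$statistic^2), tolerance = 1e-9)
})

test_that("mixed ANOVA flags incomplete grids and drops incomplete subjects", {
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:6), w = c("w1", "w2"))
  d$g <- ifelse(d$subject %in% sprintf("s%d", 1:3), "a", "b")
  d$y <- seq_len(nrow(d))
  dup <- rbind(d, d[1, ])
  expect_error(mixed_anova(dup, y, g, w, subject), "exactly one value")

  # a subject with a missing level is removed listwise, not imputed
  d_na <- d; d_na$y[1] <- NA
  res <- mixed_anova(d_na, y, g, w, subject)
  expect_equal(res$n_obs, nrow(d) - 2L)

  # identical within-levels per subject -> within F = 0
  d0 <- d; d0$y <- rep(1:6, each = 2) + ifelse(d0$g == "a", 0, 3)
  res0 <- mixed_anova(d0, y, g, w, subject)
  expect_equal(tidy(res0)$statistic[2:3], c(0, 0))
})

test_that("F p-values behave and reject invalid input", {
  expect_equal(f_pvalue(0, 1, 10), 1)
  expect_equal(f_pvalue(14.63, 1, 115), pf(14.63, 1, 115, lower.tail = FALSE))
  expect_error(f_pvalue(-1, 1, 10), "non-negative")
  expect_error(f_pvalue(1, 0, 10), "df")
})

test_that("Newman-Keuls reduces to the pooled t test for two groups", {
  set.seed(41)
  g1 <- rnorm(10, 0); g2 <- rnorm(12, 1)
  msw <- ((10 - 1) * var(g1) + (12 - 1) * var(g2)) / 20
  groups <- tibble::tibble(group = c("a", "b"), mean = c(mean(g1), mean(g2)),
                           n = c(10L, 12L))
  nk <- newman_keuls(groups, msw, 20)
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(nk$q, unname(abs(tt$statistic)) * sqrt(2), tolerance = 1e-9)
  expect_equal(nk$p.value, tt$p.value, tolerance = 1e-6)

  # studentized range at r = 2 equals the two-sided t probability
  q <- 2.7; df <- 30
  expect_equal(ptukey(q, 2, df, lower.tail = FALSE),
               2 * pt(q / sqrt(2), df, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("Newman-Keuls stepwise blocking declares nested ranges non-significant", {
  # identical means: nothing significant
  groups <- tibble::tibble(group = letters[1:4], mean = rep(1, 4), n = rep(10L, 4))
  nk0 <- newman_keuls(groups, ms_within = 1, df_within = 36)
  expect_false(any(nk0$significant))

  # an outer non-significant range blocks its nested pairs even if a nested
  # q would nominally exceed its own critical value
  groups2 <- tibble::tibble(group = letters[1:3], mean = c(0, 0.9, 1.0),
                            n = rep(4L, 3))
  nk2 <- newman_keuls(groups2, ms_within = 1.1, df_within = 9, alpha = 0.05)
  outer <- nk2[nk2$range_r == 3, ]
  if (!outer$significant) {
    expect_false(any(nk2$significant[nk2$range_r < 3]))
  }
  expect_error(newman_keuls(groups2, ms_within = 0, df_within = 9), "positive")
})
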