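test_that("two_way_anova: exact-null case gives zero F", {
  # every cell carries the same values, so observed cell means are equal
  d <- expand.grid(a = c("x", "y"), b = c("p", "q", "r"))
  d <- d[rep(seq_len(6), each = 3), ]
  y <- rep(c(1, 2, 3), times = 6)  # within-cell noise, equal cell means
  res <- two_way_anova(y, d$a, d$b)
  expect_equal(res$F[1:3], rep(0, 3), tolerance = 1e-6)
  expect_equal(res$p[1:3], rep(1, 3), tolerance = 1e-6)
})

test_that("balanced 2x3 design matches the cell-means brute-force decomposition", {
  set.seed(12)
  for (rep in 1:5) {
    d <- expand.grid(a = c("x", "y"), b = c("p", "q", "r"))
    d <- d[rep(seq_len(6), each = 4), ]
    y <- rnorm(24, mean = as.integer(d$a) + 2 * as.integer(d$b))
    res <- two_way_anova(y, d$a, d$b)
    oracle <- anova_brute_balanced(y, d$a, d$b)
    expect_equal(res$sum_sq[1], oracle$ss_a)
    expect_equal(res$sum_sq[2], oracle$ss_b)
    expect_equal(res$sum_sq[3], oracle$ss_ab)
    expect_equal(res$sum_sq[4], oracle$ss_err)
    # balanced partition conserves SS_total
    expect_equal(sum(res$sum_sq), attr(res, "ss_total"), tolerance = 1e-8)
  }
})

test_that("unbalanced designs reproduce Type-III marginal tests (drop1 oracle)", {
  set.seed(13)
  for (rep in 1:5) {
    n <- c(11, 8, 6, 11, 5, 9)  # unequal cells as in real cohorts
    d <- expand.grid(a = c("ctrl", "gf"), b = c("w4", "w8", "w12"))
    d <- d[rep(seq_len(6), times = n), ]
    y <- rnorm(sum(n), mean = 2 * (d$a == "gf") + as.integer(d$b))
    res <- two_way_anova(y, d$a, d$b)
    fit <- lm(y ~ a * b, data = cbind(d, y = y),
              contrasts = list(a = "contr.sum", b = "contr.sum"))
    dr <- drop1(fit, . ~ ., test = "F")  # Type-III SS under contr.sum
    expect_equal(res$sum_sq[1:3], dr$`Sum of Sq`[2:4], tolerance = 1e-8)
    expect_equal(res$F[1:3], dr$`F value`[2:4], tolerance = 1e-8)
    expect_equal(res$p[1:3], dr$`Pr(>F)`[2:4], tolerance = 1e-8)
  }
})

test_that("anova preconditions and reporting convention", {
  expect_error(two_way_anova(rnorm(4), c("a", "a", "a", "a"),
                             c("p", "p", "q", "q")), ">= 2 levels")
  expect_error(two_way_anova(rnorm(4), c("a", "a", "b", "b"),
                             c("p", "q", "q", "q")), "empty cell")
  set.seed(14)
  d <- expand.grid(a = c("x", "y"), b = c("p", "q", "r"))
  d <- d[rep(seq_len(6), each = 4), ]
  res <- two_way_anova(rnorm(24), d$a, d$b, c("group", "age"))
  expect_match(format_effect(res, "age"),
               "^F\\(2,18\\) = \\d+\\.\\d{2}, p (=|<) ")
  expect_equal(res$effect, c("group", "age", "group:age", "Residuals"))
})

test_that("SNK with two groups collapses to the sqrt(2) t identity", {
  set.seed(15)
  for (rep in 1:10) {
    m <- c(g1 = rnorm(1, 10), g2 = rnorm(1, 11))
    n <- sample(4:12, 2, replace = TRUE)
    ms <- runif(1, 0.5, 4); df <- sum(n) - 2
    res <- snk_posthoc(m, n, ms, df)
    tstat <- unname(abs(diff(m))) / sqrt(ms * (1 / n[1] + 1 / n[2]))
    expect_equal(res$q, sqrt(2) * tstat, tolerance = 1e-10)
    # the identity is algebraic; ptukey itself is accurate to ~1e-8 absolute
    expect_equal(res$p, 2 * pt(-tstat, df), tolerance = 1e-5)
  }
})

test_that("SNK sealing: a non-significant outer range seals nested comparisons", {
  # outer span q = 3.75 < q_crit(3, 10) ~ 3.88, so the whole triple is
  # non-significant even though the inner (0, 2.9) pair at k = 2 has
  # q = 3.625 > q_crit(2, 10) ~ 3.15
  res <- snk_posthoc(c(a = 0, b = 2.9, c = 3.0), cell_ns = c(1, 1, 1),
                     ms_error = 0.64, df_error = 10)
  expect_true(all(!res$significant))
  inner <- res[res$group_i == "a" & res$group_j == "b", ]
  expect_gt(inner$q, qtukey(0.95, 2, 10))  # would pass in isolation
  expect_true(inner$sealed)
})

test_that("SNK is never more conservative than Tukey HSD (equal n)", {
  set.seed(16)
  for (rep in 1:30) {
    K <- sample(3:6, 1)
    m <- rnorm(K, sd = 2); names(m) <- paste0("g", seq_len(K))
    n <- rep(sample(4:10, 1), K)
    ms <- runif(1, 0.5, 3); df <- sum(n) - K
    res <- snk_posthoc(m, n, ms, df)
    for (i in seq_len(nrow(res))) {
      tukey_p <- ptukey(res$q[i], nmeans = K, df = df, lower.tail = FALSE)
      if (tukey_p < 0.05) expect_true(res$significant[i])
    }
  }
})

test_that("SNK input validation", {
  expect_error(snk_posthoc(c(a = 1, b = 2), c(3, 3), ms_error = 0,
                           df_error = 5), "positive")
  expect_error(snk_posthoc(c(a = 1, b = 2), c(3, 3), ms_error = 1,
                           df_error = 0), ">= 1")
})

test_that("degree/neurogenesis correlation: degenerate, oracle and alignment", {
  # perfectly collinear points
  dc <- degree_neurogenesis_correlation(
    c(g1 = 1, g2 = 2, g3 = 3, g4 = 4),
    c(g1 = 10, g2 = 20, g3 = 30, g4 = 40))
  expect_equal(dc$r, 1)
  expect_equal(dc$r_squared, 1)
  expect_equal(dc$p, 0)

  set.seed(17)
  for (rep in 1:10) {
    deg <- stats::setNames(sample(0:7, 6, replace = TRUE) + rnorm(6, sd = 1e-9),
                           paste0("g", 1:6))
    dcx <- stats::setNames(runif(6, 500, 2500), paste0("g", 1:6))
    dc <- degree_neurogenesis_correlation(deg, dcx)
    expect_equal(dc$r, pearson_brute(deg, dcx))
    expect_equal(dc$df, 4L)
    expect_equal(dc$p, t_tail_p_oracle(dc$r, 6), tolerance = 1e-8)
    # alignment is by name, not position
    shuffled <- sample(dcx)
    expect_equal(degree_neurogenesis_correlation(deg, shuffled)$r, dc$r)
  }
  expect_error(degree_neurogenesis_correlation(c(a = 1, b = 2, c = 3),
                                               c(a = 1, b = 2, d = 3)),
               "group sets differ")
  expect_error(degree_neurogenesis_correlation(c(a = 1, b = 2),
                                               c(a = 1, b = 2)), ">= 3")
})
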