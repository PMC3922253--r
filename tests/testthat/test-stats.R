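# Group statistics: normality gate, ANOVA/SNK, Kruskal-Wallis, chi-square.

test_that("normality gate routes clean normals and obvious non-normals", {
  set.seed(1)
  norm5 <- replicate(5, rnorm(200), simplify = FALSE)
  expect_equal(normality_gate(norm5), "normal")
  withexp <- c(norm5[1:4], list(rexp(100)))
  expect_equal(normality_gate(withexp), "non_normal")
  # degenerate constant group
  expect_equal(normality_gate(list(rnorm(50), rep(1, 50))), "non_normal")
  # tiny groups cannot be assessed -> non-parametric route
  expect_equal(normality_gate(list(rnorm(3), rnorm(3))), "non_normal")
  expect_error(normality_gate(list(rnorm(5), 1)), "at least 2")
})

test_that("Lilliefors p-values are calibrated near the null", {
  set.seed(2)
  rej <- mean(replicate(400, lillie_test(rnorm(50))$p.value < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
  # strong departure is detected essentially always at n = 100
  rej_exp <- mean(replicate(50, lillie_test(rexp(100))$p.value < 0.05))
  expect_gt(rej_exp, 0.9)
})

test_that("SNK on two groups reduces to the pairwise studentized-range test", {
  set.seed(3)
  g <- list(a = rnorm(30), b = rnorm(30, 2))
  ph <- snk_posthoc(g)
  expect_equal(nrow(ph), 1)
  expect_true(ph$significant)
  # two-group studentized range == sqrt(2) * t, critical value identity
  expect_equal(stats::qtukey(0.95, 2, 58) / sqrt(2), stats::qt(0.975, 58),
               tolerance = 1e-6)
  y <- unlist(g)
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(ph$q, sqrt(2) * abs(tt$statistic), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("compare_groups detects a large separation and flags the pair", {
  set.seed(4)
  vals <- list(a = rnorm(30, 0), b = rnorm(30, 2))
  res <- compare_groups(vals)
  expect_equal(res$test_used, "anova")
  expect_lt(res$omnibus_p, 0.001)
  expect_true(res$posthoc$significant[1])
})

test_that("identical groups produce p ~ 1 and no posthoc flags", {
  x <- rep(c(1, 2, 3, 4, 5), 3)
  res <- compare_groups(list(a = x, b = x, c = x))
  expect_gte(res$omnibus_p, 0.99)
  expect_null(res$posthoc)
})

test_that("group relabeling permutes but never changes test results", {
  set.seed(5)
  vals <- list(a = rnorm(20), b = rnorm(20, 0.5), c = rnorm(20, 1))
  r1 <- compare_groups(vals)
  r2 <- compare_groups(vals[c(3, 1, 2)])
  expect_equal(r1$omnibus_p, r2$omnibus_p)
  expect_equal(r1$test_used, r2$test_used)
  if (!is.null(r1$posthoc)) {
    key <- function(ph) {
      sig <- ph[ph$significant, ]
      sort(paste(pmin(sig$group1, sig$group2), pmax(sig$group1, sig$group2)))
    }
    expect_equal(key(r1$posthoc), key(r2$posthoc))
  }
})

test_that("chi-square matches hand computation and rejects bad shapes", {
  prop <- rbind(c(20, 10), c(40, 20))   # perfectly proportional
  res <- chi_square_proportions(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  diag <- rbind(c(10, 0), c(0, 10))
  res2 <- chi_square_proportions(diag)
  expect_equal(res2$statistic, 20)   # hand-computed Pearson X^2
  expect_lt(res2$p.value, 0.001)

  expect_error(chi_square_proportions(matrix(1:3, 1)), "at least 2 x 2")
  expect_error(chi_square_proportions(rbind(c(1, 0), c(1, 0))), "expected")
})

test_that("summarize_cohort builds a full per-variable table", {
  set.seed(6)
  df <- data.frame(group = rep(c("a", "b", "c"), each = 10),
                   f1 = c(rnorm(10), rnorm(10, 3), rnorm(10, 6)),
                   f2 = rnorm(30))
  sm <- summarize_cohort(df)
  expect_equal(nrow(sm$table), 2)
  expect_true(all(c("a", "b", "c", "test", "p") %in% names(sm$table)))
  expect_true(all(sm$table$p >= 0 & sm$table$p <= 1))
  # single subject per group: no tests, mean cell without SD
  one <- data.frame(group = c("a", "b"), f1 = c(1, 2))
  sm1 <- summarize_cohort(one)
  expect_equal(sm1$table$test, "")
  expect_true(is.na(sm1$table$p))
  # empty feature list
  empty <- summarize_cohort(df, variables = character(0))$table
  expect_true(is.null(empty) || nrow(empty) == 0)
  paths <- write_cohort_summary(sm, csv_path = tempfile(),
                                txt_path = tempfile())
  expect_true(file.exists(paths$csv) && file.exists(paths$txt))
})
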