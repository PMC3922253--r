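# Fuzzy classifier: fuzzification, Mamdani inference, centroid
# defuzzification, severity thresholds.

sys <- default_fuzzy_system()

test_that("fuzzify interpolates membership and rejects out-of-universe", {
  v <- fuzzy_variable("v", c(0, 10), list(
    membership_function("low", rbind(c(0, 1), c(2, 1), c(4, 0))),
    membership_function("mid", rbind(c(2, 0), c(4, 1), c(6, 0))),
    membership_function("high", rbind(c(4, 0), c(6, 1), c(10, 1)))))
  expect_equal(unname(fuzzify(4, v)), c(0, 1, 0))       # apex
  expect_equal(unname(fuzzify(3, v)), c(0.5, 0.5, 0))   # symmetric overlap
  expect_equal(unname(fuzzify(0, v)), c(1, 0, 0))       # shoulder
  expect_error(fuzzify(-0.1, v), "outside")
  expect_error(fuzzify(10.2, v), "outside")
})

test_that("fuzzy variables must cover their universe", {
  expect_error(fuzzy_variable("bad", c(0, 10), list(
    membership_function("a", rbind(c(0, 1), c(2, 0))),
    membership_function("b", rbind(c(5, 0), c(6, 1), c(10, 0))))),
    "cover")
})

test_that("evaluate_rules uses min conjunction and max aggregation", {
  rules <- sys$rules
  out_labs <- names(sys$output$sets)
  mk <- function(vib, tac, sym) {
    list(vibration = vib, tactile = tac, symptoms = sym)
  }
  z3 <- c(mildly_altered = 0, altered = 0, very_altered = 0)
  z4 <- c(very_mild = 0, mild = 0, moderate = 0, severe = 0)

  # single rule firing at 1 dominates its output label
  d <- mk(replace(z3, 1, 1), replace(z3, 1, 1), replace(z4, 1, 1))
  act <- evaluate_rules(d, rules, out_labs)
  expect_equal(unname(act["absent"]), 1)
  expect_equal(sum(act), 1)

  # all-zero degrees give all-zero activations
  expect_equal(sum(evaluate_rules(mk(z3, z3, z4), rules, out_labs)), 0)

  # max aggregation across two rules of one label
  tab <- data.frame(vibration = c("a", "b"), tactile = c("a", "b"),
                    symptoms = c("a", "b"), output = c("x", "x"),
                    stringsAsFactors = FALSE)
  d2 <- list(vibration = c(a = 0.3, b = 0.7), tactile = c(a = 1, b = 1),
             symptoms = c(a = 1, b = 0.7))
  expect_equal(unname(evaluate_rules(d2, tab, "x")), 0.7)
})

test_that("centroid defuzzification matches geometry and a fine-grid oracle", {
  # built directly: defuzzification does not need universe coverage, and
  # deliberately sparse symmetric triangles make the geometry predictable
  sets <- list(s1 = membership_function("s1", rbind(c(1, 0), c(3, 1), c(5, 0))),
               s2 = membership_function("s2", rbind(c(5, 0), c(7, 1), c(9, 0))))
  out <- structure(list(name = "o", universe = c(0, 10), sets = sets),
                   class = "fuzzy_variable")
  # symmetric triangle fired alone: centroid at its apex
  expect_equal(defuzzify_centroid(c(s1 = 1, s2 = 0), out), 3, tolerance = 1e-3)
  expect_equal(defuzzify_centroid(c(s1 = 0, s2 = 1), out), 7, tolerance = 1e-3)
  # equal activations of two symmetric triangles: midpoint of the apices
  expect_equal(defuzzify_centroid(c(s1 = 0.6, s2 = 0.6), out), 5,
               tolerance = 1e-3)

  # derived oracle: brute-force integration on a 10x finer grid
  oracle <- function(acts, var, step) {
    x <- seq(var$universe[1], var$universe[2], by = step)
    mu <- rep(0, length(x))
    for (lab in names(var$sets)) {
      mu <- pmax(mu, pmin(acts[[lab]], approx(var$sets[[lab]]$x,
                                              var$sets[[lab]]$mu, x,
                                              rule = 2)$y))
    }
    sum(x * mu) / sum(mu)
  }
  for (acts in list(c(s1 = 0.4, s2 = 0.9), c(s1 = 1, s2 = 0.2),
                    c(s1 = 0.25, s2 = 0.25))) {
    expect_equal(defuzzify_centroid(acts, out, grid_step = 0.001),
                 oracle(as.list(acts), out, 0.001), tolerance = 0.01)
  }
  expect_error(defuzzify_centroid(c(s1 = 0, s2 = 0), out), "no fired rules")
})

test_that("defuzzification is grid-converged", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(5)
    names(a) <- names(sys$output$sets)
    expect_equal(defuzzify_centroid(a, sys$output, 0.001),
                 defuzzify_centroid(a, sys$output, 0.0001),
                 tolerance = 0.01)
  }
})

test_that("classify_severity reproduces the threshold partition", {
  expect_equal(classify_severity(2.5), "absent")
  expect_equal(classify_severity(5.0), "moderate")
  expect_equal(classify_severity(8.0), "severe")
  expect_equal(classify_severity(c(0.9, 2.9, 5.9, 8.9)),
               c("absent", "mild", "moderate", "severe"))
  expect_error(classify_severity(10.5), "outside")
  expect_error(classify_severity(-0.1), "outside")
  # partition of [0,10]: no gaps, classes in severity order
  grid <- seq(0, 10, by = 0.01)
  cls <- classify_severity(grid)
  expect_true(all(cls %in% c("absent", "mild", "moderate", "severe")))
  expect_true(!is.unsorted(match(cls, c("absent", "mild", "moderate",
                                        "severe"))))
})

test_that("classification chain lands extremes in the extreme classes", {
  lo <- classify_subject(list(vibration = 0, tactile = 0, symptoms = 0), sys)
  hi <- classify_subject(list(vibration = 10, tactile = 10, symptoms = 10),
                         sys)
  expect_equal(lo$severity, "absent")
  expect_equal(hi$severity, "severe")
  expect_gte(hi$score, 8)
  expect_lte(lo$score, 2.5)
  expect_true(all(c(lo$score, hi$score) >= 0 & c(lo$score, hi$score) <= 10))
})

test_that("fuzzy system survives a serialization round trip", {
  path <- tempfile(fileext = ".json")
  write_fuzzy_system(sys, path)
  sys2 <- read_fuzzy_system(path)
  for (case in list(c(3.3, 7.1, 2.2), c(0, 0, 0), c(9.9, 5.5, 8.1))) {
    a <- list(vibration = case[1], tactile = case[2], symptoms = case[3])
    expect_equal(classify_subject(a, sys2)$score,
                 classify_subject(a, sys)$score, tolerance = 1e-9)
  }
  expect_equal(nrow(sys2$rules), 36)
})
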