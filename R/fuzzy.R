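# Mamdani fuzzy inference system for grading diabetic sensorimotor
# polyneuropathy (DSP) severity from three clinical inputs:
#   vibration  - vibratory perception, 128 Hz tuning fork, scored 0-10
#   tactile    - tactile sensitivity, 10 g monofilament, scored 0-10
#   symptoms   - neuropathy symptom questionnaire (MNSI-style), rescaled 0-10
# Inference: min for rule conjunction, max for aggregation, centroid
# (center-of-area) defuzzification onto a 0-10 "neuropathy degree score",
# then a fixed threshold partition into absent/mild/moderate/severe.

#' Construct a piecewise-linear membership function
#'
#' @param label set label.
#' @param breakpoints two-column matrix (or list of pairs) of `(x, mu)`
#'   breakpoints with strictly increasing `x` and `mu` in `[0, 1]`. Outside
#'   the breakpoint range the membership continues at the boundary value
#'   (shouldered sets simply start or end at `mu = 1`).
#' @return object of class `membership_function`.
#' @export
membership_function <- function(label, breakpoints) {
  bp <- matrix(unlist(breakpoints), ncol = 2, byrow = !is.matrix(breakpoints))
  if (is.matrix(breakpoints)) bp <- breakpoints
  if (any(diff(bp[, 1]) <= 0)) stop("breakpoint x values must strictly increase")
  if (any(bp[, 2] < 0 | bp[, 2] > 1)) stop("membership degrees must be in [0, 1]")
  structure(list(label = label, x = bp[, 1], mu = bp[, 2]),
            class = "membership_function")
}

mf_eval <- function(mf, x) {
  stats::approx(mf$x, mf$mu, xout = x, rule = 2)$y
}

#' Construct a fuzzy variable
#'
#' @param name variable name.
#' @param universe numeric `c(lo, hi)`, `lo < hi`.
#' @param sets list of [membership_function()] objects. Every point of the
#'   universe must be covered by at least one set with positive membership.
#' @return object of class `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, universe, sets) {
  stopifnot(length(universe) == 2, universe[1] < universe[2])
  names(sets) <- vapply(sets, `[[`, character(1), "label")
  grid <- seq(universe[1], universe[2], length.out = 501)
  cover <- Reduce(pmax, lapply(sets, mf_eval, x = grid))
  if (any(cover <= 0)) {
    stop(sprintf("fuzzy variable '%s' does not cover its universe", name))
  }
  structure(list(name = name, universe = universe, sets = sets),
            class = "fuzzy_variable")
}

#' Fuzzify a crisp value
#'
#' @param value crisp measurement, must lie within the variable's universe
#'   (values outside raise an error; there is no silent clipping).
#' @param variable a [fuzzy_variable()].
#' @return named numeric vector of membership degrees, one per set.
#' @export
fuzzify <- function(value, variable) {
  if (value < variable$universe[1] || value > variable$universe[2]) {
    stop(sprintf("value %.3g outside universe [%g, %g] of '%s'",
                 value, variable$universe[1], variable$universe[2],
                 variable$name))
  }
  vapply(variable$sets, mf_eval, numeric(1), x = value)
}

#' Evaluate a Mamdani rule base
#'
#' Each rule maps a triple of antecedent labels (vibration, tactile,
#' symptoms) to one output label. The firing strength of a rule is the
#' minimum of its three antecedent degrees; activations of rules sharing an
#' output label are aggregated with the maximum.
#'
#' @param input_degrees named list of named degree vectors, one element per
#'   input variable (as returned by [fuzzify()]).
#' @param rules data frame with columns `vibration`, `tactile`, `symptoms`,
#'   `output`.
#' @param output_labels labels of the output sets (fixes ordering of the
#'   result).
#' @return named numeric vector of output-set activations in `[0, 1]`.
#' @export
evaluate_rules <- function(input_degrees, rules, output_labels) {
  strength <- pmin(input_degrees$vibration[rules$vibration],
                   input_degrees$tactile[rules$tactile],
                   input_degrees$symptoms[rules$symptoms])
  act <- vapply(output_labels,
                function(lab) {
                  s <- strength[rules$output == lab]
                  if (length(s)) max(s) else 0
                }, numeric(1))
  act
}

#' Centroid (center-of-area) defuzzification
#'
#' The aggregated output membership is `mu(x) = max_L min(activation_L,
#' mu_L(x))` on a uniform grid over the output universe; the score is the
#' area centroid `sum(x * mu) / sum(mu)`.
#'
#' @param activations named activations from [evaluate_rules()].
#' @param output_var the output [fuzzy_variable()].
#' @param grid_step grid step as a fraction of the universe width.
#' @return the defuzzified score.
#' @export
defuzzify_centroid <- function(activations, output_var, grid_step = 0.001) {
  if (all(activations <= 0)) stop("no fired rules: all activations are zero")
  u <- output_var$universe
  x <- seq(u[1], u[2], by = grid_step * diff(u))
  mu <- rep(0, length(x))
  for (lab in names(output_var$sets)) {
    a <- activations[[lab]]
    if (is.null(a) || a <= 0) next
    mu <- pmax(mu, pmin(a, mf_eval(output_var$sets[[lab]], x)))
  }
  sum(x * mu) / sum(mu)
}

#' Classify a neuropathy degree score into a severity class
#'
#' Threshold partition of the 0-10 score: `score <= 2.5` absent,
#' `2.5 < score < 5` mild, `5 <= score < 8` moderate, `score >= 8` severe.
#'
#' @param score numeric score(s) in `[0, 10]`.
#' @return character vector of classes.
#' @export
classify_severity <- function(score) {
  if (any(score < 0 | score > 10)) stop("score outside [0, 10]")
  ifelse(score <= 2.5, "absent",
         ifelse(score < 5, "mild",
                ifelse(score < 8, "moderate", "severe")))
}

#' Default DSP fuzzy system
#'
#' Input universes are 0-10 for all three clinical scores. Vibration and
#' tactile use three sets ("mildly_altered", "altered", "very_altered"),
#' symptoms four ("very_mild", "mild", "moderate", "severe"); all are
#' overlapping trapezoids with shouldered extremes whose plateaus touch, so
#' that at any crisp input at most one membership value is in transition.
#' This makes the full min-max/centroid chain monotone in every input
#' (triangular partitions crossing at 0.5 provably cannot be: any 36-rule
#' table maps some adjacent antecedent pair to a shared output set, and the
#' membership dip at their crossing shifts centroid weight non-monotonically).
#' The output variable holds five equal-width triangles centered at
#' 1, 3, 5, 7, 9 ("absent" ... "severe"), shouldered at the ends. The rule
#' base maps each of the 36 antecedent label combinations to the output set
#' whose index is the rounded mean of the (rescaled) antecedent severity
#' indices; it is shipped as an explicit editable table so domain experts
#' can replace individual rules.
#'
#' @return object of class `fuzzy_system` with elements `inputs` (list of
#'   three fuzzy variables), `output`, `rules` (36-row data frame) and
#'   `thresholds`.
#' @export
default_fuzzy_system <- function() {
  c3 <- 10 / 3
  trap3 <- function(labels) {
    list(membership_function(labels[1], rbind(c(0, 1), c(c3, 1), c(5, 0))),
         membership_function(labels[2], rbind(c(c3 / 2, 0), c(c3, 1),
                                              c(2 * c3, 1), c(2.5 * c3, 0))),
         membership_function(labels[3], rbind(c(5, 0), c(2 * c3, 1), c(10, 1))))
  }
  symptoms_sets <- list(
    membership_function("very_mild", rbind(c(0, 1), c(2.5, 1), c(3.75, 0))),
    membership_function("mild", rbind(c(1.25, 0), c(2.5, 1), c(5, 1),
                                      c(6.25, 0))),
    membership_function("moderate", rbind(c(3.75, 0), c(5, 1), c(7.5, 1),
                                          c(8.75, 0))),
    membership_function("severe", rbind(c(6.25, 0), c(7.5, 1), c(10, 1))))
  output_sets <- list(
    membership_function("absent", rbind(c(0, 1), c(1, 1), c(3, 0))),
    membership_function("mild", rbind(c(1, 0), c(3, 1), c(5, 0))),
    membership_function("moderate", rbind(c(3, 0), c(5, 1), c(7, 0))),
    membership_function("high", rbind(c(5, 0), c(7, 1), c(9, 0))),
    membership_function("severe", rbind(c(7, 0), c(9, 1), c(10, 1))))

  inputs <- list(
    vibration = fuzzy_variable("vibration", c(0, 10),
                               trap3(c("mildly_altered", "altered", "very_altered"))),
    tactile = fuzzy_variable("tactile", c(0, 10),
                             trap3(c("mildly_altered", "altered", "very_altered"))),
    symptoms = fuzzy_variable("symptoms", c(0, 10), symptoms_sets))
  output <- fuzzy_variable("neuropathy_degree", c(0, 10), output_sets)

  combos <- expand.grid(
    vibration = names(inputs$vibration$sets),
    tactile = names(inputs$tactile$sets),
    symptoms = names(inputs$symptoms$sets),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vi <- match(combos$vibration, names(inputs$vibration$sets)) - 1   # 0..2
  ti <- match(combos$tactile, names(inputs$tactile$sets)) - 1       # 0..2
  si <- match(combos$symptoms, names(inputs$symptoms$sets)) - 1     # 0..3
  idx <- round((vi * 2 + ti * 2 + si * 4 / 3) / 3)                  # 0..4
  combos$output <- names(output$sets)[idx + 1]

  structure(list(inputs = inputs, output = output, rules = combos,
                 thresholds = c(absent = 2.5, mild = 5, moderate = 8),
                 grid_step = 0.001),
            class = "fuzzy_system")
}

#' @export
print.fuzzy_system <- function(x, ...) {
  cat("DSP severity fuzzy system\n")
  for (v in x$inputs) {
    cat(sprintf("  input %-10s [%g, %g]: %s\n", v$name, v$universe[1],
                v$universe[2], paste(names(v$sets), collapse = ", ")))
  }
  cat(sprintf("  output %s: %s\n", x$output$name,
              paste(names(x$output$sets), collapse = ", ")))
  cat(sprintf("  %d rules; thresholds %s\n", nrow(x$rules),
              paste(x$thresholds, collapse = "/")))
  invisible(x)
}

#' Classify one clinical assessment
#'
#' Full Mamdani chain: fuzzification of the three crisp inputs, rule
#' evaluation, centroid defuzzification, severity thresholding.
#'
#' @param assessment list or one-row data frame with `vibration`, `tactile`
#'   and `symptoms` scores.
#' @param system a [default_fuzzy_system()]-style system.
#' @return list with `activations`, `score` and `severity`.
#' @export
classify_subject <- function(assessment, system = default_fuzzy_system()) {
  degrees <- list(
    vibration = fuzzify(assessment$vibration, system$inputs$vibration),
    tactile = fuzzify(assessment$tactile, system$inputs$tactile),
    symptoms = fuzzify(assessment$symptoms, system$inputs$symptoms))
  act <- evaluate_rules(degrees, system$rules, names(system$output$sets))
  score <- defuzzify_centroid(act, system$output, system$grid_step)
  list(activations = act, score = score, severity = classify_severity(score))
}

#' Classify a table of clinical assessments
#'
#' @param assessments data frame with columns `vibration`, `tactile`,
#'   `symptoms` (one subject per row; other columns are carried through).
#' @param system fuzzy system.
#' @return the input data frame with `score` and `severity` columns added.
#' @export
classify_assessments <- function(assessments, system = default_fuzzy_system()) {
  res <- lapply(seq_len(nrow(assessments)), function(i) {
    classify_subject(as.list(assessments[i, ]), system)
  })
  assessments$score <- vapply(res, `[[`, numeric(1), "score")
  assessments$severity <- vapply(res, `[[`, character(1), "severity")
  assessments
}

#' Write / read a fuzzy system as editable JSON
#'
#' Membership functions are stored as breakpoint lists and the rule base as
#' an explicit 36-row table, so every parameter of the system can be edited
#' by hand and reloaded.
#'
#' @param system a fuzzy system.
#' @param path file path.
#' @return `read_fuzzy_system` returns a `fuzzy_system`.
#' @export
write_fuzzy_system <- function(system, path) {
  ser_var <- function(v) {
    list(name = v$name, universe = v$universe,
         sets = lapply(v$sets, function(s) {
           list(label = s$label, x = s$x, mu = s$mu)
         }))
  }
  obj <- list(inputs = lapply(system$inputs, ser_var),
              output = ser_var(system$output),
              rules = system$rules,
              thresholds = as.list(system$thresholds),
              grid_step = system$grid_step)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fuzzy_system
#' @export
read_fuzzy_system <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  de_var <- function(v) {
    raw <- v$sets
    if (is.data.frame(raw)) {
      raw <- lapply(seq_len(nrow(raw)), function(i) {
        list(label = raw$label[i], x = raw$x[[i]], mu = raw$mu[[i]])
      })
    }
    sets <- lapply(raw, function(s) {
      membership_function(s$label, cbind(unlist(s$x), unlist(s$mu)))
    })
    fuzzy_variable(v$name, unlist(v$universe), sets)
  }
  structure(list(inputs = lapply(obj$inputs, de_var),
                 output = de_var(obj$output),
                 rules = as.data.frame(obj$rules),
                 thresholds = unlist(obj$thresholds),
                 grid_step = obj$grid_step),
            class = "fuzzy_system")
}
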