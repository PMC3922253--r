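# Normality-gated multi-group comparisons: Lilliefors-corrected
# Kolmogorov-Smirnov gate, one-way ANOVA with Student-Newman-Keuls (SNK)
# stepwise post hoc on the studentized range, Kruskal-Wallis fallback,
# Pearson chi-square for categorical tables, and a cohort summary table.

#' Lilliefors (Kolmogorov-Smirnov) test for normality
#'
#' KS test against a normal distribution with mean and SD estimated from
#' the sample, using the Dallal-Wilkinson (1986) / Stephens p-value
#' approximation. The plain KS test is anticonservative when its reference
#' parameters are fitted, hence the correction.
#'
#' @param x numeric sample (n >= 5).
#' @return list with `statistic` (D) and `p.value`.
#' @export
lillie_test <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 5) stop("Lilliefors test requires n >= 5")
  s <- stats::sd(x)
  if (s == 0) return(list(statistic = Inf, p.value = 0))  # degenerate
  p <- stats::pnorm((x - mean(x)) / s)
  D <- max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
  if (n <= 100) {
    Kd <- D
    nd <- n
  } else {
    Kd <- D * (n / 100)^0.49
    nd <- 100
  }
  pv <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
              2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
              0.974598 / sqrt(nd) + 1.67997 / nd)
  if (pv > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    pv <- if (KK <= 0.302) 1
      else if (KK <= 0.5) 2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
        138.55152 * KK^3 + 81.218052 * KK^4
      else if (KK <= 0.9) -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
        94.029866 * KK^3 - 32.355711 * KK^4
      else if (KK <= 1.31) 6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
        12.234627 * KK^3 + 2.423045 * KK^4
      else 0
  }
  list(statistic = D, p.value = min(max(pv, 0), 1))
}

#' Normality gate for a set of groups
#'
#' Routes a variable to parametric testing only if no group rejects
#' normality at `alpha`. Groups too small for the Lilliefors test (n < 5)
#' or with zero variance route the variable to the non-parametric branch.
#'
#' @param values named list of numeric vectors (one per group).
#' @param alpha significance level of the gate.
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  if (any(vapply(values, length, integer(1)) < 2)) {
    stop("each group needs at least 2 observations")
  }
  for (v in values) {
    if (stats::sd(v) == 0) return("non_normal")
    if (length(v) < 5) return("non_normal")
    if (lillie_test(v)$p.value < alpha) return("non_normal")
  }
  "normal"
}

#' Student-Newman-Keuls stepwise post hoc test
#'
#' Pairwise comparisons on ordered group means using studentized-range
#' critical values that depend on the span of each comparison, with the
#' standard stepwise blocking rule: a subset range that fails to reach
#' significance blocks all pairs it contains. Unequal group sizes are
#' handled with the harmonic pairwise standard error (Tukey-Kramer style).
#'
#' @param values named list of numeric vectors (one per group).
#' @param alpha familywise level.
#' @return data.frame with columns `group1`, `group2`, `q`, `q_crit`,
#'   `span`, `significant`.
#' @export
snk_posthoc <- function(values, alpha = 0.05) {
  k <- length(values)
  stopifnot(k >= 2)
  ns <- vapply(values, length, integer(1))
  means <- vapply(values, mean, numeric(1))
  N <- sum(ns)
  df <- N - k
  mse <- sum(vapply(values, function(v) sum((v - mean(v))^2), numeric(1))) / df
  ord <- order(means)
  res <- list()
  blocked <- matrix(FALSE, k, k)   # in sorted order
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      g1 <- ord[i]; g2 <- ord[j]
      se <- sqrt(mse / 2 * (1 / ns[g1] + 1 / ns[g2]))
      q <- (means[g2] - means[g1]) / se
      crit <- stats::qtukey(1 - alpha, span, df)
      sig <- !blocked[i, j] && is.finite(q) && q > crit
      if (!sig) {
        # block all pairs inside this range
        for (a in i:j) for (b in i:j) blocked[a, b] <- TRUE
      }
      res[[length(res) + 1]] <- data.frame(
        group1 = names(values)[g1], group2 = names(values)[g2],
        q = q, q_crit = crit, span = span, significant = sig,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Compare one variable across groups
#'
#' Applies the normality gate, then either one-way ANOVA (equal-variance
#' F test) followed -- when the omnibus test rejects -- by the SNK post hoc,
#' or the Kruskal-Wallis rank test.
#'
#' @param values named list of numeric vectors (one per group).
#' @param alpha significance level.
#' @return object of class `comparison_result`: list with `test_used`
#'   (`"anova"` or `"kruskal_wallis"`), `omnibus_p`, `posthoc` (data.frame
#'   or NULL), `group_summaries`.
#' @export
compare_groups <- function(values, alpha = 0.05) {
  stopifnot(length(values) >= 2)
  gate <- normality_gate(values, alpha)
  y <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), vapply(values, length, integer(1))))
  if (gate == "normal") {
    test_used <- "anova"
    p <- stats::oneway.test(y ~ g, var.equal = TRUE)$p.value
    # identical groups give an undefined F; treat as no evidence
    if (!is.finite(p)) p <- 1
    posthoc <- if (p < alpha) snk_posthoc(values, alpha) else NULL
  } else {
    test_used <- "kruskal_wallis"
    p <- stats::kruskal.test(y, g)$p.value
    if (!is.finite(p)) p <- 1
    posthoc <- NULL
  }
  gs <- data.frame(group = names(values),
                   n = vapply(values, length, integer(1)),
                   mean = vapply(values, mean, numeric(1)),
                   sd = vapply(values, stats::sd, numeric(1)),
                   stringsAsFactors = FALSE)
  structure(list(test_used = test_used, omnibus_p = p, posthoc = posthoc,
                 group_summaries = gs, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: omnibus p = %.4g\n", x$test_used, x$omnibus_p))
  if (!is.null(x$posthoc)) {
    sig <- x$posthoc[x$posthoc$significant, , drop = FALSE]
    cat(sprintf("  %d significant pair(s) (SNK, alpha = %g)\n",
                nrow(sig), x$alpha))
  }
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' @param counts matrix of counts, groups in rows, categories in columns
#'   (at least 2 x 2).
#' @return list with `statistic`, `df`, `p.value`, `expected`.
#' @export
chi_square_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table must be at least 2 x 2")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop("zero expected cell count; consider an exact test")
  }
  x2 <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(statistic = x2, df = df,
       p.value = stats::pchisq(x2, df, lower.tail = FALSE),
       expected = expected)
}

#' Summarize a cohort's features with group comparisons
#'
#' Builds a per-variable summary (mean +/- SD per group, test used,
#' omnibus p, significant SNK pairs) over a subject-level feature table.
#'
#' @param features data.frame with a group column and numeric feature
#'   columns.
#' @param group_col name of the group column.
#' @param variables feature columns to summarize (default: all numeric
#'   columns except the group column).
#' @param alpha significance level.
#' @return object of class `cohort_summary`: list with `table` (one row
#'   per variable) and `results` (named list of `comparison_result`).
#' @export
summarize_cohort <- function(features, group_col = "group",
                             variables = NULL, alpha = 0.05) {
  stopifnot(group_col %in% names(features))
  if (is.null(variables)) {
    variables <- names(features)[vapply(features, is.numeric, logical(1))]
    variables <- setdiff(variables, group_col)
  }
  groups <- unique(features[[group_col]])
  if (length(variables) == 0) {
    return(structure(list(table = data.frame(), results = list(),
                          alpha = alpha), class = "cohort_summary"))
  }
  results <- list()
  rows <- list()
  for (v in variables) {
    vals <- lapply(groups, function(g) {
      x <- features[[v]][features[[group_col]] == g]
      x[is.finite(x)]
    })
    names(vals) <- groups
    enough <- all(vapply(vals, length, integer(1)) >= 2)
    cmp <- if (enough) compare_groups(vals, alpha) else NULL
    results[[v]] <- cmp
    cells <- vapply(groups, function(g) {
      x <- vals[[g]]
      if (length(x) == 0) return("-")
      if (length(x) == 1) return(sprintf("%.1f", x))
      sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
    }, character(1))
    sig_pairs <- if (!is.null(cmp) && !is.null(cmp$posthoc)) {
      ph <- cmp$posthoc[cmp$posthoc$significant, , drop = FALSE]
      paste(sprintf("%s-%s", ph$group1, ph$group2), collapse = "; ")
    } else ""
    rows[[v]] <- data.frame(
      variable = v, t(cells),
      test = if (is.null(cmp)) "" else cmp$test_used,
      p = if (is.null(cmp)) NA_real_ else cmp$omnibus_p,
      significant_pairs = sig_pairs,
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  tab <- do.call(rbind, rows)
  names(tab)[2:(1 + length(groups))] <- groups
  rownames(tab) <- NULL
  structure(list(table = tab, results = results, alpha = alpha),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a cohort summary as CSV and an aligned text table
#'
#' @param summary a [summarize_cohort()] result.
#' @param csv_path,txt_path output paths (`NULL` to skip either).
#' @return invisible list of written paths.
#' @export
write_cohort_summary <- function(summary, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(summary$table, csv_path, row.names = FALSE)
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w", encoding = "UTF-8")
    widths <- vapply(names(summary$table), function(cn) {
      max(nchar(c(cn, as.character(summary$table[[cn]]))), na.rm = TRUE)
    }, numeric(1))
    fmt_row <- function(vals) {
      paste(mapply(formatC, as.character(vals), width = widths,
                   MoreArgs = list(flag = "-")), collapse = "  ")
    }
    writeLines(fmt_row(names(summary$table)), con)
    for (i in seq_len(nrow(summary$table))) {
      row <- summary$table[i, ]
      row$p <- if (is.na(row$p)) "" else sprintf("%.4f", as.numeric(row$p))
      writeLines(fmt_row(row), con)
    }
    close(con)
  }
  invisible(list(csv = csv_path, txt = txt_path))
}
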