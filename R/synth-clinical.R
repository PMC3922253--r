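# Synthetic clinical assessments with known intended severity class.

#' Generate a clinical cohort with intended severity classes
#'
#' For each diabetic subject an input triple (vibration, tactile, symptoms)
#' is drawn and accepted only if the fuzzy system classifies it into the
#' subject's intended severity class (rejection sampling, so the
#' class-conditional samples classify correctly by construction). Control
#' subjects bypass the fuzzy system: they receive low-range scores and no
#' neuropathy degree.
#'
#' @param groups data.frame with columns `label`
#'   (control/absent/mild/moderate/severe) and `n`.
#' @param system fuzzy system used for classification.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap per subject; exceeded caps
#'   raise an error naming the unreachable class.
#' @return data.frame: `subject`, `group`, `vibration`, `tactile`,
#'   `symptoms`, `score` (NA for controls), `severity`.
#' @export
generate_clinical_cohort <- function(groups, system = default_fuzzy_system(),
                                     seed = 1L, max_attempts = 5000L) {
  set.seed(seed)
  bad <- setdiff(groups$label,
                 c("control", "absent", "mild", "moderate", "severe"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  rows <- list()
  sid <- 0L
  for (gi in seq_len(nrow(groups))) {
    lab <- groups$label[gi]
    for (k in seq_len(groups$n[gi])) {
      sid <- sid + 1L
      if (lab == "control") {
        rows[[sid]] <- data.frame(
          subject = sprintf("C%03d", sid), group = lab,
          vibration = stats::runif(1, 0, 1.5),
          tactile = stats::runif(1, 0, 1.5),
          symptoms = stats::runif(1, 0, 1.5),
          score = NA_real_, severity = "control",
          stringsAsFactors = FALSE)
        next
      }
      found <- FALSE
      for (a in seq_len(max_attempts)) {
        x <- list(vibration = stats::runif(1, 0, 10),
                  tactile = stats::runif(1, 0, 10),
                  symptoms = stats::runif(1, 0, 10))
        res <- classify_subject(x, system)
        if (res$severity == lab) {
          rows[[sid]] <- data.frame(
            subject = sprintf("C%03d", sid), group = lab,
            vibration = x$vibration, tactile = x$tactile,
            symptoms = x$symptoms, score = res$score, severity = res$severity,
            stringsAsFactors = FALSE)
          found <- TRUE
          break
        }
      }
      if (!found) {
        stop(sprintf(
          "severity class '%s' unreachable under the rule base (%d attempts)",
          lab, max_attempts))
      }
    }
  }
  do.call(rbind, rows)
}
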