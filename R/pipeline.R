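# End-to-end pipeline: synthetic cohort -> fuzzy classification ->
# signal processing -> feature extraction -> group comparison, with a
# config object, per-stage seeds, and a run manifest.

#' Default pipeline configuration
#'
#' All tunables of the individual stages, at their module defaults. The
#' single `seed` fans out to fixed per-stage substreams so one stage's
#' draws never shift another's.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_per_group subject count per group (`NULL` keeps the reference
#'   group sizes).
#' @return a nested list of class `run_config`.
#' @export
default_run_config <- function(out_dir = "gaitdsp_run", seed = 1L,
                               n_per_group = NULL) {
  tg <- default_feature_targets()
  groups <- data.frame(label = tg$group,
                       n = if (is.null(n_per_group)) tg$n
                           else rep(n_per_group, nrow(tg)))
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    groups = groups,
    trials_per_subject = 5,
    stance_duration_mean = 0.70,
    stance_duration_sd = 0.05,
    rate = 2000,
    swing_pad = 0.2,
    carrier = "noise",
    within_subject_frac = 0.2,
    band = c(20, 500),
    band_order = 4,
    lp_cutoff = 5,
    stance_threshold = 20,
    stance_min_duration = 0.1,
    windows = default_feature_windows(),
    alpha = 0.05,
    write_trials = FALSE), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Static checks of the module invariants; returns a character vector of
#' violations (empty when the configuration is valid).
#'
#' @param config a [default_run_config()]-style list.
#' @return character vector of violation messages.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(all(config$groups$n >= 1), "all group sizes must be >= 1")
  chk(all(config$groups$label %in%
            c("control", "absent", "mild", "moderate", "severe")),
      "unknown group label")
  chk(config$trials_per_subject >= 1, "trials_per_subject must be >= 1")
  chk(config$rate > 2 * config$band[2],
      sprintf("band-pass upper edge %g Hz violates Nyquist at rate %g Hz",
              config$band[2], config$rate))
  chk(config$band[1] > 0 && config$band[1] < config$band[2],
      "band-pass edges must satisfy 0 < low < high")
  chk(config$lp_cutoff > 0 && config$lp_cutoff < config$rate / 2,
      "envelope cutoff must be in (0, rate/2)")
  chk(config$stance_duration_mean > 0, "stance duration must be positive")
  chk(config$stance_duration_sd >= 0, "stance duration SD must be >= 0")
  chk(config$alpha > 0 && config$alpha < 1, "alpha must be in (0, 1)")
  chk(config$stance_threshold > 0, "stance threshold must be positive")
  w <- config$windows
  for (nm in c("vl_peak", "ta_peak", "gm_peak", "ta_pushoff_peak", "vl_min",
               "ta_min", "gm_min", "ta_onset_search", "gm_onset_search")) {
    chk(w[[nm]][1] < w[[nm]][2] && all(w[[nm]] >= 0) && all(w[[nm]] <= 100),
        sprintf("window %s must be an increasing pair within [0, 100]", nm))
  }
  v
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$groups <- as.data.frame(obj$groups)
  structure(obj, class = "run_config")
}

# Small stable polynomial hash for manifests (hex string; exact in double
# arithmetic since 31 * 2^31 < 2^53).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # hash the scientific configuration, not the paths
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stage_seed <- function(seed, stage) {
  (as.numeric(seed) + stage * 1000003) %% 2147483647
}

#' Run the complete pipeline
#'
#' Stages: (1) clinical cohort generation + fuzzy classification,
#' (2) gait-trial synthesis, (3) envelope processing + feature extraction,
#' (4) group statistics, (5) manifest. Each stage writes its outputs under
#' `config$out_dir` and any stage error aborts the run with a stage-tagged
#' message.
#'
#' @param config a [default_run_config()]-style configuration.
#' @return the run manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config = default_run_config()) {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid config:\n  ", paste(viol, collapse = "\n  "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list())
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.2f s", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  clinical <- stage("clinical", {
    cc <- generate_clinical_cohort(config$groups,
                                   seed = stage_seed(config$seed, 1))
    f <- file.path(config$out_dir, "clinical.csv")
    utils::write.csv(cc, f, row.names = FALSE)
    manifest$stages$clinical <- list(path = f, records = nrow(cc))
    cc
  })

  cohort <- stage("gait_synthesis", {
    spec <- cohort_spec(groups = config$groups,
                        trials_per_subject = config$trials_per_subject,
                        stance_duration_mean = config$stance_duration_mean,
                        stance_duration_sd = config$stance_duration_sd,
                        rate = config$rate, swing_pad = config$swing_pad,
                        carrier = config$carrier,
                        within_subject_frac = config$within_subject_frac,
                        seed = stage_seed(config$seed, 2))
    coh <- generate_cohort_trials(spec, windows = config$windows,
                                  lp_cutoff = config$lp_cutoff)
    n_tr <- sum(vapply(coh, function(s) length(s$trials), integer(1)))
    if (isTRUE(config$write_trials)) {
      write_cohort(coh, file.path(config$out_dir, "trials"))
    }
    manifest$stages$gait_synthesis <- list(
      subjects = length(coh), trials = n_tr,
      written = isTRUE(config$write_trials))
    coh
  })

  features <- stage("features", {
    ft <- extract_cohort_features(cohort, windows = config$windows,
                                  band = config$band,
                                  band_order = config$band_order,
                                  lp_cutoff = config$lp_cutoff,
                                  stance_threshold = config$stance_threshold,
                                  stance_min_duration = config$stance_min_duration)
    f <- file.path(config$out_dir, "features.csv")
    utils::write.csv(ft, f, row.names = FALSE)
    manifest$stages$features <- list(path = f, records = nrow(ft))
    ft
  })

  stats_out <- stage("group_stats", {
    sm <- summarize_cohort(features, group_col = "group",
                           variables = feature_names(), alpha = config$alpha)
    paths <- write_cohort_summary(
      sm, csv_path = file.path(config$out_dir, "comparison.csv"),
      txt_path = file.path(config$out_dir, "comparison.txt"))
    manifest$stages$group_stats <- list(paths = paths,
                                         variables = nrow(sm$table))
    sm
  })

  manifest$elapsed_s <- as.numeric(Sys.time() - t_all, units = "secs")
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$stages$manifest <- list(path = mf)
  invisible(list(manifest = manifest, clinical = clinical,
                 features = features, summary = stats_out))
}
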