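#' Default pipeline configuration
#'
#' A fully-defaulted, validated configuration for [run_pipeline()]. The
#' `simulation` block is a [sim_config()]; `microstates` holds the
#' segmentation parameters; `preprocess` the signal-conditioning
#' parameters; `stats` the statistics options. Unknown keys are rejected.
#'
#' @param ... named overrides, e.g. `microstates = list(restarts = 20)`,
#'   `simulation = list(n_hp = 5, n_lp = 5, seed = 3)`.
#' @return a `pipeline_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    simulation = as.list(unclass(sim_config())),
    preprocess = list(enabled = FALSE, low = 0.1, high = 80,
                      notch_lower = 48, notch_upper = 52,
                      target_sfreq = 500),
    microstates = list(k = 4L, restarts = 100L, peak_rule = "mean+2sd",
                       seed = 1L),
    stats = list(alpha = 0.05))
  over <- list(...)
  for (blk in names(over)) {
    if (!blk %in% names(cfg)) stop("unknown config block: ", blk)
    bad <- setdiff(names(over[[blk]]), names(cfg[[blk]]))
    if (length(bad)) stop("unknown config key(s) in ", blk, ": ",
                          paste(bad, collapse = ", "))
    cfg[[blk]][names(over[[blk]])] <- over[[blk]]
  }
  cfg$simulation <- do.call(sim_config, cfg$simulation)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with (subsets of) the [default_config()] blocks.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation$transition))
    y$simulation$transition <- matrix(unlist(y$simulation$transition),
                                      nrow = length(y$simulation$transition),
                                      byrow = TRUE)
  do.call(default_config, y)
}

#' Run the full microstate analysis pipeline
#'
#' Executes simulate (or load) -> optional preprocessing -> individual
#' clustering -> group clustering -> backfitting -> temporal metrics ->
#' group statistics, and (when `out_dir` is given) writes templates,
#' metrics, subject table, stats and a JSON manifest echoing the
#' configuration, the seed and per-file checksums. Subjects excluded by
#' the bad-channel rule (> 3 damaged channels) are logged and dropped,
#' not fatal.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param recordings optional list of `recording`s; when `NULL` a cohort
#'   is simulated from `config$simulation`.
#' @param subjects subject metadata matching `recordings` (required when
#'   recordings are supplied).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list with `fit` (the `microstate_fit`), `stats`, `subjects`,
#'   `excluded` (character vector of dropped subject ids), and
#'   `ground_truth` when simulated.
#' @export
run_pipeline <- function(config = default_config(), recordings = NULL,
                         subjects = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ground_truth <- NULL
  if (is.null(recordings)) {
    cohort <- simulate_cohort(config$simulation)
    recordings <- cohort$recordings
    subjects <- cohort$subjects
    ground_truth <- cohort$ground_truth
  } else if (is.null(subjects)) stop("subjects table required with recordings")
  montage <- standard_montage()
  excluded <- character(0)
  kept <- list()
  for (rec in recordings) {
    res <- tryCatch({
      if (isTRUE(config$preprocess$enabled)) {
        pp <- config$preprocess
        preprocess(rec, montage, low = pp$low, high = pp$high,
                   notch_lower = pp$notch_lower, notch_upper = pp$notch_upper,
                   target_sfreq = pp$target_sfreq)
      } else pp_interpolate_bad(rec, montage)
    }, subject_excluded = function(e) {
      message(conditionMessage(e))
      NULL
    })
    if (is.null(res)) excluded <- c(excluded, rec$subject)
    else kept[[length(kept) + 1L]] <- res
  }
  if (!length(kept)) stop("pipeline aborted at preprocessing: no usable subjects")
  subjects <- subjects[!subjects$subject %in% excluded, , drop = FALSE]
  ms <- config$microstates
  fit <- fit_microstates(kept, k = ms$k, restarts = ms$restarts,
                         peak_rule = ms$peak_rule, montage = montage,
                         seed = ms$seed)
  st <- tryCatch(microstate_stats(fit$metrics, subjects,
                                  alpha = config$stats$alpha),
                 error = function(e)
                   stop("pipeline aborted at stats stage: ",
                        conditionMessage(e)))
  out <- list(fit = fit, stats = st, subjects = subjects,
              excluded = excluded, ground_truth = ground_truth)
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  out
}

write_pipeline_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tpl <- file.path(out_dir, "templates.csv")
  write_templates(out$fit$templates, tpl)
  met <- file.path(out_dir, "metrics.csv")
  write_metrics(out$fit$metrics, met)
  sub <- file.path(out_dir, "subjects.csv")
  utils::write.csv(out$subjects, sub, row.names = FALSE)
  sta <- file.path(out_dir, "stats.csv")
  utils::write.csv(out$stats$transitions, sta, row.names = FALSE)
  files <- c(tpl, paste0(tpl, ".json"), met, sub, sta)
  manifest <- list(
    package_version = as.character(utils::packageVersion("microstatr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$simulation$seed,
    config = config_as_list(config),
    excluded_subjects = out$excluded,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$simulation <- unclass(cfg$simulation)
  cfg$simulation$transition <- apply(cfg$simulation$transition, 1L, c,
                                     simplify = FALSE)
  cfg
}

#' Write temporal metrics / templates to delimited files
#'
#' `write_metrics` writes one CSV row per subject (columns: subject,
#' dur_A..dur_D, occ_A..occ_D, cov_A..cov_D, tr_AB..tr_DC).
#' `write_templates` writes the template maps as CSV (rows = channels
#' with labels, columns = classes) plus a JSON sidecar with GEV, CV,
#' provenance and restart count. `write_labels` writes a label sequence
#' run-length encoded (start_sample, end_sample half-open, label).
#'
#' @param metrics metrics data frame.
#' @param ts a `template_set`.
#' @param seq a `label_sequence`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
write_templates <- function(ts, path) {
  stopifnot(inherits(ts, "template_set"))
  df <- data.frame(channel = rownames(ts$maps), ts$maps, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(gev = ts$gev, cv = ts$cv, k = ts$k,
                            restarts = ts$restarts,
                            provenance = ts$provenance,
                            class_labels = ts$class_labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics
#' @export
write_labels <- function(seq, path) {
  stopifnot(inherits(seq, "label_sequence"))
  lab <- seq$labels
  lab_chr <- ifelse(is.na(lab), "masked", seq$classes[lab])
  r <- rle(lab_chr)
  ends <- cumsum(r$lengths)
  utils::write.csv(data.frame(start_sample = ends - r$lengths,
                              end_sample = ends, label = r$values),
                   path, row.names = FALSE)
  invisible(path)
}
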