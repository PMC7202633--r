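#' Pipeline configuration
#'
#' Bundles the tunable settings of every analysis stage. Fractions are in
#' (0, 1); the significance level alpha applies to the statistics stage.
#'
#' @param cycle_index hysteresis cycle analyzed (default 20).
#' @param window_fraction,nz_fraction,nz_method see [loop_control()].
#' @param smooth_window failure-ramp smoothing window (s); see
#'   [detect_failure()].
#' @param drop_fraction post-peak drop defining failure.
#' @param creep see [creep_fit_control()].
#' @param alpha significance level for the ANOVA layer.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cycle_index = 20L, window_fraction = 0.2,
                            nz_fraction = 0.1,
                            nz_method = "threshold",
                            smooth_window = 0.5, drop_fraction = 0.2,
                            creep = creep_fit_control(), alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(cycle_index = as.integer(cycle_index),
                 window_fraction = window_fraction,
                 nz_fraction = nz_fraction, nz_method = nz_method,
                 smooth_window = smooth_window,
                 drop_fraction = drop_fraction,
                 creep = creep, alpha = alpha),
            class = "pipeline_config")
}

#' Analyze one recording according to its test kind
#'
#' Dispatches a recording to the matching analysis stage and returns the
#' per-specimen outcome columns that stage contributes.
#'
#' @param rec a [ts_recording()].
#' @param config a [pipeline_config()].
#' @return One-row data.frame of outcome columns.
#' @export
analyze_recording <- function(rec, config = pipeline_config()) {
  lc <- loop_control(config$window_fraction, config$nz_fraction,
                     nz_method = config$nz_method)
  switch(rec$kind,
    axial_cyclic = {
      m <- axial_metrics(extract_cycle(rec, config$cycle_index), lc)
      data.frame(tensile_stiffness = m$stiffness_positive,
                 compressive_stiffness = m$stiffness_negative,
                 range_of_motion = m$range_of_motion,
                 neutral_zone_axial = m$neutral_zone_length)
    },
    torsional_cyclic = {
      m <- torsional_metrics(extract_cycle(rec, config$cycle_index), lc)
      data.frame(torsional_stiffness = m$stiffness_mean,
                 torque_range = m$load_range,
                 neutral_zone_torsional = m$neutral_zone_length)
    },
    creep = {
      f <- fit_creep(rec, cfg = config$creep)
      data.frame(elastic_stiffness = f$model$k0,
                 stiffness_fast = f$model$k1, stiffness_slow = f$model$k2,
                 tau1 = f$model$tau1, tau2 = f$model$tau2,
                 creep_displacement = f$creep_displacement,
                 total_displacement = f$total_displacement,
                 creep_residual_rms = f$residual_rms)
    },
    torsion_to_failure = {
      m <- detect_failure(rec, smooth_window = config$smooth_window,
                          drop_fraction = config$drop_fraction)
      data.frame(failure_strength = m$failure_strength,
                 angle_to_failure = m$angle_to_failure,
                 failed = m$failed)
    },
    stop("unknown recording kind: ", rec$kind, call. = FALSE))
}

#' Run the full analysis pipeline over a cohort manifest
#'
#' Reads every recording referenced by the manifest, analyzes it with the
#' stage matching its test kind, assembles one wide outcome row per specimen,
#' and (when group labels are present) runs the per-sex two-way
#' genotype-by-diet ANOVA with Tukey post-hoc comparisons on every outcome.
#' Failures are isolated per file: a corrupt recording flags its specimen in
#' the run report and the remaining specimens complete normally.
#'
#' @param manifest data.frame (or CSV path) with columns `specimen_id`,
#'   `kind`, `file` and optionally `sex`, `genotype`, `diet`. Relative file
#'   paths are resolved against the manifest's directory (or `data_dir`).
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL`, writes `metrics.csv`, `group_summary.csv`,
#'   `anova.csv`, `tukey.csv` and `report.json` there.
#' @param data_dir directory against which relative `file` entries are
#'   resolved.
#' @param recordings optional named list of in-memory [ts_recording()]
#'   objects keyed by the manifest `file` column (used instead of reading
#'   from disk).
#' @return List with `metrics` (wide per-specimen table), `summary`, `anova`,
#'   `tukey` (statistics tables, `NULL` without group labels) and `report`
#'   (per-file status, config hash, seed-independent run metadata).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL, data_dir = NULL,
                         recordings = NULL) {
  if (is.character(manifest)) {
    data_dir <- data_dir %||% dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  need <- c("specimen_id", "kind", "file")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  cfg_hash <- rlang::hash(config)

  status <- list(); rows <- list()
  for (i in seq_len(nrow(manifest))) {
    mrow <- manifest[i, ]
    res <- tryCatch({
      rec <- if (!is.null(recordings)) {
        recordings[[mrow$file]] %||% stop("recording not supplied: ",
                                          mrow$file, call. = FALSE)
      } else {
        path <- if (!is.null(data_dir) && !file.exists(mrow$file))
          file.path(data_dir, mrow$file) else mrow$file
        read_recording(path, kind = mrow$kind)
      }
      out <- analyze_recording(rec, config)
      out$specimen_id <- mrow$specimen_id
      list(ok = TRUE, out = out, message = "ok")
    }, error = function(e) list(ok = FALSE, out = NULL,
                                message = conditionMessage(e)))
    status[[i]] <- data.frame(specimen_id = mrow$specimen_id,
                              kind = mrow$kind, file = mrow$file,
                              ok = res$ok, message = res$message)
    if (res$ok) rows[[length(rows) + 1L]] <- res$out
  }
  status_df <- do.call(rbind, status)
  if (length(rows) == 0L)
    stop("all recordings failed to analyze; see run report", call. = FALSE)

  # merge stage outputs into one wide row per specimen
  ids <- unique(unlist(lapply(rows, `[[`, "specimen_id")))
  metrics <- data.frame(specimen_id = ids, stringsAsFactors = FALSE)
  for (r in rows) {
    for (col in setdiff(names(r), "specimen_id")) {
      if (!col %in% names(metrics)) metrics[[col]] <- NA
      metrics[[col]][match(r$specimen_id, metrics$specimen_id)] <- r[[col]]
    }
  }
  label_cols <- intersect(c("sex", "genotype", "diet"), names(manifest))
  if (length(label_cols) > 0) {
    lab <- unique(manifest[, c("specimen_id", label_cols), drop = FALSE])
    metrics <- merge(lab, metrics, by = "specimen_id", sort = FALSE)
  }
  metrics$config_hash <- cfg_hash

  stats_out <- list(summary = NULL, anova = NULL, tukey = NULL)
  if (all(c("sex", "genotype", "diet") %in% names(metrics)))
    stats_out <- cohort_statistics(metrics, alpha = config$alpha,
                                   config_hash = cfg_hash)

  report <- list(config_hash = cfg_hash,
                 package_version = as.character(utils::packageVersion("spinemech")),
                 n_files = nrow(status_df), n_failed = sum(!status_df$ok),
                 files = status_df)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    for (nm in names(stats_out))
      if (!is.null(stats_out[[nm]]))
        utils::write.csv(stats_out[[nm]],
                         file.path(out_dir, paste0(
                           c(summary = "group_summary", anova = "anova",
                             tukey = "tukey")[[nm]], ".csv")),
                         row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  c(list(metrics = metrics, report = report), stats_out)
}

#' Per-sex factorial statistics over a wide outcome table
#'
#' For every numeric outcome column and each sex separately, runs the 2 x 2
#' genotype-by-diet ANOVA ([two_way_anova()]), Tukey pairwise comparisons
#' among the four cells ([tukey_hsd()]) and the group summary
#' ([summarize_groups()]). Outcomes whose design is degenerate in a stratum
#' (empty or single-observation cells) are skipped with a note.
#'
#' @param metrics data.frame with `sex`, `genotype`, `diet` label columns and
#'   numeric outcome columns.
#' @param alpha significance level recorded alongside the results.
#' @param config_hash provenance string attached to each output row.
#' @return List of data.frames `summary`, `anova`, `tukey`.
#' @export
cohort_statistics <- function(metrics, alpha = 0.05, config_hash = NA) {
  skip <- c("specimen_id", "sex", "genotype", "diet", "config_hash",
            "creep_residual_rms", "failed")
  outcome_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                                logical(1))], skip)
  sum_l <- list(); an_l <- list(); tk_l <- list()
  for (sx in unique(metrics$sex)) {
    sub <- metrics[metrics$sex == sx, ]
    for (oc in outcome_cols) {
      y <- sub[[oc]]
      keep <- !is.na(y)
      if (sum(keep) < 8L) next
      s <- summarize_groups(y[keep],
                            sub[keep, c("genotype", "diet"), drop = FALSE])
      s <- cbind(data.frame(sex = sx, outcome = oc), s)
      sum_l[[length(sum_l) + 1L]] <- s
      an <- tryCatch(
        two_way_anova(y[keep], sub$genotype[keep], sub$diet[keep]),
        error = function(e) NULL)
      if (!is.null(an)) {
        an_l[[length(an_l) + 1L]] <-
          cbind(data.frame(sex = sx, outcome = oc), as.data.frame(an),
                alpha = alpha)
      }
      tk <- tryCatch(
        tukey_hsd(y[keep], paste(sub$genotype[keep], sub$diet[keep],
                                 sep = "/")),
        error = function(e) NULL)
      if (!is.null(tk))
        tk_l[[length(tk_l) + 1L]] <-
          cbind(data.frame(sex = sx, outcome = oc), as.data.frame(tk))
    }
  }
  bindf <- function(l) if (length(l)) {
    out <- do.call(rbind, l); out$config_hash <- config_hash
    rownames(out) <- NULL; out
  } else NULL
  list(summary = bindf(sum_l), anova = bindf(an_l), tukey = bindf(tk_l))
}
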