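## Reproducible pipeline stages: simulate scenes + cohort to disk,
## score every trajectory against its scene, run the cohort
## statistics. Every stage writes a JSON run manifest recording the
## seed and configuration it actually used.

write_manifest <- function(dir, stage, seed, config) {
  jsonlite::write_json(
    list(stage = stage, seed = seed,
         package_version = as.character(utils::packageVersion("trajsafe")),
         config = config, timestamp_free = TRUE),
    file.path(dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate scenes and a cohort to an output directory
#'
#' Writes one scene directory per tumour (NIfTI masks, .tck
#' streamlines, manifest) plus `cohort.csv` and a run manifest.
#'
#' @param out Output directory.
#' @param seed Integer seed driving scenes and cohort.
#' @param scene_base `scene_params` template.
#' @param cohort_p `cohort_params`; its seed is overridden by `seed`.
#' @return Invisible list with `scenes_dir`, `cohort_csv`, `cohort`.
#' @export
run_simulate <- function(out, seed = 1L, scene_base = scene_params(),
                         cohort_p = cohort_params()) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stopf("cannot create output directory %s", out)
  cohort_p$seed <- as.integer(seed)
  scenes <- generate_scene_set(cohort_p$n_scenes, seed = as.integer(seed),
                               base = scene_base)
  scenes_dir <- file.path(out, "scenes")
  for (sc in scenes) save_scene(sc, file.path(scenes_dir, sc$tumour_id))
  cohort <- generate_cohort(scenes, cohort_p)
  cohort_csv <- file.path(out, "cohort.csv")
  write_cohort(cohort, cohort_csv)
  write_manifest(out, "simulate", seed,
                 list(n_scenes = cohort_p$n_scenes,
                      n_trainees = cohort_p$n_trainees,
                      scene_seed_base = seed * 100L))
  invisible(list(scenes_dir = scenes_dir, cohort_csv = cohort_csv,
                 cohort = cohort, scenes = scenes))
}

#' Score every trajectory of a cohort against its scene
#'
#' @param cohort cohort data.frame (or CSV path).
#' @param scenes Named list of `anatomical_scene`s (names = tumour
#'   ids) or a scenes directory written by [run_simulate()].
#' @param thr `zone_thresholds`.
#' @return data.frame: one safety report per cohort row, with the
#'   cohort's identifying columns.
#' @export
score_cohort <- function(cohort, scenes, thr = zone_thresholds()) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  if (is.character(scenes)) {
    dirs <- list.dirs(scenes, recursive = FALSE)
    scenes <- lapply(dirs, load_scene)
    names(scenes) <- vapply(scenes, `[[`, "", "tumour_id")
  }
  if (is.null(names(scenes)))
    names(scenes) <- vapply(scenes, `[[`, "", "tumour_id")
  missing_ids <- setdiff(unique(cohort$tumour_id), names(scenes))
  if (length(missing_ids)) {
    rows <- which(cohort$tumour_id %in% missing_ids)
    stopf("cohort references unknown tumour_id(s) %s (rows %s)",
          paste(missing_ids, collapse = ", "),
          paste(head(rows, 10L), collapse = ", "))
  }
  scenes <- lapply(scenes, function(sc) {
    for (nm in c("sulci", "eloquent_cortex", "ventricles", "tumour_mask"))
      sc[[nm]] <- precompute_mask_points(sc[[nm]])
    sc
  })
  reps <- lapply(seq_len(nrow(cohort)), function(i) {
    sc <- scenes[[cohort$tumour_id[i]]]
    seg <- segment(c(cohort$entry_x[i], cohort$entry_y[i], cohort$entry_z[i]),
                   c(cohort$target_x[i], cohort$target_y[i], cohort$target_z[i]))
    evaluate_trajectory(seg, sc, thr = thr)
  })
  out <- cbind(cohort[, c("trainee_id", "tumour_id", "group")],
               do.call(rbind, reps))
  rownames(out) <- NULL
  out
}

#' Score a cohort and write the safety outputs
#'
#' @param scenes Scenes directory or named scene list.
#' @param cohort Cohort CSV path or data.frame.
#' @param out Output directory.
#' @param thr `zone_thresholds`.
#' @param seed Seed recorded in the manifest (scoring itself is
#'   deterministic).
#' @return Invisible list with `reports`, `summary` and file paths.
#' @export
run_score <- function(scenes, cohort, out, thr = zone_thresholds(),
                      seed = NA_integer_) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  reports <- score_cohort(cohort, scenes, thr)
  reports_csv <- file.path(out, "safety_reports.csv")
  write.csv(reports, reports_csv, row.names = FALSE)
  summ <- summarize_safety(reports)
  comp <- summ$components
  comp$p_value <- vapply(comp$component, function(cc) {
    if (cc == "cst") return(NA_real_)
    compare_component_incidence(summ, cc)$p_value
  }, numeric(1))
  summary_csv <- file.path(out, "safety_summary.csv")
  write.csv(comp, summary_csv, row.names = FALSE)
  write.csv(summ$group_stats, file.path(out, "group_safety.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(seq_len(nrow(reports)), function(i) as.list(reports[i, ])),
    file.path(out, "safety_reports.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out, "score", seed,
                 list(vessel_mm = thr$vessel_mm, cst_mm = thr$cst_mm,
                      midline_mm = thr$midline_mm))
  invisible(list(reports = reports, summary = summ,
                 reports_csv = reports_csv, summary_csv = summary_csv))
}

#' Run the full cohort statistics
#'
#' Normalized times, Table-1-style group comparisons with
#' experience-adjusted p-values, learning-curve trends, and the
#' planning-profile clustering; writes all tables as CSV plus a run
#' manifest.
#'
#' @param cohort Cohort CSV path or data.frame.
#' @param out Output directory.
#' @param reports Optional scored safety reports (CSV path or
#'   data.frame) for the Table-2-style summary.
#' @param seed Seed for the clustering.
#' @param knn,resolution Clustering parameters.
#' @return Invisible list with every table.
#' @export
run_analyze <- function(cohort, out, reports = NULL, seed = 1L,
                        knn = 15L, resolution = 1.0) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  if (is.character(reports)) reports <- read.csv(reports)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cohort <- normalize_planning_times(cohort)

  vars <- c("planning_time_s", "normalized_time",
            "n_trajectory_changes", "n_lobe_changes")
  table1 <- do.call(rbind, lapply(vars, function(v) {
    cmp <- adjusted_comparison(cohort, v, binary = FALSE)
    data.frame(variable = v,
               whole_mean = mean(cohort[[v]]), whole_sem = sem(cohort[[v]]),
               t_nbx_mean = cmp$mean[["T-nBx"]], t_nbx_sem = cmp$sem[["T-nBx"]],
               a_nbx_mean = cmp$mean[["A-nBx"]], a_nbx_sem = cmp$sem[["A-nBx"]],
               p_value = cmp$p_value, p_adjusted = cmp$p_adjusted)
  }))
  write.csv(table1, file.path(out, "table1_planning.csv"), row.names = FALSE)

  lc <- do.call(rbind, lapply(c("all", "T-nBx", "A-nBx"), function(gg)
    as.data.frame(learning_curve_trend(cohort, gg))))
  write.csv(lc, file.path(out, "learning_curve.csv"), row.names = FALSE)

  cl <- cluster_planning_profiles(cohort, seed = seed, knn = knn,
                                  resolution = resolution)
  assign_df <- cbind(cohort[, c("trainee_id", "tumour_id", "group")],
                     cluster = cl$cluster)
  write.csv(assign_df, file.path(out, "cluster_assignments.csv"),
            row.names = FALSE)
  write.csv(data.frame(assign_df, umap1 = cl$embedding[, 1],
                       umap2 = cl$embedding[, 2]),
            file.path(out, "embedding.csv"), row.names = FALSE)

  table2 <- NULL
  if (!is.null(reports)) {
    summ <- summarize_safety(reports)
    table2 <- summ$components
    table2$p_value <- NA_real_
    table2$p_adjusted <- NA_real_
    merged <- cbind(reports,
                    experience_years = cohort$experience_years[
                      match(paste(reports$trainee_id, reports$tumour_id),
                            paste(cohort$trainee_id, cohort$tumour_id))])
    flag_col <- c(vessel = "vessel_zone", sulcus = "sulcus_transgressed",
                  eloquent_cortex = "eloquent_transgressed",
                  ventricle = "ventricle_transgressed",
                  midline = "midline_zone")
    for (cc in names(flag_col)) {
      v <- merged[[flag_col[cc]]]
      merged$.flag <- if (is.logical(v)) as.integer(v) else as.integer(v == 1L)
      i <- which(table2$component == cc)
      if (sum(merged$.flag) %in% c(0L, nrow(merged))) next
      cmp <- try(adjusted_comparison(merged, ".flag", binary = TRUE),
                 silent = TRUE)
      if (!inherits(cmp, "try-error")) {
        table2$p_value[i] <- cmp$p_value
        table2$p_adjusted[i] <- cmp$p_adjusted
      }
    }
    write.csv(table2, file.path(out, "table2_safety.csv"), row.names = FALSE)
  }
  write_manifest(out, "analyze", seed,
                 list(knn = knn, resolution = resolution))
  invisible(list(table1 = table1, learning_curve = lc, clusters = cl,
                 table2 = table2, cohort = cohort))
}
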