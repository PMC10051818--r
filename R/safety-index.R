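## Zone classification, component flags, the Trajectory Safety Index
## (TSI), and cohort-level safety summaries.
##
## TSI assigns one point for each of: sulcal transgression, eloquent
## cortex (M1) transgression, vessel zone 1, midline zone 1. Ventricle
## transgression and CST zone are computed and reported but never
## scored. Zone 1 is the high-risk proximity class: closer than the
## structure's threshold (vessel/CST 3 mm, midline 20 mm by default).

#' Zone thresholds (mm)
#' @param vessel_mm,cst_mm,midline_mm Positive distances below which a
#'   trajectory falls in zone 1 for that structure. Defaults 3, 3, 20.
#' @return Object of class `zone_thresholds`.
#' @export
zone_thresholds <- function(vessel_mm = 3, cst_mm = 3, midline_mm = 20) {
  for (v in c(vessel_mm, cst_mm, midline_mm))
    if (!is_num1(v) || v < 0) stopf("zone thresholds must be >= 0")
  structure(list(vessel_mm = vessel_mm, cst_mm = cst_mm,
                 midline_mm = midline_mm), class = "zone_thresholds")
}

#' Classify a distance into risk zone 1 or 2
#'
#' Zone 1 iff the distance is strictly below the structure's
#' threshold. A distance exactly equal to the threshold is zone 2 (the
#' zones are defined by strict inequalities on either side; equality
#' is a measure-zero case assigned to the low-risk zone).
#'
#' @param d Distance in mm (>= 0).
#' @param structure `"vessel"`, `"cst"` or `"midline"`.
#' @param thr `zone_thresholds`.
#' @return Integer 1 or 2.
#' @export
classify_zone <- function(d, structure = c("vessel", "cst", "midline"),
                          thr = zone_thresholds()) {
  structure <- match.arg(structure)
  if (any(!is.finite(d)) || any(d < 0)) stopf("distance must be >= 0")
  lim <- switch(structure, vessel = thr$vessel_mm, cst = thr$cst_mm,
                midline = thr$midline_mm)
  ifelse(d < lim, 1L, 2L)
}

#' Trajectory Safety Index from component flags
#'
#' Sum of four indicators: sulcus transgressed, eloquent cortex
#' transgressed, vessel zone 1, midline zone 1.
#'
#' @param components List/row with logical `sulcus_transgressed`,
#'   `eloquent_transgressed` and integer `vessel_zone`, `midline_zone`.
#' @return Integer 0..4 (vectorized over equal-length inputs).
#' @export
compute_tsi <- function(components) {
  with(components,
       as.integer(sulcus_transgressed) + as.integer(eloquent_transgressed) +
         as.integer(vessel_zone == 1L) + as.integer(midline_zone == 1L))
}

#' Evaluate one trajectory against a full scene
#'
#' Computes every distance and transgression flag via the geometry
#' primitives, classifies zones, and assembles the safety report.
#' Scoring always uses the full scene, including a CST hidden from the
#' planner. When vessels are given as both centerlines and a mask the
#' minimum of the two distances is used.
#'
#' @param entry,target Trajectory endpoints (world mm), or pass a
#'   `segment` as `entry`.
#' @param scene `anatomical_scene`.
#' @param thr `zone_thresholds`.
#' @return A one-row data.frame (class `safety_report`) with distances
#'   (mm), flags, zones, `tsi` and `length_mm`.
#' @export
evaluate_trajectory <- function(entry, scene, target = NULL,
                                thr = zone_thresholds()) {
  seg <- if (inherits(entry, "segment")) entry else segment(entry, target)
  if (!inherits(scene, "anatomical_scene"))
    stopf("scene must be an anatomical_scene")
  for (nm in c("sulci", "eloquent_cortex", "ventricles"))
    if (is.null(scene[[nm]])) stopf("scene is missing structure '%s'", nm)
  d_vessel <- Inf
  if (!is.null(scene$vessels$bundle))
    d_vessel <- min(d_vessel, min_distance_to_streamlines(seg, scene$vessels$bundle))
  if (!is.null(scene$vessels$mask))
    d_vessel <- min(d_vessel, min_distance_to_mask(seg, scene$vessels$mask))
  if (!is.finite(d_vessel)) stopf("scene is missing structure 'vessels'")
  d_mid <- distance_to_midline(seg, scene$midline)
  d_cst <- if (!is.null(scene$cst))
    min_distance_to_streamlines(seg, scene$cst) else NA_real_
  rep <- data.frame(
    sulcus_transgressed = transgresses_mask(seg, scene$sulci),
    eloquent_transgressed = transgresses_mask(seg, scene$eloquent_cortex),
    ventricle_transgressed = transgresses_mask(seg, scene$ventricles),
    d_vessel = d_vessel, d_midline = d_mid, d_cst = d_cst,
    vessel_zone = classify_zone(d_vessel, "vessel", thr),
    midline_zone = classify_zone(d_mid, "midline", thr),
    cst_zone = if (is.na(d_cst)) NA_integer_ else
      classify_zone(d_cst, "cst", thr),
    length_mm = segment_length(seg))
  rep$tsi <- compute_tsi(rep)
  class(rep) <- c("safety_report", class(rep))
  rep
}

#' Cohort safety summary (incidence table)
#'
#' Per safety component: overall count and percentage plus per-group
#' counts; per-group mean TSI and mean trajectory length with their
#' standard errors. CST zone is summarized over the records whose
#' scene carried tractography (typically the T-nBx half).
#'
#' @param reports data.frame of safety reports with a `group` column
#'   (`"T-nBx"`/`"A-nBx"`), e.g. a scored cohort.
#' @return List with `components` (data.frame), `group_stats`
#'   (data.frame) and `n`.
#' @export
summarize_safety <- function(reports) {
  if (nrow(reports) == 0L)
    return(list(components = data.frame(), group_stats = data.frame(), n = 0L))
  flags <- list(
    vessel = reports$vessel_zone == 1L,
    sulcus = reports$sulcus_transgressed,
    eloquent_cortex = reports$eloquent_transgressed,
    ventricle = reports$ventricle_transgressed,
    midline = reports$midline_zone == 1L,
    cst = reports$cst_zone == 1L)
  grp <- reports$group
  comp <- do.call(rbind, lapply(names(flags), function(nm) {
    f <- flags[[nm]]
    ok <- !is.na(f)
    data.frame(component = nm,
               n = sum(ok),
               overall = sum(f[ok]),
               pct = 100 * sum(f[ok]) / sum(ok),
               t_nbx = sum(f[ok & grp == "T-nBx"]),
               a_nbx = sum(f[ok & grp == "A-nBx"]))
  }))
  gs <- do.call(rbind, lapply(split(reports, grp), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               mean_tsi = mean(g$tsi), sem_tsi = sem(g$tsi),
               mean_length_mm = mean(g$length_mm),
               sem_length_mm = sem(g$length_mm))
  }))
  rownames(gs) <- NULL
  list(components = comp, group_stats = gs, n = nrow(reports))
}

#' Compare a safety component's incidence between groups
#'
#' Chi-square test without continuity correction on the 2x2
#' group-by-flag table; falls back to Fisher's exact test (flagged)
#' when a margin is zero.
#'
#' @param summary Output of [summarize_safety()], or a data.frame of
#'   reports (summarized internally).
#' @param component Component name as in the summary table.
#' @param n_per_group Named group sizes; taken from the summary when
#'   it was built from reports.
#' @return List with `statistic`, `p_value`, `odds_ratio`, `method`,
#'   `exact_fallback`.
#' @export
compare_component_incidence <- function(summary, component,
                                        n_per_group = NULL) {
  if (is.data.frame(summary)) summary <- summarize_safety(summary)
  comp <- summary$components
  row <- comp[comp$component == component, ]
  if (nrow(row) != 1L) stopf("unknown component '%s'", component)
  if (is.null(n_per_group)) {
    gs <- summary$group_stats
    n_per_group <- setNames(gs$n, gs$group)
  }
  n_t <- n_per_group[["T-nBx"]]; n_a <- n_per_group[["A-nBx"]]
  tab <- rbind(`T-nBx` = c(yes = row$t_nbx, no = n_t - row$t_nbx),
               `A-nBx` = c(yes = row$a_nbx, no = n_a - row$a_nbx))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (zero_margin) {
    ft <- fisher.test(tab)
    return(list(statistic = NA_real_, p_value = ft$p.value, odds_ratio = or,
                method = "fisher", exact_fallback = TRUE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       odds_ratio = or, method = "chisq", exact_fallback = FALSE)
}

#' Per-group mean TSI from component counts
#'
#' The internal-consistency identity behind the cohort mean TSI: the
#' group mean equals the sum of that group's four scored component
#' counts divided by the group size.
#'
#' @param sulcus,eloquent,vessel_zone1,midline_zone1 Component counts.
#' @param n Group size.
#' @return Mean TSI.
#' @export
tsi_from_counts <- function(sulcus, eloquent, vessel_zone1, midline_zone1, n) {
  (sulcus + eloquent + vessel_zone1 + midline_zone1) / n
}
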