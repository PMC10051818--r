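## Calibrated behavioural simulator for the planning cohort: 19
## trainees plan a biopsy on each of 10 scenes (5 presented with the
## CST visible, 5 anatomy-only, alternating). Change counts, lobe
## switches and planning times are drawn from group-calibrated
## distributions; the entry point itself comes from a candidate-
## sampling model that minimizes a penalty built from the safety
## components the planner can see.

#' Parameters for the behavioural cohort generator
#'
#' Group-level defaults are the study conditions: planning-time means
#' 197.5 s (T-nBx) / 252.8 s (A-nBx), trajectory-change means 2.89 /
#' 3.66, lobe-change means 0.23 / 0.66, experience tiers 5 junior / 7
#' intermediate / 7 advanced, and a learning-curve decrement on
#' log-time for the anatomy-only group only.
#'
#' @param n_trainees Number of trainees (19).
#' @param n_scenes Number of tumours/scenes (10; 5 per group).
#' @param tier_n Trainees per experience tier (junior, intermediate,
#'   advanced).
#' @param tier_years 2-column matrix of per-tier uniform year ranges.
#' @param time_mean_s Named group means of absolute planning time (s).
#' @param sigma_log SD of the lognormal time noise (log scale).
#' @param beta_changes Log-time increment per trajectory change above
#'   the group mean.
#' @param learn_log Named per-exercise log-time slope (learning curve);
#'   negative means faster with practice. Zero for T-nBx.
#' @param changes_mean Named Poisson means of trajectory changes.
#' @param changes_shift Non-negative integer added to the Poisson draw.
#' @param lobe_mean Named means of lobe changes; the per-change lobe
#'   switch probability is `lobe_mean / changes_mean`.
#' @param cst_noise_mm SD of the planner's CST localization error in
#'   the anatomy-only group (mm); the tractography group sees the true
#'   bundle.
#' @param penalty_weights Weights of the candidate penalty: sulcus,
#'   eloquent, vessel zone 1, midline zone 1, CST zone 1, length
#'   (per 100 mm).
#' @param penalty_noise SD of the noise added to candidate penalties
#'   (imperfect optimization).
#' @param entry_tau_mm Scatter (mm) of candidate entries around the
#'   shortest-path entry point.
#' @param seed Integer seed.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n_trainees = 19L, n_scenes = 10L,
                          tier_n = c(junior = 5L, intermediate = 7L,
                                     advanced = 7L),
                          tier_years = rbind(junior = c(0.5, 2),
                                             intermediate = c(2.5, 5),
                                             advanced = c(5.5, 8)),
                          time_mean_s = c("T-nBx" = 197.5, "A-nBx" = 252.8),
                          sigma_log = 0.55,
                          beta_changes = 0.06,
                          learn_log = c("T-nBx" = 0, "A-nBx" = -0.06),
                          changes_mean = c("T-nBx" = 2.89, "A-nBx" = 3.66),
                          changes_shift = 0L,
                          lobe_mean = c("T-nBx" = 0.23, "A-nBx" = 0.66),
                          cst_noise_mm = 15,
                          penalty_weights = c(sulcus = 1, eloquent = 0.2,
                                              vessel = 0.3, midline = 0.3,
                                              cst = 3, length = 0.5),
                          penalty_noise = 0.2,
                          entry_tau_mm = 30,
                          seed = 1L) {
  p <- as.list(environment())
  if (sum(tier_n) != n_trainees)
    stopf("tier counts must sum to n_trainees")
  if (n_scenes %% 2L != 0L) stopf("n_scenes must split evenly into 2 groups")
  if (any(time_mean_s <= 0) || any(changes_mean <= 0) || any(lobe_mean < 0))
    stopf("behavioural means must be positive")
  if (any(lobe_mean > changes_mean + changes_shift))
    stopf("lobe-change mean cannot exceed the trajectory-change mean")
  class(p) <- "cohort_params"
  p
}

## penalty of one candidate entry, from the components the planner sees
candidate_penalty <- function(entry, scene, visible_cst, p, thr) {
  seg <- segment(entry, scene$target)
  w <- p$penalty_weights
  pen <- w[["length"]] * segment_length(seg) / 100
  pen <- pen + w[["sulcus"]] * transgresses_mask(seg, scene$sulci)
  pen <- pen + w[["eloquent"]] * transgresses_mask(seg, scene$eloquent_cortex)
  d_ves <- min_distance_to_streamlines(seg, scene$vessels$bundle)
  pen <- pen + w[["vessel"]] * (d_ves < thr$vessel_mm)
  pen <- pen + w[["midline"]] *
    (distance_to_midline(seg, scene$midline) < thr$midline_mm)
  if (!is.null(visible_cst)) {
    d_cst <- min_distance_to_streamlines(seg, visible_cst)
    pen <- pen + w[["cst"]] * (d_cst < thr$cst_mm)
  }
  pen + rnorm(1, sd = p$penalty_noise)
}

## the planner's belief about the CST: the true bundle for T-nBx, a
## rigidly mislocalized copy for A-nBx (anatomical guesswork)
planner_cst <- function(scene, group, p) {
  if (is.null(scene$cst)) return(NULL)
  if (group == "T-nBx") return(scene$cst)
  delta <- c(rnorm(2, sd = p$cst_noise_mm), 0)
  streamline_bundle(lapply(scene$cst$streamlines,
                           function(s) sweep(s, 2L, delta, `+`)),
                    label = "CST")
}

#' Simulate one planning session
#'
#' Draws the trajectory-change count from the group's (shifted)
#' Poisson, samples that many rejected candidate entries plus one on
#' the cortical surface — consecutive candidates switch lobe with the
#' group's calibrated probability — and accepts the candidate with the
#' lowest visible-component penalty. Planning time is lognormal with
#' the group mean, scaled by the change count and, for the
#' anatomy-only group, decreasing with exercise order.
#'
#' @param trainee List with `trainee_id` and `experience_years`.
#' @param scene `anatomical_scene`.
#' @param group `"T-nBx"` or `"A-nBx"`.
#' @param p `cohort_params`.
#' @param exercise_order Position 1..10 of this scene in the session.
#' @param order_positions Exercise positions at which this group's
#'   scenes appear (for mean-preserving centring of the learning
#'   curve); defaults to the alternating schedule.
#' @param seed Optional seed for standalone use.
#' @param thr `zone_thresholds` the planner reasons with.
#' @return One-row data.frame: a trajectory-plan record.
#' @export
simulate_planning_session <- function(trainee, scene, group, p,
                                      exercise_order = 1L,
                                      order_positions = NULL,
                                      seed = NULL,
                                      thr = zone_thresholds()) {
  group <- match.arg(group, c("T-nBx", "A-nBx"))
  with_seed(seed, {
    lam <- p$changes_mean[[group]]
    n_changes <- rpois(1L, lam) + p$changes_shift
    p_switch <- min(1, p$lobe_mean[[group]] / (lam + p$changes_shift))

    surf <- scene$cortical_surface
    lobes <- scene$extra$surface_lobe
    if (is.null(lobes)) lobes <- lobe_of_entry(surf)
    ## preference: wide Gaussian scatter around the shortest-path entry
    d_tar <- sqrt(rowSums(sweep(surf, 2L, scene$target)^2))
    wpref <- exp(-(d_tar - min(d_tar))^2 / (2 * p$entry_tau_mm^2))

    vis_cst <- planner_cst(scene, group, p)
    n_cand <- n_changes + 1L
    cand_idx <- integer(n_cand)
    cand_idx[1L] <- sample.int(nrow(surf), 1L, prob = wpref)
    for (j in seq_len(n_cand - 1L)) {
      cur_lobe <- lobes[cand_idx[j]]
      switch_lobe <- runif(1) < p_switch
      pool <- if (switch_lobe) lobes != cur_lobe else lobes == cur_lobe
      if (!any(pool)) pool <- rep(TRUE, nrow(surf))
      cand_idx[j + 1L] <- sample(which(pool), 1L, prob = wpref[pool])
    }
    pens <- vapply(cand_idx, function(i)
      candidate_penalty(surf[i, ], scene, vis_cst, p, thr), numeric(1))
    best <- cand_idx[which.min(pens)]
    entry <- surf[best, ]
    n_lobe_changes <- sum(lobes[cand_idx[-1L]] != lobes[cand_idx[-n_cand]])

    ## lognormal planning time calibrated so the group mean equals
    ## time_mean_s exactly in expectation: correct for the change-count
    ## and learning-curve multipliers in closed form
    gam <- p$learn_log[[group]]
    if (is.null(order_positions))
      order_positions <- if (group == "T-nBx") seq(1, p$n_scenes, by = 2)
        else seq(2, p$n_scenes, by = 2)
    obar <- mean(order_positions)
    k_changes <- exp(lam * (exp(p$beta_changes) - 1) - p$beta_changes * lam)
    k_order <- mean(exp(gam * (order_positions - obar)))
    mu <- log(p$time_mean_s[[group]]) - log(k_changes) - log(k_order) -
      p$sigma_log^2 / 2
    log_t <- mu + p$beta_changes * (n_changes - (lam + p$changes_shift)) +
      gam * (exercise_order - obar) + rnorm(1, sd = p$sigma_log)

    data.frame(trainee_id = trainee$trainee_id,
               tumour_id = scene$tumour_id, group = group,
               entry_x = entry[1], entry_y = entry[2], entry_z = entry[3],
               target_x = scene$target[1], target_y = scene$target[2],
               target_z = scene$target[3],
               planning_time_s = exp(log_t),
               n_trajectory_changes = n_changes,
               n_lobe_changes = n_lobe_changes,
               exercise_order = exercise_order,
               experience_years = trainee$experience_years,
               row.names = NULL)
  })
}

#' Generate a full synthetic cohort
#'
#' 19 trainees x 10 scenes = 190 planning sessions. Scenes are
#' presented in alternating group order (T-nBx at odd positions) and
#' the same order is retained for every trainee.
#'
#' @param scenes List of `anatomical_scene`s, half per group; the
#'   first half are presented with the CST visible (T-nBx).
#' @param p `cohort_params`.
#' @param thr `zone_thresholds`.
#' @return Validated `cohort_table` data.frame with 190 rows.
#' @export
generate_cohort <- function(scenes, p = cohort_params(),
                            thr = zone_thresholds()) {
  if (length(scenes) != p$n_scenes)
    stopf("expected %d scenes, got %d", p$n_scenes, length(scenes))
  half <- p$n_scenes %/% 2L
  with_seed(p$seed, {
    ## experience tiers: 5 junior, 7 intermediate, 7 advanced
    years <- unlist(lapply(seq_along(p$tier_n), function(k)
      runif(p$tier_n[k], p$tier_years[k, 1], p$tier_years[k, 2])))
    trainees <- lapply(seq_len(p$n_trainees), function(i)
      list(trainee_id = sprintf("tr%02d", i), experience_years = years[i],
           tier = rep(names(p$tier_n), p$tier_n)[i]))

    ## alternating presentation: T-nBx scenes at odd positions
    order_group <- rep(c("T-nBx", "A-nBx"), half)
    scene_at <- integer(p$n_scenes)
    scene_at[seq(1, p$n_scenes, 2)] <- seq_len(half)          # T scenes
    scene_at[seq(2, p$n_scenes, 2)] <- half + seq_len(half)   # A scenes
    pos_of_group <- split(seq_len(p$n_scenes), order_group)

    rows <- vector("list", p$n_trainees * p$n_scenes)
    k <- 0L
    for (tr in trainees) {
      for (pos in seq_len(p$n_scenes)) {
        g <- order_group[pos]
        sc <- scenes[[scene_at[pos]]]
        k <- k + 1L
        rows[[k]] <- simulate_planning_session(
          tr, sc, g, p, exercise_order = pos,
          order_positions = pos_of_group[[g]], thr = thr)
      }
    }
    out <- do.call(rbind, rows)
    out$tier <- rep(vapply(trainees, `[[`, "", "tier"),
                    each = p$n_scenes)
    validate_cohort(out)
  })
}

#' Generate the default scene set for a cohort
#'
#' @param n_scenes Number of scenes (first half T-nBx).
#' @param seed Base seed; scene i uses `seed * 100 + i`.
#' @param base `scene_params` to vary the seed on.
#' @return List of `anatomical_scene`s with `cst_visible` set by group.
#' @export
generate_scene_set <- function(n_scenes = 10L, seed = 1L,
                               base = scene_params()) {
  half <- n_scenes %/% 2L
  lapply(seq_len(n_scenes), function(i) {
    sp <- base
    sp$seed <- seed * 100L + i
    sc <- generate_scene(sp)
    sc$tumour_id <- sprintf("tum%02d", i)
    sc$cst_visible <- i <= half
    sc
  })
}
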