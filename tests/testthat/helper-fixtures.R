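## Shared fixtures, built once per test run and memoised. Everything is
## generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

## the default 10-scene set shared by cohort-level tests
get_test_scenes <- function() memo("scenes", generate_scene_set(10, seed = 1L))

## one generated + scored cohort (seed 1)
get_test_cohort <- function() memo("cohort", {
  generate_cohort(get_test_scenes(), cohort_params(seed = 1L))
})

get_test_reports <- function() memo("reports", {
  score_cohort(get_test_cohort(), get_test_scenes())
})

## 20 cohorts (seeds 1..20) over the shared scene set: the calibration
## ensemble used by the stochastic recovery checks
get_calibration_cohorts <- function() memo("cal20", {
  lapply(1:20, function(s)
    normalize_planning_times(generate_cohort(get_test_scenes(),
                                             cohort_params(seed = s))))
})

## small axis-aligned unit-voxel mask with a filled box of voxels
box_mask <- function(dims = c(9, 9, 9), lo = c(4, 4, 4), hi = c(6, 6, 6),
                     voxel = 1, origin = c(0, 0, 0), label = "vessel") {
  g <- array(0L, dims)
  g[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  aff <- diag(c(voxel, voxel, voxel, 1)); aff[1:3, 4] <- origin
  volumetric_mask(g, aff, label)
}

## random ellipsoidal blob mask with a random-scale affine
random_blob_mask <- function() {
  dims <- c(14, 14, 14); v <- runif(1, 0.8, 2.5)
  aff <- diag(c(v, v, v, 1)); aff[1:3, 4] <- runif(3, -6, 0)
  ctr <- runif(3, 3, 10); sax <- runif(3, 1.5, 5)
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  ell <- rowSums(sweep(sweep(idx, 2L, ctr), 2L, sax, `/`)^2)
  g <- array(0L, dims); g[ell <= 1] <- 1L
  if (sum(g) == 0L) g[7, 7, 7] <- 1L
  volumetric_mask(g, aff, "vessel")
}

## gently curved random polyline for oracle tests
random_polyline <- function(n = 8) {
  p0 <- runif(3, -20, 20); d <- rnorm(3); d <- d / sqrt(sum(d^2))
  t <- seq(0, runif(1, 8, 20), length.out = n)
  t(sapply(t, function(tt) p0 + tt * d)) + matrix(rnorm(3 * n, sd = 1), n)
}

## independent dense-sampling oracle: streamlines resampled at `step`,
## exact point-to-segment distance to the trajectory
oracle_streamline_dist <- function(seg, bundle, step = 0.05) {
  dmin <- Inf
  for (s in bundle$streamlines) {
    for (i in seq_len(nrow(s) - 1L)) {
      e0 <- s[i, ]; e1 <- s[i + 1L, ]
      L <- sqrt(sum((e1 - e0)^2))
      tt <- seq(0, 1, length.out = max(2L, ceiling(L / step) + 1L))
      samp <- outer(1 - tt, e0) + outer(tt, e1)
      dmin <- min(dmin, min(trajsafe:::dist_points_to_segment(samp, seg$a, seg$b)))
    }
  }
  dmin
}

## independent distance oracle: segment sampled at `step` mm, exact
## distance from each sample to the nonzero voxel-centre set
oracle_mask_dist <- function(seg, mask, step = 0.05) {
  pts <- trajsafe:::mask_points(mask)
  L <- segment_length(seg)
  tt <- seq(0, 1, length.out = max(2L, ceiling(L / step) + 1L))
  samp <- outer(1 - tt, seg$a) + outer(tt, seg$b)
  m <- Inf
  for (i in seq(1L, nrow(samp), by = 2000L)) {
    j <- min(i + 1999L, nrow(samp))
    blk <- samp[i:j, , drop = FALSE]
    D2 <- outer(rowSums(blk^2), rowSums(pts^2), `+`) - 2 * blk %*% t(pts)
    m <- min(m, sqrt(max(0, min(D2))))
  }
  m
}

## independent transgression oracle: sample the segment every 0.1 voxel
## in index space and look the voxels up directly
oracle_transgresses <- function(seg, mask, step_vox = 0.1) {
  uv <- world_to_voxel(rbind(seg$a, seg$b), mask$affine)
  L <- sqrt(sum((uv[2, ] - uv[1, ])^2))
  tt <- seq(0, 1, length.out = max(2L, ceiling(L / step_vox) + 1L))
  ijk <- round(outer(1 - tt, uv[1, ]) + outer(tt, uv[2, ]))
  dims <- dim(mask$grid)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < dims[1] & ijk[, 2] >= 0 &
    ijk[, 2] < dims[2] & ijk[, 3] >= 0 & ijk[, 3] < dims[3]
  if (!any(ok)) return(FALSE)
  sub <- ijk[ok, , drop = FALSE] + 1L
  any(mask$grid[cbind(sub[, 1], sub[, 2], sub[, 3])] != 0L)
}

## synthetic safety-report frame with prescribed per-group component
## counts (used to exercise the summary arithmetic on printed tables)
reports_from_counts <- function(n_t = 95L, n_a = 95L,
                                vessel = c(t = 51L, a = 55L),
                                sulcus = c(t = 42L, a = 51L),
                                eloquent = c(t = 23L, a = 41L),
                                ventricle = c(t = 0L, a = 1L),
                                midline = c(t = 14L, a = 12L),
                                cst_t = 14L) {
  first_k <- function(n, k) c(rep(TRUE, k), rep(FALSE, n - k))
  mk <- function(n, cnt, cst_zone) {
    df <- data.frame(
      vessel_zone = ifelse(first_k(n, cnt[["vessel"]]), 1L, 2L),
      sulcus_transgressed = first_k(n, cnt[["sulcus"]]),
      eloquent_transgressed = first_k(n, cnt[["eloquent"]]),
      ventricle_transgressed = first_k(n, cnt[["ventricle"]]),
      midline_zone = ifelse(first_k(n, cnt[["midline"]]), 1L, 2L),
      cst_zone = cst_zone, length_mm = 60)
    df$tsi <- compute_tsi(df)
    df
  }
  t_rep <- mk(n_t, c(vessel = vessel[["t"]], sulcus = sulcus[["t"]],
                     eloquent = eloquent[["t"]], ventricle = ventricle[["t"]],
                     midline = midline[["t"]]),
              ifelse(first_k(n_t, cst_t), 1L, 2L))
  t_rep$group <- "T-nBx"
  a_rep <- mk(n_a, c(vessel = vessel[["a"]], sulcus = sulcus[["a"]],
                     eloquent = eloquent[["a"]], ventricle = ventricle[["a"]],
                     midline = midline[["a"]]),
              NA_integer_)
  a_rep$group <- "A-nBx"
  rbind(t_rep, a_rep)
}

## build a small cohort-like frame with two planted planning archetypes
planted_cohort <- function(n_per = 60, seed = 13) {
  set.seed(seed)
  a_like <- data.frame(
    trainee_id = rep(sprintf("a%02d", 1:6), length.out = n_per),
    n_trajectory_changes = rpois(n_per, 7) + 3L,
    n_lobe_changes = rpois(n_per, 2),
    group = "A-nBx",
    normalized_time = pmin(1, pmax(0, rnorm(n_per, 0.85, 0.05))))
  t_like <- data.frame(
    trainee_id = rep(sprintf("t%02d", 1:6), length.out = n_per),
    n_trajectory_changes = rpois(n_per, 1),
    n_lobe_changes = 0L,
    group = "T-nBx",
    normalized_time = pmin(1, pmax(0, rnorm(n_per, 0.1, 0.05))))
  out <- rbind(a_like, t_like)
  out$n_lobe_changes <- pmin(out$n_lobe_changes, out$n_trajectory_changes)
  out$archetype <- rep(c("A", "T"), each = n_per)
  out
}

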