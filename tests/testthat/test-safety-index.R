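test_that("zone classification is strict at the threshold", {
  thr <- zone_thresholds()
  expect_equal(classify_zone(2.9, "vessel", thr), 1L)
  expect_equal(classify_zone(3.0, "vessel", thr), 2L)   # boundary -> zone 2
  expect_equal(classify_zone(16.8, "midline", thr), 1L)
  expect_equal(classify_zone(20, "midline", thr), 2L)
  expect_equal(classify_zone(2.9, "cst", thr), 1L)
  expect_error(classify_zone(-1, "vessel", thr), ">= 0")
  ## shrinking a threshold can only shrink the zone-1 set
  d <- runif(50, 0, 10)
  for (lim in c(5, 3, 1, 0.5)) {
    z <- classify_zone(d, "vessel", zone_thresholds(vessel_mm = lim))
    if (lim < 5) expect_lte(sum(z == 1L), prev)
    prev <- sum(z == 1L)
  }
})

test_that("TSI sums exactly the four scored components, 0..4", {
  none <- data.frame(sulcus_transgressed = FALSE, eloquent_transgressed = FALSE,
                     vessel_zone = 2L, midline_zone = 2L)
  all4 <- data.frame(sulcus_transgressed = TRUE, eloquent_transgressed = TRUE,
                     vessel_zone = 1L, midline_zone = 1L)
  expect_equal(compute_tsi(none), 0L)
  expect_equal(compute_tsi(all4), 4L)
  ## monotone in each flag; ventricle/CST never scored
  grid <- expand.grid(s = c(FALSE, TRUE), e = c(FALSE, TRUE),
                      v = 1:2, m = 1:2)
  tsi <- compute_tsi(data.frame(sulcus_transgressed = grid$s,
                                eloquent_transgressed = grid$e,
                                vessel_zone = grid$v, midline_zone = grid$m))
  expect_true(all(tsi >= 0 & tsi <= 4))
  expect_equal(tsi, grid$s + grid$e + (grid$v == 1) + (grid$m == 1))
})

test_that("group mean TSI equals the component-count identity", {
  ## printed component counts for the tractography group
  expect_equal(round(tsi_from_counts(42, 23, 51, 14, 95), 2), 1.37)
  ## and the identity holds exactly on any report frame
  rep <- reports_from_counts()
  s <- summarize_safety(rep)
  for (g in c("T-nBx", "A-nBx")) {
    comp <- s$components
    ident <- tsi_from_counts(
      comp$t_nbx[comp$component == "sulcus"] * (g == "T-nBx") +
        comp$a_nbx[comp$component == "sulcus"] * (g == "A-nBx"),
      comp$t_nbx[comp$component == "eloquent_cortex"] * (g == "T-nBx") +
        comp$a_nbx[comp$component == "eloquent_cortex"] * (g == "A-nBx"),
      comp$t_nbx[comp$component == "vessel"] * (g == "T-nBx") +
        comp$a_nbx[comp$component == "vessel"] * (g == "A-nBx"),
      comp$t_nbx[comp$component == "midline"] * (g == "T-nBx") +
        comp$a_nbx[comp$component == "midline"] * (g == "A-nBx"),
      sum(rep$group == g))
    expect_equal(s$group_stats$mean_tsi[s$group_stats$group == g], ident)
  }
})

test_that("evaluate_trajectory composes the geometry into a report", {
  ## constructed scene on a 30^3 unit-voxel grid, world -15..14 mm:
  ## tumour box [-1,1]^3 around the target, a sulcal sheet at
  ## x 4..6 / z 8..10, an M1 slab at x 1..3 / z 5..7, a ventricle in a
  ## far corner, one vessel centerline along y at (x,z) = (3,10)
  mk <- function(wlo, whi, label) box_mask(c(30, 30, 30), wlo + 16, whi + 16,
                                           1, c(-15, -15, -15), label)
  scene <- anatomical_scene(
    tumour_id = "fix", tumour_mask = mk(c(-1, -1, -1), c(1, 1, 1), "tumour"),
    target = c(0, 0, 0),
    cst = streamline_bundle(list(cbind(seq(-8, 8, 2), -10, -4)), "CST"),
    vessels = streamline_bundle(list(cbind(3, seq(-5, 5, 1), 10)), "vessel"),
    sulci = mk(c(4, -3, 8), c(6, 3, 10), "sulcus"),
    eloquent_cortex = mk(c(1, -3, 5), c(3, 3, 7), "eloquent_cortex"),
    ventricles = mk(c(-13, -13, -13), c(-12, -12, -12), "ventricle"),
    midline = midline_plane(c(-10, 2, 0), c(-10, -24, 0)),
    cortical_surface = matrix(c(6, 0, 12), 1))

  ## all four scored components fire: the trajectory pierces the sulcal
  ## sheet and M1, passes < 3 mm from the vessel, < 20 mm from midline
  rep4 <- evaluate_trajectory(segment(c(6, 0, 12), c(0, 0, 0)), scene)
  expect_true(rep4$sulcus_transgressed)
  expect_true(rep4$eloquent_transgressed)
  expect_lt(rep4$d_vessel, 3)
  expect_lt(rep4$d_midline, 20)
  expect_equal(rep4$tsi, 4L)
  expect_false(rep4$ventricle_transgressed)

  ## same anatomy with a distant midline: a trajectory clear of every
  ## structure scores 0, one crossing only M1 scores 1
  scene_far <- scene
  scene_far$midline <- midline_plane(c(-40, 2, 0), c(-40, -24, 0))
  rep0 <- evaluate_trajectory(segment(c(-8, -12, -2), c(-6, -11, -1)),
                              scene_far)
  expect_equal(rep0$tsi, 0L)
  rep1 <- evaluate_trajectory(segment(c(-5, 0, 6), c(5, 0, 6)), scene_far)
  expect_true(rep1$eloquent_transgressed)
  expect_false(rep1$sulcus_transgressed)
  expect_equal(rep1$vessel_zone, 2L)
  expect_equal(rep1$tsi, 1L)

  ## missing scored structure is named
  broken <- scene; broken$vessels <- list()
  expect_error(evaluate_trajectory(segment(c(6, 0, 12), c(0, 0, 0)), broken),
               "vessel")
})

test_that("cohort summary reproduces printed-table arithmetic", {
  s <- summarize_safety(reports_from_counts())
  comp <- s$components
  expect_equal(comp$overall[comp$component == "vessel"], 106)
  expect_equal(comp$pct[comp$component == "vessel"], 100 * 106 / 190)
  expect_equal(round(comp$pct[comp$component == "vessel"], 2), 55.79)
  expect_equal(round(comp$pct[comp$component == "sulcus"], 2), 48.95)
  ## CST is summarized over the 95 records that carry tractography
  expect_equal(comp$n[comp$component == "cst"], 95)
  expect_equal(round(comp$pct[comp$component == "cst"], 2), 14.74)
  ## row order of the cohort must not matter
  rep <- reports_from_counts()
  s2 <- summarize_safety(rep[sample(nrow(rep)), ])
  expect_equal(s2$components, s$components)
  expect_equal(s2$group_stats, s$group_stats)
  ## empty cohort
  s0 <- summarize_safety(rep[0, ])
  expect_equal(s0$n, 0L)
  expect_equal(nrow(s0$components), 0L)
})

test_that("component incidence test matches a 2x2 chi-square oracle", {
  s <- summarize_safety(reports_from_counts())
  ## identical counts -> no association
  same <- compare_component_incidence(
    list(components = data.frame(component = "x", t_nbx = 30, a_nbx = 30),
         group_stats = data.frame(group = c("T-nBx", "A-nBx"), n = c(95, 95))),
    "x")
  expect_equal(same$p_value, 1)
  ## eloquent cortex 23/95 vs 41/95: significant, A-nBx higher
  el <- compare_component_incidence(s, "eloquent_cortex")
  ## hand-computed Pearson chi-square (no correction) on the same table
  tab <- rbind(c(23, 72), c(41, 54))
  expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi <- sum((tab - expct)^2 / expct)
  expect_equal(el$statistic, chi, tolerance = 1e-12)
  expect_lt(el$p_value, 0.05)
  expect_gt(el$p_value, 0.001)
  expect_lt(el$odds_ratio, 1)   # tractography group at lower odds
  ## vessel 51 vs 55: non-significant
  ves <- compare_component_incidence(s, "vessel")
  expect_gt(ves$p_value, 0.05)
  ## zero-margin table -> exact-test fallback, flagged
  vent <- compare_component_incidence(
    list(components = data.frame(component = "v", t_nbx = 0, a_nbx = 0),
         group_stats = data.frame(group = c("T-nBx", "A-nBx"), n = c(95, 95))),
    "v")
  expect_true(vent$exact_fallback)
  expect_equal(vent$p_value, 1)
})
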