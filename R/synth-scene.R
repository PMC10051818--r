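## Seeded generator for anatomically plausible right-hemisphere scenes:
## a central-core tumour, a CST bundle deflected laterally around it,
## cortical/sulcal vessels, sulcal sheets, an M1 band, a ventricle and
## the midsagittal plane. Everything is deterministic given the seed.
##
## Geometry is a half-ellipsoid "hemisphere" in world mm (RAS, x >= 0 is
## the right side). Masks live on a 2 mm isotropic grid whose affine has
## integer translations, so coordinates survive the float32 NIfTI
## round-trip exactly.

#' Parameters for the synthetic scene generator
#'
#' Defaults describe a right hemisphere with a deep central-core region
#' containing the tumour. The tumour must fit inside the central-core
#' bounds; the CST is routed from the M1 band to the brainstem box and
#' deflected around the tumour with a lateral bias.
#'
#' @param voxel_mm Isotropic voxel size of all masks (mm).
#' @param hemi_center,hemi_semi Centre and semi-axes (mm) of the
#'   hemisphere ellipsoid (restricted to x >= 0).
#' @param core_lo,core_hi Central-core bounds (mm); the whole tumour
#'   stays inside this box.
#' @param tumour_radius Min/max tumour radius (mm).
#' @param n_cst Number of CST streamlines.
#' @param cst_points Samples per streamline.
#' @param cst_spread Lateral scatter of CST seed points (mm).
#' @param cst_margin Clearance kept between CST and tumour surface (mm).
#' @param n_vessels Number of cortical surface vessels.
#' @param n_deep_vessels Number of vessels running in sulcal depths.
#' @param sulcus_halfwidth Half-thickness of sulcal sheets (mm).
#' @param sulcus_y Anterior-posterior positions of the sulcal sheets (mm).
#' @param m1_y,m1_zmin Extent of the eloquent (M1) cortical band (mm).
#' @param brainstem_lo,brainstem_hi Brainstem box (mm).
#' @param n_surface Surface sample count before filtering.
#' @param seed Integer seed; the scene is a pure function of it.
#' @return Object of class `scene_params`.
#' @export
scene_params <- function(voxel_mm = 2,
                         hemi_center = c(0, -15, 10),
                         hemi_semi = c(68, 85, 65),
                         core_lo = c(10, -50, -5), core_hi = c(46, 14, 44),
                         tumour_radius = c(10, 14),
                         n_cst = 30, cst_points = 48, cst_spread = 6,
                         cst_margin = 2,
                         n_vessels = 80, n_deep_vessels = 8,
                         sulcus_halfwidth = 1.5,
                         sulcus_y = c(-66, -52, -38, -24, -10, 4, 18, 32, 46),
                         m1_y = c(-36, -8), m1_zmin = 5,
                         brainstem_lo = c(2, -38, -56),
                         brainstem_hi = c(14, -18, -40),
                         n_surface = 4000, seed = 1L) {
  p <- list(voxel_mm = voxel_mm, hemi_center = hemi_center,
            hemi_semi = hemi_semi, core_lo = core_lo, core_hi = core_hi,
            tumour_radius = tumour_radius, n_cst = n_cst,
            cst_points = cst_points, cst_spread = cst_spread,
            cst_margin = cst_margin, n_vessels = n_vessels,
            n_deep_vessels = n_deep_vessels,
            sulcus_halfwidth = sulcus_halfwidth, sulcus_y = sulcus_y,
            m1_y = m1_y, m1_zmin = m1_zmin,
            brainstem_lo = brainstem_lo, brainstem_hi = brainstem_hi,
            n_surface = n_surface, seed = seed)
  if (any(c(voxel_mm, hemi_semi, tumour_radius, cst_margin,
            sulcus_halfwidth) <= 0))
    stopf("scene_params: all extents must be positive")
  if (tumour_radius[1] > tumour_radius[2])
    stopf("scene_params: tumour radius range inverted")
  if (any(2 * tumour_radius[2] > (core_hi - core_lo)))
    stopf("scene_params: tumour does not fit inside the central-core bounds")
  class(p) <- "scene_params"
  p
}

## ellipsoidal radial coordinate: 1 on the hemisphere surface
hemi_rho <- function(pts, p) {
  sweep2 <- sweep(pts, 2L, p$hemi_center)
  sqrt(rowSums(sweep(sweep2, 2L, p$hemi_semi, `/`)^2))
}

## quasi-uniform directions via the Fibonacci sphere (deterministic)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Lobe of a cortical entry point
#'
#' Four-way partition of the hemisphere surface (frontal / parietal /
#' temporal / occipital) around fixed landmark planes: the central
#' region boundary at y = -20 mm, the occipital boundary at y = -62 mm
#' and the Sylvian plane at z = 18 mm.
#'
#' @param pts n x 3 matrix (or single point) of world coordinates.
#' @return Character vector of lobe names.
#' @export
lobe_of_entry <- function(pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  ifelse(pts[, 2] > -20, "frontal",
    ifelse(pts[, 2] <= -62, "occipital",
      ifelse(pts[, 3] > 18, "parietal", "temporal")))
}

## grid of voxel-centre world coordinates for the scene masks
scene_grid <- function(p) {
  v <- p$voxel_mm
  origin <- c(0, -102, -58)
  dims <- c(36, 88, 68)
  affine <- diag(c(v, v, v, 1))
  affine[1:3, 4] <- origin
  ## voxel-centre coordinates along each axis
  ax <- lapply(1:3, function(k) origin[k] + v * (seq_len(dims[k]) - 1L))
  list(origin = origin, dims = dims, affine = affine, ax = ax)
}

## binary mask from a predicate over world coordinates, evaluated on
## the separable grid (xv, yv, zv are per-axis coordinate arrays)
grid_mask <- function(gr, fun, label) {
  X <- array(rep(gr$ax[[1]], times = gr$dims[2] * gr$dims[3]), gr$dims)
  Y <- array(rep(rep(gr$ax[[2]], each = gr$dims[1]), times = gr$dims[3]),
             gr$dims)
  Z <- array(rep(gr$ax[[3]], each = gr$dims[1] * gr$dims[2]), gr$dims)
  volumetric_mask(fun(X, Y, Z), gr$affine, label)
}

#' Generate a synthetic anatomical scene
#'
#' @param p `scene_params`.
#' @return `anatomical_scene` with all structures present (CST
#'   included; visibility to the planner is decided by the cohort
#'   generator, not the anatomy).
#' @export
generate_scene <- function(p = scene_params()) {
  stopifnot(inherits(p, "scene_params"))
  with_seed(p$seed, {
    gr <- scene_grid(p)
    hc <- p$hemi_center; hs <- p$hemi_semi
    rho2 <- function(X, Y, Z)
      ((X - hc[1]) / hs[1])^2 + ((Y - hc[2]) / hs[2])^2 +
      ((Z - hc[3]) / hs[3])^2

    ## tumour: sphere inside the central core
    r <- runif(1, p$tumour_radius[1], p$tumour_radius[2])
    lo <- p$core_lo + r; hi <- p$core_hi - r
    tc <- lo + runif(3) * (hi - lo)
    tumour <- grid_mask(gr, function(X, Y, Z)
      (X - tc[1])^2 + (Y - tc[2])^2 + (Z - tc[3])^2 <= r^2, "tumour")
    target <- colMeans(mask_points(tumour))

    ## ventricle: deep paramedian ellipsoid
    ventricle <- grid_mask(gr, function(X, Y, Z)
      ((X - 10) / 5)^2 + ((Y + 25) / 28)^2 + ((Z - 8) / 9)^2 <= 1,
      "ventricle")

    ## sulci: thin tilted sheets folded into the cortical shell
    sy <- p$sulcus_y; hw <- p$sulcus_halfwidth
    sulci <- grid_mask(gr, function(X, Y, Z) {
      rr <- rho2(X, Y, Z)
      shell <- rr <= 1 & rr >= 0.80^2 & X >= 4 & Z >= -25
      m <- array(FALSE, dim(X))
      for (y0 in sy)
        m <- m | abs(Y - (y0 + 0.15 * (Z - 10))) <= hw
      m & shell
    }, "sulcus")

    ## eloquent cortex: M1 band of the cortical shell
    m1 <- grid_mask(gr, function(X, Y, Z) {
      rr <- rho2(X, Y, Z)
      rr <= 1 & rr >= 0.86^2 & Y >= p$m1_y[1] & Y <= p$m1_y[2] &
        Z >= p$m1_zmin & X >= 8
    }, "eloquent_cortex")

    ## cortical surface samples (entry candidates), with lobe labels
    u <- fibonacci_sphere(p$n_surface)
    surf <- sweep(sweep(u, 2L, hs, `*`), 2L, hc, `+`)
    keep <- surf[, 1] >= 6 & surf[, 3] >= -25
    surf <- surf[keep, , drop = FALSE]
    lobes <- lobe_of_entry(surf)

    vessels <- generate_vessel_bundle(p, surf)
    cst <- generate_cst_bundle(list(target = tc, radius = r), p)

    anatomical_scene(
      tumour_id = sprintf("synth-%03d", p$seed %% 1000L),
      tumour_mask = tumour, target = target, cst = cst,
      vessels = vessels, sulci = sulci, eloquent_cortex = m1,
      ventricles = ventricle,
      midline = midline_plane(c(0, 2, 0), c(0, -24, 0)),
      cortical_surface = surf, cst_visible = TRUE,
      extra = list(surface_lobe = lobes, tumour_centre = tc,
                   tumour_radius = r))
  })
}

## smooth vessel polylines: arcs over the ellipsoid surface plus a few
## vessels running in the sulcal depths
generate_vessel_bundle <- function(p, surf) {
  hc <- p$hemi_center; hs <- p$hemi_semi
  one_arc <- function(rho) {
    ## random great-circle arc in direction space, mapped to the
    ## ellipsoid at radial coordinate rho, with small wobble
    u0 <- rnorm(3); u0 <- u0 / sqrt(sum(u0^2))
    if (u0[1] < 0.15) u0[1] <- 0.15 + abs(u0[1])  # stay on the right side
    u0 <- u0 / sqrt(sum(u0^2))
    w <- rnorm(3); w <- w - sum(w * u0) * u0
    w <- w / sqrt(sum(w^2))
    len <- runif(1, 0.6, 1.1)           # arc length in radians
    t <- seq(0, len, length.out = 25L)
    dirs <- outer(cos(t), u0) + outer(sin(t), w)
    dirs <- dirs + matrix(rnorm(length(dirs), sd = 0.01), nrow(dirs))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- sweep(sweep(dirs, 2L, hs * rho, `*`), 2L, hc, `+`)
    pts[pts[, 1] >= 2, , drop = FALSE]
  }
  arcs <- list()
  n_want <- p$n_vessels
  while (length(arcs) < n_want) {
    a <- one_arc(1.0)
    if (nrow(a) >= 2L) arcs[[length(arcs) + 1L]] <- a
  }
  for (i in seq_len(p$n_deep_vessels)) {
    y0 <- sample(p$sulcus_y, 1L)
    a <- one_arc(0.82)
    ## bend the deep vessel into the chosen sulcal sheet
    a[, 2] <- y0 + 0.15 * (a[, 3] - 10) + rnorm(nrow(a), sd = 0.5)
    if (nrow(a) >= 2L) arcs[[length(arcs) + 1L]] <- a
  }
  streamline_bundle(arcs, label = "vessel")
}

#' Generate a CST streamline bundle routed around a tumour
#'
#' Streamlines start in the M1 band, descend through a deep waypoint
#' near the internal capsule and end in the brainstem box. Points that
#' would enter the tumour's clearance ball are pushed out of it with a
#' lateral (away-from-midline) bias, so the bundle is deflected, never
#' transected — the displacement a space-occupying central-core lesion
#' produces.
#'
#' @param tumour List with `target` (centre, mm) and `radius` (mm), or
#'   an `anatomical_scene` carrying `extra$tumour_centre`/`radius`.
#' @param p `scene_params`.
#' @param seed Optional seed for standalone use.
#' @param deflect Set FALSE to generate the tumour-free bundle (used
#'   to test the displacement model).
#' @return `streamline_bundle` with label CST.
#' @export
generate_cst_bundle <- function(tumour, p = scene_params(), seed = NULL,
                                deflect = TRUE) {
  if (inherits(tumour, "anatomical_scene"))
    tumour <- list(target = tumour$extra$tumour_centre,
                   radius = tumour$extra$tumour_radius)
  tc <- as.numeric(tumour$target); r <- tumour$radius
  hc <- p$hemi_center; hs <- p$hemi_semi
  with_seed(seed, {
    push_off <- 3                         # medial offset of the push centre
    cpush <- tc - c(push_off, 0, 0)
    rpush <- r + p$cst_margin + push_off
    bs_lo <- p$brainstem_lo; bs_hi <- p$brainstem_hi
    bs_c <- (bs_lo + bs_hi) / 2
    if (sqrt(sum((bs_c - cpush)^2)) <= rpush)
      stopf("infeasible geometry: tumour blocks the brainstem region")
    t <- seq(0, 1, length.out = p$cst_points)
    sl <- vector("list", p$n_cst)
    for (i in seq_len(p$n_cst)) {
      ## seed point in the M1 band, just under the cortical surface
      repeat {
        s <- c(runif(1, 14, 44),
               runif(1, p$m1_y[1] + 2, p$m1_y[2] - 2),
               0)
        zz <- 1 - ((s[1] - hc[1]) / hs[1])^2 - ((s[2] - hc[2]) / hs[2])^2
        if (zz <= 0) next
        s[3] <- hc[3] + 0.94 * hs[3] * sqrt(zz)
        if (s[3] >= p$m1_zmin + 4) break
      }
      e <- bs_lo + runif(3) * (bs_hi - bs_lo)
      if (sqrt(sum((s - cpush)^2)) <= rpush)
        stopf("infeasible geometry: tumour engulfs the M1 seed region")
      ## cubic Bezier through a corona-radiata waypoint above the
      ## tumour and a capsular waypoint: the bundle is adjacent to the
      ## lesion by construction (that is what makes it motor-eloquent)
      jit <- rnorm(3, sd = p$cst_spread / 3)
      c1 <- c(0.5 * s[1] + 0.5 * tc[1], 0.5 * s[2] + 0.5 * tc[2],
              tc[3] + r + 10) + jit
      c2 <- c(18, 0.6 * (-25) + 0.4 * tc[2], -8) + rnorm(3, sd = 2)
      B <- outer((1 - t)^3, s) + outer(3 * (1 - t)^2 * t, c1) +
        outer(3 * (1 - t) * t^2, c2) + outer(t^3, e)
      if (deflect) {
        dv <- sweep(B, 2L, cpush)
        dn <- sqrt(rowSums(dv^2))
        inside <- dn < rpush
        if (any(inside)) {
          dirs <- dv[inside, , drop = FALSE] / pmax(dn[inside], 1e-9)
          ## lateral bias: a space-occupying central-core lesion pushes
          ## the bundle away from the midline, never through itself
          dirs[, 1] <- pmax(dirs[, 1], 0.25)
          dirs <- dirs / sqrt(rowSums(dirs^2))
          B[inside, ] <- matrix(rep(cpush, each = sum(inside)),
                                ncol = 3L) + dirs * rpush
        }
      }
      sl[[i]] <- B
    }
    streamline_bundle(sl, label = "CST")
  })
}
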