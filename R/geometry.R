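## Exact 3D distance/intersection primitives between a straight needle
## trajectory (segment) and masks, polylines and the midsagittal plane.

#' Create a trajectory segment
#' @param a Entry point (world mm).
#' @param b Target point (world mm).
#' @return Object of class `segment`.
#' @export
segment <- function(a, b) {
  a <- as_point3(a, "entry"); b <- as_point3(b, "target")
  if (sum((a - b)^2) == 0) stopf("degenerate segment: entry equals target")
  structure(list(a = a, b = b), class = "segment")
}

#' Trajectory length (entry to target), mm
#' @param seg `segment`.
#' @return Euclidean length in mm.
#' @export
segment_length <- function(seg) {
  stopifnot(inherits(seg, "segment"))
  sqrt(sum((seg$a - seg$b)^2))
}

## Minimum distances from segment (a,b) to each point in an n x 3
## matrix. Vectorized point-to-segment distance.
dist_points_to_segment <- function(pts, a, b) {
  d <- b - a
  L2 <- sum(d^2)
  ap <- sweep(pts, 2L, a)
  t <- pmin(pmax((ap %*% d) / L2, 0), 1)
  diff <- ap - outer(as.numeric(t), d)
  sqrt(rowSums(diff^2))
}

## Minimum distance from segment (a,b) to each of n edges (P[i,], Q[i,]).
## Vectorized closest-point-between-segments (Ericson, Real-Time
## Collision Detection, 5.1.9): exact clamped quadratic minimization.
dist_segment_to_edges <- function(a, b, P, Q) {
  n <- nrow(P)
  u <- b - a
  v <- Q - P
  r <- matrix(rep(a, each = n), n) - P
  A <- sum(u * u)
  E <- rowSums(v * v)
  Fv <- rowSums(v * r)
  C <- as.numeric(r %*% u)
  B <- as.numeric(v %*% u)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  denom <- A * E - B * B
  s <- ifelse(denom > 1e-300, clamp01((B * Fv - C * E) / denom), 0)
  t <- ifelse(E > 1e-300, (B * s + Fv) / E, 0)
  tlo <- t < 0; thi <- t > 1
  t <- clamp01(t)
  s <- ifelse(tlo, clamp01(-C / A),
         ifelse(thi, clamp01((B - C) / A), s))
  p1 <- matrix(rep(a, each = n), n) + s * matrix(rep(u, each = n), n)
  p2 <- P + t * v
  sqrt(pmax(rowSums((p1 - p2)^2), 0))
}

#' Minimum distance from a trajectory to a streamline bundle
#'
#' Treats every polyline edge as a straight segment (TRK/TCK
#' semantics; no spline interpolation) and returns the minimum over
#' all streamlines; 0 when the trajectory intersects a streamline.
#'
#' @param seg `segment`.
#' @param bundle `streamline_bundle`.
#' @return Distance in mm.
#' @export
min_distance_to_streamlines <- function(seg, bundle) {
  stopifnot(inherits(seg, "segment"))
  if (!inherits(bundle, "streamline_bundle") ||
      length(bundle$streamlines) == 0L)
    stopf("empty or invalid streamline bundle")
  PQ <- bundle_edges(bundle)
  min(dist_segment_to_edges(seg$a, seg$b, PQ$P, PQ$Q))
}

## stack all polyline edges of a bundle into start/end matrices (cached
## on the bundle object by the generator where it helps)
bundle_edges <- function(bundle) {
  if (!is.null(bundle$edges)) return(bundle$edges)
  P <- do.call(rbind, lapply(bundle$streamlines,
                             function(s) s[-nrow(s), , drop = FALSE]))
  Q <- do.call(rbind, lapply(bundle$streamlines,
                             function(s) s[-1L, , drop = FALSE]))
  list(P = P, Q = Q)
}

#' Minimum distance from a trajectory to a mask
#'
#' Distance to the nearest nonzero voxel centre; 0 when the segment
#' passes through a nonzero voxel (crosses its axis-aligned box).
#'
#' @param seg `segment`.
#' @param mask `volumetric_mask`.
#' @return Distance in mm.
#' @export
min_distance_to_mask <- function(seg, mask) {
  stopifnot(inherits(seg, "segment"), inherits(mask, "volumetric_mask"))
  pts <- mask_points_cached(mask)
  if (nrow(pts) == 0L) stopf("mask '%s' is empty", mask$label)
  if (transgresses_mask(seg, mask)) return(0)
  min(dist_points_to_segment(pts, seg$a, seg$b))
}

## memoise nonzero voxel centres inside the mask object environment-free
## way: recompute lazily and attach via attribute on first use
mask_points_cached <- function(mask) {
  cache <- attr(mask, "world_points")
  if (!is.null(cache)) return(cache)
  mask_points(mask)
}

#' Attach precomputed voxel-centre coordinates to a mask
#'
#' Optional speed-up for repeated distance queries against one mask.
#' @param mask `volumetric_mask`.
#' @return The mask with cached world points.
#' @export
precompute_mask_points <- function(mask) {
  attr(mask, "world_points") <- mask_points(mask)
  mask
}

#' Does a trajectory transgress a mask?
#'
#' Exact segment vs axis-aligned voxel-box intersection via 3D DDA
#' traversal in voxel space (no sampling artefacts). A voxel's box is
#' the unit cube centred on its index.
#'
#' @param seg `segment`.
#' @param mask `volumetric_mask`.
#' @return TRUE iff the segment intersects at least one nonzero voxel.
#' @export
transgresses_mask <- function(seg, mask) {
  stopifnot(inherits(seg, "segment"), inherits(mask, "volumetric_mask"))
  g <- mask$grid
  dims <- dim(g)
  uv <- world_to_voxel(rbind(seg$a, seg$b), mask$affine)
  p0 <- uv[1, ]; p1 <- uv[2, ]
  ## clip the segment to the grid's bounding box [-0.5, dim-0.5]
  lo <- rep(-0.5, 3); hi <- dims - 0.5
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (k in 1:3) {
    if (abs(d[k]) < 1e-300) {
      if (p0[k] < lo[k] || p0[k] > hi[k]) return(FALSE)
    } else {
      ta <- (lo[k] - p0[k]) / d[k]; tb <- (hi[k] - p0[k]) / d[k]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(FALSE)
    }
  }
  p <- p0 + t0 * d
  pend <- p0 + t1 * d
  ijk <- pmin(pmax(round(p), 0), dims - 1L)
  ijk_end <- pmin(pmax(round(pend), 0), dims - 1L)
  if (g[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L] != 0L) return(TRUE)
  step <- sign(d); step[step == 0] <- 1
  ## parametric distance to the next voxel-boundary plane per axis
  tmax <- numeric(3); tdelta <- numeric(3)
  for (k in 1:3) {
    if (abs(d[k]) < 1e-300) {
      tmax[k] <- Inf; tdelta[k] <- Inf
    } else {
      bound <- ijk[k] + step[k] * 0.5
      tmax[k] <- (bound - p0[k]) / d[k]
      tdelta[k] <- abs(1 / d[k])
    }
  }
  repeat {
    if (all(ijk == ijk_end)) return(FALSE)
    k <- which.min(tmax)
    if (tmax[k] > t1 + 1e-12) return(FALSE)
    ijk[k] <- ijk[k] + step[k]
    if (ijk[k] < 0 || ijk[k] > dims[k] - 1L) return(FALSE)
    tmax[k] <- tmax[k] + tdelta[k]
    if (g[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L] != 0L) return(TRUE)
  }
}

#' Minimum distance from a trajectory to the midsagittal plane
#'
#' Minimum unsigned perpendicular distance over the whole segment
#' (not the entry point only); 0 when the segment crosses the plane.
#'
#' @param seg `segment`.
#' @param plane `midline_plane`.
#' @return Distance in mm.
#' @export
distance_to_midline <- function(seg, plane) {
  stopifnot(inherits(seg, "segment"), inherits(plane, "midline_plane"))
  da <- sum((seg$a - plane$mcp) * plane$normal)
  db <- sum((seg$b - plane$mcp) * plane$normal)
  if (da == 0 || db == 0 || sign(da) != sign(db)) return(0)
  min(abs(da), abs(db))
}
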