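## Domain types for anatomical scenes and planned trajectories.
## All geometry lives in one world frame: millimetres, RAS axes
## (x: left->right, y: posterior->anterior, z: inferior->superior).
## Voxel indices are 0-based; a voxel's world position is its centre.

#' Create a 3D world point
#'
#' Points are plain named numeric vectors of length 3 in world
#' millimetres (RAS convention).
#'
#' @param x,y,z Finite world coordinates in mm.
#' @return Named numeric vector `c(x=, y=, z=)`.
#' @export
point3 <- function(x, y, z) {
  p <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(p))) stopf("point3: coordinates must be finite")
  p
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p)))
    stopf("%s must be 3 finite coordinates", what)
  names(p) <- c("x", "y", "z")
  p
}

#' Create a volumetric binary mask
#'
#' @param grid 3D array (coerced to 0/1 integer).
#' @param affine 4x4 invertible voxel-to-world transform (mm). Voxel
#'   indices are 0-based and map to voxel centres.
#' @param label Structure label, one of `"sulcus"`, `"eloquent_cortex"`,
#'   `"ventricle"`, `"tumour"`, `"vessel"`.
#' @return Object of class `volumetric_mask`.
#' @export
volumetric_mask <- function(grid, affine, label) {
  label <- match.arg(label,
    c("sulcus", "eloquent_cortex", "ventricle", "tumour", "vessel"))
  if (length(dim(grid)) != 3L) stopf("mask grid must be a 3D array")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stopf("affine must be a 4x4 matrix")
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < 1e-12)
    stopf("affine must be invertible")
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vox <= 0)) stopf("voxel sizes must be positive")
  storage.mode(grid) <- "integer"
  grid[grid != 0L] <- 1L
  structure(list(grid = grid, affine = affine, label = label),
            class = "volumetric_mask")
}

## world coordinates (n x 3) of all nonzero voxel centres
mask_points <- function(mask) {
  idx <- which(mask$grid != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0L, 3L))
  voxel_to_world(idx - 1, mask$affine)
}

#' Map 0-based voxel indices to world mm
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @param affine 4x4 voxel-to-world transform.
#' @return n x 3 matrix of world coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}

#' Map world mm to 0-based (fractional) voxel indices
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix of world coordinates.
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4])
}

#' Create a streamline bundle
#'
#' @param streamlines List of n x 3 numeric matrices (world mm), each
#'   with at least 2 points.
#' @param label `"CST"` or `"vessel"`.
#' @return Object of class `streamline_bundle`.
#' @export
streamline_bundle <- function(streamlines, label = c("CST", "vessel")) {
  label <- match.arg(label)
  if (!is.list(streamlines) || length(streamlines) == 0L)
    stopf("bundle must contain at least one streamline")
  streamlines <- lapply(seq_along(streamlines), function(i) {
    s <- streamlines[[i]]
    s <- matrix(as.numeric(s), ncol = 3L)
    if (nrow(s) < 2L)
      stopf("streamline %d has fewer than 2 points", i)
    if (!all(is.finite(s))) stopf("streamline %d has non-finite points", i)
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines, label = label),
            class = "streamline_bundle")
}

#' Midsagittal plane from AC and PC landmarks
#'
#' The midline plane contains the AC-PC line; its normal is the
#' left-right axis. With both landmarks on the midsagittal plane the
#' plane passes through the middle commissural point.
#'
#' @param ac,pc Anterior / posterior commissure world points (mm).
#' @param normal Optional plane normal; defaults to the +x (left-right)
#'   axis. Normalized internally.
#' @return Object of class `midline_plane` with fields `ac`, `pc`,
#'   `mcp` and unit `normal`.
#' @export
midline_plane <- function(ac, pc, normal = c(1, 0, 0)) {
  ac <- as_point3(ac, "ac"); pc <- as_point3(pc, "pc")
  if (sqrt(sum((ac - pc)^2)) < 1e-9) stopf("AC and PC must differ")
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stopf("degenerate plane normal")
  normal <- normal / nn
  if (abs(sum(normal * (pc - ac))) > 1e-6 * sqrt(sum((pc - ac)^2)))
    stopf("plane normal must be orthogonal to the AC-PC line")
  structure(list(ac = ac, pc = pc, mcp = (ac + pc) / 2, normal = normal),
            class = "midline_plane")
}

#' Assemble an anatomical scene
#'
#' All structures of one patient in a single world frame. The CST
#' bundle may be flagged hidden from the planner (anatomy-only
#' presentation); safety scoring always uses the full scene.
#'
#' @param tumour_id Identifier.
#' @param tumour_mask,sulci,eloquent_cortex,ventricles `volumetric_mask`
#'   objects.
#' @param target Biopsy target (world mm); must lie inside the tumour
#'   mask.
#' @param cst `streamline_bundle` with label CST, or NULL when the
#'   scene has no tractography.
#' @param vessels `streamline_bundle` (label vessel) and/or a
#'   `volumetric_mask`; a list with elements `bundle`/`mask`.
#' @param midline `midline_plane`.
#' @param cortical_surface n x 3 matrix of surface points (world mm).
#' @param cst_visible Logical; FALSE models the anatomy-only (A-nBx)
#'   presentation in which the planner does not see the CST.
#' @param extra Optional named list of generator annotations (e.g.
#'   region boxes used when the scene was synthesized).
#' @return Object of class `anatomical_scene`.
#' @export
anatomical_scene <- function(tumour_id, tumour_mask, target, cst = NULL,
                             vessels, sulci, eloquent_cortex, ventricles,
                             midline, cortical_surface,
                             cst_visible = TRUE, extra = list()) {
  target <- as_point3(target, "target")
  for (nm in c("tumour_mask", "sulci", "eloquent_cortex", "ventricles")) {
    m <- get(nm)
    if (!inherits(m, "volumetric_mask"))
      stopf("%s must be a volumetric_mask", nm)
  }
  if (!is.null(cst)) {
    if (!inherits(cst, "streamline_bundle") || cst$label != "CST")
      stopf("cst must be a streamline_bundle with label CST")
  }
  if (inherits(vessels, "streamline_bundle")) vessels <- list(bundle = vessels)
  if (inherits(vessels, "volumetric_mask")) vessels <- list(mask = vessels)
  if (is.null(vessels$bundle) && is.null(vessels$mask))
    stopf("vessels must provide a bundle and/or a mask")
  if (!inherits(midline, "midline_plane"))
    stopf("midline must be a midline_plane")
  cortical_surface <- matrix(as.numeric(cortical_surface), ncol = 3L)
  if (!point_in_mask(target, tumour_mask))
    stopf("target must lie inside the tumour mask")
  structure(list(
    tumour_id = tumour_id, tumour_mask = tumour_mask, target = target,
    cst = cst, vessels = vessels, sulci = sulci,
    eloquent_cortex = eloquent_cortex, ventricles = ventricles,
    midline = midline, cortical_surface = cortical_surface,
    cst_visible = isTRUE(cst_visible), extra = extra),
    class = "anatomical_scene")
}

## TRUE iff the world point falls in a nonzero voxel of the mask
point_in_mask <- function(p, mask) {
  ijk <- round(world_to_voxel(matrix(p, 1L), mask$affine))
  d <- dim(mask$grid)
  if (any(ijk < 0) || any(ijk > d - 1L)) return(FALSE)
  mask$grid[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L] != 0L
}

#' @export
print.anatomical_scene <- function(x, ...) {
  cat(sprintf("<anatomical_scene> tumour %s\n", x$tumour_id))
  cat(sprintf("  target: (%.1f, %.1f, %.1f) mm; CST: %s (%s)\n",
              x$target[1], x$target[2], x$target[3],
              if (is.null(x$cst)) "absent"
              else sprintf("%d streamlines", length(x$cst$streamlines)),
              if (x$cst_visible) "visible to planner" else "hidden from planner"))
  invisible(x)
}
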