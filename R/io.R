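## Readers/writers for the standard on-disk formats a scene lives in:
## NIfTI masks, MRtrix .tck streamlines, a JSON manifest, CSV cohorts.

#' Write a volumetric mask as NIfTI
#' @param mask `volumetric_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  img <- RNifti::asNifti(mask$grid)
  xf <- structure(mask$affine, code = 2L)
  img <- RNifti::`sform<-`(img, xf)
  img <- RNifti::`qform<-`(img, xf)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI binary mask
#' @param path NIfTI file.
#' @param label Structure label for the mask.
#' @return `volumetric_mask`.
#' @export
read_mask_nifti <- function(path, label) {
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  volumetric_mask(array(as.integer(img != 0), dim = dim(img)), aff, label)
}

## --- MRtrix .tck streamline format -----------------------------------
## Text header terminated by "END\n", then little-endian float triples;
## streamlines separated by NaN triples, file terminated by Inf triple.
## Coordinates are world mm. Float64LE is written by default so that
## coordinates round-trip exactly; Float32LE is read and written for
## interoperability with other tools.

#' Write a streamline bundle to a .tck file
#' @param bundle `streamline_bundle`.
#' @param path Output path.
#' @param datatype `"Float64LE"` (default; lossless) or `"Float32LE"`.
#' @return `path`, invisibly.
#' @export
write_tck <- function(bundle, path, datatype = c("Float64LE", "Float32LE")) {
  datatype <- match.arg(datatype)
  size <- if (datatype == "Float64LE") 8L else 4L
  header <- paste0(
    "mrtrix tracks\n",
    "datatype: ", datatype, "\n",
    "count: ", length(bundle$streamlines), "\n",
    "trajsafe_label: ", bundle$label, "\n")
  ## the data offset appears inside the header, so iterate to the fixed
  ## point where the stated offset equals the header's byte length
  off <- 0L
  repeat {
    hdr <- paste0(header, sprintf("file: . %d\n", off), "END\n")
    n <- nchar(hdr, type = "bytes")
    if (n == off) break
    off <- n
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in bundle$streamlines) {
    writeBin(as.numeric(t(s)), con, size = size, endian = "little")
    writeBin(rep(NaN, 3), con, size = size, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = size, endian = "little")
  invisible(path)
}

#' Read a .tck streamline file
#' @param path `.tck` file.
#' @param label Bundle label (`"CST"` or `"vessel"`); defaults to the
#'   label stored by [write_tck()] when present.
#' @return `streamline_bundle`.
#' @export
read_tck <- function(path, label = NULL) {
  if (!file.exists(path)) stopf("tck file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks")) stopf("%s is not a tck file", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stopf("truncated tck header in %s", path)
    if (identical(ln, "END")) break
    kv <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1]]
    if (length(kv) == 3L) fields[[kv[2]]] <- kv[3]
  }
  datatype <- fields[["datatype"]]
  if (is.null(datatype) || !datatype %in% c("Float64LE", "Float32LE"))
    stopf("unsupported tck datatype: %s", datatype %||% "<missing>")
  size <- if (datatype == "Float64LE") 8L else 4L
  offset <- as.integer(sub("^\\. *", "", fields[["file"]]))
  seek(con, where = offset, origin = "start")
  nbytes <- file.size(path) - offset
  vals <- readBin(con, "numeric", n = nbytes %/% size, size = size,
                  endian = "little")
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  delim <- which(!is.finite(m[, 1]))  # NaN separators + final Inf
  starts <- c(1L, head(delim, -1L) + 1L)
  keep <- delim - starts >= 2L  # at least 2 points
  sl <- Map(function(a, b) m[a:(b - 1L), , drop = FALSE],
            starts[keep], delim[keep])
  if (is.null(label)) label <- fields[["trajsafe_label"]] %||% "CST"
  streamline_bundle(sl, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- Scene directory (manifest + NIfTI + tck + CSV surface) ----------

#' Save a scene to a directory
#'
#' Writes each mask as NIfTI, each streamline bundle as `.tck`, the
#' cortical surface as CSV, and a `manifest.json` naming every file
#' plus the AC/PC landmarks, target and tumour id.
#'
#' @param scene `anatomical_scene`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_scene <- function(scene, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  man <- list(tumour_id = scene$tumour_id,
              target = unname(scene$target),
              ac = unname(scene$midline$ac),
              pc = unname(scene$midline$pc),
              cst_visible = scene$cst_visible,
              structures = list(), streamlines = list())
  masks <- list(tumour = scene$tumour_mask, sulci = scene$sulci,
                eloquent_cortex = scene$eloquent_cortex,
                ventricles = scene$ventricles)
  if (!is.null(scene$vessels$mask)) masks$vessel_mask <- scene$vessels$mask
  for (nm in names(masks)) {
    f <- paste0(nm, ".nii.gz")
    write_mask_nifti(masks[[nm]], file.path(path, f))
    man$structures[[nm]] <- f
  }
  if (!is.null(scene$cst)) {
    write_tck(scene$cst, file.path(path, "cst.tck"))
    man$streamlines$cst <- "cst.tck"
  }
  if (!is.null(scene$vessels$bundle)) {
    write_tck(scene$vessels$bundle, file.path(path, "vessels.tck"))
    man$streamlines$vessels <- "vessels.tck"
  }
  surf <- as.data.frame(scene$cortical_surface)
  names(surf) <- c("x", "y", "z")
  if (!is.null(scene$extra$surface_lobe)) surf$lobe <- scene$extra$surface_lobe
  write.csv(surf, file.path(path, "cortical_surface.csv"), row.names = FALSE)
  man$surface <- "cortical_surface.csv"
  if (length(scene$extra)) {
    keep <- setdiff(names(scene$extra), "surface_lobe")
    if (length(keep)) man$extra <- scene$extra[keep]
  }
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a scene from a directory written by [save_scene()]
#' @param path Scene directory containing `manifest.json`.
#' @return `anatomical_scene`.
#' @export
load_scene <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stopf("no manifest.json in %s", path)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  need <- c("tumour", "sulci", "eloquent_cortex", "ventricles")
  for (nm in need) {
    if (is.null(man$structures[[nm]]))
      stopf("manifest in %s lacks required structure '%s'", path, nm)
  }
  rd <- function(nm, label) {
    f <- file.path(path, man$structures[[nm]])
    if (!file.exists(f)) stopf("missing %s mask file: %s", nm, f)
    read_mask_nifti(f, label)
  }
  vessels <- list()
  if (!is.null(man$streamlines$vessels))
    vessels$bundle <- read_tck(file.path(path, man$streamlines$vessels),
                               label = "vessel")
  if (!is.null(man$structures$vessel_mask))
    vessels$mask <- rd("vessel_mask", "vessel")
  if (length(vessels) == 0L) stopf("manifest in %s names no vessels", path)
  cst <- NULL
  if (!is.null(man$streamlines$cst))
    cst <- read_tck(file.path(path, man$streamlines$cst), label = "CST")
  surf <- read.csv(file.path(path, man$surface))
  extra <- if (!is.null(man$extra)) man$extra else list()
  if (!is.null(surf$lobe)) extra$surface_lobe <- surf$lobe
  anatomical_scene(
    tumour_id = man$tumour_id,
    tumour_mask = rd("tumour", "tumour"),
    target = man$target, cst = cst, vessels = vessels,
    sulci = rd("sulci", "sulcus"),
    eloquent_cortex = rd("eloquent_cortex", "eloquent_cortex"),
    ventricles = rd("ventricles", "ventricle"),
    midline = midline_plane(man$ac, man$pc),
    cortical_surface = as.matrix(surf[, c("x", "y", "z")]),
    cst_visible = isTRUE(man$cst_visible), extra = extra)
}

## --- Cohort table ----------------------------------------------------

cohort_columns <- c("trainee_id", "tumour_id", "group", "entry_x", "entry_y",
                    "entry_z", "target_x", "target_y", "target_z",
                    "planning_time_s", "n_trajectory_changes",
                    "n_lobe_changes", "exercise_order", "experience_years")

#' Validate a cohort table
#'
#' One row per planned trajectory. Checks the row-wise invariants
#' (positive time, non-negative counts, lobe changes not exceeding
#' trajectory changes, exercise order in 1..10, entry distinct from
#' target, no duplicate trainee/tumour pair) and reports offending rows
#' by line number.
#'
#' @param df data.frame with the cohort columns.
#' @return The validated data.frame (invisibly classed `cohort_table`).
#' @export
validate_cohort <- function(df) {
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols))
    stopf("cohort table lacks columns: %s", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    class(df) <- c("cohort_table", class(df))
    return(df)
  }
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      sprintf("%s (rows %s)", what,
              paste(head(rows, 10L), collapse = ", "))
    else NULL
  }
  ent <- as.matrix(df[, c("entry_x", "entry_y", "entry_z")])
  tar <- as.matrix(df[, c("target_x", "target_y", "target_z")])
  problems <- c(
    bad(!is.finite(df$planning_time_s) | df$planning_time_s <= 0,
        "planning_time_s must be > 0"),
    bad(df$n_trajectory_changes < 0 | df$n_trajectory_changes != round(df$n_trajectory_changes),
        "n_trajectory_changes must be a count >= 0"),
    bad(df$n_lobe_changes < 0 | df$n_lobe_changes != round(df$n_lobe_changes),
        "n_lobe_changes must be a count >= 0"),
    bad(df$n_lobe_changes > df$n_trajectory_changes,
        "n_lobe_changes must not exceed n_trajectory_changes"),
    bad(!(df$exercise_order %in% 1:10), "exercise_order must be in 1..10"),
    bad(df$experience_years < 0, "experience_years must be >= 0"),
    bad(!df$group %in% c("T-nBx", "A-nBx"), "group must be T-nBx or A-nBx"),
    bad(rowSums((ent - tar)^2) == 0, "entry must differ from target"),
    bad(duplicated(df[, c("trainee_id", "tumour_id")]),
        "duplicate (trainee_id, tumour_id) pair"))
  if (length(problems))
    stopf("invalid cohort table:\n  %s", paste(problems, collapse = "\n  "))
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Read a cohort CSV
#' @param path CSV with the documented cohort columns (header required).
#' @return Validated `cohort_table` data.frame.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Write a cohort CSV
#' @param cohort cohort data.frame.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort[, union(cohort_columns, names(cohort))], path,
            row.names = FALSE)
  invisible(path)
}
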