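#' 3D image volume in Hounsfield units
#'
#' The common currency of every stage: a 3D array of HU values indexed
#' `(z, y, x)` (slice, row, column) together with physical voxel spacing and
#' origin in millimetres, ordered the same way.
#'
#' @param voxels 3D numeric array, axis order (z, y, x)
#' @param spacing numeric length-3, voxel size in mm as (sz, sy, sx), all > 0
#' @param origin numeric length-3, position of voxel (0,0,0) in mm
#' @return an object of class `image_volume`
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    stop("voxels must be a 3D array with positive dimensions")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers")
  if (any(!is.finite(voxels))) stop("voxel values must be finite")
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = as.double(spacing),
                 origin = as.double(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d (z,y,x), spacing %s mm, HU [%.0f, %.0f]\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Default organ label table
#'
#' Positive integer codes for the body outline and the five organs at risk
#' evaluated throughout: bladder, spinal cord, left/right femoral heads and
#' bone marrow (pelvis).
#' @return named integer vector
#' @export
default_organ_table <- function() {
  c(body = 1L, bladder = 2L, spinal_cord = 3L,
    femoral_head_l = 4L, femoral_head_r = 5L, bone_marrow = 6L)
}

#' Integer organ label map on an image grid
#'
#' @param labels 3D integer array, same shape as its reference volume;
#'   0 is background, positive values must appear in `organ_table`
#' @param spacing voxel spacing (sz, sy, sx) in mm
#' @param organ_table named integer vector mapping organ name to label value
#' @param origin position of voxel (0,0,0) in mm
#' @return an object of class `label_map`
#' @export
label_map <- function(labels, spacing = c(1, 1, 1),
                      organ_table = default_organ_table(),
                      origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative integers")
  vals <- sort(unique(as.integer(labels)))
  vals <- setdiff(vals, 0L)
  if (length(setdiff(vals, as.integer(organ_table))) > 0)
    stop("label values present that are not in organ_table")
  structure(list(labels = labels, spacing = as.double(spacing),
                 origin = as.double(origin),
                 organ_table = organ_table),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d x %d, organs: %s\n", d[1], d[2], d[3],
              paste(names(x$organ_table), collapse = ", ")))
  invisible(x)
}

#' Extract a binary organ mask from a label map
#'
#' @param lm a [label_map]
#' @param organ organ name, must be present in `lm$organ_table`
#' @return logical 3D array, TRUE exactly where the label equals the organ code
#' @export
extract_mask <- function(lm, organ) {
  stopifnot(inherits(lm, "label_map"))
  if (!organ %in% names(lm$organ_table))
    stop(sprintf("unknown organ '%s'; known: %s", organ,
                 paste(names(lm$organ_table), collapse = ", ")))
  lm$labels == lm$organ_table[[organ]]
}

# ---- NIfTI persistence -------------------------------------------------

# NIfTI stores arrays (x,y,z) fastest-first; in memory we use (z,y,x).
#' Read a 3D NIfTI volume
#'
#' Axis order is normalized to the package convention (z, y, x); spacing is
#' taken from the header pixdim and reordered accordingly, so a file with
#' pixdim (1, 1, 5) yields spacing (5, 1, 1).
#'
#' @param path path to a `.nii` / `.nii.gz` file
#' @param labels if TRUE, return a [label_map] (values coerced to integer)
#' @param organ_table organ table to attach when `labels = TRUE`
#' @return an [image_volume] or [label_map]
#' @export
read_volume <- function(path, labels = FALSE, organ_table = default_organ_table()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("expected a 3D NIfTI image, got %dD", length(dim(img))))
  pix <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  arr <- aperm(as.array(img), c(3, 2, 1))
  spacing <- rev(pix[1:3])
  org <- tryCatch(rev(RNifti::origin(img))[1:3] * 0, error = function(e) c(0, 0, 0))
  if (labels) label_map(round(arr), spacing = spacing, organ_table = organ_table,
                        origin = org)
  else image_volume(arr, spacing = spacing, origin = org)
}

#' Write a volume or label map as NIfTI-1
#'
#' Lossless for values representable in 32-bit float (all integer-valued HU
#' grids); spacing is encoded in the header pixdim.
#'
#' @param vol an [image_volume] or [label_map]
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)))
  if (inherits(vol, "label_map")) {
    arr <- aperm(vol$labels, c(3, 2, 1))
    dt <- "int16"
    spacing <- vol$spacing
  } else {
    stopifnot(inherits(vol, "image_volume"))
    arr <- aperm(vol$voxels, c(3, 2, 1))
    dt <- "float"
    spacing <- vol$spacing
  }
  attr(arr, "pixdim") <- rev(spacing)
  tryCatch(RNifti::writeNifti(arr, path, datatype = dt),
           error = function(e) stop(sprintf("cannot write '%s': %s",
                                            path, conditionMessage(e))))
  invisible(path)
}

#' Write a displacement field as a 4D NIfTI
#'
#' @param field array (nz, ny, nx, 3), components (dz, dy, dx) in voxels
#' @param path output path
#' @param spacing voxel spacing of the underlying grid
#' @export
write_field <- function(field, path, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(field)) == 4L, dim(field)[4] == 3L)
  arr <- aperm(field, c(3, 2, 1, 4))
  attr(arr, "pixdim") <- c(rev(spacing), 1)
  RNifti::writeNifti(arr, path, datatype = "float")
  invisible(path)
}

# ---- run configuration -------------------------------------------------

#' Run configuration
#'
#' Bundle of seed, scale preset and output directory shared by the pipeline
#' entry points. The `desk` preset is sized for a single CPU; `paper` mirrors
#' the clinical grid (48 x 288 x 400 at 5 x 1 x 1 mm).
#'
#' @param seed non-negative integer master seed
#' @param scale_preset `"desk"` or `"paper"`
#' @param out_dir output directory
#' @param modules optional named list of per-module sub-configurations
#' @return object of class `run_config`
#' @export
run_config <- function(seed = 1L, scale_preset = c("desk", "paper"),
                       out_dir = ".", modules = list()) {
  scale_preset <- match.arg(scale_preset)
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0) stop("seed must be a non-negative integer")
  structure(list(seed = seed, scale_preset = scale_preset,
                 out_dir = out_dir, modules = modules),
            class = "run_config")
}

#' Read/write a run configuration as YAML
#' @param path YAML file path
#' @return a [run_config]
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(seed = y$seed %||% 1L, scale_preset = y$scale_preset %||% "desk",
             out_dir = y$out_dir %||% ".", modules = y$modules %||% list())
}

#' @rdname read_run_config
#' @param cfg a [run_config]
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
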