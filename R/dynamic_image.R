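#' 4D dynamic image
#'
#' A 4D voxel array (x, y, z, frame) of decay-corrected activity
#' concentration bound to a [frame_schedule()]. Orientation/affine handling
#' is out of scope: images are treated as aligned arrays.
#'
#' @param voxels 4D numeric array; 4th axis length must equal the number of
#'   frames.
#' @param schedule A [frame_schedule()].
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, schedule, voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(dim(voxels)) != 4L)
    stop("'voxels' must be a 4D array (x, y, z, frame)")
  if (dim(voxels)[4L] != n_frames(schedule))
    stop("4th axis length (", dim(voxels)[4L], ") != number of frames (",
         n_frames(schedule), ")")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive mm values")
  structure(list(voxels = voxels, schedule = schedule,
                 voxel_size = voxel_size),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Dynamic image: %dx%dx%d voxels x %d frames, voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size), collapse = "x")))
  print(x$schedule)
  invisible(x)
}

#' Labelled VOI mask
#'
#' 3D integer label volume aligned to a [dynamic_image()] grid, a label-to-
#' region-name map, and the label of the reference tissue (cerebellar grey
#' matter in the default protocol). Label 0 is background and carries no name.
#'
#' @param labels 3D integer array.
#' @param names Named list/character vector mapping label (as character) to
#'   region name; must cover every non-zero label present.
#' @param reference_label Integer label of the reference region.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(labels, names, reference_label) {
  if (length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  storage.mode(labels) <- "integer"
  names <- as.list(names)
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  if ("0" %in% base::names(names))
    stop("label 0 is background and must not be named")
  missing <- setdiff(as.character(present), base::names(names))
  if (length(missing))
    stop("labels without a name entry: ", paste(missing, collapse = ", "))
  reference_label <- as.integer(reference_label)
  if (!as.character(reference_label) %in% base::names(names))
    stop("reference_label ", reference_label, " has no name entry")
  structure(list(labels = labels, names = names,
                 reference_label = reference_label),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("VOI mask: %dx%dx%d, %d labelled regions, reference '%s' (label %d)\n",
              d[1], d[2], d[3], length(x$names),
              x$names[[as.character(x$reference_label)]], x$reference_label))
  invisible(x)
}

#' Target (non-reference) labels of a mask, in label order
#' @param mask A [voi_mask()].
#' @export
target_labels <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  labs <- sort(as.integer(names(mask$names)))
  setdiff(labs, mask$reference_label)
}

.sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, "_frames.tsv")
}

#' Read / write dynamic images as NIfTI + timing sidecar
#'
#' Volumes are stored as 32-bit float NIfTI; frame timing travels in a TSV
#' sidecar (`<image>_frames.tsv`, columns `frame_start_s`,
#' `frame_duration_s`). A round trip reproduces values to 32-bit float
#' precision and the schedule exactly.
#'
#' @param path NIfTI path (`.nii` or `.nii.gz`).
#' @param timing Optional explicit sidecar path; defaults to
#'   `<image>_frames.tsv`.
#' @return `read_dynamic_image` returns a [dynamic_image()].
#' @export
read_dynamic_image <- function(path, timing = NULL) {
  if (!file.exists(path)) stop("image not found: ", path)
  if (is.null(timing)) timing <- .sidecar_path(path)
  if (!file.exists(timing))
    stop("missing frame timing sidecar: ", timing)
  schedule <- read_frame_schedule(timing)
  nii <- RNifti::readNifti(path)
  arr <- array(as.numeric(nii), dim = dim(nii))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (dim(arr)[4L] != n_frames(schedule))
    stop("frame-count mismatch: sidecar has ", n_frames(schedule),
         " frames but image has ", dim(arr)[4L], " volumes")
  vs <- RNifti::pixdim(nii)[1:3]
  if (any(!is.finite(vs)) || any(vs <= 0)) vs <- c(2, 2, 2)
  dynamic_image(arr, schedule, voxel_size = vs)
}

#' @rdname read_dynamic_image
#' @param img A [dynamic_image()].
#' @export
write_dynamic_image <- function(img, path, timing = NULL) {
  stopifnot(inherits(img, "dynamic_image"))
  if (is.null(timing)) timing <- .sidecar_path(path)
  nii <- RNifti::asNifti(img$voxels)
  RNifti::pixdim(nii) <- c(img$voxel_size, 1)
  RNifti::writeNifti(nii, path, datatype = "float")
  write_frame_schedule(img$schedule, timing)
  invisible(path)
}

#' Read / write a VOI mask as NIfTI + JSON label map
#'
#' The label map JSON holds `names` (label -> region name) and
#' `reference_label`.
#'
#' @param path NIfTI path of the integer label volume.
#' @param labels_path JSON path; defaults to `<mask>_labels.json`.
#' @export
read_mask <- function(path, labels_path = NULL) {
  if (is.null(labels_path))
    labels_path <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_labels.json")
  if (!file.exists(path)) stop("mask image not found: ", path)
  if (!file.exists(labels_path)) stop("label map not found: ", labels_path)
  nii <- RNifti::readNifti(path)
  arr <- array(as.integer(round(as.numeric(nii))), dim = dim(nii)[1:3])
  meta <- jsonlite::read_json(labels_path, simplifyVector = TRUE)
  voi_mask(arr, as.list(meta$names), meta$reference_label)
}

#' @rdname read_mask
#' @param mask A [voi_mask()].
#' @export
write_mask <- function(mask, path, labels_path = NULL) {
  stopifnot(inherits(mask, "voi_mask"))
  if (is.null(labels_path))
    labels_path <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_labels.json")
  RNifti::writeNifti(RNifti::asNifti(mask$labels), path, datatype = "int16")
  jsonlite::write_json(list(names = mask$names,
                            reference_label = mask$reference_label),
                       labels_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
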