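#' Time-activity curve
#'
#' Decay-corrected activity concentration (kBq/mL) per acquisition frame for
#' one region or voxel, bound to its [frame_schedule()].
#'
#' @param schedule A [frame_schedule()].
#' @param values Numeric vector, one finite value per frame.
#' @param label Free-text label (e.g. region name).
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, label = "") {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != n_frames(schedule))
    stop("length(values) (", length(values), ") != number of frames (",
         n_frames(schedule), ")")
  if (!all(is.finite(values)))
    stop("TAC values must be finite")
  structure(list(schedule = schedule, values = values,
                 label = as.character(label)[1L]),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC '%s': %d frames over %.1f min, range [%.3g, %.3g]\n",
              x$label, n_frames(x$schedule), total_duration(x$schedule) / 60,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.tac <- function(x, ..., xlab = "Time (min)",
                     ylab = "Activity (kBq/mL)", type = "b", pch = 16) {
  graphics::plot(.midpoints_min(x$schedule), x$values, xlab = xlab,
                 ylab = ylab, type = type, pch = pch,
                 main = if (nzchar(x$label)) x$label else "TAC", ...)
  invisible(x)
}

#' Extract a regional TAC from a dynamic image
#'
#' Per-frame unweighted mean over all voxels carrying the given label, e.g.
#' the cerebellar grey matter reference TAC.
#'
#' @param img A [dynamic_image()].
#' @param mask A [voi_mask()] on the same grid.
#' @param label Integer label to average over.
#' @return A [tac()] labelled with the region name.
#' @export
extract_tac <- function(img, mask, label) {
  stopifnot(inherits(img, "dynamic_image"), inherits(mask, "voi_mask"))
  if (!identical(dim(img$voxels)[1:3], dim(mask$labels)))
    stop("mask grid ", paste(dim(mask$labels), collapse = "x"),
         " does not match image grid ",
         paste(dim(img$voxels)[1:3], collapse = "x"))
  label <- as.integer(label)
  idx <- which(mask$labels == label)
  if (length(idx) == 0L)
    stop("label ", label, " absent from mask (or empty)")
  nf <- n_frames(img$schedule)
  mat <- matrix(img$voxels, ncol = nf)[idx, , drop = FALSE]
  nm <- mask$names[[as.character(label)]]
  tac(img$schedule, colMeans(mat), label = if (is.null(nm)) "" else nm)
}

#' Read / write a TAC as TSV
#'
#' Tab-separated with columns `frame_start_s`, `frame_duration_s`, `value`.
#'
#' @param path File path.
#' @param label Label to attach on read.
#' @export
read_tac <- function(path, label = "") {
  if (!file.exists(path)) stop("TAC file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("frame_start_s", "frame_duration_s", "value")
  if (!all(need %in% names(tab)))
    stop("TAC TSV must have columns: ", paste(need, collapse = ", "))
  tac(frame_schedule(tab$frame_start_s, tab$frame_duration_s),
      tab$value, label = label)
}

#' @rdname read_tac
#' @param x A [tac()].
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  tab <- as.data.frame(x$schedule)
  tab$value <- x$values
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
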