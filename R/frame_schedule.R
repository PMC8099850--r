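#' Acquisition frame schedule
#'
#' A frame schedule describes the temporal sampling grid of a dynamic PET
#' acquisition: the start time and duration of every consecutive frame, in
#' seconds from injection. Frames must be contiguous (each frame starts where
#' the previous one ends) and the first frame starts at 0 s.
#'
#' All kinetic computations in this package work at frame midpoints, in
#' minutes; schedules and files always store seconds. The conversion happens
#' exactly once, at model entry.
#'
#' @param starts Numeric vector of frame start times (s from injection).
#' @param durations Numeric vector of frame durations (s), same length.
#' @return An object of class `frame_schedule` with elements `starts` and
#'   `durations` (seconds).
#' @examples
#' sch <- frame_schedule(c(0, 15, 20), c(15, 5, 5))
#' midpoints(sch)
#' @seealso [parse_frame_scheme()] for the compact `"1x15,3x5,..."` notation.
#' @export
frame_schedule <- function(starts, durations) {
  starts <- as.numeric(starts)
  durations <- as.numeric(durations)
  if (length(starts) != length(durations) || length(starts) == 0)
    stop("'starts' and 'durations' must be non-empty vectors of equal length")
  if (anyNA(starts) || anyNA(durations) || !all(is.finite(c(starts, durations))))
    stop("frame times must be finite")
  if (any(durations <= 0))
    stop("all frame durations must be > 0")
  if (abs(starts[1L]) > 1e-9)
    stop("first frame must start at 0 s")
  if (length(starts) > 1L) {
    expected <- starts[-length(starts)] + durations[-length(durations)]
    if (max(abs(starts[-1L] - expected)) > 1e-6)
      stop("frames must be contiguous: starts[i+1] == starts[i] + durations[i]")
  }
  structure(list(starts = starts, durations = durations),
            class = "frame_schedule")
}

#' Parse a compact frame-timing scheme
#'
#' Expands a scheme string of comma-separated `count x duration` tokens (e.g.
#' the 23-frame 90-min protocol `"1x15,3x5,3x10,2x30,3x60,2x150,2x300,7x600"`)
#' into a contiguous [frame_schedule()] starting at 0 s.
#'
#' @param scheme Character scalar, comma-separated `NxS` tokens with integer
#'   count `N >= 1` and duration `S > 0` seconds.
#' @return A [frame_schedule()].
#' @examples
#' sch <- parse_frame_scheme("1x15,3x5,3x10,2x30,3x60,2x150,2x300,7x600")
#' n_frames(sch)        # 23
#' total_duration(sch)  # 5400 s = 90 min
#' @export
parse_frame_scheme <- function(scheme) {
  if (!is.character(scheme) || length(scheme) != 1L || !nzchar(scheme))
    stop("'scheme' must be a single non-empty string")
  tokens <- strsplit(gsub("[[:space:]]", "", scheme), ",", fixed = TRUE)[[1L]]
  durations <- numeric(0)
  for (tok in tokens) {
    parts <- strsplit(tok, "x", fixed = TRUE)[[1L]]
    bad <- function() stop("malformed frame-scheme token: '", tok, "'")
    if (length(parts) != 2L) bad()
    count <- suppressWarnings(as.numeric(parts[1L]))
    dur <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(count) || is.na(dur) || count < 1 || count != round(count) || dur <= 0)
      bad()
    durations <- c(durations, rep(dur, count))
  }
  starts <- c(0, cumsum(durations))[seq_along(durations)]
  frame_schedule(starts, durations)
}

#' Serialize a frame schedule back to scheme notation
#'
#' Run-length encodes consecutive equal durations; exact left inverse of
#' [parse_frame_scheme()].
#'
#' @param schedule A [frame_schedule()].
#' @return Character scalar in `"NxS,NxS,..."` form.
#' @export
format_frame_scheme <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  r <- rle(schedule$durations)
  paste(paste0(r$lengths, "x",
               vapply(r$values, format, "", scientific = FALSE)),
        collapse = ",")
}

#' @rdname frame_schedule
#' @param schedule A `frame_schedule`.
#' @export
midpoints <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$starts + schedule$durations / 2
}

#' @rdname frame_schedule
#' @export
n_frames <- function(schedule) length(schedule$starts)

#' @rdname frame_schedule
#' @export
total_duration <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$starts[n_frames(schedule)] + schedule$durations[n_frames(schedule)]
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.0f s total (%.1f min)\n",
              n_frames(x), total_duration(x), total_duration(x) / 60))
  cat("  scheme:", format_frame_scheme(x), "\n")
  invisible(x)
}

#' @export
as.data.frame.frame_schedule <- function(x, ...) {
  data.frame(frame_start_s = x$starts, frame_duration_s = x$durations)
}

# frame midpoints in minutes -- the single seconds->minutes boundary
.midpoints_min <- function(schedule) midpoints(schedule) / 60

#' Read / write frame timing as TSV
#'
#' Tab-separated sidecar with columns `frame_start_s`, `frame_duration_s`.
#'
#' @param path File path.
#' @return `read_frame_schedule` returns a [frame_schedule()];
#'   `write_frame_schedule` returns `path` invisibly.
#' @export
read_frame_schedule <- function(path) {
  if (!file.exists(path)) stop("frame timing file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("frame_start_s", "frame_duration_s")
  if (!all(need %in% names(tab)))
    stop("frame timing TSV must have columns: ", paste(need, collapse = ", "))
  frame_schedule(tab$frame_start_s, tab$frame_duration_s)
}

#' @rdname read_frame_schedule
#' @param schedule A [frame_schedule()].
#' @export
write_frame_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
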