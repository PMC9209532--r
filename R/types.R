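#' Functional MRI series container
#'
#' A 4D array of voxel intensities indexed `(x, y, slice, time)` together
#' with the acquisition geometry needed downstream: the repetition time (TR,
#' the temporal sampling interval) and the in-plane pixel size.
#'
#' @param data 4D numeric array `(x, y, slice, time)`. 3D input is promoted
#'   to a single slice only if explicitly 4-dimensional data cannot be given.
#' @param tr repetition time in seconds (> 0).
#' @param pixel_size in-plane pixel edge length in mm (> 0).
#' @param slice_thickness slice thickness in mm.
#' @return An object of class `functional_series`.
#' @export
functional_series <- function(data, tr, pixel_size = 1, slice_thickness = 1) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, slice, time)")
  if (dim(data)[4] < 1L) stop("time dimension must be >= 1")
  if (!all(is.finite(range(data)))) stop("intensities must be finite")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("`tr` must be a positive scalar")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  structure(
    list(data = data, tr = tr, pixel_size = pixel_size,
         slice_thickness = slice_thickness),
    class = "functional_series"
  )
}

#' @export
print.functional_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<functional_series> %d x %d x %d slices x %d volumes, TR = %g s, pixel %g mm\n",
    d[1], d[2], d[3], d[4], x$tr, x$pixel_size))
  invisible(x)
}

#' @export
dim.functional_series <- function(x) dim(x$data)

n_volumes <- function(series) dim(series$data)[4]

#' Static structural image container
#'
#' A stack of 2D structural slices (T2*-weighted contrast in this
#' application) at a stated in-plane resolution; the training data for the
#' subject-specific super-resolution model.
#'
#' @param data 3D numeric array `(x, y, slice)`; a matrix is promoted to one
#'   slice.
#' @param pixel_size in-plane pixel edge length in mm.
#' @param slice_thickness slice thickness in mm.
#' @return An object of class `structural_image`.
#' @export
structural_image <- function(data, pixel_size = 1, slice_thickness = 1) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (x, y, slice) or a matrix")
  if (length(data) == 0L) stop("structural image is empty")
  if (!all(is.finite(range(data)))) stop("intensities must be finite")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  structure(
    list(data = data, pixel_size = pixel_size,
         slice_thickness = slice_thickness),
    class = "structural_image"
  )
}

#' @export
print.structural_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<structural_image> %d x %d x %d slices, pixel %g mm\n",
              d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

#' Block-paradigm task design
#'
#' The on/off timing of one or more task conditions: a table of
#' `(task, onset, duration)` blocks in seconds, plus the TR and number of
#' volumes of the series the design describes. Blocks of the same task must
#' not overlap and must end within the series.
#'
#' @param blocks data.frame with columns `task` (character), `onset` and
#'   `duration` (seconds).
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes in the series.
#' @return An object of class `task_design`.
#' @export
task_design <- function(blocks, tr, n_volumes) {
  blocks <- as.data.frame(blocks)
  need <- c("task", "onset", "duration")
  if (!all(need %in% names(blocks)))
    stop("`blocks` needs columns task, onset, duration")
  if (nrow(blocks) == 0L) stop("task design has no blocks")
  blocks$task <- as.character(blocks$task)
  if (any(blocks$onset < 0) || any(blocks$duration <= 0))
    stop("onsets must be >= 0 and durations > 0")
  total <- n_volumes * tr
  if (any(blocks$onset + blocks$duration > total + 1e-9))
    stop("a block extends beyond the end of the series")
  for (lab in unique(blocks$task)) {
    b <- blocks[blocks$task == lab, , drop = FALSE]
    b <- b[order(b$onset), , drop = FALSE]
    if (nrow(b) > 1L &&
        any(head(b$onset + b$duration, -1) > tail(b$onset, -1) + 1e-9))
      stop(sprintf("overlapping blocks for task '%s'", lab))
  }
  structure(list(blocks = blocks[order(blocks$onset), ], tr = tr,
                 n_volumes = as.integer(n_volumes)),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design> %d blocks, %d tasks (%s), %d volumes @ TR %g s\n",
              nrow(x$blocks), length(unique(x$blocks$task)),
              paste(unique(x$blocks$task), collapse = ", "),
              x$n_volumes, x$tr))
  invisible(x)
}

task_labels <- function(design) unique(design$blocks$task)
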