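#' Read a 4D functional series from a NIfTI-1 file
#'
#' The file must contain a 4D volume; TR is taken from `pixdim[4]` and the
#' in-plane pixel size from `pixdim[1]`, following the NIfTI convention.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [functional_series].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop(sprintf("expected a 4D series, got %d dims", length(dim(img))))
  pd <- RNifti::pixdim(img)
  functional_series(array(as.numeric(img), dim = dim(img)),
                    tr = pd[4], pixel_size = pd[1], slice_thickness = pd[3])
}

#' Write a functional series to NIfTI-1
#'
#' Data are stored as 64-bit floats so that a write/read round trip is
#' bit-exact; TR and pixel geometry go into `pixdim`.
#'
#' @param series a [functional_series].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "functional_series"))
  dat <- series$data
  attr(dat, "pixdim") <- c(series$pixel_size, series$pixel_size,
                           series$slice_thickness, series$tr)
  attr(dat, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(dat), path, datatype = "double")
  invisible(path)
}

#' Read / write a structural slice stack (NIfTI-1)
#'
#' @param path path to a 3D NIfTI file.
#' @return [read_structural()] returns a [structural_image];
#'   [write_structural()] returns `path` invisibly.
#' @export
read_structural <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (!length(dim(img)) %in% c(2L, 3L))
    stop(sprintf("expected a 2D/3D structural image, got %d dims",
                 length(dim(img))))
  pd <- RNifti::pixdim(img)
  dat <- array(as.numeric(img), dim = dim(img))
  if (length(dim(dat)) == 2L) dim(dat) <- c(dim(dat), 1L)
  structural_image(dat, pixel_size = pd[1],
                   slice_thickness = if (length(pd) >= 3) pd[3] else 1)
}

#' @rdname read_structural
#' @param image a [structural_image].
#' @export
write_structural <- function(image, path) {
  stopifnot(inherits(image, "structural_image"))
  dat <- image$data
  attr(dat, "pixdim") <- c(image$pixel_size, image$pixel_size,
                           image$slice_thickness)
  attr(dat, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(dat), path, datatype = "double")
  invisible(path)
}

#' Read / write a binary mask (NIfTI-1)
#'
#' Masks are stored as 0/1 volumes on the grid of the map they belong to.
#'
#' @param path file path.
#' @return [read_mask()] returns a logical array.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)  # NIfTI drops trailing singleton dims
  array(as.numeric(img) != 0, dim = d)
}

#' @rdname read_mask
#' @param mask logical or 0/1 numeric array.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.numeric(mask), dim = dim(mask)),
                         datatype = "uint8")
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a task design from YAML
#'
#' Expected layout:
#' ```yaml
#' tr: 0.5
#' n_volumes: 900
#' blocks:
#'   - {task: thumb,  onset: 20, duration: 20}
#'   - {task: little, onset: 60, duration: 20}
#' ```
#'
#' @param path YAML file path.
#' @return A validated [task_design].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_design_yaml(yaml::read_yaml(path))
}

parse_design_yaml <- function(y) {
  if (is.null(y$tr) || is.null(y$n_volumes) || is.null(y$blocks) ||
      length(y$blocks) == 0L)
    stop("design YAML needs tr, n_volumes and a non-empty blocks list")
  blocks <- do.call(rbind, lapply(y$blocks, function(b) {
    if (is.null(b$task) || is.null(b$onset) || is.null(b$duration))
      stop("each block needs task, onset, duration")
    data.frame(task = as.character(b$task), onset = as.numeric(b$onset),
               duration = as.numeric(b$duration))
  }))
  task_design(blocks, tr = y$tr, n_volumes = y$n_volumes)
}

#' @rdname read_design
#' @param design a [task_design].
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "task_design"))
  y <- list(
    tr = design$tr, n_volumes = design$n_volumes,
    blocks = lapply(seq_len(nrow(design$blocks)), function(i) {
      b <- design$blocks[i, ]
      list(task = b$task, onset = b$onset, duration = b$duration)
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
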