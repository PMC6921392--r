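#' Image sequence container
#'
#' An `xra_sequence` is a numeric `H x W x N` array (rows, columns, frames)
#' carrying the pixel spacing in millimetres as an attribute. All pipeline
#' stages take and return this container; single frames are plain matrices.
#'
#' @param frames a numeric `H x W x N` array, a matrix (single frame), or a
#'   list of equally sized matrices.
#' @param pixel_spacing_mm isotropic pixel spacing in millimetres.
#' @return an `xra_sequence` array.
#' @export
xra_sequence <- function(frames, pixel_spacing_mm = 0.3) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must have identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be an H x W x N array, matrix or list of matrices")
  if (!is.numeric(frames)) stop("'frames' must be numeric")
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1L ||
      pixel_spacing_mm <= 0)
    stop("'pixel_spacing_mm' must be a single positive number")
  structure(frames, pixel_spacing_mm = pixel_spacing_mm,
            class = c("xra_sequence", "array"))
}

#' @export
print.xra_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("xra_sequence: %d x %d pixels, %d frame(s), spacing %.3g mm\n",
              d[1L], d[2L], d[3L], attr(x, "pixel_spacing_mm")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @rdname xra_sequence
#' @param x an `xra_sequence`.
#' @export
n_frames <- function(x) dim(x)[3L]

#' @rdname xra_sequence
#' @param i frame index (1-based).
#' @export
get_frame <- function(x, i) {
  d <- dim(x)
  if (i < 1L || i > d[3L]) stop("frame index out of range")
  matrix(x[, , i], d[1L], d[2L])
}

#' @rdname xra_sequence
#' @export
pixel_spacing <- function(x) {
  p <- attr(x, "pixel_spacing_mm")
  if (is.null(p)) 0.3 else p
}

# apply f to every frame; result is an xra_sequence with the same spacing
map_frames <- function(x, f, ...) {
  d <- dim(x)
  out <- array(0, d)
  for (i in seq_len(d[3L])) out[, , i] <- f(matrix(x[, , i], d[1L], d[2L]), ...)
  xra_sequence(out, pixel_spacing(x))
}

#' Rescale a sequence to the unit intensity range
#'
#' Applies one global affine map over the whole sequence so that the minimum
#' becomes 0 and the maximum 1 (a constant sequence is returned unchanged).
#' Per-sequence rather than per-frame scaling preserves the relative contrast
#' of the contrast-agent inflow across frames.
#'
#' @param x an `xra_sequence` or numeric array.
#' @return rescaled `xra_sequence`.
#' @export
normalize_sequence <- function(x, pixel_spacing_mm = NULL) {
  p <- if (is.null(pixel_spacing_mm)) pixel_spacing(x) else pixel_spacing_mm
  r <- range(x)
  if (r[2L] > r[1L]) x <- (x - r[1L]) / (r[2L] - r[1L])
  xra_sequence(array(as.numeric(x), dim(x)), p)
}
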