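#' Read an image sequence from disk
#'
#' Accepts a multi-page TIFF file or a directory of single-frame PNG/TIFF
#' files (frames in lexicographic filename order). Integer images are scaled
#' to `[0, 1]` by their bit depth (8-bit by 1/255, 16-bit by 1/65535); RGB
#' frames are converted to grayscale by the Rec. 709 luminance
#' `0.2126 R + 0.7152 G + 0.0722 B`.
#'
#' @param path a `.tif/.tiff` file or a directory.
#' @param pixel_spacing_mm pixel spacing to attach (mm).
#' @return an [xra_sequence()].
#' @export
read_sequence <- function(path, pixel_spacing_mm = 0.3) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no PNG/TIFF frames found in ", path)
    frames <- lapply(files, function(f) {
      img <- tryCatch(
        if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
        else tiff::readTIFF(f),
        error = function(e) stop("unreadable frame '", f, "': ",
                                 conditionMessage(e), call. = FALSE))
      to_gray(img)
    })
    dims <- vapply(frames, function(m) paste(dim(m), collapse = "x"),
                   character(1L))
    if (length(unique(dims)) != 1L)
      stop("inconsistent frame sizes: ",
           paste(basename(files), dims, sep = "=", collapse = ", "))
    xra_sequence(frames, pixel_spacing_mm)
  } else if (file.exists(path)) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("unreadable TIFF '", path,
                                               "': ", conditionMessage(e),
                                               call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    xra_sequence(lapply(pages, to_gray), pixel_spacing_mm)
  } else {
    stop("input not found: ", path)
  }
}

to_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L)
      img <- 0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
    else img <- img[, , 1L]
  }
  img
}

#' Write an image sequence to disk
#'
#' A `.tif/.tiff` path gets a multi-page TIFF (`float32` by default, or
#' 8-bit with `bits = 8`, values clipped to `[0, 1]`); a directory path gets
#' one numbered PNG per frame (8-bit).
#'
#' @param sequence an [xra_sequence()] or 3-D array.
#' @param path output file (`.tif`) or directory.
#' @param bits 32 (float TIFF) or 8.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(sequence, path, bits = 32L) {
  d <- dim(sequence)
  frames <- lapply(seq_len(d[3L]), function(i) {
    f <- matrix(sequence[, , i], d[1L], d[2L])
    if (bits == 8L) pmin(pmax(f, 0), 1) else f
  })
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(frames, path, bits.per.sample = as.integer(bits),
                    reduce = TRUE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_along(frames))
      png::writePNG(pmin(pmax(frames[[i]], 0), 1),
                    file.path(path, sprintf("frame_%04d.png", i)))
  }
  invisible(path)
}

#' Write a binary mask stack as per-frame PNG files
#'
#' @param masks logical `H x W x N` stack.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return `dir`, invisibly.
#' @export
write_masks <- function(masks, dir, prefix = "mask") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(masks)
  for (i in seq_len(d[3L]))
    png::writePNG((masks[, , i] > 0) * 1,
                  file.path(dir, sprintf("%s_%04d.png", prefix, i)))
  invisible(dir)
}

#' Plain-text `key: value` manifest files
#'
#' Record a run's configuration and seed so it can be replayed exactly.
#' Values are serialized with `deparse()`, so numeric vectors and strings
#' round-trip.
#'
#' @param x a named list (nested lists are flattened with `.`-joined keys).
#' @param path output file.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` a
#'   named list of parsed values.
#' @export
write_manifest <- function(x, path) {
  flat <- flatten_config(x)
  lines <- vapply(names(flat), function(k)
    paste0(k, ": ", paste(deparse(flat[[k]]), collapse = "")), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keys <- sub(":.*$", "", lines)
  vals <- lapply(sub("^[^:]*: ", "", lines),
                 function(v) eval(parse(text = v), envir = baseenv()))
  stats::setNames(vals, keys)
}

flatten_config <- function(x, prefix = "") {
  out <- list()
  for (k in names(x)) {
    v <- x[[k]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (is.list(v) && !is.null(names(v))) out <- c(out, flatten_config(v, key))
    else { attributes(v) <- NULL; out[[key]] <- v }
  }
  out
}
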