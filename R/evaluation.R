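#' Local background ring around a vessel mask
#'
#' Dilates the vessel mask by a disk of radius `width` pixels and subtracts
#' the mask, leaving the outer neighborhood ring of the vessel boundary
#' (clipped at the frame border, no wraparound). A radius-1 disk is the
#' 4-neighborhood cross, so a single pixel with `width = 1` yields its four
#' edge neighbors.
#'
#' @param vessel_mask logical (or 0/1) matrix, non-empty.
#' @param width ring radius in pixels (default 7, the perivascular
#'   neighborhood used for local contrast evaluation).
#' @return logical ring mask.
#' @export
make_local_mask <- function(vessel_mask, width = 7) {
  vm <- vessel_mask > 0
  if (!any(vm)) stop("empty vessel mask: local background undefined")
  r <- as.integer(width)
  ax <- seq(-r, r)
  disk <- (outer(ax^2, ax^2, "+") <= r^2) * 1
  dil <- EBImage::dilate(vm * 1, disk) > 0
  dil & !vm
}

#' Evaluation mask set
#'
#' Bundles the vessel mask with the global background (its complement) and
#' the local background ring; the three are pairwise consistent: vessel and
#' backgrounds are disjoint and the local ring is contained in the global
#' background.
#'
#' @inheritParams make_local_mask
#' @return an `xra_masks` list with `vessel`, `global_background`,
#'   `local_background`.
#' @export
mask_set <- function(vessel_mask, width = 7) {
  vm <- vessel_mask > 0
  local <- make_local_mask(vm, width)
  out <- list(vessel = vm, global_background = !vm, local_background = local)
  stopifnot(!any(out$vessel & out$global_background),
            !any(out$vessel & out$local_background),
            all(!out$local_background | out$global_background))
  class(out) <- "xra_masks"
  out
}

#' Contrast-to-noise ratio
#'
#' `CNR = |mean(I[vessel]) - mean(I[background])| / sd(I[background])` with
#' the sample (n-1) standard deviation. Invariant under positive affine
#' intensity rescaling.
#'
#' @param image numeric matrix.
#' @param vessel_mask,background_mask logical masks, non-empty.
#' @return CNR value.
#' @export
cnr <- function(image, vessel_mask, background_mask) {
  fv <- image[vessel_mask > 0]; bv <- image[background_mask > 0]
  if (length(fv) == 0L || length(bv) == 0L) stop("empty evaluation mask")
  sb <- stats::sd(bv)
  if (!is.finite(sb) || sb == 0) stop("degenerate background: sd is zero")
  abs(mean(fv) - mean(bv)) / sb
}

#' Pixel-overlap segmentation metrics
#'
#' Counts true positives (vessel pixels found), false positives (background
#' pixels labelled vessel) and false negatives (vessel pixels missed) and
#' reports `precision = TP/(TP+FP)`, `sensitivity = TP/(TP+FN)` and their
#' harmonic mean `F1`. An empty denominator yields 0 with a warning.
#'
#' @param SI logical segmentation mask.
#' @param truth logical ground-truth mask, same shape.
#' @return one-row `data.frame` with `tp`, `fp`, `fn`, `precision`,
#'   `sensitivity`, `f1`.
#' @export
segmentation_metrics <- function(SI, truth) {
  if (!all(dim(SI) == dim(truth))) stop("mask shape mismatch")
  si <- SI > 0; tr <- truth > 0
  tp <- sum(si & tr); fp <- sum(si & !tr); fn <- sum(!si & tr)
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(sprintf("%s undefined (empty denominator); returning 0", what)); 0 }
    else num / den
  }
  pre <- safe_div(tp, tp + fp, "precision")
  sen <- safe_div(tp, tp + fn, "sensitivity")
  f1 <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
  data.frame(tp = tp, fp = fp, fn = fn, precision = pre,
             sensitivity = sen, f1 = f1)
}

#' Per-frame evaluation of an enhanced/segmented sequence
#'
#' Computes, for each frame with a non-empty truth mask, the global and local
#' CNR of `image_seq` and (when a segmentation stack is given) the
#' pixel-overlap metrics of `SI`.
#'
#' On enhanced sequences the background region can be exactly constant
#' (clean zero background); its contrast-to-noise ratio is then reported as
#' `Inf` when the means differ (unbounded contrast) and `NaN` when the frame
#' is fully constant, rather than raising the error [cnr()] gives.
#'
#' @param image_seq enhanced sequence to score (an [xra_sequence()]).
#' @param truth_masks logical `H x W x N` ground-truth vessel masks.
#' @param SI optional logical segmentation stack.
#' @param width local-ring radius in pixels.
#' @param frames frame indices to evaluate (default all).
#' @return `data.frame` with one row per evaluated frame.
#' @export
evaluate_sequence <- function(image_seq, truth_masks, SI = NULL, width = 7,
                              frames = NULL) {
  d <- dim(image_seq)
  if (is.null(frames)) frames <- seq_len(d[3L])
  extended_cnr <- function(img, vm, bm) {
    delta <- abs(mean(img[vm]) - mean(img[bm]))
    sb <- stats::sd(img[bm])
    if (sb == 0) { if (delta == 0) NaN else Inf } else delta / sb
  }
  rows <- lapply(frames, function(i) {
    vm <- truth_masks[, , i] > 0
    if (!any(vm)) return(NULL)
    ms <- mask_set(vm, width)
    img <- matrix(image_seq[, , i], d[1L], d[2L])
    row <- data.frame(frame = i,
                      cnr_global = extended_cnr(img, ms$vessel,
                                                ms$global_background),
                      cnr_local = extended_cnr(img, ms$vessel,
                                               ms$local_background))
    if (!is.null(SI)) row <- cbind(row, segmentation_metrics(SI[, , i], vm))
    row
  })
  do.call(rbind, rows)
}

#' Aggregate per-frame metrics
#'
#' Mean and standard deviation of every numeric column (except `frame`),
#' matching the `value +/- value` presentation of per-sequence reports.
#'
#' @param df a per-frame metrics `data.frame` from [evaluate_sequence()].
#' @return `data.frame` with `metric`, `mean`, `sd`.
#' @export
aggregate_metrics <- function(df) {
  cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1L))], "frame")
  data.frame(metric = cols,
             mean = vapply(cols, function(cl) mean(df[[cl]]), numeric(1L)),
             sd = vapply(cols, function(cl) stats::sd(df[[cl]]), numeric(1L)),
             row.names = NULL)
}
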