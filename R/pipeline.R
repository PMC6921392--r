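#' Full pipeline configuration
#'
#' @param pixel_spacing_mm pixel spacing `p` (mm); sets the
#'   structuring-element diameter `d = d' = 8.5/(2 p)`.
#' @param rpca an [rpca_config()].
#' @param features a [feature_config()].
#' @param subtract_direction difference convention of the first top-hat, see
#'   [remove_layer_by_closing()].
#' @param second_close_input `"E"` (default: the second closing is applied to
#'   the inter-frame vascular component) or `"DI"` (applied to the first
#'   difference sequence).
#' @param intra_pass run the intra-frame smoothing pass (disable to inspect
#'   the inter-frame output directly).
#' @param clip_negative clamp negative values of the vascular sequences to 0
#'   (vessels are positive in the pipeline's sign convention).
#' @param seed master seed; the decomposition basis seed derives from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(pixel_spacing_mm = 0.3, rpca = rpca_config(),
                            features = feature_config(),
                            subtract_direction = c("r_minus_i", "i_minus_r"),
                            second_close_input = c("E", "DI"),
                            intra_pass = TRUE, clip_negative = TRUE,
                            seed = 1L) {
  subtract_direction <- match.arg(subtract_direction)
  second_close_input <- match.arg(second_close_input)
  if (pixel_spacing_mm <= 0)
    stop("invalid configuration: 'pixel_spacing_mm' must be > 0")
  rpca$seed <- as.integer(seed)
  structure(list(pixel_spacing_mm = pixel_spacing_mm, rpca = rpca,
                 features = features,
                 subtract_direction = subtract_direction,
                 second_close_input = second_close_input,
                 intra_pass = intra_pass, clip_negative = clip_negative,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

clip_seq <- function(x) {
  y <- unclass(x); y[y < 0] <- 0
  xra_sequence(y, pixel_spacing(x))
}

#' Run the vessel enhancement and segmentation pipeline
#'
#' Stages, in order: (1) normalize the sequence to `[0, 1]`; (2) remove the
#' respiratory layer by circular-disk black top-hat, giving the difference
#' sequence `DI` with vessels positive; (3) inter-frame constrained
#' streaming decomposition of `DI` into quasi-static `B` and vascular `E`;
#' (4) second closing (white top-hat on the vessels-positive `E`), giving
#' `DI'`; (5) intra-frame constrained decomposition of `DI'` into the final
#' enhanced vascular sequence `V`; (6) multi-scale Hessian feature fusion of
#' each `V` frame and threshold segmentation into `SI`; (7) evaluation
#' against ground-truth masks, when given.
#'
#' @param sequence input [xra_sequence()] (vessels dark, as acquired).
#' @param config a [pipeline_config()].
#' @param truth_masks optional logical `H x W x N` ground-truth vessel masks;
#'   enables the metrics report.
#' @param output_dir optional directory: intermediates (`DI`, `E`, `DI'`,
#'   `V`, `F`), masks, metrics CSV and a manifest are written there.
#' @param eval_frames frame indices used for the metrics report (default
#'   all frames with a non-empty truth mask).
#' @param verbose print per-stage summaries.
#' @return list with `V`, `SI`, `F` (feature stack), intermediates `DI`,
#'   `B`, `E`, `DIprime`, the structuring element `se`, `metrics` (or
#'   `NULL`) and the `config`.
#' @export
run_pipeline <- function(sequence, config = pipeline_config(),
                         truth_masks = NULL, output_dir = NULL,
                         eval_frames = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  d <- dim(sequence)
  if (is.null(d) || length(d) != 3L) stop("input must be an H x W x N sequence")
  say <- function(stage, x) if (verbose)
    message(sprintf("[%s] min %.4g / mean %.4g / max %.4g", stage,
                    min(x), mean(x), max(x)))
  seqn <- normalize_sequence(sequence, config$pixel_spacing_mm)
  se <- make_circular_se(config$pixel_spacing_mm)
  DI <- remove_layer_by_closing(seqn, se, polarity = "dark",
                                subtract_direction = config$subtract_direction)
  say("DI", DI)
  rp <- inter_frame_rpca(if (config$subtract_direction == "i_minus_r")
    xra_sequence(-unclass(DI), pixel_spacing(DI)) else DI, config$rpca)
  E <- if (config$clip_negative) clip_seq(rp$E) else rp$E
  say("E", E)
  src <- if (config$second_close_input == "E") E else DI
  DIprime <- remove_layer_by_closing(src, se, polarity = "bright")
  say("DI'", DIprime)
  if (config$intra_pass) {
    V <- intra_frame_rpca(DIprime, config$rpca)$V
    if (config$clip_negative) V <- clip_seq(V)
  } else V <- DIprime
  say("V", V)
  SI <- array(FALSE, d)
  Fs <- array(0, d)
  for (i in seq_len(d[3L])) {
    fm <- fuse_multiscale(matrix(V[, , i], d[1L], d[2L]), config$features)
    Fs[, , i] <- fm$F
    SI[, , i] <- threshold_segment(fm$F, config$features$threshold)
  }
  metrics <- NULL
  if (!is.null(truth_masks))
    metrics <- evaluate_sequence(V, truth_masks, SI = SI, frames = eval_frames)
  out <- list(V = V, SI = SI, F = Fs, DI = DI, B = rp$B, E = E,
              DIprime = DIprime, se = se, metrics = metrics, config = config)
  if (!is.null(output_dir)) save_pipeline_outputs(out, output_dir)
  out
}

save_pipeline_outputs <- function(out, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  for (nm in c("DI", "E", "DIprime", "V", "F"))
    write_sequence(out[[nm]], file.path(output_dir, paste0(nm, ".tif")))
  write_masks(out$SI, file.path(output_dir, "SI"), "si")
  if (!is.null(out$metrics)) {
    utils::write.csv(out$metrics, file.path(output_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(aggregate_metrics(out$metrics),
                     file.path(output_dir, "metrics_aggregate.csv"),
                     row.names = FALSE)
  }
  write_manifest(c(list(package_version = as.character(utils::packageVersion("xraseg")),
                        r_version = R.version.string),
                   unclass(out$config)),
                 file.path(output_dir, "manifest.txt"))
  invisible(output_dir)
}

#' Simulate a reduced contrast-agent dose
#'
#' Linearly subtracts the enhanced vascular image from the original frame:
#' the enhanced sequence `V` (vessels positive) is mapped back to the
#' original dark-vessel polarity and a `(1 - dose_fraction)` share of it is
#' removed, i.e. `output = clip(original + (1 - dose_fraction) * V)`.
#' `dose_fraction = 1` returns the original; `dose_fraction = 0` removes the
#' full estimated vessel signal.
#'
#' @param original the (normalized) acquired sequence, vessels dark.
#' @param V enhanced vascular sequence from [run_pipeline()], same shape.
#' @param dose_fraction in `[0, 1]`.
#' @return simulated [xra_sequence()].
#' @export
simulate_low_dose <- function(original, V, dose_fraction) {
  if (!all(dim(original) == dim(V))) stop("shape mismatch")
  if (dose_fraction < 0 || dose_fraction > 1)
    stop("'dose_fraction' must be in [0, 1]")
  out <- unclass(original) + (1 - dose_fraction) * unclass(V)
  xra_sequence(pmin(pmax(out, 0), 1), pixel_spacing(original))
}
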