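#' Synthetic X-ray angiogram phantom configuration
#'
#' Parameters of the synthetic XRA sequence generator. The phantom is composed
#' of four layers on an absorption model: a static background with
#' vertebra/rib-like structures, a large smooth respiratory layer translating
#' sinusoidally (diaphragm/lung), a dark branching vessel tree displaced by a
#' cardiac phase and filled in progressively by contrast-agent inflow, and a
#' static catheter-like curve. Additive Gaussian noise is applied last and the
#' composite is clipped to `[0, 1]`.
#'
#' @param frame_height,frame_width frame size in pixels.
#' @param n_frames number of frames.
#' @param pixel_spacing_mm isotropic pixel spacing (mm).
#' @param n_branches number of vessel branches (including the main trunk).
#' @param diameter_range numeric length-2, min/max vessel diameter in pixels
#'   (diameter is the full width at half maximum of the Gaussian profile).
#' @param intensity_depth peak vessel absorption as a grayscale fraction in
#'   `[0, 1]`; the catheter uses half this depth.
#' @param contrast_inflow_frames frames over which the vessel tree reaches
#'   full opacity; the inflow factor of 0-based frame `i` is
#'   `min(1, i / contrast_inflow_frames)`. The default spans two thirds of
#'   the sequence, as contrast inflow does in clinical acquisitions.
#' @param respiratory_amplitude,respiratory_period translation amplitude
#'   (pixels) and period (frames) of the respiratory layer.
#' @param cardiac_amplitude,cardiac_period displacement amplitude (pixels)
#'   and period (frames, not necessarily integer — the heart rate is not
#'   locked to the frame rate) of the vessel tree. Each branch moves along
#'   its own direction with its own phase offset (elastic motion), so
#'   frame-to-frame vessel displacements never repeat exactly.
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   (grayscale fraction).
#' @param seed integer seed; the same seed and configuration give bit-identical
#'   output.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(frame_height = 128L, frame_width = 128L,
                           n_frames = 30L, pixel_spacing_mm = 0.3,
                           n_branches = 5L, diameter_range = c(1.8, 4.5),
                           intensity_depth = 0.35,
                           contrast_inflow_frames = 20L,
                           respiratory_amplitude = 6,
                           respiratory_period = 24L,
                           cardiac_amplitude = 8, cardiac_period = 9.7,
                           noise_sigma = 0.01, seed = 20L) {
  cfg <- list(frame_height = as.integer(frame_height),
              frame_width = as.integer(frame_width),
              n_frames = as.integer(n_frames),
              pixel_spacing_mm = pixel_spacing_mm,
              n_branches = as.integer(n_branches),
              diameter_range = as.numeric(diameter_range),
              intensity_depth = intensity_depth,
              contrast_inflow_frames = as.integer(contrast_inflow_frames),
              respiratory_amplitude = respiratory_amplitude,
              respiratory_period = as.numeric(respiratory_period),
              cardiac_amplitude = cardiac_amplitude,
              cardiac_period = as.numeric(cardiac_period),
              noise_sigma = noise_sigma, seed = as.integer(seed))
  for (f in c("frame_height", "frame_width", "n_frames", "n_branches",
              "contrast_inflow_frames", "respiratory_period",
              "cardiac_period"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 1)
      stop(sprintf("invalid phantom configuration: '%s' must be >= 1", f))
  for (f in c("respiratory_amplitude", "cardiac_amplitude", "noise_sigma"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("invalid phantom configuration: '%s' must be >= 0", f))
  if (cfg$intensity_depth < 0 || cfg$intensity_depth > 1)
    stop("invalid phantom configuration: 'intensity_depth' must be in [0, 1]")
  if (length(cfg$diameter_range) != 2L || any(cfg$diameter_range <= 0) ||
      diff(cfg$diameter_range) < 0)
    stop("invalid phantom configuration: 'diameter_range' must be increasing and positive")
  if (cfg$pixel_spacing_mm <= 0)
    stop("invalid phantom configuration: 'pixel_spacing_mm' must be > 0")
  class(cfg) <- "phantom_config"
  cfg
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# cubic Bezier sampled at n points -> matrix [x, y]
bezier_points <- function(p0, p1, p2, p3, n) {
  t <- seq(0, 1, length.out = n)
  b0 <- (1 - t)^3; b1 <- 3 * (1 - t)^2 * t; b2 <- 3 * (1 - t) * t^2; b3 <- t^3
  cbind(b0 * p0[1] + b1 * p1[1] + b2 * p2[1] + b3 * p3[1],
        b0 * p0[2] + b1 * p1[2] + b2 * p2[2] + b3 * p3[2])
}

# vessel-tree centerline samples in undisplaced coordinates:
# data.frame(x, y, w, branch) with w the Gaussian profile std at that point;
# attr "branches" holds the per-branch cardiac phase and motion direction
tree_geometry <- function(config) {
  H <- config$frame_height; W <- config$frame_width
  dmin <- config$diameter_range[1L]; dmax <- config$diameter_range[2L]
  # FWHM -> Gaussian sigma
  d2w <- function(d) d / 2.355
  with_seed(config$seed, {
    margin <- 4
    clipxy <- function(p) pmin(pmax(p, margin), c(W - margin, H - margin))
    p0 <- clipxy(c(0.45 * W + runif(1, -0.05, 0.05) * W, 0.06 * H))
    p3 <- clipxy(c(0.70 * W + runif(1, -0.06, 0.06) * W, 0.94 * H))
    p1 <- clipxy(p0 + c(runif(1, -0.15, 0.15) * W, 0.35 * H))
    p2 <- clipxy(p3 + c(runif(1, -0.20, 0.05) * W, -0.30 * H))
    n_trunk <- max(2L, ceiling(2 * sqrt(sum((p3 - p0)^2))))
    trunk <- bezier_points(p0, p1, p2, p3, n_trunk)
    tt <- seq(0, 1, length.out = n_trunk)
    trunk_d <- dmax * (1 - 0.4 * tt)             # trunk tapers to 60%
    pts <- data.frame(x = trunk[, 1L], y = trunk[, 2L], w = d2w(trunk_d),
                      branch = 1L)
    n_side <- config$n_branches - 1L
    if (n_side > 0L) {
      t0s <- sort(runif(n_side, 0.12, 0.70))
      for (k in seq_len(n_side)) {
        i0 <- max(2L, ceiling(t0s[k] * n_trunk))
        q0 <- trunk[i0, ]
        tang <- trunk[min(i0 + 1L, n_trunk), ] - trunk[i0 - 1L, ]
        tang <- tang / sqrt(sum(tang^2))
        side <- if (k %% 2L == 0L) 1 else -1
        ang <- side * runif(1, 30, 70) * pi / 180
        rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
        dirv <- as.numeric(rot %*% tang)
        len <- runif(1, 0.30, 0.55) * H
        q3 <- clipxy(q0 + len * dirv)
        q1 <- clipxy(q0 + 0.33 * len * dirv +
                       runif(2, -0.06, 0.06) * c(W, H))
        q2 <- clipxy(q0 + 0.66 * len * dirv +
                       runif(2, -0.08, 0.08) * c(W, H))
        nb <- max(2L, ceiling(2 * len))
        bp <- bezier_points(q0, q1, q2, q3, nb)
        tb <- seq(0, 1, length.out = nb)
        bd <- (trunk_d[i0] * 0.75) * (1 - tb) + dmin * tb
        pts <- rbind(pts, data.frame(x = bp[, 1L], y = bp[, 2L],
                                     w = d2w(bd), branch = k + 1L))
      }
    }
    # elastic cardiac motion: each branch has its own phase and direction
    nb <- config$n_branches
    ang <- stats::runif(nb, 0, 2 * pi)
    branches <- data.frame(branch = seq_len(nb),
                           phi = c(0, stats::runif(max(nb - 1L, 0L), 0, 2 * pi)),
                           ux = cos(ang), uy = sin(ang))
    attr(pts, "branches") <- branches[seq_len(nb), , drop = FALSE]
    pts
  })
}

# per-point cardiac displacement of the tree at a 0-based frame index
tree_displacement <- function(config, geom, frame_index) {
  br <- attr(geom, "branches")
  a <- config$cardiac_amplitude *
    sin(2 * pi * frame_index / config$cardiac_period + br$phi)
  idx <- match(geom$branch, br$branch)
  list(dx = (a * br$ux)[idx], dy = (a * br$uy)[idx])
}

# catheter centerline (static, no inflow): a smooth curve along the left side
catheter_geometry <- function(config) {
  H <- config$frame_height; W <- config$frame_width
  with_seed(config$seed + 7L, {
    p0 <- c(0.16 * W, 0.02 * H)
    p3 <- c(0.10 * W + runif(1, -0.02, 0.02) * W, 0.98 * H)
    p1 <- c(0.22 * W, 0.35 * H)
    p2 <- c(0.05 * W, 0.65 * H)
    n <- max(2L, ceiling(2 * H))
    bp <- bezier_points(p0, p1, p2, p3, n)
    data.frame(x = bp[, 1L], y = bp[, 2L], w = 2.2 / 2.355, branch = 1L)
  })
}

# render tubular absorption from centerline samples: compact-support Gaussian
# cross profile, truncated at 2 sigma, max-combined across samples;
# dx/dy may be scalars or per-point displacement vectors
render_tubes <- function(pts, depth, H, W, dx = 0, dy = 0) {
  img <- matrix(0, H, W)
  if (depth <= 0 || nrow(pts) == 0L) return(img)
  trunc_k <- 2                      # profile support radius in units of w
  floor_v <- exp(-trunc_k^2 / 2)
  xs <- pts$x + dx; ys <- pts$y + dy; ws <- pts$w
  for (i in seq_len(nrow(pts))) {
    w <- ws[i]
    r <- ceiling(trunc_k * w)
    cx <- xs[i]; cy <- ys[i]
    c0 <- max(1L, floor(cx - r)); c1 <- min(W, ceiling(cx + r))
    r0 <- max(1L, floor(cy - r)); r1 <- min(H, ceiling(cy + r))
    if (c0 > c1 || r0 > r1) next
    d2 <- outer((r0:r1 - cy)^2, (c0:c1 - cx)^2, "+")
    prof <- (exp(-d2 / (2 * w^2)) - floor_v) / (1 - floor_v)
    prof[prof < 0] <- 0
    blk <- img[r0:r1, c0:c1, drop = FALSE]
    img[r0:r1, c0:c1] <- pmax(blk, depth * prof)
  }
  img
}

# static anatomical background: base level + vertebra blobs + rib streaks
static_layer <- function(config) {
  H <- config$frame_height; W <- config$frame_width
  rowc <- matrix(seq_len(H), H, W)
  colc <- matrix(seq_len(W), H, W, byrow = TRUE)
  with_seed(config$seed + 13L, {
    img <- matrix(0.82, H, W)
    # vertebral column: bright blobs down the image center
    ncx <- 0.52 * W
    for (cy in seq(0.12, 0.9, length.out = 4L) * H) {
      img <- img + 0.10 * exp(-((colc - ncx)^2 / (2 * (0.09 * W)^2) +
                                  (rowc - cy)^2 / (2 * (0.06 * H)^2)))
    }
    # rib-like oblique dark streaks (wide, low contrast)
    for (k in 1:3) {
      ang <- runif(1, -25, -15) * pi / 180
      cy <- runif(1, 0.2, 0.8) * H; cx <- runif(1, 0.3, 0.8) * W
      u <- (colc - cx) * cos(ang) + (rowc - cy) * sin(ang)
      v <- -(colc - cx) * sin(ang) + (rowc - cy) * cos(ang)
      img <- img - 0.07 * exp(-(u^2 / (2 * (0.35 * W)^2) +
                                  v^2 / (2 * (0.11 * H)^2)))
    }
    img
  })
}

# respiratory pattern at a given translation offset (pixels, along rows):
# broad anisotropic Gaussian dimming centered low in the frame (diaphragm)
respiratory_layer <- function(config, offset) {
  H <- config$frame_height; W <- config$frame_width
  rowc <- matrix(seq_len(H), H, W)
  colc <- matrix(seq_len(W), H, W, byrow = TRUE)
  0.18 * exp(-((rowc - (0.85 * H + offset))^2 / (2 * (0.35 * H)^2) +
                 (colc - 0.30 * W)^2 / (2 * (0.55 * W)^2)))
}

inflow_factor <- function(config, frame_index) {
  min(1, frame_index / config$contrast_inflow_frames)
}

#' Render the phantom vessel tree for one frame
#'
#' Draws the branching vessel tree of a phantom configuration as a
#' non-negative absorption image, displaced by the cardiac phase
#' `sin(2*pi*frame_index/cardiac_period) * cardiac_amplitude` and scaled by
#' the contrast-inflow factor `min(1, frame_index/contrast_inflow_frames)`.
#'
#' @param config a [phantom_config()].
#' @param frame_index 0-based frame index, `< n_frames`.
#' @return list with `absorption` (matrix, `>= 0`) and `mask` (logical matrix,
#'   the exact support of the absorption).
#' @export
generate_vessel_tree <- function(config, frame_index) {
  stopifnot(inherits(config, "phantom_config"))
  if (frame_index < 0 || frame_index >= config$n_frames)
    stop("frame_index must be in [0, n_frames)")
  depth <- config$intensity_depth * inflow_factor(config, frame_index)
  geom <- tree_geometry(config)
  sh <- tree_displacement(config, geom, frame_index)
  abs_img <- render_tubes(geom, depth,
                          config$frame_height, config$frame_width,
                          dx = sh$dx, dy = sh$dy)
  list(absorption = abs_img, mask = abs_img > 0)
}

#' Generate a synthetic XRA sequence with ground truth
#'
#' Composes, per frame, `clip(static - respiratory - vessel - catheter +
#' noise, 0, 1)` with vessels dark (absorption dips), as in X-ray angiography.
#' The returned ground truth stores every layer and the realized noise, so the
#' emitted sequence can be reconstructed exactly.
#'
#' @param config a [phantom_config()].
#' @return list with `sequence` (an [xra_sequence()]), and `truth`: logical
#'   stack `vessel_mask`, matrices/stacks `static_layer`,
#'   `respiratory_layer`, `vessel_layer`, `catheter_layer`, `noise`, plus the
#'   `config`.
#' @export
generate_xra_sequence <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$frame_height; W <- config$frame_width; N <- config$n_frames
  stat <- static_layer(config)
  cath <- render_tubes(catheter_geometry(config),
                       0.5 * config$intensity_depth, H, W)
  frames <- array(0, c(H, W, N))
  resp <- array(0, c(H, W, N))
  vess <- array(0, c(H, W, N))
  mask <- array(FALSE, c(H, W, N))
  noise <- array(0, c(H, W, N))
  if (config$noise_sigma > 0)
    noise <- with_seed(config$seed + 1L,
                       array(stats::rnorm(H * W * N, 0, config$noise_sigma),
                             c(H, W, N)))
  geom <- tree_geometry(config)
  for (i in seq_len(N)) {
    f0 <- i - 1L                                 # 0-based phase
    off <- config$respiratory_amplitude *
      sin(2 * pi * f0 / config$respiratory_period)
    resp[, , i] <- respiratory_layer(config, off)
    depth <- config$intensity_depth * inflow_factor(config, f0)
    sh <- tree_displacement(config, geom, f0)
    v <- render_tubes(geom, depth, H, W, dx = sh$dx, dy = sh$dy)
    vess[, , i] <- v
    mask[, , i] <- v > 0
    frames[, , i] <- pmin(pmax(stat - resp[, , i] - v - cath +
                                 noise[, , i], 0), 1)
  }
  list(sequence = xra_sequence(frames, config$pixel_spacing_mm),
       truth = list(vessel_mask = mask, static_layer = stat,
                    respiratory_layer = resp, vessel_layer = vess,
                    catheter_layer = cath, noise = noise, config = config))
}
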