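#' Multi-scale feature configuration
#'
#' @param sigmas strictly increasing Gaussian scales in pixels at which the
#'   Hessian is evaluated.
#' @param alpha1,alpha2 fusion weights of the two descriptors (defaults 0.5
#'   and 0.5; their sum is logged but not enforced).
#' @param tau cutoff fraction in `(0, 1]` for the regularized eigenvalue
#'   field; `tau = 1` is the literal per-scale-maximum rule.
#' @param polarity `"bright"` if vessels are brighter than the background in
#'   the analyzed frame (enhanced sequences), `"dark"` for raw angiograms;
#'   dark frames are negated before analysis.
#' @param threshold segmentation threshold: a number, or `"otsu"` for Otsu's
#'   method on the positive feature responses, per frame.
#' @param intensity_scale frames are multiplied by this before Hessian
#'   analysis so eigenvalue magnitudes sit on the 8-bit-like grayscale range
#'   the fixed descriptor cutoff `-sqrt(2*pi)*sigma` was designed for
#'   (default 255; unit-range frames would otherwise never reach it).
#' @return a `feature_config` list.
#' @export
feature_config <- function(sigmas = c(1, 1.5, 2, 3, 4), alpha1 = 0.5,
                           alpha2 = 0.5, tau = 1.0,
                           polarity = c("bright", "dark"),
                           threshold = "otsu", intensity_scale = 255) {
  polarity <- match.arg(polarity)
  if (length(sigmas) < 1L || any(sigmas <= 0) ||
      is.unsorted(sigmas, strictly = TRUE))
    stop("'sigmas' must be strictly increasing and positive")
  if (tau <= 0 || tau > 1) stop("'tau' must be in (0, 1]")
  if (!identical(threshold, "otsu") &&
      (!is.numeric(threshold) || length(threshold) != 1L))
    stop("'threshold' must be a number or \"otsu\"")
  structure(list(sigmas = as.numeric(sigmas), alpha1 = alpha1,
                 alpha2 = alpha2, tau = tau, polarity = polarity,
                 threshold = threshold, intensity_scale = intensity_scale),
            class = "feature_config")
}

# 1-D convolution matrix (n x n) for kernel k (odd length), mirror boundary
conv_matrix <- function(n, k) {
  h <- (length(k) - 1L) %/% 2L
  C <- matrix(0, n, n)
  reflect <- function(j) {               # whole-sample mirror, any offset
    if (n == 1L) return(rep(1L, length(j)))
    p <- (j - 1L) %% (2L * n - 2L)
    ifelse(p >= n, 2L * n - 2L - p, p) + 1L
  }
  for (o in -h:h) {
    j <- reflect(seq_len(n) + o)
    idx <- cbind(seq_len(n), j)
    C[idx] <- C[idx] + k[o + h + 1L]
  }
  C
}

# Gaussian and derivative kernels, truncated at 4*sigma
gaussian_kernels <- function(sigma) {
  h <- max(1L, ceiling(4 * sigma))
  x <- (-h):h
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  g2 <- g2 - mean(g2)       # exact zero response to constants after truncation
  list(g = g, g1 = -x / sigma^2 * g, g2 = g2)
}

#' Scale-normalized Hessian field of a frame
#'
#' Convolves the frame with second-order Gaussian-derivative kernels at scale
#' `sigma` and applies the `sigma^2` scale normalization. Eigenvalues of the
#' symmetric per-pixel 2 x 2 Hessian are ordered by magnitude,
#' `|lambda1| <= |lambda2|`; for tubular structures `|lambda1| ~ 0` and
#' `|lambda2|` is large, with the `lambda1` eigenvector along the centerline.
#'
#' @param frame numeric matrix.
#' @param sigma scale in pixels, `> 0`.
#' @param vectors also return the unit eigenvector fields `v1x, v1y`
#'   (centerline direction) and `v2x, v2y` (normal).
#' @return list with matrices `hxx`, `hxy`, `hyy`, `lambda1`, `lambda2`
#'   (and eigenvectors when requested).
#' @export
hessian_at_scale <- function(frame, sigma, vectors = FALSE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive scale")
  n1 <- nrow(frame); n2 <- ncol(frame)
  k <- gaussian_kernels(sigma)
  Rg <- conv_matrix(n1, k$g);  Cg <- conv_matrix(n2, k$g)
  R1 <- conv_matrix(n1, k$g1); C1 <- conv_matrix(n2, k$g1)
  R2 <- conv_matrix(n1, k$g2); C2 <- conv_matrix(n2, k$g2)
  # rows (dim 1) = y, columns (dim 2) = x
  hxx <- sigma^2 * (Rg %*% frame %*% t(C2))
  hyy <- sigma^2 * (R2 %*% frame %*% t(Cg))
  hxy <- sigma^2 * (R1 %*% frame %*% t(C1))
  m <- (hxx + hyy) / 2
  s <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  e_hi <- m + s; e_lo <- m - s
  hi_is_2 <- abs(e_hi) >= abs(e_lo)
  lambda2 <- ifelse(hi_is_2, e_hi, e_lo)
  lambda1 <- ifelse(hi_is_2, e_lo, e_hi)
  out <- list(hxx = hxx, hxy = hxy, hyy = hyy,
              lambda1 = lambda1, lambda2 = lambda2, sigma = sigma)
  if (vectors) {
    # eigenvector of the algebraically larger eigenvalue e_hi
    vx <- hxy; vy <- e_hi - hxx
    deg <- abs(vx) + abs(vy) < 1e-12
    vx[deg] <- 1; vy[deg] <- 0
    nrm <- sqrt(vx^2 + vy^2)
    vx <- vx / nrm; vy <- vy / nrm
    # v2 belongs to lambda2 (largest magnitude), v1 is orthogonal
    out$v2x <- ifelse(hi_is_2, vx, -vy)
    out$v2y <- ifelse(hi_is_2, vy, vx)
    out$v1x <- -out$v2y
    out$v1y <- out$v2x
  }
  out
}

#' First vessel descriptor (log-scaled eigenvalue response)
#'
#' `F1 = ln(lambda2^2 + 1)` where `lambda2 < -sqrt(2*pi)*sigma`, else 0.
#' Responds to bright tubes (strongly negative `lambda2`); the log compresses
#' the response range so thin and thick vessels answer comparably.
#'
#' @param lambda2_map magnitude-ordered second eigenvalue map at scale
#'   `sigma`.
#' @param sigma the scale the map was computed at.
#' @return non-negative `F1` map.
#' @export
f1_descriptor <- function(lambda2_map, sigma) {
  ifelse(lambda2_map < -sqrt(2 * pi) * sigma, log(lambda2_map^2 + 1), 0)
}

#' Regularized eigenvalue field
#'
#' With `m` the per-map maximum of `lambda2` and cutoff `c = tau * m`:
#' `lambda_r = lambda2` where `lambda2 > c`; `lambda_r = c` where
#' `0 < lambda2 <= c`; 0 elsewhere. At `tau = 1` this is the literal
#' per-scale-maximum rule (every positive pixel is lifted to the maximum),
#' which gives the second descriptor a uniform response at bends and
#' bifurcations.
#'
#' @param lambda2_map sign-adjusted eigenvalue map (vessels positive).
#' @param tau cutoff fraction in `(0, 1]`.
#' @return `lambda_r` map; all zeros when the map has no positive values.
#' @export
lambda_r_field <- function(lambda2_map, tau = 1.0) {
  m <- max(lambda2_map)
  # maps whose maximum is numerically zero carry no structure; without this
  # floor the max normalization would amplify rounding dust to full response
  if (!is.finite(m) || m <= 1e-8) return(lambda2_map * 0)
  cutoff <- tau * m
  ifelse(lambda2_map > cutoff, lambda2_map,
         ifelse(lambda2_map > 0, cutoff, 0))
}

#' Second vessel descriptor (regularized volume ratio)
#'
#' `F2 = 0` where `lambda2 <= 0` and `lambda_r <= 0`; `F2 = 1` where
#' `lambda2 >= lambda_r/2 > 0`; otherwise
#' `lambda2^2 * (lambda_r - lambda2) * (3/(lambda_r + lambda2))^3`, clipped
#' to `[0, 1]`. Continuous across the `lambda2 = lambda_r/2` boundary.
#'
#' @param lambda2_map sign-adjusted eigenvalue map (vessels positive).
#' @param lambda_r_map matching [lambda_r_field()] map.
#' @return `F2` map in `[0, 1]`.
#' @export
f2_descriptor <- function(lambda2_map, lambda_r_map) {
  if (!all(dim(lambda2_map) == dim(lambda_r_map)))
    stop("descriptor maps must have the same shape")
  l2 <- lambda2_map; lr <- lambda_r_map
  out <- l2 * 0
  one <- (lr > 0) & (l2 >= lr / 2)
  els <- !one & !((l2 <= 0) & (lr <= 0))
  out[one] <- 1
  denom <- lr + l2
  safe <- els & (denom > 0)
  out[safe] <- (l2[safe]^2 * (lr[safe] - l2[safe])) * (3 / denom[safe])^3
  pmin(pmax(out, 0), 1)
}

#' Fused multi-scale vessel feature map
#'
#' For each scale, computes the Hessian eigenvalues of the
#' (polarity-oriented, intensity-scaled) frame; `F1` is evaluated on
#' `lambda2` directly (bright tubes give strongly negative values) and
#' `F2`/`lambda_r` on the sign-adjusted `-lambda2`, so both descriptors fire
#' on the same structures. `F1` is min-max normalized to `[0, 1]` over the
#' whole per-frame scale stack (it is log-scaled and unbounded, while `F2`
#' is already in `[0, 1]`), and the fused response is the per-pixel maximum
#' over scales of `alpha1*F1 + alpha2*F2`.
#'
#' @param frame numeric matrix.
#' @param config a [feature_config()].
#' @return list of class `feature_maps`: fused `F`, per-scale stacks `F1`
#'   (raw), `F1_norm`, `F2`, `lambda_r`, and `sigmas`.
#' @export
fuse_multiscale <- function(frame, config = feature_config()) {
  ns <- length(config$sigmas)
  if (ns < 1L) stop("empty scale list")
  work <- frame * config$intensity_scale
  if (config$polarity == "dark") work <- -work
  d <- dim(frame)
  F1 <- array(0, c(d, ns)); F2 <- array(0, c(d, ns)); LR <- array(0, c(d, ns))
  for (s in seq_len(ns)) {
    sg <- config$sigmas[s]
    hf <- hessian_at_scale(work, sg)
    F1[, , s] <- f1_descriptor(hf$lambda2, sg)
    l2pos <- -hf$lambda2
    LR[, , s] <- lambda_r_field(l2pos, config$tau)
    F2[, , s] <- f2_descriptor(l2pos, LR[, , s])
  }
  f1max <- max(F1); f1min <- min(F1)
  F1n <- if (f1max - f1min > 1e-12) (F1 - f1min) / (f1max - f1min)
         else array(0, dim(F1))
  fused <- matrix(-Inf, d[1L], d[2L])
  for (s in seq_len(ns))
    fused <- pmax(fused, config$alpha1 * F1n[, , s] + config$alpha2 * F2[, , s])
  structure(list(F = fused, F1 = F1, F1_norm = F1n, F2 = F2, lambda_r = LR,
                 sigmas = config$sigmas, config = config),
            class = "feature_maps")
}

#' Threshold segmentation of a feature map
#'
#' `SI = F >= threshold`. With `threshold = "otsu"` the cutoff is chosen by
#' Otsu's method on the positive feature responses of the frame (zeros — the
#' descriptor's explicit background label — are excluded from the
#' histogram).
#'
#' @param F non-negative feature map (matrix).
#' @param threshold a number or `"otsu"`.
#' @return logical segmentation mask.
#' @export
threshold_segment <- function(F, threshold = "otsu") {
  if (!all(is.finite(F))) stop("feature map contains non-finite values")
  if (identical(threshold, "otsu")) {
    nz <- F[F > 0]
    if (length(nz) < 2L || max(nz) == min(nz)) return(F > 0 & F >= max(F))
    th <- EBImage::otsu(EBImage::Image(matrix(nz, ncol = 1L)),
                        range = c(0, max(nz)))
    F >= th
  } else {
    F >= threshold
  }
}
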