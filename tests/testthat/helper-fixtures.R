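# Shared fixtures and independent oracles. The default phantom and its
# pipeline run are built once per test session and reused.

.fixture_cache <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(.fixture_cache$phantom))
    .fixture_cache$phantom <- generate_xra_sequence(phantom_config())
  .fixture_cache$phantom
}

default_pipeline_run <- function() {
  if (is.null(.fixture_cache$run)) {
    ph <- default_phantom()
    .fixture_cache$run <- run_pipeline(ph$sequence, pipeline_config(),
                                       truth_masks = ph$truth$vessel_mask,
                                       eval_frames = opacified_frames())
  }
  .fixture_cache$run
}

# frames where contrast inflow is complete and the streaming basis is past
# burn-in (inflow ends at 0-based index 20 -> R frame 21)
opacified_frames <- function() 21:30

# planted low-rank + sparse stream: r_true smooth random basis images with
# O(0.5) amplitudes, N(1, 0.3) coefficients, and +-[0.8, 1.2] spikes on a
# fresh 5% support per frame
make_planted <- function(seed, H = 64L, N = 50L, r_true = 3L, sfrac = 0.05) {
  set.seed(seed)
  D <- H * H
  smooth_field <- function() {
    f <- matrix(rnorm(D), H, H)
    k <- xraseg:::gaussian_kernels(6)$g
    C <- xraseg:::conv_matrix(H, k)
    m <- C %*% f %*% t(C)
    m / max(abs(m)) * 0.5
  }
  U <- sapply(seq_len(r_true), function(j) as.numeric(smooth_field()))
  Ce <- matrix(rnorm(r_true * N, 1, 0.3), r_true, N)
  S <- array(0, c(H, H, N)); supp <- array(FALSE, c(H, H, N))
  for (i in seq_len(N)) {
    m <- matrix(U %*% Ce[, i], H, H)
    idx <- sample(D, round(sfrac * D))
    sp <- numeric(D)
    sp[idx] <- sample(c(-1, 1), length(idx), TRUE) * runif(length(idx), 0.8, 1.2)
    supp[, , i][idx] <- TRUE
    S[, , i] <- m + matrix(sp, H, H)
  }
  list(S = S, supp = supp, U = U, min_amp = 0.8)
}

# pooled support-recovery F1 over given frames; detection threshold is half
# the smallest planted spike amplitude (fixed a priori, amplitude-aware)
planted_support_f1 <- function(E, planted, frames) {
  th <- planted$min_amp / 2
  tp <- fp <- fn <- 0
  for (i in frames) {
    est <- abs(E[, , i]) > th
    tp <- tp + sum(est & planted$supp[, , i])
    fp <- fp + sum(est & !planted$supp[, , i])
    fn <- fn + sum(!est & planted$supp[, , i])
  }
  2 * tp / (2 * tp + fp + fn)
}

# independent convex oracle for the per-frame objective: split E = ep - en
# (both >= 0) makes the problem smooth and box-constrained, solved by
# L-BFGS-B; returns the attained objective value
convex_oracle_objective <- function(f, Lr, l1, l2) {
  D <- length(f); r <- ncol(Lr)
  fn <- function(par) {
    Ce <- par[1:r]; ep <- par[r + 1:D]; en <- par[r + D + 1:D]
    res <- f - as.numeric(Lr %*% Ce) - ep + en
    0.5 * sum(res^2) + l1 / 2 * sum(Ce^2) + l2 * sum(ep + en)
  }
  gr <- function(par) {
    Ce <- par[1:r]; ep <- par[r + 1:D]; en <- par[r + D + 1:D]
    res <- f - as.numeric(Lr %*% Ce) - ep + en
    c(-as.numeric(crossprod(Lr, res)) + l1 * Ce, -res + l2, res + l2)
  }
  stats::optim(rep(0, r + 2 * D), fn, gr, method = "L-BFGS-B",
               lower = c(rep(-Inf, r), rep(0, 2 * D)),
               control = list(maxit = 5000, factr = 10))$value
}

# brute-force flat grayscale dilation/erosion; the disk window is clipped
# at the frame border (same rule as the package's morphology)
bf_morph <- function(frame, mask, op = max) {
  H <- nrow(frame); W <- ncol(frame)
  r <- (nrow(mask) - 1L) %/% 2L
  out <- matrix(0, H, W)
  off <- which(mask > 0, arr.ind = TRUE) - r - 1L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- i + off[, 1L]; jj <- j + off[, 2L]
    keep <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    out[i, j] <- op(frame[cbind(ii[keep], jj[keep])])
  }
  out
}

bf_close <- function(frame, mask) {
  rot <- mask[rev(seq_len(nrow(mask))), rev(seq_len(ncol(mask)))]
  bf_morph(bf_morph(frame, mask, max), rot, min)
}

# contrast of vessels against their local surround, mean over given frames
mask_contrast <- function(seqc, truth, frames, width = 7) {
  mean(sapply(frames, function(i) {
    vm <- truth$vessel_mask[, , i]
    ring <- make_local_mask(vm, width)
    mean(seqc[, , i][ring]) - mean(seqc[, , i][vm])
  }))
}
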