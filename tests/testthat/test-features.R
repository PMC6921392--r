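test_that("Hessian of a constant frame vanishes", {
  hf <- hessian_at_scale(matrix(0.7, 32, 32), 1.5)
  expect_equal(max(abs(hf$lambda1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(hf$lambda2)), 0, tolerance = 1e-12)
  expect_error(hessian_at_scale(matrix(0, 8, 8), -1), "sigma")
})

test_that("Gaussian blob eigenvalues match the symbolic closed form", {
  # frame A*exp(-r^2/(2 s^2)) convolved with a unit-mass Gaussian of std
  # sigma is A*s^2/(s^2+sigma^2)*exp(-r^2/(2(s^2+sigma^2))); its second
  # derivative at the center is -A*s^2/(s^2+sigma^2)^2, so the
  # sigma^2-normalized eigenvalues there are both
  # -sigma^2*A*s^2/(s^2+sigma^2)^2
  s <- 4; A <- 1; n <- 65; ctr <- 33
  blob <- outer(1:n, 1:n,
                function(y, x) A * exp(-((x - ctr)^2 + (y - ctr)^2) / (2 * s^2)))
  for (sigma in c(1, 2, 3)) {
    hf <- hessian_at_scale(blob, sigma)
    pred <- -sigma^2 * A * s^2 / (s^2 + sigma^2)^2
    expect_lt(abs(hf$lambda2[ctr, ctr] - pred) / abs(pred), 1e-3)
    expect_lt(abs(hf$lambda1[ctr, ctr] - pred) / abs(pred), 1e-3)
  }
})

test_that("eigenvalue maps are equivariant under 90-degree rotation", {
  set.seed(3)
  f <- EBImage::gblur(matrix(rnorm(48 * 48), 48, 48), 2)
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  h1 <- hessian_at_scale(f, 2)
  h2 <- hessian_at_scale(rot90(f), 2)
  expect_equal(rot90(h1$lambda2), h2$lambda2, tolerance = 1e-10)
  expect_equal(rot90(h1$lambda1), h2$lambda1, tolerance = 1e-10)
})

test_that("eigen decomposition is ordered and reconstructs the Hessian", {
  set.seed(4)
  f <- EBImage::gblur(matrix(runif(40 * 40), 40, 40), 1.5)
  hf <- hessian_at_scale(f, 1.5, vectors = TRUE)
  expect_true(all(abs(hf$lambda1) <= abs(hf$lambda2) + 1e-12))
  rec_xx <- hf$lambda1 * hf$v1x^2 + hf$lambda2 * hf$v2x^2
  rec_yy <- hf$lambda1 * hf$v1y^2 + hf$lambda2 * hf$v2y^2
  rec_xy <- hf$lambda1 * hf$v1x * hf$v1y + hf$lambda2 * hf$v2x * hf$v2y
  expect_equal(rec_xx, hf$hxx, tolerance = 1e-8)
  expect_equal(rec_yy, hf$hyy, tolerance = 1e-8)
  expect_equal(rec_xy, hf$hxy, tolerance = 1e-8)
})

test_that("first descriptor follows its case table", {
  expect_equal(f1_descriptor(0, 1), 0)
  expect_equal(f1_descriptor(-3, 1), log(10))   # -3 < -sqrt(2*pi)
  expect_equal(f1_descriptor(-2, 1), 0)         # -2 > -sqrt(2*pi)
  expect_equal(f1_descriptor(-4, 2), 0)         # cutoff scales with sigma
  expect_equal(f1_descriptor(-6, 2), log(37))   # past the scaled cutoff
  expect_equal(f1_descriptor(c(-3, 5, 0), 1), c(log(10), 0, 0))
})

test_that("regularized eigenvalue field matches per-pixel case enumeration", {
  lam_r_bf <- function(map, tau) {   # brute-force case table per pixel
    m <- max(map); cutoff <- tau * m
    out <- numeric(length(map))
    for (i in seq_along(map)) {
      if (m > 0 && map[i] > cutoff) out[i] <- map[i]
      else if (m > 0 && map[i] > 0) out[i] <- cutoff
      else out[i] <- 0
    }
    out
  }
  expect_equal(lambda_r_field(c(-1, -0.3, 0)), c(0, 0, 0))
  expect_equal(lambda_r_field(c(0.5, 1.0, -0.2), tau = 1), c(1, 1, 0))
  expect_equal(lambda_r_field(c(0.2, 1.0), tau = 0.5), c(0.5, 1.0))
  set.seed(6)
  for (k in 1:5) {
    map <- runif(40, -1, 2)
    tau <- sample(c(0.3, 0.7, 1), 1)
    expect_equal(lambda_r_field(map, tau), lam_r_bf(map, tau))
  }
})

test_that("second descriptor follows its cases, range and continuity", {
  expect_equal(f2_descriptor(-1, 0), 0)
  expect_equal(f2_descriptor(2, 3), 1)                       # 2 >= 1.5 > 0
  expect_equal(f2_descriptor(1, 3), 1 * 2 * (3 / 4)^3)       # 0.84375
  set.seed(8)
  l2 <- matrix(runif(400, -2, 2), 20, 20)
  lr <- matrix(runif(400, -2, 2), 20, 20)
  F2 <- f2_descriptor(l2, lr)
  expect_true(all(F2 >= 0 & F2 <= 1))
  # continuity across lambda2 = lambda_r/2: the else branch approaches 1
  for (lr1 in seq(0.2, 3, by = 0.2)) {
    below <- f2_descriptor(lr1 / 2 * (1 - 1e-9), lr1)
    expect_lt(abs(below - 1), 1e-6)
  }
  expect_error(f2_descriptor(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("multi-scale fusion responds at the tube's own scale", {
  cfg <- feature_config()
  expect_true(all(fuse_multiscale(matrix(0.5, 32, 32), cfg)$F == 0))
  expect_error(feature_config(sigmas = numeric(0)), "sigmas")
  # bright tube of Gaussian half-width w: strongest centerline response
  # within one scale step of the sigma closest to w
  tube <- function(w, n = 49) outer(1:n, 1:n, function(y, x)
    0.6 * exp(-(y - 25)^2 / (2 * w^2)))
  for (w in c(1.5, 3)) {
    fm <- fuse_multiscale(tube(w), cfg)
    resp <- sapply(seq_along(cfg$sigmas), function(s)
      mean((cfg$alpha1 * fm$F1_norm[, , s] + cfg$alpha2 * fm$F2[, , s])[25, ]))
    best <- which.max(resp)
    target <- which.min(abs(cfg$sigmas - w))
    expect_lte(abs(best - target), 1)
  }
  # degenerate weights: alpha1 = 0 leaves the max over scales of F2 alone
  cfg0 <- feature_config(alpha1 = 0, alpha2 = 1)
  fm0 <- fuse_multiscale(tube(2), cfg0)
  expect_equal(fm0$F, apply(fm0$F2, c(1, 2), max))
  expect_true(all(fm0$F >= 0) && all(fm0$F1 >= 0))
})

test_that("threshold segmentation honours fixed and Otsu thresholds", {
  expect_identical(threshold_segment(matrix(c(0.1, 0.9), 1, 2), 0.5),
                   matrix(c(FALSE, TRUE), 1, 2))
  F <- matrix(0, 4, 4); F[2, 2] <- 0.4
  expect_identical(threshold_segment(F, 1e-9), F > 0)
  # bimodal map: Otsu separates the two populations
  set.seed(10)
  Fb <- matrix(0, 20, 20)
  Fb[1:10, ] <- runif(200, 0.05, 0.15)
  Fb[15:20, ] <- runif(120, 0.7, 0.9)
  si <- threshold_segment(Fb, "otsu")
  expect_true(all(si[15:20, ]))
  expect_true(!any(si[1:10, ]))
  expect_error(threshold_segment(matrix(c(1, NaN), 1, 2), 0.5), "finite")
})
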