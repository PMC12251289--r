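test_that("SNR to pixel-noise conversion follows the 20 log10(1000/sigma) rule", {
  expect_equal(snr_to_sigma(50), 1000 * 10^(-2.5))
  expect_equal(snr_to_sigma(50), 3.162278, tolerance = 1e-6)
  expect_equal(sigma_to_snr(snr_to_sigma(37.3)), 37.3)
  # round trip holds across the range
  for (snr in c(-10, 0, 15, 30, 50, 80))
    expect_equal(sigma_to_snr(snr_to_sigma(snr)), snr)
})

test_that("bead counts are Poisson with the prescribed density", {
  expect_error(generate_bead_field(c(64, 64), -1), "non-negative")
  empty <- generate_bead_field(c(64, 64), 0, seed = 1)
  expect_equal(nrow(empty$centroids), 0L)

  d <- 5e-3; side <- 256
  counts <- vapply(1:100, function(s)
    nrow(generate_bead_field(c(side, side), d, seed = s)$centroids), numeric(1))
  lambda <- d * side^2          # 327.68
  expect_equal(mean(counts), lambda, tolerance = 3 / sqrt(lambda * 100) * 3)
  expect_equal(var(counts), lambda, tolerance = 0.25)

  # x-gradient density: left half denser than right half
  set.seed(7)
  grad <- generate_bead_field(c(512, 512), linear_density(8e-3, 8e-4, 512))
  x <- grad$centroids[, 1]
  expect_gt(sum(x < 256), sum(x >= 256))
  bt <- binom.test(sum(x < 256), length(x), 0.5, alternative = "greater")
  expect_lt(bt$p.value, 1e-10)
})

test_that("bead rendering is the clipped sum of Gaussian profiles", {
  shape <- c(33, 33)
  expect_equal(render_beads(bead_field(matrix(numeric(0), 0, 2)), shape),
               matrix(0, 33, 33))
  # single bead exactly at a pixel centre saturates that pixel
  bf <- bead_field(cbind(16, 16), peak_intensity = 1000, bead_sigma = 2)
  img <- render_beads(bf, shape)
  expect_equal(img[17, 17], 1000)
  # value at distance sigma is 1000 exp(-1/2)
  expect_equal(img[17, 17 + 2], 1000 * exp(-0.5), tolerance = 1e-10)
  expect_equal(img[17 + 2, 17], 1000 * exp(-0.5), tolerance = 1e-10)
  # two coincident beads still clip at saturation
  img2 <- render_beads(bead_field(rbind(c(16, 16), c(16, 16)), bead_sigma = 2),
                       shape)
  expect_equal(max(img2), 1000)
})

test_that("pixel noise has the prescribed standard deviation and clips", {
  img <- matrix(500, 1000, 1000)
  noisy <- add_pixel_noise(img, 20, seed = 3)
  expect_equal(sd(noisy - img), 100, tolerance = 0.01)
  expect_true(all(noisy >= 0 & noisy <= 1000))
  expect_identical(add_pixel_noise(img, Inf), img)
})

test_that("displacement specs move centroids as prescribed", {
  set.seed(11)
  shape <- c(128, 128)
  bf <- generate_bead_field(shape, 4e-3)
  # uniform (2, 0.6): every centroid shifts exactly
  mv <- apply_displacement(bf, displacement_uniform(c(2, 0.6)), shape)
  kept <- bf$centroids[, 1] + 2 <= 127 & bf$centroids[, 2] + 0.6 <= 127
  expect_equal(mv$centroids[, 1], bf$centroids[kept, 1] + 2)
  expect_equal(mv$centroids[, 2], bf$centroids[kept, 2] + 0.6)
  # zero field is the identity
  mv0 <- apply_displacement(bf, displacement_uniform(c(0, 0)), shape)
  expect_equal(mv0$centroids, bf$centroids)
  # linear field leaves the normalised origin unmoved
  spec <- displacement_linear()
  centre <- matrix(c(127 / 2, 127 / 2), 1, 2)
  expect_equal(as.numeric(eval_displacement(spec, centre, shape)), c(0, 0))
  # default shear matrix reproduces g sin(a) cos^2(a) at the corner
  corner <- eval_displacement(spec, matrix(c(127, 127), 1, 2), shape)
  expect_equal(as.numeric(corner),
               c(20 * sin(pi / 4) * cos(pi / 4)^2, 20 * cos(pi / 4) * sin(pi / 4)^2))
  # displacing by u then -u returns the surviving centroids exactly
  u <- c(1.3, -2.1)
  fwd <- apply_displacement(bf, displacement_uniform(u), shape)
  back <- apply_displacement(fwd, displacement_uniform(-u), shape)
  survived <- bf$centroids[, 1] + u[1] >= 0 & bf$centroids[, 1] + u[1] <= 127 &
              bf$centroids[, 2] + u[2] >= 0 & bf$centroids[, 2] + u[2] <= 127
  expect_equal(back$centroids, bf$centroids[survived, , drop = FALSE],
               tolerance = 1e-12)
  expect_error(eval_displacement(structure(list(kind = "bogus"),
                                           class = "displacement_spec"),
                                 centre, shape), "unknown")
})

test_that("island traction field peaks, vanishes far away, and balances", {
  L <- 354.5
  f <- four_island_field(L)
  at_centre <- f(L / 4, L / 4)
  expect_equal(as.numeric(at_centre$tx), 500, tolerance = 1e-6)
  far <- f(L / 2, L / 2)
  expect_lt(abs(far$tx), 500 * exp(-((L / 4)^2) / (2 * 15^2)) * 4 + 1e-10)
  # total vector force integrates to ~0 by symmetry
  n <- 512
  xs <- (seq_len(n) - 0.5) * (L / n)
  gx <- matrix(xs, n, n, byrow = TRUE); gy <- matrix(xs, n, n)
  tr <- f(gx, gy)
  cell <- (L / n)^2
  expect_lt(abs(sum(tr$tx) * cell) / (500 * 2 * pi * 15^2), 1e-6)
  expect_equal(sum(tr$ty), 0)
})

test_that("benchmark builder produces consistent images and ground truth", {
  cfg <- benchmark_config(image_side = 256, fine_grid = 128, WL = 64)
  # zero traction: identical images pre-noise
  cfg0 <- cfg; cfg0$tp <- 0; cfg0$snr_db <- Inf
  b0 <- build_benchmark(cfg0, seed = 5)
  expect_equal(b0$pair$ref, b0$pair$session)
  # default: displacement maxima co-located with islands on the truth grid
  cfgq <- benchmark_config(image_side = 512, fine_grid = 128, WL = 64)
  b <- build_benchmark(cfgq, seed = 5)
  um <- sqrt(b$truth$ux^2 + b$truth$uy^2)
  tm <- sqrt(b$truth$tx^2 + b$truth$ty^2)
  expect_equal(arrayInd(which.max(um), dim(um)),
               arrayInd(which.max(tm), dim(tm)))
  # same seed reproduces, different seeds differ, truth unchanged
  b2 <- build_benchmark(cfgq, seed = 5)
  expect_identical(b$pair$ref, b2$pair$ref)
  b3 <- build_benchmark(cfgq, seed = 6)
  expect_false(identical(b$pair$ref, b3$pair$ref))
  expect_equal(b$truth$tx, b3$truth$tx)
})
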