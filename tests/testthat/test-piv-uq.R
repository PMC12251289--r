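test_that("bootstrap resampling blacks out unsampled pixels consistently", {
  set.seed(5)
  w <- matrix(runif(16 * 16), 16)               # never zero
  pert <- bootstrap_window_pair(w, w * 2, paired = TRUE)
  # mask semantics: sampled pixels keep their value, unsampled become 0,
  # and with pairing the same mask applies to both windows
  expect_true(all(pert$ref == 0 | pert$ref == w))
  expect_equal(pert$session, 2 * pert$ref)
  expect_gt(sum(pert$ref == 0), 0)

  # expected unsampled fraction approaches 1/e
  fracs <- replicate(2000, {
    p <- bootstrap_window_pair(w, w)
    mean(p$ref == 0)
  })
  expect_equal(mean(fracs), (1 - 1 / 256)^256, tolerance = 0.01)
  expect_equal(mean(fracs), exp(-1), tolerance = 0.02)

  # determinism under a fixed seed
  set.seed(99); a <- bootstrap_window_pair(w, w)
  set.seed(99); b <- bootstrap_window_pair(w, w)
  expect_identical(a, b)

  # counts variant weights pixels by their multiplicity
  set.seed(1)
  pc <- bootstrap_window_pair(w, w * 2, weight_mode = "counts", paired = TRUE)
  counts <- matrix(round(pc$ref / w), 16)
  expect_true(all(counts >= 0))
  expect_equal(sum(counts), 256)                # one draw per pixel
  expect_equal(pc$ref, w * counts)

  # the default resamples each window independently
  set.seed(2)
  pu <- bootstrap_window_pair(w, w)
  expect_false(identical(pu$ref == 0, pu$session == 0))
})

test_that("bootstrap draws concentrate for clean translations and disperse for noise", {
  set.seed(6)
  shape <- c(64, 64)
  beads <- generate_bead_field(shape, 2e-2)
  ref <- render_beads(beads, shape)
  sess <- render_beads(apply_displacement(beads, displacement_uniform(c(3, 1)),
                                          shape), shape)
  draws <- bootstrap_distribution(ref, sess, 40)
  cv <- cluster_validate(draws, eps = 32 / 5, minpts = 4, WS = 32)
  expect_true(cv$valid)
  expect_lt(abs(mean(cv$draws[, 1]) - 3), 0.5)
  expect_lt(sd(cv$draws[, 1]), 1)               # floor-level spread

  # pure-noise windows under independent resampling: dispersed draw set
  noise1 <- matrix(runif(64 * 64) * 1000, 64)
  noise2 <- matrix(runif(64 * 64) * 1000, 64)
  dn <- bootstrap_distribution(noise1, noise2, 40, paired = FALSE)
  expect_gt(sd(dn[, 1], na.rm = TRUE), 1)
  # paired resampling on bright featureless windows locks onto the shared
  # sparsity pattern at zero lag (a documented limitation of the paired
  # perturbation for background-dominated content)
  dp <- bootstrap_distribution(noise1, noise2, 40, paired = TRUE)
  expect_lt(max(abs(dp), na.rm = TRUE), 1)
})

test_that("cluster validation applies the 20% window-spacing rule", {
  WS <- 32
  set.seed(8)
  tight <- cbind(rnorm(40, 0, 0.05), rnorm(40, 0, 0.05))
  cv <- cluster_validate(tight, eps = WS / 5, minpts = 4, WS = WS)
  expect_true(cv$valid)
  expect_gte(nrow(cv$draws), 38)

  # two clusters separated by 0.5 WS: invalid (multimodal)
  far <- rbind(tight, cbind(rnorm(20, 0.5 * WS + 1, 0.05), rnorm(20, 0, 0.05)))
  cv2 <- cluster_validate(far, eps = WS / 5, minpts = 4, WS = WS)
  expect_false(cv2$valid)

  # two clusters separated by 0.1 WS: still valid, largest cluster kept
  near <- rbind(tight, cbind(rnorm(15, 0.1 * WS, 0.02), rnorm(15, 3, 0.02)))
  cv3 <- cluster_validate(near, eps = 1, minpts = 4, WS = WS)
  expect_true(cv3$valid)
  expect_equal(nrow(cv3$draws), 40)

  # no cluster at all: invalid
  spread <- cbind(runif(20, -50, 50), runif(20, -50, 50))
  cv4 <- cluster_validate(spread, eps = 0.5, minpts = 5, WS = WS)
  expect_false(cv4$valid)
})

test_that("DBSCAN labels match a reference implementation on crafted sets", {
  # two well separated blobs plus isolated noise
  set.seed(10)
  pts <- rbind(cbind(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1)),
               cbind(rnorm(20, 5, 0.1), rnorm(20, 5, 0.1)),
               c(50, 50))
  lab <- dbscan_cluster(pts, eps = 1, minpts = 5)
  expect_equal(max(lab), 2)
  expect_equal(lab[41], 0)                     # far point is noise
  expect_length(unique(lab[1:20]), 1)
  expect_length(unique(lab[21:40]), 1)
  # points all within eps form one cluster when minpts is met
  one <- cbind(runif(10), runif(10))
  expect_equal(unique(dbscan_cluster(one, eps = 5, minpts = 3)), 1L)
  # minpts larger than n: everything is noise
  expect_equal(unique(dbscan_cluster(one, eps = 5, minpts = 20)), 0L)
})

test_that("run_piv_uq produces uniform sigma maps for uniform fields and fills bad windows", {
  pair <- make_uniform_pair(side = 256, snr_db = 30, seed = 12)
  res <- run_piv_uq(pair, piv_config(64), piv_uq_config(n_B = 25), seed = 1)
  s <- res$uncertainty$sigma_total
  # spatial uniformity: the bulk of the map is flat (isolated windows can
  # hit the split-cluster floor, so use robust statistics) and there is no
  # systematic left-right trend
  expect_lt(IQR(s) / median(s), 0.5)
  expect_lt(abs(median(s[, 1:3]) - median(s[, 5:7])), 0.3 * median(s))
  expect_true(all(s >= 0))

  # a featureless (signal-free) stripe invalidates windows; sigma gets the
  # 5x-max fill and displacement the median of neighbours
  set.seed(13)
  shape <- c(192, 192)
  dens <- function(x) ifelse(x > 128, 0, 1.5e-2)
  beads <- generate_bead_field(shape, dens)
  ref <- render_beads(beads, shape)
  sess <- render_beads(apply_displacement(beads, displacement_uniform(c(2, 0)),
                                          shape), shape)
  # noise only where there is signal and a hard-zero stripe (beyond any
  # bead tail), so the stripe's windows are flagged degenerate
  noisy <- function(img, sd) {
    img[, 1:128] <- pmin(pmax(img[, 1:128] +
                                matrix(rnorm(192 * 128, sd = sd), 192), 0), 1000)
    img[, 129:192] <- 0
    img
  }
  pr <- image_pair(noisy(ref, 10), noisy(sess, 10), 1)
  res2 <- run_piv_uq(pr, piv_config(64), piv_uq_config(n_B = 25), seed = 4)
  expect_true(any(!res2$uncertainty$valid))
  bad <- !res2$uncertainty$valid
  fmax <- max(res2$uncertainty$sigma_ux[!bad])
  expect_true(all(res2$uncertainty$sigma_ux[bad] == 5 * fmax))
  # median fill keeps the filled vectors near the valid consensus
  expect_lt(max(abs(res2$field$ux[bad] - 2)), 1)

  # determinism: identical seeds give identical sigma maps
  res3 <- run_piv_uq(pair, piv_config(64), piv_uq_config(n_B = 10), seed = 7)
  res4 <- run_piv_uq(pair, piv_config(64), piv_uq_config(n_B = 10), seed = 7)
  expect_identical(res3$uncertainty$sigma_total, res4$uncertainty$sigma_total)
})

test_that("circular standard deviation follows sqrt(-2 ln Rbar)", {
  # all vectors aligned: zero angular spread
  expect_equal(circular_sd(rep(1, 10), rep(0, 10)), 0)
  # two opposite vectors: Rbar = 0 -> large
  expect_gt(circular_sd(c(1, -1), c(0, 0)), 10)
  # known mixture: half at 0, half at 90 degrees -> Rbar = sqrt(2)/2
  v <- circular_sd(c(1, 0), c(0, 1))
  expect_equal(v, sqrt(-2 * log(sqrt(2) / 2)))
})

test_that("CoV convergence diagnostic decreases with the bootstrap size", {
  pair <- make_uniform_pair(side = 128, snr_db = 20, seed = 20)
  tab <- cov_convergence(pair, piv_config(64), n_B_list = c(5, 40),
                         repeats = 3, seed = 2)
  expect_true(all(is.finite(tab$median_cov)))
  expect_lt(tab$median_cov[2], tab$median_cov[1])
})
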