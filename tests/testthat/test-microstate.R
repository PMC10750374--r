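# microstate module: GFP, peaks, spatial correlation, AAHC, modified
# k-means, model selection.

test_that("gfp evaluates the spatial-SD formula", {
  expect_equal(gfp(matrix(0, 4, 1))$values, 0)
  expect_equal(gfp(matrix(c(1, -1, 1, -1), 4, 1))$values, 1)
  expect_equal(gfp(matrix(c(2, 0, 0, 0), 4, 1))$values, sqrt(0.75),
               tolerance = 1e-9)
  # reference independence: adding a common offset changes nothing
  set.seed(1)
  x <- matrix(rnorm(8 * 50), 8)
  expect_equal(gfp(x)$values, gfp(x + 3)$values, tolerance = 1e-9)
})

test_that("find_gfp_peaks: interior maxima, separation rule, determinism", {
  expect_identical(find_gfp_peaks(1:10, 0), integer(0))
  expect_identical(find_gfp_peaks(c(0, 1, 0, 2, 0), 0), c(2L, 4L))
  # separation: of two close maxima, the larger survives
  v <- c(0, 5, 0, 9, 0, 0, 0, 0, 0, 0, 0, 3, 0)
  expect_identical(find_gfp_peaks(v, min_separation_ms = 4, fs_hz = 1000),
                   c(4L, 12L))
  # rectified 5 Hz envelope over 10 s: 100 maxima (+/- 2)
  cfg <- gen_config(fs_hz = 512, length_s = 10, envelope_freq_hz = 5)
  env <- mstateri:::gfp_envelope(cfg)
  pk <- find_gfp_peaks(env, min_separation_ms = 10, fs_hz = 512)
  expect_true(abs(length(pk) - 100) <= 2)
})

test_that("spatial correlation: identity, polarity, orthogonality, errors", {
  u <- c(1, -2, 3, -4)
  expect_equal(spatial_correlation(u, u), 1)
  expect_equal(spatial_correlation(u, -u), 1)
  expect_equal(spatial_correlation(u, -u, ignore_polarity = FALSE), -1)
  expect_equal(spatial_correlation(c(1, -1, 0, 0), c(0, 0, 1, -1)), 0)
  expect_error(spatial_correlation(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(spatial_correlation(1:3, 1:4), "equal length")
})

test_that("AAHC recovers exact template copies, with and without sign flips", {
  m <- montage_1020(60)
  tpl <- generate_templates(m, 4, seed = 3)
  copies <- tpl$maps[, rep(1:4, each = 10)]
  out <- aahc_cluster(copies, 4)
  expect_equal(sort(apply(abs(stats::cor(out$maps, tpl$maps)), 2, max)),
               rep(1, 4), tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(4)
  flipped <- copies * rep(sample(c(-1, 1), 40, replace = TRUE), each = 60)
  out2 <- aahc_cluster(flipped, 4)
  expect_equal(out2$maps, out$maps, tolerance = 1e-9)
  expect_equal(out2$explained_variance, 1, tolerance = 1e-9)
  expect_error(aahc_cluster(copies, 50), "exceeds")
})

test_that("AAHC recovers generative templates from an SNR~4 render", {
  qr <- quick_render(seed = 21, n_ch = 60, fs = 256, length_s = 30)
  pm <- mstateri:::peak_maps_of(qr$rec, 10)
  out <- aahc_cluster(pm$maps, 4)
  r <- apply(abs(stats::cor(out$maps, qr$templates$maps)), 2, max)
  expect_true(all(r >= 0.95))
})

test_that("modified k-means: recovery, seed determinism, AAHC agreement", {
  m <- montage_1020(60)
  tpl <- generate_templates(m, 4, seed = 5)
  copies <- tpl$maps[, rep(1:4, each = 5)]
  km <- modified_kmeans(copies, 4, n_restarts = 3, seed = 1)
  expect_equal(sort(apply(abs(stats::cor(km$maps, tpl$maps)), 2, max)),
               rep(1, 4), tolerance = 1e-9, ignore_attr = TRUE)
  km2 <- modified_kmeans(copies, 4, n_restarts = 3, seed = 1)
  expect_identical(km$maps, km2$maps)

  qr <- quick_render(seed = 22, n_ch = 60, fs = 256, length_s = 30)
  pm <- mstateri:::peak_maps_of(qr$rec, 10)
  a <- aahc_cluster(pm$maps, 4)
  k <- modified_kmeans(pm$maps, 4, n_restarts = 5, seed = 2)
  agree <- apply(abs(stats::cor(a$maps, k$maps)), 1, max)
  expect_true(all(agree >= 0.90))
})

test_that("choose_k: selects 4 on 4-template data, flags noise, validates", {
  ok <- 0
  for (s in 1:3) {
    qr <- quick_render(seed = 30 + s, n_ch = 60, fs = 256, length_s = 20)
    pm <- mstateri:::peak_maps_of(qr$rec, 10, max_maps = 300)
    ck <- choose_k(pm$maps, 2:8)
    if (ck$k == 4 && !ck$low_confidence) ok <- ok + 1
  }
  expect_gte(ok, 2)
  # pure-noise maps: no dominant KL peak most of the time
  flagged <- 0
  for (s in 1:8) {
    set.seed(400 + s)
    wn <- matrix(rnorm(60 * 150), 60)
    flagged <- flagged + choose_k(wn, 2:8)$low_confidence
  }
  expect_gte(flagged, 5)
  expect_error(choose_k(matrix(rnorm(60 * 50), 60), k_range = 4),
               "at least 2")
})
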