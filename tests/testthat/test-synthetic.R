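# synthetic_data module: montage, templates, state sequences, rendering,
# study generation.

test_that("montage_1020 gives unique unit-norm positions", {
  for (n in c(19, 60, 33)) {
    m <- montage_1020(n)
    expect_equal(m$n_channels, n)
    expect_false(anyDuplicated(m$channel_names) > 0)
    expect_equal(sqrt(rowSums(m$positions^2)), rep(1, n),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(montage_1020(1), "between 2 and 60")
  expect_error(new_montage(c("A", "A"), diag(3)[1:2, ]), "unique")
})

test_that("generate_templates: deterministic, orthogonal, unit GFP", {
  m <- montage_1020(60)
  t1 <- generate_templates(m, 4, seed = 1)
  t2 <- generate_templates(m, 4, seed = 1)
  expect_identical(t1$maps, t2$maps)
  # all 6 pairwise spatial correlations
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lte(spatial_correlation(t1$maps[, i], t1$maps[, j]), 0.3)
  }
  expect_equal(colMeans(t1$maps), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sqrt(colMeans(t1$maps^2)), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("generate_templates: k = 2 on a 3-channel montage is orthogonal", {
  # zero-mean maps on n channels span n-1 dimensions, so the smallest
  # montage carrying two orthogonal maps has 3 channels
  m <- montage_1020(3)
  tp <- generate_templates(m, 2, seed = 4)
  expect_equal(spatial_correlation(tp$maps[, 1], tp$maps[, 2]), 0,
               tolerance = 1e-9)
  expect_error(generate_templates(m, 3), "n_channels")
  expect_error(generate_templates(montage_1020(10), 1), "k must be >= 2")
})

test_that("state sequences: mean dwell, no self-succession, determinism", {
  cfg <- gen_config(mean_durations_ms = rep(80, 4), fs_hz = 512,
                    length_s = 60, seed = 11)
  lab <- sample_state_sequence(cfg)
  runs <- lab$runs
  lens_ms <- (runs$end - runs$start + 1) * 1000 / 512
  expect_lt(abs(mean(lens_ms) - 80) / 80, 0.10)
  expect_true(all(diff(runs$state) != 0))
  expect_identical(lab$labels, sample_state_sequence(cfg)$labels)
  # run table tiles the recording exactly
  expect_identical(runs$start[1], 1L)
  expect_identical(runs$end[nrow(runs)], length(lab$labels))
  expect_true(all(runs$start[-1] == runs$end[-nrow(runs)] + 1L))
})

test_that("a state with 10x mean duration dominates coverage", {
  cfg <- gen_config(mean_durations_ms = c(500, 50, 50, 50), fs_hz = 256,
                    length_s = 60, seed = 3)
  lab <- sample_state_sequence(cfg)
  cov <- vapply(1:4, function(s) {
    sum(lab$runs$end[lab$runs$state == s] -
          lab$runs$start[lab$runs$state == s] + 1)
  }, 0) / length(lab$labels)
  expect_equal(sum(cov), 1, tolerance = 1e-9)
  expect_identical(which.max(cov), 1L)
})

test_that("render_eeg: noise-free frames equal the active template", {
  m <- montage_1020(19)
  tpl <- generate_templates(m, 4, seed = 2)
  cfg <- gen_config(noise_sd_uv = 0, fs_hz = 256, length_s = 4, seed = 5)
  lab <- sample_state_sequence(cfg)
  rec <- render_eeg(lab, tpl, cfg)
  idx <- seq(1, ncol(rec$data), by = 97)
  for (i in idx) {
    expect_equal(spatial_correlation(rec$data[, i], tpl$maps[, lab$labels[i]]),
                 1, tolerance = 1e-9)
  }
  env <- mstateri:::gfp_envelope(cfg, ncol(rec$data))
  expect_equal(gfp(rec)$values, env, tolerance = 1e-9)
  # mismatched template/label alphabets
  tpl3 <- generate_templates(m, 3, seed = 2)
  expect_error(render_eeg(lab, tpl3, cfg), "alphabet")
})

test_that("an alpha2 oscillation raises alpha2 power and only alpha2", {
  m <- montage_1020(19)
  tpl <- generate_templates(m, 4, seed = 2)
  base <- gen_config(fs_hz = 256, length_s = 30, seed = 8)
  with_osc <- gen_config(fs_hz = 256, length_s = 30, seed = 8,
                         oscillations = list(alpha2 = list(
                           low_hz = 10.5, high_hz = 12.5, amplitude_uv = 8)))
  lab <- sample_state_sequence(base)
  bp0 <- band_power(welch_psd(render_eeg(lab, tpl, base)))
  bp1 <- band_power(welch_psd(render_eeg(lab, tpl, with_osc)))
  diff <- bp1$whole_brain - bp0$whole_brain
  expect_gt(diff[["alpha2"]], 1)
  expect_lt(max(abs(diff[setdiff(names(diff), "alpha2")])), 0.5)
})

test_that("generate_study: schema, determinism, manifest validation", {
  man <- study_manifest(n_per_group = 1, seed = 2)
  # 1 subject per group x 2 groups x 3 conditions = 6 recordings
  st <- generate_study(man, gen_config(fs_hz = 128, length_s = 4, seed = 1),
                       montage = montage_1020(19))
  expect_length(st$recordings, 6)
  st2 <- generate_study(man, gen_config(fs_hz = 128, length_s = 4, seed = 1),
                        montage = montage_1020(19))
  expect_identical(st$recordings[[1]]$data, st2$recordings[[1]]$data)
  # scores respect instrument ranges
  expect_true(all(man$subjects$RI_intensity >= -5 &
                    man$subjects$RI_intensity <= 5))
  bad <- man
  bad$subjects <- rbind(man$subjects, man$subjects[1, ])
  expect_error(generate_study(structure(bad, class = "ms_manifest"),
                              gen_config(fs_hz = 128, length_s = 4)),
               "duplicate")
})

test_that("ground-truth coverages sum to 1 for every study recording", {
  man <- study_manifest(n_per_group = 2, seed = 3)
  st <- generate_study(man, gen_config(fs_hz = 128, length_s = 4, seed = 9),
                       montage = montage_1020(19))
  for (rec in st$recordings) {
    gt <- attr(rec, "ground_truth")
    lens <- gt$labels$runs$end - gt$labels$runs$start + 1
    expect_equal(sum(lens) / length(gt$labels$labels), 1, tolerance = 1e-9)
  }
})

test_that("write_study round-trips through EDF and manifest", {
  man <- study_manifest(n_per_group = 1, seed = 4)
  st <- generate_study(man, gen_config(fs_hz = 128, length_s = 3, seed = 2),
                       montage = montage_1020(19))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  mf <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(mf), 6)
  rec0 <- st$recordings[[1]]
  back <- read_recording(file.path(dir, mf$path[1]), st$montage)
  step <- max(apply(rec0$data, 1, function(v) diff(range(v)))) / 65535
  expect_lt(max(abs(back$data - rec0$data)), step + 1e-12)
  expect_true(dir.exists(file.path(dir, "truth")))
})
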