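still_config <- function(...) {
  scene_config(
    duration = 4, image_size = c(48L, 48L),
    pulse_amplitude = 0, noise_sigma = 0,
    illumination = list(amplitude = 0, freq = 0.1, ramp = 0, flicker = 0),
    motion = list(
      translation_px = 0, period_s = 5, rotation_deg = 0,
      rotation_period_s = 7, jitter_px = 0
    ),
    unstable_region = FALSE, ...
  )
}

test_that("with no time-varying term every frame is identical", {
  sc <- generate_scene(still_config(seed = 2))
  arr <- sc$frames$frames
  for (t in seq(2, dim(arr)[4], by = 17)) {
    expect_identical(arr[, , , t], arr[, , , 1])
  }
})

test_that("identical config and seed give bit-identical output", {
  cfg <- scene_config(duration = 4, image_size = c(48L, 48L), seed = 42)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_identical(a$truth$landmark_track, b$truth$landmark_track)
  # a different seed changes the noise realization
  cfg2 <- scene_config(duration = 4, image_size = c(48L, 48L), seed = 43)
  expect_false(identical(generate_scene(cfg2)$frames$frames, a$frames$frames))
})

test_that("the mean skin green trace peaks at hr/60 Hz (spectral fidelity)", {
  for (seed in 1:3) {
    cfg <- scene_config(
      hr_bpm = 72, duration = 30, seed = seed, noise_sigma = 0
    )
    sc <- generate_scene(cfg)
    arr <- sc$frames$frames
    tr <- vapply(seq_len(dim(arr)[4]), function(t) {
      mean(arr[, , 2, t][sc$truth$skin_mask[, , t]])
    }, numeric(1))
    d <- tr - stats::filter(tr, rep(1 / 151, 151), sides = 2)
    d[is.na(d)] <- 0
    ps <- welch_psd(as.numeric(d), 30)
    ib <- ps$freq >= 0.7 & ps$freq <= 4
    peak <- ps$freq[ib][which.max(ps$power[ib])]
    expect_lt(abs(peak - 1.2), 1 / 30) # within one voting bin
    # cross-check against the stored pulse waveform
    pp <- welch_psd(sc$truth$pulse, 30)
    expect_lt(abs(pp$freq[which.max(pp$power)] - 1.2), 1 / 30)
  }
})

test_that("landmarks move rigidly: pairwise distances are preserved", {
  cfg <- scene_config(
    duration = 4, image_size = c(48L, 48L), seed = 3,
    unstable_region = FALSE,
    motion = list(
      translation_px = 3, period_s = 2, rotation_deg = 4,
      rotation_period_s = 3, jitter_px = 0.5
    )
  )
  sc <- generate_scene(cfg)
  lm <- sc$truth$landmark_track
  d1 <- dist(lm[, , 1])
  for (t in c(40, 80, 120)) {
    expect_equal(as.numeric(dist(lm[, , t])), as.numeric(d1), tolerance = 1e-9)
  }
  # translation actually happens
  ctr <- apply(lm[, 1, ], 2, mean)
  expect_gt(diff(range(ctr)), 2)
})

test_that("occluder chromaticity lies outside the skin cluster's 3-sigma ellipse", {
  sc <- shared_scene()
  cfg <- sc$truth$config
  arr <- sc$frames$frames
  # glasses pixels: probe around the eye landmarks on frame 1
  lm <- sc$truth$landmark_track[, , 1]
  for (e in c(9, 10)) {
    x <- round(lm[e, 1])
    y <- round(lm[e, 2])
    px <- arr[y + 1, x + 1, , 1]
    ch <- rgb_to_cbcr(px[1], px[2], px[3])
    z2 <- sum(((c(ch) - cfg$skin_chroma_mean) / cfg$skin_chroma_sd)^2)
    expect_gt(z2, 9)
    expect_false(sc$truth$skin_mask[y + 1, x + 1, 1])
  }
})

test_that("unstable triangles are the ones incident to the oscillating nose", {
  sc <- shared_scene()
  expect_equal(
    which(!sc$truth$stability_labels),
    which(apply(sc$truth$mesh$triangles == 11, 1, any))
  )
  expect_true(any(!sc$truth$stability_labels))
  expect_gt(sum(sc$truth$stability_labels), sum(!sc$truth$stability_labels))
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config(hr_bpm = 300), "\\[42, 240\\]")
  expect_error(scene_config(hr_bpm = 240, frame_rate = 7), "Nyquist")
  expect_error(scene_config(duration = 1, frame_rate = 30), "too short")
})

test_that("skin training set matches its configuration", {
  ts <- generate_skin_training_set(seed = 12)
  expect_length(ts$images, 78)
  expect_length(ts$masks, 78)
  # masked chromaticity mean within 2*sigma/sqrt(n) of the configured mean
  cbs <- crs <- c()
  for (i in 1:78) {
    img <- ts$images[[i]]
    msk <- as.logical(ts$masks[[i]])
    ch <- rgb_to_cbcr(img[, , 1], img[, , 2], img[, , 3])
    cbs <- c(cbs, ch[msk, 1])
    crs <- c(crs, ch[msk, 2])
  }
  n <- length(cbs)
  expect_lt(abs(mean(cbs) - 110), 2 * 3 / sqrt(n) + 0.5) # +0.5 quantization
  expect_lt(abs(mean(crs) - 152), 2 * 3 / sqrt(n) + 0.5)
})

test_that("a near-zero chroma variance puts all skin pixels in one bin", {
  # chroma mean centered inside a 4-wide bin so 8-bit rounding stays put
  ts <- generate_skin_training_set(
    n_images = 3, chroma_mean = c(110, 150),
    chroma_cov = diag(c(1e-8, 1e-8)), seed = 5
  )
  bins <- c()
  for (i in 1:3) {
    img <- ts$images[[i]]
    msk <- as.logical(ts$masks[[i]])
    ch <- rgb_to_cbcr(img[, , 1], img[, , 2], img[, , 3])
    bins <- c(bins, rppgpatch:::chroma_bin(ch[msk, 1], ch[msk, 2], 64))
  }
  expect_equal(length(unique(bins)), 1L)
})

test_that("a degenerate chroma covariance errors", {
  expect_error(
    generate_skin_training_set(chroma_cov = matrix(c(9, 9, 9, 9), 2)),
    "degenerate covariance"
  )
  expect_error(
    generate_skin_training_set(chroma_cov = diag(c(9, -1))),
    "degenerate covariance"
  )
})
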