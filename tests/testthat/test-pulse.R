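tone_trace <- function(f, n = 900, fs = 30, amp = 1, noise = 0, seed = 1) {
  set.seed(seed)
  amp * sin(2 * pi * f * (seq_len(n) - 1) / fs) + rnorm(n, 0, noise)
}

test_that("traces are per-frame green means over the patch pixels", {
  arr <- array(0L, dim = c(8, 8, 3, 5))
  for (t in 1:5) arr[, , 2, t] <- 10L * t
  fs <- frame_stack(arr, 30)
  gp <- grid_patches(c(8, 8), 5, nx = 2, ny = 2)
  tr <- extract_traces(fs, gp)
  expect_length(tr, 4)
  expect_equal(tr[[1]]$values, c(10, 20, 30, 40, 50))
  expect_length(tr[[1]]$values, 5) # trace length == frame count
  expect_error(extract_traces(fs, gp, kept = 1L), "at least 2")
})

test_that("a planted pulse is recovered in the patch trace at zero noise", {
  sc <- quick_scene(
    hr_bpm = 72, seed = 4, duration = 15, noise_sigma = 0,
    illumination = list(amplitude = 0, freq = 0.1, ramp = 0, flicker = 0),
    motion = list(
      translation_px = 0, period_s = 5, rotation_deg = 0,
      rotation_period_s = 7, jitter_px = 0
    ),
    occluders = character(), unstable_region = FALSE
  )
  pt <- track_patches(sc$truth$landmark_track, sc$frames$size)
  # central patches only (clearly inside the face)
  counts <- colSums(pt$counts)
  kept <- order(counts, decreasing = TRUE)[1:2]
  tr <- extract_traces(sc$frames, pt, kept = kept)
  fs <- sc$frames$frame_rate
  for (x in tr) {
    d <- preprocess_trace(x$values, fs)
    expect_gt(abs(cor(d, sc$truth$pulse)), 0.95)
  }
})

test_that("the hypothesis votes the in-band peak and respects band limits", {
  s1 <- tone_trace(1.2)
  s2 <- tone_trace(0.2, seed = 2, noise = 0.05)
  hyp <- hypothesis_from_pair(rbind(s1, s2), fs = 30)
  expect_false(hyp$abstained)
  expect_lt(abs(hyp$bin_center - 1.2), 1 / 30)

  # 0.5 Hz is out of band: the 1.5 Hz tone must win even if weaker
  mix <- tone_trace(0.5, amp = 3) + tone_trace(1.5, amp = 1)
  hyp2 <- hypothesis_from_pair(rbind(mix, tone_trace(1.5, amp = 1, noise = 0.1, seed = 3)),
    fs = 30
  )
  expect_false(hyp2$abstained)
  expect_lt(abs(hyp2$bin_center - 1.5), 1 / 30)
})

test_that("white-noise-only components abstain at the calibrated floor", {
  set.seed(33)
  abst <- replicate(100, {
    s <- rbind(rnorm(900), rnorm(900))
    hypothesis_from_pair(s, fs = 30)$abstained
  })
  expect_gte(mean(abst), 0.95)
})

test_that("two traces give exactly one pair and its bin", {
  tr <- lapply(1:2, function(i) {
    structure(
      list(
        patch_id = i,
        values = tone_trace(1.5, noise = 0.2, seed = i) +
          tone_trace(0.1, amp = 2, seed = i + 10),
        frame_rate = 30
      ),
      class = "raw_trace"
    )
  })
  est <- estimate_hr(tr, seed = 5)
  expect_equal(est$n_pairs, 1L)
  expect_equal(est$hr_bpm, 90, tolerance = 1.1)
  expect_error(estimate_hr(tr[1]), "at least 2")
})

test_that("vote ties break toward the larger summed peak power", {
  expect_equal(rppgpatch:::tally_votes(c(3, 3, 1), c(5, 9, 2)), 2L)
  expect_equal(rppgpatch:::tally_votes(c(3, 3, 1), c(9, 5, 2)), 1L)
  expect_equal(rppgpatch:::tally_votes(c(0, 4, 4), c(0, 1, 1.5)), 3L)
})

test_that("estimates are reproducible for a fixed seed", {
  set.seed(99)
  tr <- lapply(1:5, function(i) {
    structure(
      list(
        patch_id = i,
        values = tone_trace(1.3, noise = 0.5, seed = i),
        frame_rate = 30
      ),
      class = "raw_trace"
    )
  })
  a <- estimate_hr(tr, n_pairs = 6, seed = 2)
  b <- estimate_hr(tr, n_pairs = 6, seed = 2)
  expect_identical(a$hr_bpm, b$hr_bpm)
  expect_identical(a$votes, b$votes)
})

test_that("all-noise trace sets raise the no-pulse error", {
  set.seed(7)
  tr <- lapply(1:3, function(i) {
    structure(
      list(patch_id = i, values = rnorm(900), frame_rate = 30),
      class = "raw_trace"
    )
  })
  expect_error(estimate_hr(tr, seed = 1), "no pulse found")
})

test_that("majority voting survives corruption of 30% of the traces", {
  sc <- shared_scene()
  pt <- shared_patches()
  est0 <- estimate_hr_video(
    sc$frames, sc$truth$landmark_track, shared_skin_model(), seed = 11
  )
  kept <- which(est0$selection$kept)
  traces <- extract_traces(sc$frames, pt, kept = kept)
  set.seed(55)
  for (rep in 1:5) {
    corrupted <- traces
    idx <- sample(length(corrupted), max(1, round(0.3 * length(corrupted))))
    for (i in idx) {
      corrupted[[i]]$values <- rnorm(length(corrupted[[i]]$values), 128, 20)
    }
    est <- estimate_hr(corrupted, seed = 100 + rep)
    expect_lt(abs(est$hr_bpm - est0$hr_bpm), 2.1)
  }
})

test_that("estimation error degrades monotonically with noise on average", {
  sigmas <- c(0, 8, 40, 120)
  errs <- c()
  lvls <- c()
  for (s in seq_along(sigmas)) {
    for (seed in 1:3) {
      sc <- quick_scene(
        hr_bpm = 84, seed = 200 + seed, duration = 15,
        noise_sigma = sigmas[s]
      )
      e <- tryCatch(
        abs(estimate_hr_video(
          sc$frames, sc$truth$landmark_track, shared_skin_model(),
          seed = 11
        )$hr_bpm - 84),
        error = function(e) 60 # abstention at extreme noise counts as failure
      )
      errs <- c(errs, e)
      lvls <- c(lvls, sigmas[s])
    }
  }
  rho <- suppressWarnings(cor(lvls, errs, method = "spearman"))
  if (is.na(rho)) rho <- 0 # all errors equal
  expect_gte(rho, 0)
})
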