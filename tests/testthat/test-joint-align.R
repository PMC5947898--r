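test_that("Hausdorff distance is symmetric and matches a hand case", {
  a <- rbind(c(0, 0), c(1, 0))
  b <- rbind(c(0, 0), c(0, 3))
  # furthest-from-nearest: point (0,3) is 3 from (0,0), sqrt(10) from (1,0)
  expect_equal(hausdorff_distance(a, b), 3)
  expect_equal(hausdorff_distance(b, a), 3)
  expect_equal(hausdorff_distance(a, a), 0)
})

test_that("a single cluster returns the coordinate-wise average", {
  base <- face_template("frontal") * 10
  shapes <- lapply(1:6, function(i) sweep(base, 2, c(i, -i), `+`))
  m <- cluster_representative_shapes(shapes, 1, normalize = FALSE)
  expect_length(m, 1)
  want <- Reduce(`+`, shapes) / 6
  expect_equal(as.numeric(m[[1]]), as.numeric(want), tolerance = 1e-8)
})

test_that("two well-separated shape families are recovered exactly", {
  set.seed(41)
  fam_a <- face_template("left") * 10
  fam_b <- face_template("right") * 10
  shapes <- c(
    lapply(1:5, function(i) fam_a + matrix(rnorm(30, 0, 0.05), ncol = 2)),
    lapply(1:5, function(i) fam_b + matrix(rnorm(30, 0, 0.05), ncol = 2))
  )
  m <- cluster_representative_shapes(shapes, 2, normalize = FALSE)
  # exhaustive check on <= 10 shapes: each representative sits near one
  # family mean and far from the other
  d <- outer(m, list(fam_a, fam_b), Vectorize(hausdorff_distance))
  expect_equal(sort(apply(d, 1, which.min)), 1:2)
  expect_true(all(apply(d, 1, min) < 0.1))
  expect_true(all(apply(d, 1, max) > 1))
})

test_that("three pose families give three representative shapes", {
  dat <- cascade_training_data()
  shapes <- lapply(dat$pos, function(s) s$shape / (CASCADE_SIDE - 1))
  m <- cluster_representative_shapes(shapes, 3, normalize = FALSE)
  expect_length(m, 3)
  # the three inner-landmark x centroids are ordered left / frontal / right
  xs <- sort(vapply(m, function(s) mean(s[9:13, 1]), numeric(1)))
  expect_gt(xs[2] - xs[1], 0.04)
  expect_gt(xs[3] - xs[2], 0.04)
})

test_that("shape-indexed features difference pixels relative to landmarks", {
  img0 <- matrix(7, 9, 9)
  spec <- data.frame(a1 = 1, dx1 = 2, dy1 = 0, a2 = 1, dx2 = -2, dy2 = 1)
  sh <- matrix(c(4, 4), 1)
  expect_equal(extract_features(img0, sh, spec), 0) # constant image

  # 3x3 ramp image I(x, y) = x + 10 * y, shape point at center (1,1)
  ramp <- outer(0:2, 0:2, function(y, x) x + 10 * y)
  spec2 <- data.frame(
    a1 = c(1, 1), dx1 = c(1, 0), dy1 = c(0, 1),
    a2 = c(1, 1), dx2 = c(-1, 0), dy2 = c(0, -1)
  )
  sh2 <- matrix(c(1, 1), 1)
  # feature 1: I(2,1) - I(0,1) = 2; feature 2: I(1,2) - I(1,0) = 20
  expect_equal(extract_features(ramp, sh2, spec2), c(2, 20))

  # translation invariance: same content shifted with its window
  big <- matrix(rnorm(400), 20, 20)
  spec3 <- random_feature_spec(1, 10, radius = 3, seed = 2)
  f1 <- extract_features(big, matrix(c(5, 5), 1), spec3,
    origin = c(0, 0), window_side = 12
  )
  f2 <- extract_features(big, matrix(c(5, 5), 1), spec3,
    origin = c(6, 4), window_side = 12
  )
  g1 <- big[1:12, 1:12]
  f1b <- extract_features(g1, matrix(c(5, 5), 1), spec3, window_side = 12)
  expect_identical(f1, f1b)
  expect_false(identical(f1, f2)) # different content scores differently

  expect_error(extract_features(big, matrix(c(5, 5), 1), spec3[0, ]), "empty")
})

test_that("a linearly separable toy passes all positives, rejects negatives", {
  set.seed(3)
  # windows whose left half is brighter than the right are positives
  mk <- function(bright_left) {
    img <- matrix(runif(256, 0, 40), 16, 16)
    if (bright_left) img[, 1:8] <- img[, 1:8] + 120 else img[, 9:16] <- img[, 9:16] + 120
    list(image = img, shape = matrix(c(8, 8), 1))
  }
  pos <- lapply(1:25, function(i) mk(TRUE))
  neg <- lapply(1:25, function(i) mk(FALSE))
  model <- train_cascade(pos, neg,
    config = list(n_stages = 3, depth = 1, n_feature_subset = 20, n_pose = 1, radius = 8)
  )
  pass_pos <- vapply(pos, function(s) cascade_score(model, s$image, s$shape)$survived, logical(1))
  pass_neg <- vapply(neg, function(s) cascade_score(model, s$image, s$shape)$survived, logical(1))
  expect_equal(mean(pass_pos), 1)
  expect_gte(mean(!pass_neg), 0.9)
})

test_that("a one-tree depth-1 cascade is a single feature threshold", {
  set.seed(4)
  mk <- function(hi) {
    img <- matrix(runif(64, 0, 20) + if (hi) 100 else 0, 8, 8)
    img[5:8, ] <- 10 # constant lower half as the reference pixel
    list(image = img, shape = matrix(c(4, 4), 1))
  }
  pos <- lapply(1:10, function(i) mk(TRUE))
  neg <- lapply(1:10, function(i) mk(FALSE))
  model <- train_cascade(pos, neg,
    config = list(n_stages = 1, depth = 1, n_feature_subset = 5, n_pose = 1, radius = 4)
  )
  expect_length(model$stages, 1)
  scores <- vapply(
    c(pos, neg),
    function(s) cascade_score(model, s$image, s$shape)$total, numeric(1)
  )
  expect_lte(length(unique(round(scores, 10))), 2) # two leaves only
})

test_that("rejection happens at the first stage whose threshold is missed", {
  model <- shared_cascade_model()
  dat <- cascade_training_data()
  # a background window: recompute the stagewise contract by hand
  g <- generate_face_frame("frontal", c(48L, 48L), center = c(300, 300), seed = 5000)
  cs <- cascade_score(model, g$gray, dat$pos[[1]]$shape,
    origin = c(8, 8), window_side = 32
  )
  fv <- extract_features(g$gray, dat$pos[[1]]$shape, model$spec,
    origin = c(8, 8), window_side = 32, ref_side = model$ref_side
  )
  names(fv) <- paste0("f", seq_along(fv))
  cum <- 0
  manual <- NA_integer_
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    cum <- cum + predict(st$tree, as.data.frame(as.list(fv[st$feat_ids])),
      type = "prob"
    )[, "1"]
    if (is.na(manual) && cum < st$threshold - 1e-12) manual <- i
  }
  expect_equal(cs$rejected_at, manual)
  expect_false(cs$survived)
})

test_that("detection returns nothing on a featureless frame", {
  model <- shared_cascade_model()
  expect_null(detect_face(matrix(0, 64, 64), model))
})

test_that("every window is scored against all three representative shapes", {
  model <- shared_cascade_model()
  g <- plant_face(901)
  det <- detect_face(g$gray, model, plant_scan)
  expect_false(is.null(det))
  wins <- enumerate_windows(c(72, 72), plant_scan)
  expect_equal(det$n_candidates, nrow(wins) * 3L)
})

test_that("detect matches the brute-force argmax over surviving combinations", {
  model <- shared_cascade_model()
  # a coarse scan keeps the instance small (<= 20 windows)
  scan <- list(min_side = 36, max_side = 44, stride_frac = 0.45, scales_per_octave = 3)
  for (seed in c(911, 912, 913)) {
    g <- plant_face(seed)
    wins <- enumerate_windows(c(72, 72), scan)
    expect_lte(nrow(wins), 20)
    best <- NULL
    for (r in seq_len(nrow(wins))) {
      for (p in seq_along(model$shapes)) {
        sh <- model$shapes[[p]] * (wins$side[r] - 1)
        cs <- cascade_score(model, g$gray, sh,
          origin = c(wins$x[r], wins$y[r]), window_side = wins$side[r]
        )
        if (!cs$survived) next
        better <- is.null(best) ||
          cs$total > best$total + 1e-12 ||
          (abs(cs$total - best$total) <= 1e-12 && wins$side[r]^2 < best$area)
        if (better) {
          best <- list(
            total = cs$total, area = wins$side[r]^2,
            box = c(wins$x[r], wins$y[r], wins$side[r]), pose = p
          )
        }
      }
    }
    det <- detect_face(g$gray, model, scan)
    if (is.null(best)) {
      expect_null(det)
    } else {
      expect_equal(unname(det$box), as.numeric(best$box))
      expect_equal(det$pose, best$pose)
      expect_equal(det$score, best$total, tolerance = 1e-10)
    }
  }
})

test_that("planted faces are found with IoU >= 0.5", {
  model <- shared_cascade_model()
  hits <- vapply(1:5, function(k) {
    g <- plant_face(2400 + k)
    det <- detect_face(g$gray, model, plant_scan)
    if (is.null(det)) return(0)
    box_iou(det$box, g$box)
  }, numeric(1))
  expect_gte(mean(hits >= 0.5), 0.8)
})

test_that("the refiner is identity when absent and validates K", {
  sh <- face_template("frontal") * 10 + 20
  img <- matrix(0, 48, 48)
  expect_identical(refine_shape(img, c(4, 4, 40), sh, NULL), sh)
  dat <- cascade_training_data()
  refiner <- train_shape_refiner(
    images = lapply(dat$pos[1:12], `[[`, "image"),
    true_shapes = lapply(dat$pos[1:12], `[[`, "shape"),
    init_shapes = lapply(dat$pos[1:12], function(s) s$shape + 2),
    boxes = rep(list(c(0, 0, 32)), 12),
    config = list(n_stages = 2, n_features = 60)
  )
  expect_error(
    refine_shape(img, c(0, 0, 32), sh[1:10, ], refiner),
    "trained for K"
  )
})

test_that("refinement reduces the error of perturbed initial shapes", {
  dat <- cascade_training_data()
  set.seed(71)
  n <- 60
  imgs <- lapply(dat$pos[1:n], `[[`, "image")
  truth <- lapply(dat$pos[1:n], `[[`, "shape")
  perturb <- function(s, seed) {
    set.seed(seed)
    s + matrix(rnorm(2, 0, 2.2), nrow(s), 2, byrow = TRUE) +
      matrix(rnorm(length(s), 0, 0.7), ncol = 2)
  }
  inits <- lapply(1:n, function(i) perturb(truth[[i]], i))
  boxes <- rep(list(c(0, 0, 32)), n)
  tr_id <- 1:40
  te_id <- 41:60
  refiner <- train_shape_refiner(imgs[tr_id], truth[tr_id], inits[tr_id],
    boxes[tr_id],
    config = list(n_stages = 3, n_features = 120, seed = 6)
  )
  err <- function(pred, true) alignment_error(pred, true)
  e0 <- e1 <- c()
  for (i in te_id) {
    e0 <- c(e0, err(inits[[i]], truth[[i]]))
    out <- refine_shape(imgs[[i]], c(0, 0, 32), inits[[i]], refiner)
    e1 <- c(e1, err(out, truth[[i]]))
  }
  expect_lt(mean(e1), mean(e0)) # strictly reduces held-out error
})

test_that("alignment error normalizes by the inter-ocular distance", {
  truth <- face_template("frontal") * 20
  pred <- truth + 1 # uniform 1px x and y shift: distance sqrt(2) each
  iod <- sqrt(sum((truth[9, ] - truth[10, ])^2))
  expect_equal(alignment_error(pred, truth), sqrt(2) / iod)
})
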