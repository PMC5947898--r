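# Detector training harness: synthetic faces at three poses in 48x48
# frames, 32-px training windows, and four negative families (background,
# off-face crops, grossly mismatched shapes, wrong-pose shapes).

CASCADE_SIDE <- 32L

make_face_frame48 <- function(i, pose) {
  generate_face_frame(
    pose = pose, image_size = c(48L, 48L),
    center = c(23.5, 23.5), scale = (CASCADE_SIDE / 2.5) * stats::runif(1, 0.9, 1.1),
    angle = stats::runif(1, -0.08, 0.08), seed = i
  )
}

crop_window48 <- function(g, x0, y0, side = CASCADE_SIDE) {
  x0 <- max(0, min(48 - side, x0))
  y0 <- max(0, min(48 - side, y0))
  list(
    image = g$gray[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side)],
    origin = c(x0, y0)
  )
}

cascade_training_data <- function() {
  if (!is.null(.fixtures$cascade_data)) {
    return(.fixtures$cascade_data)
  }
  set.seed(5)
  side <- CASCADE_SIDE
  poses <- rep(c("frontal", "left", "right"), each = 60)
  fulls <- lapply(seq_along(poses), function(i) make_face_frame48(i, poses[i]))
  pos <- lapply(seq_along(poses), function(i) {
    g <- fulls[[i]]
    x0 <- round(g$box[1] + (g$box[3] - side) / 2)
    y0 <- round(g$box[2] + (g$box[3] - side) / 2)
    cr <- crop_window48(g, x0 + sample(-3:3, 1), y0 + sample(-3:3, 1))
    list(image = cr$image, shape = sweep(g$landmarks, 2, cr$origin), pose = poses[i])
  })
  rnd_pos_shape <- function() pos[[sample(length(pos), 1)]]$shape
  neg <- c(
    lapply(1:80, function(i) { # pure background
      g <- generate_face_frame("frontal", c(48L, 48L),
        center = c(300, 300), seed = 1000 + i
      )
      cr <- crop_window48(g, sample(0:16, 1), sample(0:16, 1))
      list(image = cr$image, shape = rnd_pos_shape())
    }),
    lapply(1:120, function(i) { # off-face crops, near and far
      g <- fulls[[(i %% length(fulls)) + 1]]
      off <- sample(c(-16, -12, -9, 9, 12, 16), 2, replace = TRUE)
      cr <- crop_window48(g, round(g$box[1]) + off[1], round(g$box[2]) + off[2])
      list(image = cr$image, shape = rnd_pos_shape())
    }),
    lapply(1:80, function(i) { # aligned window, grossly mismatched shape
      sh <- rnd_pos_shape()
      mode <- i %% 3
      sh <- if (mode == 0) sh * 0.6 + side * 0.45 else
        if (mode == 1) sweep(sh, 2, c(side * 0.35, -side * 0.2), `+`) else
        sh * 1.45 - side * 0.2
      list(image = pos[[(i %% length(pos)) + 1]]$image, shape = sh)
    }),
    lapply(1:120, function(i) { # face with a wrong-pose shape
      j <- (i %% length(pos)) + 1
      other <- which(poses != poses[j])
      list(image = pos[[j]]$image, shape = pos[[sample(other, 1)]]$shape)
    })
  )
  .fixtures$cascade_data <- list(pos = pos, neg = neg, poses = poses)
  .fixtures$cascade_data
}

shared_cascade_model <- function() {
  if (is.null(.fixtures$cascade_model)) {
    dat <- cascade_training_data()
    spec <- rbind(
      random_feature_spec(15L, 150L, radius = CASCADE_SIDE / 4, seed = 21),
      random_feature_spec(15L, 50L, radius = CASCADE_SIDE / 8, seed = 22)
    )
    .fixtures$cascade_model <- train_cascade(
      dat$pos, dat$neg,
      spec = spec,
      config = list(
        seed = 2, depth = 2L, n_feature_subset = 32L,
        n_stages = 25L, pass_rate = 0.997
      )
    )
  }
  .fixtures$cascade_model
}

# plant a face in a 72x72 frame; returns frame, truth box and landmarks
plant_face <- function(seed, poses = c("frontal", "left", "right")) {
  set.seed(seed)
  pose <- sample(poses, 1)
  sc <- stats::runif(1, 12, 14.5)
  ctr <- c(stats::runif(1, 28, 44), stats::runif(1, 28, 44))
  g <- generate_face_frame(pose, c(72L, 72L), center = ctr, scale = sc, seed = seed)
  g$pose <- pose
  g
}

plant_scan <- list(
  min_side = 28, max_side = 44, stride_frac = 0.15, scales_per_octave = 6
)
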