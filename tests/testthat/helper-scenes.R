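# Shared fixtures, built once per test session and memoized.

.fixtures <- new.env(parent = emptyenv())

shared_skin_model <- function() {
  if (is.null(.fixtures$skin_model)) {
    ts <- generate_skin_training_set(seed = 3)
    .fixtures$skin_training <- ts
    .fixtures$skin_model <- train_skin_model(ts$images, ts$masks)
  }
  .fixtures$skin_model
}

shared_skin_training <- function() {
  shared_skin_model()
  .fixtures$skin_training
}

# the stock 30-s scene used by several suites
shared_scene <- function() {
  if (is.null(.fixtures$scene)) {
    .fixtures$scene <- generate_scene(scene_config(hr_bpm = 72, seed = 7))
  }
  .fixtures$scene
}

shared_patches <- function() {
  if (is.null(.fixtures$patches)) {
    sc <- shared_scene()
    .fixtures$patches <- track_patches(sc$truth$landmark_track, sc$frames$size)
  }
  .fixtures$patches
}

# a short clip for cheaper property tests
quick_scene <- function(hr_bpm = 72, seed = 1, duration = 15, ...) {
  generate_scene(scene_config(
    hr_bpm = hr_bpm, seed = seed, duration = duration, ...
  ))
}

# intersection-over-union of two square boxes c(x, y, side)
box_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[3], b[2] + b[3]) - max(a[2], b[2]))
  ix * iy / (a[3]^2 + b[3]^2 - ix * iy)
}
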