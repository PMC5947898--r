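#' Synthetic facial-scene configuration
#'
#' Describes a synthetic facial video whose pixel intensities follow the
#' additive reflectance decomposition
#' `P(x, y, t) = base(x, y) + alpha(x, y) p(t) + beta(x, y) w(t) + noise`:
#' a location-weighted pulse component `p(t)` (fundamental at
#' `hr_bpm / 60` Hz plus a 0.3-amplitude first harmonic, so harmonic SNR
#' terms are exercisable), a location-weighted illumination component
#' `w(t)` (slow sinusoid plus linear ramp, below the heart-rate band), and
#' per-pixel Gaussian camera noise. `alpha` is zero on non-skin pixels.
#' The rendered face carries eyes and a mouth, optional non-skin occluders
#' ("glasses", "beard") whose chromaticity lies far outside the skin
#' cluster, and, when `unstable_region` is on, a nose-tip landmark that
#' oscillates laterally with an attached skin-toned shadow blob — the
#' triangles incident to it periodically change area, emulating
#' self-occlusion under head motion.
#'
#' @param frame_rate frames per second.
#' @param duration clip length in seconds (`frame_rate * duration >= 64`).
#' @param image_size `c(width, height)` in pixels.
#' @param hr_bpm true heart rate, beats per minute, in `[42, 240]`;
#'   `frame_rate` must exceed twice `hr_bpm / 60` (Nyquist).
#' @param pulse_amplitude pulse strength as a fraction of the local mean
#'   skin intensity (blood-volume change is a few percent).
#' @param illumination list: `amplitude` (fraction of base intensity),
#'   `freq` (Hz, default 0.1, below the 0.7 Hz band edge), `ramp`
#'   (fractional linear drift over the clip), and `flicker`, the fractional
#'   amplitude of a weak in-band screen-flicker component (a few random
#'   sinusoids between 0.9 and 3.5 Hz) that illuminates face and
#'   background alike, as when a subject faces a flashing screen.
#' @param motion list: `translation_px`, `period_s`, `rotation_deg`,
#'   `rotation_period_s` for the slow rigid head motion, plus `jitter_px`,
#'   the RMS of a band-limited (about 0-4 Hz) random translation tremor.
#'   Landmarks follow the full motion, so landmark-tracked patches see
#'   almost none of it, while any patch fixed in frame coordinates sweeps
#'   across image structure and picks up in-band tracking artifacts.
#' @param face_scale_frac face half-width as a fraction of the short frame
#'   side (0.25 leaves a realistic margin of background around the face).
#' @param occluders character subset of `c("glasses", "beard")`.
#' @param unstable_region logical; add the oscillating nose region.
#' @param unstable_freq oscillation frequency in Hz, or `NULL` to draw one
#'   from 1.4-2.6 Hz using the seed.
#' @param unstable_amp_px lateral oscillation amplitude of the nose tip.
#' @param noise_sigma per-pixel Gaussian noise standard deviation (8-bit
#'   levels).
#' @param skin_chroma_mean,skin_chroma_sd center and spread of the skin
#'   Cb-Cr cluster.
#' @param landmark_jitter_sd additive Gaussian jitter on every landmark
#'   (non-rigid motion / alignment error), in pixels.
#' @param seed integer; all randomness in the scene derives from it.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(frame_rate = 30, duration = 30,
                         image_size = c(64L, 64L), hr_bpm = 72,
                         pulse_amplitude = 0.02,
                         illumination = list(
                           amplitude = 0.04, freq = 0.1, ramp = 0.02,
                           flicker = 0.012
                         ),
                         motion = list(
                           translation_px = 2, period_s = 5,
                           rotation_deg = 2, rotation_period_s = 7,
                           jitter_px = 0.7
                         ),
                         face_scale_frac = 0.25,
                         occluders = c("glasses", "beard"),
                         unstable_region = TRUE,
                         unstable_freq = NULL, unstable_amp_px = 3.5,
                         noise_sigma = 2,
                         skin_chroma_mean = c(cb = 110, cr = 152),
                         skin_chroma_sd = c(3, 3),
                         landmark_jitter_sd = 0,
                         seed = 1L) {
  if (hr_bpm < 42 || hr_bpm > 240) {
    stop("hr_bpm must lie in [42, 240]")
  }
  if (frame_rate <= 2 * hr_bpm / 60) {
    stop("Nyquist violation: frame_rate must exceed 2 * hr_bpm / 60")
  }
  if (duration * frame_rate < 64) {
    stop("clip too short for spectral estimation: need at least 64 frames")
  }
  stopifnot(length(image_size) == 2L, all(image_size >= 32L))
  structure(
    list(
      frame_rate = frame_rate, duration = duration,
      image_size = as.integer(image_size), hr_bpm = hr_bpm,
      pulse_amplitude = pulse_amplitude, illumination = illumination,
      motion = motion, occluders = occluders,
      face_scale_frac = face_scale_frac,
      unstable_region = isTRUE(unstable_region),
      unstable_freq = unstable_freq, unstable_amp_px = unstable_amp_px,
      noise_sigma = noise_sigma,
      skin_chroma_mean = unname(skin_chroma_mean),
      skin_chroma_sd = unname(skin_chroma_sd),
      landmark_jitter_sd = landmark_jitter_sd,
      seed = as.integer(seed)
    ),
    class = "scene_config"
  )
}

#' The 15-landmark face template
#'
#' Landmark layout used by the synthetic scenes, in face units (x right,
#' y down, chin toward +y): points 1-8 on the face boundary, 9/10 the
#' left/right eyes, 11 the nose tip, 12/13 the mouth corners, 14 the
#' forehead, 15 the chin. For the side poses the inner features shift
#' and compress horizontally, as under yaw.
#'
#' @param pose `"frontal"`, `"left"` or `"right"`.
#' @return 15 x 2 coordinate matrix.
#' @export
face_template <- function(pose = c("frontal", "left", "right")) {
  pose <- match.arg(pose)
  ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
  boundary <- cbind(0.95 * cos(ang), 1.19 * sin(ang))
  inner <- rbind(
    c(-0.45, -0.35), c(0.45, -0.35), # eyes
    c(0.00, 0.15), # nose tip
    c(-0.40, 0.60), c(0.40, 0.60), # mouth corners
    c(0.00, -0.75), # forehead
    c(0.00, 0.85) # chin
  )
  if (pose != "frontal") {
    shift <- if (pose == "left") -0.2 else 0.2
    inner[, 1L] <- inner[, 1L] * 0.7 + shift
  }
  rbind(boundary, inner)
}

NOSE_ID <- 11L
EYE_IDS <- c(9L, 10L)

# Render one frame. u, v are face-unit coordinate matrices for the pixel
# grid; tmpl is the (possibly oscillated) landmark template in face units.
render_face_fields <- function(u, v, tmpl, cfg, nose_blob = FALSE,
                               blob_ctr = NULL) {
  inside <- u^2 + (v / 1.25)^2 <= 1
  ybase <- 155 + 20 * u - 12 * v - 10 * (u^2 + (v / 1.25)^2)
  cbm <- cfg$skin_chroma_mean[1L]
  crm <- cfg$skin_chroma_mean[2L]
  cb <- cbm + 1.5 * sin(4 * u) + 1.0 * cos(3 * v)
  cr <- crm + 1.2 * cos(4 * u) - 1.0 * sin(3 * v)

  occluded <- matrix(FALSE, nrow(u), ncol(u))
  feat <- matrix(FALSE, nrow(u), ncol(u))

  draw <- function(mask, yv, cbv, crv) {
    ybase[mask] <<- yv
    cb[mask] <<- cbv
    cr[mask] <<- crv
  }
  # facial features follow the landmarks
  for (e in EYE_IDS) {
    m <- inside & ((u - tmpl[e, 1L])^2 + (v - tmpl[e, 2L])^2 <= 0.09^2)
    draw(m, 50, 128, 128)
    feat <- feat | m
  }
  mc <- colMeans(tmpl[12:13, , drop = FALSE])
  mw <- abs(tmpl[13L, 1L] - tmpl[12L, 1L]) / 2
  m <- inside & (((u - mc[1L]) / mw)^2 + ((v - mc[2L]) / 0.07)^2 <= 1)
  draw(m, 90, 112, 162)
  feat <- feat | m

  if ("beard" %in% cfg$occluders) {
    m <- inside & v >= 0.55 &
      !(((u - mc[1L]) / (mw * 1.15))^2 + ((v - mc[2L]) / 0.1)^2 <= 1)
    draw(m, 55, 118, 135)
    occluded <- occluded | m
  }
  if ("glasses" %in% cfg$occluders) {
    for (e in EYE_IDS) {
      m <- abs(u - tmpl[e, 1L]) <= 0.26 & abs(v - tmpl[e, 2L]) <= 0.17
      draw(m, 60, 128, 128)
      occluded <- occluded | m
    }
  }
  if (nose_blob) {
    if (is.null(blob_ctr)) blob_ctr <- tmpl[NOSE_ID, ]
    m <- inside &
      ((u - blob_ctr[1L])^2 + ((v - blob_ctr[2L]) / 1.2)^2 <= 0.2^2)
    # skin-toned shadow: dark but inside the chroma cluster
    draw(m, 95, cbm, crm)
  }
  skin <- inside & !occluded & !feat
  list(ybase = ybase, cb = cb, cr = cr, inside = inside, skin = skin)
}

#' Generate a synthetic facial video with known embedded pulse
#'
#' Renders the scene described by a [scene_config()]: the face undergoes
#' the configured rigid motion, skin pixels carry the pulse component
#' `alpha(x, y) p(t)`, every pixel carries the illumination component
#' `beta(x, y) w(t)` plus Gaussian noise, and the result is quantized to
#' 8 bits. Identical `config` (including `seed`) gives bit-identical
#' output.
#'
#' @param config a [scene_config()].
#' @return list with `frames` (a [frame_stack()]) and `truth`, a
#'   `scene_truth` list carrying `hr_bpm`, the pulse waveform `pulse`,
#'   `landmark_track` (K x 2 x T), per-frame logical `skin_mask`
#'   (occluders excluded), the first-frame Delaunay `mesh`, per-triangle
#'   `stability_labels` (`FALSE` = flagged unstable), and the oscillation
#'   frequency `unstable_freq_hz`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  set.seed(config$seed)

  w <- config$image_size[1L]
  h <- config$image_size[2L]
  n_t <- round(config$frame_rate * config$duration)
  tt <- (seq_len(n_t) - 1L) / config$frame_rate
  f0 <- config$hr_bpm / 60

  pulse <- sin(2 * pi * f0 * tt) + 0.3 * sin(4 * pi * f0 * tt + 0.9)
  il <- config$illumination
  wsig <- sin(2 * pi * il$freq * tt + stats::runif(1L, 0, 2 * pi)) +
    il$ramp / max(il$amplitude, 1e-9) * (2 * tt / max(tt[n_t], 1e-9) - 1)
  flicker_amp <- if (is.null(il$flicker)) 0 else il$flicker
  flick <- numeric(n_t)
  if (flicker_amp > 0) {
    ff <- stats::runif(3L, 0.9, 3.5)
    fp <- stats::runif(3L, 0, 2 * pi)
    for (q in 1:3) flick <- flick + sin(2 * pi * ff[q] * tt + fp[q]) / sqrt(3)
  }

  # the nose tip orbits a small circle while its shadow counter-orbits:
  # every incident triangle both changes area (flagging it unstable) and
  # sees the shadow move relative to it (corrupting its trace), as under
  # genuine self-occlusion
  f_occ <- config$unstable_freq
  if (is.null(f_occ)) f_occ <- stats::runif(1L, 1.4, 2.6)
  osc_x <- 0.5 * config$unstable_amp_px * cos(2 * pi * f_occ * tt)
  osc_y <- 0.5 * config$unstable_amp_px * sin(2 * pi * f_occ * tt)

  mo <- config$motion
  theta <- pi / 180 * mo$rotation_deg * sin(2 * pi * tt / max(mo$rotation_period_s, 1e-9))
  tx <- mo$translation_px * sin(2 * pi * tt / max(mo$period_s, 1e-9))
  ty <- mo$translation_px * cos(2 * pi * tt / max(mo$period_s, 1e-9) + 1.1) -
    mo$translation_px * cos(1.1)
  jit_px <- if (is.null(mo$jitter_px)) 0 else mo$jitter_px
  if (jit_px > 0) {
    # band-limited tremor: smoothed white noise, rescaled to the target RMS
    ksm <- max(3L, round(config$frame_rate / 8))
    jx <- stats::filter(stats::rnorm(n_t + 2L * ksm), rep(1 / ksm, ksm), sides = 2L)
    jy <- stats::filter(stats::rnorm(n_t + 2L * ksm), rep(1 / ksm, ksm), sides = 2L)
    jx <- as.numeric(jx)[ksm + seq_len(n_t)]
    jy <- as.numeric(jy)[ksm + seq_len(n_t)]
    tx <- tx + jit_px * (jx - mean(jx)) / stats::sd(jx)
    ty <- ty + jit_px * (jy - mean(jy)) / stats::sd(jy)
  }

  scale <- config$face_scale_frac * min(w, h)
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  tmpl0 <- face_template("frontal")
  k <- nrow(tmpl0)

  # static background: smooth pseudo-random color field in frame coords
  xg <- matrix(rep(0:(w - 1L), each = h), h, w)
  yg <- matrix(rep(0:(h - 1L), times = w), h, w)
  ph <- stats::runif(6L, 0, 2 * pi)
  bg_y <- 115 + 30 * sin(2 * pi * xg / w * 1.7 + ph[1L]) * cos(2 * pi * yg / h * 1.3 + ph[2L])
  bg_cb <- 128 + 45 * sin(2 * pi * xg / w * 0.9 + ph[3L] + 2 * pi * yg / h * 0.6)
  bg_cr <- 128 + 45 * cos(2 * pi * yg / h * 1.1 + ph[4L] - 2 * pi * xg / w * 0.5)

  arr <- array(0L, dim = c(h, w, 3L, n_t))
  skin_mask <- array(FALSE, dim = c(h, w, n_t))
  lm_track <- array(NA_real_, dim = c(k, 2L, n_t))
  jit <- if (config$landmark_jitter_sd > 0) {
    array(stats::rnorm(k * 2L * n_t, 0, config$landmark_jitter_sd), c(k, 2L, n_t))
  }
  for (t in seq_len(n_t)) {
    tmpl <- tmpl0
    blob_ctr <- tmpl0[NOSE_ID, ]
    if (config$unstable_region) {
      tmpl[NOSE_ID, ] <- tmpl[NOSE_ID, ] + c(osc_x[t], osc_y[t]) / scale
      blob_ctr <- blob_ctr - c(osc_x[t], osc_y[t]) / scale
    }
    ct <- cos(theta[t])
    st <- sin(theta[t])
    # landmarks: frame = center + trans + R %*% (scale * template)
    lx <- scale * tmpl[, 1L]
    ly <- scale * tmpl[, 2L]
    lm <- cbind(cx + tx[t] + ct * lx - st * ly, cy + ty[t] + st * lx + ct * ly)
    if (!is.null(jit)) lm <- lm + jit[, , t]
    lm_track[, , t] <- lm

    # inverse map pixel grid into face units
    dx <- xg - cx - tx[t]
    dy <- yg - cy - ty[t]
    u <- (ct * dx + st * dy) / scale
    v <- (-st * dx + ct * dy) / scale
    fl <- render_face_fields(u, v, tmpl, cfg = config,
      nose_blob = config$unstable_region, blob_ctr = blob_ctr
    )

    y_img <- ifelse(fl$inside, fl$ybase, bg_y)
    cb_img <- ifelse(fl$inside, fl$cb, bg_cb)
    cr_img <- ifelse(fl$inside, fl$cr, bg_cr)

    alpha <- config$pulse_amplitude * fl$ybase * (0.75 + 0.5 * exp(-(u^2 + ((v - 0.2) / 1.1)^2)))
    alpha[!fl$skin] <- 0
    bsp <- 1 + 0.3 * ifelse(fl$inside, u, 0)
    beta <- il$amplitude * y_img * bsp
    y_img <- y_img + alpha * pulse[t] + beta * wsig[t] +
      flicker_amp * y_img * bsp * flick[t]

    rgb <- ycbcr_to_rgb(as.numeric(y_img), as.numeric(cb_img), as.numeric(cr_img))
    if (config$noise_sigma > 0) {
      rgb <- rgb + stats::rnorm(length(rgb), 0, config$noise_sigma)
    }
    rgb <- round(pmin(pmax(rgb, 0), 255))
    arr[, , 1L, t] <- rgb[, 1L]
    arr[, , 2L, t] <- rgb[, 2L]
    arr[, , 3L, t] <- rgb[, 3L]
    skin_mask[, , t] <- fl$skin
  }

  mesh <- delaunay_triangulate(lm_track[, , 1L])
  stable <- !apply(mesh$triangles == NOSE_ID, 1L, any)
  if (!config$unstable_region) stable[] <- TRUE

  truth <- structure(
    list(
      hr_bpm = config$hr_bpm, pulse = pulse, times = tt,
      illumination = wsig, flicker = flick,
      landmark_track = lm_track, skin_mask = skin_mask,
      mesh = mesh, stability_labels = stable,
      unstable_freq_hz = if (config$unstable_region) f_occ else NA_real_,
      config = config
    ),
    class = "scene_truth"
  )
  list(
    frames = frame_stack(arr, config$frame_rate),
    truth = truth
  )
}

#' Generate a synthetic skin-segmentation training set
#'
#' Emulates a collection of photographs each containing human skin and
#' background: a random disk of skin whose chromaticity is drawn from a
#' Gaussian Cb-Cr cluster, over a background whose chromaticity spreads
#' broadly. Masks mark the skin pixels.
#'
#' @param n_images number of image/mask pairs (default 78).
#' @param image_size `c(width, height)` per image.
#' @param chroma_mean length-2 Cb-Cr cluster mean.
#' @param chroma_cov 2 x 2 cluster covariance; must be symmetric positive
#'   definite (a degenerate covariance is an error).
#' @param seed integer seed.
#' @return list with `images` (list of `h x w x 3` arrays) and `masks`
#'   (list of logical matrices).
#' @export
generate_skin_training_set <- function(n_images = 78L,
                                       image_size = c(32L, 32L),
                                       chroma_mean = c(110, 152),
                                       chroma_cov = diag(c(9, 9)),
                                       seed = 1L) {
  chroma_cov <- as.matrix(chroma_cov)
  if (!isTRUE(all.equal(chroma_cov, t(chroma_cov))) ||
    any(eigen(chroma_cov, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("degenerate covariance: chroma_cov must be symmetric positive definite")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  set.seed(seed)

  ev <- eigen(chroma_cov, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(ev$values), 2L) %*% t(ev$vectors)
  w <- image_size[1L]
  h <- image_size[2L]
  xg <- matrix(rep(0:(w - 1L), each = h), h, w)
  yg <- matrix(rep(0:(h - 1L), times = w), h, w)

  images <- vector("list", n_images)
  masks <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    c0 <- c(stats::runif(1L, 0.3, 0.7) * w, stats::runif(1L, 0.3, 0.7) * h)
    r0 <- stats::runif(1L, 0.22, 0.38) * min(w, h)
    msk <- (xg - c0[1L])^2 + (yg - c0[2L])^2 <= r0^2
    n_px <- w * h
    chroma <- matrix(stats::rnorm(2L * n_px), ncol = 2L) %*% rt
    cb <- chroma[, 1L] + chroma_mean[1L]
    cr <- chroma[, 2L] + chroma_mean[2L]
    bg_cb <- stats::runif(n_px, 60, 200)
    bg_cr <- stats::runif(n_px, 60, 200)
    cb[!msk] <- bg_cb[!msk]
    cr[!msk] <- bg_cr[!msk]
    y <- stats::runif(n_px, 100, 200)
    y[!msk] <- stats::runif(sum(!msk), 40, 220)
    rgb <- ycbcr_to_rgb(y, cb, cr)
    rgb <- round(pmin(pmax(rgb, 0), 255))
    img <- array(0L, dim = c(h, w, 3L))
    img[, , 1L] <- rgb[, 1L]
    img[, , 2L] <- rgb[, 2L]
    img[, , 3L] <- rgb[, 3L]
    images[[i]] <- img
    masks[[i]] <- msk
  }
  list(images = images, masks = masks)
}

#' Render a single synthetic face frame (for detector training and tests)
#'
#' A static version of [generate_scene()]'s renderer: one frame with a face
#' of the requested pose at a given center and scale, its landmarks, and
#' the enclosing square bounding box.
#'
#' @param pose `"frontal"`, `"left"` or `"right"` (inner features shifted
#'   as under yaw).
#' @param image_size `c(width, height)`.
#' @param center face center in pixels (default frame center).
#' @param scale face half-width in pixels (default 25% of the short side).
#' @param angle in-plane rotation in radians.
#' @param noise_sigma per-pixel Gaussian noise.
#' @param occluders,seed as in [scene_config()].
#' @return list with `frame` (`h x w x 3` array), `gray` (luma matrix),
#'   `landmarks` (K x 2), `box` `c(x, y, side)`.
#' @export
generate_face_frame <- function(pose = "frontal", image_size = c(64L, 64L),
                                center = NULL, scale = NULL, angle = 0,
                                noise_sigma = 2, occluders = character(),
                                seed = 1L) {
  w <- image_size[1L]
  h <- image_size[2L]
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  if (is.null(scale)) scale <- 0.25 * min(w, h)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  set.seed(seed)

  tmpl <- face_template(pose)
  cfg <- list(
    skin_chroma_mean = c(110, 152), occluders = occluders
  )
  xg <- matrix(rep(0:(w - 1L), each = h), h, w)
  yg <- matrix(rep(0:(h - 1L), times = w), h, w)
  ph <- stats::runif(4L, 0, 2 * pi)
  bg_y <- 115 + 30 * sin(2 * pi * xg / w * 1.7 + ph[1L]) * cos(2 * pi * yg / h * 1.3 + ph[2L])
  bg_cb <- 128 + 45 * sin(2 * pi * xg / w * 0.9 + ph[3L])
  bg_cr <- 128 + 45 * cos(2 * pi * yg / h * 1.1 + ph[4L])

  ct <- cos(angle)
  st <- sin(angle)
  dx <- xg - center[1L]
  dy <- yg - center[2L]
  u <- (ct * dx + st * dy) / scale
  v <- (-st * dx + ct * dy) / scale
  fl <- render_face_fields(u, v, tmpl, cfg = cfg, nose_blob = FALSE)
  y_img <- ifelse(fl$inside, fl$ybase, bg_y)
  cb_img <- ifelse(fl$inside, fl$cb, bg_cb)
  cr_img <- ifelse(fl$inside, fl$cr, bg_cr)
  rgb <- ycbcr_to_rgb(as.numeric(y_img), as.numeric(cb_img), as.numeric(cr_img))
  if (noise_sigma > 0) rgb <- rgb + stats::rnorm(length(rgb), 0, noise_sigma)
  rgb <- round(pmin(pmax(rgb, 0), 255))
  frame <- array(0L, dim = c(h, w, 3L))
  frame[, , 1L] <- rgb[, 1L]
  frame[, , 2L] <- rgb[, 2L]
  frame[, , 3L] <- rgb[, 3L]

  lx <- scale * tmpl[, 1L]
  ly <- scale * tmpl[, 2L]
  lm <- cbind(
    center[1L] + ct * lx - st * ly,
    center[2L] + st * lx + ct * ly
  )
  side <- 2 * 1.25 * scale
  box <- c(center[1L] - side / 2, center[2L] - side / 2, side)
  list(
    frame = frame,
    gray = matrix(rgb_to_luma(rgb[, 1L], rgb[, 2L], rgb[, 3L]), h, w),
    landmarks = lm, box = box
  )
}
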