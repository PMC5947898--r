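#' Random shape-indexed feature specification
#'
#' Each feature references two pixels, each indexed by an offset in the
#' local coordinates of a facial landmark (its anchor); the feature value
#' is the intensity difference of the two pixels. Being anchored to the
#' shape makes the features pose-covariant: translating the shape with its
#' window leaves the feature vector unchanged.
#'
#' @param k number of landmarks.
#' @param n_features number of pixel-difference features.
#' @param radius maximum offset magnitude in reference-window pixels.
#' @param seed integer seed.
#' @return data.frame with columns `a1, dx1, dy1, a2, dx2, dy2`.
#' @export
random_feature_spec <- function(k, n_features = 200L, radius = 6, seed = 1L) {
  stopifnot(n_features >= 1L, k >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  set.seed(seed)
  data.frame(
    a1 = sample.int(k, n_features, replace = TRUE),
    dx1 = stats::runif(n_features, -radius, radius),
    dy1 = stats::runif(n_features, -radius, radius),
    a2 = sample.int(k, n_features, replace = TRUE),
    dx2 = stats::runif(n_features, -radius, radius),
    dy2 = stats::runif(n_features, -radius, radius)
  )
}

#' Extract shape-indexed pixel-difference features
#'
#' Reads the two referenced pixels of every feature (anchor landmark plus
#' offset, with offsets scaled by `window_side / ref_side` when scanning at
#' a size different from the training windows) and returns their signed
#' intensity differences. References falling outside the window clamp to
#' the nearest valid pixel, so shapes near borders remain scoreable.
#'
#' @param image grayscale matrix (rows = y, cols = x, 0-based pixel
#'   coordinates).
#' @param shape K x 2 landmark matrix in window-local pixels.
#' @param spec a [random_feature_spec()].
#' @param origin window top-left `c(x, y)` within `image`.
#' @param window_side window side length (default: the whole image).
#' @param ref_side training window side for offset scaling (default
#'   `window_side`).
#' @return numeric vector, one signed difference per feature.
#' @export
extract_features <- function(image, shape, spec, origin = c(0, 0),
                             window_side = NULL, ref_side = NULL) {
  if (nrow(spec) == 0L) {
    stop("empty feature specification")
  }
  h <- nrow(image)
  w <- ncol(image)
  if (is.null(window_side)) window_side <- min(w, h)
  if (is.null(ref_side)) ref_side <- window_side
  sc <- window_side / ref_side
  shape <- as.matrix(shape)

  px_at <- function(a, dx, dy) {
    x <- shape[a, 1L] + dx * sc
    y <- shape[a, 2L] + dy * sc
    # clamp to window, then to frame
    x <- pmin(pmax(x, 0), window_side - 1) + origin[1L]
    y <- pmin(pmax(y, 0), window_side - 1) + origin[2L]
    x <- pmin(pmax(round(x), 0), w - 1)
    y <- pmin(pmax(round(y), 0), h - 1)
    image[cbind(y + 1, x + 1)]
  }
  px_at(spec$a1, spec$dx1, spec$dy1) - px_at(spec$a2, spec$dx2, spec$dy2)
}

#' Train the cascaded random-forest face/shape detector
#'
#' Every training sample is a (window, shape) combination: positives pair
#' a face window with a roughly aligned shape, negatives pair any window
#' with a mismatched shape or non-face content. Each cascade stage is a
#' depth-limited decision tree over a random subset of the shape-indexed
#' features, scoring in `[0, 1]` (class probability), so cumulative scores
#' are non-decreasing and early rejection is sound. Stage thresholds are
#' set so a fraction `pass_rate` of the surviving positives pass; later
#' stages train only on survivors. Representative pose shapes (enumerated
#' at detection time) come from Hausdorff clustering of the positive
#' shapes.
#'
#' @param positives,negatives lists of `list(image, shape)`; `image` is a
#'   square grayscale window, `shape` K x 2 window-local landmarks.
#' @param config list overriding any of: `n_stages` (10), `depth` (4),
#'   `n_feature_subset` (30), `pass_rate` (0.99), `n_pose` (3),
#'   `n_features` (200), `radius` (side / 4), `seed` (1).
#' @param spec optional pre-built feature spec.
#' @return object of class `face_cascade`.
#' @export
train_cascade <- function(positives, negatives, config = list(), spec = NULL) {
  stopifnot(length(positives) >= 2L, length(negatives) >= 2L)
  side <- ncol(positives[[1L]]$image)
  k <- nrow(positives[[1L]]$shape)
  sides <- vapply(c(positives, negatives), function(s) ncol(s$image), integer(1L))
  if (!all(sides == side)) {
    stop("all training windows must be square with the same side length")
  }
  cfg <- utils::modifyList(
    list(
      n_stages = 10L, depth = 4L, n_feature_subset = 30L, pass_rate = 0.99,
      n_pose = 3L, n_features = 200L, radius = side / 4, seed = 1L
    ),
    config
  )
  if (is.null(spec)) {
    spec <- random_feature_spec(k, cfg$n_features, cfg$radius, seed = cfg$seed)
  }
  feat <- function(s) extract_features(s$image, s$shape, spec, window_side = side)
  xp <- t(vapply(positives, feat, numeric(nrow(spec))))
  xn <- t(vapply(negatives, feat, numeric(nrow(spec))))
  colnames(xp) <- colnames(xn) <- paste0("f", seq_len(nrow(spec)))

  pos_alive <- rep(TRUE, nrow(xp))
  neg_alive <- rep(TRUE, nrow(xn))
  f_pos <- numeric(nrow(xp))
  f_neg <- numeric(nrow(xn))
  stages <- list()
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  for (i in seq_len(cfg$n_stages)) {
    if (!any(neg_alive)) break
    set.seed(cfg$seed + 1000L * i)
    ids <- sort(sample.int(nrow(spec), min(cfg$n_feature_subset, nrow(spec))))
    dat <- data.frame(
      rbind(xp[pos_alive, ids, drop = FALSE], xn[neg_alive, ids, drop = FALSE])
    )
    dat$y <- factor(
      rep(c(1L, 0L), c(sum(pos_alive), sum(neg_alive))),
      levels = c(0L, 1L)
    )
    tree <- rpart::rpart(
      y ~ ., data = dat, method = "class",
      control = rpart::rpart.control(
        maxdepth = cfg$depth, minsplit = 4L, minbucket = 2L, cp = 0, xval = 0L
      )
    )
    sp <- predict(tree, data.frame(xp[, ids, drop = FALSE]), type = "prob")[, "1"]
    sn <- predict(tree, data.frame(xn[, ids, drop = FALSE]), type = "prob")[, "1"]
    f_pos <- f_pos + sp
    f_neg <- f_neg + sn
    theta <- stats::quantile(f_pos[pos_alive], 1 - cfg$pass_rate,
      type = 7, names = FALSE
    )
    pos_alive <- pos_alive & f_pos >= theta - 1e-12
    neg_alive <- neg_alive & f_neg >= theta - 1e-12
    if (!any(pos_alive)) {
      stop("cascade training failed: stage ", i, " rejects every positive")
    }
    stages[[i]] <- list(tree = tree, feat_ids = ids, threshold = theta)
  }
  # representative shapes live in window-relative coordinates (divide by the
  # window side) so their placement inside the scan window matches training
  shapes <- cluster_representative_shapes(
    lapply(positives, function(s) s$shape / (side - 1)),
    n_clusters = min(cfg$n_pose, length(positives)),
    normalize = FALSE
  )
  structure(
    list(
      stages = stages, spec = spec, ref_side = side, k = k,
      shapes = shapes, config = cfg
    ),
    class = "face_cascade"
  )
}

#' Score one (window, shape) combination through the cascade
#'
#' Evaluates the cumulative cascade sum for a single candidate, recording
#' where early rejection would occur. Used by [detect_face()] and directly
#' useful for auditing.
#'
#' @param model a [train_cascade()] model.
#' @param image grayscale frame matrix.
#' @param shape K x 2 landmarks in window-local pixels.
#' @param origin window top-left `c(x, y)` in the frame.
#' @param window_side window side (default model reference side).
#' @return list with `total` (full cascade sum), `rejected_at` (first
#'   stage whose threshold the cumulative score misses, `NA` if it
#'   survives) and `survived`.
#' @export
cascade_score <- function(model, image, shape, origin = c(0, 0),
                          window_side = NULL) {
  if (is.null(window_side)) window_side <- model$ref_side
  fv <- extract_features(image, shape, model$spec,
    origin = origin,
    window_side = window_side, ref_side = model$ref_side
  )
  names(fv) <- paste0("f", seq_along(fv))
  total <- 0
  rejected_at <- NA_integer_
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    nd <- as.data.frame(as.list(fv[st$feat_ids]))
    total <- total + predict(st$tree, nd, type = "prob")[, "1"]
    if (is.na(rejected_at) && total < st$threshold - 1e-12) {
      rejected_at <- i
    }
  }
  list(
    total = unname(total), rejected_at = rejected_at,
    survived = is.na(rejected_at)
  )
}

#' Enumerate sliding windows for detection
#'
#' Square windows at three scales per octave between `min_side` and
#' `max_side`, stride 25% of the window side, in scan order (size
#' ascending, then rows, then columns); the final row/column positions are
#' clamped so the frame edge is always covered.
#'
#' @param frame_size `c(width, height)`.
#' @param scan_config list overriding `min_side`, `max_side`,
#'   `stride_frac` (0.25), `scales_per_octave` (3).
#' @return data.frame with columns `x`, `y`, `side`.
#' @export
enumerate_windows <- function(frame_size, scan_config = list()) {
  w <- frame_size[1L]
  h <- frame_size[2L]
  sc <- utils::modifyList(
    list(
      min_side = round(0.5 * min(w, h)), max_side = min(w, h),
      stride_frac = 0.25, scales_per_octave = 3L
    ),
    scan_config
  )
  if (sc$min_side > min(w, h)) {
    stop("frame smaller than the minimum scan window")
  }
  sides <- sc$min_side
  while (TRUE) {
    nxt <- round(sides[length(sides)] * 2^(1 / sc$scales_per_octave))
    if (nxt > sc$max_side || nxt == sides[length(sides)]) break
    sides <- c(sides, nxt)
  }
  out <- lapply(sides, function(s) {
    stride <- max(1L, round(sc$stride_frac * s))
    xs <- unique(c(seq(0L, w - s, by = stride), w - s))
    ys <- unique(c(seq(0L, h - s, by = stride), h - s))
    expand.grid(x = xs, y = ys, side = s)[, c("x", "y", "side")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Joint face detection and alignment initialization
#'
#' Slides windows over the frame, scores every (window, representative
#' shape) combination through the cascade with early rejection, and
#' returns the surviving combination with the greatest cascade sum: an
#' alignment-friendly bounding box together with a rough initial shape.
#' Ties are broken by smaller window area, then scan order.
#'
#' @param frame grayscale matrix, or `h x w x 3` RGB array (converted by
#'   BT.601 luma).
#' @param model a [train_cascade()] model.
#' @param scan_config passed to [enumerate_windows()].
#' @return `NULL` when every combination is rejected, else list with
#'   `box` (`c(x, y, side)`), `shape` (K x 2 in frame pixels), `score`,
#'   `pose` (index of the winning representative shape) and `n_candidates`.
#' @export
detect_face <- function(frame, model, scan_config = list()) {
  gray <- if (length(dim(frame)) == 3L) {
    matrix(
      rgb_to_luma(
        as.numeric(frame[, , 1L]), as.numeric(frame[, , 2L]),
        as.numeric(frame[, , 3L])
      ),
      dim(frame)[1L], dim(frame)[2L]
    )
  } else {
    frame
  }
  wins <- enumerate_windows(c(ncol(gray), nrow(gray)), scan_config)
  n_shape <- length(model$shapes)
  cand <- wins[rep(seq_len(nrow(wins)), each = n_shape), ]
  cand$pose <- rep(seq_len(n_shape), times = nrow(wins))
  n <- nrow(cand)

  fmat <- matrix(0, n, nrow(model$spec))
  for (r in seq_len(n)) {
    s <- cand$side[r]
    shp <- model$shapes[[cand$pose[r]]] * (s - 1)
    fmat[r, ] <- extract_features(gray, shp, model$spec,
      origin = c(cand$x[r], cand$y[r]),
      window_side = s, ref_side = model$ref_side
    )
  }
  colnames(fmat) <- paste0("f", seq_len(ncol(fmat)))

  alive <- rep(TRUE, n)
  score <- numeric(n)
  for (st in model$stages) {
    if (!any(alive)) break
    nd <- data.frame(fmat[alive, st$feat_ids, drop = FALSE])
    score[alive] <- score[alive] + predict(st$tree, nd, type = "prob")[, "1"]
    alive <- alive & score >= st$threshold - 1e-12
  }
  if (!any(alive)) {
    return(NULL)
  }
  idx <- which(alive)
  best <- idx[order(-score[idx], cand$side[idx]^2, idx)][1L]
  s <- cand$side[best]
  shp <- model$shapes[[cand$pose[best]]] * (s - 1)
  shp <- sweep(shp, 2L, c(cand$x[best], cand$y[best]), `+`)
  list(
    box = c(x = cand$x[best], y = cand$y[best], side = s),
    shape = shp, score = score[best], pose = cand$pose[best],
    n_candidates = n
  )
}
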