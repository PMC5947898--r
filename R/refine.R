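#' Train a cascaded-regression shape refiner
#'
#' A light shape-refinement stage that takes the detector's (box, initial
#' shape) output and regresses landmark corrections from shape-indexed
#' pixel-difference features: at each stage a ridge regression maps the
#' feature vector (extracted at the current shape estimate) to a
#' box-normalized shape update. Refinement reduces the mean point error on
#' the perturbation distribution it is trained on.
#'
#' @param images list of grayscale frame matrices.
#' @param true_shapes list of K x 2 ground-truth shapes (frame pixels).
#' @param init_shapes list of K x 2 initial shapes (frame pixels).
#' @param boxes list of `c(x, y, side)` face boxes.
#' @param config list overriding `n_stages` (3), `n_features` (120),
#'   `radius` (side / 5), `ridge` (1), `seed` (1).
#' @return object of class `shape_refiner`.
#' @export
train_shape_refiner <- function(images, true_shapes, init_shapes, boxes,
                                config = list()) {
  n <- length(images)
  stopifnot(
    length(true_shapes) == n, length(init_shapes) == n, length(boxes) == n,
    n >= 4L
  )
  k <- nrow(true_shapes[[1L]])
  ref_side <- stats::median(vapply(boxes, `[`, numeric(1L), 3L))
  cfg <- utils::modifyList(
    list(
      n_stages = 3L, n_features = 120L, radius = ref_side / 5,
      ridge = 1, seed = 1L
    ),
    config
  )
  current <- init_shapes
  stages <- vector("list", cfg$n_stages)
  for (s in seq_len(cfg$n_stages)) {
    spec <- random_feature_spec(k, cfg$n_features, cfg$radius,
      seed = cfg$seed + 17L * s
    )
    x <- t(vapply(seq_len(n), function(i) {
      b <- boxes[[i]]
      extract_features(
        images[[i]], sweep(current[[i]], 2L, b[1:2]), spec,
        origin = b[1:2], window_side = b[3L], ref_side = ref_side
      )
    }, numeric(cfg$n_features)))
    x <- cbind(1, x)
    y <- t(vapply(seq_len(n), function(i) {
      as.numeric(true_shapes[[i]] - current[[i]]) / boxes[[i]][3L]
    }, numeric(2L * k)))
    xtx <- crossprod(x) + diag(cfg$ridge, ncol(x))
    w <- solve(xtx, crossprod(x, y))
    stages[[s]] <- list(spec = spec, w = w)
    current <- lapply(seq_len(n), function(i) {
      upd <- drop(x[i, ] %*% w) * boxes[[i]][3L]
      current[[i]] + matrix(upd, ncol = 2L)
    })
  }
  structure(
    list(stages = stages, k = k, ref_side = ref_side, config = cfg),
    class = "shape_refiner"
  )
}

#' Refine an initial facial shape within its bounding box
#'
#' Applies the trained cascaded regressor. With `refiner = NULL` the
#' function is the identity and returns the initial shape unchanged.
#'
#' @param frame grayscale matrix (or RGB array).
#' @param box `c(x, y, side)` face box.
#' @param shape K x 2 initial shape in frame pixels.
#' @param refiner a [train_shape_refiner()] model, or `NULL`.
#' @return K x 2 refined shape.
#' @export
refine_shape <- function(frame, box, shape, refiner = NULL) {
  if (is.null(refiner)) {
    return(shape)
  }
  if (nrow(shape) != refiner$k) {
    stop(
      "refiner was trained for K = ", refiner$k,
      " landmarks, got ", nrow(shape)
    )
  }
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
  cur <- shape
  for (st in refiner$stages) {
    fv <- extract_features(
      gray, sweep(cur, 2L, box[1:2]), st$spec,
      origin = box[1:2], window_side = box[3L], ref_side = refiner$ref_side
    )
    upd <- drop(c(1, fv) %*% st$w) * box[3L]
    cur <- cur + matrix(upd, ncol = 2L)
  }
  cur
}
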