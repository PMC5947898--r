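#' RGB to Cb-Cr chromaticity (BT.601 full range)
#'
#' Skin tones cluster tightly in the Cb-Cr plane across ethnicities while
#' background colors spread broadly, which is what makes the naive-Bayes
#' skin model work. Inputs are 8-bit RGB values; outputs are real-valued
#' Cb, Cr in `[0, 255]` (binning happens in the histogram model, not here).
#'
#' @param r,g,b numeric vectors of 8-bit channel values.
#' @return two-column matrix `cb`, `cr`.
#' @examples
#' rgb_to_cbcr(128, 128, 128) # achromatic -> (128, 128)
#' @export
rgb_to_cbcr <- function(r, g, b) {
  cb <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  cr <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  cbind(
    cb = pmin(pmax(as.numeric(cb), 0), 255),
    cr = pmin(pmax(as.numeric(cr), 0), 255)
  )
}

# full-range BT.601 luma (detector grayscale) and inverse conversion
rgb_to_luma <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

ycbcr_to_rgb <- function(y, cb, cr) {
  r <- y + 1.402 * (cr - 128)
  g <- y - 0.344136 * (cb - 128) - 0.714136 * (cr - 128)
  b <- y + 1.772 * (cb - 128)
  cbind(r = r, g = g, b = b)
}

#' Train the naive-Bayes skin-chromaticity model
#'
#' Accumulates two 2D histograms over (Cb, Cr) bins: `h_skin` counts pixels
#' under the skin masks, `h_total` counts every pixel. By Bayes' rule the
#' posterior probability of skin at a chromaticity bin reduces to
#' `h_skin / h_total` (see [skin_posterior()]).
#'
#' @param images list of `h x w x 3` arrays, 8-bit RGB.
#' @param masks list of logical matrices marking skin pixels, aligned with
#'   `images`.
#' @param bin_count bins per chroma axis; the default 64 (4-wide bins)
#'   smooths the sparse statistics of a small training set.
#' @param smoothing additive (Laplace) count added to `h_skin` and twice to
#'   `h_total` at lookup time; 0 disables smoothing so unseen bins get
#'   posterior 0.
#' @return object of class `skin_model`.
#' @export
train_skin_model <- function(images, masks, bin_count = 64L, smoothing = 0) {
  stopifnot(length(images) == length(masks), length(images) >= 1L)
  bin_count <- as.integer(bin_count)
  h_skin <- matrix(0, bin_count, bin_count)
  h_total <- matrix(0, bin_count, bin_count)
  for (i in seq_along(images)) {
    img <- images[[i]]
    msk <- as.logical(masks[[i]])
    if (length(msk) != prod(dim(img)[1:2])) {
      stop("image ", i, " and its mask have different sizes")
    }
    ch <- rgb_to_cbcr(img[, , 1L], img[, , 2L], img[, , 3L])
    bins <- chroma_bin(ch[, 1L], ch[, 2L], bin_count)
    h_total <- h_total + matrix(
      tabulate(bins, nbins = bin_count^2), bin_count, bin_count
    )
    h_skin <- h_skin + matrix(
      tabulate(bins[msk], nbins = bin_count^2), bin_count, bin_count
    )
  }
  n_skin <- sum(h_skin)
  n_total <- sum(h_total)
  if (n_skin == 0) {
    stop("training set contains no skin pixels")
  }
  structure(
    list(
      h_skin = h_skin, h_total = h_total,
      n_skin = n_skin, n_total = n_total,
      bin_count = bin_count, smoothing = smoothing
    ),
    class = "skin_model"
  )
}

# linear bin index into a bin_count x bin_count table (cb rows, cr cols)
chroma_bin <- function(cb, cr, bin_count) {
  wd <- 256 / bin_count
  i <- pmin(pmax(floor(cb / wd), 0), bin_count - 1)
  j <- pmin(pmax(floor(cr / wd), 0), bin_count - 1)
  as.integer(i + j * bin_count + 1)
}

#' Posterior probability of skin at a chromaticity
#'
#' Bayes' rule with the histogram estimates
#' `p(cb,cr | skin) = h_skin/N_skin`, `p(skin) = N_skin/N_total` and
#' `p(cb,cr) = h_total/N_total` reduces algebraically to
#' `h_skin(b) / h_total(b)`. Bins never observed in training yield 0
#' (treated as non-skin) unless the model was built with `smoothing > 0`.
#'
#' @param model a [train_skin_model()] fit.
#' @param cb,cr numeric vectors of chromaticity values.
#' @return vector of posteriors in `[0, 1]`.
#' @export
skin_posterior <- function(model, cb, cr) {
  bins <- chroma_bin(cb, cr, model$bin_count)
  hs <- model$h_skin[bins] + model$smoothing
  ht <- model$h_total[bins] + 2 * model$smoothing
  p <- ifelse(ht > 0, hs / ht, 0)
  pmin(pmax(p, 0), 1)
}

#' Skin probability map for one RGB frame
#'
#' @param frame `h x w x 3` 8-bit RGB array.
#' @param model a `skin_model`.
#' @return `h x w` matrix of skin posteriors.
#' @export
skin_probability_map <- function(frame, model) {
  ch <- rgb_to_cbcr(frame[, , 1L], frame[, , 2L], frame[, , 3L])
  matrix(
    skin_posterior(model, ch[, 1L], ch[, 2L]),
    nrow = dim(frame)[1L]
  )
}

#' Filter non-skin patches by mean skin probability
#'
#' A patch's skin score is its mean posterior over member pixels, averaged
#' over the frames where the patch is valid; patches scoring below the
#' threshold (default 0.7) are filtered out as non-skin (eyes, glasses,
#' beards, background). The score pools all frames so the kept patch set is
#' fixed for the whole clip, as the downstream ICA requires.
#'
#' @param patches a `patch_track_set`.
#' @param frames a [frame_stack()] (or bare `h x w x 3 x T` array).
#' @param model a `skin_model`.
#' @param threshold minimum mean skin probability to keep a patch.
#' @return list with `kept` (integer patch ids) and `scores` (per patch;
#'   `NA` for patches empty on every frame, which are excluded with a
#'   warning).
#' @export
filter_skin_patches <- function(patches, frames, model, threshold = 0.7) {
  arr <- frame_array(frames)
  h <- dim(arr)[1L]
  w <- dim(arr)[2L]
  n_frames <- dim(arr)[4L]
  stopifnot(n_frames == patches$n_frames)
  m <- ncol(patches$counts)

  plane <- h * w
  score_sum <- numeric(m)
  score_n <- integer(m)
  for (t in seq_len(n_frames)) {
    ch <- rgb_to_cbcr(
      as.numeric(arr[, , 1L, t]),
      as.numeric(arr[, , 2L, t]),
      as.numeric(arr[, , 3L, t])
    )
    post <- skin_posterior(model, ch[, 1L], ch[, 2L])
    px <- patches$pixels[[t]]
    for (i in seq_len(m)) {
      if (length(px[[i]])) {
        score_sum[i] <- score_sum[i] + mean(post[px[[i]]])
        score_n[i] <- score_n[i] + 1L
      }
    }
  }
  scores <- ifelse(score_n > 0L, score_sum / pmax(score_n, 1L), NA_real_)
  if (anyNA(scores)) {
    warning(sum(is.na(scores)), " patch(es) had zero pixels on all frames; excluded")
  }
  list(kept = which(!is.na(scores) & scores >= threshold), scores = scores)
}

#' Read or write a skin model as JSON
#'
#' @param model a `skin_model`.
#' @param path file path.
#' @export
write_skin_model <- function(model, path) {
  jsonlite::write_json(
    list(
      bin_count = model$bin_count, smoothing = model$smoothing,
      n_skin = model$n_skin, n_total = model$n_total,
      h_skin = model$h_skin, h_total = model$h_total
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_skin_model
#' @export
read_skin_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      h_skin = as.matrix(obj$h_skin), h_total = as.matrix(obj$h_total),
      n_skin = obj$n_skin, n_total = obj$n_total,
      bin_count = as.integer(obj$bin_count), smoothing = obj$smoothing
    ),
    class = "skin_model"
  )
}

#' @export
print.skin_model <- function(x, ...) {
  cat(
    "skin_model:", x$bin_count, "x", x$bin_count, "Cb-Cr bins;",
    x$n_skin, "skin /", x$n_total, "total training pixels\n"
  )
  invisible(x)
}
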