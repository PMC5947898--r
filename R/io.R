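#' Write a frame stack as a PNG sequence with a JSON sidecar
#'
#' Frames become `frame_000001.png`, ... plus `scene.json` holding the
#' frame rate and size.
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if needed).
#' @export
write_frames <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_frames(stack)
  for (t in seq_len(n)) {
    png::writePNG(
      stack$frames[, , , t] / 255,
      file.path(dir, sprintf("frame_%06d.png", t))
    )
  }
  jsonlite::write_json(
    list(
      frame_rate = stack$frame_rate,
      width = unname(stack$size[1L]), height = unname(stack$size[2L]),
      n_frames = n
    ),
    file.path(dir, "scene.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"))
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  stopifnot(length(files) == meta$n_frames)
  arr <- array(0L, dim = c(meta$height, meta$width, 3L, length(files)))
  for (t in seq_along(files)) {
    img <- png::readPNG(files[t])
    arr[, , , t] <- round(img[, , 1:3] * 255)
  }
  frame_stack(arr, meta$frame_rate)
}

#' Write or read a landmark track as CSV
#'
#' Long format with columns `frame`, `point_id`, `x`, `y` (0-based pixel
#' coordinates, frame and point_id 1-based).
#'
#' @param track K x 2 x T landmark array.
#' @param path CSV path.
#' @export
write_landmark_track <- function(track, path) {
  k <- dim(track)[1L]
  n <- dim(track)[3L]
  df <- data.frame(
    frame = rep(seq_len(n), each = k),
    point_id = rep(seq_len(k), times = n),
    x = as.numeric(track[, 1L, ]),
    y = as.numeric(track[, 2L, ])
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmark_track
#' @export
read_landmark_track <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame", "point_id", "x", "y") %in% names(df)))
  k <- max(df$point_id)
  n <- max(df$frame)
  arr <- array(NA_real_, dim = c(k, 2L, n))
  arr[cbind(df$point_id, 1L, df$frame)] <- df$x
  arr[cbind(df$point_id, 2L, df$frame)] <- df$y
  arr
}
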