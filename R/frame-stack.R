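#' Frame stack container
#'
#' An ordered sequence of 8-bit RGB frames at a fixed frame rate — the raw
#' observation the pipeline consumes.
#'
#' @param frames `h x w x 3 x T` array of 8-bit values (stored as integer).
#' @param frame_rate frames per second.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate) {
  stopifnot(length(dim(frames)) == 4L, dim(frames)[3L] == 3L, frame_rate > 0)
  storage.mode(frames) <- "integer"
  structure(
    list(
      frames = frames,
      frame_rate = frame_rate,
      size = c(width = dim(frames)[2L], height = dim(frames)[1L])
    ),
    class = "frame_stack"
  )
}

frame_array <- function(x) {
  if (inherits(x, "frame_stack")) x$frames else x
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(
    "frame_stack:", dim(x$frames)[4L], "frames,",
    x$size[1L], "x", x$size[2L], "px @", x$frame_rate, "fps\n"
  )
  invisible(x)
}

#' Number of frames in a stack
#' @param x a `frame_stack`.
#' @export
n_frames <- function(x) {
  dim(frame_array(x))[4L]
}
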