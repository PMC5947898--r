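#' Rasterize mesh triangles at one frame's landmark positions
#'
#' A pixel belongs to a triangle iff its center lies inside it. Pixel centers
#' sit on the integer grid (0-based, x = column, y = row). Boundaries use a
#' half-open convention (rows span `[ymin, ymax)`, row intervals span
#' `[xlo, xhi)`), so a pixel on an edge shared by two triangles is assigned
#' to exactly one of them and the patches tile the landmark hull with no
#' overlap. Pixels outside the frame are dropped; a degenerate (zero-area)
#' triangle rasterizes to the empty set.
#'
#' @param mesh a [delaunay_triangulate()] mesh.
#' @param landmarks K x 2 matrix of landmark positions for this frame.
#' @param frame_size integer `c(width, height)` in pixels.
#' @return list with `pixels` (per triangle, integer vector of column-major
#'   1-based indices into a `height x width` plane) and `counts`.
#' @export
rasterize_mesh <- function(mesh, landmarks, frame_size) {
  landmarks <- as.matrix(landmarks)
  stopifnot(nrow(landmarks) >= mesh$n_points, length(frame_size) == 2L)
  px <- lapply(seq_len(nrow(mesh$triangles)), function(i) {
    rasterize_triangle(landmarks[mesh$triangles[i, ], , drop = FALSE], frame_size)
  })
  list(pixels = px, counts = vapply(px, length, integer(1L)))
}

# Half-open scanline rasterization of one triangle (3x2 matrix of x, y).
# Returns column-major indices (x * h + y + 1) into an h x w plane.
rasterize_triangle <- function(v, frame_size) {
  w <- as.integer(frame_size[1L])
  h <- as.integer(frame_size[2L])
  area2 <- (v[2L, 1L] - v[1L, 1L]) * (v[3L, 2L] - v[1L, 2L]) -
    (v[3L, 1L] - v[1L, 1L]) * (v[2L, 2L] - v[1L, 2L])
  if (!is.finite(area2) || abs(area2) < 1e-12) {
    return(integer(0L))
  }
  y0 <- max(0, ceiling(min(v[, 2L])))
  y1 <- min(h - 1, ceiling(max(v[, 2L])) - 1)
  if (y1 < y0) {
    return(integer(0L))
  }
  yv <- y0:y1
  xlo <- rep(-Inf, length(yv))
  xhi <- rep(Inf, length(yv))
  idx <- rbind(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  for (e in 1:3) {
    p <- v[idx[e, 1L], ]
    q <- v[idx[e, 2L], ]
    r <- v[idx[e, 3L], ] # opposite vertex fixes the interior side
    nx <- q[2L] - p[2L]
    ny <- -(q[1L] - p[1L])
    cc <- nx * p[1L] + ny * p[2L]
    side <- nx * r[1L] + ny * r[2L] - cc
    if (side > 0) {
      nx <- -nx
      ny <- -ny
      cc <- -cc
    }
    # interior satisfies nx*x + ny*y <= cc; horizontal edges are implied by
    # the half-open row range and are skipped
    if (nx > 0) {
      xhi <- pmin(xhi, (cc - ny * yv) / nx)
    } else if (nx < 0) {
      xlo <- pmax(xlo, (cc - ny * yv) / nx)
    }
  }
  a <- pmax(0, ceiling(xlo))
  b <- pmin(w - 1, ceiling(xhi) - 1)
  len <- pmax(0L, as.integer(b - a + 1))
  if (sum(len) == 0L) {
    return(integer(0L))
  }
  rows <- rep.int(yv, len)
  cols <- unlist(lapply(which(len > 0L), function(i) a[i]:b[i]), use.names = FALSE)
  as.integer(cols * h + rows + 1L)
}
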