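#' Delaunay triangulation of facial landmarks
#'
#' Builds the triangular local patches used throughout the pipeline by the
#' Bowyer-Watson incremental algorithm. The Delaunay triangulation connects
#' points that are close in distance while maximizing the minimum interior
#' angle over all triangles, so patches have a "proper" aspect ratio; its
#' defining property is that no input point lies strictly inside the
#' circumcircle of any triangle, which also guarantees the patches tile the
#' convex hull of the landmarks without overlap.
#'
#' Cocircular point sets (e.g. the four corners of a square) are resolved
#' deterministically by insertion order: a point exactly on a circumcircle
#' (within relative tolerance `1e-10`) is treated as outside it.
#'
#' @param points numeric matrix with one row per landmark and columns `x`,
#'   `y` (0-based pixel convention, x = column, y = row, origin top-left).
#' @return An object of class `triangle_mesh`: a list with `triangles`
#'   (integer matrix, one row per triangle, vertex indices into `points`,
#'   each row sorted ascending and rows in lexicographic order) and
#'   `n_points`.
#' @examples
#' mesh <- delaunay_triangulate(cbind(c(0, 4, 0, 4), c(0, 0, 4, 4)))
#' mesh$triangles
#' @export
delaunay_triangulate <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) {
    stop("`points` must be a two-column (x, y) matrix")
  }
  if (nrow(points) < 3L) {
    stop("at least 3 landmarks are required for triangulation")
  }
  if (!all(is.finite(points))) {
    stop("landmark coordinates must be finite")
  }
  if (anyDuplicated(points)) {
    stop("duplicate landmark coordinates")
  }
  n <- nrow(points)
  ctr <- colMeans(points)
  dev <- sweep(points, 2L, ctr)
  if (svd(dev, nu = 0L, nv = 0L)$d[2L] < 1e-9 * max(1, svd(dev, nu = 0L, nv = 0L)$d[1L])) {
    stop("landmarks are collinear; no triangulation exists")
  }

  # super-triangle comfortably enclosing all points
  span <- max(apply(points, 2L, function(v) diff(range(v))), 1)
  big <- 50 * span
  sup <- rbind(
    ctr + big * c(0, -2),
    ctr + big * c(-2, 1.6),
    ctr + big * c(2, 1.6)
  )
  pts <- rbind(points, sup)
  sup_ids <- n + 1:3

  tri <- matrix(sup_ids, nrow = 1L) # triangle vertex ids
  cc <- matrix(0, nrow = 1L, ncol = 3L) # circumcenter x, y, r^2
  cc[1L, ] <- circumcircle(pts[sup_ids, ])

  for (ip in seq_len(n)) {
    p <- pts[ip, ]
    d2 <- (cc[, 1L] - p[1L])^2 + (cc[, 2L] - p[2L])^2
    bad <- which(d2 < cc[, 3L] * (1 - 1e-10))
    if (length(bad) == 0L) {
      # numerically on-circle everywhere; fall back to nearest circumcircle
      bad <- which.min(d2 - cc[, 3L])
    }
    # boundary polygon: edges of bad triangles not shared by two bad triangles
    edges <- do.call(rbind, lapply(bad, function(t) {
      v <- tri[t, ]
      rbind(v[c(1L, 2L)], v[c(2L, 3L)], v[c(3L, 1L)])
    }))
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    keep_edge <- !(key %in% key[duplicated(key)])
    boundary <- edges[keep_edge, , drop = FALSE]

    tri <- tri[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    new_tri <- cbind(boundary, ip)
    new_cc <- t(apply(new_tri, 1L, function(v) circumcircle(pts[v, ])))
    tri <- rbind(tri, new_tri)
    cc <- rbind(cc, new_cc)
  }

  keep <- rowSums(matrix(tri %in% sup_ids, nrow = nrow(tri))) == 0L
  tri <- tri[keep, , drop = FALSE]
  tri <- t(apply(tri, 1L, sort))
  tri <- tri[order(tri[, 1L], tri[, 2L], tri[, 3L]), , drop = FALSE]
  dimnames(tri) <- NULL
  storage.mode(tri) <- "integer"
  structure(
    list(triangles = tri, n_points = n),
    class = "triangle_mesh"
  )
}

# circumcenter (x, y) and squared radius of a triangle given as 3x2 matrix
circumcircle <- function(v) {
  ax <- v[1L, 1L]; ay <- v[1L, 2L]
  bx <- v[2L, 1L]; by <- v[2L, 2L]
  cx <- v[3L, 1L]; cy <- v[3L, 2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-300) {
    return(c(Inf, Inf, Inf))
  }
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
    (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
    (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(
    "Delaunay mesh:", nrow(x$triangles), "triangles over",
    x$n_points, "landmarks\n"
  )
  invisible(x)
}

#' Serialize a triangle mesh to JSON
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @export
write_mesh_json <- function(mesh, path) {
  jsonlite::write_json(
    list(
      n_points = mesh$n_points,
      triangles = unname(apply(mesh$triangles, 1L, identity, simplify = FALSE))
    ),
    path,
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tri <- matrix(as.integer(t(obj$triangles)), ncol = 3L, byrow = TRUE)
  structure(
    list(triangles = tri, n_points = as.integer(obj$n_points)),
    class = "triangle_mesh"
  )
}
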