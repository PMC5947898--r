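#' Symmetric Hausdorff distance between two shapes
#'
#' `max(max_a min_b d(a, b), max_b min_a d(a, b))` over the two landmark
#' point sets.
#'
#' @param a,b K x 2 coordinate matrices.
#' @export
hausdorff_distance <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1L, min))), sqrt(max(apply(d2, 2L, min))))
}

# translate + isotropically scale a shape into the unit box
normalize_shape_box <- function(s) {
  s <- as.matrix(s)
  mins <- apply(s, 2L, min)
  span <- max(apply(s, 2L, function(v) diff(range(v))), 1e-12)
  sweep(sweep(s, 2L, mins), 1L, span, `/`)
}

# similarity (Procrustes) alignment of shape s onto reference r
procrustes_align <- function(s, r) {
  s <- scale(as.matrix(s), scale = FALSE)
  r <- scale(as.matrix(r), scale = FALSE)
  sv <- svd(crossprod(s, r))
  rot <- sv$u %*% t(sv$v)
  sc <- sum(sv$d) / sum(s^2)
  sweep(sc * s %*% rot, 2L, -attr(r, "scaled:center"))
}

#' Representative pose shapes by Hausdorff clustering
#'
#' Clusters training shapes with complete-linkage agglomeration on the
#' symmetric Hausdorff distance and returns one mean shape per cluster
#' (coordinate-wise average after similarity alignment within the
#' cluster). With the default `n_clusters = 3` the clusters typically
#' correspond to left-looking, right-looking and frontal poses; the face
#' detector enumerates exactly these representative shapes per window.
#'
#' @param shapes list of K x 2 matrices (same K throughout).
#' @param n_clusters number of representative shapes.
#' @param normalize normalize each shape into the unit box first (default);
#'   returned representatives are in unit-box coordinates.
#' @return list of `n_clusters` mean shapes, each with attribute
#'   `cluster_size`.
#' @export
cluster_representative_shapes <- function(shapes, n_clusters = 3L, normalize = TRUE) {
  n <- length(shapes)
  if (n_clusters > n) {
    stop("more clusters requested than shapes available")
  }
  ks <- vapply(shapes, nrow, integer(1L))
  if (length(unique(ks)) != 1L) {
    stop("all shapes must share the same number of landmarks")
  }
  if (normalize) shapes <- lapply(shapes, normalize_shape_box)
  # cluster on centroid-centered shapes so residual placement jitter does
  # not mask the pose differences
  centered <- lapply(shapes, function(s) scale(as.matrix(s), scale = FALSE))
  if (n_clusters == n) {
    cl <- seq_len(n)
  } else if (n_clusters == 1L) {
    cl <- rep(1L, n)
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- hausdorff_distance(centered[[i]], centered[[j]])
      }
    }
    cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "complete"), k = n_clusters)
  }
  lapply(seq_len(n_clusters), function(g) {
    members <- which(cl == g)
    ref <- centered[[members[1L]]]
    aligned <- lapply(centered[members], procrustes_align, r = ref)
    m <- Reduce(`+`, aligned) / length(aligned)
    ctr <- Reduce(`+`, lapply(shapes[members], colMeans)) / length(members)
    m <- sweep(m, 2L, ctr, `+`)
    attr(m, "cluster_size") <- length(members)
    m
  })
}

#' Normalized face-alignment error
#'
#' Mean Euclidean landmark-to-groundtruth distance divided by the
#' inter-ocular distance (between the configured eye landmarks of the
#' ground truth).
#'
#' @param pred,truth K x 2 matrices.
#' @param eye_idx indices of the two eye landmarks in `truth`.
#' @export
alignment_error <- function(pred, truth, eye_idx = c(9L, 10L)) {
  pred <- as.matrix(pred)
  truth <- as.matrix(truth)
  stopifnot(all(dim(pred) == dim(truth)))
  iod <- sqrt(sum((truth[eye_idx[1L], ] - truth[eye_idx[2L], ])^2))
  mean(sqrt(rowSums((pred - truth)^2))) / iod
}
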