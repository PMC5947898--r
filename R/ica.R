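#' FastICA unmixing of a patch-pair observation
#'
#' Each pair of per-patch traces is modeled as a linear 2 x 2 mixture of the
#' pulse signal p(t) and the illumination signal w(t); FastICA recovers the
#' two sources up to sign, scale and permutation. Fixed-point iteration
#' with the logcosh contrast and deflation (Gram-Schmidt) after whitening.
#'
#' @param trace_i,trace_j numeric vectors of equal length (centered and
#'   scaled internally).
#' @param maxit,tol fixed-point iteration controls.
#' @param seed optional integer making the random initial vectors (and thus
#'   the output) reproducible; the RNG state of the caller is restored.
#' @return list with `S` (2 x T source estimates), `W` (unmixing matrix in
#'   whitened space) and `converged`; or `NULL` (with a warning) when the
#'   traces are collinear and the mixture is degenerate.
#' @export
ica_pair <- function(trace_i, trace_j, maxit = 200L, tol = 1e-8, seed = NULL) {
  stopifnot(length(trace_i) == length(trace_j), length(trace_i) >= 16L)
  x <- rbind(trace_i - mean(trace_i), trace_j - mean(trace_j))
  sds <- sqrt(rowMeans(x^2))
  if (any(sds < 1e-12)) {
    warning("constant trace in pair; skipped")
    return(NULL)
  }
  x <- x / sds
  rho <- mean(x[1L, ] * x[2L, ])
  if (abs(rho) > 1 - 1e-10) {
    warning("collinear traces; pair skipped")
    return(NULL)
  }
  cv <- tcrossprod(x) / ncol(x)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2L] < 1e-12 * eg$values[1L]) {
    warning("degenerate mixture; pair skipped")
    return(NULL)
  }
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  z <- K %*% x

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
      add = TRUE
    )
    set.seed(seed)
  }

  W <- matrix(0, 2L, 2L)
  converged <- TRUE
  for (comp in 1:2) {
    w <- stats::rnorm(2L)
    w <- w / sqrt(sum(w^2))
    ok <- FALSE
    for (it in seq_len(maxit)) {
      wz <- drop(crossprod(w, z))
      g <- tanh(wz)
      gp <- 1 - g^2
      w_new <- drop(z %*% g) / ncol(z) - mean(gp) * w
      if (comp == 2L) {
        w_new <- w_new - sum(w_new * W[1L, ]) * W[1L, ]
      }
      nw <- sqrt(sum(w_new^2))
      if (nw < 1e-12) break
      w_new <- w_new / nw
      if (abs(abs(sum(w_new * w)) - 1) < tol) {
        w <- w_new
        ok <- TRUE
        break
      }
      w <- w_new
    }
    if (!ok) converged <- FALSE
    W[comp, ] <- w
  }
  list(S = W %*% z, W = W, converged = converged)
}
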