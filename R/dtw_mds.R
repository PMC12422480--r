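#' Dynamic time warping distance between two contours
#'
#' Classic DTW with the symmetric step pattern (diagonal, horizontal and
#' vertical moves, unit weights), absolute-difference local cost and no
#' warping-window constraint. Contours are compared as given — no
#' z-normalisation — so register differences between call types are preserved.
#'
#' @param a,b numeric vectors (e.g. dominant-frequency contours in kHz).
#' @return nonnegative scalar; 0 for identical contours; symmetric in (a, b).
#' @export
dtw_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("contours must be nonempty")
  if (anyNA(a) || anyNA(b)) stop("contours must not contain NA")
  .dtw_pair(as.numeric(a), as.numeric(b))
}

#' Pairwise DTW distance matrix over a set of contours
#'
#' @param contours numeric matrix, one contour per row (equal lengths), or a
#'   list of equal-length numeric vectors.
#' @return symmetric n x n matrix with zero diagonal; row/col names taken from
#'   `contours` row names.
#' @export
dtw_distance_matrix <- function(contours) {
  if (is.list(contours)) contours <- do.call(rbind, contours)
  if (!is.matrix(contours) || ncol(contours) == 0L)
    stop("contours must form a nonempty matrix")
  if (anyNA(contours)) stop("contours must not contain NA")
  d <- .dtw_matrix(contours)
  dimnames(d) <- list(rownames(contours), rownames(contours))
  d
}

#' Classical (Torgerson) multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and returns
#' the top-`dims` eigenvector coordinates scaled by the square root of their
#' eigenvalues. Axis signs are fixed deterministically: each axis is oriented
#' so that its largest-magnitude coordinate is positive. If fewer than `dims`
#' positive eigenvalues exist, the deficient axes are zero-filled with a
#' warning.
#'
#' @param d symmetric, zero-diagonal distance matrix (n x n).
#' @param dims number of output dimensions (default 5).
#' @return n x dims coordinate matrix; columns named `mds1` ... `mds<dims>`.
#' @export
mds_embed <- function(d, dims = 5L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-8) stop("distance matrix must have a zero diagonal")
  if (n <= dims) stop("need more points (", n, ") than dimensions (", dims, ")")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2                      # symmetrise against fp drift
  eig <- eigen(B, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values[1], 0) * 1e-12)
  k <- min(dims, length(pos))
  if (k < dims)
    warning("only ", k, " positive eigenvalues; padding ", dims - k,
            " axis/axes with zeros")
  coords <- matrix(0, n, dims)
  if (k > 0) {
    v <- eig$vectors[, seq_len(k), drop = FALSE]
    coords[, seq_len(k)] <- sweep(v, 2, sqrt(eig$values[seq_len(k)]), `*`)
  }
  for (j in seq_len(dims)) {               # deterministic sign convention
    i <- which.max(abs(coords[, j]))
    if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(d), paste0("mds", seq_len(dims)))
  coords
}
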