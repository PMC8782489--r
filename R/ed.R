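#' Essential dynamics of a coordinate ensemble
#'
#' Principal component analysis of the positional covariance: frames are
#' least-squares superposed onto a shared reference (Kabsch), the covariance
#' of the flattened coordinates is eigendecomposed, and the sum of the first
#' k eigenvalues summarizes the fluctuation amplitude.
#'
#' @param x A frames-by-coordinates numeric matrix, or a
#'   [dna_trajectory()] (whose coordinates are flattened to `3 N` columns).
#' @param reference Reference coordinates for superposition: a frame index
#'   into `x`, or a vector/matrix of coordinates.  Defaults to the first
#'   frame.  Superposition requires a multiple-of-3 column count and is
#'   skipped when `superpose = FALSE` (e.g. for generic series input).
#' @param k Number of leading eigenvalues to sum.
#' @param superpose Superpose frames before the covariance?
#' @return An `ed_result`: list with `values` (descending eigenvalues,
#'   angstrom^2), `vectors`, `sum_first_k`, `k`, `trace`, `n_frames`.
#' @export
ed_eigen <- function(x, reference = 1L, k = 10L, superpose = TRUE) {
  if (inherits(x, "dna_trajectory")) {
    nf <- n_frames(x)
    X <- matrix(0, nf, 3L * n_atoms(x))  # per-frame x1,y1,z1,x2,...
    for (f in seq_len(nf)) X[f, ] <- as.vector(t(frame_coords(x, f)))
  } else {
    X <- as.matrix(x)
  }
  nf <- nrow(X)
  abort_if(nf < k + 1L, "need at least k + 1 frames")
  d <- ncol(X)

  if (superpose && d %% 3L == 0L) {
    ref <- if (length(reference) == 1L && is.numeric(reference) &&
               reference == as.integer(reference) && reference <= nf) {
      matrix(X[as.integer(reference), ], ncol = 3L, byrow = TRUE)
    } else {
      matrix(as.numeric(reference), ncol = 3L, byrow = TRUE)
    }
    refc <- scale(ref, scale = FALSE)
    for (f in seq_len(nf)) {
      M <- matrix(X[f, ], ncol = 3L, byrow = TRUE)
      ctr <- colMeans(M)
      Mc <- sweep(M, 2L, ctr)
      R <- kabsch_rotation(Mc, refc)
      X[f, ] <- as.vector(t(Mc %*% R))
    }
  }

  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- min(k, length(vals))
  structure(
    list(values = vals, vectors = e$vectors,
         sum_first_k = sum(vals[seq_len(k)]), k = k,
         trace = sum(diag(C)), n_frames = nf),
    class = "ed_result"
  )
}

#' Essential dynamics from a covariance matrix
#'
#' @param C Symmetric covariance matrix.
#' @param k Number of leading eigenvalues to sum.
#' @return An `ed_result` (with `n_frames = NA`).
#' @export
ed_eigen_from_cov <- function(C, k = 10L) {
  C <- as.matrix(C)
  abort_if(nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))),
           "`C` must be a symmetric square matrix")
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- min(k, length(vals))
  structure(
    list(values = vals, vectors = e$vectors,
         sum_first_k = sum(vals[seq_len(k)]), k = k,
         trace = sum(diag(C)), n_frames = NA_integer_),
    class = "ed_result"
  )
}

#' @export
print.ed_result <- function(x, ...) {
  cat("<ed_result> sum of first", x$k, "eigenvalues:",
      signif(x$sum_first_k, 6), "(trace", signif(x$trace, 6), ")\n")
  invisible(x)
}

#' Difference of leading-eigenvalue sums between two conditions
#'
#' @param a,b `ed_result` objects (same k).
#' @return `a$sum_first_k - b$sum_first_k`.
#' @export
ed_sum_diff <- function(a, b) {
  abort_if(a$k != b$k, "results use different k")
  a$sum_first_k - b$sum_first_k
}

#' Normalized covariance (subspace) overlap
#'
#' Similarity of the leading k-dimensional eigenspaces of two covariance
#' matrices: `(1/k) * sum_{i,j <= k} (v_i . w_j)^2`, which is 1 for
#' identical subspaces and 0 for orthogonal ones.
#'
#' @param cov_a,cov_b Symmetric covariance matrices of equal dimension.
#' @param k Subspace dimension (k <= matrix dimension).
#' @return Scalar in `[0, 1]`.
#' @export
covariance_overlap <- function(cov_a, cov_b, k = 10L) {
  cov_a <- as.matrix(cov_a); cov_b <- as.matrix(cov_b)
  abort_if(!all(dim(cov_a) == dim(cov_b)), "dimension mismatch")
  abort_if(k > nrow(cov_a), "k exceeds the matrix dimension")
  va <- eigen(cov_a, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  vb <- eigen(cov_b, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  sum(crossprod(va, vb)^2) / k
}
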