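#' Spectral covariance matrix of log-normalized spectra
#'
#' Builds the 70 x 70 second-moment matrix
#' \eqn{C(f, f') = \sum_{m,n} \tilde P_n^m(f)\, \tilde P_n^m(f')},
#' pooling every (segment, channel) pair across all conditions as one
#' observation, so that a single spectral basis serves every channel. No
#' mean-centering is applied beyond the log normalization itself (which
#' already references the mean spectrum).
#'
#' @param logpsd A `logpsd_set`.
#' @return A symmetric positive semidefinite 70 x 70 matrix.
#' @export
spectral_covariance <- function(logpsd) {
  v <- logpsd$values
  if (is.null(v) || length(v) == 0 || dim(v)[1] < 1)
    stop("empty log-PSD input", call. = FALSE)
  m <- dim(v)[1]; n <- dim(v)[2]; nf <- dim(v)[3]
  obs <- matrix(aperm(v, c(3, 1, 2)), nrow = nf)   # nf x (m*n)
  C <- tcrossprod(obs)
  (C + t(C)) / 2
}

#' Eigendecomposition of the spectral covariance
#'
#' Full eigensystem of the spectral covariance, eigenvalues in descending
#' order. Small negative eigenvalues in `[-1e-10, 0)` (numerical noise)
#' are clipped to zero; larger negative values error. Each eigenvector's
#' sign is fixed deterministically: flipped so its mean over the 8-12 Hz
#' bins is >= 0, with an exact-zero tie resolved by making the
#' largest-magnitude component positive.
#'
#' @param C Symmetric PSD matrix (frequencies x frequencies).
#' @param tol Asymmetry tolerance.
#' @return A `spectral_basis`: list with `eigenvalues` (descending),
#'   `vectors` (frequencies x k matrix of orthonormal columns), `freq`,
#'   and `sign_convention`.
#' @export
eigendecompose <- function(C, tol = 1e-8) {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop("C must be a square matrix", call. = FALSE)
  if (max(abs(C - t(C))) > tol * max(1, max(abs(C))))
    stop("C is asymmetric beyond tolerance", call. = FALSE)
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- eg$values
  neg <- lam < 0
  if (any(lam < -1e-10 * max(1, max(abs(lam)))))
    stop("covariance has substantially negative eigenvalues", call. = FALSE)
  lam[neg] <- 0
  vec <- eg$vectors
  nf <- nrow(C)
  alpha_bins <- intersect(8:12, seq_len(nf))
  for (k in seq_len(ncol(vec))) {
    mu <- if (length(alpha_bins)) mean(vec[alpha_bins, k]) else 0
    if (mu < 0) {
      vec[, k] <- -vec[, k]
    } else if (mu == 0) {
      big <- which.max(abs(vec[, k]))
      if (vec[big, k] < 0) vec[, k] <- -vec[, k]
    }
  }
  structure(list(eigenvalues = lam, vectors = vec, freq = seq_len(nf),
                 sign_convention = "mean over 8-12 Hz bins >= 0"),
            class = "spectral_basis")
}

#' Project log-normalized spectra onto spectral principal components
#'
#' Computes the projection weights
#' \eqn{W_{n,k}^m = \sum_f e_k(f) \tilde P_n^m(f)} for the first `K`
#' components of the basis; the same basis is applied at every channel.
#'
#' @param logpsd A `logpsd_set`.
#' @param basis A `spectral_basis`.
#' @param K Number of retained components (default 3).
#' @return A `projection_table`: list with `weights` (segments x channels
#'   x K array), `K`, `labels`, `channel_labels`, `montage`.
#' @export
project <- function(logpsd, basis, K = 3) {
  v <- logpsd$values
  nf <- dim(v)[3]
  if (nf != nrow(basis$vectors))
    stop("basis/frequency-grid length mismatch", call. = FALSE)
  if (K > ncol(basis$vectors)) stop("K exceeds number of components", call. = FALSE)
  m <- dim(v)[1]; n <- dim(v)[2]
  E <- basis$vectors[, seq_len(K), drop = FALSE]
  obs <- matrix(aperm(v, c(3, 1, 2)), nrow = nf)   # nf x (m*n)
  W <- array(t(crossprod(obs, E)), dim = c(K, m, n))
  structure(list(weights = aperm(W, c(2, 3, 1)), K = K, labels = logpsd$labels,
                 channel_labels = logpsd$channel_labels, montage = logpsd$montage),
            class = "projection_table")
}

#' Export a spectral basis as a CSV table
#'
#' Writes the first `K` spectral principal component profiles as a CSV
#' with a frequency column and one column per component (named
#' `PC1..PCK`), eigenvalues recorded in the header comment line.
#'
#' @param basis A `spectral_basis`.
#' @param path Output CSV path.
#' @param K Components to export.
#' @return `path`, invisibly.
#' @export
write_basis_csv <- function(basis, path, K = 3) {
  K <- min(K, ncol(basis$vectors))
  df <- data.frame(freq_hz = basis$freq)
  for (k in seq_len(K)) df[[paste0("PC", k)]] <- basis$vectors[, k]
  hdr <- paste0("# eigenvalues: ",
                paste(signif(basis$eigenvalues[seq_len(K)], 10), collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
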