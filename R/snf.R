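#' Similarity network fusion
#'
#' Construction of per-modality subject affinity matrices with the scaled
#' exponential kernel and their fusion into a single similarity network by
#' iterative cross-diffusion (SNF, Wang-style message passing).
#'
#' @name snf
NULL

#' SNF hyperparameters
#'
#' @param K number of nearest neighbours used by the kernel bandwidth and the
#'   sparse (local) kernel. Clamped to `n - 1` with a warning for small
#'   cohorts.
#' @param mu positive bandwidth weight of the scaled exponential kernel.
#' @param T number of cross-diffusion iterations (no convergence stopping).
#' @param standardize z-score each feature column before computing distances.
#'
#' @return an object of class `snf_params`.
#' @export
snf_params <- function(K = 30L, mu = 0.8, T = 20L, standardize = TRUE) {
  K <- as.integer(K)
  T <- as.integer(T)
  if (K < 1L) stop("K must be >= 1")
  if (!is.numeric(mu) || mu <= 0) stop("mu must be a positive real")
  if (T < 1L) stop("T must be >= 1")
  structure(list(K = K, mu = mu, T = T, standardize = isTRUE(standardize)),
            class = "snf_params")
}

#' Pairwise squared Euclidean distances
#'
#' @param values numeric matrix, subjects in rows.
#' @return symmetric `n x n` matrix of squared Euclidean distances with zero
#'   diagonal; dimnames carry the subject ids when `values` has rownames.
#' @export
pairwise_sq_euclidean <- function(values) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) {
    bad <- which(!apply(values, 1L, function(r) all(is.finite(r))))
    ids <- if (is.null(rownames(values))) bad else rownames(values)[bad]
    stop("non-finite feature values for subject(s): ",
         paste(ids, collapse = ", "))
  }
  sq <- rowSums(values ^ 2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(values)
  D[D < 0] <- 0           # clip float negatives
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(rownames(values), rownames(values))
  D
}

# mean distance to the K nearest neighbours (self excluded), per row, on the
# plain (non-squared) distance scale; ties at the K-th neighbour broken by
# ascending subject index via order()'s stable tie-breaking.
.knn_mean_dist <- function(d, K) {
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    o <- order(d[i, -i])
    mean(d[i, -i][o[seq_len(K)]])
  }, numeric(1L))
}

#' Scaled exponential affinity kernel
#'
#' Converts a squared-Euclidean distance matrix to affinities
#' `W(i,j) = exp(-D(i,j) / (mu * eps_ij^2))` where the adaptive local
#' bandwidth `eps_ij = (mean_knn(i) + mean_knn(j) + d(i,j)) / 3` is
#' computed on the plain distance `d = sqrt(D)`. Squaring the bandwidth
#' makes the exponent dimensionless, so affinities are invariant to a
#' global rescaling of the features. The result is symmetrized.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal
#'   (squared Euclidean scale, as from [pairwise_sq_euclidean()]).
#' @param params an [snf_params()] object.
#' @return nonnegative symmetric affinity matrix with unit diagonal.
#' @export
scaled_exp_kernel <- function(D, params = snf_params()) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 subjects")
  if (max(abs(D - t(D))) > 1e-10 || any(D < 0) || any(abs(diag(D)) > 1e-12))
    stop("D must be symmetric, nonnegative, with zero diagonal")
  K <- .clamp_K(params$K, n)
  d <- sqrt(D)
  mk <- .knn_mean_dist(d, K)
  eps <- (outer(mk, mk, "+") + d) / 3
  if (any(eps <= 0)) {
    warning("zero kernel bandwidth for some pair (duplicate-heavy data); ",
            "flooring at machine epsilon")
    eps[eps <= 0] <- .Machine$double.eps
  }
  W <- exp(-D / (params$mu * eps ^ 2))
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(D)
  W
}

.clamp_K <- function(K, n) {
  if (K >= n) {
    warning(sprintf("K = %d >= n = %d; clamping to n - 1", K, n))
    K <- n - 1L
  }
  as.integer(K)
}

#' Full (global) transition kernel
#'
#' Row-stochastic normalization used by SNF: off-diagonal entries carry half
#' the row mass, the diagonal is fixed at 1/2.
#'
#' @param W nonnegative affinity matrix.
#' @return matrix `P` with `P(i,j) = W(i,j) / (2 * sum_{k != i} W(i,k))` for
#'   `j != i` and `P(i,i) = 1/2`; every row sums to 1.
#' @export
full_kernel <- function(W) {
  W <- as.matrix(W)
  off <- rowSums(W) - diag(W)
  if (any(off <= 0)) {
    bad <- which(off <= 0)
    ids <- if (is.null(rownames(W))) bad else rownames(W)[bad]
    stop("isolated subject(s) with zero off-diagonal affinity: ",
         paste(ids, collapse = ", "))
  }
  P <- W / (2 * off)
  diag(P) <- 0.5
  P
}

#' Sparse (local) KNN kernel
#'
#' Keeps each row's K largest affinities (self excluded) and renormalizes
#' them to sum to one; all other entries are zero. Ties at the K-th
#' neighbour are broken by ascending subject index.
#'
#' @param W nonnegative affinity matrix.
#' @param K neighbour count, `K < n`.
#' @return row-stochastic matrix supported on each subject's K neighbours.
#' @export
sparse_kernel <- function(W, K) {
  W <- as.matrix(W)
  n <- nrow(W)
  K <- .clamp_K(as.integer(K), n)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf                       # self excluded
    nb <- order(w, decreasing = TRUE)[seq_len(K)]
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  S
}

#' Fuse modality affinity networks (SNF)
#'
#' Iterative cross-diffusion: each modality's global kernel is propagated
#' through its own local KNN kernel against the average of the other
#' modalities' kernels, re-symmetrized and renormalized each round, and the
#' final kernels are averaged into one fused similarity network.
#'
#' @param affinities list of affinity matrices over the same subjects in the
#'   same order (as from [scaled_exp_kernel()]).
#' @param params an [snf_params()] object.
#' @return symmetric nonnegative fused similarity matrix (class
#'   `fused_network`) with subject dimnames.
#' @export
snf_fuse <- function(affinities, params = snf_params()) {
  if (!is.list(affinities) || length(affinities) < 1L)
    stop("need a non-empty list of affinity matrices")
  if (params$T < 1L) stop("T must be >= 1")
  ids <- rownames(affinities[[1L]])
  for (W in affinities) {
    if (!identical(dim(W), dim(affinities[[1L]])))
      stop("affinity matrices differ in dimension")
    if (!identical(rownames(W), ids))
      stop("subject ids differ across modalities")
  }
  m <- length(affinities)
  P <- lapply(affinities, full_kernel)
  S <- lapply(affinities, sparse_kernel, K = params$K)
  for (t in seq_len(params$T)) {
    Pnew <- vector("list", m)
    for (v in seq_len(m)) {
      other <- if (m == 1L) P[[1L]] else Reduce(`+`, P[-v]) / (m - 1L)
      M <- S[[v]] %*% other %*% t(S[[v]])
      M <- (M + t(M)) / 2              # guard float drift before renormalizing
      Pnew[[v]] <- full_kernel(M)
    }
    P <- Pnew
  }
  Sf <- Reduce(`+`, P) / m
  Sf <- full_kernel((Sf + t(Sf)) / 2)
  Sf <- (Sf + t(Sf)) / 2
  dimnames(Sf) <- list(ids, ids)
  class(Sf) <- c("fused_network", class(Sf))
  Sf
}

#' Standardize feature columns
#'
#' z-scores each column, optionally with statistics taken from a reference
#' (training) matrix so that held-out data is scaled consistently.
#'
#' @param values numeric matrix, subjects in rows.
#' @param stats optional list with `center` and `scale` vectors from a
#'   previous call; when `NULL` they are computed from `values`.
#' @return the standardized matrix with the statistics attached as
#'   attributes `center` and `scale`.
#' @export
standardize_features <- function(values, stats = NULL) {
  values <- as.matrix(values)
  if (is.null(stats)) {
    ctr <- colMeans(values)
    scl <- apply(values, 2L, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- stats$center
    scl <- stats$scale
  }
  out <- sweep(sweep(values, 2L, ctr), 2L, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Affinity matrix from a raw modality table
#'
#' Convenience wrapper: optional per-feature standardization, squared
#' Euclidean distances, scaled exponential kernel.
#'
#' @inheritParams pairwise_sq_euclidean
#' @inheritParams scaled_exp_kernel
#' @export
modality_affinity <- function(values, params = snf_params()) {
  if (params$standardize) values <- standardize_features(values)
  scaled_exp_kernel(pairwise_sq_euclidean(values), params)
}
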