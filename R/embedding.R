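#' Diffusion map embedding parameters
#'
#' @param n_components number of non-trivial components to return.
#' @param t diffusion time; `t = 0` (the default) uses the global-scale
#'   spectral weighting `lambda / (1 - lambda)` instead of `lambda^t`.
#' @param alpha anisotropy exponent in `[0, 1]`; `0.5` gives the
#'   density-corrected diffusion operator.
#' @param scale_eigenvectors if `FALSE`, return plain `psi_k` without the
#'   `lambda`-dependent weighting.
#' @return an object of class `embedding_params`.
#' @export
embedding_params <- function(n_components = 10L, t = 0, alpha = 0.5,
                             scale_eigenvectors = TRUE) {
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be >= 1")
  if (t < 0) stop("diffusion time t must be nonnegative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(n_components = n_components, t = t, alpha = alpha,
                 scale_eigenvectors = isTRUE(scale_eigenvectors)),
            class = "embedding_params")
}

# deterministic eigenvector sign: nonnegative skewness, falling back to a
# nonnegative first entry when the skewness is (numerically) zero.
.fix_sign <- function(v) {
  ctr <- v - mean(v)
  sk <- mean(ctr ^ 3)
  if (abs(sk) > 1e-12) {
    if (sk < 0) v <- -v
  } else if (v[1L] < 0) {
    v <- -v
  }
  v
}

#' Diffusion map embedding of a fused similarity network
#'
#' Forms the anisotropic kernel `L(i,j) = S(i,j) / (d_i^alpha d_j^alpha)`,
#' row-normalizes it to a Markov transition matrix `M`, and embeds subjects
#' on the leading non-trivial right eigenvectors of `M`. Eigenvectors are
#' normalized to unit norm in `L2(pi)` (`pi` the stationary distribution),
#' the convention of the diffusion-map reference implementations, so entries
#' are O(1) regardless of cohort size. Component `k` is weighted by
#' `lambda_k^t`, or by `lambda_k / (1 - lambda_k)` at `t = 0`. The
#' eigenproblem is solved on the symmetric conjugate
#' `D^{-1/2} L D^{-1/2}` for numerical stability.
#'
#' @param net symmetric nonnegative similarity matrix (e.g. from
#'   [snf_fuse()]) with subject ids as dimnames.
#' @param params an [embedding_params()] object.
#' @return list of class `embedding_result` with elements `subject_ids`,
#'   `scores` (n x n_components), `eigenvalues` (leading non-trivial
#'   eigenvalues of `M`, strictly decreasing in `(0, 1)`).
#' @export
diffusion_map_embed <- function(net, params = embedding_params()) {
  S <- unclass(as.matrix(net))
  n <- nrow(S)
  if (max(abs(S - t(S))) > 1e-10 || any(S < 0))
    stop("similarity matrix must be symmetric and nonnegative")
  k <- params$n_components
  if (k >= n - 1L) stop("n_components must be < n_subjects - 1")

  d <- rowSums(S)
  if (any(d <= 0)) stop("similarity graph has an isolated subject")
  L <- S / outer(d ^ params$alpha, d ^ params$alpha)
  d2 <- rowSums(L)                      # degrees of the anisotropic kernel
  inv_sqrt <- 1 / sqrt(d2)
  A <- L * outer(inv_sqrt, inv_sqrt)    # symmetric conjugate of M
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  lambda <- eig$values

  if (sum(lambda > 1 - 1e-9) > 1L)
    stop("similarity graph appears disconnected (eigenvalue 1 has ",
         "multiplicity > 1); consider a larger K")
  if (any(abs(Im(lambda)) > 1e-8)) stop("complex eigenvalue residue")

  # right eigenvectors of M, unit norm in L2(pi): psi = D^{-1/2} v * sqrt(sum d2)
  scl <- sqrt(sum(d2))
  keep <- 2L:(k + 1L)
  lam <- lambda[keep]
  scores <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    psi <- .fix_sign(eig$vectors[, keep[j]] * inv_sqrt * scl)
    wgt <- if (!params$scale_eigenvectors) 1
           else if (params$t == 0) lam[j] / (1 - lam[j])
           else lam[j] ^ params$t
    scores[, j] <- psi * wgt
  }
  rownames(scores) <- rownames(S)
  colnames(scores) <- paste0("embedding_", seq_len(k))
  structure(list(subject_ids = rownames(S), scores = scores,
                 eigenvalues = lam),
            class = "embedding_result")
}

#' Orthogonal Procrustes alignment of embedding matrices
#'
#' Finds the orthogonal (rotation/reflection) transform of the source scores
#' minimizing the Frobenius distance to the target scores, via the SVD of
#' the cross-product of the column-centered matrices. For a single
#' component this reduces to a sign flip that makes the correlation
#' nonnegative. Optionally includes an isotropic scale factor.
#'
#' @param source_scores,target_scores n x k numeric matrices over the same
#'   subjects in the same order.
#' @param scale also fit the isotropic scaling minimizing the residual
#'   (default `FALSE`: rotation/reflection only).
#' @return the aligned source scores (target column means restored).
#' @export
procrustes_align <- function(source_scores, target_scores, scale = FALSE) {
  A <- as.matrix(source_scores)
  B <- as.matrix(target_scores)
  if (!identical(dim(A), dim(B))) stop("score matrices differ in shape")
  mB <- colMeans(B)
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, mB)
  sv <- svd(crossprod(Ac, Bc))
  R <- sv$u %*% t(sv$v)
  s <- if (scale) sum(sv$d) / sum(Ac ^ 2) else 1
  aligned <- s * (Ac %*% R)
  sweep(aligned, 2L, mB, "+")
}

#' Prediction-quality metrics for embedding scores
#'
#' @param predicted,truth aligned numeric vectors (or single-column
#'   matrices) of embedding scores over the same subjects.
#' @return list of class `embedding_comparison`: `rmse`, `mae`, `r2`
#'   (coefficient of determination), `pearson_r`.
#' @export
compare_embeddings <- function(predicted, truth) {
  p <- as.numeric(predicted)
  y <- as.numeric(truth)
  if (length(p) != length(y)) stop("score vectors differ in length")
  if (stats::sd(y) == 0) stop("truth has zero variance; r undefined")
  e <- p - y
  structure(list(rmse = sqrt(mean(e ^ 2)),
                 mae = mean(abs(e)),
                 r2 = 1 - sum(e ^ 2) / sum((y - mean(y)) ^ 2),
                 pearson_r = stats::cor(p, y)),
            class = "embedding_comparison")
}

#' Feature loadings on an embedding component
#'
#' Pearson correlation of every feature column with the (first) embedding
#' score — the basis of the brain maps relating regional features to the
#' similarity axis.
#'
#' @param values subjects x features matrix aligned with `scores`.
#' @param scores numeric vector of per-subject embedding scores.
#' @return named numeric vector of correlations; constant features are
#'   reported as `NA` (undefined), not zero.
#' @export
feature_loadings <- function(values, scores) {
  values <- as.matrix(values)
  scores <- as.numeric(scores)
  if (nrow(values) != length(scores)) stop("subjects not aligned")
  out <- apply(values, 2L, function(col) {
    if (stats::sd(col) == 0) NA_real_ else stats::cor(col, scores)
  })
  out
}
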