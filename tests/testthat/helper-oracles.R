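# Independent, deliberately naive reference implementations used as oracles.
# They share no code with the package paths they check.

naive_sq_euclidean <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      D[i, j] <- sum((X[i, ] - X[j, ]) ^ 2)
  D
}

# scalar implementation of the scaled exponential kernel
naive_kernel <- function(D, K, mu) {
  n <- nrow(D)
  d <- sqrt(D)
  mk <- numeric(n)
  for (i in seq_len(n)) {
    di <- sort(d[i, -i])
    mk[i] <- mean(di[seq_len(K)])
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      eps <- (mk[i] + mk[j] + d[i, j]) / 3
      W[i, j] <- exp(-D[i, j] / (mu * eps ^ 2))
    }
  (W + t(W)) / 2
}

naive_full_kernel <- function(W) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_len(n)) if (k != i) s <- s + W[i, k]
    for (j in seq_len(n)) P[i, j] <- if (i == j) 0.5 else W[i, j] / (2 * s)
  }
  P
}

naive_sparse_kernel <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nb <- order(w, decreasing = TRUE)[seq_len(K)]
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  S
}

# loop-based matrix product (no %*%)
naive_matmul <- function(A, B) {
  n <- nrow(A); p <- ncol(B)
  C <- matrix(0, n, p)
  for (i in seq_len(n))
    for (j in seq_len(p))
      C[i, j] <- sum(A[i, ] * B[, j])
  C
}

naive_snf <- function(affinities, K, T) {
  m <- length(affinities)
  P <- lapply(affinities, naive_full_kernel)
  S <- lapply(affinities, naive_sparse_kernel, K = K)
  for (t in seq_len(T)) {
    Pn <- vector("list", m)
    for (v in seq_len(m)) {
      other <- matrix(0, nrow(P[[1]]), ncol(P[[1]]))
      if (m == 1L) other <- P[[1]]
      else {
        for (u in seq_len(m)) if (u != v) other <- other + P[[u]]
        other <- other / (m - 1)
      }
      M <- naive_matmul(naive_matmul(S[[v]], other), t(S[[v]]))
      M <- (M + t(M)) / 2
      Pn[[v]] <- naive_full_kernel(M)
    }
    P <- Pn
  }
  Sf <- Reduce(`+`, P) / m
  Sf <- naive_full_kernel((Sf + t(Sf)) / 2)
  (Sf + t(Sf)) / 2
}

# dense diffusion-map oracle via the plain (non-symmetric) eigen solve of the
# row-normalized transition matrix
naive_diffusion_embed <- function(S, n_comp, alpha = 0.5, t = 0) {
  d <- rowSums(S)
  L <- S / outer(d ^ alpha, d ^ alpha)
  d2 <- rowSums(L)
  M <- L / d2
  eig <- eigen(M)
  stopifnot(max(abs(Im(eig$values))) < 1e-8)
  lam <- Re(eig$values)
  o <- order(lam, decreasing = TRUE)
  lam <- lam[o]
  V <- Re(eig$vectors)[, o, drop = FALSE]
  pi_ <- d2 / sum(d2)
  out <- matrix(0, nrow(S), n_comp)
  for (k in seq_len(n_comp)) {
    psi <- V[, k + 1L]                       # skip trivial constant pair
    psi <- psi / sqrt(sum(pi_ * psi ^ 2))    # unit norm in L2(pi)
    ctr <- psi - mean(psi)
    sk <- mean(ctr ^ 3)
    if (abs(sk) > 1e-12) { if (sk < 0) psi <- -psi } else if (psi[1] < 0) psi <- -psi
    w <- if (t == 0) lam[k + 1L] / (1 - lam[k + 1L]) else lam[k + 1L] ^ t
    out[, k] <- psi * w
  }
  list(scores = out, eigenvalues = lam[seq_len(n_comp) + 1L])
}

# a random valid affinity matrix over n subjects
random_affinity <- function(n, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  rownames(X) <- sprintf("s%02d", seq_len(n))
  scaled_exp_kernel(pairwise_sq_euclidean(X),
                    snf_params(K = max(2L, min(10L, n - 1L))))
}
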