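# ICA unmixing engines operating on row-whitened data (components x samples).
# Spatial group ICA treats masked voxels as samples, so these are called with
# the PCA-whitened group data Z (c x K) and return the unmixing matrix W such
# that S = W %*% Z has maximally independent rows.

# Infomax (Bell-Sejnowski) with the natural gradient and a logistic score,
# suited to the super-Gaussian (sparse) sources typical of spatial brain maps.
# Converged when the relative natural-gradient norm |G|/|W| falls below tol.
# The learning rate grows gently while the gradient norm keeps falling and is
# cut hard on a rise; the separating directions settle quickly but the source
# scale adapts slowly, so the cap matters more than the starting rate.
ica_infomax <- function(Z, maxit = 2000L, tol = 1e-6, lrate = 0.02,
                        verbose = FALSE) {
  c <- nrow(Z)
  K <- ncol(Z)
  W <- random_orthonormal(c)
  last <- Inf
  for (it in seq_len(maxit)) {
    U <- W %*% Z
    Y <- 1 / (1 + exp(-U))
    # natural-gradient direction: (I + (1 - 2y) u') W, averaged over samples
    G <- (diag(c) + ((1 - 2 * Y) %*% t(U)) / K) %*% W
    gnorm <- sqrt(sum(G^2) / sum(W^2))
    if (gnorm < tol) {
      return(list(W = W, iterations = it, converged = TRUE))
    }
    W <- W + lrate * G
    lrate <- if (gnorm > last * 1.05) lrate * 0.6 else min(lrate * 1.05, 0.3)
    last <- gnorm
  }
  list(W = W, iterations = maxit, converged = FALSE)
}

# FastICA with symmetric decorrelation and the tanh contrast.
ica_fastica <- function(Z, maxit = 500L, tol = 1e-6, verbose = FALSE) {
  c <- nrow(Z)
  K <- ncol(Z)
  W <- random_orthonormal(c)
  for (it in seq_len(maxit)) {
    U <- W %*% Z
    G <- tanh(U)
    W1 <- (G %*% t(Z)) / K - diag(rowMeans(1 - G^2), c) %*% W
    W1 <- sym_decorrelate(W1)
    conv <- 1 - min(abs(diag(W1 %*% t(W))))
    W <- W1
    if (conv < tol) {
      return(list(W = W, iterations = it, converged = TRUE))
    }
  }
  list(W = W, iterations = maxit, converged = FALSE)
}

random_orthonormal <- function(c) {
  qr.Q(qr(matrix(rnorm(c * c), c, c)))
}

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(W)) %*% t(e$vectors) %*% W
}

# flip rows to positive skewness; returns the sign vector applied
fix_signs <- function(S) {
  sk <- apply(S, 1L, function(r) {
    z <- r - mean(r)
    s <- sqrt(mean(z^2))
    if (s == 0) return(0)
    mean((z / s)^3)
  })
  signs <- ifelse(sk < 0, -1, 1)
  list(S = S * signs, signs = signs)
}
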