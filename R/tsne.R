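# Exact t-SNE on a precomputed dissimilarity matrix.
#
# Standard formulation: Gaussian input affinities with per-point
# bandwidths found by bisection on the perplexity, symmetrised and
# normalised; Student-t output kernel; gradient descent with momentum,
# adaptive gains, and early exaggeration.  Exact (all-pairs) gradients —
# the ensembles embedded here are small, so no tree approximation is
# needed.

# per-row conditional affinities at the bandwidth matching log-perplexity
tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-d2 * beta)
      sw <- sum(w)
      if (sw < 1e-300) { h <- 0 } else {
        p <- w / sw
        h <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(h - target) < 1e-7) break
      if (h > target) {            # entropy too high -> narrow kernel
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta + beta_lo) / 2
      }
    }
    w <- exp(-d2 * beta)
    P[i, -i] <- w / max(sum(w), 1e-300)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_exact <- function(D, perplexity, max_iter = 1000, seed = 0,
                       eta = 200, exaggeration = 12, exag_iter = 250) {
  n <- nrow(D)
  P <- tsne_affinities(D^2, perplexity)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    V <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (it in seq_len(max_iter)) {
      Pe <- if (it <= exag_iter) P * exaggeration else P
      d2 <- cross_dist2(Y, Y)
      num <- 1 / (1 + d2); diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
      mom <- if (it <= exag_iter) 0.5 else 0.8
      gains <- pmax(0.01, ifelse(sign(grad) != sign(V),
                                 gains + 0.2, gains * 0.8))
      V <- mom * V - eta * gains * grad
      Y <- Y + V
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
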