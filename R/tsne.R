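#' Exact t-SNE embedding
#'
#' A direct (O(n^2)) implementation of t-distributed stochastic neighbor
#' embedding: Gaussian input affinities with per-point bandwidths tuned to
#' the target perplexity by bisection, Student-t output affinities, and
#' gradient descent with momentum and early exaggeration. Intended for the
#' modest frame counts of latent-space visualization.
#'
#' @param X numeric matrix (rows = points).
#' @param dims output dimensionality (2 or 3).
#' @param perplexity target perplexity (effective neighbour count).
#' @param iter gradient-descent iterations.
#' @param seed seed for the random initialization.
#' @return `n x dims` matrix of embedded coordinates.
#' @export
tsne_embed <- function(X, dims = 2L, perplexity = 30, iter = 300L,
                       seed = 1L) {
  n <- nrow(X)
  if (n < 4L) stop("too few points for t-SNE")
  perplexity <- max(2, min(perplexity, (n - 1) / 3))
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) { H <- 0; p[] <- 1 / length(p) }
      else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- with_seed(seed, matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims))
  G <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  momentum <- 0.5
  for (it in seq_len(iter)) {
    Pe <- if (it <= 100L) P * 4 else P   # early exaggeration
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - 200 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
    if (it == 50L) momentum <- 0.8
  }
  Y
}
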