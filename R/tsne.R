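## Exact t-SNE (O(n^2)), sufficient at the package's working scales
## (hundreds to a few thousand profiles). Standard formulation: Gaussian
## input kernels calibrated to a target perplexity by bisection, Student-t
## output kernel, gradient descent with momentum and early exaggeration.

tsnePerplexityCalibrate <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp < 1e-300) {
        H <- 0; p <- p * 0
      } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < tol) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

#' 2-D t-SNE embedding (exact)
#'
#' @param X n x d numeric matrix (rows = items).
#' @param perplexity Gaussian kernel perplexity; requires
#'   `n >= 3 * perplexity + 1` points (lower it for small sets).
#' @param iterations gradient-descent iterations.
#' @param seed integer seed (initialization).
#' @param learningRate,exaggeration standard optimizer settings.
#' @return n x 2 matrix of coordinates.
#' @export
tsneEmbed <- function(X, perplexity = 30, iterations = 500, seed = 1,
                      learningRate = 200, exaggeration = 12) {
  n <- nrow(X)
  if (n < 3 * perplexity + 1) {
    stop("too few points for perplexity ", perplexity,
         "; use a smaller perplexity")
  }
  D2 <- as.matrix(dist(X))^2
  P <- tsnePerplexityCalibrate(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withSeed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (it in seq_len(iterations)) {
      Pit <- if (it <= 100) P * exaggeration else P
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pit - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (it <= 250) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- mom * dY - learningRate * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
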