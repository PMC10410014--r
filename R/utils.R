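# internal helpers shared across modules

# Gauss-Hermite nodes/weights for E[f(Z)], Z ~ N(0, sd^2).
# 40 nodes is ample for the smooth logistic integrands used here.
gh_rule <- function(n = 40L) {
  # Golub-Welsch on the Hermite Jacobi matrix
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1L, ]^2)
}

gauss_expect <- function(f, sd, rule = gh_rule()) {
  # E[f(Z)] for Z ~ N(0, sd^2) via Gauss-Hermite (change of variable x = z/(sd*sqrt(2)))
  x <- rule$nodes * sd * sqrt(2)
  sum(rule$weights * f(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# sample sd / weighted helpers
weighted_sd <- function(x, w) {
  m <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}
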