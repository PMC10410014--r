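# shared fixtures and independent oracles

# harmonized instrument set assembled directly (bypasses allele logic)
make_set <- function(bx, sex, by, sey, ids = NULL) {
  out <- data.frame(
    variant_id = ids %||% paste0("rs", seq_along(bx)),
    beta_exposure = bx, se_exposure = sex,
    beta_outcome = by, se_outcome = sey,
    eaf_exposure = 0.3, stringsAsFactors = FALSE)
  out$ratio <- by / bx
  out$ratio_se <- sey / abs(bx)
  out$flipped <- FALSE
  class(out) <- c("harmonized_instruments", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Benjamini-Hochberg step-up: largest k with p_(k) <= k*q/m
bh_brute <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# closed-form weighted least squares oracle: (X'WX)^-1 X'Wy
wls_oracle <- function(X, y, w) solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), y * sqrt(w)))

# CR1 cluster-robust sandwich, written independently of the package
cr1_oracle <- function(X, y, cl) {
  b <- solve(crossprod(X), crossprod(X, y))
  e <- drop(y - X %*% b)
  n <- nrow(X); k <- ncol(X); G <- length(unique(cl))
  bread <- solve(crossprod(X))
  meat <- matrix(0, k, k)
  for (g in unique(cl)) {
    idx <- cl == g
    sg <- crossprod(X[idx, , drop = FALSE], e[idx])
    meat <- meat + sg %*% t(sg)
  }
  (G / (G - 1)) * ((n - 1) / (n - k)) * bread %*% meat %*% bread
}
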