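# Independent brute-force oracles used to check the implementation.
# These deliberately share no code with the package internals.

# exhaustive threshold search straight from the definitions
oracle_otsu <- function(counts) {
  B <- length(counts)
  p <- counts / sum(counts)
  lev <- 0:(B - 1)
  best_k <- NA_integer_; best <- -Inf
  for (k in 1:(B - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * lev[1:k]) / w0
    mu1 <- sum(p[(k + 1):B] * lev[(k + 1):B]) / w1
    crit <- w0 * w1 * (mu0 - mu1)^2
    if (crit > best) { best <- crit; best_k <- k }
  }
  best_k
}

oracle_max_entropy <- function(counts) {
  B <- length(counts)
  p <- counts / sum(counts)
  shannon <- function(q) {
    tot <- sum(q)
    if (tot == 0) return(0)
    q <- q[q > 0] / tot
    -sum(q * log(q))
  }
  best_k <- NA_integer_; best <- -Inf
  for (k in 1:(B - 1)) {
    if (sum(p[1:k]) == 0 || sum(p[(k + 1):B]) == 0) next
    crit <- shannon(p[1:k]) + shannon(p[(k + 1):B])
    if (crit > best) { best <- crit; best_k <- k }
  }
  best_k
}

# per-pixel loop projections
oracle_project <- function(slices, fun) {
  out <- matrix(0, nrow(slices[[1]]), ncol(slices[[1]]))
  for (i in seq_len(nrow(out)))
    for (j in seq_len(ncol(out)))
      out[i, j] <- fun(vapply(slices, function(s) s[i, j], numeric(1)))
  out
}

# double-loop circular-neighbourhood mean with edge clipping
oracle_mean_filter <- function(frame, r) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0; cnt <- 0
    for (di in -floor(r):floor(r)) for (dj in -floor(r):floor(r)) {
      if (di^2 + dj^2 > r^2) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      acc <- acc + frame[ii, jj]; cnt <- cnt + 1
    }
    out[i, j] <- acc / cnt
  }
  out
}

# recursive-style flood fill (explicit stack), 8-connectivity
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <- cur
      for (di in -1:1) for (dj in -1:1)
        if (di != 0 || dj != 0)
          stack[[length(stack) + 1]] <- c(p[1] + di, p[2] + dj)
    }
  }
  lab
}

# per-pixel Chebyshev-distance dilation test
oracle_dilate <- function(mask, k) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cheb <- min(pmax(abs(idx[, 1] - i), abs(idx[, 2] - j)))
    out[i, j] <- cheb <= k
  }
  out
}

# tricube weighted least squares at a single point, solved by normal equations
oracle_wls_fit <- function(x, y, x0, span) {
  n <- length(x)
  k <- max(3, ceiling(span * n))
  d <- abs(x - x0)
  idx <- order(d)[1:k]
  dmax <- max(d[idx])
  w <- (1 - pmin(1, d[idx] / dmax)^3)^3
  X <- cbind(1, x[idx])
  W <- diag(w)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y[idx])
  beta[1] + beta[2] * x0
}

# a small random binary mask with a few blobs
random_blob_mask <- function(nr = 30, nc = 30, n_blobs = 3) {
  m <- matrix(FALSE, nr, nc)
  for (b in seq_len(n_blobs)) {
    ci <- sample(5:(nr - 5), 1); cj <- sample(5:(nc - 5), 1)
    r <- sample(2:4, 1)
    for (i in max(1, ci - r):min(nr, ci + r))
      for (j in max(1, cj - r):min(nc, cj + r))
        if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- TRUE
  }
  m
}

random_histogram <- function(n_bins = 256) {
  counts <- integer(n_bins)
  # a mixture of spread-out mass and a few spikes, always >= 2 non-empty bins
  nz <- sample(2:n_bins, 1)
  bins <- sample(n_bins, nz)
  counts[bins] <- rpois(nz, lambda = sample(c(2, 20, 200), 1)) + 1L
  h <- build_histogram(0:(n_bins - 1), n_bins = n_bins, range = c(0, n_bins - 1))
  h$counts <- counts
  h
}
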