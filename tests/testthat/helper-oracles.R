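# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (naive loops, dense matrices) so that agreement is
# a genuine cross-check.

# SSIM by direct enumeration of all windows (population window statistics)
naive_ssim_loop <- function(uhat, u, w = 7, L = diff(range(u))) {
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  H <- nrow(u); W <- ncol(u)
  vals <- numeric(0)
  for (i in 1:(H - w + 1)) {
    for (j in 1:(W - w + 1)) {
      a <- uhat[i:(i + w - 1), j:(j + w - 1)]
      b <- u[i:(i + w - 1), j:(j + w - 1)]
      ma <- mean(a); mb <- mean(b)
      sa <- mean((a - ma)^2); sb <- mean((b - mb)^2)
      sab <- mean((a - ma) * (b - mb))
      vals <- c(vals, (2 * ma * mb + c1) * (2 * sab + c2) /
                  ((ma^2 + mb^2 + c1) * (sa + sb + c2)))
    }
  }
  mean(vals)
}

# orbit count of the order-m rotation action on an s x s grid, via complex
# coordinates (independent of the package's counter)
oracle_orbit_count <- function(s, m) {
  c0 <- (s + 1) / 2
  pts <- outer(seq_len(s) - c0, 1i * (seq_len(s) - c0), `+`)
  key <- function(z) paste(round(Re(z), 6), round(Im(z), 6))
  seen <- character(0)
  orbits <- 0L
  for (z in as.vector(pts)) {
    if (key(z) %in% seen) next
    orbits <- orbits + 1L
    rot <- z * exp(2i * pi * (seq_len(m) - 1) / m)
    seen <- c(seen, vapply(rot, key, character(1)))
  }
  orbits
}

# dense matrix of a linear operator pair acting on n x n x channels images
dense_operator_matrix <- function(op, n, channels = 1L) {
  probe <- array(0, c(n, n, channels))
  y0 <- op$apply(probe)
  A <- matrix(0, length(y0), n * n * channels)
  for (j in seq_len(n * n * channels)) {
    e <- array(0, c(n, n, channels))
    e[j] <- 1
    A[, j] <- as.vector(op$apply(e))
  }
  A
}

# dense Gaussian operator pair with well-conditioned full column rank,
# wrapped in the package's operator-pair interface
dense_gaussian_op <- function(n, rows_factor = 1.6, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(ceiling(rows_factor * n * n) * n * n),
              ncol = n * n) / sqrt(n * n)
  list(name = "dense", image_channels = 1L,
       apply = function(u) A %*% as.vector(u),
       adjoint = function(y) array(crossprod(A, as.vector(y)), c(n, n, 1)),
       matrix = A)
}

random_trivial_field <- function(n, channels, m = 4, seed = 1) {
  set.seed(seed)
  feature_field(array(rnorm(n * n * channels), c(n, n, channels)),
                rep(list(trivial_rep(cyclic_group(m))), channels))
}

rel_err <- function(a, b) {
  sqrt(sum((as.numeric(a) - as.numeric(b))^2)) /
    (sqrt(sum(as.numeric(b)^2)) + .Machine$double.eps)
}
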