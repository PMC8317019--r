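#' Solve the steerable-kernel constraint
#'
#' Computes an orthonormal basis (under the Frobenius inner product) of the
#' space of \code{size x size} matrix-valued convolution kernels
#' \code{k : R^2 -> Hom(R^d_in, R^d_out)} satisfying the steerability
#' constraint \code{k(R x) = pi_out(R) k(x) pi_in(R^-1)} for the rotation
#' group generator \code{R}, discretised on the kernel grid. For a cyclic
#' group, satisfying the constraint for the generator implies it for every
#' element. The constraint is solved directly as a numerical null space
#' (singular value decomposition; relative singular values below \code{1e-10}
#' kept). For groups of on-grid rotations (m dividing 4) the spatial rotation
#' of the grid is an exact permutation and the basis satisfies the constraint
#' to machine precision; for other orders the grid rotation uses bilinear
#' resampling with zero fill and steerability is approximate.
#'
#' @param rep_in,rep_out input/output \code{group_rep} (same group).
#' @param size odd kernel side length.
#' @param group the \code{cyclic_group}; defaults to the representations'.
#' @return An object of class \code{steerable_basis}: list with \code{basis}
#'   (list of arrays \code{[size, size, d_in, d_out]}), \code{bmat} (matrix
#'   whose columns are the vectorised basis elements), and metadata.
#' @export
solve_kernel_basis <- function(rep_in, rep_out, size, group = rep_in$group) {
  stopifnot(size %% 2 == 1, size >= 1)
  if (rep_in$group$order != rep_out$group$order) {
    stop("representations must share the group", call. = FALSE)
  }
  m <- group$order
  d_in <- rep_in$dim; d_out <- rep_out$dim
  n <- size * size * d_in * d_out
  if (m == 1) {
    bmat <- diag(n)
  } else {
    S <- grid_rotation_operator(size, 2 * pi / m)
    Q <- kronecker(rep_matrix(rep_out, 1L),
                   t(rep_matrix(rep_in, group_inverse(group, 1L))))
    # vec ordering of k[s, s, d_in, d_out]: spatial fastest, then channels
    L <- kronecker(diag(d_in * d_out), S) - kronecker(Q, diag(size * size))
    sv <- svd(L, nu = 0, nv = n)
    tol <- 1e-10 * max(1, max(sv$d))
    keep <- which(c(sv$d, rep(0, n - length(sv$d))) < tol)
    bmat <- sv$v[, keep, drop = FALSE]
  }
  basis <- lapply(seq_len(ncol(bmat)), function(i) {
    array(bmat[, i], c(size, size, d_in, d_out))
  })
  structure(list(basis = basis, bmat = bmat, size = size,
                 rep_in = rep_in, rep_out = rep_out, group = group),
            class = "steerable_basis")
}

# Linear operator on a size x size grid mapping samples of k to samples of
# k(R .): output at grid point x equals k evaluated at R x (exact permutation
# for quarter turns, bilinear with zero fill otherwise). Grid centred at the
# kernel centre, coordinates (x right, y up).
grid_rotation_operator <- function(size, theta) {
  c0 <- (size - 1) / 2
  n <- size * size
  S <- matrix(0, n, n)
  ct <- cos(theta); st <- sin(theta)
  for (col in seq_len(size)) {
    for (row in seq_len(size)) {
      x <- (col - 1) - c0
      y <- c0 - (row - 1)
      xr <- ct * x - st * y
      yr <- st * x + ct * y
      # sample k at (xr, yr): array position
      rr <- c0 - yr; cc <- c0 + xr
      r0 <- floor(rr); ccol0 <- floor(cc)
      fr <- rr - r0; fc <- cc - ccol0
      out_idx <- row + size * (col - 1)
      for (dr in 0:1) {
        for (dc in 0:1) {
          r <- r0 + dr; cl <- ccol0 + dc
          w <- (if (dr == 1) fr else 1 - fr) * (if (dc == 1) fc else 1 - fc)
          if (w == 0 || r < 0 || r >= size || cl < 0 || cl >= size) next
          S[out_idx, (r + 1) + size * cl] <- S[out_idx, (r + 1) + size * cl] + w
        }
      }
    }
  }
  S
}

#' Residual of the steerability constraint for one kernel
#'
#' Maximum absolute violation of
#' \code{k(R_k x) - pi_out(R_k) k(x) pi_in(R_k^-1)} over all group elements.
#'
#' @param kernel array \code{[s, s, d_in, d_out]}.
#' @param rep_in,rep_out representations; \code{group} their group.
#' @param group the \code{cyclic_group}.
#' @return nonnegative scalar.
#' @export
kernel_constraint_residual <- function(kernel, rep_in, rep_out,
                                       group = rep_in$group) {
  s <- dim(kernel)[1]
  d_in <- dim(kernel)[3]; d_out <- dim(kernel)[4]
  m <- group$order
  worst <- 0
  for (k in seq_len(m) - 1L) {
    S <- grid_rotation_operator(s, 2 * pi * k / m)
    Pin <- rep_matrix(rep_in, group_inverse(group, k))
    Pout <- rep_matrix(rep_out, k)
    lhs <- array(S %*% matrix(kernel, s * s), dim(kernel))
    rhs <- kernel
    # apply pi_out on the left, pi_in^{-1} on the right of each k(x)
    rhs <- apply_channel_maps(rhs, Pout, Pin)
    worst <- max(worst, max(abs(lhs - rhs)))
  }
  worst
}

# For kernel array K[s,s,d_in,d_out] holding matrices k(x) with entry
# (row = out, col = in) = K[x,,ci,co], computes pi_out k(x) pi_in at each x.
apply_channel_maps <- function(kernel, Pout, Pin) {
  s <- dim(kernel)[1]
  d_in <- dim(kernel)[3]; d_out <- dim(kernel)[4]
  M <- matrix(kernel, s * s, d_in * d_out)
  out <- array(0, dim(kernel))
  for (co in seq_len(d_out)) {
    for (ci in seq_len(d_in)) {
      acc <- matrix(0, s, s)
      for (cj in seq_len(d_in)) {
        for (ck in seq_len(d_out)) {
          w <- Pout[co, ck] * Pin[cj, ci]
          if (w != 0) acc <- acc + w * kernel[, , cj, ck]
        }
      }
      out[, , ci, co] <- acc
    }
  }
  out
}

#' Number of orbits of the cyclic rotation action on kernel grid cells
#'
#' Brute-force orbit count of the quarter/half-turn action on the
#' \code{size x size} grid; equals the steerable basis dimension for
#' trivial-to-trivial kernels and on-grid groups.
#'
#' @param size odd kernel side.
#' @param m group order (1, 2 or 4).
#' @return integer orbit count.
#' @export
count_grid_orbits <- function(size, m) {
  stopifnot(m %in% c(1L, 2L, 4L))
  cells <- expand.grid(r = seq_len(size), c = seq_len(size))
  idx <- function(r, c) r + size * (c - 1)
  seen <- rep(FALSE, size * size)
  orbits <- 0L
  c0 <- (size + 1) / 2
  for (i in seq_len(nrow(cells))) {
    if (seen[idx(cells$r[i], cells$c[i])]) next
    orbits <- orbits + 1L
    r <- cells$r[i]; c <- cells$c[i]
    for (k in seq_len(m)) {
      # rotate (r, c) by 2*pi/m CCW about centre, exact for m | 4
      x <- c - c0; y <- c0 - r
      th <- 2 * pi * k / m
      xr <- round(cos(th) * x - sin(th) * y)
      yr <- round(sin(th) * x + cos(th) * y)
      seen[idx(c0 - yr, c0 + xr)] <- TRUE
    }
  }
  orbits
}
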