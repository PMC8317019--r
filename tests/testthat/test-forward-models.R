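test_that("ray transform and its adjoint satisfy the dot-product identity", {
  geom <- radon_geometry(12, n_angles = 10)
  set.seed(1)
  for (i in 1:100) {
    x <- matrix(rnorm(144), 12, 12)
    y <- matrix(rnorm(geom$n_angles * geom$n_detectors), geom$n_angles)
    lhs <- sum(radon_apply(x, geom) * y)
    rhs <- sum(x * radon_adjoint(y, geom))
    denom <- sqrt(sum(radon_apply(x, geom)^2)) * sqrt(sum(y^2))
    expect_lt(abs(lhs - rhs) / denom, 1e-6)
  }
})

test_that("projections of a centred disk match the analytic chord length", {
  N <- 64; r <- 20
  cc <- (N - 1) / 2
  xs <- outer(rep(1, N), 0:(N - 1)) - cc
  ys <- cc - outer(0:(N - 1), rep(1, N))
  disk <- (xs^2 + ys^2 <= r^2) * 1
  geom <- radon_geometry(N, n_angles = 8)
  sino <- radon_apply(disk, geom)
  offs <- (seq_len(geom$n_detectors) - (geom$n_detectors + 1) / 2) *
    geom$detector_spacing
  analytic <- ifelse(abs(offs) < r, 2 * sqrt(pmax(r^2 - offs^2, 0)), 0)
  # compare away from the tangent rays, where the discrete edge dominates
  interior <- abs(offs) < r - 3
  err <- abs(sweep(sino[, interior], 2, analytic[interior]))
  expect_lt(max(err) / max(analytic), 0.03)
})

test_that("ray transform is linear and maps zero to zero", {
  geom <- radon_geometry(16, n_angles = 6)
  expect_true(all(radon_apply(matrix(0, 16, 16), geom) == 0))
  set.seed(2)
  u1 <- matrix(rnorm(256), 16, 16); u2 <- matrix(rnorm(256), 16, 16)
  expect_equal(radon_apply(u1 + u2, geom),
               radon_apply(u1, geom) + radon_apply(u2, geom),
               tolerance = 1e-12)
})

test_that("adjoint of a single-ray indicator is a streak along that ray", {
  geom <- radon_geometry(17, n_angles = 4)
  sino <- matrix(0, geom$n_angles, geom$n_detectors)
  ctr <- (geom$n_detectors + 1) / 2
  sino[1, ctr] <- 1  # angle 0: vertical ray through the centre column
  img <- radon_adjoint(sino, geom)
  centre_col <- img[, 9]
  expect_gt(min(centre_col), 0.4)
  expect_true(all(img[, -(8:10)] == 0))
  expect_true(all(radon_adjoint(0 * sino, geom) == 0))
})

test_that("filtered backprojection inverts dense-angle data on smooth phantoms", {
  N <- 64; r <- 18
  cc <- (N - 1) / 2
  xs <- outer(rep(1, N), 0:(N - 1)) - cc
  ys <- cc - outer(0:(N - 1), rep(1, N))
  disk <- matrix(1 / (1 + exp((sqrt(xs^2 + ys^2) - r) * 2)), N, N)
  geom <- radon_geometry(N, n_angles = 360)
  rec <- fbp(radon_apply(disk, geom), geom)
  expect_lt(rel_err(rec, disk), 0.05)
  expect_true(all(fbp(matrix(0, 360, geom$n_detectors), geom) == 0))
  # linearity in the sinogram
  s1 <- radon_apply(disk, geom)
  expect_equal(fbp(2 * s1, geom), 2 * fbp(s1, geom), tolerance = 1e-10)
})

test_that("post-log measurements behave per the noise model", {
  geom <- radon_geometry(16, n_angles = 6)
  u <- ellipse_phantom(phantom_spec(16, seed = 3))
  nm <- ct_noise_model(mu = calibrate_mu(u, geom), seed = 4)
  # noiseless, no clip: y = R(u) exactly
  expect_equal(simulate_ct(u, geom, nm, noiseless = TRUE),
               radon_apply(u, geom), tolerance = 1e-12)
  # zero counts activate the log clip
  nm0 <- ct_noise_model(N_in = 1e-6, mu = 1, eta = 1e-8, seed = 5)
  y0 <- simulate_ct(u, geom, nm0)
  expect_true(any(abs(y0 - (-log(1e-8))) < 1e-12))
  # Monte-Carlo mean approaches the noiseless value
  g8 <- radon_geometry(8, n_angles = 4)
  u8 <- ellipse_phantom(phantom_spec(16, seed = 6))[5:12, 5:12]
  mu8 <- 2 / max(radon_apply(u8, g8))
  y_ref <- simulate_ct(u8, g8, ct_noise_model(mu = mu8), noiseless = TRUE)
  draws <- vapply(1:2000, function(i) {
    simulate_ct(u8, g8, ct_noise_model(mu = mu8, seed = i))[2, 6]
  }, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - y_ref[2, 6]), 3 * se + 1e-3)
})

test_that("cartesian masks hit the target fraction and are reproducible", {
  m1 <- generate_cartesian_mask(c(32, 32), seed = 9)
  m2 <- generate_cartesian_mask(c(32, 32), seed = 9)
  expect_identical(m1$mask, m2$mask)
  expect_lt(abs(mean(m1$mask) - 0.203), 1 / 32)
  # columns are fully sampled or fully absent
  expect_true(all(apply(m1$mask, 2, function(col) all(col) || !any(col))))
  full <- generate_cartesian_mask(c(16, 16), target_fraction = 1)
  expect_true(all(full$mask))
  expect_error(generate_cartesian_mask(c(16, 16), target_fraction = 0.05,
                                       center_fraction = 0.2), "at least")
})

test_that("masked Fourier operator is a unitary partial isometry", {
  set.seed(10)
  u <- matrix(rnorm(32 * 32), 32, 32)
  full <- generate_cartesian_mask(c(32, 32), target_fraction = 1)
  expect_lt(max(Mod(mri_adjoint(mri_apply(u, full), full) - u)), 1e-12)
  samp <- generate_cartesian_mask(c(32, 32), seed = 2)
  # adjoint identity
  yk <- matrix(complex(real = rnorm(1024), imaginary = rnorm(1024)), 32, 32)
  lhs <- sum(Re(Conj(yk) * mri_apply(u, samp)))
  rhs <- sum(u * Re(mri_adjoint(yk, samp)))
  expect_lt(abs(lhs - rhs) / (sqrt(sum(u^2)) * sqrt(sum(Mod(yk)^2))), 1e-10)
  # A A^T restricted to sampled lines is the identity
  yk_m <- yk; yk_m[!samp$mask] <- 0i
  back <- mri_apply(matrix(complex(real = Re(mri_adjoint(yk_m, samp,
                                                         channels = TRUE)[, , 1]),
                                   imaginary = mri_adjoint(yk_m, samp,
                                                           channels = TRUE)[, , 2]),
                           32, 32), samp)
  expect_lt(max(Mod(back - yk_m)), 1e-10)
})

test_that("nonzero singular values of the MRI operator all equal one", {
  s8 <- generate_cartesian_mask(c(8, 8), target_fraction = 0.5, seed = 1)
  A <- matrix(0 + 0i, 64, 64)
  for (j in 1:64) {
    e <- matrix(0, 8, 8); e[j] <- 1
    A[, j] <- as.vector(mri_apply(e, s8))
  }
  sv <- svd(A)$d
  nz <- sv[sv > 1e-8]
  expect_equal(length(nz), sum(s8$mask))
  expect_lt(max(abs(nz - 1)), 1e-10)
})

test_that("discrepancy gradients match central differences and vanish at fit", {
  geom <- radon_geometry(12, n_angles = 8)
  op <- op_radon(geom)
  set.seed(11)
  u_star <- array(runif(144), c(12, 12, 1))
  y <- op$apply(u_star)
  expect_lt(max(abs(discrepancy_gradient(u_star, y, op))), 1e-9)
  u <- array(rnorm(144), c(12, 12, 1))
  g <- discrepancy_gradient(u, y, op)
  d <- array(rnorm(144), c(12, 12, 1))
  h <- 1e-6
  fd <- (discrepancy_value(u + h * d, y, op) -
           discrepancy_value(u - h * d, y, op)) / (2 * h)
  expect_lt(abs(fd - sum(g * d)) / abs(fd), 1e-4)
  # same check through the complex MRI path
  samp <- generate_cartesian_mask(c(12, 12), seed = 3)
  opm <- op_masked_fourier(samp)
  um <- array(rnorm(288), c(12, 12, 2))
  ym <- simulate_mri(array(runif(288), c(12, 12, 2)), samp, 0.05, seed = 4)
  gm <- discrepancy_gradient(um, ym, opm)
  dm <- array(rnorm(288), c(12, 12, 2))
  fdm <- (discrepancy_value(um + h * dm, ym, opm) -
            discrepancy_value(um - h * dm, ym, opm)) / (2 * h)
  expect_lt(abs(fdm - sum(gm * dm)) / abs(fdm), 1e-4)
})

test_that("operator normalisation yields unit operator norm", {
  geom <- radon_geometry(16, n_angles = 10)
  opn <- op_normalise(op_radon(geom), 16)
  expect_lt(abs(operator_norm(opn, 16) - 1), 1e-3)
})
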