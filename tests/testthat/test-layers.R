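make_eq_layer <- function(m = 4, n_in = 2, n_out = 3, padding = "circular",
                          seed = 5) {
  g <- cyclic_group(m)
  lay <- equivariant_conv_layer(trivial_rep(g), regular_rep(g), n_in, n_out,
                                3, padding, seed = seed)
  set.seed(seed + 1)
  lay$bias <- rnorm(n_out)
  lay
}

test_that("steerable convolutions commute with all roto-translations", {
  lay <- make_eq_layer()
  f <- random_trivial_field(16, 2, seed = 7)
  map <- function(x) equivariant_conv(lay, x)
  for (k in 0:3) {
    expect_lt(equivariance_residual(map, f, k, c(3, -2), wrap = TRUE), 1e-5)
  }
})

test_that("a random unconstrained convolution is not equivariant", {
  ord <- ordinary_conv_layer(2, 2, 3, "circular", seed = 7)
  triv <- trivial_rep(cyclic_group(4))
  map <- function(x) feature_field(conv_apply(ord, x$values),
                                   rep(list(triv), 2))
  f <- random_trivial_field(16, 2, seed = 8)
  expect_gt(equivariance_residual(map, f, 1, c(0, 0), wrap = TRUE), 1e-3)
})

test_that("zero fields map to bias-valued constants", {
  lay <- make_eq_layer()
  f <- feature_field(array(0, c(8, 8, 2)),
                     rep(list(trivial_rep(cyclic_group(4))), 2))
  out <- equivariant_conv(lay, f)
  expected <- rep(rep(lay$bias, each = 4), each = 64)
  expect_equal(as.numeric(out$values), expected)
})

test_that("impulse response of an unconstrained basis element stamps the kernel", {
  g1 <- cyclic_group(1)
  lay <- equivariant_conv_layer(trivial_rep(g1), trivial_rep(g1), 1, 1, 3,
                                init = "zero")
  lay$coef[4, 1, 1] <- 1
  D <- matrix(0, 9, 9); D[5, 5] <- 1
  out <- conv_apply(lay, D)[, , 1]
  K <- expand_kernel(lay)[, , 1, 1]
  # cross-correlation of a centred delta stamps the flipped kernel
  expect_equal(out[4:6, 4:6], K[3:1, 3:1], tolerance = 1e-14)
  expect_true(all(out[-(4:6), ] == 0))
})

test_that("layer subsumption: expanded ordinary layer reproduces the steerable layer", {
  lay <- make_eq_layer()
  ord <- ordinary_conv_layer(lay$c_in, lay$c_out, 3, lay$padding,
                             init = "zero")
  ord$weight <- expand_kernel(lay)
  ord$bias <- rep(lay$bias, each = lay$rep_out$dim)
  x <- array(rnorm(10 * 10 * lay$c_in), c(10, 10, lay$c_in))
  expect_identical(conv_apply(ord, x), conv_apply(lay, x))
})

test_that("pointwise nonlinearity implements the leaky ReLU and preserves equivariance", {
  expect_equal(leaky_relu(2), 2)
  expect_equal(leaky_relu(-2), -0.02)
  lay <- make_eq_layer()
  f <- random_trivial_field(12, 2, seed = 9)
  idmap <- pointwise_nonlinearity(f, function(x) x)
  expect_identical(idmap$values, f$values)
  map <- function(x) pointwise_nonlinearity(equivariant_conv(lay, x))
  for (k in 0:3) {
    expect_lt(equivariance_residual(map, f, k, c(-1, 2), wrap = TRUE), 1e-5)
  }
  bad_rep <- structure(list(group = cyclic_group(4), dim = 2L,
                            kind = "irrep"), class = "group_rep")
  bad <- feature_field(array(1, c(4, 4, 2)), list(bad_rep))
  expect_error(pointwise_nonlinearity(bad), "permutation")
})

test_that("norm nonlinearity scales block norms and stays equivariant", {
  g <- cyclic_group(4)
  f0 <- feature_field(array(0, c(6, 6, 4)), regular_rep(g))
  expect_true(all(norm_nonlinearity(f0, function(n) n + 1)$values == 0))
  lay <- make_eq_layer()
  f <- random_trivial_field(12, 2, seed = 10)
  h <- equivariant_conv(lay, f)
  expect_equal(norm_nonlinearity(h, function(n) rep(1, length(n)))$values,
               h$values)
  map <- function(x) norm_nonlinearity(equivariant_conv(lay, x),
                                       function(n) 1 / (1 + n))
  for (k in 0:3) {
    expect_lt(equivariance_residual(map, f, k, c(2, 1), wrap = TRUE), 1e-5)
  }
})

test_that("three-layer stacks remain equivariant (composition property)", {
  g <- cyclic_group(4)
  l1 <- make_eq_layer(n_in = 1, n_out = 2, seed = 21)
  l2 <- equivariant_conv_layer(regular_rep(g), regular_rep(g), 2, 2, 3,
                               "circular", seed = 22)
  l3 <- equivariant_conv_layer(regular_rep(g), trivial_rep(g), 2, 1, 3,
                               "circular", seed = 23)
  set.seed(24)
  l2$bias <- rnorm(2); l3$bias <- rnorm(1)
  map <- function(x) {
    equivariant_conv(l3, pointwise_nonlinearity(
      equivariant_conv(l2, pointwise_nonlinearity(
        equivariant_conv(l1, x)))))
  }
  f <- random_trivial_field(14, 1, seed = 25)
  for (k in 0:3) {
    expect_lt(equivariance_residual(map, f, k, c(4, -3), wrap = TRUE), 1e-5)
  }
})

test_that("layer contracts reject mismatched inputs", {
  lay <- make_eq_layer()
  f_wrong <- random_trivial_field(8, 3, seed = 1)
  expect_error(equivariant_conv(lay, f_wrong), "match")
  expect_error(conv_apply(lay, array(0, c(4, 4, 5))), "channels")
})
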