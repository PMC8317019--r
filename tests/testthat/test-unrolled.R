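small_ct_net <- function(flavour, size = 12, it = 2, width = 8, seed = 3,
                         n_angles = 8, padding = "zeros") {
  geom <- radon_geometry(size, n_angles = n_angles)
  net <- build_unrolled_net(flavour, op_radon(geom), size, it = it,
                            width_product = width, m = 4, padding = padding,
                            seed = seed)
  list(net = net, geom = geom)
}

perturb <- function(net, sd = 0.05, seed = 5) {
  th <- net_params(net)
  set.seed(seed)
  net_set_params(net, th + rnorm(length(th)) * sd)
}

test_that("channel accounting follows the architecture conventions", {
  # CT: lift input 7 = 1 + 5 + 1, project output 6 = 1 + 5
  pn <- prox_net("equivariant", image_channels = 1L, memory_channels = 5L,
                 width_product = 96L, m = 4L)
  expect_equal(pn$lift$c_in, 7L)
  expect_equal(pn$project$c_out, 6L)
  # 96 intermediate channels = 24 regular fields of dimension 4
  expect_equal(pn$lift$n_out, 24L)
  expect_equal(pn$lift$rep_out$dim, 4L)
  expect_equal(pn$intermediate$c_in, 96L)
  # MRI: complex images as two scalar channels
  pn2 <- prox_net("ordinary", image_channels = 2L, memory_channels = 5L,
                  width_product = 16L)
  expect_equal(pn2$lift$c_in, 9L)
  expect_equal(pn2$project$c_out, 7L)
  # group order must divide the width
  expect_error(prox_net("equivariant", width_product = 10L, m = 4L),
               "divide")
  # m = 1 equivariant has the same parameter count as the ordinary net
  p1 <- prox_net("equivariant", width_product = 8L, m = 1L)
  po <- prox_net("ordinary", width_product = 8L, m = 1L)
  expect_equal(length(steerrec:::prox_net_params(p1)), length(steerrec:::prox_net_params(po)))
})

test_that("at initialisation the residual branch is the identity", {
  pn <- prox_net("equivariant", 1, 5, 8, 4, seed = 2)
  set.seed(7)
  u <- array(rnorm(64), c(8, 8, 1))
  s <- array(rnorm(320), c(8, 8, 5))
  g <- array(rnorm(64), c(8, 8, 1))
  res <- prox_net_apply(pn, u, s, g)
  z <- array(c(u, s, g), c(8, 8, 7))
  direct <- conv_apply(pn$project, conv_apply(pn$lift, z))
  expect_identical(as.numeric(c(res$u, res$s)), as.numeric(direct))
  # zero input with zero biases maps to zero
  z0 <- array(0, c(8, 8, 1))
  res0 <- prox_net_apply(pn, z0, array(0, c(8, 8, 5)), z0)
  expect_true(all(res0$u == 0) && all(res0$s == 0))
})

test_that("equivariant prox-nets commute with the group; ordinary ones do not", {
  geom <- radon_geometry(12, n_angles = 8)
  net <- build_unrolled_net("equivariant", op_radon(geom), 12, it = 2,
                            width_product = 8, m = 4, padding = "circular",
                            seed = 4)
  net <- perturb(net, 0.1, seed = 8)  # activate the intermediate branch
  expect_true(all(net_equivariance_residuals(net) < 1e-5))
  ord <- build_unrolled_net("ordinary", op_radon(geom), 12, it = 1,
                            width_product = 8, padding = "circular",
                            seed = 4)
  ord <- perturb(ord, 0.1, seed = 9)
  expect_gt(max(net_equivariance_residuals(ord)), 1e-3)
})

test_that("backpropagated gradients match central finite differences", {
  for (flavour in c("ordinary", "equivariant")) {
    sc <- small_ct_net(flavour)
    net <- perturb(sc$net, 0.05, seed = 10)
    set.seed(11)
    u <- array(runif(144), c(12, 12, 1))
    y <- radon_apply(u[, , 1], sc$geom)
    lg <- net_loss_grad(net, u, y)
    th <- net_params(net)
    ids <- sample(length(th), 8)
    h <- 1e-6
    for (i in ids) {
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      fd <- (net_loss_grad(net_set_params(net, tp), u, y)$loss -
               net_loss_grad(net_set_params(net, tm), u, y)$loss) / (2 * h)
      expect_lt(abs(fd - lg$grad[i]) / max(abs(fd), 1e-8), 1e-4)
    }
  }
})

test_that("all-zero networks reconstruct zero; outputs are finite and shaped", {
  sc <- small_ct_net("ordinary")
  net <- net_set_params(sc$net, 0 * net_params(sc$net))
  y <- matrix(rnorm(sc$geom$n_angles * sc$geom$n_detectors), sc$geom$n_angles)
  out <- unrolled_reconstruct(net, y)
  expect_equal(dim(out), c(12, 12, 1))
  expect_true(all(out == 0))
  out2 <- unrolled_reconstruct(perturb(sc$net, 0.02, 12), y)
  expect_true(all(is.finite(out2)))
})

test_that("classical prox substitutions reproduce the proximal gradient method", {
  size <- 12
  geom <- radon_geometry(size, n_angles = 10)
  op <- op_radon(geom)
  tau <- 1 / operator_norm(op, size)^2
  J <- functional_tikhonov(0.5)
  u <- ellipse_phantom(phantom_spec(16, seed = 5))[3:14, 3:14]
  y <- radon_apply(u, geom)
  net <- build_unrolled_net("ordinary", op, size, it = 5, width_product = 4,
                            m = 1)
  net$prox_nets <- lapply(1:5, function(i) {
    function(u, s, g) list(u = J$prox(u - tau * g, tau), s = s)
  })
  expect_identical(unrolled_reconstruct(net, y),
                   proximal_gradient(y, op, J, tau = tau, iters = 5,
                                     image_size = size)$u)
})

test_that("weights are untied across iterations", {
  sc <- small_ct_net("equivariant")
  net <- sc$net
  before <- steerrec:::prox_net_params(net$prox_nets[[2]])
  th <- net_params(net)
  n1 <- length(steerrec:::prox_net_params(net$prox_nets[[1]]))
  th[seq_len(n1)] <- th[seq_len(n1)] + 1
  net2 <- net_set_params(net, th)
  expect_identical(steerrec:::prox_net_params(net2$prox_nets[[2]]), before)
  expect_false(identical(steerrec:::prox_net_params(net2$prox_nets[[1]]),
                         steerrec:::prox_net_params(net$prox_nets[[1]])))
})

test_that("short training reduces the loss on a toy denoising task", {
  op <- op_identity(1)
  losses <- vapply(1:2, function(sd) {
    fx <- figure1_fixture(seed = sd, size = 32)
    dataset <- list(list(u = array(fx$clean, c(32, 32, 1)),
                         y = array(fx$noisy, c(32, 32, 1))))
    net <- build_unrolled_net("equivariant", op, 32, it = 1,
                              width_product = 8, memory_channels = 2L,
                              seed = sd)
    tr <- train_erm(net, dataset, n_iters = 60, lr = 1e-3, seed = sd)
    c(first = tr$trace[1], last = tr$trace[length(tr$trace)])
  }, numeric(2))
  expect_true(all(losses["last", ] < losses["first", ]))
})

test_that("training a degenerate zero-target dataset drives the output to zero", {
  op <- op_identity(1)
  set.seed(20)
  dataset <- list(list(u = array(0, c(16, 16, 1)),
                       y = array(rnorm(256), c(16, 16, 1))))
  net <- build_unrolled_net("ordinary", op, 16, it = 1, width_product = 4,
                            m = 1, memory_channels = 2L, seed = 21)
  tr <- train_erm(net, dataset, n_iters = 150, lr = 5e-3, seed = 22)
  expect_lt(tr$trace[150], 0.1 * tr$trace[1])
})

test_that("subsumption embedding reproduces the equivariant net exactly", {
  sc <- small_ct_net("equivariant", padding = "circular")
  net <- perturb(sc$net, 0.1, seed = 13)
  emb <- subsumption_embed(net)
  expect_equal(emb$flavour, "ordinary")
  set.seed(14)
  y <- matrix(rnorm(sc$geom$n_angles * sc$geom$n_detectors), sc$geom$n_angles)
  expect_lt(max(abs(unrolled_reconstruct(emb, y) -
                      unrolled_reconstruct(net, y))), 1e-12)
  # zero equivariant net embeds to the zero ordinary net
  z <- net_set_params(net, 0 * net_params(net))
  expect_true(all(net_params(subsumption_embed(z)) == 0))
  # gradients through the embedded parameterisation are finite
  u <- array(runif(144), c(12, 12, 1))
  yr <- radon_apply(u[, , 1], sc$geom)
  lg <- net_loss_grad(emb, u, yr)
  expect_true(all(is.finite(lg$grad)))
})
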