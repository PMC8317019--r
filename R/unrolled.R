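#' Learned proximal operator (prox-net)
#'
#' The three-affine-layer block
#' \code{K_project o (id + phi o K_intermediate) o K_lift} with a pointwise
#' leaky ReLU, mapping the channel concatenation of the current image
#' estimate \code{u}, the memory state \code{s} and the data-discrepancy
#' gradient \code{g} to an updated \code{(u, s)}. In the equivariant flavour
#' the input/output channels carry trivial representations and the
#' intermediate channels regular representations of the rotation group, so
#' the whole block commutes with on-grid roto-translations; the ordinary
#' flavour uses unconstrained convolutions of identical widths.
#'
#' \code{K_intermediate} (weights and bias) is initialised to zero, so at
#' initialisation the inner residual branch is exactly the identity and the
#' block reduces to \code{K_project o K_lift}.
#'
#' @param flavour \code{"ordinary"} or \code{"equivariant"}.
#' @param image_channels channels of \code{u} (1 for CT, 2 for MRI).
#' @param memory_channels memory state width (default 5).
#' @param width_product total intermediate channel count (the group order
#'   times the number of regular fields in the equivariant flavour).
#' @param m rotation-group order (equivariant flavour; must divide
#'   \code{width_product}).
#' @param kernel_size odd convolution size (default 3).
#' @param padding \code{"zeros"} or \code{"circular"}.
#' @param seed seed for the He initialisation of lift and project.
#' @return object of class \code{prox_net}.
#' @export
prox_net <- function(flavour = c("ordinary", "equivariant"),
                     image_channels = 1L, memory_channels = 5L,
                     width_product = 96L, m = 4L, kernel_size = 3L,
                     padding = "zeros", seed = 1L) {
  flavour <- match.arg(flavour)
  c_in <- 2L * image_channels + memory_channels
  c_out <- image_channels + memory_channels
  if (flavour == "equivariant") {
    if (width_product %% m != 0) {
      stop("group order m must divide width_product", call. = FALSE)
    }
    group <- cyclic_group(m)
    triv <- trivial_rep(group); reg <- regular_rep(group)
    n_f <- width_product %/% m
    lift <- equivariant_conv_layer(triv, reg, c_in, n_f, kernel_size,
                                   padding, "he", derive_seed(seed, 1L))
    inter <- equivariant_conv_layer(reg, reg, n_f, n_f, kernel_size,
                                    padding, "zero")
    proj <- equivariant_conv_layer(reg, triv, n_f, c_out, kernel_size,
                                   padding, "he", derive_seed(seed, 2L))
  } else {
    lift <- ordinary_conv_layer(c_in, width_product, kernel_size, padding,
                                "he", derive_seed(seed, 1L))
    inter <- ordinary_conv_layer(width_product, width_product, kernel_size,
                                 padding, "zero")
    proj <- ordinary_conv_layer(width_product, c_out, kernel_size, padding,
                                "he", derive_seed(seed, 2L))
  }
  structure(list(lift = lift, intermediate = inter, project = proj,
                 flavour = flavour, image_channels = image_channels,
                 memory_channels = memory_channels,
                 width_product = width_product, m = m,
                 kernel_size = kernel_size, padding = padding),
            class = "prox_net")
}

concat_channels <- function(...) {
  parts <- list(...)
  H <- dim(parts[[1]])[1]; W <- dim(parts[[1]])[2]
  array(unlist(parts, use.names = FALSE),
        c(H, W, sum(vapply(parts, function(p) dim(p)[3], numeric(1)))))
}

#' Apply a prox-net
#'
#' @param net a \code{prox_net}.
#' @param u image estimate array \code{[H, W, image_channels]}.
#' @param s memory state array \code{[H, W, memory_channels]}.
#' @param g discrepancy gradient, same shape as \code{u}.
#' @param tape logical; also return intermediates for backpropagation.
#' @return list with updated \code{u} and \code{s} (and \code{tape} data).
#' @export
prox_net_apply <- function(net, u, s, g, tape = FALSE) {
  cu <- net$image_channels; cs <- net$memory_channels
  if (dim(u)[3] != cu || dim(s)[3] != cs || dim(g)[3] != cu) {
    stop("channel counts do not match the prox-net", call. = FALSE)
  }
  z <- concat_channels(u, s, g)
  if (!tape) {
    h1 <- conv_apply(net$lift, z)
    pre2 <- conv_apply(net$intermediate, h1)
    h2 <- h1 + leaky_relu(pre2)
    out <- conv_apply(net$project, h2)
    return(list(u = out[, , seq_len(cu), drop = FALSE],
                s = out[, , cu + seq_len(cs), drop = FALSE]))
  }
  # cache expanded weight matrices and im2col matrices for backprop
  ks <- net$kernel_size; pd <- pad_code(net$padding)
  W1 <- layer_weight_matrix(net$lift)
  W2 <- layer_weight_matrix(net$intermediate)
  W3 <- layer_weight_matrix(net$project)
  t1 <- conv2d_fwd_tape_cpp(z, W1, expand_bias(net$lift), ks, pd)
  t2 <- conv2d_fwd_tape_cpp(t1$out, W2, expand_bias(net$intermediate), ks, pd)
  h2 <- t1$out + leaky_relu(t2$out)
  t3 <- conv2d_fwd_tape_cpp(h2, W3, expand_bias(net$project), ks, pd)
  out <- t3$out
  list(u = out[, , seq_len(cu), drop = FALSE],
       s = out[, , cu + seq_len(cs), drop = FALSE],
       tape = list(X1 = t1$X, X2 = t2$X, X3 = t3$X, pre2 = t2$out,
                   W1 = W1, W2 = W2, W3 = W3))
}

# ---- parameter flattening -------------------------------------------------

layer_params <- function(layer) {
  if (inherits(layer, "equivariant_conv")) {
    c(as.numeric(layer$coef), layer$bias)
  } else {
    c(as.numeric(layer$weight), layer$bias)
  }
}

layer_set_params <- function(layer, v) {
  if (inherits(layer, "equivariant_conv")) {
    nc <- length(layer$coef)
    layer$coef <- array(v[seq_len(nc)], dim(layer$coef))
    layer$bias <- v[nc + seq_along(layer$bias)]
  } else {
    nw <- length(layer$weight)
    layer$weight <- array(v[seq_len(nw)], dim(layer$weight))
    layer$bias <- v[nw + seq_along(layer$bias)]
  }
  layer
}

layer_n_params <- function(layer) length(layer_params(layer))

# gradient w.r.t. a layer's parameters from the compiled backward outputs
layer_param_grad <- function(layer, dW, db) {
  s <- layer$size
  if (inherits(layer, "equivariant_conv")) {
    d_in <- layer$rep_in$dim; d_out <- layer$rep_out$dim
    dK <- array(t(dW), c(s, s, layer$c_in, layer$c_out))
    nb <- dim(layer$coef)[1]
    dcoef <- array(0, dim(layer$coef))
    if (nb > 0) {
      for (io in seq_len(layer$n_out)) {
        for (ji in seq_len(layer$n_in)) {
          blk <- dK[, , (ji - 1) * d_in + seq_len(d_in),
                    (io - 1) * d_out + seq_len(d_out), drop = FALSE]
          dcoef[, ji, io] <- crossprod(layer$basis$bmat, as.numeric(blk))
        }
      }
    }
    dbias <- vapply(seq_len(layer$n_out), function(io) {
      sum(db[(io - 1) * d_out + seq_len(d_out)])
    }, numeric(1))
    c(as.numeric(dcoef), dbias)
  } else {
    c(as.numeric(t(dW)), db)
  }
}

prox_net_params <- function(net) {
  c(layer_params(net$lift), layer_params(net$intermediate),
    layer_params(net$project))
}

prox_net_set_params <- function(net, v) {
  n1 <- layer_n_params(net$lift)
  n2 <- layer_n_params(net$intermediate)
  n3 <- layer_n_params(net$project)
  net$lift <- layer_set_params(net$lift, v[seq_len(n1)])
  net$intermediate <- layer_set_params(net$intermediate, v[n1 + seq_len(n2)])
  net$project <- layer_set_params(net$project, v[n1 + n2 + seq_len(n3)])
  net
}

#' Flattened network parameters
#'
#' @param net an \code{unrolled_net}.
#' @return numeric vector of all learnable parameters (untied across the
#'   unrolled iterations).
#' @export
net_params <- function(net) {
  unlist(lapply(net$prox_nets, prox_net_params), use.names = FALSE)
}

#' @rdname net_params
#' @param v replacement parameter vector.
#' @export
net_set_params <- function(net, v) {
  offset <- 0L
  for (i in seq_along(net$prox_nets)) {
    ni <- length(prox_net_params(net$prox_nets[[i]]))
    net$prox_nets[[i]] <- prox_net_set_params(net$prox_nets[[i]],
                                              v[offset + seq_len(ni)])
    offset <- offset + ni
  }
  net
}

# backward through one prox-net; returns parameter grads and input grads
prox_net_backward <- function(net, tape, du, ds) {
  ks <- net$kernel_size; pd <- pad_code(net$padding)
  gy3 <- concat_channels(du, ds)
  b3 <- conv2d_bwd_cpp(tape$X3, tape$W3, gy3, ks, pd)
  dh2 <- b3$dx
  dpre2 <- dh2 * leaky_relu_grad(tape$pre2)
  b2 <- conv2d_bwd_cpp(tape$X2, tape$W2, dpre2, ks, pd)
  dh1 <- dh2 + b2$dx
  b1 <- conv2d_bwd_cpp(tape$X1, tape$W1, dh1, ks, pd)
  cu <- net$image_channels; cs <- net$memory_channels
  dz <- b1$dx
  list(grad = c(layer_param_grad(net$lift, b1$dW, b1$db),
                layer_param_grad(net$intermediate, b2$dW, b2$db),
                layer_param_grad(net$project, b3$dW, b3$db)),
       du = dz[, , seq_len(cu), drop = FALSE],
       ds = dz[, , cu + seq_len(cs), drop = FALSE],
       dg = dz[, , cu + cs + seq_len(cu), drop = FALSE])
}

#' Build an unrolled learned proximal gradient network
#'
#' Assembles \code{it} untied prox-nets around a forward-operator pair. The
#' equivariant flavour lifts the trivial input fields to
#' \code{width_product / m} regular fields; the ordinary flavour uses plain
#' convolutions with the matched channel counts, so both have identical
#' activation shapes at every layer and the ordinary parameterisation strictly
#' contains the equivariant one.
#'
#' @param flavour \code{"ordinary"} or \code{"equivariant"}.
#' @param operator operator pair (\code{\link{op_radon}} or
#'   \code{\link{op_masked_fourier}}).
#' @param image_size reconstructed image side length.
#' @param it number of unrolled iterations (default 8).
#' @param width_product intermediate width (paper-scale preset 96;
#'   desk-scale experiments in this package use smaller values).
#' @param m rotation-group order (default 4).
#' @param memory_channels memory width (default 5).
#' @param kernel_size odd convolution size.
#' @param padding convolution padding.
#' @param seed master seed for initialisation.
#' @return object of class \code{unrolled_net}.
#' @export
build_unrolled_net <- function(flavour = c("ordinary", "equivariant"),
                               operator, image_size, it = 8L,
                               width_product = 96L, m = 4L,
                               memory_channels = 5L, kernel_size = 3L,
                               padding = "zeros", seed = 1L) {
  flavour <- match.arg(flavour)
  nets <- lapply(seq_len(it), function(i) {
    prox_net(flavour, operator$image_channels, memory_channels,
             width_product, m, kernel_size, padding,
             seed = derive_seed(seed, 100L + i))
  })
  structure(list(prox_nets = nets, operator = operator, flavour = flavour,
                 image_size = as.integer(image_size), it = as.integer(it),
                 width_product = width_product, m = m,
                 memory_channels = memory_channels,
                 image_channels = operator$image_channels,
                 kernel_size = kernel_size, padding = padding),
            class = "unrolled_net")
}

unrolled_forward <- function(net, y, tape = FALSE) {
  n <- net$image_size
  cu <- net$image_channels; cs <- net$memory_channels
  u <- array(0, c(n, n, cu))
  s <- array(0, c(n, n, cs))
  tapes <- if (tape) vector("list", net$it) else NULL
  for (i in seq_len(net$it)) {
    g <- discrepancy_gradient(u, y, net$operator)
    pn <- net$prox_nets[[i]]
    if (is.function(pn)) {
      res <- pn(u, s, g)
      if (tape) tapes[[i]] <- list(classical = TRUE)
    } else {
      res <- prox_net_apply(pn, u, s, g, tape = tape)
      if (tape) tapes[[i]] <- res$tape
    }
    u <- res$u; s <- res$s
    if (any(!is.finite(u))) {
      stop("non-finite iterate at unrolled iteration ", i, call. = FALSE)
    }
  }
  list(u = u, s = s, tapes = tapes)
}

#' Reconstruct an image from measurements
#'
#' Runs the unrolled learned proximal gradient method from \code{u = 0},
#' \code{s = 0}. Elements of \code{prox_nets} may also be plain functions
#' \code{(u, s, g) -> list(u, s)}; substituting the classical update
#' \code{u <- prox_tauJ(u - tau g)} recovers the classical proximal gradient
#' method exactly.
#'
#' @param net an \code{unrolled_net}.
#' @param y measurements matching the network's operator.
#' @return reconstructed image array \code{[H, W, image_channels]}.
#' @export
unrolled_reconstruct <- function(net, y) {
  unrolled_forward(net, y, tape = FALSE)$u
}

#' Loss and gradient of one training pair
#'
#' Mean squared error of the reconstruction against the ground truth, with
#' the exact gradient with respect to all network parameters obtained by
#' backpropagation through the unrolled iterations (the image-to-image path
#' through the data-discrepancy gradient contributes its own term
#' \code{A^T A} per iteration, applied via the operator pair).
#'
#' @param net an \code{unrolled_net} (all prox-nets learnable).
#' @param u_true ground-truth image array.
#' @param y measurements.
#' @return list with \code{loss} and flattened \code{grad}.
#' @export
net_loss_grad <- function(net, u_true, y) {
  fw <- unrolled_forward(net, y, tape = TRUE)
  n_el <- length(u_true)
  diffv <- fw$u - u_true
  loss <- mean(diffv^2)
  du <- 2 * diffv / n_el
  ds <- array(0, c(net$image_size, net$image_size, net$memory_channels))
  grads <- vector("list", net$it)
  for (i in rev(seq_len(net$it))) {
    bk <- prox_net_backward(net$prox_nets[[i]], fw$tapes[[i]], du, ds)
    grads[[i]] <- bk$grad
    # g_i = A^T (A u_{i-1} - y): contributes A^T A applied to dg
    ata_dg <- net$operator$adjoint(net$operator$apply(bk$dg))
    du <- bk$du + array(as.numeric(ata_dg), dim(bk$du))
    ds <- bk$ds
  }
  list(loss = loss, grad = unlist(grads, use.names = FALSE))
}

#' Train by empirical risk minimisation
#'
#' Minimises the mean reconstruction error over the training pairs with Adam
#' (minibatch size 1: one uniformly drawn pair per iteration). Deterministic
#' given the seed. Paper-scale preset: learning rate 1e-4, beta1 0.9,
#' beta2 0.999, eps 1e-8; desk-scale experiments shorten the schedule and
#' raise the learning rate.
#'
#' @param net an \code{unrolled_net}.
#' @param dataset list of pairs as from \code{\link{make_dataset}}.
#' @param n_iters Adam iterations.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param restart_every optional warm-restart period: every this many
#'   iterations the Adam moment estimates (and bias-correction counter) are
#'   reset while the parameters are kept. Restarts help short schedules
#'   escape the slow tail of the second-moment accumulation; \code{NULL}
#'   (default) is plain Adam.
#' @param seed seed controlling minibatch sampling.
#' @param verbose print progress every \code{verbose} iterations (0 = quiet).
#' @return list with the trained \code{net} and the per-iteration loss
#'   \code{trace}.
#' @export
train_erm <- function(net, dataset, n_iters = 100L, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      restart_every = NULL, seed = 1L, verbose = 0L) {
  theta <- net_params(net)
  m1 <- numeric(length(theta))
  m2 <- numeric(length(theta))
  tick <- 0L
  trace <- numeric(n_iters)
  N <- length(dataset)
  order_seed <- derive_seed(seed, 555L)
  picks <- with_seed(order_seed, sample.int(N, n_iters, replace = TRUE))
  for (it in seq_len(n_iters)) {
    if (!is.null(restart_every) && it > 1 &&
        (it - 1) %% restart_every == 0) {
      m1[] <- 0; m2[] <- 0; tick <- 0L
    }
    pair <- dataset[[picks[it]]]
    lg <- net_loss_grad(net, pair$u, pair$y)
    if (!is.finite(lg$loss)) {
      stop("non-finite training loss at iteration ", it, call. = FALSE)
    }
    trace[it] <- lg$loss
    tick <- tick + 1L
    m1 <- beta1 * m1 + (1 - beta1) * lg$grad
    m2 <- beta2 * m2 + (1 - beta2) * lg$grad^2
    mhat <- m1 / (1 - beta1^tick)
    vhat <- m2 / (1 - beta2^tick)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    net <- net_set_params(net, theta)
    if (verbose > 0 && it %% verbose == 0) {
      message(sprintf("iter %d loss %.6g", it, lg$loss))
    }
  }
  list(net = net, trace = trace)
}

#' Embed an equivariant network into the ordinary parameterisation
#'
#' Expands every steerable layer's kernel and tied bias into plain
#' convolution weights, returning a width-matched ordinary network whose
#' outputs coincide with the source network on any input (same arithmetic
#' path once expanded).
#'
#' @param net an equivariant \code{unrolled_net}.
#' @return an ordinary \code{unrolled_net}.
#' @export
subsumption_embed <- function(net) {
  stopifnot(net$flavour == "equivariant")
  out <- net
  out$flavour <- "ordinary"
  out$prox_nets <- lapply(net$prox_nets, function(pn) {
    stopifnot(inherits(pn, "prox_net"))
    embed_layer <- function(layer) {
      ord <- ordinary_conv_layer(layer$c_in, layer$c_out, layer$size,
                                 layer$padding, init = "zero")
      ord$weight <- expand_kernel(layer)
      ord$bias <- expand_bias(layer)
      ord
    }
    pn$lift <- embed_layer(pn$lift)
    pn$intermediate <- embed_layer(pn$intermediate)
    pn$project <- embed_layer(pn$project)
    pn$flavour <- "ordinary"
    pn
  })
  out
}

#' Per-prox-net equivariance residuals of a network
#'
#' For each prox-net, measures the relative commutation residual of the map
#' \code{(u, s, g) -> (u', s')} (as a trivial-field image-to-image map) under
#' every rotation of the group and a fixed integer translation, using
#' circular padding semantics (wrap translations). The end-to-end network is
#' not expected to be equivariant (the data-discrepancy gradient is not an
#' equivariant operator for incomplete measurements); only the prox-nets are.
#'
#' @param net an \code{unrolled_net}.
#' @param m group order to test (default the net's).
#' @param seed seed for the random probe field.
#' @param t integer translation used in the probe.
#' @return numeric vector of worst-case residuals, one per prox-net.
#' @export
net_equivariance_residuals <- function(net, m = net$m, seed = 1L, t = NULL) {
  if (is.null(t)) {
    # zero padding breaks exact translation equivariance at the boundary,
    # so probe rotations only in that case
    t <- if (identical(net$padding, "circular")) c(3L, -2L) else c(0L, 0L)
  }
  group <- cyclic_group(m)
  triv <- trivial_rep(group)
  n <- net$image_size
  cu <- net$image_channels; cs <- net$memory_channels
  c_in <- 2L * cu + cs
  probe <- with_seed(seed, array(rnorm(n * n * c_in), c(n, n, c_in)))
  field <- feature_field(probe, rep(list(triv), c_in))
  vapply(net$prox_nets, function(pn) {
    map <- function(f) {
      v <- f$values
      res <- prox_net_apply(pn, v[, , seq_len(cu), drop = FALSE],
                            v[, , cu + seq_len(cs), drop = FALSE],
                            v[, , cu + cs + seq_len(cu), drop = FALSE])
      feature_field(concat_channels(res$u, res$s),
                    rep(list(triv), cu + cs))
    }
    worst <- 0
    for (k in seq_len(group$order) - 1L) {
      worst <- max(worst, equivariance_residual(map, field, k, t, wrap = TRUE))
    }
    worst
  }, numeric(1))
}
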