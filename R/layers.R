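#' Ordinary convolution layer
#'
#' A plain 2-D cross-correlation layer with same padding and one bias per
#' output channel. Weight layout: array \code{[s, s, C_in, C_out]}.
#'
#' @param c_in,c_out channel counts.
#' @param size odd kernel side (default 3).
#' @param padding \code{"zeros"} or \code{"circular"}.
#' @param init \code{"he"}, \code{"zero"}.
#' @param seed integer seed for the He draw.
#' @return object of class \code{c("ordinary_conv", "conv_layer")}.
#' @export
ordinary_conv_layer <- function(c_in, c_out, size = 3L, padding = "zeros",
                                init = "he", seed = 1L) {
  stopifnot(size %% 2 == 1)
  n <- size * size * c_in * c_out
  w <- if (init == "zero") rep(0, n) else {
    with_seed(seed, rnorm(n, sd = sqrt(2 / (size * size * c_in))))
  }
  structure(list(weight = array(w, c(size, size, c_in, c_out)),
                 bias = rep(0, c_out), c_in = c_in, c_out = c_out,
                 size = size, padding = padding),
            class = c("ordinary_conv", "conv_layer"))
}

#' Equivariant (steerable) convolution layer
#'
#' A convolution layer whose kernel is constrained to a steerable basis so
#' that the layer commutes with roto-translations of the cyclic group. Input
#' and output channels are organised into fields: \code{n_in} copies of
#' \code{rep_in} and \code{n_out} copies of \code{rep_out}. One basis is
#' solved per representation pair; the learnable parameters are the expansion
#' coefficients (one coefficient block per field pair) and one bias per
#' output field, replicated across that field's channels (ties required for
#' exact equivariance under channel-permuting regular representations).
#'
#' He-style initialisation scales the coefficients so that the expanded
#' kernel has the variance a fan-in He initialisation would give an ordinary
#' kernel of the same shape.
#'
#' @param rep_in,rep_out field representations (shared group).
#' @param n_in,n_out numbers of input/output fields.
#' @param size odd kernel side.
#' @param padding \code{"zeros"} or \code{"circular"}.
#' @param init \code{"he"} or \code{"zero"}.
#' @param seed seed for the coefficient draw.
#' @return object of class \code{c("equivariant_conv", "conv_layer")}.
#' @export
equivariant_conv_layer <- function(rep_in, rep_out, n_in, n_out, size = 3L,
                                   padding = "zeros", init = "he", seed = 1L) {
  basis <- solve_kernel_basis(rep_in, rep_out, size)
  nb <- ncol(basis$bmat)
  c_in <- n_in * rep_in$dim
  c_out <- n_out * rep_out$dim
  ncoef <- nb * n_in * n_out
  coef <- if (init == "zero" || ncoef == 0) rep(0, ncoef) else {
    # basis columns are Frobenius-orthonormal, so E||K_block||_F^2 = sum c^2;
    # match He: per-element variance 2 / (s*s*c_in)
    sc <- sqrt(2 / (size * size * c_in) *
                 size * size * rep_in$dim * rep_out$dim / nb)
    with_seed(seed, rnorm(ncoef, sd = sc))
  }
  structure(list(coef = array(coef, c(nb, n_in, n_out)),
                 bias = rep(0, n_out),
                 basis = basis, rep_in = rep_in, rep_out = rep_out,
                 n_in = n_in, n_out = n_out,
                 c_in = c_in, c_out = c_out, size = size, padding = padding),
            class = c("equivariant_conv", "conv_layer"))
}

#' Expand an equivariant layer into an ordinary convolution kernel
#'
#' Assembles the blockwise linear combination of basis elements into a full
#' kernel array \code{[s, s, C_in, C_out]}. Linear in the coefficients.
#'
#' @param layer an \code{equivariant_conv} layer.
#' @return kernel array.
#' @export
expand_kernel <- function(layer) {
  stopifnot(inherits(layer, "equivariant_conv"))
  s <- layer$size
  d_in <- layer$rep_in$dim; d_out <- layer$rep_out$dim
  K <- array(0, c(s, s, layer$c_in, layer$c_out))
  nb <- dim(layer$coef)[1]
  for (io in seq_len(layer$n_out)) {
    for (ji in seq_len(layer$n_in)) {
      if (nb > 0) {
        blk <- array(layer$basis$bmat %*% layer$coef[, ji, io],
                     c(s, s, d_in, d_out))
        K[, , (ji - 1) * d_in + seq_len(d_in),
          (io - 1) * d_out + seq_len(d_out)] <- blk
      }
    }
  }
  K
}

# per-channel bias vector (tied within each output field)
expand_bias <- function(layer) {
  if (inherits(layer, "equivariant_conv")) {
    rep(layer$bias, each = layer$rep_out$dim)
  } else {
    layer$bias
  }
}

# weight matrix [C_out, s*s*C_in] for the compiled kernel
layer_weight_matrix <- function(layer) {
  K <- if (inherits(layer, "equivariant_conv")) expand_kernel(layer) else layer$weight
  s <- layer$size
  t(matrix(K, s * s * layer$c_in, layer$c_out))
}

pad_code <- function(padding) if (identical(padding, "circular")) 1L else 0L

#' Apply a convolution layer to a channel stack
#'
#' Low-level entry point: cross-correlation with same padding plus bias.
#'
#' @param layer a \code{conv_layer}.
#' @param x array \code{[H, W, C_in]} (or matrix for C_in = 1).
#' @return array \code{[H, W, C_out]}.
#' @export
conv_apply <- function(layer, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (dim(x)[3] != layer$c_in) {
    stop("input channels do not match the layer", call. = FALSE)
  }
  conv2d_fwd_cpp(x, layer_weight_matrix(layer), expand_bias(layer),
                 layer$size, pad_code(layer$padding))
}

#' Equivariant convolution of a feature field
#'
#' Checks that the field's types match the layer's input fields, performs the
#' ordinary convolution with the expanded kernel, and returns a field carrying
#' the layer's output types.
#'
#' @param layer an \code{equivariant_conv} layer.
#' @param field a \code{feature_field}.
#' @return a \code{feature_field}.
#' @export
equivariant_conv <- function(layer, field) {
  kinds <- vapply(field$field_types, function(r) r$kind, character(1))
  if (field_channels(field) != layer$c_in ||
      !all(kinds == layer$rep_in$kind)) {
    stop("field types do not match the layer's input fields", call. = FALSE)
  }
  out <- conv_apply(layer, field$values)
  feature_field(out, rep(list(layer$rep_out), layer$n_out))
}

#' Leaky rectified linear unit
#'
#' \code{phi(x) = x} for \code{x > 0} and \code{0.01 x} otherwise; the
#' pointwise nonlinearity used throughout the learned reconstruction nets.
#'
#' @param x numeric.
#' @return numeric of the same shape.
#' @export
leaky_relu <- function(x) ifelse(x > 0, x, 0.01 * x)

leaky_relu_grad <- function(x) ifelse(x > 0, 1, 0.01)

#' Pointwise nonlinearity on a feature field
#'
#' Applies a scalar function elementwise. Valid (equivariance-preserving)
#' only when every field type acts by permutation matrices, i.e. trivial or
#' regular representations; other types raise an error.
#'
#' @param field a \code{feature_field}.
#' @param phi scalar function (default \code{\link{leaky_relu}}).
#' @return a \code{feature_field} with unchanged types.
#' @export
pointwise_nonlinearity <- function(field, phi = leaky_relu) {
  kinds <- vapply(field$field_types, function(r) r$kind, character(1))
  if (!all(kinds %in% c("trivial", "regular"))) {
    stop("pointwise nonlinearities require permutation representations",
         call. = FALSE)
  }
  feature_field(array(phi(field$values), dim(field$values)),
                field$field_types)
}

#' Norm nonlinearity on a feature field
#'
#' Per pixel and per field block, maps the feature vector \code{f} to
#' \code{f * phi(||f||)}. Equivariant whenever all field types are unitary.
#'
#' @param field a \code{feature_field}.
#' @param phi scalar function applied to the per-pixel block norm.
#' @return a \code{feature_field}.
#' @export
norm_nonlinearity <- function(field, phi) {
  v <- field$values
  out <- array(0, dim(v))
  offset <- 0L
  for (rep in field$field_types) {
    d <- rep$dim
    block <- v[, , offset + seq_len(d), drop = FALSE]
    nrm <- sqrt(apply(block^2, c(1, 2), sum))
    g <- array(phi(nrm), dim(nrm))
    for (i in seq_len(d)) out[, , offset + i] <- block[, , i] * g
    offset <- offset + d
  }
  feature_field(out, field$field_types)
}

#' Relative equivariance residual of a field-to-field map
#'
#' Measures \code{||map(act(f)) - act(map(f))|| / (||map(act(f))|| + eps)}
#' for a roto-translation \code{(k, t)}; zero (up to floating point) for an
#' exactly equivariant map.
#'
#' @param map function \code{feature_field -> feature_field}.
#' @param field input \code{feature_field}.
#' @param k rotation element.
#' @param t integer translation.
#' @param wrap use circular translation (exact on the torus).
#' @return nonnegative scalar.
#' @export
equivariance_residual <- function(map, field, k, t = c(0L, 0L), wrap = TRUE) {
  lhs <- map(act_on_field(field, k, t, wrap = wrap))
  rhs <- act_on_field(map(field), k, t, wrap = wrap)
  num <- sqrt(sum((lhs$values - rhs$values)^2))
  den <- sqrt(sum(lhs$values^2)) + .Machine$double.eps
  num / den
}
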