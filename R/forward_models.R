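#' Parallel-beam acquisition geometry
#'
#' Uniformly spaced view angles in \code{[0, pi)}; detector offsets centred on
#' the image centre. The default detector count \code{ceiling(sqrt(2) * n)}
#' (rounded up to odd, so the central detector sits on the rotation axis)
#' covers every pixel at every angle.
#'
#' @param image_size side length of the square image.
#' @param n_angles number of views (default 50).
#' @param n_detectors detector count; default covers the image diagonal.
#' @param detector_spacing detector pitch in pixels.
#' @param step ray-integration step in pixels (default half a pixel).
#' @return object of class \code{radon_geometry}.
#' @export
radon_geometry <- function(image_size, n_angles = 50L, n_detectors = NULL,
                           detector_spacing = 1, step = 0.5) {
  if (is.null(n_detectors)) {
    n_detectors <- ceiling(sqrt(2) * image_size / detector_spacing)
    if (n_detectors %% 2 == 0) n_detectors <- n_detectors + 1
  }
  structure(list(image_size = as.integer(image_size),
                 n_angles = as.integer(n_angles),
                 angles = seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)],
                 n_detectors = as.integer(n_detectors),
                 detector_spacing = detector_spacing, step = step),
            class = "radon_geometry")
}

#' Ray transform (sinogram) of an image
#'
#' Ray-driven line integrals with bilinear sampling along each ray.
#'
#' @param image square numeric matrix.
#' @param geom a \code{radon_geometry}.
#' @return sinogram matrix \code{[n_angles, n_detectors]}.
#' @export
radon_apply <- function(image, geom) {
  stopifnot(nrow(image) == geom$image_size, ncol(image) == geom$image_size)
  radon_fwd_cpp(image, geom$angles, geom$n_detectors, geom$detector_spacing,
                geom$step)
}

#' Exact adjoint of the ray transform
#'
#' Transposed scatter of the forward map's interpolation weights, so the
#' dot-product identity holds to machine precision by construction.
#'
#' @param sinogram matrix \code{[n_angles, n_detectors]}.
#' @param geom a \code{radon_geometry}.
#' @return image matrix.
#' @export
radon_adjoint <- function(sinogram, geom) {
  stopifnot(nrow(sinogram) == geom$n_angles,
            ncol(sinogram) == geom$n_detectors)
  radon_adj_cpp(sinogram, geom$image_size, geom$image_size, geom$angles,
                geom$n_detectors, geom$detector_spacing, geom$step)
}

# symmetric discrete frequencies in cycles per sample
fft_freq <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k < (n + 1) %/% 2, k, k - n) / n
}

#' Filtered backprojection
#'
#' Ram-Lak (ramp) filtering of each view in the frequency domain followed by
#' pixel-driven linearly interpolated backprojection scaled by
#' \code{pi / n_angles}.
#'
#' @param sinogram matrix \code{[n_angles, n_detectors]}.
#' @param geom a \code{radon_geometry}.
#' @return reconstructed image matrix.
#' @export
fbp <- function(sinogram, geom) {
  n <- geom$n_detectors
  tau <- geom$detector_spacing
  # band-limited ramp built in the spatial domain (correct DC behaviour),
  # applied by FFT on zero-padded projections to avoid wrap-around
  npad <- 2^ceiling(log2(2 * n))
  idx <- 0:(npad - 1)
  k <- ifelse(idx <= npad %/% 2, idx, idx - npad)
  h <- numeric(npad)
  h[1] <- 1 / (4 * tau^2)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi * k[odd] * tau)^2
  H <- Re(fft(h))
  filtered <- t(apply(sinogram, 1, function(p) {
    q <- Re(fft(fft(c(p, rep(0, npad - n))) * H, inverse = TRUE)) / npad
    q[seq_len(n)] * tau
  }))
  bp <- backproject_cpp(filtered, geom$image_size, geom$image_size,
                        geom$angles, geom$n_detectors, geom$detector_spacing)
  bp * pi / geom$n_angles
}

#' Low-dose CT noise model
#'
#' Photon-count (Poisson) noise on the attenuated beam, converted to post-log
#' measurements: with mean photon count \code{N_in} per detector pixel and
#' base attenuation \code{mu}, counts are drawn as
#' \code{n ~ Pois(N_in exp(-mu R(u)))} and returned as
#' \code{y = -(1/mu) log(max(n / N_in, eta))}.
#'
#' @param N_in mean photons per detector pixel (default 10000).
#' @param mu base attenuation coefficient (1 / pixel length).
#' @param eta positive clip constant keeping the log argument positive
#'   (default 1e-8).
#' @param seed integer RNG seed.
#' @return object of class \code{ct_noise_model}.
#' @export
ct_noise_model <- function(N_in = 10000, mu = 0.1, eta = 1e-8, seed = 1L) {
  stopifnot(N_in > 0, mu > 0, eta > 0)
  structure(list(N_in = N_in, mu = mu, eta = eta, seed = as.integer(seed)),
            class = "ct_noise_model")
}

#' Calibrate the base attenuation coefficient
#'
#' Chooses \code{mu} so that the maximum attenuation line integral
#' \code{mu * max(R(u))} reaches a target optical depth (default 5, i.e.
#' transmission \code{exp(-5)} along the densest ray).
#'
#' @param u reference image.
#' @param geom a \code{radon_geometry}.
#' @param target target maximum of \code{mu * R(u)}.
#' @return scalar \code{mu}.
#' @export
calibrate_mu <- function(u, geom, target = 5) {
  target / max(radon_apply(u, geom))
}

#' Simulate low-dose CT measurements
#'
#' @param u square image (attenuation map).
#' @param geom a \code{radon_geometry}.
#' @param noise a \code{ct_noise_model}; if \code{noiseless = TRUE} the counts
#'   are replaced by their expectation (and with no active clip the result is
#'   exactly \code{R(u)}).
#' @param noiseless logical.
#' @return sinogram of post-log measurements.
#' @export
simulate_ct <- function(u, geom, noise, noiseless = FALSE) {
  Ru <- radon_apply(u, geom)
  lambda <- noise$N_in * exp(-noise$mu * Ru)
  n <- if (noiseless) lambda else {
    with_seed(noise$seed, array(rpois(length(lambda), lambda), dim(lambda)))
  }
  -(1 / noise$mu) * log(pmax(n / noise$N_in, noise$eta))
}

#' Variable-density Cartesian sampling mask
#'
#' Samples whole k-space columns (frequency-encoding lines): the central
#' \code{center_fraction} of columns is always fully sampled and the
#' remaining columns are drawn without replacement with probability decaying
#' with distance from the centre, until \code{target_fraction} of columns is
#' reached. Deterministic given the seed. The default target fraction 0.203
#' reproduces a ~20 percent sampling budget.
#'
#' @param shape image shape \code{c(H, W)}.
#' @param target_fraction overall fraction of sampled columns (0, 1].
#' @param center_fraction fraction of fully-sampled central columns.
#' @param seed integer seed.
#' @param decay exponent of the polynomial density decay.
#' @return object of class \code{mri_sampling}: logical mask \code{[H, W]}
#'   (constant along rows within a column), plus parameters.
#' @export
generate_cartesian_mask <- function(shape, target_fraction = 0.203,
                                    center_fraction = 0.08, seed = 1L,
                                    decay = 2) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  if (target_fraction < center_fraction) {
    stop("target_fraction must be at least center_fraction", call. = FALSE)
  }
  H <- shape[1]; W <- shape[2]
  n_target <- max(1L, round(target_fraction * W))
  n_center <- min(n_target, max(1L, round(center_fraction * W)))
  centre <- (W + 1) / 2
  ord <- order(abs(seq_len(W) - centre))
  cols <- ord[seq_len(n_center)]
  remaining <- setdiff(seq_len(W), cols)
  n_extra <- n_target - length(cols)
  if (n_extra > 0) {
    d <- abs(remaining - centre) / (W / 2)
    prob <- (1 - 0.95 * d)^decay
    extra <- with_seed(seed, sample(remaining, n_extra, prob = prob))
    cols <- c(cols, extra)
  }
  mask <- matrix(FALSE, H, W)
  mask[, cols] <- TRUE
  structure(list(mask = mask, columns = sort(cols),
                 target_fraction = target_fraction, seed = as.integer(seed)),
            class = "mri_sampling")
}

as_complex_image <- function(u) {
  if (is.complex(u)) return(u)
  if (is.matrix(u)) return(u + 0i)
  stopifnot(length(dim(u)) == 3, dim(u)[3] == 2)
  matrix(complex(real = u[, , 1], imaginary = u[, , 2]),
         dim(u)[1], dim(u)[2])
}

complex_to_channels <- function(z) {
  array(c(Re(z), Im(z)), c(nrow(z), ncol(z), 2))
}

unitary_fft2 <- function(z, inverse = FALSE) {
  n <- sqrt(length(z))
  if (inverse) fft(z, inverse = TRUE) / length(z) * n else fft(z) / n
}

#' Masked-Fourier MRI forward operator
#'
#' \code{y = S F u}: unitary 2-D discrete Fourier transform followed by
#' Cartesian column masking (unsampled entries set to zero). The adjoint is
#' zero-filling followed by the unitary inverse transform. Since \code{F} is
#' unitary, the operator is a partial isometry: all nonzero singular values
#' equal 1.
#'
#' @param u complex matrix, real matrix, or 2-channel real array.
#' @param sampling an \code{mri_sampling}.
#' @return complex k-space matrix with unsampled entries zero.
#' @export
mri_apply <- function(u, sampling) {
  z <- unitary_fft2(as_complex_image(u))
  z[!sampling$mask] <- 0i
  z
}

#' @rdname mri_apply
#' @param y complex k-space matrix.
#' @param channels logical; return a 2-channel real array instead of a
#'   complex matrix.
#' @export
mri_adjoint <- function(y, sampling, channels = FALSE) {
  y[!sampling$mask] <- 0i
  u <- unitary_fft2(y, inverse = TRUE)
  if (channels) complex_to_channels(u) else u
}

#' Simulate subsampled MRI measurements
#'
#' \code{y = S F u + eps} with complex white Gaussian noise of standard
#' deviation \code{noise_sd} per real component on the sampled lines.
#'
#' @param u image (complex, real, or 2-channel array).
#' @param sampling an \code{mri_sampling}.
#' @param noise_sd per-component noise standard deviation.
#' @param seed integer seed.
#' @return complex k-space measurements.
#' @export
simulate_mri <- function(u, sampling, noise_sd = 0, seed = 1L) {
  y <- mri_apply(u, sampling)
  if (noise_sd > 0) {
    n <- sum(sampling$mask)
    eps <- with_seed(seed, complex(real = rnorm(n, sd = noise_sd),
                                   imaginary = rnorm(n, sd = noise_sd)))
    y[sampling$mask] <- y[sampling$mask] + eps
  }
  y
}

#' Forward/adjoint operator pairs
#'
#' Bundles a linear forward operator with its exact adjoint, acting on
#' channel-stacked real arrays (\code{[H, W, 1]} for CT; \code{[H, W, 2]}
#' real/imaginary for MRI) so they can drive the data-discrepancy gradient of
#' the reconstruction methods.
#'
#' @param geom a \code{radon_geometry}.
#' @return list with fields \code{apply}, \code{adjoint}, \code{name},
#'   \code{image_channels}.
#' @export
op_radon <- function(geom) {
  list(name = "radon",
       image_channels = 1L,
       apply = function(u) {
         if (!is.matrix(u)) u <- u[, , 1]
         radon_apply(u, geom)
       },
       adjoint = function(y) {
         array(radon_adjoint(y, geom), c(geom$image_size, geom$image_size, 1))
       })
}

#' @rdname op_radon
#' @param sampling an \code{mri_sampling}.
#' @export
op_masked_fourier <- function(sampling) {
  H <- nrow(sampling$mask); W <- ncol(sampling$mask)
  list(name = "masked_fourier",
       image_channels = 2L,
       apply = function(u) mri_apply(u, sampling),
       adjoint = function(y) mri_adjoint(y, sampling, channels = TRUE))
}

#' Gradient of the quadratic data discrepancy
#'
#' For \code{E_y(u) = 0.5 ||A u - y||^2} returns \code{A^T (A u - y)} via the
#' operator pair's exact adjoint.
#'
#' @param u image (channel-stacked array or matrix).
#' @param y measurements.
#' @param op an operator pair from \code{\link{op_radon}} or
#'   \code{\link{op_masked_fourier}}.
#' @return gradient with the shape of \code{u}.
#' @export
discrepancy_gradient <- function(u, y, op) {
  op$adjoint(op$apply(u) - y)
}

#' Quadratic data discrepancy value
#' @rdname discrepancy_gradient
#' @export
discrepancy_value <- function(u, y, op) {
  r <- op$apply(u) - y
  0.5 * sum(Mod(r)^2)
}

#' Normalise an operator pair to unit operator norm
#'
#' Rescales forward and adjoint by \code{1 / ||A||} (power-iteration
#' estimate). Feeding a learned iterative method the gradient of the
#' discrepancy of the normalised operator (with measurements scaled the same
#' way) keeps the gradient input at unit scale, which makes short training
#' schedules well-conditioned; the reconstruction problem is unchanged up to
#' this fixed scaling.
#'
#' @param op operator pair.
#' @param image_size image side used for the norm estimate.
#' @return list with the scaled operator pair (field \code{scale} holds
#'   \code{1 / ||A||}).
#' @export
op_normalise <- function(op, image_size) {
  s <- 1 / operator_norm(op, image_size)
  out <- list(name = paste0(op$name, "_normalised"),
              image_channels = op$image_channels,
              apply = function(u) op$apply(u) * s,
              adjoint = function(y) op$adjoint(y) * s,
              scale = s)
  out
}

#' Operator norm estimate by power iteration
#'
#' @param op operator pair.
#' @param image_size image side.
#' @param iters number of power iterations (default 30).
#' @param seed seed for the start vector.
#' @return estimate of \code{||A||}.
#' @export
operator_norm <- function(op, image_size, iters = 30L, seed = 1L) {
  x <- with_seed(seed, array(rnorm(image_size^2 * op$image_channels),
                             c(image_size, image_size, op$image_channels)))
  nrm <- 1
  for (i in seq_len(iters)) {
    x <- op$adjoint(op$apply(x))
    nrm <- sqrt(sum(x^2))
    x <- x / nrm
  }
  sqrt(nrm)
}
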