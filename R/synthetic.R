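#' Phantom specification
#'
#' Parameters of the random ellipse phantoms that stand in for anatomical
#' images. Ellipses are deliberately elongated (small axis ratios) and, like
#' anatomy in consistently acquired scans, share a preferred orientation
#' (mean angle \code{orientation} with uniform jitter
#' \code{orientation_jitter}). Both choices make rotation generalisation of
#' learned reconstructions non-trivial: isotropic blobs, or fully random
#' orientations, would leave the image distribution rotation-invariant and
#' mask any gap between ordinary and equivariant methods on rotated test
#' images. Set \code{orientation = NA} for fully random orientations.
#'
#' @param size image side length (at least 16).
#' @param n_ellipses number of overlaid ellipses.
#' @param intensity range of per-ellipse additive intensities.
#' @param semi_axis range of the major semi-axis, as a fraction of size.
#' @param axis_ratio range of minor/major axis ratios (eccentricity control).
#' @param orientation mean ellipse angle in radians (NA = random).
#' @param orientation_jitter half-width of the uniform angle jitter.
#' @param seed integer seed.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(size, n_ellipses = 8L, intensity = c(0.2, 1),
                         semi_axis = c(0.08, 0.28), axis_ratio = c(0.2, 0.55),
                         orientation = pi / 5, orientation_jitter = pi / 12,
                         seed = 1L) {
  stopifnot(size >= 16)
  structure(list(size = as.integer(size), n_ellipses = as.integer(n_ellipses),
                 intensity = intensity, semi_axis = semi_axis,
                 axis_ratio = axis_ratio, orientation = orientation,
                 orientation_jitter = orientation_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Random ellipse phantom
#'
#' Sum of randomly placed, oriented, anti-aliased ellipses (edges ramp
#' linearly over about one pixel), clipped to the declared intensity range.
#' A pure function of the spec: the same seed always returns byte-identical
#' arrays. Background is zero.
#'
#' @param spec a \code{phantom_spec}.
#' @return numeric matrix \code{[size, size]} with values in
#'   \code{[0, max(intensity)]}.
#' @export
ellipse_phantom <- function(spec) {
  n <- spec$size
  img <- matrix(0, n, n)
  if (spec$n_ellipses == 0) return(img)
  pars <- with_seed(spec$seed, {
    data.frame(
      cx = runif(spec$n_ellipses, 0.22 * n, 0.78 * n),
      cy = runif(spec$n_ellipses, 0.22 * n, 0.78 * n),
      a = runif(spec$n_ellipses, spec$semi_axis[1] * n, spec$semi_axis[2] * n),
      ratio = runif(spec$n_ellipses, spec$axis_ratio[1], spec$axis_ratio[2]),
      th = if (is.na(spec$orientation)) {
        runif(spec$n_ellipses, 0, pi)
      } else {
        spec$orientation + runif(spec$n_ellipses, -spec$orientation_jitter,
                                 spec$orientation_jitter)
      },
      val = runif(spec$n_ellipses, spec$intensity[1], spec$intensity[2]))
  })
  xs <- matrix(rep(seq_len(n), each = n), n, n)    # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)   # row index
  for (i in seq_len(spec$n_ellipses)) {
    a <- pars$a[i]; b <- max(pars$a[i] * pars$ratio[i], 1.5)
    ct <- cos(pars$th[i]); st <- sin(pars$th[i])
    dx <- xs - pars$cx[i]; dy <- ys - pars$cy[i]
    xr <- (ct * dx + st * dy) / a
    yr <- (-st * dx + ct * dy) / b
    r <- sqrt(xr^2 + yr^2)
    # ~1-pixel anti-aliasing ramp at the boundary
    edge <- 1 / min(a, b)
    cover <- pmin(1, pmax(0, (1 - r) / edge + 0.5))
    img <- img + pars$val[i] * cover
  }
  pmin(img, max(spec$intensity))
}

#' Rotate an image about its centre
#'
#' Exact array permutation for multiples of 90 degrees; bilinear
#' interpolation with zero fill otherwise (which low-pass filters the image,
#' so rotated copies of high-frequency content are slightly smoothed).
#'
#' @param image numeric matrix.
#' @param angle rotation angle in degrees, counter-clockwise.
#' @return rotated matrix; attribute \code{interpolated} flags off-grid
#'   angles.
#' @export
rotate_image <- function(image, angle) {
  a <- angle %% 360
  if (abs(a - round(a)) < 1e-12 && round(a) %% 90 == 0) {
    q <- (round(a) %/% 90) %% 4
    out <- image
    if (q >= 1) for (i in seq_len(q)) out <- rot90ccw(out)
    attr(out, "interpolated") <- FALSE
    return(out)
  }
  H <- nrow(image); W <- ncol(image)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  th <- a * pi / 180
  ct <- cos(th); st <- sin(th)
  cols <- matrix(rep(seq_len(W) - 1, each = H), H, W) - cx
  rows <- cy - (matrix(rep(seq_len(H), times = W), H, W) - 1)
  # source point = R^{-1} (x, y)
  sx <- ct * cols + st * rows
  sy <- -st * cols + ct * rows
  sc <- cx + sx; sr <- cy - sy
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(r, c) {
    ok <- r >= 0 & r < H & c >= 0 & c < W
    v <- matrix(0, H, W)
    v[ok] <- image[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
  attr(out, "interpolated") <- TRUE
  out
}

#' Simulated training/test datasets
#'
#' Generates phantom/measurement pairs for supervised training: CT pairs use
#' the post-log low-dose noise model, MRI pairs use masked-Fourier sampling
#' with complex Gaussian noise (images returned as 2-channel real arrays).
#' Per-pair seeds are derived disjointly from the master seed.
#'
#' @param n number of pairs.
#' @param modality \code{"ct"} or \code{"mri"}.
#' @param spec a \code{phantom_spec} (its seed field is overridden per pair).
#' @param geom a \code{radon_geometry} (CT).
#' @param noise a \code{ct_noise_model} (CT).
#' @param sampling an \code{mri_sampling} (MRI).
#' @param noise_sd MRI noise standard deviation.
#' @param noiseless CT only: replace counts by their expectation, so that
#'   \code{y} equals the ray transform of the phantom exactly.
#' @param seed master seed.
#' @return list of \code{n} lists with elements \code{u} (image array
#'   \code{[H, W, C]}) and \code{y} (measurements).
#' @export
make_dataset <- function(n, modality = c("ct", "mri"), spec,
                         geom = NULL, noise = NULL,
                         sampling = NULL, noise_sd = 0.05,
                         noiseless = FALSE, seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- derive_seed(seed, 2L * i)
    u <- ellipse_phantom(s)
    if (modality == "ct") {
      nm <- noise
      nm$seed <- derive_seed(seed, 2L * i + 1L)
      y <- simulate_ct(u, geom, nm, noiseless = noiseless)
      list(u = array(u, c(dim(u), 1)), y = y)
    } else {
      y <- simulate_mri(u, sampling, noise_sd,
                        seed = derive_seed(seed, 2L * i + 1L))
      list(u = array(c(u, 0 * u), c(dim(u), 2)), y = y)
    }
  })
}

#' Single-pair denoising fixture
#'
#' One phantom with strongly oriented structure (parallel elongated
#' ellipses), a noisy copy with additive Gaussian noise, and rotated test
#' copies. The default 90-degree rotation is an exact grid permutation, so
#' test-time rotation introduces no interpolation loss; off-grid angles (for
#' example 20 degrees) demonstrate the interpolation smoothing caveat.
#'
#' @param seed integer seed.
#' @param size image side.
#' @param noise_sd additive noise standard deviation.
#' @param angle test rotation angle in degrees (default 90).
#' @return list with \code{clean}, \code{noisy}, \code{rotated_clean},
#'   \code{rotated_noisy}, \code{angle}, \code{noise_sd}.
#' @export
figure1_fixture <- function(seed = 1L, size = 64L, noise_sd = 0.3,
                            angle = 90) {
  n <- size
  img <- matrix(0, n, n)
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  offsets <- with_seed(seed, runif(4, -0.26, 0.26)) * n
  th <- pi / 7   # fixed oblique orientation shared by all bars
  ct <- cos(th); st <- sin(th)
  for (i in seq_along(offsets)) {
    dx <- xs - n / 2; dy <- ys - n / 2
    u1 <- ct * dx + st * dy
    u2 <- -st * dx + ct * dy - offsets[i]
    cover <- pmin(1, pmax(0, (1 - sqrt((u1 / (0.34 * n))^2 +
                                         (u2 / (0.035 * n))^2)) *
                            0.05 * n + 0.5))
    img <- img + 0.8 * cover
  }
  clean <- pmin(img, 1)
  noisy <- clean + with_seed(derive_seed(seed, 7L),
                             matrix(rnorm(n * n, sd = noise_sd), n, n))
  rc <- rotate_image(clean, angle)
  rn <- rotate_image(noisy, angle)
  list(clean = clean, noisy = noisy, rotated_clean = rc, rotated_noisy = rn,
       angle = angle, noise_sd = noise_sd)
}
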