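#' Peak signal-to-noise ratio
#'
#' \code{PSNR(uhat, u) = 10 log10( n max_i |u_i|^2 / ||u - uhat||^2 )} with
#' the peak taken from the ground truth \code{u} (not a fixed bit depth).
#' Identical inputs return \code{Inf} (documented sentinel).
#'
#' @param uhat reconstruction.
#' @param u ground truth of the same shape; must not be identically zero.
#' @return PSNR in decibels.
#' @export
psnr <- function(uhat, u) {
  stopifnot(length(uhat) == length(u))
  if (all(u == 0)) stop("ground truth is identically zero", call. = FALSE)
  err <- sum((as.numeric(u) - as.numeric(uhat))^2)
  if (err == 0) return(Inf)
  10 * log10(length(u) * max(abs(u))^2 / err)
}

# box-filter window means via cumulative sums; returns matrix of window
# means anchored at the window's top-left corner (valid windows only)
window_means <- function(x, w) {
  H <- nrow(x); W <- ncol(x)
  cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  padded <- matrix(0, H + 1, W + 1)
  padded[-1, -1] <- cs
  i <- seq_len(H - w + 1); j <- seq_len(W - w + 1)
  (padded[i + w, j + w, drop = FALSE] - padded[i, j + w, drop = FALSE] -
      padded[i + w, j, drop = FALSE] + padded[i, j, drop = FALSE]) / (w * w)
}

reflect_pad <- function(x, p) {
  H <- nrow(x); W <- ncol(x)
  ridx <- c(rev(seq_len(p) + 1), seq_len(H), H - seq_len(p))
  cidx <- c(rev(seq_len(p) + 1), seq_len(W), W - seq_len(p))
  x[ridx, cidx, drop = FALSE]
}

ssim_map_valid <- function(uhat, u, w, c1, c2) {
  m1 <- window_means(uhat, w)
  m2 <- window_means(u, w)
  s11 <- window_means(uhat * uhat, w) - m1 * m1
  s22 <- window_means(u * u, w) - m2 * m2
  s12 <- window_means(uhat * u, w) - m1 * m2
  ((2 * m1 * m2 + c1) * (2 * s12 + c2)) /
    ((m1^2 + m2^2 + c1) * (s11 + s22 + c2))
}

#' Structural similarity index
#'
#' Windowed SSIM with a uniform \code{w x w} window (default 7), population
#' window statistics, and stabilisers \code{c1 = (0.01 L)^2},
#' \code{c2 = (0.03 L)^2} where \code{L} is the ground truth's data range.
#' The per-window statistics are averaged over all fully interior windows;
#' with \code{pad = TRUE} the images are first reflection-padded by
#' \code{floor(w/2)} so that the SSIM map is pixel-aligned with the inputs
#' (the convention used for masked averaging).
#'
#' @param uhat,u numeric matrices of equal size, at least \code{w x w}.
#' @param w odd window side.
#' @param data_range value range L; defaults to \code{max(u) - min(u)}.
#' @param pad use the padded, pixel-aligned map convention.
#' @return scalar in (-1, 1]; 1 exactly for identical images.
#' @export
ssim <- function(uhat, u, w = 7L, data_range = NULL, pad = FALSE) {
  stopifnot(all(dim(uhat) == dim(u)), w %% 2 == 1)
  if (nrow(u) < w || ncol(u) < w) {
    stop("image smaller than the SSIM window", call. = FALSE)
  }
  if (is.null(data_range)) data_range <- diff(range(u))
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  if (pad) {
    p <- w %/% 2
    uhat <- reflect_pad(uhat, p)
    u <- reflect_pad(u, p)
  }
  mean(ssim_map_valid(uhat, u, w, c1, c2))
}

#' Masked SSIM via the SSIM map
#'
#' Reflection-pads both images by \code{floor(w/2)}, computes the
#' pixel-aligned SSIM map, and averages it over the points inside the mask.
#' With an all-true mask this equals \code{ssim(..., pad = TRUE)} exactly.
#'
#' @param uhat,u numeric matrices.
#' @param mask logical matrix of the same shape, with at least one TRUE.
#' @param w odd window side.
#' @param data_range value range L (default from \code{u}).
#' @return masked mean SSIM.
#' @export
masked_ssim <- function(uhat, u, mask, w = 7L, data_range = NULL) {
  stopifnot(all(dim(mask) == dim(u)))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (is.null(data_range)) data_range <- diff(range(u))
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  p <- w %/% 2
  map <- ssim_map_valid(reflect_pad(uhat, p), reflect_pad(u, p), w, c1, c2)
  mean(map[mask])
}

#' Metrics for complex-valued (two-channel) images
#'
#' PSNR and SSIM computed on the pixelwise magnitude images, the evaluation
#' rule for complex MRI reconstructions.
#'
#' @param uhat,u complex matrices or 2-channel real arrays.
#' @param w SSIM window.
#' @return list with \code{psnr} and \code{ssim}.
#' @export
complex_metrics <- function(uhat, u, w = 7L) {
  mag <- function(x) {
    if (is.complex(x)) return(Mod(x))
    if (is.matrix(x)) return(abs(x))
    sqrt(x[, , 1]^2 + x[, , 2]^2)
  }
  mh <- mag(uhat); mu <- mag(u)
  list(psnr = psnr(mh, mu), ssim = ssim(mh, mu, w = w))
}
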