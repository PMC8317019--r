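#' Finite cyclic rotation groups
#'
#' A cyclic group of order \code{m}, identified with the group of planar
#' rotations by multiples of \code{2*pi/m}. Elements are stored as integers
#' \code{0..m-1} (never floating-point angles) so that group arithmetic is
#' exact: \code{a*b = (a+b) mod m}, \code{a^-1 = (m-a) mod m}, identity 0.
#'
#' @param m positive integer order of the group.
#' @return An object of class \code{cyclic_group} with field \code{order}.
#' @examples
#' g <- cyclic_group(4)
#' group_multiply(g, 3, 2)  # 1
#' @export
cyclic_group <- function(m) {
  m <- as.integer(m)
  stopifnot(length(m) == 1, m >= 1)
  structure(list(order = m), class = "cyclic_group")
}

check_element <- function(group, k) {
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 0 || k >= group$order) {
    stop("group element out of range [0, m)", call. = FALSE)
  }
  k
}

#' @rdname cyclic_group
#' @param group a \code{cyclic_group}.
#' @param a,b group elements (integers in \code{0..m-1}).
#' @export
group_multiply <- function(group, a, b) {
  (check_element(group, a) + check_element(group, b)) %% group$order
}

#' @rdname cyclic_group
#' @export
group_inverse <- function(group, a) {
  (group$order - check_element(group, a)) %% group$order
}

#' Rotation matrix of a cyclic-group element
#'
#' Returns the 2x2 special-orthogonal matrix of the counter-clockwise rotation
#' by angle \code{2*pi*k/m}.
#'
#' @param group a \code{cyclic_group} of order m.
#' @param k element in \code{0..m-1}.
#' @return 2x2 rotation matrix.
#' @export
rotation_matrix <- function(group, k) {
  k <- check_element(group, k)
  th <- 2 * pi * k / group$order
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Group representations (trivial and regular)
#'
#' A representation assigns each group element an invertible matrix so that
#' matrix multiplication mirrors the group law. \code{trivial_rep} acts as the
#' 1x1 identity for every element; \code{regular_rep} permutes coordinates
#' indexed by the group elements themselves: element \code{i} maps basis vector
#' \code{e_j} to \code{e_{(i+j) mod m}}. Regular representation matrices are
#' permutation matrices, hence orthogonal.
#'
#' @param group a \code{cyclic_group}.
#' @return An object of class \code{group_rep} with fields \code{group},
#'   \code{dim} and \code{kind}.
#' @export
trivial_rep <- function(group) {
  structure(list(group = group, dim = 1L, kind = "trivial"),
            class = "group_rep")
}

#' @rdname trivial_rep
#' @export
regular_rep <- function(group) {
  structure(list(group = group, dim = group$order, kind = "regular"),
            class = "group_rep")
}

#' Representation matrix of a group element
#'
#' @param rep a \code{group_rep}.
#' @param k group element.
#' @return A \code{dim x dim} matrix.
#' @export
rep_matrix <- function(rep, k) {
  k <- check_element(rep$group, k)
  if (rep$kind == "trivial") {
    return(matrix(1, 1, 1))
  }
  m <- rep$group$order
  M <- matrix(0, m, m)
  # column j (element j-1) maps to row (k + j - 1) mod m
  for (j in seq_len(m)) M[(k + j - 1) %% m + 1, j] <- 1
  M
}

#' Planar feature fields
#'
#' A feature field is a stack of planar channels together with a declaration
#' of how the channels transform under rotation: an ordered list of
#' representations whose dimensions sum to the number of channels. The grid
#' origin is the image centre \code{((H-1)/2, (W-1)/2)}; rotations are
#' counter-clockwise in standard (x right, y up) coordinates.
#'
#' @param values numeric array \code{[H, W, C]} (a matrix is treated as C = 1).
#' @param field_types list of \code{group_rep} objects, dims summing to C.
#' @return An object of class \code{feature_field}.
#' @export
feature_field <- function(values, field_types) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3)
  if (inherits(field_types, "group_rep")) field_types <- list(field_types)
  dims <- vapply(field_types, function(r) r$dim, integer(1))
  if (sum(dims) != dim(values)[3]) {
    stop("field_types dims must sum to the number of channels", call. = FALSE)
  }
  structure(list(values = values, field_types = field_types),
            class = "feature_field")
}

field_group <- function(field) field$field_types[[1]]$group

#' Total channels of a feature field
#' @param field a \code{feature_field}.
#' @export
field_channels <- function(field) dim(field$values)[3]

# Exact counter-clockwise quarter rotation of a matrix about its centre.
rot90ccw <- function(M) t(M[, rev(seq_len(ncol(M))), drop = FALSE])

# Spatial rotation of a [H,W] image by angle 2*pi*k/m about the image centre.
# Exact re-indexing for quarter-turn multiples; bilinear otherwise.
rotate_plane <- function(M, k, m) {
  if ((4 * k) %% m == 0) {
    q <- ((4 * k) %/% m) %% 4
    out <- M
    if (q >= 1) for (i in seq_len(q)) out <- rot90ccw(out)
    return(out)
  }
  rotate_image(M, 360 * k / m)
}

on_grid_element <- function(k, m) (k * 4) %% m == 0

# Integer translation of an image: content moves by t = (tx, ty) in (x right,
# y up) coordinates. wrap = TRUE shifts circularly (exact group action on the
# torus); otherwise vacated pixels are zero-filled.
shift_plane <- function(M, tx, ty, wrap = FALSE) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(0, H, W)
  rows <- seq_len(H); cols <- seq_len(W)
  src_r <- rows + ty   # value at row r comes from old row r + ty
  src_c <- cols - tx
  if (wrap) {
    out <- M[(src_r - 1) %% H + 1, (src_c - 1) %% W + 1, drop = FALSE]
  } else {
    ok_r <- src_r >= 1 & src_r <= H
    ok_c <- src_c >= 1 & src_c <= W
    out[rows[ok_r], cols[ok_c]] <- M[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  out
}

#' Roto-translational action on a feature field
#'
#' Applies the induced action of the group element \code{(t, R_k)}: the pixel
#' grid is rotated by \code{2*pi*k/m} about the image centre and shifted by the
#' integer translation \code{t}, and each channel block is multiplied by its
#' representation matrix. For groups of on-grid rotations (orders dividing 4,
#' or elements that are quarter-turn multiples) the spatial rotation is an
#' exact array re-indexing; otherwise bilinear interpolation is used and the
#' result carries attribute \code{approximate = TRUE}. Translations that move
#' content off-grid are zero-filled and flagged via attribute \code{clipped}
#' unless \code{wrap = TRUE} (circular shift).
#'
#' @param field a \code{feature_field}.
#' @param k rotation element in \code{0..m-1}.
#' @param t integer translation \code{c(tx, ty)} in pixels (x right, y up).
#' @param wrap logical; translate circularly instead of zero-filling.
#' @return The transformed \code{feature_field}.
#' @export
act_on_field <- function(field, k, t = c(0L, 0L), wrap = FALSE) {
  group <- field_group(field)
  k <- check_element(group, k)
  t <- as.integer(round(t))
  v <- field$values
  H <- dim(v)[1]; W <- dim(v)[2]; C <- dim(v)[3]
  out <- array(0, dim(v))
  for (ci in seq_len(C)) {
    p <- rotate_plane(v[, , ci], k, group$order)
    out[, , ci] <- shift_plane(p, t[1], t[2], wrap = wrap)
  }
  # channel mixing per field block
  offset <- 0L
  for (rep in field$field_types) {
    d <- rep$dim
    if (rep$kind != "trivial") {
      M <- rep_matrix(rep, k)
      block <- out[, , offset + seq_len(d), drop = FALSE]
      mixed <- array(0, dim(block))
      for (i in seq_len(d)) {
        for (j in seq_len(d)) {
          if (M[i, j] != 0) {
            mixed[, , i] <- mixed[, , i] + M[i, j] * block[, , j]
          }
        }
      }
      out[, , offset + seq_len(d)] <- mixed
    }
    offset <- offset + d
  }
  res <- feature_field(out, field$field_types)
  attr(res, "approximate") <- !on_grid_element(k, group$order)
  attr(res, "clipped") <- !wrap && any(t != 0L)
  res
}

#' Compose two roto-translation group elements
#'
#' Composition in the semi-direct product: \code{(t1, R1) (t2, R2) =
#' (t1 + R1 t2, R1 R2)}. Used to verify that the field action is a group
#' action. The rotated translation is rounded to the integer grid (exact for
#' on-grid rotations).
#'
#' @param group a \code{cyclic_group}.
#' @param k1,k2 rotation elements.
#' @param t1,t2 integer translations \code{c(tx, ty)}.
#' @return list with elements \code{k} and \code{t}.
#' @export
se2_compose <- function(group, k1, t1, k2, t2) {
  R1 <- rotation_matrix(group, k1)
  list(k = group_multiply(group, k1, k2),
       t = as.integer(round(t1 + as.vector(R1 %*% t2))))
}
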