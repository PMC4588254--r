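# Pelvis-specific coordinate frame, rigid transforms and orthographic
# projection into the inlet / outlet / AP image planes.
#
# Frame convention (right-handed, origin at the centre of the superior S1
# endplate, "S"):
#   +X  toward the patient's left (transverse axis),
#   +Y  perpendicular to the inlet plane (the inlet beam axis),
#   +Z  perpendicular to the outlet plane (the outlet beam axis).
# The inlet radiograph is the X/Z plane and the outlet radiograph the X/Y
# plane; the AP beam lies between the inlet and outlet axes, tilted by the
# patient's pelvic obliquity (typically 40-60 degrees).

#' Construct a radiographic view
#'
#' A view is an orthographic (parallel-beam) projection defined by a unit
#' projection axis (the beam direction, along which depth is discarded) and
#' an orthonormal in-plane basis mapping 3D millimetre coordinates to image
#' `(u, v)` coordinates.
#'
#' @param name View name (`"inlet"`, `"outlet"` or `"ap"`).
#' @param axis Unit length-3 numeric, the projection (beam) axis.
#' @param basis 2 x 3 numeric matrix; rows are the `u` and `v` image axes.
#' @return An object of class `radiograph_view`.
#' @keywords internal
new_view <- function(name, axis, basis) {
  check_finite(axis, "view axis")
  check_finite(basis, "view basis")
  if (length(axis) != 3L || !identical(dim(basis), c(2L, 3L))) {
    stop_pelvimetrix("view axis must be length 3 and basis 2 x 3")
  }
  g <- rbind(basis, axis)
  if (max(abs(g %*% t(g) - diag(3))) > 1e-9) {
    stop_pelvimetrix(sprintf(
      "degenerate view '%s': basis rows and axis must be orthonormal", name))
  }
  structure(list(name = name, axis = axis, basis = basis),
    class = "radiograph_view")
}

#' Standard inlet view: image (u, v) = (x, z)
#'
#' The inlet radiograph is the pelvis-frame X/Z plane; the beam runs along
#' +Y and the image vertical `v` is the +Z (outlet-axis) coordinate.
#'
#' @return A `radiograph_view`.
#' @export
#' @examples
#' project_points(rbind(c(10, 99, -4)), make_inlet_view()) # u = 10, v = -4
make_inlet_view <- function() {
  new_view("inlet", axis = c(0, 1, 0), basis = rbind(c(1, 0, 0), c(0, 0, 1)))
}

#' Standard outlet view: image (u, v) = (x, y)
#'
#' The outlet radiograph is the pelvis-frame X/Y plane; the beam runs along
#' +Z and the image vertical `v` is the +Y (inlet-axis) coordinate, so
#' superior is up.
#'
#' @return A `radiograph_view`.
#' @export
make_outlet_view <- function() {
  new_view("outlet", axis = c(0, 0, 1), basis = rbind(c(1, 0, 0), c(0, 1, 0)))
}

#' AP view: inlet beam axis tilted about X by the pelvic obliquity
#'
#' The anterior-posterior beam axis is the inlet axis rotated by `tilt_deg`
#' about +X toward +Z, i.e. `(0, cos t, sin t)`. The image horizontal is +X
#' and the image vertical is the in-plane direction with a positive
#' superior (+Y) component, `(0, sin t, -cos t)`, so cephalad is up. At
#' `tilt_deg -> 90` the AP view coincides with the outlet X/Y mapping.
#'
#' @param tilt_deg Pelvic obliquity in degrees, strictly between 0 and 90.
#'   Default 45, inside the 40-60 degree range reported across adults.
#' @return A `radiograph_view`.
#' @export
make_ap_view <- function(tilt_deg = 45) {
  check_finite(tilt_deg, "tilt_deg")
  if (length(tilt_deg) != 1L || tilt_deg <= 0 || tilt_deg >= 90) {
    stop_pelvimetrix("tilt_deg must lie strictly between 0 and 90 degrees")
  }
  t <- tilt_deg * pi / 180
  new_view("ap",
    axis = c(0, cos(t), sin(t)),
    basis = rbind(c(1, 0, 0), c(0, sin(t), -cos(t))))
}

#' The three standard views as a named list
#'
#' @param ap_tilt_deg Pelvic obliquity used for the AP view (degrees).
#' @return Named list with elements `inlet`, `outlet`, `ap`.
#' @export
default_views <- function(ap_tilt_deg = 45) {
  list(
    inlet = make_inlet_view(),
    outlet = make_outlet_view(),
    ap = make_ap_view(ap_tilt_deg)
  )
}

#' Orthographic projection of 3D points into a view
#'
#' @param points Numeric n x 3 matrix of pelvis-frame coordinates (mm).
#' @param view A `radiograph_view`.
#' @return n x 2 matrix with columns `u`, `v` (mm); row names preserved.
#' @export
project_points <- function(points, view) {
  if (!inherits(view, "radiograph_view")) {
    stop_pelvimetrix("view must be a radiograph_view")
  }
  points <- as_points3(points)
  out <- points %*% t(view$basis)
  colnames(out) <- c("u", "v")
  out
}

as_points3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop_pelvimetrix("points must be n x 3")
  check_finite(points, "points")
  points
}

#' Rigid transform of the pelvis frame
#'
#' Rotations are given in degrees about the frame axes and composed in the
#' intrinsic order X then Y then Z (matrix `Rx %*% Ry %*% Rz` applied to
#' column vectors), about `pivot`, followed by `translation`. Default
#' simulations use single-axis rotations, for which the order is
#' immaterial.
#'
#' @param rot_x,rot_y,rot_z Rotation angles in degrees (right-handed about
#'   +X, +Y, +Z respectively).
#' @param pivot Length-3 point (mm) about which the rotation is applied.
#' @param translation Length-3 translation (mm) applied after rotation.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rot_x = 0, rot_y = 0, rot_z = 0,
                            pivot = c(0, 0, 0), translation = c(0, 0, 0)) {
  check_finite(c(rot_x, rot_y, rot_z), "rotation angles")
  check_finite(pivot, "pivot")
  check_finite(translation, "translation")
  if (length(pivot) != 3L || length(translation) != 3L) {
    stop_pelvimetrix("pivot and translation must have length 3")
  }
  structure(
    list(rot = c(x = rot_x, y = rot_y, z = rot_z),
         pivot = as.numeric(pivot), translation = as.numeric(translation)),
    class = "rigid_transform")
}

rotation_matrix <- function(rot) {
  a <- rot * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rx %*% ry %*% rz
}

#' Apply a rigid transform to 3D points
#'
#' Pairwise distances are preserved to better than 1e-9 mm.
#'
#' @param points Numeric n x 3 matrix (mm).
#' @param transform A `rigid_transform`.
#' @return Transformed n x 3 matrix; dimnames preserved.
#' @export
#' @examples
#' p <- rbind(c(1, 0, 0))
#' apply_rigid(p, rigid_transform(rot_z = 90)) # ~ (0, 1, 0)
apply_rigid <- function(points, transform) {
  if (!inherits(transform, "rigid_transform")) {
    stop_pelvimetrix("transform must be a rigid_transform")
  }
  points <- as_points3(points)
  r <- rotation_matrix(transform$rot)
  centred <- sweep(points, 2, transform$pivot)
  out <- centred %*% t(r)
  out <- sweep(out, 2, transform$pivot + transform$translation, "+")
  dimnames(out) <- dimnames(points)
  out
}

#' Pixel-to-millimetre calibration scale from the femoral head fiducial
#'
#' The intact femoral head's true diameter (from the 3D model or a
#' calibration object) divided by its measured pixel diameter in a given
#' view gives that view's mm-per-pixel scale.
#'
#' @param fh_true_mm True femoral head diameter (mm), > 0.
#' @param fh_pixels Measured femoral head diameter in the image (pixels), > 0.
#' @return Scale in mm per pixel.
#' @export
#' @examples
#' mm_per_pixel(48, 96) # 0.5
mm_per_pixel <- function(fh_true_mm, fh_pixels) {
  check_finite(fh_true_mm, "fh_true_mm")
  check_finite(fh_pixels, "fh_pixels")
  if (any(fh_true_mm <= 0) || any(fh_pixels <= 0)) {
    stop_pelvimetrix("femoral head diameters must be strictly positive")
  }
  fh_true_mm / fh_pixels
}

#' @export
print.radiograph_view <- function(x, ...) {
  cat(sprintf("<radiograph_view '%s'> axis = (%s)\n", x$name,
    paste(formatC(x$axis, format = "f", digits = 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (deg) x=%.3g y=%.3g z=%.3g; pivot (%s); t (%s)\n",
    x$rot[1], x$rot[2], x$rot[3],
    paste(formatC(x$pivot, format = "g"), collapse = ", "),
    paste(formatC(x$translation, format = "g"), collapse = ", ")))
  invisible(x)
}
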