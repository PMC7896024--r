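#' Relaxed B-DNA reference step
#'
#' The reference state for twist bookkeeping: a straight, torsionally relaxed
#' base-pair step with twist 34.3 degrees (10.5 bp per helical turn) and rise
#' 0.34 nm. All linking-number changes reported by the package are relative
#' to DNA made entirely of this step.
#'
#' @format A named numeric vector of class `step_params`.
#' @export
relaxed_step <- function() {
  step_params(twist = 34.3, rise = 0.34)
}

#' Rigid base-pair step parameters
#'
#' The six degrees of freedom of local DNA geometry: three rotations (tilt,
#' roll, twist, in degrees) and three displacements (shift, slide, rise, in
#' nm) carrying base-pair frame i onto frame i+1.
#'
#' @param tilt,roll,twist rotational parameters, degrees.
#' @param shift,slide,rise translational parameters, nm.
#' @return A named numeric vector of class `step_params`.
#' @examples
#' relaxed <- step_params(twist = 34.3, rise = 0.34)
#' @export
step_params <- function(tilt = 0, roll = 0, twist = 0,
                        shift = 0, slide = 0, rise = 0) {
  s <- c(tilt = tilt, roll = roll, twist = twist,
         shift = shift, slide = slide, rise = rise)
  if (!all(is.finite(s))) stop("all six step parameters must be finite")
  class(s) <- "step_params"
  s
}

step_names <- c("tilt", "roll", "twist", "shift", "slide", "rise")

#' Coerce input to an n x 6 step matrix
#'
#' Accepts a single `step_params` vector (recycled `n` times when `n` is
#' given), a length-6 numeric vector, or an n x 6 matrix/data.frame with the
#' canonical column order tilt, roll, twist, shift, slide, rise.
#'
#' @param x steps in any accepted form.
#' @param n optional number of rows to recycle a single step into.
#' @return A numeric matrix with 6 named columns.
#' @export
as_step_matrix <- function(x, n = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x[, step_names])
  if (is.matrix(x)) {
    if (ncol(x) != 6) stop("step matrix must have 6 columns")
    m <- x
  } else {
    x <- unclass(x)
    if (length(x) != 6) stop("a single step must have 6 parameters")
    m <- matrix(x, nrow = if (is.null(n)) 1L else n, ncol = 6, byrow = TRUE)
  }
  if (!all(is.finite(m))) stop("non-finite step parameters")
  colnames(m) <- step_names
  m
}

#' Base-pair frame
#'
#' A rigid frame attached to a base pair: an origin (nm) and a right-handed
#' orthonormal 3 x 3 axes matrix whose columns are the short axis, the long
#' axis, and the normal (the local helical tangent).
#'
#' @param origin numeric length-3, nm.
#' @param axes 3 x 3 orthonormal matrix with determinant +1.
#' @param tol orthonormality tolerance.
#' @return An object of class `bp_frame`.
#' @export
bp_frame <- function(origin = c(0, 0, 0), axes = diag(3), tol = 1e-9) {
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  if (length(origin) != 3 || !all(dim(axes) == c(3, 3)))
    stop("bp_frame needs a 3-vector origin and 3x3 axes")
  if (max(abs(crossprod(axes) - diag(3))) > tol)
    stop("axes must be orthonormal")
  if (det(axes) < 0)
    stop("axes must be right-handed (determinant +1)")
  structure(list(origin = origin, axes = axes), class = "bp_frame")
}

#' Rigid transform of a base-pair step
#'
#' Returns the rotation and translation carrying frame i onto frame i+1
#' under the mid-step compounding convention: the step rotation is
#' Rz(Tw/2 - phi) Ry(Gamma) Rz(Tw/2 + phi) with bend magnitude
#' Gamma = sqrt(tilt^2 + roll^2) and phase phi = atan2(tilt, roll), and the
#' displacement is applied in the half-rotated mid-step frame.
#'
#' @param step a `step_params` vector.
#' @return A list with `rotation` (3 x 3) and `translation` (nm 3-vector),
#'   expressed in the coordinates of frame i.
#' @examples
#' tf <- step_to_transform(step_params(twist = 36, rise = 0.34))
#' @export
step_to_transform <- function(step) {
  m <- as_step_matrix(step)
  cpp_step_transform(as.numeric(m[1, ]))
}

#' Compound steps into a chain of base-pair frames
#'
#' @param start a `bp_frame` to grow the chain from.
#' @param steps steps in any form accepted by [as_step_matrix()].
#' @return A list with `origins` ((n+1) x 3) and `axes` ((n+1) x 9, each row
#'   a column-major flattened 3 x 3 frame). Frames are re-orthogonalized as
#'   the chain is compounded so numerical drift never exceeds 1e-9.
#' @export
build_chain <- function(start = bp_frame(), steps) {
  if (!inherits(start, "bp_frame")) stop("start must be a bp_frame")
  if (is.null(steps) || (is.matrix(steps) && nrow(steps) == 0)) {
    return(list(origins = matrix(start$origin, 1, 3),
                axes = matrix(as.numeric(start$axes), 1, 9)))
  }
  m <- as_step_matrix(steps)
  cpp_build_chain(start$origin, start$axes, m)
}

#' Recover step parameters from a chain of frames
#'
#' Inverse of [build_chain()]: extracts the six step parameters between each
#' consecutive pair of frames. Round-tripping through [build_chain()]
#' reproduces the origins to better than 1e-6 nm.
#'
#' @param origins n x 3 matrix of frame origins (nm).
#' @param axes n x 9 matrix of flattened frames.
#' @return An (n-1) x 6 step matrix.
#' @export
extract_steps <- function(origins, axes) {
  s <- cpp_extract_steps(origins, axes)
  colnames(s) <- step_names
  s
}

#' @export
print.step_params <- function(x, ...) {
  cat("base-pair step: tilt/roll/twist =",
      sprintf("%.3f/%.3f/%.3f deg,", x[1], x[2], x[3]),
      "shift/slide/rise =",
      sprintf("%.3f/%.3f/%.3f nm\n", x[4], x[5], x[6]))
  invisible(x)
}
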