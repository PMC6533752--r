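#' 2-D affine transforms
#'
#' A plane affine map `p -> A p + b` used to carry H&E pixel coordinates into
#' SHG pixel coordinates. The `model` tag records the transform family the
#' matrix was estimated under (`translation`, `rigid`, `similarity`, or
#' `affine`); the representation is always the full 2x2 matrix plus a
#' translation vector.
#'
#' @param A 2x2 linear part (must be invertible).
#' @param b length-2 translation.
#' @param model one of `"translation"`, `"rigid"`, `"similarity"`, `"affine"`.
#' @return an object of class `affine2d`.
#' @export
affine2d <- function(A = diag(2), b = c(0, 0), model = "affine") {
  A <- matrix(as.numeric(A), 2, 2)
  b <- as.numeric(b)
  model <- match.arg(model, c("translation", "rigid", "similarity", "affine"))
  if (length(b) != 2) stopf("translation must have length 2")
  if (abs(det(A)) < 1e-12) stopf("linear part of affine transform is singular")
  structure(list(A = A, b = b, model = model), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("affine2d (%s)\n", x$model))
  cat(sprintf("  A = [%8.4f %8.4f; %8.4f %8.4f]\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2]))
  cat(sprintf("  b = (%.4f, %.4f)\n", x$b[1], x$b[2]))
  invisible(x)
}

#' Build a similarity transform from scale, rotation and translation
#'
#' @param scale isotropic scale factor.
#' @param rot_deg counter-clockwise rotation in degrees (in the image
#'   convention with y pointing down, positive angles rotate x toward y).
#' @param tx,ty translation in target pixels.
#' @param model model tag for the result.
#' @return an `affine2d`.
#' @export
similarity2d <- function(scale = 1, rot_deg = 0, tx = 0, ty = 0,
                         model = "similarity") {
  th <- rot_deg * pi / 180
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  affine2d(A, c(tx, ty), model = model)
}

#' Apply an affine transform to points
#'
#' @param t an `affine2d`.
#' @param pts n x 2 matrix of (x, y) coordinates (a length-2 vector is
#'   treated as one point).
#' @return n x 2 matrix of transformed coordinates.
#' @export
affine_apply <- function(t, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  sweep(pts %*% t(t$A), 2, t$b, "+")
}

#' Compose two affine transforms
#'
#' Returns the transform that applies `t2` first, then `t1`.
#' @param t1,t2 `affine2d` objects.
#' @return an `affine2d` with model tag `"affine"` unless both inputs share
#'   a more specific common model.
#' @export
affine_compose <- function(t1, t2) {
  model <- if (identical(t1$model, t2$model)) t1$model else "affine"
  affine2d(t1$A %*% t2$A, as.numeric(t1$A %*% t2$b) + t1$b, model = model)
}

#' Invert an affine transform
#' @param t an `affine2d`.
#' @return the inverse `affine2d`.
#' @export
affine_invert <- function(t) {
  Ai <- solve(t$A)
  affine2d(Ai, -as.numeric(Ai %*% t$b), model = t$model)
}

#' Decompose a similarity transform
#'
#' Reads the isotropic scale, rotation and translation off an `affine2d`
#' whose linear part is (close to) a scaled rotation; used for reporting and
#' for comparing recovered transforms against ground truth.
#'
#' @param t an `affine2d`.
#' @return list with `scale`, `rot_deg`, `tx`, `ty`.
#' @export
affine_params <- function(t) {
  s <- sqrt(abs(det(t$A)))
  th <- atan2(t$A[2, 1], t$A[1, 1]) * 180 / pi
  list(scale = s, rot_deg = th, tx = t$b[1], ty = t$b[2])
}
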