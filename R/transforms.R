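#' Rigid-body transform
#'
#' A proper rigid motion in 3-space, stored as a 3x3 rotation matrix
#' \code{R} and a translation row-vector \code{t}, acting on coordinate
#' rows as \code{y = x \%*\% R + t}.
#'
#' @param R 3x3 proper orthogonal matrix (det = +1).
#' @param t translation, numeric length-3 (Angstrom).
#' @return An object of class \code{"rigid_transform"}.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  stopifnot(identical(dim(R), c(3L, 3L)), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthogonal")
  if (abs(det(R) - 1) > 1e-8)
    stop("rotation matrix is not proper (det != +1)")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform: rotation angle",
      sprintf("%.3f deg,", rotation_angle(x)),
      "translation", sprintf("(%.3f, %.3f, %.3f) A\n", x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param tr \code{rigid_transform}.
#' @param xyz n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(tr, xyz) {
  xyz <- coord_matrix(xyz)
  sweep(xyz %*% tr$R, 2, -tr$t)
}

#' Compose rigid transforms (apply \code{a}, then \code{b})
#'
#' @param a,b \code{rigid_transform} objects.
#' @return The composite \code{rigid_transform}.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, drop(a$t %*% b$R) + b$t)
}

#' Invert a rigid transform
#' @param tr \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$R), drop(-tr$t %*% t(tr$R)))
}

#' Rotation angle of a transform
#' @param tr \code{rigid_transform}.
#' @return Angle in degrees, in [0, 180].
#' @export
rotation_angle <- function(tr) {
  ct <- (sum(diag(tr$R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

coord_matrix <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("coordinates must be an n x 3 matrix")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  xyz
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rigid motion (rotation with det = +1, never a
#' reflection, plus translation) that minimizes the RMSD of \code{mobile}
#' onto \code{target}. The sign of the smallest singular value is
#' corrected so that peptide chirality is preserved even when the best
#' orthogonal fit would be a reflection.
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows
#'   (n >= 3, not collinear).
#' @return A \code{rigid_transform} mapping \code{mobile} onto
#'   \code{target}.
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- coord_matrix(mobile)
  target <- coord_matrix(target)
  if (nrow(mobile) != nrow(target))
    stop("point sets must have equal sizes")
  if (nrow(mobile) < 3)
    stop("at least 3 points are required for superposition")
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  A <- sweep(mobile, 2, cm)
  B <- sweep(target, 2, ct)
  for (X in list(A, B)) {
    s <- svd(X, nu = 0, nv = 0)$d
    if (s[1] == 0 || s[2] / s[1] < 1e-12)
      stop("degenerate (collinear) point set: rotation is underdetermined")
  }
  H <- crossprod(A, B)            # maximizes tr(R' H) over proper R
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  rigid_transform(R, ct - drop(cm %*% R))
}

#' RMSD after optimal superposition
#'
#' Root-mean-square deviation of two matched point sets after Kabsch
#' fitting of \code{a} onto \code{b}.
#'
#' @param a,b n x 3 coordinate matrices with matched rows.
#' @return RMSD in Angstrom (scalar, >= 0).
#' @export
rmsd_after_fit <- function(a, b) {
  a <- coord_matrix(a)
  b <- coord_matrix(b)
  fitted <- apply_transform(kabsch_fit(a, b), a)
  sqrt(mean(rowSums((fitted - b)^2)))
}
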