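#' Long axis of a fibril model
#'
#' First principal direction of the per-chain CA centers of mass,
#' anchored at their centroid. The sign is fixed so that chain order
#' increases along the axis (the last chain projects further than the
#' first).
#'
#' @param model a \code{fibril_model} with M >= 2 chains.
#' @return List with unit 3-vector \code{axis} and \code{anchor} point.
#' @export
fibril_axis <- function(model) {
  if (n_chains(model) < 2) stop("fibril axis needs at least 2 chains")
  centers <- chain_centers(model)
  anchor <- colMeans(centers)
  dev <- sweep(centers, 2, anchor)
  if (max(abs(dev)) < 1e-9)
    stop("all chain centers coincide; fibril axis is undefined")
  ax <- svd(dev, nu = 0, nv = 1)$v[, 1]
  if (sum((centers[nrow(centers), ] - centers[1, ]) * ax) < 0) ax <- -ax
  list(axis = ax, anchor = anchor)
}

#' Order chains along the fibril axis
#'
#' Sorts chains by the projection of their CA center of mass onto the
#' fibril axis, making "first chain" and "last chain" well defined for
#' length and interface measurements.
#'
#' @param model a \code{fibril_model}.
#' @return The model with chains re-ordered.
#' @export
order_chains <- function(model) {
  ax <- fibril_axis(model)
  proj <- drop(sweep(chain_centers(model), 2, ax$anchor) %*% ax$axis)
  model$chains <- model$chains[order(proj)]
  model
}

#' Fibril length
#'
#' Distance, measured between the CA centers of mass of the first and
#' the last peptide chain, i.e. the end-to-end length of the stack along
#' the fibril.
#'
#' @param model a \code{fibril_model}, chains ordered along the axis
#'   (see \code{\link{order_chains}}; applied automatically when
#'   \code{reorder = TRUE}).
#' @param reorder order chains along the axis first (default TRUE).
#' @return Length in Angstrom.
#' @export
fibril_length <- function(model, reorder = TRUE) {
  if (n_chains(model) < 2) stop("fibril length needs at least 2 chains")
  if (reorder) model <- order_chains(model)
  centers <- chain_centers(model)
  sqrt(sum((centers[nrow(centers), ] - centers[1, ])^2))
}

#' Per-interface rotation (twist) angles
#'
#' In each chain a line segment connects the CA atoms of two marker
#' residues (positions \code{residue_a} and \code{residue_b} along the
#' chain); each segment is projected onto the plane perpendicular to the
#' fibril axis, and for every adjacent chain pair the unsigned angle
#' between the two projections is returned. Handedness (the sign of the
#' axis component of the cross product of consecutive projections) is
#' reported separately, since twist magnitudes alone do not fix it.
#'
#' @param model a \code{fibril_model} with M >= 2 chains.
#' @param residue_a,residue_b 1-based residue positions of the segment
#'   end points (defaults 3 and 9, the extended-strand markers of a
#'   13-residue hairpin monomer).
#' @param reorder order chains along the axis first (default TRUE).
#' @return List with \code{angles} (degrees, length M-1, in [0, 180]),
#'   \code{handedness} (-1/0/+1 per interface) and the \code{axis} used.
#' @export
interface_angles <- function(model, residue_a = 3, residue_b = 9,
                             reorder = TRUE) {
  if (n_chains(model) < 2) stop("interface angles need at least 2 chains")
  N <- chain_length(model)
  if (!(residue_a >= 1 && residue_b <= N && residue_a < residue_b))
    stop("marker residues must satisfy 1 <= a < b <= ", N)
  if (reorder) model <- order_chains(model)
  ax <- fibril_axis(model)$axis
  proj <- t(vapply(model$chains, function(ch) {
    seg <- ch$ca[residue_b, ] - ch$ca[residue_a, ]
    p <- seg - sum(seg * ax) * ax
    if (sqrt(sum(p^2)) < 1e-6)
      stop("marker segment of chain ", ch$chain_id,
           " is parallel to the fibril axis; projection vanishes")
    p
  }, numeric(3)))
  M <- nrow(proj)
  i <- seq_len(M - 1)
  p1 <- proj[i, , drop = FALSE]
  p2 <- proj[i + 1, , drop = FALSE]
  cosang <- rowSums(p1 * p2) /
    (sqrt(rowSums(p1^2)) * sqrt(rowSums(p2^2)))
  angles <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  crossz <- p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1]
  cr <- cbind(p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2],
              p1[, 3] * p2[, 1] - p1[, 1] * p2[, 3],
              crossz)
  list(angles = angles, handedness = sign(round(drop(cr %*% ax), 10)),
       axis = ax)
}

#' Helical pitch from fibril length and mean twist
#'
#' Converts the measured end-to-end length of an n-chain fibril and the
#' mean per-interface rotation angle into the helical pitch: with
#' chains_per_turn = 360 / twist and rise = length / n (see
#' \code{convention}), pitch = chains_per_turn x rise. A zero twist is
#' reported as a distinguished untwisted result with infinite pitch.
#'
#' @param length_d fibril length in Angstrom.
#' @param n_chains number of chains in the fibril.
#' @param mean_twist mean per-interface rotation angle in degrees.
#' @param convention divisor for the per-chain rise: \code{"n"}
#'   (default, rise = d / n) or \code{"n-1"} (rise = d / (n - 1), the
#'   construction convention for an ideal helix whose n chains span
#'   n - 1 rises).
#' @return An object of class \code{"helical_pitch"}: list with
#'   \code{pitch} (Angstrom), \code{pitch_nm}, \code{chains_per_turn},
#'   \code{rise} (Angstrom) and \code{untwisted} flag.
#' @export
helical_pitch <- function(length_d, n_chains, mean_twist,
                          convention = c("n", "n-1")) {
  convention <- match.arg(convention)
  if (n_chains < 2) stop("n_chains must be >= 2")
  if (mean_twist < 0) stop("mean_twist must be >= 0")
  rise <- length_d / switch(convention, "n" = n_chains, "n-1" = n_chains - 1)
  untwisted <- mean_twist == 0
  cpt <- if (untwisted) Inf else 360 / mean_twist
  structure(list(pitch = cpt * rise, pitch_nm = cpt * rise / 10,
                 chains_per_turn = cpt, rise = rise,
                 untwisted = untwisted, convention = convention),
            class = "helical_pitch")
}

#' @export
print.helical_pitch <- function(x, ...) {
  if (x$untwisted)
    cat("Untwisted stack: rise", sprintf("%.3f A,", x$rise),
        "infinite helical pitch\n")
  else
    cat(sprintf("Helical pitch %.1f A (%.1f nm): %.1f chains per turn at rise %.3f A/chain\n",
                x$pitch, x$pitch_nm, x$chains_per_turn, x$rise))
  invisible(x)
}

#' Full geometric characterization of a fibril model
#'
#' Measures the standard observables of a fibril model in one call:
#' end-to-end length, per-interface twist angles (mean and sd), rise per
#' chain, helical pitch and chains per turn.
#'
#' @param model a \code{fibril_model} with M >= 2 chains.
#' @param residue_a,residue_b marker residues for the twist segments
#'   (see \code{\link{interface_angles}}).
#' @param convention rise convention passed to
#'   \code{\link{helical_pitch}}.
#' @return An object of class \code{"fibril_geometry"}: list with
#'   \code{length_d}, \code{interface_angles}, \code{mean_twist},
#'   \code{sd_twist}, \code{handedness}, \code{rise_per_chain},
#'   \code{pitch}, \code{pitch_nm}, \code{chains_per_turn}, \code{M},
#'   \code{N}.
#' @export
fibril_geometry <- function(model, residue_a = 3, residue_b = 9,
                            convention = "n") {
  model <- order_chains(model)
  d <- fibril_length(model, reorder = FALSE)
  ia <- interface_angles(model, residue_a, residue_b, reorder = FALSE)
  mt <- mean(ia$angles)
  hp <- helical_pitch(d, n_chains(model), mt, convention)
  structure(list(length_d = d, interface_angles = ia$angles,
                 mean_twist = mt,
                 sd_twist = if (length(ia$angles) > 1) sd(ia$angles) else 0,
                 handedness = ia$handedness,
                 rise_per_chain = hp$rise, pitch = hp$pitch,
                 pitch_nm = hp$pitch_nm, chains_per_turn = hp$chains_per_turn,
                 untwisted = hp$untwisted,
                 M = n_chains(model), N = chain_length(model)),
            class = "fibril_geometry")
}

#' @export
print.fibril_geometry <- function(x, ...) {
  cat(sprintf("Fibril geometry (M = %d chains x N = %d residues)\n", x$M, x$N))
  cat(sprintf("  length d:        %.2f A\n", x$length_d))
  cat(sprintf("  twist angle:     %.2f +/- %.2f deg per interface\n",
              x$mean_twist, x$sd_twist))
  cat(sprintf("  rise per chain:  %.3f A\n", x$rise_per_chain))
  if (x$untwisted)
    cat("  pitch:           untwisted (infinite)\n")
  else
    cat(sprintf("  pitch:           %.1f A (%.1f nm), %.1f chains/turn\n",
                x$pitch, x$pitch_nm, x$chains_per_turn))
  invisible(x)
}
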