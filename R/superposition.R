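#' Pairwise RMSD matrix over an ensemble of models
#'
#' RMSD after optimal superposition, over all CA atoms of whole models,
#' for every unordered pair. The result is symmetric with a zero
#' diagonal.
#'
#' @param models list of \code{fibril_model} objects with identical
#'   layout (>= 2).
#' @param labels optional model identifiers; defaults to model labels.
#' @return An \code{"rmsd_matrix"}: a symmetric numeric matrix in
#'   Angstrom.
#' @export
model_rmsd_matrix <- function(models, labels = NULL) {
  if (length(models) < 2) stop("need at least 2 models")
  check_same_layout(models)
  if (is.null(labels))
    labels <- make.unique(vapply(models, `[[`, "", "label"))
  xyz <- lapply(models, ca_coords)
  n <- length(models)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      m[i, j] <- m[j, i] <- rmsd_after_fit(xyz[[i]], xyz[[j]])
  structure(m, class = c("rmsd_matrix", "matrix"))
}

#' @export
print.rmsd_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise RMSD matrix (A), ", nrow(x), " models; mean off-diagonal ",
      sprintf("%.3f", mean(x[upper.tri(x)])), " A\n", sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' @export
plot.rmsd_matrix <- function(x, ...) {
  n <- nrow(x)
  graphics::image(seq_len(n), seq_len(n), unclass(x)[, n:1],
                  xlab = "model", ylab = "model",
                  main = "pairwise RMSD (A)", ...)
  invisible(x)
}

#' Centroid (most representative) model of an ensemble
#'
#' Selects the frame minimizing the mean RMSD-after-fit to all other
#' frames, the usual single-cluster representative of a trajectory.
#' Ties are broken by the lowest index.
#'
#' @param frames list of \code{fibril_model} objects.
#' @return List with \code{index}, \code{model} and \code{mean_rmsd}
#'   (mean RMSD of the centroid to the other frames, Angstrom).
#' @export
centroid_model <- function(frames) {
  if (!length(frames)) stop("empty frame list")
  if (length(frames) == 1)
    return(list(index = 1L, model = frames[[1]], mean_rmsd = 0))
  m <- model_rmsd_matrix(frames)
  means <- rowSums(m) / (nrow(m) - 1)
  idx <- unname(which.min(means))  # which.min takes the first minimum
  list(index = idx, model = frames[[idx]], mean_rmsd = means[[idx]])
}

#' Best candidate against a reference structure
#'
#' Returns the candidate with the lowest all-CA RMSD-after-fit to the
#' reference. Because a fibril has no intrinsic chain labelling, the
#' chain order of each candidate is matched to the reference both as
#' given and reversed, and the lower RMSD is kept.
#'
#' @param candidates list of \code{fibril_model} objects.
#' @param reference a \code{fibril_model} with the same chain count and
#'   residue count.
#' @return List with \code{index}, \code{rmsd} (Angstrom) and
#'   \code{rmsds} (per-candidate vector).
#' @export
best_model_rmsd <- function(candidates, reference) {
  if (!length(candidates)) stop("empty candidate list")
  check_same_layout(c(list(reference), candidates))
  ref <- ca_coords(reference)
  rmsds <- vapply(candidates, function(m) {
    fwd <- rmsd_after_fit(ca_coords(m), ref)
    rev_m <- m
    rev_m$chains <- rev(m$chains)
    min(fwd, rmsd_after_fit(ca_coords(rev_m), ref))
  }, 0)
  idx <- which.min(rmsds)
  list(index = idx, rmsd = rmsds[[idx]], rmsds = rmsds)
}
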