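#' Peptide-chain-average RMSD (pcaRMSD)
#'
#' Translational-symmetry score of a multi-chain protofilament model:
#' every unordered pair of chains is superposed (proper-rotation Kabsch
#' fit over all CA atoms) and the pairwise RMSDs are averaged,
#'
#' \deqn{pcaRMSD = \frac{1}{M^2 - M} \sum_{i=1}^{M} \sum_{j=1}^{M}
#'       RMSD(i, j)}
#'
#' where M is the number of chains and RMSD(i, j) the post-fit Calpha
#' RMSD of chains i and j. Diagonal terms vanish and RMSD is symmetric,
#' so this equals the plain mean over the M(M-1)/2 unordered pairs.
#' A perfectly translationally symmetric stack scores 0; the score grows
#' with conformational divergence between the monomers.
#'
#' @param model a \code{fibril_model} with M >= 2 equal-length chains.
#' @return An object of class \code{"pca_rmsd"}: list with
#'   \code{pcaRMSD} (Angstrom), \code{pairs} (data frame i, j, rmsd),
#'   \code{M}, \code{N} and the model \code{label}.
#' @export
pca_rmsd <- function(model) {
  M <- n_chains(model)
  if (M < 2) stop("pcaRMSD requires at least 2 chains")
  xyz <- lapply(model$chains, `[[`, "ca")
  idx <- utils::combn(M, 2)
  r <- apply(idx, 2, function(p) rmsd_after_fit(xyz[[p[1]]], xyz[[p[2]]]))
  structure(list(pcaRMSD = mean(r),
                 pairs = data.frame(i = idx[1, ], j = idx[2, ], rmsd = r),
                 M = M, N = chain_length(model), label = model$label),
            class = "pca_rmsd")
}

#' @export
print.pca_rmsd <- function(x, ...) {
  cat(sprintf("pcaRMSD = %.3f A  (model '%s': M = %d chains, N = %d CA atoms, %d pairs)\n",
              x$pcaRMSD, x$label, x$M, x$N, nrow(x$pairs)))
  invisible(x)
}

#' Rank protofilament models by translational symmetry
#'
#' Scores every model with \code{\link{pca_rmsd}} and returns the
#' \code{top_k} lowest-scoring (most symmetric) models in ascending
#' order; ties keep the input order.
#'
#' @param models list of \code{fibril_model} objects.
#' @param top_k how many models to return (default: all).
#' @return List of \code{"pca_rmsd"} objects, ascending by score.
#' @export
rank_models <- function(models, top_k = length(models)) {
  if (!length(models)) stop("no models to rank")
  if (top_k < 1) stop("top_k must be >= 1")
  scored <- lapply(models, pca_rmsd)
  ord <- order(vapply(scored, `[[`, 0, "pcaRMSD"))  # stable for ties
  scored[ord][seq_len(min(top_k, length(scored)))]
}

#' Scoring table for a set of models
#'
#' @param scored list of \code{"pca_rmsd"} objects (e.g. from
#'   \code{\link{rank_models}}).
#' @return Data frame with columns model, pcaRMSD, M, N.
#' @export
score_table <- function(scored) {
  data.frame(model = vapply(scored, `[[`, "", "label"),
             pcaRMSD = vapply(scored, `[[`, 0, "pcaRMSD"),
             M = vapply(scored, `[[`, 0L, "M"),
             N = vapply(scored, `[[`, 0L, "N"))
}
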