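# Kabsch-Sander electrostatic H-bond model constants
KS_COUPLING <- 0.084 * 332          # kcal/mol * A
KS_CUTOFF <- -0.5                   # bond exists below this energy
KS_EMIN <- -9.9                     # clamp for overlapping atoms
KS_MIN_DIST <- 0.1                  # A; closer atom pairs are clamped

#' Place amide hydrogens on a backbone chain
#'
#' Standard DSSP convention: the amide H of residue i sits 1.0 A from
#' its N, along the direction of the preceding residue's O -> C bond
#' (i.e. opposite the carbonyl). The first residue and prolines carry no
#' amide hydrogen (their rows are NA).
#'
#' @param chain a \code{peptide_chain} with backbone atoms.
#' @return The chain with an \code{h} coordinate matrix added.
#' @export
place_amide_hydrogens <- function(chain) {
  if (!has_backbone_chain(chain))
    stop("backbone (N/CA/C/O) required to place amide hydrogens")
  nres <- length(chain)
  h <- matrix(NA_real_, nres, 3)
  if (nres >= 2) {
    co <- chain$c[-nres, , drop = FALSE] - chain$o[-nres, , drop = FALSE]
    co <- co / sqrt(rowSums(co^2))
    h[-1, ] <- chain$n[-1, , drop = FALSE] + co
    h[chain$resid == "PRO", ] <- NA_real_
  }
  chain$h <- h
  chain
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of a putative backbone H-bond from the N-H of
#' the donor residue to the C=O of the acceptor residue:
#' E = 0.084 x 332 x (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol.
#' A bond is assigned when E < -0.5 kcal/mol. Overlapping atoms (any
#' distance below 0.1 A) clamp the energy to the DSSP minimum of
#' -9.9 kcal/mol.
#'
#' @param donor list with \code{n} and \code{h} 3-vectors.
#' @param acceptor list with \code{c} and \code{o} 3-vectors.
#' @return Energy in kcal/mol.
#' @export
hbond_energy <- function(donor, acceptor) {
  r <- c(on = sqrt(sum((acceptor$o - donor$n)^2)),
         ch = sqrt(sum((acceptor$c - donor$h)^2)),
         oh = sqrt(sum((acceptor$o - donor$h)^2)),
         cn = sqrt(sum((acceptor$c - donor$n)^2)))
  if (any(r < KS_MIN_DIST)) {
    warning("overlapping atoms in H-bond candidate; energy clamped")
    return(KS_EMIN)
  }
  KS_COUPLING * (1 / r["on"] + 1 / r["ch"] - 1 / r["oh"] - 1 / r["cn"])[[1]]
}

# stack per-residue atom coordinates of a whole model into flat tables
model_residue_table <- function(model) {
  stopifnot(has_backbone(model))
  chains <- lapply(model$chains, function(ch)
    if (is.null(ch$h)) place_amide_hydrogens(ch) else ch)
  list(chain = rep(seq_along(chains), vapply(chains, length, 0L)),
       resi = unlist(lapply(chains, function(ch) seq_len(length(ch)))),
       resno = unlist(lapply(chains, `[[`, "resno")),
       resid = unlist(lapply(chains, `[[`, "resid")),
       n = do.call(rbind, lapply(chains, `[[`, "n")),
       h = do.call(rbind, lapply(chains, `[[`, "h")),
       c = do.call(rbind, lapply(chains, `[[`, "c")),
       o = do.call(rbind, lapply(chains, `[[`, "o")))
}

cross_dist <- function(a, b) {
  # Euclidean distances between rows of a and rows of b
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Backbone hydrogen bonds of a model
#'
#' Evaluates the Kabsch-Sander energy for every donor/acceptor residue
#' pair of the model (amide hydrogens are placed on demand) and returns
#' the pairs bonded at the energy cutoff. Within a chain, pairs with
#' |i - j| < 2 are never counted (no self or nearest-neighbour bonds).
#'
#' @param model a \code{fibril_model} with full backbones.
#' @param cutoff bond energy cutoff in kcal/mol (default -0.5).
#' @return Data frame: donor_chain, donor_res (position), acceptor_chain,
#'   acceptor_res, energy (kcal/mol).
#' @export
hbond_table <- function(model, cutoff = KS_CUTOFF) {
  rt <- model_residue_table(model)
  E <- hbond_energy_matrix(rt)
  hit <- which(E < cutoff, arr.ind = TRUE)
  data.frame(donor_chain = rt$chain[hit[, 1]],
             donor_res = rt$resi[hit[, 1]],
             acceptor_chain = rt$chain[hit[, 2]],
             acceptor_res = rt$resi[hit[, 2]],
             energy = E[hit])
}

# donors x acceptors energy matrix; +Inf where no bond is admissible
hbond_energy_matrix <- function(rt) {
  ok_donor <- stats::complete.cases(rt$h)
  rON <- cross_dist(rt$n, rt$o)
  rCH <- cross_dist(rt$h, rt$c)
  rOH <- cross_dist(rt$h, rt$o)
  rCN <- cross_dist(rt$n, rt$c)
  clamped <- (rON < KS_MIN_DIST | rOH < KS_MIN_DIST |
              rCH < KS_MIN_DIST | rCN < KS_MIN_DIST)
  clamped[is.na(clamped)] <- FALSE
  E <- KS_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[clamped] <- KS_EMIN
  E[!ok_donor, ] <- Inf
  E[is.na(E)] <- Inf
  same_chain <- outer(rt$chain, rt$chain, `==`)
  near <- abs(outer(rt$resi, rt$resi, `-`)) < 2
  E[same_chain & near] <- Inf
  E
}

#' Beta-sheet residue content
#'
#' Assigns residues to beta-bridges and ladders from the backbone
#' H-bond network using the DSSP bridge patterns. With Hbond(i, j)
#' denoting a bond from the C=O of residue i to the N-H of residue j:
#' a parallel bridge (i, j) requires Hbond(i-1, j) and Hbond(j, i+1),
#' or Hbond(j-1, i) and Hbond(i, j+1); an antiparallel bridge requires
#' Hbond(i, j) and Hbond(j, i), or Hbond(i-1, j+1) and Hbond(j-1, i+1).
#' Bridges repeated along the chain form ladders (state E); a lone
#' bridge is an isolated beta-bridge (state B). The reported fraction is
#' the percentage of residues in states E/B (or E only, when isolated
#' bridges are excluded).
#'
#' @param model a \code{fibril_model} with full backbones.
#' @param cutoff H-bond energy cutoff in kcal/mol.
#' @param include_isolated_bridges count B residues as beta (default
#'   TRUE).
#' @return An object of class \code{"beta_content"}: list with
#'   \code{fraction} (percent), \code{count} (residues),
#'   \code{total_residues}, \code{states} (per-residue "E"/"B"/"-" by
#'   chain) and the H-bond table.
#' @export
beta_fraction <- function(model, cutoff = KS_CUTOFF,
                          include_isolated_bridges = TRUE) {
  if (!has_backbone(model))
    stop("backbone required: Calpha-only models cannot be scored for beta content")
  rt <- model_residue_table(model)
  n <- length(rt$chain)
  E <- hbond_energy_matrix(rt)
  # HB[i, j]: C=O of i accepts from N-H of j (Kabsch-Sander orientation)
  HB <- t(E < cutoff)

  prv <- c(NA, seq_len(n - 1))
  nxt <- c(seq_len(n)[-1], NA)
  prv[c(TRUE, rt$chain[-1] != rt$chain[-n])] <- NA
  nxt[c(rt$chain[-1] != rt$chain[-n], TRUE)] <- NA

  shift <- function(m, rows, cols) {
    out <- matrix(FALSE, n, n)
    okr <- !is.na(rows); okc <- !is.na(cols)
    out[okr, okc] <- m[rows[okr], cols[okc], drop = FALSE]
    out
  }
  idx <- seq_len(n)
  P1 <- shift(HB, prv, idx) & t(shift(HB, idx, nxt))   # Hbond(i-1,j) & Hbond(j,i+1)
  par_bridge <- P1 | t(P1)
  A1 <- HB & t(HB)                                     # Hbond(i,j) & Hbond(j,i)
  B1 <- shift(HB, prv, nxt)                            # Hbond(i-1,j+1)
  anti_bridge <- A1 | (B1 & t(B1))

  admissible <- outer(rt$chain, rt$chain, `!=`) |
    (abs(outer(rt$resi, rt$resi, `-`)) >= 3)
  par_bridge <- par_bridge & admissible
  anti_bridge <- anti_bridge & admissible

  states <- rep("-", n)
  ladder <- function(bridge, dj) {
    # bridge (i,j) extends to a ladder if (i+1, j+dj) or (i-1, j-dj) bridges
    up <- shift(bridge, nxt, if (dj > 0) nxt else prv)
    dn <- shift(bridge, prv, if (dj > 0) prv else nxt)
    bridge & (up | dn)
  }
  in_E <- rowSums(ladder(par_bridge, 1) | ladder(anti_bridge, -1)) > 0
  in_any <- rowSums(par_bridge | anti_bridge) > 0
  states[in_any] <- "B"
  states[in_E] <- "E"
  beta <- if (include_isolated_bridges) in_any else in_E

  hb <- which(t(HB), arr.ind = TRUE)
  structure(list(
    fraction = 100 * sum(beta) / n,
    count = sum(beta),
    total_residues = n,
    states = split(states, rt$chain),
    hbonds = data.frame(donor_chain = rt$chain[hb[, 1]],
                        donor_res = rt$resi[hb[, 1]],
                        acceptor_chain = rt$chain[hb[, 2]],
                        acceptor_res = rt$resi[hb[, 2]],
                        energy = E[hb[, c(1, 2), drop = FALSE]])),
    class = "beta_content")
}

#' @export
print.beta_content <- function(x, ...) {
  cat(sprintf("Beta-sheet content: %.2f%% (%d of %d residues), %d backbone H-bonds\n",
              x$fraction, x$count, x$total_residues, nrow(x$hbonds)))
  invisible(x)
}

#' Extinction-coefficient correction of amide-I band fractions
#'
#' Integral intensities of amide-I components over-weight secondary
#' structures with large vibrational molar extinction coefficients
#' (beta-sheet absorbs roughly twice as strongly as turns). The
#' structure fraction of component c is recovered as
#' (I_c / w_c) / sum_k (I_k / w_k), where I are the intensity fractions
#' (summing to 1) and w the relative extinction weights.
#'
#' @param intensity numeric intensity fractions of the amide-I
#'   components (must sum to 1 within 1e-6, all in [0, 1]).
#' @param weight positive relative extinction weights, same length.
#' @param labels optional component labels.
#' @return Named numeric vector of corrected structure fractions
#'   (summing to 1).
#' @export
band_correction <- function(intensity, weight, labels = NULL) {
  if (length(intensity) != length(weight))
    stop("intensity and weight must have the same length")
  if (any(weight <= 0)) stop("extinction weights must be > 0")
  if (any(intensity < 0 | intensity > 1))
    stop("intensity fractions must lie in [0, 1]")
  if (abs(sum(intensity) - 1) > 1e-6)
    stop("intensity fractions must sum to 1")
  corrected <- (intensity / weight) / sum(intensity / weight)
  if (!is.null(labels)) names(corrected) <- labels
  corrected
}
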