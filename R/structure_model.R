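#' @importFrom stats rnorm sd
#' @importFrom utils write.table combn
NULL

# Single-character chain identifiers in assignment order. The PDB chain
# field is one character, so long fibrils cycle A-Z, then a-z, then 0-9.
CHAIN_ID_ALPHABET <- c(LETTERS, letters, as.character(0:9))

#' Chain identifiers for an assembly
#'
#' Deterministic chain-ID policy used when writing models: A-Z, then
#' a-z, then 0-9 (62 chains maximum, enough for a 30-chain fibril).
#'
#' @param m number of chains.
#' @return Character vector of \code{m} single-character IDs.
#' @export
chain_id_policy <- function(m) {
  if (m > length(CHAIN_ID_ALPHABET))
    stop("more than ", length(CHAIN_ID_ALPHABET),
         " chains cannot be written to a single PDB file; ",
         "split the model across files")
  CHAIN_ID_ALPHABET[seq_len(m)]
}

#' Peptide chain container
#'
#' One peptide monomer: ordered Calpha coordinates with residue
#' identities, optionally carrying the full backbone (N, C, O and, once
#' placed, the amide H) needed for hydrogen-bond assignment.
#'
#' @param chain_id single-character chain label.
#' @param resno integer residue numbers, strictly increasing.
#' @param resid three-letter residue codes.
#' @param ca n x 3 Calpha coordinates (Angstrom).
#' @param n,c,o optional n x 3 backbone N, C and O coordinates.
#' @param h optional n x 3 amide-hydrogen coordinates (rows may be NA
#'   for residues without an amide H).
#' @return An object of class \code{"peptide_chain"}.
#' @export
peptide_chain <- function(chain_id, resno, resid, ca,
                          n = NULL, c = NULL, o = NULL, h = NULL) {
  ca <- coord_matrix(ca)
  nres <- nrow(ca)
  resno <- as.integer(resno)
  resid <- as.character(resid)
  if (length(resno) != nres || length(resid) != nres)
    stop("residue metadata length does not match the number of residues")
  if (nres < 1) stop("a chain needs at least one residue")
  if (nres > 1 && any(diff(resno) <= 0))
    stop("residue numbers must be strictly increasing in chain ", chain_id)
  bb <- list(n = n, c = c, o = o)
  have <- !vapply(bb, is.null, logical(1))
  if (any(have) && !all(have))
    stop("backbone requires all of N, C and O coordinates")
  if (all(have)) {
    bb <- lapply(bb, coord_matrix)
    if (any(vapply(bb, nrow, 0L) != nres))
      stop("backbone atom count does not match residue count")
  } else bb <- list(n = NULL, c = NULL, o = NULL)
  if (!is.null(h)) {
    h <- as.matrix(h)
    if (nrow(h) != nres || ncol(h) != 3)
      stop("H coordinates must be n x 3")
  }
  structure(list(chain_id = as.character(chain_id), resno = resno,
                 resid = resid, ca = ca,
                 n = bb$n, c = bb$c, o = bb$o, h = h),
            class = "peptide_chain")
}

#' @export
length.peptide_chain <- function(x) nrow(x$ca)

has_backbone_chain <- function(chain) !is.null(chain$n)

#' Validate backbone bond geometry of a chain
#'
#' Checks that intra-residue backbone distances are physically
#' plausible (0.5 A < |CA-N|, |CA-C|, |C-O| < 3 A).
#'
#' @param chain a \code{peptide_chain} with backbone atoms.
#' @return Invisibly \code{TRUE}; errors on violation.
#' @export
validate_backbone <- function(chain) {
  if (!has_backbone_chain(chain)) stop("chain carries no backbone atoms")
  d <- cbind(sqrt(rowSums((chain$ca - chain$n)^2)),
             sqrt(rowSums((chain$ca - chain$c)^2)),
             sqrt(rowSums((chain$c - chain$o)^2)))
  if (any(d <= 0.5 | d >= 3))
    stop("implausible backbone bond length in chain ", chain$chain_id,
         " (residue ", chain$resno[which(d <= 0.5 | d >= 3, arr.ind = TRUE)[1, 1]],
         ")")
  invisible(TRUE)
}

#' Multi-chain assembly model
#'
#' An ordered collection of equal-length peptide chains representing a
#' protofilament or a fibril. All chains must share residue count and
#' sequence; chain order is taken to follow position along the fibril
#' axis (see \code{\link{order_chains}}).
#'
#' @param chains list of \code{\link{peptide_chain}} objects.
#' @param label provenance label (file name, generator tag, ...).
#' @return An object of class \code{"fibril_model"}.
#' @export
fibril_model <- function(chains, label = "model") {
  if (!length(chains)) stop("a model needs at least one chain")
  if (!all(vapply(chains, inherits, TRUE, "peptide_chain")))
    stop("all chains must be peptide_chain objects")
  len <- vapply(chains, length, 0L)
  if (length(unique(len)) != 1L)
    stop("chains have unequal lengths: ",
         paste(vapply(chains, function(ch) ch$chain_id, ""), len,
               sep = "=", collapse = ", "))
  seqs <- vapply(chains, function(ch) paste(ch$resid, collapse = "-"), "")
  if (length(unique(seqs)) != 1L)
    stop("chains do not share an identical residue sequence")
  structure(list(chains = chains, label = as.character(label)),
            class = "fibril_model")
}

#' @export
print.fibril_model <- function(x, ...) {
  cat("Fibril/protofilament model '", x$label, "': ",
      n_chains(x), " chain(s) x ", chain_length(x), " residues",
      if (has_backbone(x)) " (full backbone)" else " (Calpha trace)",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.fibril_model <- function(object, ...) {
  cat("Model '", object$label, "'\n", sep = "")
  cat("  chains:   ", n_chains(object), "\n")
  cat("  residues: ", chain_length(object), " per chain (",
      paste(object$chains[[1]]$resid[seq_len(min(5, chain_length(object)))],
            collapse = " "),
      if (chain_length(object) > 5) " ..." else "", ")\n", sep = "")
  cat("  backbone: ", if (has_backbone(object)) "N/CA/C/O" else "CA only", "\n")
  if (n_chains(object) >= 2) {
    g <- try(fibril_geometry(object), silent = TRUE)
    if (!inherits(g, "try-error")) print(g)
  }
  invisible(object)
}

#' Number of chains in a model
#' @param model a \code{fibril_model}.
#' @return Integer chain count M.
#' @export
n_chains <- function(model) length(model$chains)

#' Residues per chain
#' @param model a \code{fibril_model}.
#' @return Integer residue count N (common to all chains).
#' @export
chain_length <- function(model) length(model$chains[[1]])

#' Does every chain carry a full backbone?
#' @param model a \code{fibril_model}.
#' @return Logical.
#' @export
has_backbone <- function(model)
  all(vapply(model$chains, has_backbone_chain, TRUE))

#' All-CA coordinate matrix of a model
#' @param model a \code{fibril_model}.
#' @return (M*N) x 3 matrix, chains stacked in order.
#' @export
ca_coords <- function(model) do.call(rbind, lapply(model$chains, `[[`, "ca"))

#' Per-chain Calpha centers of mass
#'
#' Equal-weight CA centroid of every chain (CA atoms as the mass proxy,
#' appropriate for Calpha-trace models).
#'
#' @param model a \code{fibril_model}.
#' @return M x 3 matrix of chain centers.
#' @export
chain_centers <- function(model)
  do.call(rbind, lapply(model$chains, function(ch) colMeans(ch$ca)))

#' Apply a rigid transform to a whole model
#' @param model a \code{fibril_model}.
#' @param tr a \code{rigid_transform}.
#' @return The transformed model.
#' @export
transform_model <- function(model, tr) {
  model$chains <- lapply(model$chains, transform_chain, tr = tr)
  model
}

transform_chain <- function(chain, tr) {
  for (at in c("ca", "n", "c", "o", "h"))
    if (!is.null(chain[[at]])) {
      ok <- stats::complete.cases(chain[[at]])
      chain[[at]][ok, ] <- apply_transform(tr, chain[[at]][ok, , drop = FALSE])
    }
  chain
}

atom_order <- c("N", "CA", "C", "O")

#' Read a multi-chain model from a PDB file
#'
#' Parses ATOM records into one \code{\link{fibril_model}} per MODEL
#' block (a single model when the file has no MODEL records). Alternate
#' locations keep the highest-occupancy conformer (ties: first record);
#' insertion codes are rejected. When \code{calpha_only} is \code{FALSE}
#' the full N/CA/C/O backbone is retained if complete, enabling
#' hydrogen-bond analysis.
#'
#' @param path PDB file path.
#' @param calpha_only keep only CA atoms even if a backbone is present.
#' @return A \code{fibril_model}, or a list of them for multi-MODEL
#'   files.
#' @export
read_model <- function(path, calpha_only = FALSE) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e)))
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(atom)) stop("no ATOM records in '", path, "'")
  if (any(!is.na(atom$insert)))
    stop("insertion codes are not supported (residue ",
         atom$resno[which(!is.na(atom$insert))[1]], ")")
  atom$row <- seq_len(nrow(atom))
  # alt-loc policy: highest occupancy, ties resolved to the first record
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  keep <- atom[order(-occ, atom$row), , drop = FALSE]
  key <- paste(keep$chain, keep$resno, keep$elety)
  keep <- keep[!duplicated(key), , drop = FALSE]
  keep <- keep[order(keep$row), , drop = FALSE]

  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)

  models <- lapply(seq_len(nmod), function(m) {
    coords <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    build_model_from_atoms(keep, coords, calpha_only,
                           label = if (nmod > 1)
                             sprintf("%s#%d", basename(path), m)
                           else basename(path))
  })
  if (nmod == 1L) models[[1]] else models
}

build_model_from_atoms <- function(atom, coords, calpha_only, label) {
  chains <- unique(atom$chain)
  built <- lapply(chains, function(cid) {
    rows <- atom[atom$chain == cid, , drop = FALSE]
    resnos <- unique(rows$resno)
    ca_rows <- rows[rows$elety == "CA", , drop = FALSE]
    miss <- setdiff(resnos, ca_rows$resno)
    if (length(miss))
      stop("missing CA atom for residue ", miss[1], " in chain ", cid)
    grab <- function(ety) {
      r <- rows[rows$elety == ety, , drop = FALSE]
      if (!all(resnos %in% r$resno)) return(NULL)
      coords[r$row[match(resnos, r$resno)], , drop = FALSE]
    }
    ca <- coords[ca_rows$row[match(resnos, ca_rows$resno)], , drop = FALSE]
    bb <- if (!calpha_only) lapply(c(n = "N", c = "C", o = "O"), grab)
          else list(n = NULL, c = NULL, o = NULL)
    if (any(vapply(bb, is.null, TRUE))) bb <- list(n = NULL, c = NULL, o = NULL)
    peptide_chain(cid, resnos,
                  rows$resid[match(resnos, rows$resno)], ca,
                  n = bb$n, c = bb$c, o = bb$o)
  })
  fibril_model(built, label = label)
}

#' Write a model (or ensemble) to a PDB file
#'
#' Emits standard ATOM/TER records (plus MODEL/ENDMDL blocks for an
#' ensemble), chain IDs assigned by \code{\link{chain_id_policy}},
#' coordinates at the PDB precision of 3 decimals.
#'
#' @param model a \code{fibril_model} or a list of them with identical
#'   layout (written as a multi-MODEL file).
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_model <- function(model, path) {
  models <- if (inherits(model, "fibril_model")) list(model) else model
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    write_model_records(models[[m]], con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

write_model_records <- function(model, con) {
  ids <- chain_id_policy(n_chains(model))
  serial <- 0L
  for (k in seq_len(n_chains(model))) {
    ch <- model$chains[[k]]
    atoms <- if (has_backbone_chain(ch)) atom_order else "CA"
    slot <- c(N = "n", CA = "ca", C = "c", O = "o")
    for (i in seq_len(length(ch))) {
      for (a in atoms) {
        serial <- serial + 1L
        xyz <- ch[[slot[[a]]]][i, ]
        writeLines(sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial %% 100000L, a, ch$resid[i], ids[k], ch$resno[i],
          xyz[1], xyz[2], xyz[3], 1, 0), con)
      }
    }
    writeLines(sprintf("TER   %5d      %3s %1s%4d",
                       (serial + 1L) %% 100000L,
                       ch$resid[length(ch)], ids[k],
                       ch$resno[length(ch)]), con)
    serial <- serial + 1L
  }
}

#' Average an ensemble of conformers
#'
#' Superposes every conformer onto the first (best fit over all CA
#' atoms) and returns the per-atom arithmetic mean structure, the usual
#' reference structure for an NMR-style ensemble.
#'
#' @param ensemble list of \code{fibril_model} objects with identical
#'   chain/residue layout.
#' @return The average \code{fibril_model}.
#' @export
average_conformers <- function(ensemble) {
  if (!length(ensemble)) stop("empty ensemble")
  check_same_layout(ensemble)
  ref <- ensemble[[1]]
  fitted <- lapply(ensemble, function(m)
    transform_model(m, kabsch_fit(ca_coords(m), ca_coords(ref))))
  out <- ref
  for (k in seq_len(n_chains(ref))) {
    for (at in c("ca", "n", "c", "o")) {
      if (is.null(ref$chains[[k]][[at]])) next
      stack <- lapply(fitted, function(m) m$chains[[k]][[at]])
      if (any(vapply(stack, is.null, TRUE))) {
        out$chains[[k]][at] <- list(NULL)
        next
      }
      out$chains[[k]][[at]] <- Reduce(`+`, stack) / length(stack)
    }
  }
  out$label <- paste0("average(", length(ensemble), " conformers)")
  out
}

check_same_layout <- function(models) {
  m0 <- models[[1]]
  for (m in models[-1]) {
    if (n_chains(m) != n_chains(m0) || chain_length(m) != chain_length(m0))
      stop("models do not share an identical chain/residue layout")
  }
  invisible(TRUE)
}
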