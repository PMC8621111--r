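# Idealized backbone geometry for the synthetic builders (Angstrom).
# Offsets are chosen so that per-residue bond lengths sit on canonical
# values (CA-N 1.46, CA-C 1.52, C-O 1.23, consecutive CA-CA 3.8) and
# carbonyls alternate up/down out of the strand plane, which is what
# lets stacked copies form the in-register parallel beta H-bond network
# of an amyloid.
BB_CA_STEP <- 3.788     # CA-CA step along an extended strand
BB_PLEAT <- 0.15        # in-plane pleat amplitude
BB_N_BACK <- 1.35       # N offset against the chain direction
BB_N_OUT <- 0.55        # N offset out of plane
BB_C_FWD <- 1.17        # C offset along the chain direction
BB_C_OUT <- 0.97        # C offset out of plane
BB_CO_LEN <- 1.23       # C=O bond length
TURN_RADIUS <- 3.8      # U-turn arc radius (= CA-CA step on the arc)

# 13-residue insulin-A-chain-derived amyloidogenic peptide (Cys7->Ala)
ACC_SEQUENCE <- c("GLY", "ILE", "VAL", "GLU", "GLN", "CYS", "ALA",
                  "ALA", "SER", "VAL", "CYS", "SER", "LEU")

#' Idealized beta-hairpin monomer with full backbone
#'
#' Builds a deterministic single-chain backbone model of a beta-arch
#' monomer: two extended strand arms (consecutive CA-CA distance
#' ~3.8 A, carbonyls alternating out of the strand plane) joined by a
#' two-residue U-turn on a circular arc. Stacking copies of this
#' monomer along the out-of-plane axis produces in-register parallel
#' beta-sheets, which is the architecture the synthetic fibril
#' generator emulates.
#'
#' @param n_residues chain length (>= 5); default 13.
#' @param turn_at 1-based indices of the two turn residues (interior,
#'   consecutive); default c(8, 9).
#' @param sequence three-letter residue codes, length
#'   \code{n_residues}; defaults to the 13-residue insulin-derived
#'   peptide for \code{n_residues = 13}, poly-alanine otherwise.
#' @return A \code{\link{peptide_chain}} with N/CA/C/O coordinates.
#' @export
make_hairpin_monomer <- function(n_residues = 13, turn_at = c(8, 9),
                                 sequence = NULL) {
  if (n_residues < 5) stop("a hairpin needs at least 5 residues")
  t1 <- turn_at[1]; t2 <- turn_at[2]
  if (t2 != t1 + 1) stop("turn residues must be consecutive")
  if (t1 < 2 || t2 > n_residues - 1)
    stop("turn must be interior (not at the termini)")
  if (is.null(sequence))
    sequence <- if (n_residues == 13) ACC_SEQUENCE
                else rep("ALA", n_residues)
  if (length(sequence) != n_residues)
    stop("sequence length must equal n_residues")

  s <- (-1)^(seq_len(n_residues))
  ca <- matrix(0, n_residues, 3)
  arm1 <- seq_len(t1 - 1)
  ca[arm1, 1] <- (arm1 - 1) * BB_CA_STEP
  ca[arm1, 2] <- BB_PLEAT * s[arm1]
  xL <- ca[t1 - 1, 1]; yL <- ca[t1 - 1, 2]
  # two turn residues on a semicircular arc of radius = CA step
  ca[t1, ] <- c(xL + TURN_RADIUS * sin(pi / 3),
                yL + TURN_RADIUS * (1 - cos(pi / 3)), 0)
  ca[t2, ] <- c(xL + TURN_RADIUS * sin(pi / 3),
                yL + TURN_RADIUS * (1 + cos(pi / 3)), 0)
  arm2 <- seq.int(t2 + 1, n_residues)
  ca[arm2, 1] <- xL - (arm2 - t2 - 1) * BB_CA_STEP
  ca[arm2, 2] <- yL + 2 * TURN_RADIUS + BB_PLEAT * (s[arm2] - s[t2 + 1])

  # local chain tangent; central differences, one-sided at the ends
  nxt <- pmin(seq_len(n_residues) + 1, n_residues)
  prv <- pmax(seq_len(n_residues) - 1, 1)
  tang <- ca[nxt, , drop = FALSE] - ca[prv, , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  out <- cbind(0, 0, s)   # out-of-plane alternation
  n_xyz <- ca - BB_N_BACK * tang - BB_N_OUT * out
  c_xyz <- ca + BB_C_FWD * tang + BB_C_OUT * out
  o_xyz <- c_xyz + BB_CO_LEN * out
  peptide_chain("A", seq_len(n_residues), sequence, ca,
                n = n_xyz, c = c_xyz, o = o_xyz)
}

#' Synthetic helical fibril/protofilament generator
#'
#' Ground-truth generator: chain t (t = 1..n_chains) is the template
#' monomer moved by the (t-1)-fold screw motion — rotation by
#' \code{twist} degrees about the fibril axis and translation by
#' \code{rise} Angstrom along it — with optional isotropic per-atom
#' Gaussian noise applied after the screw motion. With zero noise the
#' model is exactly helical: every interface angle equals \code{twist},
#' the end-to-end length is (n_chains - 1) x rise, and pcaRMSD is 0.
#'
#' @param n_chains number of chains (default 30).
#' @param rise translation per chain along the axis, Angstrom (default
#'   4.625).
#' @param twist rotation per chain about the axis, degrees (default 9).
#' @param monomer template \code{peptide_chain}; default
#'   \code{\link{make_hairpin_monomer}()}. Its CA centroid is moved
#'   onto the axis before stacking.
#' @param noise_sigma per-atom isotropic Gaussian sd, Angstrom
#'   (default 0).
#' @param seed RNG seed for the noise (required when
#'   \code{noise_sigma > 0} for a reproducible model).
#' @return A \code{fibril_model} with full backbones.
#' @export
make_fibril <- function(n_chains = 30, rise = 4.625, twist = 9,
                        monomer = make_hairpin_monomer(),
                        noise_sigma = 0, seed = NULL) {
  if (n_chains < 1) stop("n_chains must be >= 1")
  if (rise <= 0) stop("rise must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  center <- colMeans(monomer$ca)
  template <- transform_chain(monomer,
                              rigid_transform(t = c(-center[1], -center[2], 0)))
  theta <- twist * pi / 180
  ids <- chain_id_policy(n_chains)
  if (!is.null(seed)) set.seed(seed)
  chains <- lapply(seq_len(n_chains), function(t) {
    a <- (t - 1) * theta
    R <- matrix(c(cos(a), sin(a), 0,
                  -sin(a), cos(a), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
    ch <- transform_chain(template,
                          rigid_transform(R, c(0, 0, (t - 1) * rise)))
    if (noise_sigma > 0)
      for (at in c("n", "ca", "c", "o"))
        ch[[at]] <- ch[[at]] + matrix(rnorm(3 * nrow(ch[[at]]),
                                            sd = noise_sigma),
                                      ncol = 3)
    ch$chain_id <- ids[t]
    ch
  })
  fibril_model(chains,
               label = sprintf("synthetic(n=%d, rise=%.3f, twist=%.2f, sigma=%.2f)",
                               n_chains, rise, twist, noise_sigma))
}

#' Inter-chain distance restraints for coarse-grained peptide docking
#'
#' Builds the restraint table used to bias a coarse-grained docking run
#' toward in-register stacking: one side-chain(SC)-to-side-chain
#' restraint per residue per adjacent chain pair, i.e.
#' n_residues x (n_chains - 1) inter-chain restraints, each at
#' \code{pair_distance} with \code{weight}. Optionally one intra-chain
#' CA-CA restraint per chain models a disulfide bridge (e.g. Cys6-Cys11
#' at 6.5 A).
#'
#' @param n_residues residues per chain (>= 1).
#' @param n_chains number of chains (>= 2).
#' @param pair_distance restraint distance in Angstrom (default 5).
#' @param weight restraint weight (default 1).
#' @param ssbond optional c(i, j, distance): an intra-chain CA-CA
#'   restraint between residues i and j in every chain.
#' @return Data frame with class \code{"restraint_table"}: columns
#'   chain_i, residue_i, chain_j, residue_j, distance, weight, atom
#'   ("SC" inter-chain, "CA" intra-chain).
#' @export
cabsdock_restraints <- function(n_residues, n_chains, pair_distance = 5,
                                weight = 1, ssbond = NULL) {
  if (n_residues < 1) stop("n_residues must be >= 1")
  if (n_chains < 2) stop("n_chains must be >= 2")
  ids <- chain_id_policy(n_chains)
  inter <- expand.grid(residue = seq_len(n_residues),
                       pair = seq_len(n_chains - 1))
  tab <- data.frame(chain_i = ids[inter$pair],
                    residue_i = inter$residue,
                    chain_j = ids[inter$pair + 1],
                    residue_j = inter$residue,
                    distance = pair_distance,
                    weight = weight,
                    atom = "SC")
  if (!is.null(ssbond)) {
    if (length(ssbond) != 3) stop("ssbond must be c(i, j, distance)")
    i <- ssbond[1]; j <- ssbond[2]
    if (i < 1 || j < 1 || i > n_residues || j > n_residues || i == j)
      stop("ssbond residue indices out of range")
    tab <- rbind(tab,
                 data.frame(chain_i = ids, residue_i = i,
                            chain_j = ids, residue_j = j,
                            distance = ssbond[3], weight = weight,
                            atom = "CA"))
  }
  class(tab) <- c("restraint_table", "data.frame")
  tab
}

#' Write a restraint table as plain text
#'
#' Six tab-separated columns (chain, residue, chain, residue, distance,
#' weight) preceded by header comments that document the mapping to a
#' docking tool's \code{--sc-rest-add} style arguments; the atom column
#' distinguishes side-chain from CA restraints.
#'
#' @param restraints a \code{\link{cabsdock_restraints}} table.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_restraints <- function(restraints, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# inter-chain distance restraints for coarse-grained peptide docking",
    "# columns: chain_i residue_i chain_j residue_j distance weight atom",
    "# SC rows map to --sc-rest-add CHAINi:RESi CHAINj:RESj DISTANCE WEIGHT",
    "# CA rows are intra-chain (disulfide-style) CA-CA restraints"), con)
  write.table(restraints, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
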