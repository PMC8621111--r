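#' Fibril assembly configuration
#'
#' Parameters of the iterated overlap-superposition assembly: a fresh
#' copy of the protofilament is fitted so that its first \code{overlap}
#' chains superpose onto the last \code{overlap} chains of the fixed
#' model, and the central chain of each translated copy is collected.
#' Defaults follow the 5-chain protofilament recipe: 30 iterations,
#' chains 1-4 of the copy fitted onto chains 2-5 of the fixed model,
#' chain 3 extracted.
#'
#' @param iterations number of assembly iterations n (fibril chain
#'   count).
#' @param overlap number of chains used in the fit (1 .. M-1); default
#'   M-1.
#' @param central_index 1-based index of the chain extracted per
#'   iteration; default the middle chain, ceiling(M/2).
#' @param M chain count of the protofilament the config will be applied
#'   to (used to resolve the defaults).
#' @return An object of class \code{"assembly_config"}.
#' @export
assembly_config <- function(M, iterations = 30,
                            overlap = M - 1,
                            central_index = ceiling(M / 2)) {
  if (M < 2) stop("assembly needs a protofilament with at least 2 chains")
  if (iterations < 1) stop("iterations must be >= 1")
  if (overlap < 1 || overlap > M - 1)
    stop("overlap must be between 1 and M-1 = ", M - 1)
  if (central_index < 1 || central_index > M)
    stop("central_index must be between 1 and M = ", M)
  structure(list(M = as.integer(M), iterations = as.integer(iterations),
                 overlap = as.integer(overlap),
                 central_index = as.integer(central_index),
                 fixed_window = seq.int(M - overlap + 1, M),
                 mobile_window = seq_len(overlap)),
            class = "assembly_config")
}

#' @export
print.assembly_config <- function(x, ...) {
  cat(sprintf(
    "Assembly config: %d iterations; fit copy chains %d-%d onto fixed chains %d-%d; extract chain %d\n",
    x$iterations, min(x$mobile_window), max(x$mobile_window),
    min(x$fixed_window), max(x$fixed_window), x$central_index))
  invisible(x)
}

#' Per-iteration overlap transform of a protofilament
#'
#' The rigid motion taking a fresh copy of the protofilament so that its
#' chains \code{1..overlap} superpose (joint Kabsch fit over the CA
#' atoms of all overlap chains) onto chains \code{M-overlap+1..M} of the
#' fixed model. For an exactly helical protofilament this recovers the
#' generating screw motion: rotation by the twist angle and translation
#' by the rise along the axis.
#'
#' @param fixed a \code{fibril_model} protofilament (M chains).
#' @param config an \code{\link{assembly_config}} for M chains.
#' @return A \code{rigid_transform}.
#' @export
overlap_transform <- function(fixed, config = assembly_config(n_chains(fixed))) {
  M <- n_chains(fixed)
  if (config$M != M) stop("config was built for M = ", config$M,
                          " chains, model has ", M)
  mob <- do.call(rbind,
                 lapply(fixed$chains[config$mobile_window], `[[`, "ca"))
  tgt <- do.call(rbind,
                 lapply(fixed$chains[config$fixed_window], `[[`, "ca"))
  kabsch_fit(mob, tgt)
}

#' Assemble a long fibril from a protofilament
#'
#' Builds an n-chain fibril by composing the per-iteration overlap
#' transform: iteration t contributes the protofilament's central chain
#' moved by the (t-1)-fold composition of the transform (iteration 1
#' contributes the untransformed central chain). Because the copies are
#' identical rigid bodies, composing one transform is mathematically
#' identical to re-fitting each copy in turn, without accumulating
#' floating-point refit noise. Backbone atoms, when present, are carried
#' along, so the assembled fibril can be analyzed for hydrogen bonding.
#'
#' @param protofilament a \code{fibril_model} (M >= 2 chains).
#' @param config an \code{\link{assembly_config}}; its
#'   \code{iterations} sets the fibril chain count.
#' @return A \code{fibril_model} with \code{config$iterations} chains,
#'   ordered by iteration (i.e. along the fibril axis).
#' @export
build_fibril <- function(protofilament,
                         config = assembly_config(n_chains(protofilament))) {
  tr <- overlap_transform(protofilament, config)
  template <- protofilament$chains[[config$central_index]]
  cur <- rigid_transform()
  ids <- chain_id_policy(config$iterations)
  chains <- vector("list", config$iterations)
  for (t in seq_len(config$iterations)) {
    ch <- transform_chain(template, cur)
    ch$chain_id <- ids[t]
    chains[[t]] <- ch
    cur <- compose_transform(cur, tr)
  }
  fibril_model(chains,
               label = sprintf("fibril(%s, n=%d)", protofilament$label,
                               config$iterations))
}
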