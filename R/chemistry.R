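# Small-molecule chemistry on a compartment's pools, in reference R form.
# The C++ engine applies the same per-molecule Bernoulli rules inside the
# step loop; these functions define the semantics on a single compartment
# and are convenient for oracle tests and for exploring rates interactively.

#' Molecule pools of a compartment
#'
#' A grid room (or protocell interior) holds counts of nucleotide precursors
#' (`np`), free nucleotides per letter (`nt`, named A/C/G/U), amphiphile
#' precursors (`ap`) and free amphiphiles (`am`).
#'
#' @param np,ap,am Non-negative counts.
#' @param nt Named numeric vector of per-letter nucleotide counts.
#' @return An `rw_pools` object.
#' @export
molecule_pools <- function(np = 0, nt = c(A = 0, C = 0, G = 0, U = 0),
                           ap = 0, am = 0) {
  nt <- nt[c("A", "C", "G", "U")]
  if (any(c(np, nt, ap, am) < 0)) stop("pool counts must be >= 0")
  structure(list(np = np, nt = nt, ap = ap, am = am), class = "rw_pools")
}

#' Non-enzymatic / NSR-catalyzed nucleotide formation
#'
#' Each precursor converts independently this step, with probability `P_NFR`
#' when a free functional NSR shares the compartment (saturating catalysis:
#' one NSR is enough, more do not stack) and `P_NF` otherwise. Each new
#' nucleotide's letter is uniform over \{A,C,G,U\}.
#'
#' @param pools An `rw_pools` object.
#' @param nsr_present Logical.
#' @param params An `rw_params` object.
#' @return Updated pools.
#' @export
nucleotide_formation <- function(pools, nsr_present = FALSE,
                                 params = default_params()) {
  p <- if (nsr_present) params$P_NFR else params$P_NF
  k <- rbinom(1, pools$np, p)
  if (k > 0) {
    letters4 <- stats::rmultinom(1, k, rep(0.25, 4))[, 1]
    pools$nt <- pools$nt + letters4
    pools$np <- pools$np - k
  }
  pools
}

#' Nucleotide decay
#'
#' Each free nucleotide reverts to a precursor with `P_ND`; letter identity
#' is lost.
#'
#' @inheritParams nucleotide_formation
#' @return Updated pools.
#' @export
nucleotide_decay <- function(pools, params = default_params()) {
  k <- rbinom(4, pools$nt, params$P_ND)
  pools$nt <- pools$nt - k
  pools$np <- pools$np + sum(k)
  pools
}

#' Amphiphile formation and decay
#'
#' Precursors form amphiphiles with `P_AF`; free amphiphiles decay back with
#' `P_AD`. Membrane amphiphiles decay with the smaller `P_ADM` (the membrane
#' protects them); a decayed membrane amphiphile leaves the membrane as a
#' precursor in the exterior. The amphiphile-equivalent total
#' `ap + am + membrane` is conserved.
#'
#' @param pools An `rw_pools` object.
#' @param in_membrane_count Amphiphiles currently in a membrane bordering the
#'   compartment (0 if none).
#' @param params An `rw_params` object.
#' @return List with updated `pools` and `in_membrane_count`.
#' @export
amphiphile_events <- function(pools, in_membrane_count = 0,
                              params = default_params()) {
  formed <- rbinom(1, pools$ap, params$P_AF)
  decayed <- rbinom(1, pools$am, params$P_AD)
  mem_decayed <- rbinom(1, in_membrane_count, params$P_ADM)
  pools$ap <- pools$ap - formed + decayed + mem_decayed
  pools$am <- pools$am + formed - decayed
  list(pools = pools, in_membrane_count = in_membrane_count - mem_decayed)
}

#' Total nucleotide-equivalents of a pool set
#'
#' Precursors, free nucleotides and chain residues each count as one unit of
#' the conserved mass ledger.
#'
#' @param pools An `rw_pools` object.
#' @param strand_residues Total residues across RNA strands sharing the
#'   compartment.
#' @return Numeric total.
#' @export
nucleotide_equivalents <- function(pools, strand_residues = 0) {
  pools$np + sum(pools$nt) + strand_residues
}
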