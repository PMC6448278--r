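# Closed-form event probabilities. These plain R implementations are the
# reference forms of the rules the C++ engine applies internally; tests
# compare the two routes over parameter lattices.

#' Bond-breaking probability at a chain site
#'
#' A phosphodiester bond in a single-chain region breaks with `P_BB`. Within
#' a double-chain region the two parallel bonds must break simultaneously;
#' the synergy of the two events is modelled with exponent 3/2 rather than 2,
#' giving `P_BB^(3/2)`.
#'
#' @param double_chain Logical (vectorized): is the site base-paired?
#' @param params An `rw_params` object.
#' @return Probability vector.
#' @export
bond_break_probability <- function(double_chain, params = default_params()) {
  ifelse(double_chain, params$P_BB^1.5, params$P_BB)
}

#' Strand-separation probability of a duplex
#'
#' A duplex held by `r` base pairs dissociates with `P_SP^((r+1)/2)`; for a
#' single pair this is `P_SP` itself, and the probability falls with every
#' additional pair. The division by 2 in the exponent reflects self-folding
#' of the single chains aiding dissociation.
#'
#' @param r Number of base pairs (vectorized, >= 1).
#' @param params An `rw_params` object.
#' @return Probability vector.
#' @export
separation_probability <- function(r, params = default_params()) {
  if (any(r < 1)) stop("r must be >= 1")
  params$P_SP^((r + 1) / 2)
}

#' Membrane-formation probability in a room
#'
#' With `a` free amphiphiles in a room, a membrane self-assembles with
#' probability `1 - (1 - P_MF)^(a - L_AM + 1)` once `a` reaches the lower
#' limit `L_AM`, and never below it. At `a = L_AM` this equals `P_MF`.
#'
#' @param a Free amphiphile count (vectorized).
#' @param params An `rw_params` object.
#' @return Probability vector.
#' @export
membrane_formation_probability <- function(a, params = default_params()) {
  ifelse(a < params$L_AM, 0, 1 - (1 - params$P_MF)^(a - params$L_AM + 1))
}

#' Osmotic-corrected amphiphile-leave probability
#'
#' A membrane amphiphile leaves with `P_ALM / (1 + F_OP * n / (b/2)^(3/2))`,
#' where `n` is the interior impermeable-ion tally (free nucleotides plus
#' RNA residues) and `b` the membrane amphiphile count; `b/2` scales the
#' membrane surface (two layers) and `(b/2)^(3/2)` the enclosed volume. A
#' swollen cell (high interior concentration) loses amphiphiles more slowly.
#'
#' @param b Membrane amphiphile count (vectorized).
#' @param n Interior impermeable-ion quantity.
#' @param params An `rw_params` object.
#' @return Probability vector.
#' @export
amphiphile_leave_probability <- function(b, n, params = default_params()) {
  params$P_ALM / (1 + params$F_OP * n / (b / 2)^1.5)
}

#' Donnan-corrected inward permeation probability of a nucleotide precursor
#'
#' `P_NPP * (b / L_AM) / (1 + F_DE * n / (b/2)^(3/2))`, clamped to \[0,1\].
#' The `b/L_AM` factor grows with cell size; the denominator suppresses the
#' influx of the like-charged precursor as interior impermeable ions
#' accumulate (Donnan equilibrium). Nucleotides and RNA never cross.
#'
#' @param b Membrane amphiphile count (vectorized).
#' @param n Interior impermeable-ion quantity.
#' @param params An `rw_params` object.
#' @return Probability vector.
#' @export
precursor_permeation_in_probability <- function(b, n,
                                                params = default_params()) {
  p <- params$P_NPP * (b / params$L_AM) / (1 + params$F_DE * n / (b / 2)^1.5)
  pmin(pmax(p, 0), 1)
}

#' Division probability of a protocell
#'
#' `max(0, P_CD * (1 - 2 * L_AM / b))`: a cell cannot divide until its
#' membrane exceeds twice the assembly lower limit, and larger cells divide
#' more readily (physical instability).
#'
#' @param b Membrane amphiphile count (vectorized).
#' @param params An `rw_params` object.
#' @return Probability vector.
#' @export
division_probability <- function(b, params = default_params()) {
  pmax(0, params$P_CD * (1 - 2 * params$L_AM / b))
}

#' Movement probability of a molecule
#'
#' Nucleotide/amphiphile precursors, nucleotides and amphiphiles move with
#' `P_MV`; an RNA of mass `m` (chain length, relative to a nucleotide) moves
#' with `P_MV / sqrt(m)` — the square-root size scaling of polymer diffusion
#' (Zimm model).
#'
#' @param m Relative molecular mass (vectorized, >= 1).
#' @param params An `rw_params` object.
#' @return Probability vector.
#' @export
molecule_move_probability <- function(m, params = default_params()) {
  if (any(m < 1)) stop("m must be >= 1")
  params$P_MV / sqrt(m)
}
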