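---
title: "The protoworld model: chemistry, tag-mediated replication, and protocells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The protoworld model: chemistry, tag-mediated replication, and protocells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protoworld)
```

## The model

`protoworld` simulates an RNA-world scenario on an N x N toroidal lattice of
"rooms". Only molecules sharing a room (or a protocell interior) interact
within one Monte Carlo step. The molecular inventory is deliberately coarse:

* **nucleotide precursors** (`np`) — featureless raw-material tokens;
* **nucleotides** (`nt`) — free monomers with a letter in {A, C, G, U};
* **RNA strands** — 5'→3' letter chains; a strand of length m has relative
  mass m;
* **amphiphile precursors / amphiphiles** (`ap`, `am`) — membrane material;
* **protocells** — membranes of `b` amphiphiles occupying one room each,
  enclosing their own pools and strands.

Every event is a per-entity Bernoulli trial per step, with the probabilities
of the parameter table (`param_table()`). Two conserved ledgers run through
everything: nucleotide-equivalents (precursor = monomer = chain residue = 1)
and amphiphile-equivalents (precursor = free amphiphile = membrane
amphiphile = 1). The engine verifies both, plus every protocell's cached
impermeable-ion tally `n`, at regular intervals and stops hard on any
violation.

### Small-molecule chemistry

Precursors convert to nucleotides with `P_NF` (non-enzymatic) or `P_NFR`
when a free nucleotide synthetase ribozyme (NSR) shares the compartment;
one NSR saturates the compartment — multiple NSRs do not stack, the
simplest reading of enzyme saturation. New letters are uniform. Free
nucleotides decay back with `P_ND`, so an unperturbed pool equilibrates at
`nt/np ≈ P_NF/P_ND` (0.04 at defaults). Amphiphile precursors and
amphiphiles interconvert with `P_AF`/`P_AD`; membrane amphiphiles decay
with the smaller `P_ADM`, the membrane protecting them.

### Collisions and non-enzymatic synthesis

`C_T` times per step, the RNA entities of a compartment — free strands,
template complexes, and mononucleotides — are paired uniformly at random.
A pair undergoes exactly one candidate event, in priority order: REP
binding (if one partner is a catalytically functional replicase and the
other carries a single-stranded 5' tag), substrate attraction (the longer
molecule, if at least 5 nt, attracts the shorter with `P_AT`), or random
end-to-end ligation with `P_RL`. REP binding first reflects that tag
recognition is the defining event of the replication mechanism.

Whether a single strand may act as a non-enzymatic template is decided once
per single-strand episode: at its first attraction opportunity the strand
turns template with `P_RTT` or declines for the rest of the episode. This
once-per-episode reading matters quantitatively: with attraction at
`P_AT = 0.4` and eight collision rounds per step, a per-attempt roll
decorates every strand with substrates within a few steps, leaving no
clean ribozymes to catalyze anything.

Substrates anneal at a maximal-complementarity register chosen uniformly
among ties; each non-complementary position must pass the false-pairing
trial `P_FP`, which is the model's mutation mechanism. Adjacent substrates
ligate with `P_TL`. Aligned partners separate with `P_SP^((r+1)/2)`, `r`
the partner's paired length; bonds break with `P_BB` (single-chain) or
`P_BB^(3/2)` (double-chain, the two parallel bonds breaking
synergistically); only unpaired terminal residues decay (`P_NDE` per end
per step, crediting a precursor).

### The tag-mediated REP cycle

A replicase (REP) is a strand beginning with the 4-nt palindromic tag
(its tag-recognizing domain) followed by the 10-nt catalytic domain; to
spread it also needs a 3' reverse-tag, hence the minimal functional and
spreadable lengths of 14 and 18 nt (10 and 18 for the NSR, whose function
needs no tag). The tag's palindromy makes the complement of a spreadable
ribozyme again tag-flanked, so both strands of the duplex are serviceable
templates — the core of the mechanism.

A free REP binds a recognizable template with `P_RBT` and copies it
3'→5' (the product growing 5'→3'), incorporating only mononucleotides:
attraction `P_AT`, then ligation `P_TLR` per junction, `P_FLR` after a
mismatch, mismatch incorporation with `P_FP`. A substrate annealed ahead
of the polymerase blocks it until separation — there is no strand
displacement — but a partial product still annealed at the template's 3'
end is adopted and extended (primer extension), so interrupted copies are
rescued rather than accumulating as dead debris. When copying reaches the
template's 5' tag the recognition pairing releases; on completing the
chain the REP drops, and it may drop prematurely with `P_RD` per step. A
bound REP still risks chain breaking with `P_BB`.

Tag-flanked strands without any catalytic domain are parasites: they
exploit REP for replication and contribute nothing. We deliberately do
*not* classify strands containing the reverse complement of a catalytic
domain as parasites — those are the obligatory complement intermediates of
the ribozymes themselves, and counting them as parasites would make the
parasite observable shadow the ribozyme count.

### Protocells

Where `a ≥ L_AM` amphiphiles gather in a room (in a region that permits
protocells), a membrane self-assembles with `1-(1-P_MF)^(a-L_AM+1)`,
enclosing the room's contents. The cell occupies the whole room; its
exterior neighbourhood is the four adjacent rooms, and the membrane's four
faces mediate all exchange: exterior amphiphiles join at `P_AJM/4` per
face (interior ones at `P_AJM`), leavers and outward permeants exit into a
uniformly chosen cell-free neighbour. Amphiphiles leave the membrane at
`P_ALM / (1 + F_OP n/(b/2)^{3/2})` — interior impermeable ions (free
nucleotides plus RNA residues, the tally `n`) swell the cell and retard
loss. Nucleotide precursors permeate inward at
`P_NPP (b/L_AM) / (1 + F_DE n/(b/2)^{3/2})` per neighbour-room precursor
per face — the Donnan term suppressing influx of the like-charged
permeant — and outward at flat `P_NPP`; amphiphile precursors cross at
`P_APP` both ways; nucleotides and RNA never cross. Cells divide with
`max(0, P_CD (1 - 2 L_AM/b))`, splitting the membrane evenly and
partitioning each interior molecule independently (binomial); they break
(`P_CB`), fuse (`P_CF`, the merged cell keeping the larger membrane's
room), engulf a neighbouring room's entire free content (`P_CC`,
cytophagy — the route by which empty vesicles acquire ribozymes), and move
(`P_MC`), swapping contents with the target room. Degradation rates inside
a protocell are never subject to the solution region's degradation
multiplier: the interior is not free water.

### Regions, movement, and the step

The grid is uniform ("rocky") or a rocky core inside a solution frame. The
near-reality solution profile moves molecules 10x faster, degrades (P_BB,
P_ND, P_NDE, P_AD) 2x faster outside cells, and synthesizes (P_RL, P_NF)
20x slower. Pools move with `P_MV`; a strand of mass m with `P_MV/√m`
(Zimm scaling); a template complex moves as one unit with the summed mass
of its chains. That last reading matters: the protected duplex awaiting
strand separation is the main long-range dispersal vehicle of the
replicators — naked strands mostly decay before completing a room hop.
The interface policy vetoes boundary crossings by class
(`precursors_only` admits the two precursor classes; `all_molecules`
everything); protocells never enter the rocky region.

A step runs phases in fixed order — chemistry, collisions, polymer events,
protocell events, movement (molecules then protocells) — with room order
reshuffled every step to avoid sweep bias, entity updates seeing the
running state. One 64-bit-seeded RNG stream drives everything; identical
configuration and seed give bit-identical trajectories.

## Parameters

All defaults, magnitude ranges (stored as metadata only — the study
attaches no sampling scheme to them), and one-line meanings are in
`param_table()`. Orderings such as `P_TLR >> P_TL` or `P_ADM < P_AD` are
validated as warnings, not errors, so sweeps may cross them deliberately.
Probabilities pushed above 1 by region multipliers clamp to 1.

## Observables

The count series reports two views of each ribozyme. The *role* counts
(`rep_naked`, `rep_cell`, ...) tally strands whose classification flags
mark them catalytically functional — for REP that requires the intact
5' tag-recognizing domain directly followed by the catalytic domain. The
*species* counts (`rep_species`, `nsr_species`) tally strands carrying the
catalytic domain in sense orientation anywhere in the chain. The species
view is how molecule counts of a ribozyme are naturally tallied in this
class of models — a species is defined by its characteristic sequence —
and it is already the only possible reading for the NSR, whose function
needs nothing but the domain. End-eroded replicases and partial copies
therefore appear in `rep_species` while they persist, exactly as they
remain members of the molecular species while they decay.

## Scenario presets and scales

The `fig*` presets reproduce the study setups at full scale (20x20 or
40x40 grids, 10^6–10^7 steps); they are provided for completeness and are
expensive. The `tiny_*` presets scale material totals and inocula by the
grid-area factor, keeping every probability at its default so per-room
densities and per-event physics are unchanged. Two timescales do not
shrink with area: a full duplex separates on the order of 10^4 steps
(`P_SP^(19/2)`) and a strand hops rooms on the order of 4x10^4 steps.
Replicator spread is therefore colonization-limited, and the spread
presets (`tiny_fig2`, `tiny_fig5`) use a 14x14 grid — half the full-scale
area, the smallest grid whose plateau population sits comfortably above
the inoculum while a run of ~2x10^6 steps still completes in minutes. On
a 10x10 grid the carrying capacity (a few dozen replicases) falls below
three times the smallest inoculum that reliably escapes demographic
extinction (~25 molecules), so no 10x10 spread experiment can demonstrate
a threefold rise; the two-region competition (`tiny_fig11`), which
compares two subsystems rather than measuring absolute growth, does run
at quarter scale. The default membrane size of inoculated protocells is
b = 750, between the assembly limit and the division threshold.

Two further notes on the co-spread preset. First, `tiny_fig5` runs at the
*default* non-enzymatic synthesis rate throughout: that rate is already
the scarce, cooperation-dependent regime of this model (it is why most
raw material stays unused in the spread scenario), so no mid-run rate
change is needed to put the two ribozymes in their cooperative state;
mid-run sweeps remain available through the scenario schedule. Second,
at half scale the synthetase census is only a few dozen molecules, so
its coexistence with the replicase is long — on the order of 10^6 steps,
dozens of replication generations — but eventually ends by demographic
drift; indefinite coexistence, like the full-scale balance, needs the
full grid. The competition/cooperation cycle between the two ribozymes
runs on a ~10^5-step timescale: read against a 2x10^5-step moving mean,
their fluctuations are clearly reverse-synchronous (correlation about
-0.4), while the free-nucleotide level swings with the synthetase, in
phase.

What the tiny runs do and do not show: they exercise every mechanism of
the full model under the study's own rates, and they reproduce the
qualitative dynamics (replicator spread limited by raw-material flux and
colonization, ribozyme cooperation, naked-versus-cellular competition).
They are not statistically calibrated replicas of the full-scale figures:
at 10x10, populations are small enough that demographic noise is visible
and single-seed trajectories fluctuate strongly.

## Numerical and degenerate-input choices

* Letters are encoded 0–3 with complement `3 - x`; all sequence logic is
  exact integer work.
* A length-1 strand *is* a free nucleotide and returns to the pool.
* Strand separation, bond breaking and end decay guard their boundary
  cases (empty complexes dissolve; a strand eroded to nothing credits all
  residues as precursors).
* Division aborts when no adjacent cell-free room exists, or when the
  displaced content of the daughter room would have nowhere to go.
* A membrane that loses its last amphiphile dissolves as a break.
* Ledger checks run every 10^3 steps by default and at every checkpoint.

## Known limitations

* No secondary structure, folding thermodynamics, or strand displacement.
* No recombination operator and no chromosome-like linkage.
* Checkpoints store complexes as their member strands; resuming restarts
  them unhybridized.
* The collision scheme pairs entities uniformly; no excluded-volume or
  diffusion-limited kinetics within a room.

## A worked example

```{r example, eval = FALSE}
res <- run_scenario("tiny_fig2", seed = 1, stop_step = 2e5)
tail(res$series[, c("step", "np", "nt", "rep_naked", "para_naked")])
```

The series shows the nucleotide/precursor balance establishing within
~10^3 steps, the inoculated replicase persisting and beginning to spread
from the central rooms, and the precursor pool barely dented — the
hallmark of the low non-enzymatic synthesis rate that later makes the
nucleotide synthetase ribozyme valuable.
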