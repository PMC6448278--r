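# protoworld

An agent-based Monte Carlo simulator of an RNA-world scenario: naked
ribozyme replicators spreading on a porous-rock lattice, tag-flanked
parasites exploiting them, and membrane-bounded protocells that grow,
divide, fuse, engulf, and compete with the naked phase. It is aimed at
origin-of-life researchers who want a configurable, seeded, testable
implementation of this class of spatial replicator models.

## The model in brief

An N x N toroidal grid of rooms holds nucleotide precursors, free
nucleotides (letters A/C/G/U), RNA strands, amphiphiles and their
precursors, and protocells (one per room, membrane size *b*). Every event
is a per-entity Bernoulli trial per Monte Carlo step. The core pieces:

* **Chemistry** — precursors form nucleotides at *P*<sub>NF</sub>
  (non-enzymatic) or *P*<sub>NFR</sub> when a nucleotide synthetase
  ribozyme (NSR) is present; nucleotides decay at *P*<sub>ND</sub>.
* **Template-directed replication** — an RNA replicase (REP) recognizes a
  palindromic 5′ tag (default `ACGU`), copies the template 3′→5′ from
  mononucleotides (*P*<sub>TLR</sub> per junction), and drops at
  completion. A spreadable REP reads
  5′-tag + catalytic domain + reverse-tag (18 nt); tag-flanked strands
  without a catalytic domain are parasites.
* **Duplex physics** — a partner paired by *r* base pairs separates with
  *P*<sub>SP</sub><sup>(r+1)/2</sup>; double-chain bonds break with
  *P*<sub>BB</sub><sup>3/2</sup>; only unpaired chain ends decay.
* **Protocells** — membranes assemble above *L*<sub>AM</sub> amphiphiles
  with 1−(1−*P*<sub>MF</sub>)<sup>a−L<sub>AM</sub>+1</sup>; amphiphiles
  leave at *P*<sub>ALM</sub>/\[1+*F*<sub>OP</sub>·n/(b/2)<sup>3/2</sup>\]
  (osmotic retardation); precursors permeate inward at
  *P*<sub>NPP</sub>(b/*L*<sub>AM</sub>)/\[1+*F*<sub>DE</sub>·n/(b/2)<sup>3/2</sup>\]
  (Donnan suppression); division runs at
  *P*<sub>CD</sub>(1−2*L*<sub>AM</sub>/b).
* **Space** — molecules move at *P*<sub>MV</sub>/√m; a rocky core can sit
  inside a faster, more degradative, less synthetic solution region;
  protocells are confined to the solution.

All rates live in one validated parameter table (`param_table()`); the
conservation of nucleotide- and amphiphile-equivalents is enforced at run
time. The step loop is compiled (Rcpp); a 10×10 system runs at roughly
10<sup>4</sup> steps per second.

## A worked example

```r
library(protoworld)
res <- run_scenario("tiny_fig2", seed = 1, stop_step = 2e5)
tail(res$series[, c("step", "np", "nt", "rep_naked", "rep_species", "para_naked")], 3)
#>       step    np   nt rep_naked rep_species para_naked
#> 99  196000 36501 1391        28          60          0
#> 100 198000 36475 1435        32          65          0
#> 101 200000 36500 1484        27          58          0
```

At step 2×10<sup>5</sup> of the half-scale replicator-spread preset the
precursor/nucleotide pool sits near its *P*<sub>NF</sub>/*P*<sub>ND</sub>
balance (~0.04), the 25 inoculated replicases have persisted and begun to
spread (27 catalytically functional REP strands; 58 molecules of the REP
species counting eroded and partial copies), and over 90% of the raw
material is still unused — the hallmark of the slow non-enzymatic
nucleotide supply. The full preset horizon (2.6×10<sup>6</sup> steps)
carries the spread to a plateau of roughly a hundred REP-species
molecules.

Scenario presets (`scenario_names()`) cover replicase spread, REP+NSR
co-spread, the two-region near-reality system, protocell emergence by
cytophagy, fair naked-versus-protocell competition, and periodic parasite
inoculation, plus `tiny_*` variants scaled for test budgets.

A command-line entry point is installed at `inst/cli/protoworld`:

```sh
Rscript inst/cli/protoworld --print-defaults
Rscript inst/cli/protoworld --scenario tiny_fig2 --seed 1 \
    --steps 20000 --out runs/demo
```

which writes `series.csv`, `snapshot.csv` and a `manifest.cfg` with the
fully resolved configuration and seed.

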