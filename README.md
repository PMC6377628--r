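# k2pgate

Tools for systematically engineering gain-of-function mutants of two-pore
domain potassium (K2P) channels, and for quantifying what those mutations
do to channel gating.

K2P channels set the resting membrane potential of excitable and
non-excitable cells. Each subunit carries two pore-forming domains (pore
helix + selectivity filter, `SF1`/`SF2`) and four transmembrane helices
(`TM1`–`TM4`). A conserved glycine hinge near the middle of TM2 — usually
a Gly-Ile-Pro ("GIP") tripeptide, with degenerate variants in divergent
channels — anchors a residue numbering in which **TM2.1** is the hinge and
**TM2.6** lies five residues downstream, facing the cytoplasmic vestibule
next to the inner end of the selectivity filter. Replacing TM2.6 with
polar or charged residues raises single-channel open probability, and the
effect is graded:

    strong  N, D   >   intermediate  S, T   >   weak  G, V

Because whole-cell current obeys I = N · γ · Po · (V − V_rev), a
Po increase maps directly onto macroscopic current. And because reaching
Asn from the hydrophobic codons at most wild-type TM2.6 positions
(Val/Phe/Leu) requires at least two base changes, such alleles are
essentially out of reach of single-base chemical mutagenesis — but
straightforward for genome editing, once you know exactly which residue
and which bases to change. This package computes exactly that.

For whom: ion-channel labs designing allelic series in heterologous
systems or by CRISPR knock-in, and anyone analyzing K2P sequence
conservation or single-channel records.

## What it does

* **Architecture annotation** — `annotateArchitecture()` finds SF1/SF2 by
  the `T-x-G-[YFL]-G` signature and TM1–TM4 by windowed Kyte–Doolittle
  hydropathy, returning a validated `K2PArchitecture` (S4, IRanges-backed).
* **TM2 numbering** — `mapTM2()` matches the hinge motif with a tiered
  grammar (GIP > GVP > THIK-type `GC[SAT]` > enumerated degenerates >
  opt-in generalized class) and assigns TM2.1–TM2.6; `classifyTM26()`
  reports how common the wild-type TM2.6 residue is across the family.
* **Conservation** — `columnProfiles()` / `informationProfile()` compute
  per-column entropy, sequence-logo information content and letter
  heights; `hingeCensus()` tallies hinge classes and TM2.6 identities.
* **Mutation design** — `designSeries()`, `substitutionPlan()`,
  `minCodonEdits()` and `planCdsEdit()` produce the graded substitution
  series with mutation labels (e.g. `L122N`) and minimal-base-change codon
  edits at absolute CDS coordinates.
* **Gating simulation** — `gatingModel()` + `simulateTrace()` run exact
  Markov jump simulations (two-state or bursting), `idealizeTrace()`
  applies half-amplitude idealization with a dead time, `channelStats()`
  yields NPo and dwell times, `unitaryIV()` and `fitActivationTau()`
  handle single-channel i–V and activation kinetics, and
  `wholeCellCurrent()` / `foldChange()` close the loop from Po to current.
* **Synthetic fixtures** — `k2pFixture()`, `makeCds()`, `makeMsa()`
  generate ground-truthed channels, coding sequences and alignments so the
  whole pipeline is testable without any downloads;
  `validateKnownChannels()` checks annotations of user-supplied reference
  sequences against published TM2.6 labels (`knownTM26Labels()`).

A thin command-line wrapper (`inst/scripts/k2p`, subcommands `annotate`,
`tm26`, `design`, `logo`, `summarize`, `simulate`, `idealize`, `synth`)
exposes the same functions for shell pipelines via `runCLI()`.

## Worked example

Annotate a channel, number TM2, and design the allelic series with codon
edits:

```r
library(k2pgate)

fx   <- k2pFixture(42)                      # ground-truthed synthetic K2P
arch <- annotateArchitecture(fx$sequence)
m    <- mapTM2(fx$sequence, arch)
m
#> TM2Map for synthK2P_42 (hinge GIP, canonical_GIP)
#>   label position residue
#> 1 TM2.1      110       G
#> 2 TM2.2      111       I
#> 3 TM2.3      112       P
#> 4 TM2.4      113       V
#> 5 TM2.5      114       L
#> 6 TM2.6      115       L

substitutionPlan(fx$sequence, m, cds = makeCds(fx$sequence))
#>    channel_id wt_label target         tier mutation_label wt_codon new_codon n_changes cds_positions
#> 1 synthK2P_42     L115      N       strong          L115N      CTA       AAC         3   343,344,345
#> 2 synthK2P_42     L115      D       strong          L115D      CTA       GAC         3   343,344,345
#> 3 synthK2P_42     L115      S intermediate          L115S      CTA       TCA         2       343,344
#> 4 synthK2P_42     L115      T intermediate          L115T      CTA       ACA         2       343,344
#> 5 synthK2P_42     L115      G         weak          L115G      CTA       GGA         2       343,344
#> 6 synthK2P_42     L115      V         weak          L115V      CTA       GTA         1           343
```

The TM2.6 leucine sits at position 115; the strong asparagine/aspartate
edits each need three base changes from this leucine codon (`CTA`), the
serine/threonine tier two, and the valine control one — the codon-distance
asymmetry that makes these alleles invisible to single-base mutagenesis.

Simulate what a TM2.6 mutation does to single-channel activity — a
wild-type-like channel (mean open time 0.41 ms, Po ≈ 0.04) against a
mutant with doubled open dwell and ten-fold NPo:

```r
wt  <- gatingModel(kCO = 1/9,   kOC = 1/0.41)   # rates per ms
mut <- gatingModel(kCO = 1/0.9, kOC = 1/0.81)
poWt  <- channelStats(idealizeTrace(
           simulateTrace(wt,  voltage = -80, duration = 30, seed = 1),
           deadTime = 0))$NPo
poMut <- channelStats(idealizeTrace(
           simulateTrace(mut, voltage = -80, duration = 30, seed = 2),
           deadTime = 0))$NPo
cat(sprintf("wild-type Po = %.3f, mutant Po = %.3f, fold change = %.1f\n",
            poWt, poMut, foldChange(poMut, poWt)))
#> wild-type Po = 0.042, mutant Po = 0.473, fold change = 11.3
```

At fixed channel count, conductance and driving force,
`wholeCellCurrent()` scales linearly in Po, so this is also the predicted
whole-cell fold change.

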