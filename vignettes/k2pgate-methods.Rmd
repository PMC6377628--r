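---
title: "Methods: K2P channel annotation, gain-of-function design, and gating simulation"
author: "k2pgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: K2P channel annotation, gain-of-function design, and gating simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(k2pgate)
```

## Scope and model of the channel

Two-pore domain potassium (K2P) channel subunits contain two pore-forming
domains in tandem — each a pore helix (Ph1, Ph2) followed by a
selectivity filter (SF1, SF2) — threaded through four transmembrane
helices (TM1–TM4), in the order

    TM1 < Ph1 < SF1 < TM2 < TM3 < Ph2 < SF2 < TM4

along the sequence. Near the middle of TM2 sits a conserved glycine hinge,
usually followed by isoleucine and proline (the "GIP" motif). Numbering
the hinge glycine TM2.1 and counting forward, the residue TM2.6 — five
positions downstream — faces the cytoplasmic vestibule near the inner end
of the selectivity filter. Substituting TM2.6 with polar or charged
residues raises single-channel open probability and hence whole-cell
current; the effect is graded, strongest for asparagine and aspartate,
intermediate for serine and threonine, weakest for glycine and valine.
`k2pgate` turns that design strategy into software: locate the
architecture, number TM2, rank substitutions, plan the codon edits, and
quantify (by simulation) how an open-probability change propagates to
whole-cell current.

## Architecture annotation

Selectivity filters are found with the potassium-channel signature
`T-x-G-[YFL]-G` (five residues; `x` arbitrary). Hits must be at least 40
residues apart; when more than two raw hits exist, the pair whose
start-to-start spacing is closest to an expected 190 residues (the typical
separation of the two filters in a K2P subunit; configurable) is kept, and
a tied spacing score is an error that lists the candidates rather than
guessing. A second filter matching only the laxer `T-x-G-[YFL]-G` form is
accepted because degenerate SF2 sequences occur in divergent nematode
channels.

Transmembrane helices come from a Kyte–Doolittle hydropathy profile:

* window 15 residues (odd, 5–31 allowed), the length of a membrane-spanning
  helix core; `X` contributes 0;
* a candidate helix is a maximal run of window centers with mean
  hydropathy ≥ 1.0 (permissive, because the TM2 of K2Ps is short and
  carries the polar hinge), extended outward by the half-window;
* the extended edges are then trimmed inward while the terminal residue's
  own Kyte–Doolittle value is negative. Half-window extension alone
  overshoots into flanking loops by up to seven residues whenever the
  neighboring loop is hydrophilic; trimming at the per-residue sign
  recovers sharp boundaries without disturbing helices whose interiors dip
  (the hinge proline, a charged TM2.6). Accepted helices are 15–35
  residues long.

Helices are then assigned by position relative to the filters: TM2 is the
first helix starting within 15 residues after SF1, TM4 the first within 15
residues after SF2, TM1 the last helix ending at least 10 residues before
Ph1 (the 8 residues preceding SF1), and TM3 any helix between TM2 and Ph2.
Every element is reported 1-based and inclusive, and the canonical
ordering is enforced by the `K2PArchitecture` validity method. Annotation
is deterministic, and unannotatable inputs fail with an error naming the
missing element rather than returning a partial result.

`findSelectivityFilters()` errors when a filter pair cannot be resolved
(the "not a recognizable K2P" rule); `requirePair = FALSE` returns the raw
hit list for exploratory scans of non-K2P sequences.

## TM2 numbering and the hinge grammar

The hinge tripeptide is matched inside the annotated TM2 with a tiered
grammar, higher tiers winning outright:

1. `GIP` — canonical;
2. `GVP` — valine variant (TWIK2, TASK2, and several nematode channels);
3. `G-C-[SAT]` — the THIK-type motif;
4. the enumerated degenerate motifs `GMP, MIP, FVP, GIA, GLP, GAP`;
5. (opt-in) a generalized class `[GMF]-[IVCLMA]-[PSAT]`. This is an
   extrapolation beyond the documented motifs, so it must be requested
   explicitly (`allowGeneralized = TRUE`).

Among equal-tier matches the one whose center is closest to the TM2
midpoint wins — hinge glycines sit near the helix center — and remaining
ties go upstream. TM2.1 is the first motif residue even when it is not a
glycine (the `MIP`/`FVP` channels), because the numbering anchors on the
hinge position; the hinge class in the output flags such channels.
TM2.4–TM2.6 are read from the full sequence and may extend up to three
residues past the annotated helix end, since hydropathy-derived edges are
soft. `classifyTM26()` encodes the family census: leucine and isoleucine
common; glycine, phenylalanine, valine, methionine, alanine rare (each
with its exemplar channels); everything else unclassified.

## Conservation

`columnProfiles()` computes, per alignment column, residue frequencies,
Shannon entropy $H=-\sum_a p_a\log_2 p_a$, and the sequence-logo
information content $R=\log_2 S-H$ with letter heights $p_aR$. By default
gaps are excluded from the frequencies and $S=20$; a `count_as_21st`
policy treats the gap as an extra symbol ($S=21$). The small-sample
correction $(S-1)/(2n\ln 2)$ is available but off by default so that the
closed forms ($R=\log_2 20$ for a fixed column, $0$ for a uniform one,
$\log_2 20-1$ for a half/half column) hold exactly and the defaults stay
analytically testable. All-gap columns are flagged and given zero
information. No phylogenetic weighting is applied: conservation is a
property of whatever alignment the user supplies.

## Mutation design and codon edits

`designSeries()` emits the graded substitution tiers — strong {N, D},
intermediate {S, T}, weak {G, V}, plus opt-in hydrophobic controls
{L, V} — with the wild-type residue removed from its tier. Tiers rather
than a strict total order are exposed deliberately: the whole-cell and
in-vivo allelic series agree that N/D are strongest and that S/T sit above
G/V, but individual channels disagree on the finer ordering, so a total
order would overstate what the data support.

`minCodonEdits()` brute-forces every codon of the target amino acid and
returns all codons at the minimum Hamming distance, sorted
lexicographically; `planCdsEdit()` picks the lexicographic leader and
emits absolute 1-based CDS coordinates. Codon-usage-aware tie-breaking is
deliberately out of scope of the default (the lexicographic choice is
deterministic and auditable); the full minimal set is always available
for a downstream chooser. One consequence the package makes checkable: no
valine, phenylalanine or leucine codon reaches asparagine in fewer than
two base changes, while glycine-to-aspartate is available as a single
transition — which is why strong gain-of-function alleles at hydrophobic
TM2.6 positions are effectively invisible to single-base chemical
mutagenesis but easy for genome editing.

## Gating simulation and idealization

`gatingModel()` supports a two-state scheme C⇌O (rates `kCO`, `kOC` per
millisecond; stationary $P_o=k_{CO}/(k_{CO}+k_{OC})$) and a three-state
burst scheme C1⇌C2⇌O that produces openings interrupted by brief
closures. Simulation is exact stochastic jump simulation on the
aggregated open-count chain (propensity = occupancy × rate), started from
the stationary law so time averages need no burn-in; a single two-state
channel takes a vectorized alternating-dwell fast path. Sampling at
`sampleRate` (default 20 kHz) happens after the continuous-time path is
drawn, avoiding per-sample Bernoulli time-step bias, and the exact jump
path is retained in the trace object. The single-open-channel current is
$i = \gamma (V - V_\mathrm{rev})/1000$ pA with $\gamma$ in pS and
potentials in mV. Gaussian noise is added per sample; optional low-pass
smoothing uses a Gaussian kernel matched to the −3 dB point of an 8-pole
Bessel filter at `filterCutoff` (default 2 kHz) — a standard
approximation; exact Bessel filtering is out of scope.

Idealization follows the half-amplitude convention: each sample is
assigned the nearest non-negative integer multiple of the unitary
amplitude, but a level transition is accepted only when the current moves
more than `thresholdFraction` (default 0.5) of one amplitude away from
the held level — hysteresis that also handles multi-channel records.
Events shorter than the dead time (default 100 µs) are absorbed into the
longer neighboring event, shortest first, ties toward the preceding
event. The 100 µs default is the explicitly stated dead time of the
recording convention the simulator emulates, even though the companion
formula 0.3/cutoff gives 150 µs at 2 kHz and the associated detection
limit is quoted as 50 µs; the three values are mutually inconsistent, so
the named one is the default and the others are reachable through the
`deadTime` argument.

`channelStats()` computes NPo $=\sum_k \ell_k d_k / T$ (time-averaged
open-channel count), mean open/closed times under single-channel
semantics (level ≥ 1 is open), and per-channel $P_o$ when N is known.
Two estimators of dwell statistics coexist deliberately:

* `idealizeTrace()` on the sampled record — the measurement pipeline. Its
  NPo is unbiased (point sampling), but dwell *means* inherit a positive
  bias of order dt and of order the probability that a closed gap falls
  between samples, exactly as real recordings suffer missed-event bias.
* `trueEvents()` on the retained continuous path — sampling-free ground
  truth, used when assessing parameter recovery of the simulator itself.

The dead-time direction test (mean open time with 100 µs dead time ≥ the
dead-time-0 estimate on the same bursty trace) checks the measurement
pipeline's bias has the physiologically expected sign. Rate-constant
estimation from dwell histograms (missed-event-corrected estimators) is a
non-goal.

`fitActivationTau()` fits $I(t)=I_\infty+(I_0-I_\infty)e^{-(t-t_0)/\tau}$
by Levenberg–Marquardt least squares with an analytic Jacobian
(`minpack.lm::nls.lm`; the `nls`-based interfaces reject zero-residual
data), starting from the data range and the 63% rise time. Constant
traces and non-positive fitted τ are errors. `wholeCellCurrent()`
implements $I=N\gamma P_o(V-V_\mathrm{rev})$, the macroscopic model under
which a fold change in $P_o$ maps one-to-one onto whole-cell current at
fixed N, γ and driving force.

## The synthetic-fixture generator

`k2pFixture()` assembles K2P-like proteins with every true coordinate
recorded: hydrophilic N-terminus, TM1, Ph1, SF1 (`TIGYG` by default), a
linker, TM2 carrying a chosen hinge motif with a chosen TM2.6 residue,
intracellular loop, TM3, Ph2, SF2 (`TVGFG`), TM4, C-terminus. Design
choices that make exact-recovery testing meaningful rather than
accidental:

* helix bodies are sampled from {I, L, V, F} (Kyte–Doolittle ≥ 2.8) and
  all loops, pore helices and termini from strictly hydrophilic residues,
  so segment boundaries are sharp and window means stay comfortably above
  the detection threshold even around the polar hinge — fixtures are not
  supposed to sit at detector boundaries except in dedicated edge-case
  tests;
* the filter-to-helix linkers are 11–14 residues, keeping the detector's
  half-window overshoot away from the aromatic/aliphatic letters inside
  the filter texts while respecting the 15-residue SF-to-TM rule;
* SF1–SF2 spacing lands in ≈150–220 residues, exercising the
  spacing-based pair disambiguation;
* TM2.4/TM2.5 avoid phenylalanine so that no spurious hinge match (e.g.
  `FVP`) can start at TM2.4 whatever TM2.6 residue is requested.

These sequences emulate the *architecture* of K2P channels, not their
evolution: no realistic amino-acid composition in loops, no indels, no
codon-usage structure in `makeCds()`. A pipeline that recovers 100% of
fixture coordinates has therefore demonstrated correct bookkeeping and
detector logic under clean conditions, not performance on divergent real
sequences — which is why the validation harness for real, user-supplied
reference isoforms (`validateKnownChannels()`) exists separately and
reports numbering discrepancies instead of absorbing them. The package
bundles no reference sequences; stand-ins used in tests are generated and
labelled synthetic.

## Problem sizes and numerical choices

Quantitative checks run at: 200 fixtures across all grammar tiers for the
round-trip; 120-second, 20 kHz noiseless records across
$P_o\in\{0.05,0.2,0.5,0.8,0.95\}$ with the faster dwell pinned at 0.5 ms
(so the rarer event class still accumulates thousands of events, keeping
Monte-Carlo error in dwell means near 1%); 100 replicates at 1% noise for
the τ-fit; and the full 61 × 20 codon table against exhaustive
enumeration. NPo recovery is measured through the sampled-trace
idealization; mean open time through the exact event path, for the bias
reasons above. Dwell durations of sampled idealizations are integer
multiples of dt; event merging uses a 10⁻¹² s tolerance when comparing
against the dead time.

## Known limitations

* Hydropathy-based helix detection is a reconstruction of standard
  practice, not a general-purpose topology predictor; heavily charged or
  broken helices in real channels may need per-channel thresholds.
* The exact composition of published multi-channel alignments is not
  reproduced; census counts apply to whatever channel set the user
  annotates.
* Burst-model aggregation simulates event counts faithfully but mean
  open-time semantics are defined for N = 1; multi-channel dwell
  attribution is reported at the aggregate level only.
* CRISPR reagent design (guides, PAMs, homology arms) is out of scope;
  codon planning stops at substitution coordinates.
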