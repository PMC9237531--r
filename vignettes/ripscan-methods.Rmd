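---
title: "Predicting regulated intramembrane proteolysis of membrane-bound transcription factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting regulated intramembrane proteolysis of membrane-bound transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripscan)
```

## The biological model

Membrane-bound transcription factors (MB-TFs) carry a transcription factor
family domain (TFFD) and at least one transmembrane domain (TMD). The TMD
locks the protein in a membrane; activation requires removing it, either by
regulated intramembrane proteolysis (RIP) — cleavage in or next to the TMD by
an intramembrane protease — or by an alternative transcript that omits the
TMD-coding sequence. For the released fragment to act in the nucleus, the
TFFD should reside on the cytosolic face of the membrane, so membrane
topology is as much part of the prediction as the sequence features.

`ripscan` operationalizes this as four evidence streams per protein, each
computed by a dedicated module and combined in a tiered report:

1. protease recognition motifs (exact S1P site `RRIL`, its degenerate
   consensus `Rx[LIT][KL]`, rhomboid sites derived from the Drosophila
   Spitz substrate, and a minimal pan-rhomboid consensus) in TMD-anchored
   search windows;
2. structural features that destabilize the transmembrane helix:
   helix-breaking motifs (`NP`, `NxxP`, `PxxP`, `GxxN`, `PxxN`, `PN`, `GA`)
   inside the TMD, and lysine/arginine in the TMD or its flanks;
3. membrane topology: the TMD position class (N-terminal, C-terminal or
   overlapping the TFFD) combined with the type-I/II call gives the
   membrane side of the TFFD;
4. independent proteolysis evidence: PTMs and experimentally observed
   proteolytic N-termini located between the TFFD and the TMD.

## Coordinates, windows and the TMD policy

All spans are 1-based and inclusive at both ends, matching the `389-440`
style of published domain tables. Search windows are resolved relative to a
TMD span and clipped to `[1, length]`:

* `tmd` — the TMD span itself;
* `tmd_plus_flank(k)` — `[start - k, end + k]`, the "TMD plus flanking
  sequence" window used for protease-motif scans (both sides: the relative
  orientation of protease and substrate is generally unknown);
* `flank_tffd_side(k)` — the `k` residues abutting the TMD on the side
  facing the TFFD, excluding the TMD. This is the window family
  (k = 5, 10, 15, 20) used for charge enrichment, because positive residues
  that matter for S2P/rhomboid substrates sit between the TFFD and the
  membrane.

The clipped window length — not the nominal `k` — feeds every enrichment
denominator, so windows truncated at a protein terminus are tested at their
true size. For proteins whose TMD overlaps the TFFD no TFFD-side flank
exists; the window is defined-degenerate (empty) and the test is skipped
while still counting toward the correction family.

Some proteins carry several alternative TMD predictions. They are kept as
an ordered list and all TMD-anchored operations take a selection policy,
default `"first"` (the first-listed prediction), with `"all"` available for
presence/absence motif calls across every alternative.

One inventory protein (SCP) illustrates a boundary case: its printed TFFD
(36–136) and TMD (14–37) overlap by two residues, so the strict geometric
rule classifies it as overlap-class even though the published table classes
it as N. We keep the strict rule for topology — set algebra should not
bend — but treat the table's transcribed helix-motif and K/R columns as
evidence in their own right, so annotation-driven censuses reproduce the
published counts.

## Motif semantics

Motif notation supports literals, `x` (any residue), `[SET]` and `[^SET]`
(complement). Compilation mirrors the notation token by token; scanning
reports every match whose span lies wholly inside the window, including
overlapping matches — presence/absence collapsing happens only at the
protein level, so positional output remains available for figures and
audits. Reverse orientation reverses token order and scans forward:
proteins have no strand complement, and the purpose is direction-agnostic
detection of helix-destabilizing motifs. Protease motifs are scanned
forward only by default, since directional recognition is part of their
definition. The unknown residue `X` is matched by `x` only; literal, set
and complement tokens never match it (conservative calling). The two
redundant rhomboid cleavage positions of the Spitz-derived site are carried
as pattern metadata (`cleavage_offsets`), not used in matching.

Under i.i.d. uniform residues the per-position match probability is the
product over tokens of class size / 20; the test suite verifies the
scanner against this analytic value and against an independent
positional-membership oracle.

## Enrichment statistics

All overrepresentation tests are upper-tail hypergeometric:
`P(X >= k)` drawing `n` from `N` with `K` feature-positive, via
`stats::phyper`. At protein level, `k/n` are feature-positive counts in the
cohort and `K/N` in a background set (whole proteome, or membrane proteome
with TMD spans when the feature needs a TMD-anchored window — requesting
such a window against a TMD-less background is a configuration error). When
the cohort is not a subset of the background urn the sample is pooled into
the urn so the draw is well defined; reported `k, n, K, N` always echo the
raw inputs. At residue level, `k` is the K+R count of a window, `n` the
clipped window length, and `K/N` the composition of the matched background
scope (whole-proteome residues, or TMD-flank residues of membrane
proteins).

Published tables state Bonferroni correction but not the family. We adopt
the most conservative reading: for each feature, family = (proteins
tested) × (window sizes), with skipped empty-window tests still counted.
When only a background proportion is known (printed rates such as 50% or
45%), the finite-urn counts are unavailable: fold enrichment uses the
proportion directly and the test falls back to an upper-tail binomial,
flagged `mode = "proportion"` in the result. Fold values are stored
unrounded and displayed to two decimals. No FDR procedures are offered:
the method family is Bonferroni-only by design.

## The tier decision table

No combined score is published; the integration rule is therefore the
package's own, versioned and documented here:

* `RIP-candidate` — cytosolic TFFD **and** (a protease-site flag, or a
  helix breaker in the TMD together with K/R in or enriched next to the
  TMD);
* `RIP-possible` — any single RIP-consistent flag (also the ceiling when
  topology is unknown);
* `splicing-candidate` — a TMD-lacking alternative transcript with no
  RIP-consistent evidence at all;
* `uninformative` — otherwise.

Proteolysis evidence takes precedence over the splicing fallback; with the
opposite precedence, removing a RIP-consistent flag could *promote* a
protein from splicing-candidate to RIP-possible, breaking monotonicity
(adding evidence must never demote). The property suite checks the rule
over the whole flag lattice. The pan-rhomboid consensus is reported but
never drives a tier — it matches the vast majority of membrane proteins and
has no discriminative value. NLS presence is likewise reported but not used
as a veto: NLS predictors miss a substantial fraction of true nuclear
proteins.

## TMD similarity trees

TMD peptides (18–25 residues) are aligned with MAFFT (global pairwise guide
alignments, BLOSUM matrix, affine gaps), deterministic for a fixed input
order. Distances between aligned rows are normalized substitution-matrix
dissimilarities, `d = max(0, 1 - S_ab / min(S_aa, S_bb))` under BLOSUM62
with gap columns scored as the worst substitution; identical rows get
distance 0. Trees are neighbor-joining (`ape::nj`) — standard, fast and
deterministic; no likelihood inference is attempted, since short
single-helix peptides carry too little signal to support model selection.
Bootstrap resamples alignment columns with replacement; all replicate draws
derive from one integer seed, so reruns are bit-identical. The summary is a
majority-rule (>50%) consensus with bipartition supports in percent.
Cluster extraction reports maximal clades whose subtending support exceeds
a threshold; the root's trivial "clade" is ignored, and because the
consensus is effectively unrooted a family may surface as either side of
its splitting edge. An alignment with no resolving signal (all pairwise
distances zero) yields an explicit star tree rather than an arbitrary
topology.

## Network-based function prediction

Per TF, GO biological-process enrichment of its target set uses the same
hypergeometric machinery over a gene universe, testing only terms
annotating at least 3 universe genes (noise guard, configurable) and
correcting per TF over the terms actually tested. Direct annotations only —
no GO-graph propagation. TFs with at least one enriched term form a binary
TF × term matrix, clustered by Jaccard distance (`stats::dist(method =
"binary")` on sparse binary profiles) with average linkage.

## The synthetic-data generator

The generator exists so that every stage has planted ground truth without
any external download. Defaults are fixed once and define the test
conditions: a 57-protein cohort (the analysis-set size of the motivating
inventory), lengths 300–700, i.i.d. **uniform** residues — chosen so that
analytic per-position match probabilities are exact — TMDs of 18–25
residues drawn from a hydrophobic alphabet with bias 0.9, a 40/50/10
C-class/N-class/overlap placement mix, 60% type-II topology, and
backgrounds of 2,000 (proteome) and 1,000 (membrane) proteins. Motifs are
planted by realizing the degenerate pattern and overwriting residues at a
uniformly chosen legal offset inside the target window; collisions with
previously planted features resample the offset up to a bounded retry
count, then raise a spec error, as does any plan whose motif cannot fit its
window. Charge planting scrubs K/R from the TMD neighborhood and writes a
controlled count into one flank window, so the planted window carries the
signal. Every planted instance is recorded with its span and realized
peptide and is verifiable against the emitted sequence.

What the generator does **not** emulate: real amino-acid composition
(an alternative residue-frequency profile can be supplied, but uniform is
the default for analytic tractability), hydropathy structure beyond the
biased alphabet, evolutionary correlation between cohort members, and the
length/domain architecture diversity of a real proteome. Passing tests on
synthetic cohorts therefore demonstrate correctness of the machinery —
sensitivity, calibration, reproducibility — not biological performance on
real sequences.

## Numerical and testing choices

* Hypergeometric tails are validated against exhaustive enumeration of all
  draws for every urn with N ≤ 12, and against the binomial limit at large
  N.
* The motif scanner is validated against an independent substring oracle on
  1,000 random 200-mers for every catalog pattern in both orientations, and
  its background hit rate against the analytic product within a 99%
  binomial interval.
* Null calibration of the residue-level charge enrichment uses 1,000
  unplanted proteins; the family-wise adjusted rejection rate must stay at
  or below 0.05.
* Tree recovery uses two planted 10-member TMD families at 1,000 bootstrap
  replicates (support ≥ 95 and Rand index ≥ 0.95 against the planted
  partition); network recovery uses 4-block planted networks (wiring rate
  0.9, 40 replicates).
* These problem sizes are the package's standing test conditions; the
  whole suite runs in well under two minutes on one CPU.

## Known limitations

* The tier rule is a transparent conjunction table, not a calibrated
  probability; tiers order evidence, they do not estimate cleavage
  likelihood.
* Printed hypergeometric P-values from the motivating study that depend on
  its unpublished supplementary background counts are not reproducible at
  desk scale and are deliberately not targeted; the package reproduces the
  statistics that are fully determined by printed inputs (fold 1.33, the
  28-protein cytosolic census, the 11-protein helix census).
* TMD spans and topology calls are inputs, not predictions — the package
  does not re-run membrane-topology predictors, and its conclusions inherit
  their errors.
* Rhomboid/S2P substrate recognition is structural as much as sequential;
  sequence motifs alone (especially the pan-rhomboid consensus) have
  limited specificity, which is exactly why the evidence tiers demand
  conjunction with topology and structural features.
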