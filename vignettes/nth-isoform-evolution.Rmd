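---
title: "NTH isoform architecture and apicomplexan gene loss: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NTH isoform architecture and apicomplexan gene loss: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nthscan)
```

`nthscan` turns two observations about proton-translocating NAD(P)
transhydrogenase (NTH) into testable machinery: (i) the two single-chain
eukaryotic isoforms differ only in the order of the NAD(H)-binding domain
(I) and the NADP(H)-binding domain (III) around the transmembrane region,
and (ii) the phylogenetic distribution of those isoforms — three
characters: αβ, and the two ancestral βα paralogue groups I and II —
constrains the order in which the apicomplexan lineages diverged, via
minimal gene-loss counts under Dollo parsimony. This vignette documents
the models, the tunable parameters, the synthetic data, and the design
choices that were genuinely open.

## The architecture model

A protein's architecture is an ordered, non-overlapping list of elements:
at most one domain I, at most one domain III, and TM stretches (runs of
helices separated by soluble gaps). Three rules produce an isoform call:

* **Configuration** is decided by domain order alone: domain I before
  domain III is `ALPHA_BETA`, the reverse is `BETA_ALPHA`. TM counts are
  treated as characteristic, not defining, so deviations are flagged but
  never change the label.
* **Parity**: the enzyme requires domains I and III on the same membrane
  side, so the helix count strictly between them must be even; an odd
  count gives `INVALID` with a `PARITY_VIOLATION` flag. Sidedness is
  handled purely relationally — the package predicts no absolute
  inside/outside orientation.
* **Templates**: one stretch of 14 helices (αβ) or stretches of 9 and 4
  (βα). Observed stretch structure departing by more than
  `tolerance = 2` helices per stretch raises `TM_COUNT_DEVIATION`;
  a different stretch count raises `STRETCH_COUNT_DEVIATION`. The
  tolerance reflects natural variation around the typical counts. A
  missing domain demotes the call to `AMBIGUOUS` — with only one domain
  there is no order, and no parity check is possible.

We assume the 9-helix stretch is N-terminal in βα proteins (the β
portion, which carries the larger bacterial β-subunit helix bundle, sits
amino-terminally); the generator and templates encode that order. Domain
II's split across the ancestral α/β subunits is not modelled as separate
sub-elements — stretches are plain helix runs.

## TM scanning

`predict_tm_helices()` is a deliberately transparent hydropathy scanner,
standing in at desk scale for neural-network topology predictors (whose
re-implementation is out of scope; their output can be supplied instead
through `parse_external_annotations()`, which accepts 1-based inclusive
coordinates and converts to the package's 0-based half-open convention).
Steps, all deterministic:

1. per-residue mean Kyte–Doolittle hydropathy over a centred window
   (`window = 19`, truncated at the termini; `X` scores 0, gaps are
   rejected);
2. maximal runs at or above `threshold = 1.6` seed candidate helices;
3. runs separated by fewer than `min_loop_len = 4` residues are merged;
4. runs longer than `max_helix_len = 30` are split recursively at their
   least hydrophobic interior residue (leftmost minimum on ties), with
   both pieces kept at `min_helix_len` or more — hence the requirement
   `max_helix_len >= 2 * min_helix_len`;
5. shorter runs are grown symmetrically to `min_helix_len = 15`, never
   across a neighbouring helix or a sequence end.

Step 5 matters: window smoothing erodes a planted 21-residue helix to a
supra-threshold core of roughly 9–17 residues depending on the flanking
loop composition, and extension makes the helix count robust to that
erosion. The cost is that an isolated noise blip can be inflated into a
helix; at the mutation rates where that happens the deviation flags fire
first.

`group_stretches()` starts a new stretch when the inter-helix gap
exceeds `max_gap = 80` residues or when a soluble domain hit lies wholly
inside the gap. Both mechanisms are exercised: in βα proteins the two
domains sit between the stretches (and the gap is long), while the
generator's inter-stretch spacer of 120 residues forces a split by
`max_gap` even with no domain in the gap.

## Domain scanning

Domains I and III are located with per-position score matrices built from
two in-package Rossmann-fold-style consensus strings (48 residues each,
both carrying the classical G-x-G-x-x-G dinucleotide-binding
fingerprint); the consensus residue scores 2, everything else 0, and a
placement is reported when it reaches 60% of the maximum score, with
greedy best-score-first, ties to the smaller start, non-overlapping
selection. The consensus strings were authored with hydrophobic residues
kept isolated so that a planted domain never crosses the TM threshold.
The 60% threshold sits more than three standard deviations above the
maximum-score distribution of unrelated loop sequence (asserted in the
test suite), and tolerates roughly 40% point substitution before a
planted domain is lost. These matrices are a functional stand-in for
curated domain models — no profile HMM, no E-values; real annotations
can be substituted via `parse_external_annotations()`.

## Distances, trees, paralogue groups

`pairwise_distance()` globally aligns two sequences (Needleman–Wunsch via
`Biostrings::pairwiseAlignment()`; match +1, mismatch −1, linear gap −2
per residue — the smallest defensible scheme, configurable) and returns
the p-distance over gap-free columns or its Poisson correction
`-log(1 - p)`, capped at `distance_cap = 10` as `p → 1`.
`neighbor_joining()` wraps `ape::nj()` and clamps negative branch
lengths to zero; on additive matrices it recovers the generating topology
exactly. `root_with_outgroup()` places the root at the midpoint of the
outgroup's pendant edge.

βα sequences are assigned to paralogue groups I/II by mean distance to
two reference sets, with the margin (absolute difference of the two
means) quantifying support; a margin below `min_margin = 0.02` expected
substitutions/site leaves the query `UNASSIGNED`. Mean-distance
assignment was chosen over tree-clade membership because it is
deterministic and margin-quantified, and does not hinge on how NJ
resolves deep branches; a tree built from the same distances is the
natural cross-check. The packaged reference FASTAs are synthetic
(generated by `make_reference_families()`, seed 42, and labelled as such)
because no curated list of canonical group I/II representatives exists;
users supply their own references for real analyses.

## Dollo gene-loss inference

For each character, `dollo_losses()` assumes a single gain at or above
the root and counts one loss on the edge above each maximal all-absent
subtree — the unique minimal explanation, verified exhaustively against
`brute_force_losses()` (edge-subset enumeration, ≤12 edges) over a
1000-case random sweep in the test suite. Polytomies are allowed.
Characters are treated independently (no linkage between the βα groups).

A character observed in no tip is **not** inferred present at the root:
`root_present = FALSE`, zero losses, flag `NEVER_OBSERVED`. Absence alone
is not evidence of ancestral presence — for Piroplasmida, loss is
inferred through its hematozoan relatives, not through its own empty row.
Callers who do assert ancestral presence (`assume_ancestral_presence =
TRUE`) get the root-edge convention of exactly one loss, which is also
the brute-force oracle's convention.

`compare_topologies()` scores each candidate tree by total losses across
characters (ascending, name as tie-break). On the packaged matrix the
Mathur-style topology is the unique minimiser for the αβ character
(one loss, after the Gregarinia + Marosporida divergence) and overall
(7 vs 9 and 10).

### Candidate topologies

The three packaged trees encode only the published monophyly claims:
`mathur` groups Cryptosporidia with Coccidia + Hematozoa (and places
Gregarinia + Marosporida basal); `janouskovec` groups Gregarinia with
Cryptosporidia; `salomaki` groups Gregarinia with Coccidia + Hematozoa.
Everything else was a free choice, fixed as follows: Chromerida is the
outgroup; Sarcocystidae + Eimeriidae and Haemosporida + Piroplasmida are
sisters in all trees; Nephromycida is an independent branch inside the
non-gregarine/marosporid clade (consistent with the rejection of
Nephromycida + Hematozoa groupings); in `salomaki`, Cryptosporidia
diverges before Nephromycida. The headline single-αβ-loss result depends
only on Gregarinia + Marosporida being basal in the Mathur-style tree,
not on these placements — moving Nephromycida within its clade leaves
every reported count unchanged (covered by the invariance of the loss
counts tested on the packaged trees).

## Synthetic data: what it emulates, what it does not

`make_isoform_sequence()` concatenates hydrophilic loops (residues drawn
from E, D, K, R, S, T, N, Q, G, P), the two domain consensus segments,
and hydrophobic helix blocks (L, I, V, F) in template order, then applies
uniform point substitutions at a configurable rate; one seed drives all
randomness, so fixtures are bit-reproducible. Defaults: helix length 21,
loop length 25, inter-stretch spacer 120. The residue pools keep helices
(~+3.8 mean hydropathy) and loops (~−2.6) far from the 1.6 threshold, so
classification tests probe pipeline logic rather than scanner
calibration.

What this does not emulate: realistic substitution processes (no
BLOSUM-style exchange preferences), amphipathic or marginally
hydrophobic helices, re-entrant loops, signal peptides, low-complexity
regions, or compositional drift between taxa. Passing tests therefore
demonstrate the correctness of the classification logic and its graceful
degradation with noise — not that the scanner matches modern predictors
on real proteomes. For real data the intended route is external
predictor output through `parse_external_annotations()`.

`simulate_complement_evolution()` starts every character present at the
root and loses it on each edge with a fixed probability while present
(irreversible, so simulated losses are never nested). One subtlety shapes
the recovery tests: two sibling clades losing a character independently
are indistinguishable from one loss on their parent edge, so inference
can merge events and the inferred count is a lower bound on the true
event count. At the simulated conditions (8-leaf tree, per-edge loss
probability 0.1, 500 replicates) the two agree exactly in over 90% of
character-replicates and differ by under 0.1 in the mean.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; 1-based
  inclusive only at the external-annotation boundary.
* Window width must be odd and at least 3; the profile uses truncated
  windows at the termini.
* All greedy selections and splits have deterministic tie-breaks
  (higher score first, then smaller start; leftmost hydropathy minimum).
* Empty inputs return empty tibbles (batch classification, stretch
  grouping, paralogue assignment); per-record pipeline failures become
  `ERROR` rows rather than aborting a batch.
* `brute_force_losses()` includes a virtual root edge, so an all-absent
  pattern costs exactly one loss under asserted ancestral presence.
* Problem sizes in the test suite — 1000 oracle-sweep cases, 200
  neighbor-joining recovery trees, 500 Dollo replicates, 150 ranking
  replicates — keep the whole suite around a minute while leaving the
  Monte-Carlo assertions well away from their thresholds.

## Limitations

The scanner and motif library are desk-scale stand-ins chosen for
transparency and testability; they are not competitive predictors.
Paralogue-group references are synthetic until a user supplies curated
ones. Loss counting is parsimony, not likelihood: no loss-rate model, no
uncertainty on the reconstruction, and no horizontal transfer. The
candidate topologies encode published constraints plus documented free
choices, not full published trees.
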