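---
title: "Screening proteomes for short toxin-like proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for short toxin-like proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tolipscan)
```

## The problem and the model

Toxin-like proteins (TOLIPs) are short (< 120 residues), secreted, endogenous
proteins whose sequences carry the signature of animal toxins without any
venom context: numerous *spaced* cysteine residues supporting a compact
disulfide-stabilized fold, a high frequency of charged residues, and an
N-terminal signal peptide. The Ly-6/uPAR (LU) family — built on the
three-finger fold of elapid α-neurotoxins, with ten conserved cysteines
forming five disulfide bridges per 80–90-residue domain — is the archetype,
and its members sit in tandem paralog clusters (mouse chromosome 9qA4 and the
chromosome-15 Ly-6 locus).

`tolipscan` operationalizes this description as a five-stage screen: input
filtering, feature extraction, tiered ensemble classification, candidate
annotation (signal peptide, cysteine scaffold, paralog-cluster membership)
and report integration. This vignette documents the model behind each stage,
the tunable parameters, the numerical choices, and what the synthetic
benchmark does and does not demonstrate.

## Input filtering

Two filters define the screening universe, applied in this order:

* **fragment exclusion** — entries whose description carries the
  `(Fragment)` token (or an explicit `is_fragment` column in TSV input) are
  incomplete sequences whose absent termini would corrupt terminal features;
* **length filter** — strictly fewer than `max_length = 120` residues; a
  120-residue protein is *not* short under this definition.

Both counts are recorded in the scan's run log, so the effect of each filter
on a given input is always reconstructible. Residues are restricted to the 20
standard letters plus `X`; `B`/`Z`/`U`/`O` are rejected outright rather than
silently recoded, so every feature has an unambiguous meaning. Duplicate ids
are an error — silent deduplication hides upstream data problems.

## The feature catalogue

The screen's discriminative signal lives in four feature families, computed
as a fixed, versioned catalogue of 49 named values per sequence
(`feature_catalogue()`). Fractions use the number of non-`X` residues as the
denominator, so unknown residues neither count for nor against any class.

* **Cysteine block.** Count and fraction of cysteines, plus gap statistics
  over differences of consecutive 1-based cysteine positions (min, max,
  mean, count), the number of *spaced* pairs (gap ≥ 3; adjacent `CC`/`CxC`
  pairs are scaffold-internal, not spaced), and a C-terminal-cysteine flag
  (final 3 residues). With fewer than two cysteines all gap statistics are 0.
* **Charge block.** Basic (K,R), acidic (D,E) and histidine fractions, the
  integer net charge `#KR − #DE`, and the combined charged fraction.
* **Polarity profiles.** Per-residue Kyte–Doolittle hydropathy and Zimmerman
  polarity values (`X` contributes 0), averaged in sliding windows of width
  5 (a sequence shorter than the window is a single window); each windowed
  profile is summarized by mean, sd, max, min, plus the unwindowed mean over
  residues 1–20 and over residues 21–end (0 if absent). The N-terminal/mature
  split at residue 20 captures the asymmetry a cleavable signal peptide
  induces.
* **Composition.** The 20 single-residue frequencies plus aromatic (F,W,Y)
  and small (A,G,S,T) class fractions, and `length`/`log(length)`.

The exact feature set of the original toxin-likeness classifiers was never
published; this catalogue is therefore a documented, versioned choice
covering the feature families known to matter, with reproducibility
preferred over fidelity to an unpublished list. An independent single-pass
implementation of every feature is kept in the test suite as an oracle and
must agree to within 1e−9 on 1,000 random sequences.

## The tiered stump ensemble

The classifier is an ensemble of `M = 9` discrete-AdaBoost members over
axis-aligned decision stumps — a deliberately transparent learner: every
decision is a named feature compared with a threshold, and training is exactly
reproducible from (data, `T`, `M`, seed) with no ML framework involved.

Each member runs `T = 50` boosting rounds. A round scans all features and all
thresholds (midpoints of consecutive distinct sorted values, both stump
polarities) for the minimum weighted 0/1 error ε, with ties broken by lowest
feature index, then lowest threshold, then positive polarity; the stump gets
weight α = ½·ln((1 − ε)/ε) with ε clamped to `[1e−10, 1 − 1e−10]` (the clamp
bounds α ≈ 11.5 on separable data rather than producing infinities), and
example weights are multiplied by `exp(∓α)` and renormalized. Note that the
0/1 training error of AdaBoost is *not* monotone round-by-round; the monotone
quantity, asserted in the tests, is the exponential bound
`∏_t 2√(ε_t(1 − ε_t))` that dominates it.

Members differ only by their balanced bootstrap resamples — each draws
`min(n_pos, n_neg)` examples with replacement from each class, with seeds
`seed … seed + M − 1`. Balancing matters because a proteome scan is extremely
imbalanced; an unbalanced resample would let members minimize error by
voting negative.

A prediction's **votes** are the members with positive signed margin; its
score is the mean margin. Tier thresholds are vote fractions: unanimity for
`P3`, ≥ 75 % (`ceiling(0.75·M)` = 7 of 9) for `P2`, ≥ 50 % (5 of 9) for `P1`.
The four-level output is fixed by the screen's design; the fractions
themselves are this package's choice and are exposed as `tier_fractions`.
Models serialize to versioned JSON with 17 significant digits, which reloads
doubles bit-exactly — two trainings with the same seed produce byte-identical
model files and identical predictions.

## Signal-peptide heuristic

The screen needs a secretion flag that is computable offline and
deterministic; `predict_signal_peptide()` is an explicit rule encoding of the
classical tripartite signal-peptide architecture, not a re-implementation of
any trained predictor. All four rules must hold: length ≥ 25; n-region
(residues 1–5) net charge ≥ 0; an 8-residue window within residues 3–20 with
mean Kyte–Doolittle hydropathy ≥ 1.6 (the maximum is reported as `h_score`);
and a cleavage position `p` ∈ [12, 35] with small residues (A,G,S,C,T) at `p`
and `p − 2` — the von Heijne −3/−1 rule. The cleavage position is the
smallest qualifying `p` at or after the end of the best h-window. The SP flag
does not gate classification; it is reported alongside tiers, matching the
post-hoc role secretion evidence plays in the screen.

## Cysteine-scaffold detection

`detect_lu_scaffold()` looks for the LU/three-finger cysteine complement: a
window that starts and ends on a cysteine, spans 60–95 residues, holds 8–12
cysteines, and contains no internal cysteine-free stretch longer than 30
residues. The length bounds bracket the 80–90-residue LU domain and the
shorter three-finger-toxin variants; `min_cys = 8` admits the 4-bridge
variants while `max_cys = 12` rejects cysteine-saturated low-complexity
regions. Overlapping candidate windows are reduced to the one with maximal
cysteine count, then minimal length, then leftmost start. Bridge capacity is
reported as `floor(n_cys/2)` — ten conserved cysteines support five bridges —
with no attempt to assign the actual pairing, which sequence alone does not
determine.

## Paralog clusters

Tandemly duplicated TOLIP genes form runs of loci within bounded genomic
distance. `find_clusters()` chains loci per chromosome by single linkage:
two loci link when the gap between them (`next start − prev end − 1`, 0 if
overlapping) is at most `max_gap`; chains with ≥ `min_genes = 3` members are
reported with their span `max(end) − min(start)`. The chaining is implemented
on `GenomicRanges::reduce()`; the tests keep a naive O(n²) transitive-closure
oracle that must agree on 1,000 random tables. `max_gap` defaults to 200 kb,
chosen once so that the two loci the screen describes — ≈ 1.1 Mb spanning a
dozen genes, and ≈ 0.9 Mb spanning 28 single-LU-domain genes — each chain
into one cluster; there is no published clustering rule to inherit. Strand is
ignored (tandem clusters mix orientations). Coordinates are 1-based inclusive
internally; BED input is converted at the boundary and every output file
names the convention in its header.

## Report integration

A record is a TOLIP candidate when it is positively tiered (`P1`–`P3`), has a
signal peptide *or* a scaffold match, and is not flagged as one of the
classifier's known false-positive families (keratins, zinc fingers,
RNase-like, plexin/semaphorin — matched as case-insensitive description
keywords, the offline proxy for domain-level annotation). The conjunction is
this package's operationalization of the screen's prose definition; each
clause can be relaxed via arguments.

Tier accounting reports, per tier and for the combined `high` (P2+P3) and
`positive` (P1+P2+P3) rows, the count and two percentage renderings: `pct`,
one decimal truncated toward zero — the convention under which 114 of 7,337
prints as 1.5 % — and `pct_int`, nearest integer with halves away from zero,
under which 418 of 7,337 prints as 6 %. Two conventions are kept because the
screen's own headline numbers mix them, and neither rounding reproduces both.

## The synthetic benchmark

`generate_proteome()` emulates the input classes the screen must separate.

* **Positives** (default 500): an optional signal-peptide prefix
  (`M` + two K/R + nine hydrophobics + small-residue cleavage context; drawn
  for 90 % of positives) followed by a mature domain of 75–85 residues
  carrying ten cysteines whose nine inter-cysteine gaps are drawn uniformly
  from 5–13 residues, resampled until the cysteine-bounded window fills
  70–83 residues. Background residues are drawn from average proteome
  frequencies with K/R multiplied by 1.5 (charge enrichment) and strongly
  hydrophobic residues (I,L,V,F,M,W) multiplied by 0.6 — disulfide-stabilized
  secreted domains are surface-exposed and hydrophilic, and an
  average-hydrophobicity background would plant spurious h-regions inside
  mature domains.
* **Decoys** (default 500, even mixture): residue *shuffles* of freshly
  generated positives (identical composition, destroyed spacing and SP — the
  hardest class, isolating the spacing/profile signal), cysteine-poor
  *random* sequences, G/S-rich *keratin-like* low-complexity repeats
  (emulating the dominant real-world false-positive family, though without
  "keratin" in the description — the keyword flag is tested separately), and
  *long* (≥ 150 residue) sequences that the length filter must remove.
  Two percent of decoys are marked as fragments to exercise that filter.

Ground truth ships as a sidecar table, never encoded in ids or descriptions,
so leakage into features is impossible. All generators are pure functions of
the configuration seed.

**What passing means.** Under these defaults the held-out screen reaches
sensitivity ≥ 0.90 at tier ≥ P1 (and ≥ 0.80 at ≥ P2) with specificity ≥ 0.95,
and the scaffold detector recalls ≥ 95 % of planted scaffolds. These
thresholds validate the machinery — features carry the designed signal,
boosting finds it, tiers order it — under planted effect sizes that are
deliberately strong and homogeneous. Real proteomes are harder in ways the
generator does not emulate: genuine toxin-like families are evolutionarily
heterogeneous, their cysteine spacing is conserved loosely rather than drawn
from a template, backgrounds contain structured domains (EGF, defensin,
protease-inhibitor folds) that share partial signatures, and annotation text
is noisy. Synthetic recovery rates therefore say nothing quantitative about
sensitivity on a real proteome; they are regression guards, not performance
claims.

## Numerical choices and degenerate inputs

* Stump-search ties broken deterministically (feature order, threshold order,
  positive polarity first); ε clamped to `[1e−10, 1 − 1e−10]`.
* Margin exactly 0 counts as a non-vote (votes require strictly positive
  margin) and as an error in training-error accounting.
* Empty FASTA → empty record table; empty post-filter set → empty report and
  zero-total tier table, exit without error.
* A sequence shorter than the profile window is one whole-sequence window;
  `sd` of a single window is 0.
* Percentage truncation adds 1e−9 before truncating to keep exact decimals
  (e.g. 1.5) from dropping a digit through floating-point representation.
* Problem sizes in the shipped tests: 1,000-sequence feature-oracle and
  1,000-table cluster-oracle sweeps, 500 sequences per class for end-to-end
  recovery, 500 planted scaffolds for detector recall — sizes at which all
  simulation-based checks are stable across seeds.

## Known limitations

* The classifier is not the original toxin-likeness server: its training
  data here is synthetic, its feature list is this package's catalogue, and
  no calibration to published precision figures is attempted or possible.
* The signal-peptide rule is a heuristic; it has no notion of
  transmembrane-helix discrimination and will mis-call some hydrophobic
  N-termini.
* Scaffold detection is sequence-only: it reports disulfide *capacity*, not
  connectivity, and cannot distinguish the three-finger fold from other
  cysteine-rich arrangements with similar spacing.
* False-positive-family flagging is keyword-based and inherits the quality
  of input descriptions.
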