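---
title: "Mining aureocin A53-like leaderless bacteriocins: models and methods"
author: "aureomine authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining aureocin A53-like leaderless bacteriocins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aureomine)
```

# The problem

Aureocin A53-like leaderless bacteriocins are short (~50 residue), highly
cationic, tryptophan-rich antimicrobial peptides translated without an
N-terminal leader, so the mature peptide is the open reading frame itself.
Finding new family members in large protein catalogs is a remote-homology
problem over very short sequences: the signal is a conserved profile, not
high pairwise identity, and databases contain millions of short spurious
ORFs. The standard attack is iterative profile-HMM search: align known core
peptides, estimate a profile HMM, sweep a database restricted to short
proteins, add confident hits to the alignment, rebuild, and sweep again.
`aureomine` implements that loop plus the downstream characterization
stages — identity networks, physicochemistry, a representative peptide
tree, and gene-neighborhood classification — as a single tested pipeline.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

# The profile HMM

`buildHmm()` estimates a classic match/insert/delete profile from an
aligned seed set:

* **Match columns.** A column becomes a match state when its gap fraction
  is *strictly below* the occupancy threshold (default 0.5). The tie at
  exactly 0.5 goes to insert; a rule had to be picked, and strict-less
  keeps a 2-row alignment with one gap out of the match set.
* **Emissions.** Column residue counts are normalized to frequencies and
  mixed with the background: `(f + w·bg) / (1 + w)` with pseudocount weight
  `w = 1` by default. A single background-mixture parameter (rather than
  Dirichlet mixtures) keeps the estimator deterministic and
  hand-checkable: two identical ungapped rows give emission
  `(1 + w·bg)/(1 + w)` for the observed letter.
* **Transitions.** Each alignment row induces a state path (match-column
  residue → M, match-column gap → D, insert-column residue → I); transitions
  are counted over all rows and Laplace-smoothed (+1 on every legal edge of
  each source-state bundle). D→I and I→D adjacencies, which have no edge in
  the plan-7-style architecture, are skipped rather than counted.

Scoring is **glocal** — the entire model against the entire sequence —
because the targets are whole small proteins and hits are kept only when
the match spans the whole protein. `forwardScore()` returns
`log2 P(s|HMM)/P(s|bg)` summed over all paths (log-space forward
recursion); `viterbiAlign()` returns the best path with the fixed
tie-break priority M < D < I, and renders the sequence over the model's
match columns, which is how round-1 hits are appended to the alignment for
the round-2 model (the alternative — a fresh de novo MSA each round — is
slower and not better defined). Unknown residues (`X`) emit at background
frequency in every state, i.e. odds 1. Forward and Viterbi are verified
against a brute-force enumeration of all state paths on toy models (M ≤ 3,
sequences ≤ 4) to 1e-9 in log space.

# E-values

`calibrateNull()` scores `nNull` i.i.d. sequences drawn from the database's
residue composition, with lengths resampled from the lengths of the actual
filtered database — glocal scores are strongly length-dependent (each
residue beyond the model length pays insert transitions), so the null must
match the length distribution being searched. Two fits are stored:

* **Gumbel by the method of moments**, `lambda = pi/(sd·sqrt(6))`,
  `mu = mean − gamma/lambda`. This is the classical extreme-value form for
  alignment score statistics and is kept as `method = "moments"`.
* **Weibull tail fit** (`method = "tail"`, the default): the exceedances
  over the empirical 90% quantile are fitted by maximum likelihood with
  `P(S ≥ tau + x) = q·exp(-(x/sigma)^k)`; below the threshold the Gumbel
  bulk is rescaled to meet the tail continuously.

The tail method exists because glocal *forward* null scores are close to
normal with a mildly heavy right tail: their survival decays faster than
any Gumbel. On a 1e5-sequence null reference the quantile spacing per
decade of survival shrinks (6.0 → 4.7 → 4.0 bits), which a stretched
exponential with shape k ≈ 1.2 tracks well, while a moment-fitted Gumbel
overshoots the 1e-4 quantile by tens of bits and therefore reports
essentially no hits at E ≤ 1 on a pure-null database of 10⁴ sequences
(expected count ≈ 1 under a calibrated E-value). With the tail fit the
measured mean count across replicate null databases is 0.8–1.1. E-values
are `E = dbSize · P(null ≥ s)`, monotone decreasing in the score by
construction.

`iterativeSearch()` runs the full loop: strict length filter (< 100
residues), calibrate, score, gate at E < 1e-5, extend the alignment with
Viterbi-rendered hits, rebuild, recalibrate, rescore. Hits are reported
with the round of first discovery. Recalibration can in principle move
borderline E-values between rounds; the monotone-expansion property is
therefore guaranteed (and tested) for well-separated planted scores, not
for hits sitting exactly at the gate.

# Alignment and identity conventions

`globalAlign()` is affine-gap Needleman–Wunsch (Gotoh) with BLOSUM62,
gap open −10, gap extend −1, where a gap of length L costs
`open + (L−1)·extend`. Traceback ties are broken diagonal > up > left so
the output is a pure function of its inputs. Percent identity is
**identical columns over total alignment columns, gaps included** — the
only convention under which 14 shared residues in a 52-column alignment of
two 52-residue peptides print as 26.9%, and the one matching clustal
percent-identity distance matrices. `starMsa()` provides a fully defined
progressive MSA (center = highest summed pairwise score, "once a gap,
always a gap") used where a reproducible multiple alignment is needed;
muscle-style iterative refinement is deliberately out of scope because its
output is not reproducible from parameters alone.

The SSN (`buildSsn`) keeps an edge when pid is *strictly greater* than the
threshold (default 64.29%), so singletons are exactly the peptides with
< 64.29% identity to every other peptide. Greedy clustering
(`greedyCluster`, default 0.90) follows the CD-HIT contract — longest
sequence founds a cluster, each next sequence joins the first
representative at or above the threshold — with exact pairwise identities
instead of word-filter heuristics: at a few hundred peptides correctness is
cheap.

# Phylogeny

Cluster representatives are placed on a neighbor-joining tree over
`d = 1 − pid/100`. NJ was chosen over maximum-likelihood inference
deliberately: a desk-scale, fully specified algorithm whose output is
exactly checkable (NJ recovers any additive matrix exactly, tested on
random 4–8 taxon trees), serving the tree's role here — grouping
representatives into clades. Negative branch lengths are clamped to zero
with the deficit moved to the sister branch; Q-criterion ties take the
smallest index pair. `rootAtOutgroup()` places the root at the midpoint of
the outgroup's pendant branch (the outgroup, e.g. a class IIa bacteriocin
such as pediocin PA-1, is user-supplied — the package embeds no real
peptide sequences).

# Peptide properties

GRAVY is the mean Kyte–Doolittle hydropathy; molecular weight uses average
residue masses plus one water (matching kDa-level reporting); net charge is
the Henderson–Hasselbalch sum over termini and ionizable side chains with
the EMBOSS pK set (N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5, D 3.9,
E 4.1, C 8.5, Y 10.1) stored as swappable data. The pI is the bisection
root of the charge curve; the interval is narrowed to 1e-6 pH units so the
residual charge at the reported pI stays far below 1e-3 elementary charges
even for long, charge-dense peptides. The summary table reports charge at
pH 7.0 — a documented assumption, since "charge" without a pH is
ill-defined. `doseToMolar()` is the assay arithmetic
`(μg/mL) / Da × 1000 = μM`.

The phylum contrast uses the Kruskal–Wallis rank test (tie-corrected H,
chi-square p on k−1 df, via `stats::kruskal.test`). At very small group
sizes (4 vs 4) the chi-square p deviates from the exact permutation
distribution by up to ~0.13; the tests compare against a complete
permutation enumeration with that approximation error in mind. H itself is
exact (e.g. {1,2,3} vs {4,5,6} gives H = 27/7 ≈ 3.857).

# BGC neighborhoods

`extractBgc()` takes every CDS overlapping ±5 kb around the span of the
core gene(s) — operons in this family are under 5 kb — merging cores that
fall in one window into a single BGC. Roles come from case-insensitive
keyword sets over product strings (data, overridable) with fixed precedence
core > transport > membrane > regulator > repair > hypothetical > other;
keyword matching suffices because upstream annotation has already done the
domain-level work. Flags record transport/membrane/regulator presence,
window truncation by the contig bounds (`contig_edge`), and machinery on
the opposite strand from the core. `functional_operon` is the conjunction
has_transport ∧ (has_membrane ∨ has_regulator) — a reported flag mirroring
qualitative usage, never a biological claim.

# The synthetic study

The generator encodes the study conditions under which the pipeline is
validated:

* **Seed peptide**: a synthetic 52-residue cationic peptide with
  tryptophans at positions 21, 32 and 52 — the *positions* 21/32 echo the
  conserved-tryptophan architecture of the family; the sequence itself is
  invented, so no real peptide is fabricated.
* **Families**: each family has a center at a configured substitution
  distance from the seed; members are mutated from the center at a small
  within-family distance (default 0.05), giving cohesive clusters at
  controlled distances. `mutatePeptide()` substitutes exactly
  `round(f·L)` positions, draws replacements from a K/R-enriched
  background (preserving the cationic character), and loses at most one
  tryptophan per call unless the requested distance forces more — at
  fraction 1 every position is substituted.
* **Decoys**: per-sequence compositions drawn from a Dirichlet around the
  global background, sequences i.i.d. — no homologous signal, which is
  what an E-value null needs. Default lengths 40–130 straddle the
  100-residue filter.
* **Taxonomy**: families alternate Actinomycetota/Bacillota so the phylum
  contrast always has two non-empty groups.
* **Operons**: four archetypes (single core; k = 2..8 cores in one window;
  contig truncated < 2 kb after the core; transporter and regulator
  antisense to the core) emitted as GFF3-subset CDS tables.

Everything is deterministic under the configured seed (byte-identical
FASTA/GFF3/TSV across runs).

Default problem sizes were chosen as the smallest at which the validated
properties are statistically meaningful: recovery and false-positive
checks run against 10⁴ decoys; calibration checks use 20 replicate
(database + null) draws of 10⁴ sequences with 1000-sequence calibrations;
oracle batteries use ≥ 200 toy cases.

**What passing does and does not show.** The synthetic data reproduces the
*statistical* structure the method assumes — family identity gradients,
composition-matched nulls, operon layouts — but real catalogs differ in
ways the generator does not emulate: residue correlations within real
proteins, fragmentary ORF calls, compositional bias of individual clades,
annotation vocabulary drift in product strings, and homologs that are
genuinely closer to the decoy distribution than any planted family.
Recovery rates measured here are upper bounds on real-database behaviour;
the keyword role classifier is only as good as the annotation vocabulary
it is given.

# Degenerate inputs and edge cases

Parsers reject rather than repair (duplicate ids, non-canonical residues,
end < start, unknown strands). An empty filtered database is a warning and
an empty hit table, not an error; downstream stages then produce empty but
well-formed outputs. Peptides whose charge never crosses zero report the
boundary pH with a `boundary` attribute. All-identical Kruskal–Wallis
input returns H = 0, p = 1. The identity matrix of a single peptide is the
1×1 matrix [100].

# Known limitations

* No HMMER3 file-format compatibility, multihit/local envelopes, or
  acceleration filters; models are serialized in a simple versioned text
  format (`writeProfileHmm`).
* The E-value tail fit extrapolates a parametric law ~3 decades beyond the
  calibration sample; it is validated at E ≈ 1 on 10⁴-sequence databases,
  and the E < 1e-5 gate relies on planted scores sitting far above the
  threshold rather than on tail accuracy at 1e-9.
* The two-database semantics of a real nr + MGnify search (whether round-1
  hits from one catalog seed searches of the other separately) are
  collapsed into a single merged-database search.
* `hmmbuild`-style entropy weighting and effective-sequence-number
  heuristics are not replicated; with curated small seed sets the
  single-parameter pseudocount is adequate and testable.
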