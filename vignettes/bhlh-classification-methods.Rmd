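---
title: "Methods: profile-HMM discovery and classification of bHLH transcription factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-HMM discovery and classification of bHLH transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures behind `bhlhscan`, the
assumptions they make, the tunable parameters and their defaults, and the
design decisions taken where reasonable alternatives existed.

## The domain model

Basic helix-loop-helix proteins share a compact, strongly conserved domain:
a basic region of about 13 residues that contacts DNA, two amphipathic
helices of 14–15 residues, and a connecting loop of 5–14 residues. The
package fixes this anatomy as a 55-column canonical coordinate frame
(`canonical_scheme()`): basic 1–13, helix 1 14–28, loop 29–40 (a nominal
12-column window; shorter loops leave gap columns, longer ones are counted
through insertions), helix 2 41–55. Second-helix numbering follows the
package's own canonical alignment. All residue rules, conservation
statistics and intron coordinates are expressed in this frame, which is
what makes them comparable across highly divergent family members.

## Profile HMMs and the local Viterbi search

`build_profile()` constructs a profile HMM from a motif alignment in the
conventional way: columns whose gap fraction is below `match_threshold`
(default 0.5) become match states; other columns feed the insert state of
the preceding node. Emissions receive Laplace (+1) pseudocounts and
transitions +0.1 by default (`pseudocount = "laplace"`); the scheme label is
recorded in `build_metadata`. Laplace pseudocounts were chosen over
Dirichlet mixtures for transparency and testability — with the alignment
sizes involved here (tens of rows) the difference is dwarfed by the
match/mismatch contrast.

The search (`viterbi_search()`, C++ core) is a Smith–Waterman-style local
Viterbi over a Plan-7-like node architecture *without* flanking null
states: any match state can start or end the alignment at zero cost, and
scores are log₂-odds against a background distribution (uniform by
default). `X` is scored as a background wildcard; other non-standard
symbols are rejected (stop codons are handled by curation, not by the
search). Tie-breaks in the dynamic program are fixed (entry preferred,
then match, insert, delete predecessors) so traced paths are
deterministic; tied paths share the maximal score either way. The
correctness contract is oracle equivalence: on models with ≤ 4 match
states and sequences of ≤ 6 residues the DP score equals exhaustive
enumeration of every legal state path, which the test suite and the
acceptance script verify on 200 random instances each run.

By default no reporting floor is applied — every best hit is returned with
its score, and downstream curation decides what survives. This mirrors the
practice of maximizing sensitivity at search time for poorly annotated
proteomes and filtering afterwards.

### E-values

Rather than analytic Karlin–Altschul statistics, `calibrate_evalues()` fits
a Gumbel (type-I extreme value) distribution to the maximal bit scores of
`n_shuffles` (default 200, minimum 100) background sequences of a fixed
length (default 400 residues, a typical full-length transcription factor).
The fit is closed-form method-of-moments (λ = π/(σ√6), μ = mean − γ/λ), so
it is exactly reproducible under the seed, which is mandatory. E-values
scale linearly with the database size supplied at search time. Absolute
E-values from different tools are not comparable; what the package relies
on is the *relative* behavior — planted motifs score many standard
deviations above the shuffled maximum (E ≪ 10⁻⁷ at these settings), while
background sequences essentially never reach E < 10⁻⁴. The pipeline calls
a protein domain-positive at `max_domain_evalue = 1e-3` (scaled to the
scanned proteome size).

## Binding classification

Flags are read at canonical positions 5, 9, 12 and 13; the basic-residue
count uses the set {R, K, H} over positions 1–13 (H is included because it
participates in the H/K₅ rule; the set is configurable). A gap at a rule
position never satisfies the rule — a conservative and easily testable
convention. Categories, in precedence order:

* **G_BOX_BINDER** — E₉ ∧ R₁₂ ∧ (H/K₅ ∧ E₉ ∧ R₁₃, the raw G-box rule);
* **E_BOX_BINDER** — E₉ ∧ R₁₂;
* **NON_EBOX_BINDER** — not (E₉ ∧ R₁₂) with ≥ 5 basic residues;
* **NON_BINDING_HLH** — everything else (≤ 4 basic residues).

Two deliberate choices here. First, the raw G-box rule as classically
stated does not mention R₁₂, yet the G-box (CACGTG) is an E-box subtype;
the census therefore reports the raw-rule count (`gbox_rule_raw`)
separately, while the *category* additionally requires R₁₂ so that G-box
binders remain a subset of E-box binders. Second, the rare E₉-without-R₁₂
configuration cannot simultaneously satisfy "four categories partition the
set" and "non-E-box binders lack E₉"; the package treats such domains as
binders (category by basic count), keeps `ebox_rule = FALSE`, and reports
the flag combination distinctly (`e9_not_r12`) in the census.

## Curation

`curate()` fails a record for an internal stop (`*` anywhere before the
final residue) or an incomplete domain (no accepted hit, or a mapped
domain with no aligned residue in the basic region, helix 1 or helix 2).
Mismatch counts against a canonical residue table (11 core positions
nested inside 19 defined positions) are computed and reported, but the
historical cutoffs (6 core / 11 defined) are **not** enforced by default —
they would discard genuine atypical family members. The shipped table
(`inst/extdata/canonical_residues.tsv`) is reconstructed from the
package's own canonical consensus and labelled as such; users with an
external reference table can supply their own.

## Intron patterns

Introns are projected into domain coordinates by walking the CDS segments
in transcription order: an intron is assigned the canonical position of
the codon containing the last exonic base, with the codon phase recorded
separately. GFF3 is read as 1-based inclusive and converted once to
0-based half-open internally; the conversion is a tested boundary. The
pattern taxonomy is driven by `intron_pattern_def()`: three conserved
positions (defaults c1 = 10, c2 = 27, c3 = 44), an alternative position
(17) for pattern F, two further positions (21, 50) for patterns G/H, and a
matching tolerance of ±2 canonical columns. The concrete positions are
package configuration, chosen to sit in anchored (non-loop) columns where
the Viterbi mapping is exact; the defining output is the matched-canonical
set, with the letters A–H as presentation labels. Which two-intron subsets
map to B, C and E ({c1,c2} → B, {c1,c3} → C, {c2,c3} → E, any single
conserved intron → D) is likewise configuration — the biggest single
assumption in this module, and deliberately exposed as data rather than
code.

## Families, distances and trees

Subfamily assignment is distance-based: p-distance (mismatches over shared
non-gap canonical columns; Poisson correction −ln(1−p) optional) to
labelled reference exemplars, nearest reference wins, margin to the best
*other* family measures confidence. Below `margin_threshold` (default 0.05
substitutions/site) a call is ambiguous unless a family-diagnostic motif
(default map: Motif 40 → Family X, at E ≤ 10⁻⁷) corroborates it. Distance
ties within 10⁻¹² break to the lexicographically smaller family label —
tie-breaks are documented and tested everywhere rather than left to
floating-point accident. A family never appears in the output unless a
reference for it was supplied; the shipped synthetic reference set
deliberately omits Family XIV.

The accompanying tree is classical neighbor-joining with a deterministic
tie-break (minimal Q, ties to the lexicographically smallest joined pair),
implemented in the package so that determinism is guaranteed, and
cross-checked in the tests against an independent implementation (`ape`)
on additive matrices, which NJ must recover exactly. This is a pragmatic
surrogate for likelihood tree inference, which is out of scope; margins
plus motif support stand in for bootstrap-style confidence.

## Homeologs, orthologs, expression

Homeolog grouping is a transitive closure (union-find) over evidence pairs
with CDS identity ≥ `min_identity` (default 90%, inclusive) and, by
default, a shared duplication block (`require_block = TRUE`). The defaults
reflect the very high DNA identity (up to ~98%) of recent whole-genome
duplicates; both are recorded in every output. Reciprocal-best-hit
matching uses the fixed tie-break chain bit score → E-value →
lexicographic subject id.

Expression categories are rule-based on a genes × tissues matrix with a
detection threshold (default 1.0 normalized units) and a seed-enrichment
fold (default 5×, boundary inclusive), both exposed as parameters since no
canonical thresholds exist. "Aerial tissues" for the nodule-preferential
rule are leaf, pod wall and the seed stages; root is deliberately
excluded, since root and nodule expression overlap heavily. Precedence is
total (NOT_EXPRESSED > POD_WALL_ONLY > NODULE_PREFERENTIAL > SEED_ENRICHED
> UBIQUITOUS > TISSUE_RESTRICTED), so every profile receives exactly one
category.

## The synthetic generator

`generate_bundle()` is first-class, tested code, not a fixture. Its
defaults *are* the study conditions the rest of the package is validated
under: 200 bHLH genes and 300 decoys; binding mix ≈ 58/18/3/21% across
G-box/E-box/non-E-box/non-binding; intron patterns A 31%, D 43%, B+C+E 4%,
F/G/H ~8%, OTHER 2%, intron-free 12%; homeolog copy-number spectrum over
{1, 2, 3, 4, 6} with ~⅔ of genes multi-copy; expression mix with ~88% of
genes expressed, including small nodule-preferential, seed-enriched and
pod-wall-only classes; per-site mutation rate 0.05 from a family
consensus; copy CDS identity 95 ± 1%; multiplicative log-normal expression
noise of 10%. Family consensus domains are deterministic seeded variants
of one canonical consensus; Family X genes carry the diagnostic Motif 40
consensus in their C-terminal flank. Rule positions are stamped exactly
and protected from mutation, hydrophobic anchors (23/45/52/55) are drawn
with probability 0.97, and loop lengths are uniform on 5–14.

What the generator does **not** emulate: realistic amino-acid composition
(background is uniform by default, configurable), codon usage and splice
consensus, empirical expression distributions, alignment uncertainty from
a real aligner, and annotation errors beyond the two planted failure modes
(internal stop; domain truncated before helix 2). Passing the closed-loop
tests therefore demonstrates internal correctness of every stage and the
detectability of cleanly planted signal — not performance on real
proteomes, where divergence, fragmentary gene models and compositional
bias will erode sensitivity in ways the synthetic conditions cannot show.

## Numerical and reproducibility choices

All randomness flows through explicit integer seeds (`withr::with_seed`;
no global RNG state leaks); generator outputs are sorted by identifier and
written with fixed float formatting, so repeated runs are byte-identical.
Output precision is fixed for diffability: percentages to 1 decimal,
distances to 4, scores to 2. Degenerate inputs fail loudly: empty
alignments, all-equal calibration scores, pairs of sequences with zero
shared columns, CDS lengths that are not a multiple of three, and evidence
naming unknown genes are all errors with informative messages, while
per-record pipeline failures are collected into an error table without
aborting the run.

Problem sizes in the shipped tests were chosen to keep the whole suite
around half a minute on one core: oracle equivalence on 200 instances of
(L ≤ 4, length ≤ 6), neighbor-joining recovery on 50 additive matrices of
5–8 taxa, and one full pipeline run on the default 500-protein bundle,
which doubles as the acceptance workload.

## Known limitations

* The search implements Viterbi (best path) only; there is no
  forward/backward posterior decoding, domain-envelope refinement or
  bias-composition filter, so envelopes are best-path envelopes.
* E-values extrapolate a moments-fitted Gumbel far into its tail; they are
  honest rankings and order-of-magnitude estimates, not calibrated
  p-values at 10⁻²⁵.
* The canonical residue table and the concrete intron positions are
  package defaults reconstructed from its own consensus, not community
  standards; both are configuration files/objects precisely so they can be
  replaced.
* Family labels are nearest-exemplar calls; families that are not
  monophyletic in reality will be split or merged according to the
  reference set supplied.
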