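---
title: "Methods: motif keys, family screening and characterization in famscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif keys, family screening and characterization in famscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscreen)
```

`famscreen` implements the computational core of a genome-wide gene-family
identification study, using the 29-member cyclic nucleotide-gated channel
(CNGC) family of *Brassica rapa* as its reference case. This vignette
documents the models and procedures, the tunable parameters, the numerical
choices, what the synthetic-data generators do and do not emulate, and the
known limitations.

## The PROSITE-dialect pattern model

A motif pattern is an ordered list of elements, each one of:

* a **fixed residue** (`L`, or equivalently `[L]` — the bracketed single
  form appears in printed keys and is matched identically; the written form
  is preserved for round-tripping),
* a **residue class** `[ABC]`,
* an **excluded class** `{ABC}`,
* a **bounded wildcard** `X`, `X(n)`, `X(n,m)`.

Any element may carry a repeat count. The enumerated repeat form
`X(0,1,2)` found in printed keys is read as the range 0–2. Tokens are
separated by dashes; ASCII and typographic dashes and stray whitespace are
accepted interchangeably, because printed keys mix them freely. A repeat
minimum of 0 is only allowed on wildcards, and a pattern must have a
minimum span of at least 1. `<` and `>` anchors are supported for
completeness though the family key uses neither.

### Scan semantics

`scanPattern()` tests **every start position**. At one start, the matcher
propagates a set of reachable positions through the elements and reports
the shortest satisfying expansion. Consequences:

* overlapping matches at distinct starts are all reported;
* the match count equals the number of matching start positions, which for
  fixed-length patterns is exactly the classic PROSITE/ScanProsite count;
* for variable-length patterns the per-start choice is deterministic
  (leftmost-shortest), so counts are reproducible. Site-count conventions
  of external scanners may differ for variable-length patterns — a known
  caveat when comparing against published per-protein site tables.

Unknown sequence letters (`X`, `B`, `Z`, `U`, …) match **wildcards only**,
never fixed residues, classes, or excluded classes. This is the
conservative reading: an exclusion `{P}` asserts the residue is known and
not proline, which an unknown letter cannot certify.

The test suite checks the scanner against an independent brute-force
oracle — an anchored regex translation evaluated over every start position
and every span between the pattern's minimum and maximum span — on over a
thousand random (pattern, sequence) instances per run.

## Consensus-key induction

`induceKey()` reproduces the procedure behind the family's published
consensus key: align the member proteins, then read off a PROSITE-dialect
pattern at a conservation threshold (the published key used > 90%
conservation over the PBC + hinge region of the CNBD).

Per column, conservation is the fraction of **non-gap** rows carrying the
most frequent residue. Columns at or above the threshold become tokens;
maximal runs of the remaining columns become `X(min,max)`, where min/max
are the fewest/most non-gap residues any single row contributes across the
run — this makes the wildcard bounds tight for the training alignment.
Choices worth recording:

* **Threshold operator.** "> 90%" is ambiguous between ≥ and >; the
  default is ≥ 0.90, with `strictGreater = TRUE` available. The threshold
  must exceed 0.5 so the top residue is unique.
* **Gap-dominated columns** (> 50% gaps) never become tokens; they carry
  no consensus signal and are folded into wildcard runs.
* **Cover mode** (the default) guarantees the induced key matches every
  training sequence: imperfectly conserved columns widen to the class of
  all residues observed there, and any column containing a gap is folded
  into a wildcard run (a fixed token at a gapped column would exclude the
  gapped rows). **Strict mode** instead fixes the top residue, emitted in
  brackets when conservation is below 1 — mirroring the printed key's
  mixed `[L]` / `L` style — and accepts that coverage may drop below 1.
* **Flanking wildcard runs are trimmed.** They carry no information, and a
  leading `X(0,k)` would violate the minimum-span invariant.
* **Adjacent identical conserved columns are not merged** into repeat
  tokens: the printed key writes `L-L` explicitly, and we mirror that.
* **Region selection is the user's.** The PBC/hinge interval is supplied
  as a column range; the package does not auto-detect domain boundaries.
  Because the exact alignment behind the published key (full-length vs
  CNBD-only, gap handling) is not recoverable from the publication,
  string-identity with the printed key is not promised — the testable
  contract is coverage: a cover-mode key matches all of its members, as
  the published key recognizes all 29 family proteins.

Monotonicity (raising the threshold never adds fixed tokens), the
cover-mode guarantee, and exact recovery of planted motifs at ≥ 90%
conservation are all property-tested on seeded synthetic families.

## Family screening

`screenCandidates()` encodes the published membership rule: a candidate is
a family member iff its protein length **strictly exceeds 500 aa** and it
carries both the cNMP-binding and ion-transport domains; a consensus key
can be added as a third rule where sequences are available. The strict
reading of "> 500" is configurable (`strict = FALSE` for ≥) since the
observed family minimum (556 aa) cannot distinguish the two. Domain calls
are **inputs** (an InterProScan/SMART/Pfam-style table); the package does
not run profile searches. Every failed rule is enumerated in the decision's
`reasons`, so a rejection is auditable — the packaged table's one rejected
accession fails as `short-length,missing-domain:cNMP`.

## Physicochemical profiling

All quantities follow the ProtParam conventions:

* **Molecular weight**: sum of average residue masses plus one water
  (18.0153 Da).
* **GRAVY**: mean Kyte–Doolittle hydropathy (bounded by the scale extremes
  ±4.5).
* **Aliphatic index**: `100·(fA + 2.9·fV + 3.9·(fI + fL))`.
* **Instability index**: `(10/L)·Σ DIWV(xᵢ, xᵢ₊₁)` with the Guruprasad
  400-entry dipeptide weight table bundled as package data; > 40 predicts
  in vitro instability. Defined as 0 (with a warning) for single residues.
* **Net charge**: Henderson–Hasselbalch sum over D, E, C, Y, H, K, R and
  the termini, with the Bjellqvist pKa set used by ProtParam, including
  residue-specific terminal pKas. Charge is strictly decreasing in pH.
* **Theoretical pI**: the root of the charge function, found by bisection
  on [0, 14] to 1e-4 pH units; tested against an independent fine-grid
  scan to within 2e-3.

Ambiguous letters error under the default `strict` policy (replicating a
published property table requires clean sequences); `lenient` mode excludes
them from composition-based indices and assigns the mean residue mass for
weight. The pH for the reported net charge defaults to 7.0 and is always
recorded on the report, because the published family table's charge
convention (values like 38.0) is not stated; its charge column should not
be compared to any fixed-pH Henderson–Hasselbalch value without knowing
that convention.

## Gene structure and intron phases

Gene models come from GFF3 via `rtracklayer`; internal intervals are
1-based inclusive in genomic order and strand decides transcription order
at computation time, which keeps the I/O conversion at the boundary and
lets a mirror test assert that strand reversal leaves intron lengths and
phases unchanged. When a gene has several transcripts the longest-CDS one
represents it. The phase of a coding intron is the cumulative CDS length
transcriptionally upstream of it, mod 3; introns outside the CDS get the
label `"-"`. A CDS whose total length is not a codon multiple warns but
still phases — truncated annotations are common and the upstream lengths
are still meaningful. Phases are verified against an independent
codon-walk oracle and against generator-planted truth. The published
family-wide phase-1/phase-2 totals (33/35) depend on the annotation
version and are deliberately not asserted offline.

## Tandem duplication

`findTandemPairs()` calls a pair tandem when the two genes share a
chromosome and phylogenetic group, the intergenic gap (downstream start −
upstream stop, floored at 0) is at most 50 kb, and at most one other
family gene lies between them. The published pairs sit 1.7–7.3 kb apart,
so the call is robust across a wide threshold band; both knobs are
configurable. Segmental-duplication labelling
(`labelDuplicationClasses()`) is explicitly heuristic — same group,
different chromosome — because confirming segmental events needs
collinearity analysis, which is out of scope; the published count of
"likely segmental" genes is therefore not a target of this heuristic.

## Expression classification

Following the study's conventions: a gene is *expressed* in a condition
when FPKM > 1 (strict); responses are classified per treatment/control
pair by `fc = log2((t + pseudo)/(c + pseudo))` with a pseudo-count of 1
(the source is silent on zero handling; the pseudo-count is configurable).
The published rule labels ≥ 0 up and ≤ 0 down, which double-counts 0; we
resolve fc = 0 as `unchanged`. A pair where neither sample exceeds the
expression threshold is `not-expressed` — a symmetric rule, so
antisymmetry under treatment/control swap holds exactly. Both log2 and
linear ratios are emitted because published fold-change phrasing ("ninefold
down") is ambiguous between the two scales.

## Synthetic-data generators

The generators exist so every downstream module has an oracle-by-construction
test, and their defaults mirror the study's scale:

* `generateFamily()` (default n = 29, the family size): plants a
  fixed-span motif into random flanks (20–60 aa, a realistic spacing for a
  CNBD sub-motif). Per motif column, exactly `floor((1−conservation)·n)`
  rows are mutated, so realized conservation never drifts below the
  requested level — threshold-recovery tests are exact, not probabilistic.
  Flanks are padded with gaps in the alignment output.
* `generateGff()` plants intron phases first and derives exon lengths from
  them (`len ≡ Δphase mod 3`), with exon counts 1–11 (the family's
  observed range is 6–11) and intron lengths 80–500 bp.
* `generateExpression()` plants up/down/unchanged/not-expressed labels and
  applies a 2^2-fold effect; expressed genes' control FPKM is floored at 2
  so the expression filter cannot mask a planted effect.

All generators restore the caller's RNG state and are byte-reproducible
under a seed. What they do **not** emulate: real alignments have gaps
inside motifs, correlated columns and phylogenetic structure; real FPKM
matrices have dispersion, batch effects and genes near the expression
threshold; real annotations have UTRs, alternative isoforms and
non-codon-multiple CDSs. Passing the synthetic suites therefore
demonstrates algorithmic correctness under the stated model, not
robustness to every artifact of real data.

## Problem sizes used by the packaged checks

The property suites run at sizes chosen to exercise the combinatorics
thoroughly while keeping a full run fast on a laptop: ≥ 1000 random
(pattern, sequence) oracle comparisons per run (patterns ≤ 8 elements,
sequences ≤ 60 aa), a dozen synthetic families of 15–20 members for
induction properties, 20–25 random 30-mers for pI cross-checks, and
10–12-gene GFF sets for phase recovery. The packaged family tables are
used at full size (29 + 1 records).

## Known limitations

* Domain calls, alignments and expression matrices are inputs; BLAST/HMM
  search, alignment construction, phylogeny, synteny and miRNA-target
  prediction are out of scope by design.
* The bundled family key is transcribed from the printed form; its
  per-accession validation requires the member protein sequences, which
  are not redistributable with the package (they are fetchable from the
  BRAD database under the accessions in `loadTable1()`).
* Site counts for variable-length PTM patterns may differ from external
  scanners whose overlap conventions are undocumented.
* The discarded accession's record carries a synthetic length (221 aa)
  because the source states only that it is short and truncated; the
  rejection the package asserts rests on the documented missing-domain
  call, which is transcribed, not synthesized.
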