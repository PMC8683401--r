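# famscreen

Gene-family mining with PROSITE-style motif keys, built around the cyclic
nucleotide-gated channel (CNGC) family of *Brassica rapa* L. (field mustard).

Plant CNGCs are ligand-gated cation channels with an N-terminal ion-transport
(IT) domain and a C-terminal cyclic-nucleotide-binding domain (CNBD) that
contains the phosphate-binding cassette (PBC) and hinge region. Genome-wide
identification of such a family follows a standard recipe: collect candidate
proteins, require the diagnostic domains and a full-length sequence, validate
the survivors against a family-specific consensus motif key, then
characterize the members (physicochemical properties, exon/intron structure,
duplication history, expression responses). `famscreen` implements that
recipe as a set of composable, tested R functions plus a command-line tool.

## What it computes

* **Pattern engine** — parses PROSITE-dialect motifs
  (`[ST]-X(2)-[DE]`, `{P}` exclusions, bounded wildcards `X(n,m)`, anchors)
  and scans proteins with them. Every start position is tested; at a given
  start the leftmost-shortest wildcard expansion is reported, so match
  counts are deterministic and equal the classic PROSITE behaviour for
  fixed-length patterns. A bundled PTM set (casein kinase II, PKC,
  cAMP/cGMP kinase, tyrosine kinase, N-glycosylation, N-myristoylation,
  amidation, leucine zipper, P-loop) drives `ptmScan()`.
* **Key induction** — `induceKey()` derives a consensus motif key from a
  protein multiple sequence alignment at a conservation threshold
  (default ≥ 0.90): conserved columns become fixed/class tokens, the rest
  collapse into bounded wildcards `X(min,max)`. In *cover* mode the key is
  guaranteed to match 100% of its training sequences. The package bundles
  the 22-element BrCNGC key (span 39–53 residues) spanning the PBC and
  hinge region; `brcngcKey()` returns it parsed.
* **Family screening** — `screenCandidates()` applies the membership rules
  (length > 500 aa, cNMP-binding + IT domains present, optional key match)
  and reports per-candidate accept/reject decisions with reasons.
* **Physicochemical profiling** — ProtParam-style `physchemReport()`:
  molecular weight, theoretical pI (Bjellqvist pKa set, bisection),
  Guruprasad instability index (bundled 400-entry DIWV table), aliphatic
  index, Kyte–Doolittle GRAVY, net charge, amino-acid and atomic
  composition.
* **Gene structure** — `readGeneModels()` (GFF3 via rtracklayer) and
  `intronPhases()`: the phase of a coding intron is the cumulative CDS
  length upstream of it mod 3 (0 = between codons, 1 = after the first
  nucleotide, 2 = between second and third).
* **Duplication** — `findTandemPairs()` calls tandem duplicates from
  coordinates + family grouping (same chromosome, same group,
  gap ≤ 50 kb, ≤ 1 intervening family gene) and
  `labelDuplicationClasses()` flags candidate segmental duplicates.
* **Expression** — `foldChange()` classifies FPKM responses per
  treatment/control pair: `fc = log2((t + 1)/(c + 1))`, up when fc > 0,
  down when fc < 0, expressed when FPKM > 1.
* **Fixtures and simulators** — the transcribed 30-record family
  coordinate table and 29-row property table (`loadTable1()`,
  `loadTable3()`), plus seeded generators for planted-motif families,
  GFF3 gene sets with known intron phases, and FPKM matrices with known
  up/down calls.

## Worked example

```r
library(famscreen)

# screen the packaged candidate table
t1  <- loadTable1()
dec <- screenCandidates(t1)
summarizeDecisions(dec)
#> $accepted
#> [1] 29
#> $rejected
#> [1] 1
#> $byReason
#> reasons
#> missing-domain:cNMP        short-length
#>                   1                   1

dec[!dec$accepted, ]
#>    accession accepted                          reasons
#> 30 Bra022235    FALSE short-length,missing-domain:cNMP

# chromosome/strand bookkeeping and tandem duplicates
chromosomeSummary(t1)$strands
#> forward reverse
#>      15      14
findTandemPairs(t1[!is.na(t1$start), ])
#>     gene_a   gene_b chromosome gap_bp group
#> 3 BrCNGC22 BrCNGC27        A03   7275  IV-b
#> 2 BrCNGC25 BrCNGC28        A01   2257  IV-b
#> 1 BrCNGC26 BrCNGC29        A05   1763  IV-b

# induce a consensus key from a seeded synthetic family and validate it
fam <- generateFamily(n = 20, conservation = 0.95, seed = 7)
key <- induceKey(fam$msa, threshold = 0.9, mode = "cover")
key@coverage
#> [1] 1
```

The screen reproduces the published family: 29 members accepted, the one
truncated accession rejected for its missing cNMP-binding domain; the three
group-IV-b tandem pairs sit 1.7–7.3 kb apart on chromosomes A01, A03 and
A05; and a cover-mode key always recognizes all of its training sequences.

The command-line tool exposes the same operations
(`inst/scripts/famscreen`): `scan`, `induce`, `physchem`, `screen`,
`genestruct`, `tandem`, `expr`, `simulate`, each writing TSV plus a
`.params.json` run manifest.

The 29 member protein sequences themselves are not redistributed with the
package; they are available from the BRAD database under the `Bra`
accessions in `loadTable1()`. Any FASTA of them can be fed directly to
`validateKey(brcngcKey(), seqs)`, `physchemTable()` and `ptmScan()` to
reproduce the per-protein published values.

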