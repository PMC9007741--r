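# txharmony

Tools for converging two gene annotation sets — think of a RefSeq-style
and an Ensembl/GENCODE-style source annotating the same assembly — on a
single representative **Select** transcript per protein-coding gene,
plus supplementary **PlusClinical** transcripts where known pathogenic
variants fall in exons the Select model does not cover. It is written
for annotation engineers and computational biologists who need the full
harmonization machinery to be scriptable and testable: every stage is a
plain R function over tibbles, and a deterministic synthetic-locus
generator makes the whole workflow runnable with no downloads.

## What it computes

**Per-gene selection**, under two independent schemes. The composite
scheme scores each coding candidate on five components and picks the
argmax of the weighted sum

```
S(t) = w_e·expr(t) + w_c·cons(t) + w_l·len(t) + w_a·appris(t) + w_u·canonical(t)
```

where `expr(t)` is the mean junction support normalized by the gene
maximum, `cons(t)` the fraction of CDS bases under positive
conservation signal, and `len(t)` the CDS length relative to the locus
maximum — with the exception that a candidate containing a coding exon
that is neither expressed nor conserved ranks below every candidate
free of such exons. The hierarchical scheme assigns each candidate a
boolean vector (clinical use, conservation pass, expression pass,
longest CDS, APPRIS principal, canonical protein) and compares vectors
lexicographically, i.e. as binary numbers with clinical use as the most
significant bit.

**Identifier-free structural matching** bins each cross-source pair into
`IDENTICAL`, `END_EXTENT_ONLY`, `UTR_EXON_DIFF`, `SAME_SPLICE_CDS_DIFF`,
`SPLICE_DIFF` or `NO_COUNTERPART`, and the same relation classifies
annotation updates into five categories (`NO_CHANGE` … `NEW_CDS`).

**End standardization** merges stranded per-position CAGE (or poly(A))
counts into clusters (gap ≤ 50 nt, same strand) and applies the
*longest-strong* rule: the representative TSS is the 5′-most peak with
≥ 50% of the cluster's maximum count (mirrored for 3′ ends). Matched
pairs adopt the same evidence-derived boundaries and become identical;
CDS coordinates are never touched.

**Promoter signatures**: positional nucleotide frequencies (purine
fraction at +1) and best-match PWM scanning of 200-nt TSS-centred
windows with *exact* p-values computed by convolution over an integer
log-odds lattice (`p ≤ 0.01` reporting threshold; offsets use the
no-position-zero convention, so a TATA box sits near −30 and an
initiator at −1).

**PlusClinical nomination**: P/LP variants uncovered by the Select
transcript but lying in conserved coding exons of sibling transcripts
drive a greedy minimum cover; nominated transcripts are matched and
end-standardized exactly like Select pairs.

## Worked example

Generate a reference bundle (a MEN1-style gene whose alternative exon is
neither expressed nor conserved) and run the full workflow:

```r
library(txharmony)

fx <- make_reference_fixtures(tempfile("fx"), seed = 42)
f  <- fx$men1_like$files
res <- run_workflow(list(
  annotation_a = f$annotation_a, annotation_b = f$annotation_b,
  genome = f$genome, coverage = f$coverage, junctions = f$junctions,
  conservation = f$conservation, flags = f$flags,
  ctss = f$ctss, polya = f$polya))
res
#> <txh_workflow> 1 gene(s); 1 Select, 0 PlusClinical pair(s)
#> # A tibble: 6 × 3
#>   category             n_genes percent
#>   <chr>                  <int>   <dbl>
#> 1 IDENTICAL                  1     100
#> ...
tidy(res)
#> # A tibble: 1 × 9
#>   gene_id symbol accession_a accession_b tag    contig start   end strand
#> 1 GME1    MEN1L  NM_100.1    ENT100.1    Select chrM1    985  2956 +
```

Both schemes picked `NM_100`/`ENT100` — the isoform *excluding* the
unsupported exon — because the inclusive isoform's extra exon fails both
the expression and the conservation test (its junction support and
conservation components are visibly lower):

```r
ev <- evidence_bundle(read_expression(f$coverage, f$junctions),
                      read_conservation(f$conservation), read_flags(f$flags))
component_scores(res$setA, "GME1", ev)[, 1:4]
#>   accession expression conservation cds_length
#> 1 NM_100          1           1          0.833
#> 2 NM_101          0.36        0.833      1
```

The summary's `start = 985` is not the annotated TSS (1000): the CAGE
cluster over the first exon has strong peaks at 985 and 1000, and the
longest-strong rule moved both transcripts 15 nt outward; similarly the
3′ end moved to the 3′-most strong poly(A) peak (2955, so the half-open
end prints 2956):

```r
res$end_updates[, c("accession", "end", "old_pos", "new_pos", "applied")]
#>   accession end         old_pos new_pos applied
#> 1 NM_100    five_prime     1000     985 TRUE
#> 2 ENT100    five_prime     1000     985 TRUE
#> 3 NM_100    three_prime    2899    2955 TRUE
#> 4 ENT100    three_prime    2899    2955 TRUE
```

A thin command-line wrapper over the same functions ships in
`inst/cli/txharmony.R` (subcommands `run`, `select`, `match`,
`standardize`, `signatures`, `plus-clinical`, `fixtures`).

### Input formats

GTF2.2 / GFF3 annotation (stop codons handled per dialect), multi-contig
FASTA, 4-column bedGraph exon coverage, BED6 junction counts (score =
spanning reads, interval = intron) and conservation segments (score =
conservation, name = frame or `.`), 5-column *stranded* bedGraph for
CAGE CTSS and poly(A) site counts (`contig start end count strand`, one
position per line), ClinVar-style variants as VCF (`CLNSIG`) or TSV, and
JASPAR-format PWMs.

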