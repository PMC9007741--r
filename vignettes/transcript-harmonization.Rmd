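---
title: "Harmonizing transcript annotation across sources: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing transcript annotation across sources: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txharmony)
```

## The problem

Two annotation sources describing the same genome rarely agree on a default
transcript per protein-coding gene, and even when they pick structurally
equivalent models the 5' and 3' extents usually differ. `txharmony`
implements the machinery needed to converge two sources on a single
representative ("Select") transcript per gene: independent per-source
selection, identifier-free structural matching, evidence-driven
standardization of transcript ends, and nomination of supplementary
("PlusClinical") transcripts where known pathogenic variants fall outside
the Select model.

All coordinates inside the package are 0-based half-open; GTF and GFF3
coordinates (1-based closed) are converted at the I/O boundary. This is
the least error-prone internal convention: interval widths are `end -
start`, adjacency is equality, and no `±1` arithmetic leaks into the
algorithms.

## Per-gene selection: two schemes

Both schemes consume the same evidence bundle — aggregate RNA-seq exon
coverage, intron-junction spanning-read counts, conservation segments
over coding sequence, and per-transcript flags (APPRIS principal,
canonical protein, prior clinical use).

**Composite scoring** (`composite_select()`). Five components in
`[0, 1]` per candidate: expression (mean of the transcript's junction
counts, normalized by the gene's maximum junction count; intronless
transcripts score 1 when their coverage clears the depth threshold),
conservation (fraction of CDS bases under positive signal), CDS length
(normalized to the locus maximum), and the two 0/1 flag concordances.
The composite is a weighted sum; weights default to 0.2 each because the
production weights of the corresponding pipelines are unpublished — the
test suite therefore asserts behaviour, never weight values. One length
exception applies: a candidate whose CDS includes a coding exon failing
*both* the expression and the conservation test ranks below every
candidate free of such exons, regardless of its length advantage. This
operationalizes the curation logic in which a longer isoform loses to a
shorter one when its extra exon is neither expressed nor conserved,
while a conserved exon expressed below its neighbours (but above the
absolute threshold) is retained.

**Hierarchical ranking** (`hierarchical_select()`). Each candidate gets
a boolean vector — prior clinical use, conservation pass, expression
pass, longest CDS, APPRIS principal, canonical protein, in that default
priority order — and candidates compare lexicographically, i.e. as
binary numbers with the top parameter as the most significant bit. The
transcript-level conservation/expression booleans are defined as "every
coding exon passes the respective exon rule"; the aggregation is not
specified anywhere authoritative, and all-exons-pass is the strictest
reading consistent with the exon-level decisions above.

Exon-level rules: an exon *passes expression* when its mean coverage
reaches `min_expression_depth` (default 5 reads/base) **and** every
flanking junction used by the candidate has `min_junction_reads`
(default 5). It *passes conservation* when at least 50% of its CDS bases
lie under segments scoring above 0. The depth/junction thresholds are
deliberately configuration, calibrated once against the synthetic
fixtures (supported exons are generated at depth 30 / junction 50,
weak-but-real exons at 8 / 10, unsupported exons at 2 / 2).

Ties in either scheme resolve deterministically: higher clinical-use
count, longer CDS, then lexicographically smallest accession. The real
projects resolve such cases by manual curation, which is out of scope
here; determinism is the property the pipeline needs.

## Structural matching

`compare_pair()` bins a cross-source pair into exactly one of:
`IDENTICAL`, `END_EXTENT_ONLY` (equal CDS, same exon count and internal
junctions, only terminal outer boundaries differ), `UTR_EXON_DIFF`
(equal CDS, different UTR exon structure — including a changed terminal
splice junction), `SAME_SPLICE_CDS_DIFF` (equal chains, moved CDS,
typically a start-codon change), or `SPLICE_DIFF`. Comparison never
consults identifiers. The same relation, read longitudinally, gives the
five update categories of `classify_update()` (`NO_CHANGE`,
`END_CHANGE`, `NEW_UTR_SAME_CDS`, `SAME_EXONS_CDS_CHANGED`, `NEW_CDS`).
The test suite checks the binning against an independent brute-force
oracle built from per-base coordinate sets and junction sets.

## End standardization and the longest-strong rule

CAGE CTSS counts (and their poly(A) mirror for 3' ends) arrive as sparse
per-position stranded counts. Positions on one contig and strand merge
transitively whenever successive positions are at most 50 nt apart
(`cage_merge_gap`); the example pair 100/149 merges, 100/151 does not.
Within a merged cluster the representative site is the strand-aware
5'-most peak with at least 50% of the cluster's maximum count
(`strong_peak_fraction`) — the "longest strong" rule, which prefers a
frequently used outer site over the absolute maximum. The 3' rule is the
strict mirror (3'-most strong peak); the source material says only that
"similar logic" applies, so the mirror is asserted here as a documented
interpretation.

`assign_end()` considers clusters overlapping the terminal exon or lying
within 500 nt (`tss_assignment_window`) outward of the terminal
nucleotide — measured from the transcript's first nucleotide to the
nearest cluster edge, since the reference point is not stated more
precisely. Updates only ever move the outer boundary of the terminal
exon: splice junctions and every CDS coordinate are invariant, and an
update that would truncate the CDS or cross a junction is refused with a
reason. When no cluster is eligible for an end, both transcripts of a
pair adopt the strand-aware outermost of their two current boundaries,
so `standardize_pair()` always converges an `END_EXTENT_ONLY` pair to
`IDENTICAL` and is idempotent (a second pass applies zero updates).

## Promoter signatures

`extract_tss_windows()` cuts the 200-nt window centred on each TSS,
strand-normalized; index 101 is position +1 and there is no position 0
(−1 abuts +1). `nucleotide_profile()` gives positional base frequencies
and the purine (A/G) fraction at +1. Motif scanning is forward-strand
only — promoter elements are orientation-specific relative to a
strand-normalized window, so double-strand scanning would be wrong here.
Scores are integer-scaled log-odds (scale 1000 by default; the scale
bounds p-value granularity and is tested against the unscaled oracle at
one-unit tolerance), and p-values are *exact*: the null score
distribution under an i.i.d. background is built by positional
convolution over the integer score lattice and compared in tests against
exhaustive enumeration of all `4^w` words up to width 8. The default
background is the empirical base composition of the scanned window set,
with uniform as an option; the best-scoring offset is reported iff its
p-value is at most 0.01, ties to the 5'-most offset. Bundled matrices
are fixture PWMs; real JASPAR matrices are drop-in inputs via
`read_jaspar()`.

## Plus Clinical nomination

Starting from all P/LP variants (review status is never consulted), a
variant is *uncovered* when its reference span overlaps no Select exon
but does overlap a conserved coding exon of another transcript of the
gene. SNVs use point-in-exon overlap; indels count on any overlap of the
reference span (inclusive overlap chosen; the source is silent).
UTR-only coverage never qualifies. `nominate()` runs a greedy minimum
cover over transcripts (ties via the selector tie-break); greedy is used
because no selection rule among multiple sufficient transcripts is
specified, and tests verify the greedy cover size equals the exact
minimum (exhaustive search) on instances with up to 10 candidates.
Variants no transcript can cover are always reported, never dropped.
Whether a nominated transcript must also clear Select-grade expression
thresholds is not specified; only the conservation rule is enforced
(`require_conserved = TRUE`), with a permissive switch for exploration.

## The synthetic-locus generator

`generate_locus()` realizes a declarative locus description into a
mutually consistent bundle: genome FASTA, source-A GTF, source-B GFF3
(deliberately cross-dialect), coverage/junction/conservation tracks,
CAGE and poly(A) site tracks, a variant table, and a JSON ground-truth
manifest. Generated sequence is i.i.d. GC≈0.5 with planted features:
GT..AG at every intron used by any isoform, ATG at the CDS start, TAA at
the CDS end, and internal stop codons purged per isoform — so every
generated transcript passes `qa_checks()` unless a defect is planted.
Every exon's CDS portion is a multiple of 3, which keeps all isoforms in
one codon frame and makes exon skipping frame-neutral; this is what
makes multi-isoform sanitization sound. All generated genes are
plus-strand (minus-strand code paths are exercised by hand-built models
in the unit tests). Fixtures are minimal and adversarial, not
biological: they do not emulate realistic exon-length or expression
distributions, tissue specificity, or sequencing noise beyond optional
Poisson singleton tags on the CAGE track, so passing tests demonstrate
decision-logic correctness, not robustness to real-data noise.

The reference bundles (`make_reference_fixtures()`) encode the canonical
cases: `men1_like` (unsupported alternative exon, excluded),
`tsc2_like` (conserved weak exon, included), `scn5a_like` (mutually
exclusive exons with P/LP variants, one PlusClinical nomination),
`utr_panel` (one gene per match category), `cage_panel` (end
standardization against planned clusters). Problem sizes are small by
design — 11 genes, kilobase contigs, 1,000-pair randomized oracles,
exhaustive PWM enumeration to width 8 — chosen so the whole suite
documents the behaviour in minutes on one core while still exercising
every code path.

## Numerical and degenerate-input choices

* Duplicate site-track positions sum; non-positive counts are dropped
  with a warning.
* A gene with no coding transcript is skipped with a message (never an
  error) and recorded alongside the selections.
* Contig/strand mismatches in `compare_pair()` warn and bin as
  `SPLICE_DIFF` rather than erroring, so one bad pair cannot abort a
  genome-wide run.
* A coordinate-identical pair whose spliced sequences differ against the
  genome indicates corrupted inputs and is a hard error at tagging time.
* All-N profile columns are flagged (`n = 0`, `NA` frequencies), not
  errors; words containing N are skipped during scanning.
* GTF stop codons are folded into the internal CDS on read and split
  back out on write; a transcript lacking a stop-codon feature keeps a
  stop-exclusive CDS (`cds_includes_stop = FALSE`) so round trips are
  exact and the QA layer, not the parser, reports the defect.

## Known limitations

The QA vocabulary is a reconstruction of the quality-assurance criteria
summarized in the source material, not a transcription of the full
production list. Manual curation — the mechanism that resolves
`UTR_EXON_DIFF`/`SAME_SPLICE_CDS_DIFF`/`SPLICE_DIFF` pairs in the real
projects — is out of scope, so such genes remain unresolved in the
binning report by design. Trans-splicing, ribosomal slippage,
mitochondrial genes, assembly liftover and cross-assembly mapping are
not modelled.
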