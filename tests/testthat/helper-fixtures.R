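# Shared helpers: compact model builders, a memoized reference-fixture
# bundle set, and the brute-force structural-comparison oracle.

`%||%` <- function(x, y) if (is.null(x)) y else x

mk_chain <- function(starts, ends, contig = "chr1", strand = "+") {
  exon_chain(contig, starts, ends, strand)
}

mk_tx <- function(accession, exon_starts, exon_ends, cds_starts = NULL,
                  cds_ends = NULL, gene_id = "G1", contig = "chr1",
                  strand = "+", source = "sourceA") {
  cds <- if (!is.null(cds_starts))
    exon_chain(contig, cds_starts, cds_ends, strand)
  transcript_model(accession, gene_id,
                   exon_chain(contig, exon_starts, exon_ends, strand),
                   cds, source = source)
}

mk_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

# random genome of given length (depends on caller's RNG state)
rand_genome <- function(len, contig = "chr1") {
  mk_genome(setNames(paste(sample(c("A", "C", "G", "T"), len,
                                  replace = TRUE), collapse = ""), contig))
}

# Reference bundles are expensive; build once per test run.
.fixture_env <- new.env(parent = emptyenv())
ref_fixtures <- function() {
  if (is.null(.fixture_env$bundles)) {
    dir <- file.path(tempdir(), "txh-ref-fixtures")
    .fixture_env$bundles <-
      suppressMessages(make_reference_fixtures(dir, seed = 42L))
  }
  .fixture_env$bundles
}

bundle_config <- function(bundle, ...) {
  f <- bundle$files
  c(list(annotation_a = f$annotation_a, annotation_b = f$annotation_b,
         genome = f$genome, coverage = f$coverage, junctions = f$junctions,
         conservation = f$conservation, flags = f$flags, ctss = f$ctss,
         polya = f$polya, variants = f$variants),
    list(...))
}

bundle_evidence <- function(bundle) {
  f <- bundle$files
  evidence_bundle(read_expression(f$coverage, f$junctions),
                  read_conservation(f$conservation),
                  read_flags(f$flags))
}

# Structural equality of two annotation sets (identifier-aware).
expect_sets_equal <- function(a, b) {
  expect_setequal(names(a$transcripts), names(b$transcripts))
  for (acc in names(a$transcripts)) {
    ta <- a$transcripts[[acc]]; tb <- b$transcripts[[acc]]
    expect_true(chains_equal(ta$exons, tb$exons), label = acc)
    expect_identical(is.null(ta$cds), is.null(tb$cds))
    if (!is.null(ta$cds))
      expect_true(chains_equal(ta$cds, tb$cds), label = paste(acc, "cds"))
    expect_identical(ta$gene_id, tb$gene_id)
    expect_identical(ta$version, tb$version)
    expect_setequal(ta$tags, tb$tags)
  }
}

# Brute-force category oracle from per-base exon/CDS sets and junction
# sets; independent of the chain representation used by compare_pair().
chain_base_set <- function(ch) {
  unlist(mapply(seq.int, ch$start, ch$end - 1L, SIMPLIFY = FALSE))
}
oracle_relation <- function(tA, tB) {
  if (tA$contig != tB$contig || tA$strand != tB$strand) return("splice")
  cds_eq <- setequal(chain_base_set(tA$cds), chain_base_set(tB$cds))
  ex_eq <- setequal(chain_base_set(tA$exons), chain_base_set(tB$exons))
  jA <- junctions_of(tA$exons); jB <- junctions_of(tB$exons)
  if (cds_eq && ex_eq) return("identical")
  if (cds_eq) {
    if (nrow(tA$exons) == nrow(tB$exons) && setequal(jA, jB))
      return("end_extent")
    return("utr_exon")
  }
  if (ex_eq) return("same_splice_cds")
  "splice"
}
junctions_of <- function(ch) {
  if (nrow(ch) < 2) return(character())
  paste(ch$end[-nrow(ch)], ch$start[-1], sep = "-")
}
oracle_compare <- function(tA, tB) {
  switch(oracle_relation(tA, tB),
         identical = "IDENTICAL", end_extent = "END_EXTENT_ONLY",
         utr_exon = "UTR_EXON_DIFF", same_splice_cds = "SAME_SPLICE_CDS_DIFF",
         "SPLICE_DIFF")
}

tempfile_with <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

# Random coding transcript and a random structural perturbation of it.
rand_tx <- function(acc = "TX1", n_exons = sample(2:5, 1), strand = "+") {
  widths <- sample(60:180, n_exons, replace = TRUE)
  gaps <- if (n_exons > 1) sample(50:120, n_exons - 1, replace = TRUE)
          else integer()
  starts <- 200L + cumsum(c(0L, widths[-n_exons] + gaps))
  ends <- starts + widths
  cds_s <- starts[1] + 10L
  cds_e <- ends[n_exons] - 10L
  ex <- exon_chain("chr1", starts, ends, strand)
  cds <- ex
  cds$start <- pmax(cds$start, cds_s); cds$end <- pmin(cds$end, cds_e)
  transcript_model(acc, "G1", ex, cds)
}

perturb_tx <- function(t, kind) {
  ex <- t$exons; cds <- t$cds
  n <- nrow(ex)
  if (kind == "none") {
  } else if (kind == "end_jitter") {
    ex$start[1] <- ex$start[1] - sample(1:40, 1)
    ex$end[n] <- ex$end[n] + sample(1:40, 1)
  } else if (kind == "utr_exon") {
    extra <- tibble::tibble(contig = ex$contig[1],
                            start = ex$start[1] - 90L,
                            end = ex$start[1] - 50L, strand = ex$strand[1])
    ex <- dplyr::arrange(dplyr::bind_rows(extra, ex), start)
  } else if (kind == "cds_shift") {
    cds$start[1] <- cds$start[1] + 3L
  } else if (kind == "splice") {
    # intron gaps are >= 50 by construction; a 21-nt exon fits at +15
    gs <- ex$end[1] + 15L
    extra <- tibble::tibble(contig = ex$contig[1], start = gs,
                            end = gs + 21L, strand = ex$strand[1])
    ex <- dplyr::arrange(dplyr::bind_rows(ex, extra), start)
    cds <- dplyr::arrange(dplyr::bind_rows(
      cds, tibble::tibble(contig = cds$contig[1], start = gs,
                          end = gs + 21L, strand = cds$strand[1])),
      start)
  }
  transcript_model(paste0(t$accession, "p"), t$gene_id,
                   exon_chain(ex$contig[1], ex$start, ex$end, ex$strand[1]),
                   exon_chain(cds$contig[1], cds$start, cds$end,
                              cds$strand[1]))
}
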