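test_that("exon chains enforce their invariants", {
  expect_error(exon_chain("chr1", 10, 5, "+"), "start < end")
  expect_error(exon_chain("chr1", c(10, 15), c(20, 30), "+"), "separated")
  expect_error(exon_chain("chr1", c(10, 20), c(20, 30), "+"), "separated")
  expect_error(exon_chain("", 10, 20, "+"), "non-empty")
  ch <- exon_chain("chr1", c(300, 100), c(500, 200), "+")
  expect_equal(ch$start, c(100L, 300L))  # sorted on construction
})

test_that("chains_equal is exact coordinate-list equality", {
  a <- mk_chain(c(100, 300), c(200, 500))
  expect_true(chains_equal(a, a))
  b <- mk_chain(c(100, 300), c(200, 501))
  expect_false(chains_equal(a, b))
  expect_false(chains_equal(a, mk_chain(c(100, 300), c(200, 500),
                                        strand = "-")))
  expect_false(chains_equal(a, mk_chain(100, 200)))
})

test_that("chains_equal agrees with the base-set + junction-set oracle", {
  set.seed(101)
  chains_equal_oracle <- function(a, b) {
    if (nrow(a) == 0 || nrow(b) == 0) return(nrow(a) == nrow(b))
    a$contig[1] == b$contig[1] && a$strand[1] == b$strand[1] &&
      setequal(chain_base_set(a), chain_base_set(b)) &&
      setequal(junctions_of(a), junctions_of(b)) &&
      nrow(a) == nrow(b)
  }
  for (i in 1:250) {
    t1 <- rand_tx()
    t2 <- if (runif(1) < 0.3) t1 else
      perturb_tx(t1, sample(c("none", "end_jitter", "utr_exon", "splice"), 1))
    expect_identical(chains_equal(t1$exons, t2$exons),
                     chains_equal_oracle(t1$exons, t2$exons))
  }
})

test_that("spliced_sequence extracts and strand-flips correctly", {
  g <- mk_genome(c(chr1 = "AAAAAAAAAAGATTACAAAAAAAAAAAAAA"))
  tp <- mk_tx("T1", 10, 16)
  expect_identical(spliced_sequence(tp, g, "exons"), "GATTAC")
  tm <- mk_tx("T2", 10, 16, strand = "-")
  expect_identical(spliced_sequence(tm, g, "exons"), "GTAATC")
  expect_error(spliced_sequence(mk_tx("T3", 10, 99), g), "beyond")
})

test_that("two-exon spliced sequence equals a per-base walk", {
  set.seed(7)
  g <- rand_genome(600)
  contig_chars <- strsplit(as.character(g[["chr1"]]), "")[[1]]
  t2 <- mk_tx("T1", c(50, 200), c(120, 280))
  naive <- paste(contig_chars[c(51:120, 201:280)], collapse = "")
  expect_identical(spliced_sequence(t2, g, "exons"), naive)
  tm <- mk_tx("T2", c(50, 200), c(120, 280), strand = "-")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  naive_m <- paste(rev(comp[contig_chars[c(51:120, 201:280)]]),
                   collapse = "")
  expect_identical(spliced_sequence(tm, g, "exons"), naive_m)
  # length identity
  expect_identical(nchar(spliced_sequence(t2, g, "exons")),
                   as.integer(sum(t2$exons$end - t2$exons$start)))
})

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

single_gene_gtf <- function(with_stop = TRUE) {
  lines <- c(
    'chr1\tsrc\tgene\t101\t900\t.\t+\t.\tgene_id "G1"; gene_name "ALPHA";',
    'chr1\tsrc\ttranscript\t101\t900\t.\t+\t.\tgene_id "G1"; transcript_id "T1.2";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1.2";',
    'chr1\tsrc\texon\t301\t500\t.\t+\t.\tgene_id "G1"; transcript_id "T1.2";',
    'chr1\tsrc\texon\t601\t900\t.\t+\t.\tgene_id "G1"; transcript_id "T1.2";',
    'chr1\tsrc\tCDS\t151\t200\t.\t+\t0\tgene_id "G1"; transcript_id "T1.2";',
    'chr1\tsrc\tCDS\t301\t500\t.\t+\t1\tgene_id "G1"; transcript_id "T1.2";',
    'chr1\tsrc\tCDS\t601\t697\t.\t+\t2\tgene_id "G1"; transcript_id "T1.2";')
  if (with_stop)
    lines <- c(lines,
      'chr1\tsrc\tstop_codon\t698\t700\t.\t+\t0\tgene_id "G1"; transcript_id "T1.2";')
  write_lines_tmp(lines, ".gtf")
}

single_gene_gff3 <- function() {
  write_lines_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t900\t.\t+\t.\tID=G1;gene_name=ALPHA",
    "chr1\tsrc\tmRNA\t101\t900\t.\t+\t.\tID=T1.2;Parent=G1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=T1.2",
    "chr1\tsrc\texon\t301\t500\t.\t+\t.\tParent=T1.2",
    "chr1\tsrc\texon\t601\t900\t.\t+\t.\tParent=T1.2",
    "chr1\tsrc\tCDS\t151\t200\t.\t+\t0\tParent=T1.2",
    "chr1\tsrc\tCDS\t301\t500\t.\t+\t1\tParent=T1.2",
    "chr1\tsrc\tCDS\t601\t700\t.\t+\t2\tParent=T1.2"), ".gff3")
}

test_that("GTF parsing assembles transcripts with 0-based half-open coordinates", {
  set <- read_annotation(single_gene_gtf(), "sourceA")
  expect_length(set$transcripts, 1)
  t <- get_transcript(set, "T1")
  expect_equal(t$version, 2L)
  expect_equal(nrow(t$exons), 3)
  expect_equal(t$exons$start, c(100L, 300L, 600L))  # GTF start - 1
  expect_equal(t$exons$end, c(200L, 500L, 900L))    # GTF end
  # stop codon folded into the CDS chain
  expect_equal(max(t$cds$end), 700L)
  expect_true(t$cds_includes_stop)
})

test_that("GFF3 parse of the same locus is structurally equal to the GTF parse", {
  a <- read_annotation(single_gene_gtf(), "s")
  b <- read_annotation(single_gene_gff3(), "s")
  expect_sets_equal(a, b)
})

test_that("GTF with no stop_codon feature keeps a stop-exclusive CDS and QA flags it", {
  set <- read_annotation(single_gene_gtf(with_stop = FALSE), "s")
  t <- get_transcript(set, "T1")
  expect_equal(max(t$cds$end), 697L)
  expect_false(t$cds_includes_stop)
  set.seed(1)
  g <- rand_genome(1000)
  expect_true("MISSING_STOP_CODON" %in%
                qa_checks(t, g, check_splice = FALSE)$code)
})

test_that("malformed lines are rejected with a line number", {
  f <- write_lines_tmp(c("chr1\tsrc\tgene\t1\t10", "bad line"), ".gtf")
  expect_error(read_annotation(f, "s"), "line 1")
})

test_that("write/parse round trips are structurally exact in both dialects", {
  for (src in list(single_gene_gtf(), single_gene_gff3())) {
    set <- read_annotation(src, "s")
    for (dialect in c("gtf", "gff3")) {
      out <- tempfile(fileext = paste0(".", dialect))
      write_annotation(set, out, dialect)
      expect_sets_equal(set, read_annotation(out, "s"))
    }
  }
})

test_that("GTF emission restores 1-based closed coordinates", {
  set <- read_annotation(single_gene_gtf(), "s")
  out <- tempfile(fileext = ".gtf")
  write_annotation(set, out, "gtf")
  lines <- grep("\texon\t", readLines(out), value = TRUE)
  f <- do.call(rbind, strsplit(lines, "\t"))
  t <- get_transcript(set, "T1")
  expect_equal(as.integer(f[, 4]), t$exons$start + 1L)
  expect_equal(as.integer(f[, 5]), t$exons$end)
  # stop codon split back out of the CDS features
  expect_true(any(grepl("\tstop_codon\t698\t700\t", readLines(out))))
})

test_that("minus-strand transcripts emit ascending exon lines with strand '-'", {
  t <- mk_tx("TM.1", c(100, 300), c(200, 400),
             cds_starts = c(150, 300), cds_ends = c(200, 360), strand = "-")
  set <- annotation_set(list(t), source = "s")
  out <- tempfile(fileext = ".gtf")
  write_annotation(set, out, "gtf")
  lines <- grep("\texon\t", readLines(out), value = TRUE)
  f <- do.call(rbind, strsplit(lines, "\t"))
  expect_equal(as.integer(f[, 4]), c(101L, 301L))  # ascending
  expect_true(all(f[, 7] == "-"))
  # minus-strand stop codon sits at the chain's low end (3' in transcript order)
  stop_line <- grep("\tstop_codon\t", readLines(out), value = TRUE)
  expect_equal(as.integer(strsplit(stop_line, "\t")[[1]][4]), 151L)
  expect_sets_equal(set, read_annotation(out, "s"))
})

test_that("empty annotation sets write header-only output", {
  set <- annotation_set(list(), genes = tibble::tibble(gene_id = character(),
                                                       symbol = character()))
  out <- tempfile(fileext = ".gff3")
  write_annotation(set, out, "gff3")
  expect_equal(readLines(out), "##gff-version 3")
})

test_that("QA checks catch the planted defects and pass clean transcripts", {
  bundles <- ref_fixtures()
  m <- bundles$men1_like
  expect_equal(nrow(qa_checks_set(m$setA, m$genome)), 0)
  expect_equal(nrow(qa_checks_set(m$setB, m$genome)), 0)

  # CDS of length 10
  set.seed(3)
  g <- rand_genome(1000)
  t10 <- mk_tx("T10", 100, 300, cds_starts = 150, cds_ends = 160)
  expect_true("CDS_NOT_MULTIPLE_OF_3" %in%
                qa_checks(t10, g, check_splice = FALSE)$code)

  # planted internal TAA, verified with the standard-codon-table oracle
  seqs <- paste0(strrep("A", 100),
                 "ATG", "GGG", "TAA", "GGG", "TGA", strrep("A", 50))
  g2 <- mk_genome(c(chr1 = seqs))
  t_int <- mk_tx("TS", 100, 115 + 50, cds_starts = 100, cds_ends = 115)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(spliced_sequence(t_int, g2, "cds"))))
  expect_true(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))  # oracle agrees
  flags <- qa_checks(t_int, g2, check_splice = FALSE)
  expect_true("INTERNAL_STOP" %in% flags$code)

  # missing ATG
  t_no_start <- mk_tx("TN", 100, 160, cds_starts = 101, cds_ends = 113)
  expect_true("MISSING_START_CODON" %in%
                qa_checks(t_no_start, g2, check_splice = FALSE)$code)

  # non-canonical splice flagged on a coding transcript
  sp <- paste0(strrep("C", 200))
  g3 <- mk_genome(c(chr1 = sp))
  t_sp <- mk_tx("TSP", c(10, 100), c(50, 150),
                cds_starts = c(20, 100), cds_ends = c(50, 120))
  expect_true("NONCANONICAL_SPLICE" %in% qa_checks(t_sp, g3)$code)
})
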