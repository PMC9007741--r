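# Selection-scheme behaviour on the reference bundles and on randomized
# synthetic score tables.

test_that("exon support reproduces the conservation-versus-expression logic", {
  b <- ref_fixtures()
  params <- txh_params()

  # alternative exon failing both tests (skipped-exon case)
  m <- b$men1_like
  ev <- bundle_evidence(m)
  t_incl <- get_transcript(m$setA, "NM_101")
  alt <- list(contig = "chrM1", start = 1500L, end = 1620L)
  sup <- exon_support(alt, t_incl, ev$expression, ev$conservation, params)
  expect_false(sup$expression_pass)
  expect_false(sup$conservation_pass)

  # conserved exon expressed below its neighbours but above threshold
  t2 <- b$tsc2_like
  ev2 <- bundle_evidence(t2)
  t_incl2 <- get_transcript(t2$setA, "NM_200")
  alt2 <- list(contig = "chrT2", start = 1500L, end = 1620L)
  sup2 <- exon_support(alt2, t_incl2, ev2$expression, ev2$conservation, params)
  expect_true(sup2$expression_pass)
  expect_true(sup2$conservation_pass)

  # zero evidence of any kind
  empty_ev <- read_expression(tempfile_with(character()),
                              tempfile_with(character()))
  empty_cons <- tibble::tibble(contig = character(), start = integer(),
                               end = integer(), strand = character(),
                               score = numeric(), frame = character())
  sup3 <- exon_support(alt, t_incl, empty_ev, empty_cons, params)
  expect_false(sup3$expression_pass)
  expect_false(sup3$conservation_pass)
})

test_that("component scores normalize CDS length within the locus", {
  g <- mk_genome(c(chr1 = strrep("A", 2000)))
  t1 <- mk_tx("T1.1", 100, 500, cds_starts = 150, cds_ends = 450)
  set1 <- annotation_set(list(t1))
  ev <- evidence_bundle(
    read_expression(tempfile_with("chr1\t100\t500\t20"), tempfile_with(character())),
    tibble::tibble(contig = character(), start = integer(), end = integer(),
                   strand = character(), score = numeric(), frame = character()))
  sc1 <- component_scores(set1, "G1", ev)
  expect_equal(sc1$cds_length, 1.0)  # self-normalization
  expect_equal(sc1$expression, 1.0)  # intronless, above depth threshold

  t2 <- mk_tx("T2.1", 100, 800, cds_starts = 150, cds_ends = 750)
  set2 <- annotation_set(list(t1, t2))
  sc2 <- component_scores(set2, "G1", ev)
  expect_equal(sc2$cds_length[sc2$accession == "T1"], 0.5)
  expect_equal(sc2$cds_length[sc2$accession == "T2"], 1.0)
})

test_that("component scores match a brute-force recomputation on the fixtures", {
  b <- ref_fixtures()$tsc2_like
  ev <- bundle_evidence(b)
  sc <- component_scores(b$setA, "GTS2", ev)
  # oracle: recompute from raw evidence tables
  jx <- ev$expression$junctions
  for (acc in sc$accession) {
    t <- get_transcript(b$setA, acc)
    introns <- t$exons$start[-1]
    istart <- t$exons$end[-nrow(t$exons)]
    counts <- purrr::map2_dbl(istart, introns, function(s, e) {
      hit <- jx$start == s & jx$end == e
      if (any(hit)) sum(jx$count[hit]) else 0
    })
    gene_max <- max(jx$count[jx$contig == "chrT2"])
    expect_equal(sc$expression[sc$accession == acc], mean(counts / gene_max))
    # conservation: per-base positive fraction over the CDS
    cons <- ev$conservation
    cds_pos <- unlist(mapply(seq.int, t$cds$start, t$cds$end - 1,
                             SIMPLIFY = FALSE))
    positive <- unique(unlist(mapply(
      seq.int, cons$start[cons$score > 0], cons$end[cons$score > 0] - 1,
      SIMPLIFY = FALSE)))
    expect_equal(sc$conservation[sc$accession == acc],
                 mean(cds_pos %in% positive))
  }
})

test_that("composite selection follows the Fig-1-style decisions", {
  b <- ref_fixtures()
  for (case in list(list(b$men1_like, "GME1", "NM_100"),
                    list(b$tsc2_like, "GTS2", "NM_200"))) {
    ev <- bundle_evidence(case[[1]])
    res <- composite_select(case[[1]]$setA, case[[2]], ev)
    expect_equal(res$accession, case[[3]])
    res_h <- hierarchical_select(case[[1]]$setA, case[[2]], ev)
    expect_equal(res_h$accession, case[[3]])
  }
})

test_that("byte-identical candidates fall to the lexicographic tie-break", {
  tA <- mk_tx("TB.1", c(100, 300), c(200, 500),
              cds_starts = c(150, 300), cds_ends = c(200, 450))
  tB <- mk_tx("TA.1", c(100, 300), c(200, 500),
              cds_starts = c(150, 300), cds_ends = c(200, 450))
  set <- annotation_set(list(tA, tB))
  ev <- evidence_bundle(
    read_expression(tempfile_with("chr1\t100\t500\t20"),
                    tempfile_with("chr1\t200\t300\t.\t50\t+")),
    tibble::tibble(contig = "chr1", start = 100L, end = 500L, strand = "+",
                   score = 10, frame = "any"))
  res <- composite_select(set, "G1", ev)
  expect_equal(res$accession, "TA")
  expect_true(res$tie_broken)
  res_h <- hierarchical_select(set, "G1", ev)
  expect_equal(res_h$accession, "TA")
  expect_true(res_h$tie_broken)
})

test_that("genes without a coding transcript are skipped with a message", {
  t_nc <- mk_tx("TNC.1", 100, 400)
  set <- annotation_set(list(t_nc))
  ev <- evidence_bundle(
    read_expression(tempfile_with(character()), tempfile_with(character())),
    tibble::tibble(contig = character(), start = integer(), end = integer(),
                   strand = character(), score = numeric(), frame = character()))
  expect_message(res <- composite_select(set, "G1", ev), "no coding")
  expect_equal(nrow(res), 0)
})

random_scores <- function(n) {
  tibble::tibble(
    accession = sprintf("T%02d", seq_len(n)),
    expression = runif(n), conservation = runif(n), cds_length = runif(n),
    appris_concordance = sample(0:1, n, TRUE),
    canonical_concordance = sample(0:1, n, TRUE),
    cds_len = sample(300:900, n), clinical_use_count = sample(0:3, n, TRUE),
    expression_pass = sample(c(TRUE, FALSE), n, TRUE),
    conservation_pass = sample(c(TRUE, FALSE), n, TRUE),
    has_unsupported_exon = FALSE)
}

test_that("hierarchical ranking equals the binary-number oracle", {
  set.seed(23)
  hierarchy <- txh_params()$hierarchy
  for (i in 1:200) {
    sc <- random_scores(sample(2:6, 1))
    h <- txharmony:::hierarchical_order(sc, hierarchy)
    bits <- cbind(sc$clinical_use_count > 0, sc$conservation_pass,
                  sc$expression_pass, sc$cds_len == max(sc$cds_len),
                  sc$appris_concordance > 0, sc$canonical_concordance > 0)
    value <- as.numeric(bits %*% 2^(5:0))  # clinical_use as MSB
    winner <- h$ord[1]
    expect_equal(value[winner], max(value))
  }
})

test_that("a weakly dominating transcript always wins the composite scheme", {
  set.seed(29)
  comp <- c("expression", "conservation", "cds_length",
            "appris_concordance", "canonical_concordance")
  for (i in 1:100) {
    sc <- random_scores(sample(2:5, 1))
    k <- sample(nrow(sc), 1)
    for (cn in comp) sc[[cn]][k] <- max(sc[[cn]]) # weak dominance
    sc$expression[k] <- max(sc$expression) + 0.1  # strict in one
    w <- runif(5, 0.05, 1); names(w) <- comp
    sc$composite <- txharmony:::composite_score(sc, w)
    expect_equal(txharmony:::composite_order(sc)[1], k)
  }
})

test_that("selection is deterministic across repeated runs", {
  b <- ref_fixtures()$scn5a_like
  ev <- bundle_evidence(b)
  r1 <- select_transcripts(b$setA, ev, scheme = "composite")
  r2 <- select_transcripts(b$setA, ev, scheme = "composite")
  expect_identical(r1$accession, r2$accession)
  expect_identical(r1$tie_broken, r2$tie_broken)
})
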