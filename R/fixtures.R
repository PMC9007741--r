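#' Declare a synthetic gene for the locus generator
#'
#' Plus-strand gene described by its union exon set, a shared CDS span,
#' and one or more isoforms as index vectors into the union exons. Every
#' exon's CDS portion must be a multiple of 3 so that all isoforms share
#' codon frame and exon skipping never shifts it.
#'
#' @param gene_id,symbol Identifiers.
#' @param exons List of `c(start, end)` 0-based half-open union exons,
#'   ascending, non-overlapping.
#' @param cds_span `c(start, end)` genomic CDS span (stop-inclusive),
#'   intersected with each isoform's exons.
#' @param isoforms Named list: accession (source A) to integer vector of
#'   union-exon indices. The first isoform is the perturbation target.
#' @param intents Character vector per union exon:
#'   `"supported"` (well expressed, conserved), `"weak_but_above"`
#'   (lower but above-threshold expression, conserved), `"unconserved"`
#'   (expressed, no conservation signal), `"low_expression"` (below
#'   threshold, conserved), `"both_fail"` (below threshold, no signal).
#' @param flags Named list: accession to
#'   `list(appris, canonical, clinical)`.
#' @param perturb_b One of `"none"`, `"end_jitter"`, `"utr_exon_swap"`,
#'   `"start_codon_shift"`, `"exon_gain"`, applied to the first isoform's
#'   source-B mirror.
#' @param only_in `"both"`, `"A"`, or `"B"`.
#' @param cage_peaks,polya_peaks Tibbles (`pos`, `count`) of planned
#'   site-track peaks (absolute coordinates), or `NULL`.
#' @param variants Tibble (`position`, `ref_len`, `classification`, `id`)
#'   or `NULL`.
#' @param expected Named list of ground-truth claims stored verbatim in
#'   the manifest.
#' @return A list consumed by [generate_locus()].
#' @export
fixture_gene <- function(gene_id, symbol = gene_id, exons, cds_span,
                         isoforms, intents = NULL, flags = list(),
                         perturb_b = "none", only_in = "both",
                         cage_peaks = NULL, polya_peaks = NULL,
                         variants = NULL, expected = list()) {
  intents <- intents %||% rep("supported", length(exons))
  stopifnot(length(intents) == length(exons))
  list(gene_id = gene_id, symbol = symbol, exons = exons,
       cds_span = cds_span, isoforms = isoforms, intents = intents,
       flags = flags, perturb_b = perturb_b, only_in = only_in,
       cage_peaks = cage_peaks, polya_peaks = polya_peaks,
       variants = variants, expected = expected)
}

#' Declare a synthetic locus
#'
#' @param name Bundle name.
#' @param contig Contig name.
#' @param contig_length Contig length (bases).
#' @param seed Integer seed; fixed seed gives byte-identical bundles.
#' @param genes List of [fixture_gene()] declarations.
#' @param cage_noise_rate Poisson background tag rate for the CAGE track
#'   (0 = planned peaks only).
#' @return A list of class `txh_locus_spec`.
#' @export
locus_spec <- function(name, contig, contig_length, seed, genes,
                       cage_noise_rate = 0) {
  for (g in genes) {
    hi <- max(map_dbl(g$exons, 2))
    if (hi > contig_length)
      abort(sprintf("gene %s overflows the contig (%d > %d).",
                    g$gene_id, hi, contig_length))
  }
  structure(list(name = name, contig = contig,
                 contig_length = as.integer(contig_length),
                 seed = as.integer(seed), genes = genes,
                 cage_noise_rate = cage_noise_rate),
            class = "txh_locus_spec")
}

intersect_span <- function(chain, s, e) {
  out <- chain
  out$start <- pmax(chain$start, s)
  out$end <- pmin(chain$end, e)
  out <- out[out$start < out$end, ]
  out
}

# Depth / junction / conservation realization of the evidence intents.
intent_depth <- c(supported = 30, weak_but_above = 8, unconserved = 30,
                  low_expression = 2, both_fail = 2)
intent_junction <- c(supported = 50, weak_but_above = 10, unconserved = 50,
                     low_expression = 2, both_fail = 2)
intent_conserved <- c(supported = TRUE, weak_but_above = TRUE,
                      unconserved = FALSE, low_expression = TRUE,
                      both_fail = FALSE)

#' Generate a synthetic locus bundle
#'
#' Realizes a [locus_spec()] into a mutually consistent file bundle:
#' genome FASTA, source-A GTF, source-B GFF3, exon-coverage bedGraph,
#' junction BED, conservation BED, flag TSV, CAGE CTSS and poly(A) site
#' tracks, variant TSV, and a JSON ground-truth manifest. Splice sites
#' are canonical GT..AG, each CDS starts with ATG, ends with TAA, and is
#' free of internal stops (for every isoform), so generated transcripts
#' pass [qa_checks()].
#'
#' @param spec A [locus_spec()].
#' @param dir Output directory (created).
#' @return A list with `name`, `dir`, `files` (named paths), `manifest`,
#'   and the in-memory `setA`/`setB`/`genome`.
#' @export
generate_locus <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  seqc <- sample(DNA, spec$contig_length, replace = TRUE)
  plant <- function(pos0, s) {
    b <- strsplit(s, "")[[1]]
    seqc[(pos0 + 1):(pos0 + length(b))] <<- b
  }
  txsA <- list(); txsB <- list()
  genesA <- list(); genesB <- list()
  cov_rows <- list(); junc_rows <- list(); cons_rows <- list()
  flag_rows <- list(); var_rows <- list()
  cage_plan <- list(); polya_plan <- list()

  for (g in spec$genes) {
    ex <- tibble(start = map_int(g$exons, ~ as.integer(.x[1])),
                 end = map_int(g$exons, ~ as.integer(.x[2])))
    cds_s <- g$cds_span[1]; cds_e <- g$cds_span[2]

    chain_of <- function(idx)
      exon_chain(spec$contig, ex$start[idx], ex$end[idx], "+")
    iso_accs <- names(g$isoforms)
    chainsA <- map(g$isoforms, chain_of)
    cds_chainsA <- map(chainsA, intersect_span, s = cds_s, e = cds_e)

    # source-B mirrors, with the declared perturbation on the first isoform
    chainsB <- chainsA
    cds_chainsB <- cds_chainsA
    cds_sB <- cds_s
    if (g$perturb_b != "none") {
      ch <- chainsB[[1]]
      if (g$perturb_b == "end_jitter") {
        ch$start[1] <- ch$start[1] - 30L
        ch$end[nrow(ch)] <- ch$end[nrow(ch)] + 20L
      } else if (g$perturb_b == "utr_exon_swap") {
        s1 <- ch$start[1]
        extra <- tibble(contig = spec$contig, start = s1 - 60L,
                        end = s1 - 40L, strand = "+")
        ch$start[1] <- s1 + 10L
        ch <- bind_rows(extra, ch)
      } else if (g$perturb_b == "start_codon_shift") {
        cds_sB <- cds_s + 6L
        cds_chainsB[[1]] <- intersect_span(ch, cds_sB, cds_e)
      } else if (g$perturb_b == "exon_gain") {
        gap_s <- ch$end[1]; gap_e <- ch$start[2]
        mid <- gap_s + ((gap_e - gap_s) %/% 2L)
        extra <- tibble(contig = spec$contig, start = mid, end = mid + 30L,
                        strand = "+")
        ch <- arrange(bind_rows(ch, extra), .data$start)
        cds_chainsB[[1]] <- intersect_span(ch, cds_s, cds_e)
      }
      ch <- arrange(ch, .data$start)
      chainsB[[1]] <- ch
      if (g$perturb_b %in% c("end_jitter", "utr_exon_swap"))
        cds_chainsB[[1]] <- intersect_span(ch, cds_s, cds_e)
    }

    # canonical splice sites for every intron used by any chain
    all_chains <- c(chainsA, chainsB)
    introns <- distinct(list_rbind(map(unname(all_chains), chain_introns)))
    for (i in seq_len(nrow(introns))) {
      plant(introns$start[i], "GT")
      plant(introns$end[i] - 2L, "AG")
    }
    plant(cds_s, "ATG")
    if (cds_sB != cds_s) plant(cds_sB, "ATG")
    plant(cds_e - 3L, "TAA")

    # purge internal stop codons, isoform by isoform (shared codon frame)
    sanitize <- function(cds_chain) {
      pos <- chain_positions(cds_chain)
      n_cod <- length(pos) %/% 3L
      if (n_cod < 2) return(invisible())
      for (k in seq_len(n_cod - 1L)) {
        p <- pos[(3L * (k - 1L) + 1L):(3L * k)]
        if (paste(seqc[p + 1L], collapse = "") %in% stop_codons)
          seqc[p[1] + 1L] <<- "C"
      }
    }
    for (cc in c(cds_chainsA, cds_chainsB)) sanitize(cc)

    # models
    for (i in seq_along(iso_accs)) {
      accA <- iso_accs[i]
      accB <- sub("^[A-Za-z_]+", "ENT", accA)
      if (g$only_in != "B")
        txsA[[length(txsA) + 1]] <- transcript_model(
          accA, g$gene_id, chainsA[[i]], cds_chainsA[[i]], source = "sourceA")
      if (g$only_in != "A")
        txsB[[length(txsB) + 1]] <- transcript_model(
          accB, g$gene_id, chainsB[[i]], cds_chainsB[[i]], source = "sourceB")
      fl <- g$flags[[accA]] %||% list(appris = FALSE, canonical = FALSE,
                                      clinical = 0L)
      flag_rows[[length(flag_rows) + 1]] <- tibble(
        accession = c(sub("\\.[0-9]+$", "", accA), sub("\\.[0-9]+$", "", accB)),
        appris_principal = fl$appris, canonical_protein = fl$canonical,
        clinical_use_count = as.integer(fl$clinical))
    }
    if (g$only_in != "B")
      genesA[[length(genesA) + 1]] <- tibble(gene_id = g$gene_id,
                                             symbol = g$symbol)
    if (g$only_in != "A")
      genesB[[length(genesB) + 1]] <- tibble(gene_id = g$gene_id,
                                             symbol = g$symbol)

    # evidence: coverage per union exon (plus perturbation-born exons)
    extra_ex <- anti_join(distinct(list_rbind(map(unname(all_chains),
                                                  ~ .x[c("start", "end")]))),
                          ex, by = c("start", "end"))
    cov_rows[[length(cov_rows) + 1]] <- tibble(
      contig = spec$contig,
      start = c(ex$start, extra_ex$start), end = c(ex$end, extra_ex$end),
      depth = c(unname(intent_depth[g$intents]),
                rep(30, nrow(extra_ex))))
    # junctions: count from the worse flanking union exon's intent
    exon_intent_at <- function(pos_s, pos_e) {
      # intron [pos_s, pos_e): flanking exons end at pos_s / start at pos_e
      left <- which(ex$end == pos_s); right <- which(ex$start == pos_e)
      cands <- c(g$intents[left], g$intents[right])
      if (!length(cands)) return(50)
      min(intent_junction[cands])
    }
    junc_rows[[length(junc_rows) + 1]] <- mutate(
      introns, count = map_dbl(seq_len(nrow(introns)), function(i)
        exon_intent_at(introns$start[i], introns$end[i])))
    # conservation over exon-CDS intersections
    for (i in seq_len(nrow(ex))) {
      s <- max(ex$start[i], cds_s); e <- min(ex$end[i], cds_e)
      if (s >= e) next
      cons_rows[[length(cons_rows) + 1]] <- tibble(
        contig = spec$contig, start = s, end = e,
        score = if (intent_conserved[g$intents[i]]) 10 else -5)
    }
    if (nrow(extra_ex) > 0)
      for (i in seq_len(nrow(extra_ex))) {
        s <- max(extra_ex$start[i], cds_s); e <- min(extra_ex$end[i], cds_e)
        if (s < e)
          cons_rows[[length(cons_rows) + 1]] <- tibble(
            contig = spec$contig, start = s, end = e, score = 10)
      }
    if (!is.null(g$cage_peaks))
      cage_plan[[length(cage_plan) + 1]] <- mutate(g$cage_peaks,
                                                   contig = spec$contig,
                                                   strand = "+")
    if (!is.null(g$polya_peaks))
      polya_plan[[length(polya_plan) + 1]] <- mutate(g$polya_peaks,
                                                     contig = spec$contig,
                                                     strand = "+")
    if (!is.null(g$variants)) {
      v <- g$variants
      for (i in seq_len(nrow(v))) {
        p <- v$position[i]
        ref <- paste(seqc[(p + 1):(p + v$ref_len[i])], collapse = "")
        alt <- chartr("ACGT", "GTAC", substr(ref, 1, 1))
        var_rows[[length(var_rows) + 1]] <- tibble(
          contig = spec$contig, position = p, ref = ref, alt = alt,
          classification = v$classification[i], id = v$id[i])
      }
    }
  }

  # ---- emit files ----
  files <- list()
  emit <- function(key, fname) {
    files[[key]] <<- file.path(dir, fname)
    files[[key]]
  }
  fa <- emit("genome", "genome.fa")
  seq_str <- paste(seqc, collapse = "")
  writeLines(c(sprintf(">%s", spec$contig),
               substring(seq_str, seq(1, nchar(seq_str), 60),
                         pmin(seq(60, nchar(seq_str) + 59, 60),
                              nchar(seq_str)))), fa)
  setA <- annotation_set(txsA, genes = list_rbind(genesA),
                         source = "sourceA", dialect = "gtf")
  setB <- annotation_set(txsB, genes = list_rbind(genesB),
                         source = "sourceB", dialect = "gff3")
  write_annotation(setA, emit("annotation_a", "sourceA.gtf"), "gtf")
  write_annotation(setB, emit("annotation_b", "sourceB.gff3"), "gff3")

  cov <- arrange(distinct(list_rbind(cov_rows)), .data$start)
  readr::write_tsv(cov, emit("coverage", "coverage.bedgraph"),
                   col_names = FALSE, progress = FALSE)
  jx <- arrange(distinct(list_rbind(junc_rows)), .data$start)
  readr::write_tsv(tibble(jx$contig, jx$start, jx$end, ".", jx$count,
                          jx$strand),
                   emit("junctions", "junctions.bed"),
                   col_names = FALSE, progress = FALSE)
  cons <- arrange(distinct(list_rbind(cons_rows)), .data$start)
  readr::write_tsv(tibble(cons$contig, cons$start, cons$end, ".",
                          cons$score, "+"),
                   emit("conservation", "conservation.bed"),
                   col_names = FALSE, progress = FALSE)
  flags <- distinct(list_rbind(flag_rows))
  readr::write_tsv(flags, emit("flags", "flags.tsv"), progress = FALSE)

  write_track <- function(plan_rows, key, fname, noise_rate) {
    plan <- if (length(plan_rows)) list_rbind(plan_rows) else
      tibble(contig = character(), pos = integer(), strand = character(),
             count = numeric())
    track <- make_cage_track(plan, noise_rate = noise_rate)
    readr::write_tsv(tibble(track$contig, track$pos, track$pos + 1L,
                            track$count, track$strand),
                     emit(key, fname), col_names = FALSE, progress = FALSE)
    track
  }
  write_track(cage_plan, "ctss", "ctss.bedgraph", spec$cage_noise_rate)
  write_track(polya_plan, "polya", "polya.bedgraph", 0)

  vars <- if (length(var_rows)) list_rbind(var_rows) else
    tibble(contig = character(), position = integer(), ref = character(),
           alt = character(), classification = character(), id = character())
  readr::write_tsv(vars, emit("variants", "variants.tsv"), progress = FALSE)

  manifest <- list(
    name = spec$name, seed = spec$seed, contig = spec$contig,
    genes = map(spec$genes, function(g)
      c(list(gene_id = g$gene_id, perturb_b = g$perturb_b,
             only_in = g$only_in), g$expected))
  )
  jsonlite::write_json(manifest, emit("manifest", "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(name = spec$name, dir = dir, files = files, manifest = manifest,
       setA = setA, setB = setB,
       genome = read_genome(fa))
}

#' Build a planned site track, optionally with Poisson background noise
#'
#' Background tags are singletons (count 1) scattered around each planned
#' peak, so they stay below the strong-peak threshold and never move the
#' longest-strong site; they can, however, widen cluster spans.
#'
#' @param tss_plan Tibble (`contig`, `pos`, `strand`, `count`) of planned
#'   peaks; counts must be >= 3 when noise is added.
#' @param noise_rate Expected background tags per planned peak (Poisson).
#' @param seed Optional seed applied locally.
#' @return A `txh_site_track`.
#' @export
make_cage_track <- function(tss_plan, noise_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(tss_plan) == 0)
    return(site_track(character(), integer(), character(), numeric()))
  rows <- tss_plan[c("contig", "pos", "strand", "count")]
  if (noise_rate > 0) {
    if (any(tss_plan$count < 3))
      abort("planned peak counts must be >= 3 when noise is added.")
    noise <- map(seq_len(nrow(tss_plan)), function(i) {
      n <- rpois(1, noise_rate)
      if (n == 0) return(NULL)
      tibble(contig = tss_plan$contig[i],
             pos = tss_plan$pos[i] +
               as.integer(round(runif(n, -150, 150))),
             strand = tss_plan$strand[i], count = 1)
    })
    noise <- list_rbind(noise)
    if (!is.null(noise) && nrow(noise)) {
      noise <- anti_join(noise, rows, by = c("contig", "pos", "strand"))
      rows <- bind_rows(rows, noise)
    }
  }
  site_track(rows$contig, rows$pos, rows$strand, rows$count)
}

#' Reference fixture bundles
#'
#' Five fixed-seed bundles exercising the decision logic end-to-end:
#' * `men1_like` — an alternatively spliced coding exon that is neither
#'   expressed nor conserved; the Select transcript must exclude it.
#' * `tsc2_like` — a conserved coding exon expressed above threshold but
#'   below its neighbours; the Select transcript must include it.
#' * `scn5a_like` — mutually exclusive exons with P/LP variants on the
#'   non-Select exon; exactly one Plus Clinical nomination.
#' * `utr_panel` — six single-isoform genes covering every match
#'   category, including a gene present in one source only.
#' * `cage_panel` — genes with CAGE/poly(A) clusters whose longest-strong
#'   sites differ from the annotated ends.
#'
#' @param dir Parent directory; one subdirectory per bundle.
#' @param seed Base seed; bundle seeds are derived deterministically.
#' @return Named list of [generate_locus()] bundles.
#' @export
make_reference_fixtures <- function(dir, seed = 42L) {
  specs <- reference_specs(seed)
  out <- map(specs, ~ generate_locus(.x, file.path(dir, .x$name)))
  setNames(out, names(specs))
}

reference_specs <- function(seed = 42L) {
  flags_main <- function(acc) setNames(list(
    list(appris = TRUE, canonical = TRUE, clinical = 0L)), acc)

  men1 <- locus_spec(
    "men1_like", "chrM1", 6000, seed + 1L,
    list(fixture_gene(
      "GME1", "MEN1L",
      exons = list(c(1000, 1200), c(1500, 1620), c(2000, 2300),
                   c(2600, 2900)),
      cds_span = c(1101, 2801),
      isoforms = list(NM_100.1 = c(1L, 3L, 4L), NM_101.1 = 1:4),
      intents = c("supported", "both_fail", "supported", "supported"),
      flags = flags_main("NM_100.1"),
      cage_peaks = tibble(pos = c(985L, 1000L), count = c(30, 40)),
      polya_peaks = tibble(pos = c(2940L, 2955L), count = c(40, 25)),
      expected = list(select = "NM_100", category_initial = "IDENTICAL",
                      category_final = "IDENTICAL",
                      tss_five = 985, tss_three = 2955)
    )))

  tsc2 <- locus_spec(
    "tsc2_like", "chrT2", 6000, seed + 2L,
    list(fixture_gene(
      "GTS2", "TSC2L",
      exons = list(c(1000, 1200), c(1500, 1620), c(2000, 2300),
                   c(2600, 2900)),
      cds_span = c(1101, 2801),
      isoforms = list(NM_200.1 = 1:4, NM_201.1 = c(1L, 3L, 4L)),
      intents = c("supported", "weak_but_above", "supported", "supported"),
      flags = flags_main("NM_200.1"),
      expected = list(select = "NM_200", category_initial = "IDENTICAL",
                      category_final = "IDENTICAL",
                      tss_five = 1000, tss_three = 2899)
    )))

  scn5a <- locus_spec(
    "scn5a_like", "chrS5", 8000, seed + 3L,
    list(fixture_gene(
      "GSC5", "SCN5AL",
      exons = list(c(1000, 1200), c(1500, 1650), c(1900, 2050),
                   c(2400, 2700), c(3000, 3300)),
      cds_span = c(1101, 3201),
      isoforms = list(NM_300.1 = c(1L, 2L, 4L, 5L),
                      NM_301.1 = c(1L, 3L, 4L, 5L)),
      intents = c("supported", "supported", "weak_but_above",
                  "supported", "supported"),
      flags = flags_main("NM_300.1"),
      variants = tibble(position = c(1920L, 1950L, 2010L, 2200L, 1600L),
                        ref_len = c(1L, 1L, 1L, 1L, 1L),
                        classification = c("P", "LP", "P", "P", "other"),
                        id = c("V1", "V2", "V3", "V4", "V5")),
      expected = list(select = "NM_300", category_initial = "IDENTICAL",
                      category_final = "IDENTICAL",
                      plus_clinical = "NM_301",
                      covered_variants = c("V1", "V2", "V3"),
                      uncoverable_variants = "V4")
    )))

  up_gene <- function(gid, base, perturb, only_in = "both",
                      expect_cat = "IDENTICAL", tss = NULL) {
    fixture_gene(
      gid, gid,
      exons = list(c(base + 500, base + 700), c(base + 900, base + 1200)),
      cds_span = c(base + 601, base + 1101),
      isoforms = setNames(list(1:2), sprintf("NM_%d.1", base)),
      perturb_b = perturb, only_in = only_in,
      expected = c(list(select = sprintf("NM_%d", base),
                        category_initial = expect_cat), tss)
    )
  }
  utr <- locus_spec(
    "utr_panel", "chrUP", 12000, seed + 4L,
    list(
      up_gene("GUP0", 0L, "none", expect_cat = "IDENTICAL",
              tss = list(category_final = "IDENTICAL",
                         tss_five = 500, tss_three = 1199)),
      up_gene("GUP2", 2000L, "end_jitter", expect_cat = "END_EXTENT_ONLY",
              tss = list(category_final = "IDENTICAL",
                         tss_five = 2470, tss_three = 3219)),
      up_gene("GUP4", 4000L, "utr_exon_swap",
              expect_cat = "UTR_EXON_DIFF"),
      up_gene("GUP6", 6000L, "start_codon_shift",
              expect_cat = "SAME_SPLICE_CDS_DIFF"),
      up_gene("GUP8", 8000L, "exon_gain", expect_cat = "SPLICE_DIFF"),
      up_gene("GUPX", 10000L, "none", only_in = "A",
              expect_cat = "NO_COUNTERPART")
    ))

  cage <- locus_spec(
    "cage_panel", "chrCP", 6000, seed + 5L,
    list(
      fixture_gene(
        "GCP1", "GCP1",
        exons = list(c(1000, 1300), c(1600, 1900)),
        cds_span = c(1102, 1801),
        isoforms = list(NM_400.1 = 1:2),
        perturb_b = "end_jitter",
        cage_peaks = tibble(pos = c(960L, 980L), count = c(30, 40)),
        polya_peaks = tibble(pos = c(1950L, 1965L), count = c(40, 25)),
        expected = list(select = "NM_400",
                        category_initial = "END_EXTENT_ONLY",
                        category_final = "IDENTICAL",
                        tss_five = 960, tss_three = 1965)
      ),
      fixture_gene(
        "GCP2", "GCP2",
        exons = list(c(3500, 3800), c(4100, 4400)),
        cds_span = c(3602, 4301),
        isoforms = list(NM_500.1 = 1:2),
        perturb_b = "end_jitter",
        cage_peaks = tibble(pos = c(3470L, 3490L), count = c(30, 40)),
        expected = list(select = "NM_500",
                        category_initial = "END_EXTENT_ONLY",
                        category_final = "IDENTICAL",
                        tss_five = 3470, tss_three = 4419)
      )
    ))

  list(men1_like = men1, tsc2_like = tsc2, scn5a_like = scn5a,
       utr_panel = utr, cage_panel = cage)
}
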