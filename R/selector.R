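#' Bundle locus evidence for selection
#'
#' @param expression A `txh_expression` (see [read_expression()]).
#' @param conservation A `txh_conservation` (see [read_conservation()]).
#' @param flags A `txh_flags` (see [read_flags()]); may be `NULL`.
#' @return A list of class `txh_evidence`.
#' @export
evidence_bundle <- function(expression, conservation, flags = NULL) {
  if (is.null(flags))
    flags <- tibble(accession = character(), appris_principal = logical(),
                    canonical_protein = logical(),
                    clinical_use_count = integer())
  structure(list(expression = expression, conservation = conservation,
                 flags = flags), class = "txh_evidence")
}

lookup_flags <- function(flags, accession) {
  i <- match(accession, flags$accession)
  if (is.na(i))
    return(list(appris_principal = FALSE, canonical_protein = FALSE,
                clinical_use_count = 0L))
  list(appris_principal = isTRUE(flags$appris_principal[i]),
       canonical_protein = isTRUE(flags$canonical_protein[i]),
       clinical_use_count = flags$clinical_use_count[i])
}

#' Expression and conservation support for one coding exon
#'
#' An exon passes expression when its mean read depth reaches
#' `min_expression_depth` and every flanking intron junction used by the
#' candidate transcript has at least `min_junction_reads` spanning reads.
#' It passes conservation when at least `conservation_min_fraction` of its
#' CDS bases sit under positive conservation signal.
#'
#' @param exon One-row interval (list or tibble row with `contig`, `start`,
#'   `end`).
#' @param t The candidate `txh_transcript` (supplies the flanking
#'   junctions and the CDS restriction).
#' @param expr A `txh_expression`.
#' @param cons A `txh_conservation`.
#' @param params A [txh_params()].
#' @return `list(expression_pass =, conservation_pass =)`.
#' @export
exon_support <- function(exon, t, expr, cons, params = txh_params()) {
  depth_ok <- mean_depth(expr, exon$contig, exon$start, exon$end) >=
    params$min_expression_depth
  introns <- chain_introns(t$exons)
  flank <- introns[introns$end == exon$start | introns$start == exon$end, ]
  junc_ok <- all(map_dbl(seq_len(nrow(flank)), function(i)
    junction_count(expr, flank$contig[i], flank$start[i], flank$end[i])) >=
      params$min_junction_reads)
  cds_s <- exon$start; cds_e <- exon$end
  if (!is.null(t$cds)) {
    ov <- t$cds[pmax(t$cds$start, exon$start) < pmin(t$cds$end, exon$end), ]
    if (nrow(ov)) {
      cds_s <- max(min(ov$start), exon$start)
      cds_e <- min(max(ov$end), exon$end)
    }
  }
  cf <- conserved_fraction(cons, exon$contig, cds_s, cds_e,
                           params$conservation_positive_threshold)
  list(expression_pass = depth_ok && junc_ok,
       conservation_pass = cf >= params$conservation_min_fraction)
}

# Per coding exon of t: support booleans. Coding exon = exon overlapping CDS.
tx_exon_support <- function(t, evidence, params) {
  if (is.null(t$cds)) return(tibble(start = integer(), end = integer(),
                                    expression_pass = logical(),
                                    conservation_pass = logical()))
  coding <- t$exons[map_lgl(seq_len(nrow(t$exons)), function(i)
    span_overlaps_chain(t$cds, t$exons$start[i], t$exons$end[i])), ]
  sup <- map(seq_len(nrow(coding)), function(i)
    exon_support(coding[i, ], t, evidence$expression, evidence$conservation,
                 params))
  tibble(start = coding$start, end = coding$end,
         expression_pass = map_lgl(sup, "expression_pass"),
         conservation_pass = map_lgl(sup, "conservation_pass"))
}

#' Per-transcript component scores for one gene
#'
#' Components, all in `[0, 1]`:
#' * `expression` — mean over the transcript's introns of the junction
#'   count normalized by the gene's maximum junction count; an intronless
#'   transcript scores 1 when its exon coverage clears the depth
#'   threshold, else 0.
#' * `conservation` — fraction of CDS bases under positive signal.
#' * `cds_length` — CDS length over the longest CDS at the locus.
#' * `appris_concordance`, `canonical_concordance` — 0/1 from the flag
#'   table.
#'
#' @param set A `txh_annotation`.
#' @param gene_id Gene to score.
#' @param evidence A `txh_evidence`.
#' @param params A [txh_params()].
#' @return A tibble, one row per coding transcript, with the five
#'   components plus `cds_len`, `clinical_use_count`, transcript-level
#'   `expression_pass`/`conservation_pass`, and `has_unsupported_exon`
#'   (TRUE when some coding exon fails both exon-level tests).
#' @export
component_scores <- function(set, gene_id, evidence, params = txh_params()) {
  txs <- keep(gene_transcripts(set, gene_id), ~ !is.null(.x$cds))
  if (!length(txs))
    return(tibble(accession = character(), expression = numeric(),
                  conservation = numeric(), cds_length = numeric(),
                  appris_concordance = numeric(),
                  canonical_concordance = numeric(), cds_len = integer(),
                  clinical_use_count = integer(), expression_pass = logical(),
                  conservation_pass = logical(),
                  has_unsupported_exon = logical()))
  all_juncs <- distinct(list_rbind(map(unname(txs),
                                       ~ chain_introns(.x$exons))))
  gene_max_junc <- if (nrow(all_juncs) == 0) 0 else
    max(map_dbl(seq_len(nrow(all_juncs)), function(i)
      junction_count(evidence$expression, all_juncs$contig[i],
                     all_juncs$start[i], all_juncs$end[i])))
  max_cds <- max(map_int(txs, ~ as.integer(chain_width(.x$cds))))
  rows <- map(unname(txs), function(t) {
    introns <- chain_introns(t$exons)
    if (nrow(introns) == 0) {
      expr_score <- as.numeric(
        mean_depth(evidence$expression, t$contig, t$exons$start[1],
                   t$exons$end[1]) >= params$min_expression_depth)
    } else if (gene_max_junc == 0) {
      expr_score <- 0
    } else {
      jc <- map_dbl(seq_len(nrow(introns)), function(i)
        junction_count(evidence$expression, introns$contig[i],
                       introns$start[i], introns$end[i]))
      expr_score <- mean(jc / gene_max_junc)
    }
    cons_score <- sum(map_dbl(seq_len(nrow(t$cds)), function(i)
      conserved_fraction(evidence$conservation, t$contig, t$cds$start[i],
                         t$cds$end[i],
                         params$conservation_positive_threshold) *
        (t$cds$end[i] - t$cds$start[i]))) / chain_width(t$cds)
    fl <- lookup_flags(evidence$flags, t$accession)
    sup <- tx_exon_support(t, evidence, params)
    tibble(accession = t$accession,
           expression = expr_score,
           conservation = cons_score,
           cds_length = chain_width(t$cds) / max_cds,
           appris_concordance = as.numeric(fl$appris_principal),
           canonical_concordance = as.numeric(fl$canonical_protein),
           cds_len = as.integer(chain_width(t$cds)),
           clinical_use_count = as.integer(fl$clinical_use_count),
           expression_pass = all(sup$expression_pass),
           conservation_pass = all(sup$conservation_pass),
           has_unsupported_exon = any(!sup$expression_pass &
                                        !sup$conservation_pass))
  })
  list_rbind(rows)
}

# Deterministic tie-break shared by both schemes: higher clinical use,
# then longer CDS, then lexicographically smallest accession.
tie_break_order <- function(scores) {
  order(-scores$clinical_use_count, -scores$cds_len, scores$accession)
}

selection_row <- function(gene_id, scores, ord, scheme, tie_broken) {
  tibble(gene_id = gene_id, accession = scores$accession[ord[1]],
         scheme = scheme, tie_broken = tie_broken,
         breakdown = list(scores))
}

#' Composite-score selection for one gene
#'
#' The composite score is the weighted sum of the five components. The
#' highest composite wins, with one length exception: a candidate whose
#' CDS includes a coding exon failing both the expression and the
#' conservation test is outranked by any candidate free of such exons,
#' regardless of its `cds_length` advantage. Full ties fall to the
#' deterministic tie-break.
#'
#' @param set,gene_id,evidence,params As for [component_scores()].
#' @return A one-row tibble (`gene_id`, `accession`, `scheme`,
#'   `tie_broken`, `breakdown` list-column), or a zero-row tibble when the
#'   gene has no coding transcript (with a message).
#' @export
composite_select <- function(set, gene_id, evidence, params = txh_params()) {
  scores <- component_scores(set, gene_id, evidence, params)
  if (nrow(scores) == 0) {
    inform(sprintf("composite_select: gene %s has no coding transcript; skipped.",
                   gene_id))
    return(selection_row(gene_id, scores, integer(), "composite", FALSE)[0, ])
  }
  scores$composite <- composite_score(scores, params$weights)
  ord <- composite_order(scores)
  tie <- nrow(scores) > 1 &&
    scores$has_unsupported_exon[ord[1]] == scores$has_unsupported_exon[ord[2]] &&
    scores$composite[ord[1]] == scores$composite[ord[2]]
  selection_row(gene_id, scores, ord, "composite", tie)
}

composite_score <- function(scores, weights) {
  as.numeric(as.matrix(scores[names(weights)]) %*% weights)
}

# Rank candidates: clean (no unsupported coding exon) before not, then by
# composite, then the deterministic tie-break.
composite_order <- function(scores) {
  order(scores$has_unsupported_exon, -scores$composite,
        -scores$clinical_use_count, -scores$cds_len, scores$accession)
}

#' Ranked-binary hierarchical selection for one gene
#'
#' Each candidate gets a boolean vector over the configured hierarchy
#' (default: clinical use, conservation pass, expression pass, longest
#' CDS, APPRIS principal, canonical protein). Candidates compare
#' lexicographically in that priority order — equivalently, as binary
#' numbers with the top parameter as the most significant bit. Full ties
#' fall to the deterministic tie-break.
#'
#' @param set,gene_id,evidence,params As for [component_scores()].
#' @return A one-row tibble as for [composite_select()].
#' @export
hierarchical_select <- function(set, gene_id, evidence,
                                params = txh_params()) {
  scores <- component_scores(set, gene_id, evidence, params)
  if (nrow(scores) == 0) {
    inform(sprintf("hierarchical_select: gene %s has no coding transcript; skipped.",
                   gene_id))
    return(selection_row(gene_id, scores, integer(), "hierarchical", FALSE)[0, ])
  }
  h <- hierarchical_order(scores, params$hierarchy)
  tie <- nrow(scores) > 1 && h$key[h$ord[1]] == h$key[h$ord[2]]
  scores$binary_vector <- chartr("10", "01", h$key)
  selection_row(gene_id, scores, h$ord, "hierarchical", tie)
}

# Lexicographic comparison of the boolean vectors in hierarchy order
# (equivalently: descending order of the vector read as a binary number
# with the top parameter as the most significant bit).
hierarchical_order <- function(scores, hierarchy) {
  vecs <- binary_vectors(scores, hierarchy)
  key <- apply(vecs, 1, function(b) paste(as.integer(!b), collapse = ""))
  list(ord = order(key, -scores$clinical_use_count, -scores$cds_len,
                   scores$accession),
       key = unname(key))
}

binary_vectors <- function(scores, hierarchy) {
  cols <- list(
    clinical_use = scores$clinical_use_count > 0,
    conservation_pass = scores$conservation_pass,
    expression_pass = scores$expression_pass,
    longest_cds = scores$cds_len == max(scores$cds_len),
    appris_principal = scores$appris_concordance > 0,
    canonical_protein = scores$canonical_concordance > 0
  )
  m <- do.call(cbind, cols[hierarchy])
  rownames(m) <- scores$accession
  m
}

#' Select a representative transcript for every gene in a set
#'
#' @param set A `txh_annotation`.
#' @param evidence A `txh_evidence`.
#' @param params A [txh_params()].
#' @param scheme `"composite"` or `"hierarchical"`.
#' @return A tibble with one row per gene that has a coding transcript;
#'   genes without one are listed in the `skipped` attribute.
#' @export
select_transcripts <- function(set, evidence, params = txh_params(),
                               scheme = c("composite", "hierarchical")) {
  scheme <- match.arg(scheme)
  fn <- if (scheme == "composite") composite_select else hierarchical_select
  res <- map(set$genes$gene_id, function(g)
    suppressMessages(fn(set, g, evidence, params)))
  out <- list_rbind(res)
  attr(out, "skipped") <- setdiff(set$genes$gene_id, out$gene_id)
  out
}
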