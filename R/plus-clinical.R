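#' Keep only pathogenic / likely pathogenic variants
#'
#' Order-preserving filter to classifications `P` and `LP`; review status
#' is never consulted.
#'
#' @param variants A `txh_variants` tibble.
#' @return The P/LP subset, same columns.
#' @export
filter_plp <- function(variants) {
  variants[variants$classification %in% c("P", "LP"), ]
}

#' P/LP variants not covered by the Select transcript
#'
#' A variant qualifies when its reference span overlaps no exon of the
#' Select transcript but does overlap at least one *coding* exon of
#' another transcript of the gene, and that exon passes the conservation
#' rule. SNV overlap is point-in-exon; indels count on any overlap of the
#' reference span.
#'
#' @param set A `txh_annotation`.
#' @param gene_id The gene.
#' @param select_accession Accession of the gene's Select transcript.
#' @param variants A `txh_variants` tibble (pre-filtered or not; only
#'   P/LP records are considered).
#' @param cons A `txh_conservation`.
#' @param params A [txh_params()].
#' @param require_conserved Set `FALSE` to drop the conservation
#'   requirement on candidate exons.
#' @return A tibble, one row per (qualifying variant, candidate exon):
#'   `id`, `contig`, `position`, `classification`, `accession`,
#'   `exon_start`, `exon_end`, `conserved`.
#' @export
uncovered_variants <- function(set, gene_id, select_accession, variants,
                               cons, params = txh_params(),
                               require_conserved = TRUE) {
  sel <- get_transcript(set, select_accession)
  if (sel$gene_id != gene_id)
    abort("`select_accession` does not belong to `gene_id`.")
  vv <- filter_plp(variants)
  vv <- vv[vv$contig == sel$contig, ]
  others <- keep(gene_transcripts(set, gene_id),
                 ~ .x$accession != sel$accession && !is.null(.x$cds))
  empty <- tibble(id = character(), contig = character(),
                  position = integer(), classification = character(),
                  accession = character(), exon_start = integer(),
                  exon_end = integer(), conserved = logical())
  if (nrow(vv) == 0) return(empty)
  rows <- map(seq_len(nrow(vv)), function(i) {
    v <- vv[i, ]
    v_s <- v$position; v_e <- v$position + max(nchar(v$ref), 1L)
    if (span_overlaps_chain(sel$exons, v_s, v_e)) return(NULL)
    cand <- map(unname(others), function(t) {
      hit <- t$exons[pmax(t$exons$start, v_s) < pmin(t$exons$end, v_e), ]
      if (nrow(hit) == 0) return(NULL)
      hit <- hit[map_lgl(seq_len(nrow(hit)), function(j)
        span_overlaps_chain(t$cds, hit$start[j], hit$end[j])), ]
      if (nrow(hit) == 0) return(NULL)
      hit$conserved <- map_lgl(seq_len(nrow(hit)), function(j) {
        ov <- t$cds[pmax(t$cds$start, hit$start[j]) <
                      pmin(t$cds$end, hit$end[j]), ]
        cf <- conserved_fraction(cons, t$contig,
                                 max(min(ov$start), hit$start[j]),
                                 min(max(ov$end), hit$end[j]),
                                 params$conservation_positive_threshold)
        cf >= params$conservation_min_fraction
      })
      if (require_conserved) hit <- hit[hit$conserved, ]
      if (nrow(hit) == 0) return(NULL)
      tibble(accession = t$accession, exon_start = hit$start,
             exon_end = hit$end, conserved = hit$conserved)
    })
    cand <- list_rbind(cand)
    if (is.null(cand) || nrow(cand) == 0) return(NULL)
    mutate(cand, id = v$id, contig = v$contig, position = v$position,
           classification = v$classification)
  })
  out <- list_rbind(rows)
  if (is.null(out) || nrow(out) == 0) return(empty)
  select(out, "id", "contig", "position", "classification", "accession",
         "exon_start", "exon_end", "conserved")
}

#' Nominate supplementary clinical transcripts
#'
#' Greedy minimum cover over the uncovered-variant table: repeatedly
#' nominate the transcript covering the most remaining uncovered
#' variants (ties broken by clinical-use count, CDS length, then
#' accession, via the selector tie-break); stops when no remaining
#' variant is coverable. Variants that stay uncoverable are reported,
#' never silently dropped.
#'
#' @param set A `txh_annotation`.
#' @param gene_id The gene.
#' @param uncovered Output of [uncovered_variants()].
#' @param all_plp Optional tibble of all P/LP variant ids in the gene
#'   (adds never-coverable ones to `uncovered_ids`).
#' @param evidence Optional `txh_evidence` for tie-breaking on flags.
#' @return A list of class `txh_nomination`: `gene_id`, `nominations`
#'   (tibble `accession`, `n_covered`, `variant_ids` list-col) and
#'   `uncovered_ids`.
#' @export
nominate <- function(set, gene_id, uncovered, all_plp = NULL,
                     evidence = NULL) {
  noms <- list()
  remaining <- unique(uncovered$id)
  covers <- split(uncovered$id, uncovered$accession)
  covers <- map(covers, unique)
  while (length(remaining)) {
    gain <- map_int(covers, ~ length(intersect(.x, remaining)))
    if (!length(gain) || max(gain) == 0) break
    cand <- names(covers)[gain == max(gain)]
    if (length(cand) > 1) {
      info <- map(cand, function(a) {
        t <- get_transcript(set, a)
        fl <- if (is.null(evidence)) list(clinical_use_count = 0L)
              else lookup_flags(evidence$flags, a)
        tibble(accession = a,
               clinical_use_count = as.integer(fl$clinical_use_count),
               cds_len = as.integer(chain_width(t$cds)))
      })
      info <- list_rbind(info)
      cand <- info$accession[tie_break_order(info)][1]
    } else cand <- cand[1]
    got <- intersect(covers[[cand]], remaining)
    noms[[length(noms) + 1]] <- tibble(accession = cand,
                                       n_covered = length(got),
                                       variant_ids = list(got))
    remaining <- setdiff(remaining, got)
    covers[[cand]] <- NULL
  }
  uncovered_ids <- remaining
  if (!is.null(all_plp))
    uncovered_ids <- union(uncovered_ids,
                           setdiff(all_plp$id, uncovered$id))
  structure(list(gene_id = gene_id,
                 nominations = if (length(noms)) list_rbind(noms)
                               else tibble(accession = character(),
                                           n_covered = integer(),
                                           variant_ids = list()),
                 uncovered_ids = uncovered_ids),
            class = "txh_nomination")
}

#' @export
print.txh_nomination <- function(x, ...) {
  cat(sprintf("<txh_nomination> gene %s: %d transcript(s), %d variant(s) uncoverable\n",
              x$gene_id, nrow(x$nominations), length(x$uncovered_ids)))
  invisible(x)
}

# Exact minimum-cover size by exhaustive search; small instances only.
# Used as the oracle against the greedy cover.
exact_cover_size <- function(uncovered) {
  ids <- unique(uncovered$id)
  covers <- map(split(uncovered$id, uncovered$accession), unique)
  coverable <- intersect(ids, unlist(covers))
  if (!length(coverable)) return(0L)
  n <- length(covers)
  if (n > 10) abort("exact_cover_size is for <= 10 candidate transcripts.")
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k, simplify = FALSE)
    for (cmb in combos)
      if (all(coverable %in% unlist(covers[cmb]))) return(k)
  }
  n
}

#' Pair and tag nominated clinical transcripts
#'
#' Each nominated transcript is matched against the other source's
#' transcripts of the same gene by structural identity, end-standardized
#' exactly like Select pairs, and both sides tagged `PlusClinical` when
#' the pair converges. Transcripts with no structural counterpart are
#' reported unpaired.
#'
#' @param nomination A `txh_nomination`.
#' @param setA Annotation set containing the nominated transcripts.
#' @param setB The other source's annotation set.
#' @param genome Named `DNAStringSet`.
#' @param cage,polya `txh_site_track` objects.
#' @param params A [txh_params()].
#' @param gene_id_b The gene's id in `setB` (defaults to the same id).
#' @return `list(setA =, setB =, log =)`; `log` has one row per nominated
#'   transcript with `paired`, `accession_b`, `reason`.
#' @export
pair_plus_clinical <- function(nomination, setA, setB, genome, cage, polya,
                               params = txh_params(), gene_id_b = NULL) {
  gene_b <- gene_id_b %||% nomination$gene_id
  cand_b <- keep(gene_transcripts(setB, gene_b), ~ !is.null(.x$cds))
  logs <- map(nomination$nominations$accession, function(acc) {
    tA <- get_transcript(setA, acc)
    if (any(tA$tags == "Select"))
      abort(sprintf("nominated transcript %s already carries the Select tag.", acc))
    cats <- map_chr(cand_b, ~ suppressWarnings(compare_pair(tA, .x)))
    ok <- names(cand_b)[cats %in% c("IDENTICAL", "END_EXTENT_ONLY")]
    if (!length(ok))
      return(tibble(accession_a = acc, accession_b = NA_character_,
                    paired = FALSE, reason = "no structural counterpart"))
    tB <- cand_b[[ok[1]]]
    std <- standardize_pair(tA, tB, cage, polya, params)
    std$a$tags <- union(std$a$tags, "PlusClinical")
    std$b$tags <- union(std$b$tags, "PlusClinical")
    setA$transcripts[[std$a$accession]] <<- std$a
    setB$transcripts[[std$b$accession]] <<- std$b
    tibble(accession_a = acc, accession_b = tB$accession, paired = TRUE,
           reason = NA_character_)
  })
  list(setA = setA, setB = setB, log = list_rbind(logs))
}
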