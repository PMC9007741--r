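match_categories <- c("IDENTICAL", "END_EXTENT_ONLY", "UTR_EXON_DIFF",
                      "SAME_SPLICE_CDS_DIFF", "SPLICE_DIFF", "NO_COUNTERPART")

update_categories <- c("NO_CHANGE", "END_CHANGE", "NEW_UTR_SAME_CDS",
                       "SAME_EXONS_CDS_CHANGED", "NEW_CDS")

# Shared structural comparison. Returns one of the generic levels:
# identical / end_extent / utr_exon / same_splice_cds / splice.
structural_relation <- function(tA, tB) {
  if (tA$contig != tB$contig || tA$strand != tB$strand) return("splice")
  cds_eq <- !is.null(tA$cds) && !is.null(tB$cds) &&
    chains_equal(tA$cds, tB$cds)
  ex_eq <- chains_equal(tA$exons, tB$exons)
  if (cds_eq && ex_eq) return("identical")
  if (cds_eq) {
    same_n <- nrow(tA$exons) == nrow(tB$exons)
    same_junc <- identical(junction_keys(tA$exons), junction_keys(tB$exons))
    if (same_n && same_junc) return("end_extent")
    return("utr_exon")
  }
  if (ex_eq) return("same_splice_cds")
  "splice"
}

#' Categorize a cross-source transcript pair
#'
#' Pairs are binned by CDS and exon structure, independent of
#' identifiers: `IDENTICAL` (both chains equal), `END_EXTENT_ONLY` (equal
#' CDS, same exon count and internal junctions, only the outer boundaries
#' of the terminal exons differ), `UTR_EXON_DIFF` (equal CDS, exon
#' structure differs beyond terminal extents), `SAME_SPLICE_CDS_DIFF`
#' (equal exon chain, different CDS — typically a moved start codon),
#' `SPLICE_DIFF` otherwise. A contig or strand mismatch yields
#' `SPLICE_DIFF` with a warning rather than an error.
#'
#' @param tA,tB `txh_transcript` objects, both coding.
#' @return A single category string.
#' @export
compare_pair <- function(tA, tB) {
  if (tA$contig != tB$contig || tA$strand != tB$strand)
    warn(sprintf("compare_pair: %s and %s are on different contig/strand.",
                 tA$accession, tB$accession))
  switch(structural_relation(tA, tB),
         identical = "IDENTICAL",
         end_extent = "END_EXTENT_ONLY",
         utr_exon = "UTR_EXON_DIFF",
         same_splice_cds = "SAME_SPLICE_CDS_DIFF",
         "SPLICE_DIFF")
}

#' Classify the update from an old transcript to its replacement
#'
#' The five update categories mirror the cross-source bins but read as a
#' longitudinal change: `NO_CHANGE`, `END_CHANGE` (only terminal extents,
#' CDS equal), `NEW_UTR_SAME_CDS`, `SAME_EXONS_CDS_CHANGED`, `NEW_CDS`
#' (no equivalent splice pattern). Comparison ignores accessions and
#' versions; a version increment is reported separately where relevant.
#'
#' @param old,new `txh_transcript` objects for the same gene.
#' @return A single category string.
#' @export
classify_update <- function(old, new) {
  switch(structural_relation(old, new),
         identical = "NO_CHANGE",
         end_extent = "END_CHANGE",
         utr_exon = "NEW_UTR_SAME_CDS",
         same_splice_cds = "SAME_EXONS_CDS_CHANGED",
         "NEW_CDS")
}

#' Match per-gene selections across two sources
#'
#' Joins the two selection tables on `gene_id` (optionally through a
#' two-column mapping table when the sources use different identifiers),
#' runs [compare_pair()] on each shared gene, and aggregates category
#' counts and percentages. Genes present in only one source are binned
#' `NO_COUNTERPART`.
#'
#' @param selA,selB Selection tibbles from [select_transcripts()].
#' @param setA,setB The corresponding annotation sets.
#' @param gene_map Optional tibble (`gene_a`, `gene_b`) mapping source-A
#'   gene ids to source-B gene ids.
#' @return A list of class `txh_match_report`: `pairs` (per-gene tibble)
#'   and `summary` (per-category counts and percentages). Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
match_selected <- function(selA, selB, setA, setB, gene_map = NULL) {
  if (anyDuplicated(selA$gene_id) || anyDuplicated(selB$gene_id))
    abort("duplicated gene_id within a source's selections.")
  b_of <- function(ga) {
    if (is.null(gene_map)) return(ga)
    i <- match(ga, gene_map$gene_a)
    ifelse(is.na(i), ga, gene_map$gene_b[i])
  }
  genesA <- selA$gene_id
  mappedA <- b_of(genesA)
  shared <- genesA[mappedA %in% selB$gene_id]
  only_a <- genesA[!mappedA %in% selB$gene_id]
  only_b <- setdiff(selB$gene_id, b_of(genesA))
  rows <- map(shared, function(ga) {
    gb <- b_of(ga)
    accA <- selA$accession[selA$gene_id == ga]
    accB <- selB$accession[selB$gene_id == gb]
    tA <- get_transcript(setA, accA)
    tB <- get_transcript(setB, accB)
    tibble(gene_id = ga, accession_a = accA, accession_b = accB,
           category = suppressWarnings(compare_pair(tA, tB)))
  })
  pairs <- bind_rows(
    list_rbind(rows),
    tibble(gene_id = only_a, accession_a = selA$accession[match(only_a, selA$gene_id)],
           accession_b = NA_character_, category = "NO_COUNTERPART"),
    tibble(gene_id = only_b, accession_a = NA_character_,
           accession_b = selB$accession[match(only_b, selB$gene_id)],
           category = "NO_COUNTERPART")
  )
  summary <- pairs |>
    count(category = factor(.data$category, levels = match_categories),
          .drop = FALSE, name = "n_genes") |>
    mutate(category = as.character(.data$category),
           percent = 100 * .data$n_genes / sum(.data$n_genes))
  structure(list(pairs = pairs, summary = summary),
            class = "txh_match_report")
}

#' @export
print.txh_match_report <- function(x, ...) {
  cat(sprintf("<txh_match_report> %d gene(s)\n", nrow(x$pairs)))
  print(x$summary)
  invisible(x)
}

#' @rdname match_selected
#' @param x A `txh_match_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.txh_match_report <- function(x, ...) x$pairs

#' @rdname match_selected
#' @exportS3Method generics::glance
glance.txh_match_report <- function(x, ...) {
  wide <- setNames(as.list(x$summary$percent),
                   paste0("pct_", tolower(x$summary$category)))
  as_tibble(c(list(n_genes = nrow(x$pairs)), wide))
}

#' @rdname match_selected
#' @param object A `txh_match_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.txh_match_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$category, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Cross-source selection concordance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Tag fully matched pairs as Select
#'
#' A pair is tagged only when its category is `IDENTICAL` and the spliced
#' exonic sequences of the two models are byte-equal against the genome;
#' anything else is refused with a logged reason. Coordinate-identical
#' pairs whose sequences differ indicate an internal inconsistency and
#' raise an error.
#'
#' @param pairs Tibble with `gene_id`, `accession_a`, `accession_b`,
#'   `category` (from [match_selected()], possibly after end
#'   standardization).
#' @param setA,setB Annotation sets (modified copies are returned).
#' @param genome Named `DNAStringSet`.
#' @param tag Tag to apply (`"Select"` or `"PlusClinical"`).
#' @return `list(setA =, setB =, log =)` where `log` records per pair
#'   whether it was tagged and the refusal reason otherwise.
#' @export
tag_select_pairs <- function(pairs, setA, setB, genome, tag = "Select") {
  log <- map(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    if (is.na(p$accession_a) || is.na(p$accession_b) ||
        p$category != "IDENTICAL")
      return(tibble(gene_id = p$gene_id, tagged = FALSE,
                    reason = sprintf("category %s", p$category)))
    tA <- get_transcript(setA, p$accession_a)
    tB <- get_transcript(setB, p$accession_b)
    if (!identical(spliced_sequence(tA, genome, "exons"),
                   spliced_sequence(tB, genome, "exons")))
      abort(sprintf("internal inconsistency: %s/%s identical in coordinates but sequences differ.",
                    p$accession_a, p$accession_b))
    tA$tags <- union(tA$tags, tag)
    tB$tags <- union(tB$tags, tag)
    setA$transcripts[[tA$accession]] <<- tA
    setB$transcripts[[tB$accession]] <<- tB
    tibble(gene_id = p$gene_id, tagged = TRUE, reason = NA_character_)
  })
  list(setA = setA, setB = setB, log = list_rbind(log))
}
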