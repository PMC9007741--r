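#' Run the full harmonization workflow
#'
#' Stages, in order: per-source representative-transcript selection
#' (composite scheme for source A, hierarchical for source B by default);
#' cross-source matching and binning; end standardization of resolvable
#' pairs (`IDENTICAL` / `END_EXTENT_ONLY`) from CAGE and poly(A)
#' evidence; re-matching; Select tagging of perfectly converged pairs;
#' Plus Clinical nomination, pairing and tagging when a variant table is
#' supplied; summary emission. Unresolved genes stay in the binning
#' report with their category.
#'
#' @param config Named list (or path to a YAML file) with entries
#'   `annotation_a`, `annotation_b`, `genome`, `coverage`, `junctions`,
#'   `conservation`, `flags` (paths); optional `ctss`, `polya`,
#'   `variants`, `gene_map`, `out_dir`, `scheme_a`, `scheme_b`, and
#'   `params` (a [txh_params()] or a list of overrides).
#' @return A list of class `txh_workflow` with the selections, the
#'   initial and final match reports, the end-update log, nominations,
#'   the tagged annotation sets, and the `summary` tibble (one row per
#'   tagged transcript pair: `gene_id`, `symbol`, `accession_a`,
#'   `accession_b`, `tag`, `contig`, `start`, `end`, `strand`). Has
#'   [tidy()] and [glance()] methods.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- config$params %||% txh_params()
  if (!inherits(params, "txh_params")) params <- do.call(txh_params, params)
  need <- c("annotation_a", "annotation_b", "genome", "coverage",
            "junctions", "conservation", "flags")
  missing <- setdiff(need, names(config))
  if (length(missing))
    abort(paste0("config lacks required entries: ",
                 paste(missing, collapse = ", ")))

  setA <- read_annotation(config$annotation_a, "sourceA")
  setB <- read_annotation(config$annotation_b, "sourceB")
  genome <- read_genome(config$genome)
  evidence <- evidence_bundle(
    read_expression(config$coverage, config$junctions),
    read_conservation(config$conservation),
    read_flags(config$flags)
  )
  cage <- if (!is.null(config$ctss)) read_site_track(config$ctss, "CAGE_CTSS")
          else site_track(character(), integer(), character(), numeric())
  polya <- if (!is.null(config$polya)) read_site_track(config$polya, "POLYA")
           else site_track(character(), integer(), character(), numeric(),
                           "POLYA")
  gene_map <- if (!is.null(config$gene_map))
    readr::read_tsv(config$gene_map, col_types = "cc", progress = FALSE)
  variants <- if (!is.null(config$variants)) read_variants(config$variants)

  # (1) per-source selection
  selA <- select_transcripts(setA, evidence, params,
                             config$scheme_a %||% "composite")
  selB <- select_transcripts(setB, evidence, params,
                             config$scheme_b %||% "hierarchical")

  # (2) matching and binning
  match_initial <- match_selected(selA, selB, setA, setB, gene_map)

  # (3) end standardization of resolvable pairs
  updates <- list()
  pairs <- match_initial$pairs
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    if (!p$category %in% c("IDENTICAL", "END_EXTENT_ONLY")) next
    std <- standardize_pair(get_transcript(setA, p$accession_a),
                            get_transcript(setB, p$accession_b),
                            cage, polya, params)
    setA$transcripts[[std$a$accession]] <- std$a
    setB$transcripts[[std$b$accession]] <- std$b
    updates[[length(updates) + 1]] <- mutate(std$updates, gene_id = p$gene_id)
  }
  updates <- if (length(updates)) list_rbind(updates) else
    tibble(accession = character(), end = character(), old_pos = integer(),
           new_pos = integer(), cluster_id = character(),
           applied = logical(), reason = character(), gene_id = character())

  # (4) re-match and Select tagging
  match_final <- match_selected(selA, selB, setA, setB, gene_map)
  tagged <- tag_select_pairs(match_final$pairs, setA, setB, genome, "Select")
  setA <- tagged$setA; setB <- tagged$setB

  # (5) Plus Clinical
  nominations <- list()
  pc_log <- list()
  if (!is.null(variants)) {
    sel_pairs <- match_final$pairs[match_final$pairs$category == "IDENTICAL", ]
    for (i in seq_len(nrow(sel_pairs))) {
      p <- sel_pairs[i, ]
      unc <- uncovered_variants(setA, p$gene_id, p$accession_a, variants,
                                evidence$conservation, params)
      sel <- get_transcript(setA, p$accession_a)
      gene_plp <- filter_plp(variants)
      gene_plp <- gene_plp[gene_plp$contig == sel$contig, ]
      if (nrow(unc) == 0 && nrow(gene_plp) == 0) next
      nom <- nominate(setA, p$gene_id, unc, all_plp = gene_plp,
                      evidence = evidence)
      if (nrow(nom$nominations) == 0) next
      nominations[[length(nominations) + 1]] <- nom
      pc <- pair_plus_clinical(nom, setA, setB, genome, cage, polya, params)
      setA <- pc$setA; setB <- pc$setB
      pc_log[[length(pc_log) + 1]] <- mutate(pc$log, gene_id = p$gene_id)
    }
  }
  pc_log <- if (length(pc_log)) list_rbind(pc_log) else
    tibble(accession_a = character(), accession_b = character(),
           paired = logical(), reason = character(), gene_id = character())

  # (6) summary
  summary <- workflow_summary(setA, setB, match_final$pairs, pc_log)
  res <- structure(list(
    selections_a = selA, selections_b = selB,
    match_initial = match_initial, match_final = match_final,
    end_updates = updates, select_log = tagged$log,
    nominations = nominations, plus_clinical_log = pc_log,
    setA = setA, setB = setB, summary = summary, params = params
  ), class = "txh_workflow")
  if (!is.null(config$out_dir)) write_workflow(res, config$out_dir)
  res
}

workflow_summary <- function(setA, setB, pairs, pc_log) {
  rows <- list()
  add_row <- function(gene_id, accA, accB, tag) {
    tA <- get_transcript(setA, accA)
    tB <- get_transcript(setB, accB)
    symbol <- setA$genes$symbol[match(gene_id, setA$genes$gene_id)]
    rows[[length(rows) + 1]] <<- tibble(
      gene_id = gene_id, symbol = symbol,
      accession_a = versioned_accession(tA),
      accession_b = versioned_accession(tB),
      tag = tag, contig = tA$contig, start = min(tA$exons$start),
      end = max(tA$exons$end), strand = tA$strand)
  }
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    if (is.na(p$accession_a) || is.na(p$accession_b)) next
    tA <- get_transcript(setA, p$accession_a)
    if ("Select" %in% tA$tags) add_row(p$gene_id, p$accession_a,
                                       p$accession_b, "Select")
  }
  for (i in seq_len(nrow(pc_log))) {
    p <- pc_log[i, ]
    if (isTRUE(p$paired)) add_row(p$gene_id, p$accession_a, p$accession_b,
                                  "PlusClinical")
  }
  out <- if (length(rows)) list_rbind(rows) else
    tibble(gene_id = character(), symbol = character(),
           accession_a = character(), accession_b = character(),
           tag = character(), contig = character(), start = integer(),
           end = integer(), strand = character())
  sel <- out[out$tag == "Select", ]
  if (anyDuplicated(sel$gene_id))
    abort("internal error: more than one Select per gene in the summary.")
  dup <- intersect(sel$accession_a, out$accession_a[out$tag == "PlusClinical"])
  if (length(dup))
    abort("internal error: Select and PlusClinical share an accession.")
  out
}

write_workflow <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$summary, file.path(out_dir, "summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$match_initial$pairs,
                   file.path(out_dir, "match_initial.tsv"), progress = FALSE)
  readr::write_tsv(res$match_final$pairs,
                   file.path(out_dir, "match_final.tsv"), progress = FALSE)
  readr::write_tsv(res$end_updates, file.path(out_dir, "end_updates.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$plus_clinical_log,
                   file.path(out_dir, "plus_clinical.tsv"), progress = FALSE)
  counts <- glance(res)
  jsonlite::write_json(as.list(counts), file.path(out_dir, "counts.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.txh_workflow <- function(x, ...) {
  cat(sprintf("<txh_workflow> %d gene(s); %d Select, %d PlusClinical pair(s)\n",
              nrow(x$match_final$pairs),
              sum(x$summary$tag == "Select"),
              sum(x$summary$tag == "PlusClinical")))
  print(x$match_final$summary)
  invisible(x)
}

#' @rdname run_workflow
#' @param x,object A `txh_workflow`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.txh_workflow <- function(x, ...) x$summary

#' @rdname run_workflow
#' @exportS3Method generics::glance
glance.txh_workflow <- function(object, ...) {
  cats <- object$match_final$summary
  wide <- setNames(as.list(cats$n_genes),
                   paste0("n_", tolower(cats$category)))
  as_tibble(c(list(
    n_genes = nrow(object$match_final$pairs),
    n_select = sum(object$summary$tag == "Select"),
    n_plus_clinical = sum(object$summary$tag == "PlusClinical"),
    n_end_updates = sum(object$end_updates$applied)
  ), wide))
}
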