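qa_codes <- c("CDS_NOT_MULTIPLE_OF_3", "MISSING_START_CODON",
              "MISSING_STOP_CODON", "INTERNAL_STOP",
              "NONCANONICAL_SPLICE", "CDS_OUTSIDE_EXONS")

stop_codons <- c("TAA", "TAG", "TGA")

#' Quality-assurance checks for one transcript
#'
#' Applies the structural and sequence-level sanity checks used to flag
#' discrepancies before a transcript can be tagged: CDS length a multiple
#' of 3, ATG at the CDS start, a stop codon at the CDS end, no in-frame
#' internal stop, canonical GT..AG introns (optional), and CDS containment
#' within the exons. An empty result means the transcript passes.
#'
#' @param t A `txh_transcript`.
#' @param genome Named `DNAStringSet` covering the transcript's contig.
#' @param check_splice Also require canonical GT..AG intron boundaries.
#' @return A tibble with columns `accession`, `code`, `detail`; zero rows
#'   when clean.
#' @export
#' @examples
#' \dontrun{
#' qa_checks(get_transcript(set, "T1"), genome)
#' }
qa_checks <- function(t, genome, check_splice = TRUE) {
  flags <- list()
  add <- function(code, detail)
    flags[[length(flags) + 1]] <<- tibble(accession = t$accession,
                                          code = code, detail = detail)
  if (is.null(t$cds))
    return(tibble(accession = character(), code = character(),
                  detail = character()))
  if (!chain_contains(t$exons, t$cds))
    add("CDS_OUTSIDE_EXONS", "CDS bases fall outside the exon chain")
  cds_len <- chain_width(t$cds)
  if (cds_len %% 3 != 0)
    add("CDS_NOT_MULTIPLE_OF_3", sprintf("CDS length %d", cds_len))
  cds_seq <- spliced_sequence(t, genome, "cds")
  if (substr(cds_seq, 1, 3) != "ATG")
    add("MISSING_START_CODON",
        sprintf("CDS starts with %s", substr(cds_seq, 1, 3)))
  n_codons <- nchar(cds_seq) %/% 3
  if (n_codons >= 1) {
    codons <- substring(cds_seq, seq(1, by = 3, length.out = n_codons),
                        seq(3, by = 3, length.out = n_codons))
    if (!t$cds_includes_stop || !codons[n_codons] %in% stop_codons)
      add("MISSING_STOP_CODON",
          sprintf("CDS ends with %s", codons[n_codons]))
    internal <- codons[-n_codons] %in% stop_codons
    if (any(internal))
      add("INTERNAL_STOP",
          sprintf("stop codon at codon %s",
                  paste(which(internal), collapse = ",")))
  }
  if (check_splice && nrow(t$exons) > 1) {
    introns <- chain_introns(t$exons)
    ctg <- genome[[t$contig]]
    for (i in seq_len(nrow(introns))) {
      s <- introns$start[i]; e <- introns$end[i]
      left <- as.character(Biostrings::subseq(ctg, s + 1L, s + 2L))
      right <- as.character(Biostrings::subseq(ctg, e - 1L, e))
      ok <- if (t$strand == "+") left == "GT" && right == "AG"
            else left == "CT" && right == "AC"
      if (!ok)
        add("NONCANONICAL_SPLICE",
            sprintf("intron %d [%d,%d) is not GT..AG", i, s, e))
    }
  }
  if (!length(flags))
    return(tibble(accession = character(), code = character(),
                  detail = character()))
  list_rbind(flags)
}

#' QA checks over a whole annotation set
#'
#' @param set A `txh_annotation`.
#' @param genome Named `DNAStringSet`.
#' @param check_splice Passed to [qa_checks()].
#' @return A tibble of flags across all transcripts.
#' @export
qa_checks_set <- function(set, genome, check_splice = TRUE) {
  out <- map(unname(set$transcripts), qa_checks, genome = genome,
             check_splice = check_splice)
  list_rbind(out)
}
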