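#' Extract TSS-centred windows from an annotation set
#'
#' For each accession, takes the `scan_window`-long genomic sequence
#' centred on the transcript's 5' terminal nucleotide, strand-normalized
#' so transcription reads left to right. Index `scan_window/2 + 1` is
#' position +1 (the TSS base); there is no position 0, and -1 is the base
#' immediately 5' of +1.
#'
#' @param set A `txh_annotation`.
#' @param accessions Accessions to extract (default: all).
#' @param genome Named `DNAStringSet`.
#' @param params A [txh_params()] (uses `scan_window`).
#' @return A tibble (`accession`, `seq`) of class `txh_windows` with the
#'   TSS index in the `"tss_index"` attribute. Transcripts whose window
#'   would leave the contig are skipped with a message.
#' @export
extract_tss_windows <- function(set, genome, accessions = NULL,
                                params = txh_params()) {
  accessions <- accessions %||% names(set$transcripts)
  half <- params$scan_window %/% 2L
  rows <- map(accessions, function(acc) {
    t <- get_transcript(set, acc)
    p <- terminal_info(t, "five_prime")$pos
    ctg <- genome[[t$contig]]
    if (t$strand == "+") { s <- p - half; e <- p + half }
    else { s <- p - half + 1L; e <- p + half + 1L }
    if (s < 0 || e > length(ctg)) {
      inform(sprintf("extract_tss_windows: %s window leaves the contig; skipped.", acc))
      return(NULL)
    }
    sq <- as.character(Biostrings::subseq(ctg, s + 1L, e))
    if (t$strand == "-")
      sq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    tibble(accession = acc, seq = sq)
  })
  out <- list_rbind(rows)
  if (is.null(out) || nrow(out) == 0)
    out <- tibble(accession = character(), seq = character())
  attr(out, "tss_index") <- half + 1L
  class(out) <- c("txh_windows", class(out))
  out
}

#' Build a window set from raw sequences
#'
#' @param seqs Character vector of equal-length windows.
#' @param tss_index 1-based index of the +1 base (default: midpoint + 1).
#' @return A `txh_windows` tibble.
#' @export
tss_windows <- function(seqs, tss_index = NULL) {
  L <- unique(nchar(seqs))
  if (length(L) > 1) abort("all windows must have the same length.")
  out <- tibble(accession = sprintf("w%d", seq_along(seqs)), seq = seqs)
  attr(out, "tss_index") <- tss_index %||% (L %/% 2L + 1L)
  class(out) <- c("txh_windows", class(out))
  out
}

window_offsets <- function(L, tss_index) {
  i <- seq_len(L)
  i - tss_index + as.integer(i >= tss_index)
}

#' Positional nucleotide frequencies and purine enrichment
#'
#' Per window position, base frequencies over A/C/G/T among non-N bases
#' (each defined row sums to 1); plus the purine (A or G) fraction at
#' position +1, the signature of RNA polymerase II initiation.
#'
#' @param windows A `txh_windows` tibble.
#' @return A list of class `txh_profile`: `profile` (tibble with
#'   `offset`, `A`, `C`, `G`, `T`, `n`; all-N columns have `n = 0` and
#'   `NA` frequencies) and `purine_fraction_plus1`.
#' @export
nucleotide_profile <- function(windows) {
  if (nrow(windows) == 0) abort("empty window set.")
  tss_index <- attr(windows, "tss_index")
  mat <- do.call(rbind, strsplit(toupper(windows$seq), ""))
  L <- ncol(mat)
  freq <- map(seq_len(L), function(j) {
    col <- mat[, j]
    ok <- col %in% DNA
    n <- sum(ok)
    if (n == 0) return(c(A = NA_real_, C = NA_real_, G = NA_real_,
                         T = NA_real_, n = 0))
    tab <- table(factor(col[ok], levels = DNA)) / n
    c(tab, n = n)
  })
  prof <- as_tibble(do.call(rbind, freq))
  prof$offset <- window_offsets(L, tss_index)
  prof <- select(prof, "offset", "A", "C", "G", "T", "n")
  at1 <- prof[prof$offset == 1L, ]
  structure(list(profile = prof,
                 purine_fraction_plus1 = at1$A + at1$G),
            class = "txh_profile")
}

#' Compare promoter signatures of two TSS window sets
#'
#' For each set: the purine fraction at +1, the fraction of windows with
#' a qualifying TATA-box hit starting in `tata_band`, and the fraction
#' with a qualifying initiator hit starting in `inr_band`. Scanning uses
#' [scan_best_match()] with the set's own empirical base composition as
#' background (or uniform).
#'
#' @param before,after `txh_windows` tibbles (e.g. original versus
#'   end-standardized TSSs).
#' @param pwms Named list with elements `tata` and `inr`, each a
#'   `txh_pwm`.
#' @param params A [txh_params()].
#' @param tata_band,inr_band Inclusive offset bands for the motif start.
#' @param background `"empirical"` or `"uniform"`.
#' @return A list of class `txh_signature_report` with a `metrics` tibble
#'   (`metric`, `before`, `after`, `difference`) and the per-window hit
#'   tables. Has a [tidy()] method.
#' @export
signature_report <- function(before, after, pwms, params = txh_params(),
                             tata_band = c(-35L, -25L),
                             inr_band = c(-3L, 3L),
                             background = c("empirical", "uniform")) {
  background <- match.arg(background)
  if (nrow(before) == 0 || nrow(after) == 0)
    abort("both window sets must be non-empty.")
  if (!all(c("tata", "inr") %in% names(pwms)))
    abort("`pwms` must contain elements 'tata' and 'inr'.")
  eval_set <- function(windows) {
    tssi <- attr(windows, "tss_index")
    bg <- if (background == "uniform") setNames(rep(0.25, 4), DNA)
          else empirical_background(windows$seq)
    hit_frac <- function(pwm, band) {
      lo <- log_odds(pwm, params$pwm_scale, bg)
      tbl <- score_pvalue_table(lo)
      hits <- map(windows$seq, function(s)
        scan_best_match(s, pwm, params, background = bg,
                        pvalue_table = tbl, tss_index = tssi))
      hits <- list_rbind(hits)
      frac <- if (nrow(hits) == 0) 0 else
        sum(hits$offset >= band[1] & hits$offset <= band[2]) / nrow(windows)
      list(frac = frac, hits = hits)
    }
    tata <- hit_frac(pwms$tata, tata_band)
    inr <- hit_frac(pwms$inr, inr_band)
    list(purine = nucleotide_profile(windows)$purine_fraction_plus1,
         tata_frac = tata$frac, inr_frac = inr$frac,
         tata_hits = tata$hits, inr_hits = inr$hits)
  }
  b <- eval_set(before); a <- eval_set(after)
  metrics <- tibble(
    metric = c("purine_fraction_plus1", "tata_fraction", "inr_fraction"),
    before = c(b$purine, b$tata_frac, b$inr_frac),
    after = c(a$purine, a$tata_frac, a$inr_frac)
  )
  metrics$difference <- metrics$after - metrics$before
  structure(list(metrics = metrics,
                 before_hits = list(tata = b$tata_hits, inr = b$inr_hits),
                 after_hits = list(tata = a$tata_hits, inr = a$inr_hits)),
            class = "txh_signature_report")
}

empirical_background <- function(seqs) {
  chars <- unlist(strsplit(toupper(paste(seqs, collapse = "")), ""))
  chars <- chars[chars %in% DNA]
  tab <- table(factor(chars, levels = DNA))
  p <- as.numeric(tab) / sum(tab)
  p[p == 0] <- 1e-6          # guard degenerate compositions
  setNames(p / sum(p), DNA)
}

#' @export
print.txh_signature_report <- function(x, ...) {
  cat("<txh_signature_report>\n")
  print(x$metrics)
  invisible(x)
}

#' @rdname signature_report
#' @param x A `txh_signature_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.txh_signature_report <- function(x, ...) x$metrics

#' @rdname signature_report
#' @param object A `txh_signature_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.txh_signature_report <- function(object, ...) {
  long <- pivot_longer(object$metrics, c("before", "after"),
                       names_to = "set", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of windows",
                  title = "Promoter signatures before/after end standardization") +
    ggplot2::theme_minimal()
}
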