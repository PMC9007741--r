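DNA <- c("A", "C", "G", "T")

#' Build a position weight matrix
#'
#' @param counts 4-by-width numeric matrix of base counts (or
#'   probabilities) with rownames A, C, G, T.
#' @param background Named background probability vector over A/C/G/T
#'   (default uniform).
#' @param pseudocount Added to every count before column normalization so
#'   all probabilities are strictly positive.
#' @return A list of class `txh_pwm` with `width`, `probs` (columns sum
#'   to 1), `background`, `pseudocount`.
#' @export
pwm_matrix <- function(counts, background = NULL, pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) == 4) rownames(counts) <- DNA
  if (!identical(sort(rownames(counts)), DNA))
    abort("`counts` must have rownames A, C, G, T.")
  counts <- counts[DNA, , drop = FALSE]
  if (any(counts < 0)) abort("counts must be non-negative.")
  probs <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  if (any(probs <= 0))
    abort("zero probability after pseudocount; use a positive pseudocount.")
  background <- background %||% setNames(rep(0.25, 4), DNA)
  background <- background[DNA] / sum(background[DNA])
  structure(list(width = ncol(probs), probs = probs,
                 background = background, pseudocount = pseudocount),
            class = "txh_pwm")
}

#' @export
print.txh_pwm <- function(x, ...) {
  cat(sprintf("<txh_pwm> width %d, pseudocount %g\n", x$width, x$pseudocount))
  print(round(x$probs, 3))
  invisible(x)
}

#' Read JASPAR-format matrices
#'
#' Parses the JASPAR text format (`>ID name` header followed by four
#' `A [ ... ]` rows). Also accepts the bracket-free variant.
#'
#' @param path File with one or more matrices.
#' @return A named list of count matrices (4 rows A/C/G/T), suitable for
#'   [pwm_matrix()].
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) abort("no '>' header in JASPAR file.")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    name <- strsplit(sub("^>", "", lines[heads[k]]), "\\s+")[[1]][1]
    rows <- map(block, function(l) {
      base <- toupper(sub("^\\s*([ACGTacgt]).*", "\\1", l))
      nums <- as.numeric(strsplit(trimws(gsub("[][]", " ",
                                              sub("^\\s*[ACGTacgt]", "", l))),
                                  "\\s+")[[1]])
      list(base = base, nums = nums)
    })
    m <- do.call(rbind, map(rows, "nums"))
    rownames(m) <- map_chr(rows, "base")
    if (!setequal(rownames(m), DNA))
      abort(sprintf("matrix %s lacks the four A/C/G/T rows.", name))
    out[[name]] <- m[DNA, , drop = FALSE]
  }
  out
}

#' Integer-scaled log-odds scoring matrix
#'
#' `score(pos, base) = round(scale * log2(p(pos, base) / background(base)))`.
#' The integer lattice makes the exact p-value convolution in
#' [score_pvalue_table()] possible; the scale bounds the granularity.
#'
#' @param pwm A `txh_pwm`.
#' @param scale Integer scale (default 1000).
#' @param background Optional override of the PWM's background.
#' @return A 4-by-width integer matrix with rownames A/C/G/T and the
#'   background stored in the `"background"` attribute.
#' @export
log_odds <- function(pwm, scale = 1000L, background = NULL) {
  bg <- background %||% pwm$background
  bg <- bg[DNA] / sum(bg[DNA])
  if (any(pwm$probs <= 0)) abort("PWM has zero probabilities.")
  m <- round(scale * log2(sweep(pwm$probs, 1, bg, "/")))
  storage.mode(m) <- "integer"
  attr(m, "background") <- bg
  attr(m, "scale") <- scale
  m
}

#' Exact null distribution of PWM word scores
#'
#' Builds the distribution of the total score of a random word under the
#' i.i.d. background by positional convolution over the integer score
#' lattice, and returns its survival function: for each attainable score
#' `s`, `P(random word scores >= s)`.
#'
#' @param matrix Integer scoring matrix from [log_odds()].
#' @param background Named background probabilities (defaults to the
#'   matrix's own attribute).
#' @return A tibble (`score`, `prob`, `pvalue`) sorted by score, of class
#'   `txh_pvalue_table`.
#' @export
score_pvalue_table <- function(matrix, background = NULL) {
  bg <- background %||% attr(matrix, "background")
  bg <- bg[DNA] / sum(bg[DNA])
  dist <- c("0" = 1)
  for (j in seq_len(ncol(matrix))) {
    keys <- as.integer(names(dist))
    s <- matrix[, j]
    newkeys <- as.vector(outer(keys, s, "+"))
    newprob <- as.vector(outer(unname(dist), unname(bg), "*"))
    agg <- tapply(newprob, newkeys, sum)
    dist <- setNames(as.numeric(agg), names(agg))
  }
  sc <- as.integer(names(dist))
  o <- order(sc)
  sc <- sc[o]; pr <- unname(dist[o])
  out <- tibble(score = sc, prob = pr,
                pvalue = rev(cumsum(rev(pr))))
  class(out) <- c("txh_pvalue_table", class(out))
  out
}

# P(random word >= score) from a table; exact for attainable scores,
# conservative (next attainable score up) otherwise.
pwm_pvalue <- function(table, score) {
  i <- which(table$score >= score)
  if (!length(i)) return(0)
  table$pvalue[i[1]]
}

#' Best PWM match within one window
#'
#' Forward-strand scan at every offset of the (strand-normalized) window;
#' the highest-scoring offset is reported iff its exact p-value is at
#' most `motif_p_threshold`. Words containing non-A/C/G/T characters are
#' skipped; score ties go to the 5'-most offset. The reported offset is
#' relative to the TSS under the no-position-zero convention (-1 abuts
#' +1).
#'
#' @param window A single window string (see [extract_tss_windows()]).
#' @param pwm A `txh_pwm`.
#' @param params A [txh_params()] (uses `pwm_scale`, `motif_p_threshold`).
#' @param background Optional background override (defaults to the PWM's).
#' @param pvalue_table Optional precomputed [score_pvalue_table()] (must
#'   match `background`).
#' @param tss_index 1-based index of the +1 base in the window (defaults
#'   to `nchar(window)/2 + 1`).
#' @return A one-row tibble (`offset`, `start_index`, `score`, `pvalue`)
#'   or a zero-row tibble when no offset qualifies.
#' @export
scan_best_match <- function(window, pwm, params = txh_params(),
                            background = NULL, pvalue_table = NULL,
                            tss_index = NULL) {
  lo <- log_odds(pwm, params$pwm_scale, background)
  if (is.null(pvalue_table)) pvalue_table <- score_pvalue_table(lo)
  tss_index <- tss_index %||% (nchar(window) %/% 2L + 1L)
  L <- nchar(window); w <- pwm$width
  none <- tibble(offset = integer(), start_index = integer(),
                 score = integer(), pvalue = numeric())
  if (L < w) abort("window shorter than the PWM.")
  chars <- strsplit(toupper(window), "")[[1]]
  base_idx <- match(chars, DNA)
  n_off <- L - w + 1L
  scores <- rep(NA_integer_, n_off)
  for (i in seq_len(n_off)) {
    idx <- base_idx[i:(i + w - 1L)]
    if (anyNA(idx)) next
    scores[i] <- sum(lo[cbind(idx, seq_len(w))])
  }
  if (all(is.na(scores))) return(none)
  best <- which(scores == max(scores, na.rm = TRUE))[1]
  p <- pwm_pvalue(pvalue_table, scores[best])
  if (p > params$motif_p_threshold) return(none)
  off <- best - tss_index + as.integer(best >= tss_index)
  tibble(offset = as.integer(off), start_index = as.integer(best),
         score = scores[best], pvalue = p)
}
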