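#' Construct a transcript model
#'
#' A transcript model holds the exon chain, the optional CDS chain, and the
#' bookkeeping needed for cross-source matching. Internally the CDS chain
#' includes the stop codon; the GTF writer splits the stop codon back out
#' per the Ensembl dialect convention (see [write_annotation()]).
#'
#' @param accession Transcript accession, optionally suffixed
#'   `".<version>"`; the version is split off (default 1 when absent).
#' @param gene_id Gene identifier the transcript belongs to.
#' @param exons Exon chain built by [exon_chain()].
#' @param cds CDS chain, or `NULL` for a non-coding transcript. Must be
#'   contained within `exons` base-by-base.
#' @param source Source label (e.g. `"sourceA"`).
#' @param tags Character vector of tags (e.g. `"Select"`, `"PlusClinical"`).
#' @param cds_includes_stop Does the stored CDS chain cover the stop codon?
#'   `FALSE` models annotations lacking a stop-codon feature; QA checks
#'   flag these.
#' @param attrs Named character vector of opaque attributes preserved
#'   across read/write.
#' @return A list of class `txh_transcript`.
#' @export
transcript_model <- function(accession, gene_id, exons, cds = NULL,
                             source = "sourceA", tags = character(),
                             cds_includes_stop = TRUE,
                             attrs = character()) {
  ver <- 1L
  acc <- accession
  m <- regmatches(accession, regexec("^(.*)\\.([0-9]+)$", accession))[[1]]
  if (length(m) == 3) {
    acc <- m[2]
    ver <- as.integer(m[3])
  }
  validate_chain(exons)
  if (!is.null(cds)) {
    validate_chain(cds)
    if (!chain_contains(exons, cds))
      abort(sprintf("transcript %s: CDS is not contained in its exons.", acc))
    if (cds$contig[1] != exons$contig[1] || cds$strand[1] != exons$strand[1])
      abort(sprintf("transcript %s: CDS contig/strand differ from exons.", acc))
  }
  structure(list(accession = acc, version = ver, gene_id = gene_id,
                 contig = exons$contig[1] %||% NA_character_,
                 strand = exons$strand[1] %||% NA_character_,
                 exons = exons, cds = cds, source = source, tags = tags,
                 cds_includes_stop = cds_includes_stop, attrs = attrs),
            class = "txh_transcript")
}

#' @export
print.txh_transcript <- function(x, ...) {
  cat(sprintf("<txh_transcript> %s.%d (%s) %s:%s %d exon(s)%s%s\n",
              x$accession, x$version, x$gene_id, x$contig, x$strand,
              nrow(x$exons),
              if (is.null(x$cds)) ", non-coding"
              else sprintf(", CDS %d nt", chain_width(x$cds)),
              if (length(x$tags)) paste0(" [", paste(x$tags, collapse = ","), "]")
              else ""))
  invisible(x)
}

versioned_accession <- function(t) sprintf("%s.%d", t$accession, t$version)

#' Construct an annotation set
#'
#' @param transcripts List of [transcript_model()] objects. Accessions must
#'   be unique within the set.
#' @param genes Tibble with columns `gene_id` and `symbol`. Defaults to one
#'   row per distinct `gene_id` seen in `transcripts`, with the id as
#'   symbol.
#' @param source Source label applied to the whole set.
#' @param assembly Assembly name (free text).
#' @param dialect Dialect the set was read from (`"gtf"` or `"gff3"`),
#'   re-used as the default on write.
#' @return A list of class `txh_annotation`.
#' @export
annotation_set <- function(transcripts, genes = NULL, source = "sourceA",
                           assembly = "synthetic", dialect = "gtf") {
  accs <- map_chr(transcripts, "accession")
  if (anyDuplicated(accs))
    abort(paste0("duplicate transcript accessions: ",
                 paste(unique(accs[duplicated(accs)]), collapse = ", ")))
  names(transcripts) <- accs
  gids <- unique(map_chr(transcripts, "gene_id"))
  if (is.null(genes)) genes <- tibble(gene_id = gids, symbol = gids)
  missing <- setdiff(gids, genes$gene_id)
  if (length(missing))
    abort(paste0("transcripts reference unknown gene_id(s): ",
                 paste(missing, collapse = ", ")))
  structure(list(genes = genes, transcripts = transcripts, source = source,
                 assembly = assembly, dialect = dialect),
            class = "txh_annotation")
}

#' @export
print.txh_annotation <- function(x, ...) {
  cat(sprintf("<txh_annotation> source=%s: %d gene(s), %d transcript(s)\n",
              x$source, nrow(x$genes), length(x$transcripts)))
  invisible(x)
}

#' Flatten an annotation set to a feature tibble
#'
#' One row per exon or CDS interval, 0-based half-open coordinates.
#'
#' @param x An annotation set.
#' @param ... Unused.
#' @return A tibble with columns `contig`, `start`, `end`, `strand`,
#'   `type`, `gene_id`, `accession`, `version`, `source`.
#' @exportS3Method tibble::as_tibble
as_tibble.txh_annotation <- function(x, ...) {
  rows <- map(x$transcripts, function(t) {
    ex <- mutate(t$exons, type = "exon")
    cd <- if (is.null(t$cds)) NULL else mutate(t$cds, type = "CDS")
    feats <- bind_rows(ex, cd)
    mutate(feats, gene_id = t$gene_id, accession = t$accession,
           version = t$version, source = t$source)
  })
  out <- list_rbind(unname(rows))
  class(out) <- class(tibble())
  out
}

#' Fetch one transcript from an annotation set
#'
#' @param set An annotation set.
#' @param accession Accession, with or without a `.version` suffix.
#' @return A `txh_transcript`.
#' @export
get_transcript <- function(set, accession) {
  acc <- sub("\\.[0-9]+$", "", accession)
  t <- set$transcripts[[acc]]
  if (is.null(t)) t <- set$transcripts[[accession]]
  if (is.null(t)) abort(sprintf("no transcript '%s' in set '%s'.",
                                accession, set$source))
  t
}

gene_transcripts <- function(set, gene_id) {
  keep(set$transcripts, ~ .x$gene_id == gene_id)
}

# ---- parsing ----------------------------------------------------------------

#' Read a GTF or GFF3 annotation file
#'
#' Coordinates are converted to the package's internal 0-based half-open
#' convention. For GTF input, `stop_codon` features are folded into the CDS
#' chain (the Ensembl GTF dialect excludes the stop codon from CDS
#' features); GFF3 CDS features are taken as stop-inclusive. A transcript
#' whose GTF CDS has no stop-codon feature keeps a stop-exclusive chain and
#' is flagged by [qa_checks()] downstream. Unknown feature types are
#' ignored with a message.
#'
#' @param path Path to the annotation file.
#' @param source_label Label recorded on the resulting set and each model.
#' @param dialect `"gtf"`, `"gff3"`, or `"auto"` (by file extension).
#' @return A `txh_annotation`.
#' @export
read_annotation <- function(path, source_label = "sourceA",
                            dialect = c("auto", "gtf", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  check_annotation_lines(path)
  gr <- rtracklayer::import(path, format = dialect)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  feats <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type)
  )
  feats$gene_id <- attr_col(mc, "gene_id")
  feats$transcript_id <- attr_col(mc, "transcript_id")
  feats$id <- attr_col(mc, "ID")
  feats$parent <- attr_col(mc, "Parent")
  feats$gene_name <- attr_col(mc, "gene_name")

  tx_types <- c("transcript", "mRNA")
  part_types <- c("exon", "CDS", "stop_codon")
  known <- c("gene", tx_types, part_types)
  n_unknown <- sum(!feats$type %in% known)
  if (n_unknown > 0)
    inform(sprintf("read_annotation: ignored %d feature(s) of unknown type.",
                   n_unknown))

  gene_rows <- feats[feats$type == "gene", ]
  genes <- tibble(
    gene_id = dplyr::coalesce(gene_rows$gene_id, gene_rows$id),
    symbol = dplyr::coalesce(gene_rows$gene_name,
                             gene_rows$gene_id, gene_rows$id)
  )
  tx_rows <- feats[feats$type %in% tx_types, ]
  tx_rows$key <- dplyr::coalesce(tx_rows$transcript_id, tx_rows$id)
  tx_rows$gene_key <- dplyr::coalesce(tx_rows$gene_id, tx_rows$parent)

  parts <- feats[feats$type %in% part_types, ]
  parts$key <- dplyr::coalesce(parts$transcript_id, parts$parent)
  if (anyNA(parts$key))
    abort("exon/CDS feature lacks both transcript_id and Parent.")

  transcripts <- map(seq_len(nrow(tx_rows)), function(i) {
    key <- tx_rows$key[i]
    p <- parts[parts$key == key, ]
    ex <- p[p$type == "exon", ]
    if (nrow(ex) == 0)
      abort(sprintf("transcript %s has no exon features.", key))
    if (any(ex$contig != tx_rows$contig[i]))
      abort(sprintf("structural error: exon of %s on a different contig than its transcript.", key))
    exch <- exon_chain(ex$contig[1], ex$start, ex$end, ex$strand[1])
    cd <- p[p$type %in% c("CDS", "stop_codon"), ]
    has_stop <- any(p$type == "stop_codon")
    cdch <- NULL
    if (any(cd$type == "CDS")) {
      iv <- coalesce_intervals(cd$start, cd$end)
      cdch <- exon_chain(cd$contig[1], iv$start, iv$end, cd$strand[1])
    }
    a <- tx_attrs(mc, gr, key)
    tags <- if ("tag" %in% names(a)) strsplit(a[["tag"]], ",")[[1]]
            else character()
    a <- a[setdiff(names(a), "tag")]
    transcript_model(
      accession = key, gene_id = tx_rows$gene_key[i], exons = exch,
      cds = cdch, source = source_label, tags = tags,
      cds_includes_stop = if (dialect == "gtf") has_stop else TRUE,
      attrs = a
    )
  })
  annotation_set(transcripts, genes = genes, source = source_label,
                 dialect = dialect)
}

# Merge bookended/overlapping intervals (used when folding stop codons into
# the CDS chain).
coalesce_intervals <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], ends[i])
    } else {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, ends[i])
    }
  }
  list(start = out_s, end = out_e)
}

attr_col <- function(mc, name) {
  if (!name %in% names(mc)) return(rep(NA_character_, nrow(mc)))
  v <- mc[[name]]
  if (is.list(v) || methods::is(v, "List"))
    v <- map_chr(as.list(v), ~ if (length(.x)) as.character(.x[[1]]) else NA_character_)
  as.character(v)
}

# Opaque attributes on the transcript line, minus the structural ones.
tx_attrs <- function(mc, gr, key) {
  structural <- c("type", "source", "score", "phase", "gene_id",
                  "transcript_id", "ID", "Parent", "gene_name")
  idx <- which(as.character(mc$type) %in% c("transcript", "mRNA") &
                 (attr_col(mc, "transcript_id") == key |
                    attr_col(mc, "ID") == key))
  if (!length(idx)) return(character())
  row <- mc[idx[1], setdiff(names(mc), structural), drop = FALSE]
  vals <- map_chr(names(row), ~ {
    v <- row[[.x]]
    if (is.list(v) || methods::is(v, "List")) v <- unlist(as.list(v))
    if (!length(v) || all(is.na(v))) NA_character_ else as.character(v[[1]])
  })
  names(vals) <- names(row)
  vals[!is.na(vals)]
}

# Pre-scan for malformed lines so errors can name the offending line.
check_annotation_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf < 8]
  if (length(bad))
    abort(sprintf("malformed annotation line %d in %s (expected >= 8 tab-separated fields).",
                  bad[1], path))
  invisible(TRUE)
}

# ---- writing ----------------------------------------------------------------

#' Write an annotation set as GTF or GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' closed convention. For GTF output the stop codon (last 3 CDS bases in
#' translation order, possibly split across introns) is emitted as
#' `stop_codon` features and excluded from the CDS features; GFF3 CDS
#' features are written stop-inclusive. `parse(write(x))` is structurally
#' identical to `x` for both dialects.
#'
#' @param set A `txh_annotation`.
#' @param path Output path.
#' @param dialect `"gtf"` or `"gff3"`; defaults to the set's own dialect.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(set, path, dialect = NULL) {
  dialect <- dialect %||% set$dialect
  if (!dialect %in% c("gtf", "gff3")) abort('`dialect` must be "gtf" or "gff3".')
  rows <- list()
  for (g in seq_len(nrow(set$genes))) {
    gid <- set$genes$gene_id[g]
    txs <- gene_transcripts(set, gid)
    if (!length(txs)) next
    spans <- map(txs, ~ c(min(.x$exons$start), max(.x$exons$end)))
    rows[[length(rows) + 1]] <- tibble(
      contig = txs[[1]]$contig, start = min(map_dbl(spans, 1)),
      end = max(map_dbl(spans, 2)), strand = txs[[1]]$strand,
      type = "gene", gene_id = gid, transcript_id = NA_character_,
      gene_name = set$genes$symbol[g], phase = NA_integer_,
      id = gid, parent = NA_character_, attrs = list(character())
    )
    for (t in txs) {
      acc <- versioned_accession(t)
      rows[[length(rows) + 1]] <- tibble(
        contig = t$contig, start = min(t$exons$start), end = max(t$exons$end),
        strand = t$strand, type = "transcript", gene_id = gid,
        transcript_id = acc, gene_name = NA_character_, phase = NA_integer_,
        id = acc, parent = gid,
        attrs = list(c(t$attrs,
                       if (length(t$tags)) c(tag = paste(t$tags, collapse = ","))))
      )
      rows[[length(rows) + 1]] <- tibble(
        contig = t$contig, start = t$exons$start, end = t$exons$end,
        strand = t$strand, type = "exon", gene_id = gid, transcript_id = acc,
        gene_name = NA_character_, phase = NA_integer_,
        id = NA_character_, parent = acc, attrs = list(character())
      )
      if (!is.null(t$cds)) {
        if (dialect == "gtf" && t$cds_includes_stop &&
            chain_width(t$cds) > 3) {
          sp <- split_stop_codon(t$cds)
          cds_iv <- sp$cds; stop_iv <- sp$stop
        } else {
          cds_iv <- t$cds; stop_iv <- NULL
        }
        rows[[length(rows) + 1]] <- tibble(
          contig = t$contig, start = cds_iv$start, end = cds_iv$end,
          strand = t$strand, type = "CDS", gene_id = gid, transcript_id = acc,
          gene_name = NA_character_, phase = cds_phases(cds_iv),
          id = NA_character_, parent = acc, attrs = list(character())
        )
        if (!is.null(stop_iv) && nrow(stop_iv) > 0)
          rows[[length(rows) + 1]] <- tibble(
            contig = t$contig, start = stop_iv$start, end = stop_iv$end,
            strand = t$strand, type = "stop_codon", gene_id = gid,
            transcript_id = acc, gene_name = NA_character_,
            phase = 0L, id = NA_character_, parent = acc,
            attrs = list(character())
          )
      }
    }
  }
  if (!length(rows)) {
    writeLines(if (dialect == "gff3") "##gff-version 3" else "#!txharmony gtf",
               path)
    return(invisible(path))
  }
  df <- list_rbind(rows)
  lines <- map_chr(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    a <- r$attrs[[1]]
    if (dialect == "gtf") {
      at <- sprintf('gene_id "%s";', r$gene_id)
      if (!is.na(r$transcript_id))
        at <- paste(at, sprintf('transcript_id "%s";', r$transcript_id))
      if (!is.na(r$gene_name))
        at <- paste(at, sprintf('gene_name "%s";', r$gene_name))
      if (length(a))
        at <- paste(at, paste(sprintf('%s "%s";', names(a), a), collapse = " "))
    } else {
      kv <- c(
        if (!is.na(r$id)) sprintf("ID=%s", r$id),
        if (!is.na(r$parent)) sprintf("Parent=%s", r$parent),
        sprintf("gene_id=%s", r$gene_id),
        if (!is.na(r$transcript_id)) sprintf("transcript_id=%s", r$transcript_id),
        if (!is.na(r$gene_name)) sprintf("gene_name=%s", r$gene_name),
        if (length(a)) sprintf("%s=%s", names(a), a)
      )
      at <- paste(kv, collapse = ";")
    }
    sprintf("%s\ttxharmony\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            r$contig, r$type, r$start + 1L, r$end, r$strand,
            if (is.na(r$phase)) "." else as.character(r$phase), at)
  })
  header <- if (dialect == "gff3") "##gff-version 3" else "#!txharmony gtf"
  writeLines(c(header, lines), path)
  invisible(path)
}

# Split the stop codon (last 3 bases in translation order) off a
# stop-inclusive CDS chain. Returns list(cds=, stop=) interval tibbles.
split_stop_codon <- function(cds) {
  minus <- cds$strand[1] == "-"
  iv <- cds[order(cds$start, decreasing = minus), ]  # translation order
  remaining <- 3L
  stop_s <- integer(); stop_e <- integer()
  for (i in rev(seq_len(nrow(iv)))) {   # trim from the 3' end
    if (remaining == 0) break
    w <- iv$end[i] - iv$start[i]
    take <- min(w, remaining)
    if (minus) {
      stop_s <- c(stop_s, iv$start[i]); stop_e <- c(stop_e, iv$start[i] + take)
      iv$start[i] <- iv$start[i] + take
    } else {
      stop_s <- c(stop_s, iv$end[i] - take); stop_e <- c(stop_e, iv$end[i])
      iv$end[i] <- iv$end[i] - take
    }
    remaining <- remaining - take
  }
  iv <- iv[iv$end > iv$start, ]
  o <- order(iv$start)
  so <- order(stop_s)
  list(cds = tibble(contig = cds$contig[1], start = iv$start[o],
                    end = iv$end[o], strand = cds$strand[1]),
       stop = tibble(contig = cds$contig[1], start = stop_s[so],
                     end = stop_e[so], strand = cds$strand[1]))
}

# GTF/GFF3 phase per CDS interval, in ascending genomic order.
cds_phases <- function(cds) {
  minus <- cds$strand[1] == "-"
  ord <- order(cds$start, decreasing = minus)  # translation order
  w <- (cds$end - cds$start)[ord]
  before <- c(0L, cumsum(w))[seq_along(w)]
  ph <- (3L - before %% 3L) %% 3L
  ph[order(ord)]  # back to ascending genomic order
}

# ---- sequence ---------------------------------------------------------------

#' Read a multi-contig FASTA genome
#'
#' @param path FASTA path.
#' @return A named `Biostrings::DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Spliced transcript sequence
#'
#' Concatenates the genomic substrings of the requested chain in 5'-to-3'
#' transcript order; minus-strand transcripts return the reverse
#' complement.
#'
#' @param t A `txh_transcript`.
#' @param genome Named `DNAStringSet` (see [read_genome()]).
#' @param region `"exons"` or `"cds"`.
#' @return A single character string over A/C/G/T.
#' @export
spliced_sequence <- function(t, genome, region = c("exons", "cds")) {
  region <- match.arg(region)
  ch <- if (region == "cds") t$cds else t$exons
  if (is.null(ch)) abort(sprintf("transcript %s has no CDS.", t$accession))
  if (!t$contig %in% names(genome))
    abort(sprintf("contig '%s' absent from genome.", t$contig))
  ctg <- genome[[t$contig]]
  if (any(ch$end > length(ctg)))
    abort(sprintf("interval beyond end of contig '%s' (length %d).",
                  t$contig, length(ctg)))
  pieces <- map_chr(seq_len(nrow(ch)), function(i)
    as.character(Biostrings::subseq(ctg, ch$start[i] + 1L, ch$end[i])))
  s <- paste(pieces, collapse = "")
  if (t$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}
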