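#' Read expression evidence (exon coverage + intron junctions)
#'
#' Coverage is a plain 4-column bedGraph (contig, start, end, depth);
#' junctions are BED6 whose intervals are intron coordinates and whose
#' score column carries the spanning-read count.
#'
#' @param coverage_path bedGraph path (may be empty).
#' @param junction_path BED6 path (may be empty).
#' @return A list of class `txh_expression` with tibbles `coverage`
#'   (`contig`, `start`, `end`, `depth`) and `junctions` (`contig`,
#'   `start`, `end`, `strand`, `count`).
#' @export
read_expression <- function(coverage_path, junction_path) {
  cov <- read_tsv_quiet(coverage_path,
                        c("contig", "start", "end", "depth"),
                        c("c", "i", "i", "d"))
  if (any(cov$depth < 0)) abort("negative depth in coverage bedGraph.")
  jx <- read_tsv_quiet(junction_path,
                       c("contig", "start", "end", "name", "count", "strand"),
                       c("c", "i", "i", "c", "d", "c"))
  if (any(jx$count < 0)) abort("negative junction count.")
  structure(list(coverage = cov,
                 junctions = select(jx, "contig", "start", "end",
                                    "strand", "count")),
            class = "txh_expression")
}

read_tsv_quiet <- function(path, col_names, col_abbrev) {
  types <- paste(col_abbrev, collapse = "")
  df <- readr::read_tsv(path, col_names = col_names, col_types = types,
                        comment = "#", progress = FALSE)
  as_tibble(df)
}

#' Mean read depth over an interval
#'
#' Length-weighted mean of the bedGraph segments across `[start, end)`;
#' uncovered bases count as depth 0. Overlapping segments sum.
#'
#' @param expr A `txh_expression`.
#' @param contig,start,end Query interval (0-based half-open).
#' @return A single number.
#' @export
mean_depth <- function(expr, contig, start, end) {
  seg <- expr$coverage[expr$coverage$contig == contig, ]
  if (nrow(seg) == 0) return(0)
  ov_s <- pmax(seg$start, start); ov_e <- pmin(seg$end, end)
  w <- pmax(ov_e - ov_s, 0)
  sum(w * seg$depth) / (end - start)
}

#' Look up a junction count
#'
#' @param expr A `txh_expression`.
#' @param contig,start,end Intron interval (0-based half-open).
#' @param strand Strand; `NULL` matches either.
#' @return The spanning-read count (0 when the junction is absent).
#' @export
junction_count <- function(expr, contig, start, end, strand = NULL) {
  jx <- expr$junctions
  hit <- jx$contig == contig & jx$start == start & jx$end == end
  if (!is.null(strand)) hit <- hit & jx$strand == strand
  if (!any(hit)) return(0)
  sum(jx$count[hit])
}

#' Read conservation segments
#'
#' BED6 where the score column is the conservation score and the name
#' column the reading frame (`0`, `1`, `2`, or `.` for frame-agnostic).
#' Scores above the configured threshold count as positive coding signal.
#'
#' @param path BED6 path.
#' @return A tibble (`contig`, `start`, `end`, `strand`, `score`, `frame`)
#'   of class `txh_conservation`.
#' @export
read_conservation <- function(path) {
  df <- read_tsv_quiet(path,
                       c("contig", "start", "end", "name", "score", "strand"),
                       c("c", "i", "i", "c", "d", "c"))
  out <- tibble(contig = df$contig, start = df$start, end = df$end,
                strand = df$strand, score = df$score,
                frame = ifelse(df$name %in% c("0", "1", "2"), df$name, "any"))
  out <- arrange(out, .data$contig, .data$start)
  class(out) <- c("txh_conservation", class(out))
  out
}

#' Fraction of an interval's bases under positive conservation signal
#'
#' A base is positive when any overlapping segment (any frame) scores above
#' `threshold`.
#'
#' @param cons A `txh_conservation` tibble.
#' @param contig,start,end Query interval.
#' @param threshold Score threshold (exclusive).
#' @return Fraction in `[0, 1]`.
#' @export
conserved_fraction <- function(cons, contig, start, end, threshold = 0) {
  seg <- cons[cons$contig == contig & cons$score > threshold, ]
  if (nrow(seg) == 0 || end <= start) return(0)
  pos <- rep(FALSE, end - start)
  for (i in seq_len(nrow(seg))) {
    s <- max(seg$start[i], start); e <- min(seg$end[i], end)
    if (s < e) pos[(s - start + 1):(e - start)] <- TRUE
  }
  mean(pos)
}

#' Read per-transcript selection flags
#'
#' Header TSV with columns `accession`, `appris_principal`,
#' `canonical_protein`, `clinical_use_count`.
#'
#' @param path TSV path.
#' @return A tibble of class `txh_flags`.
#' @export
read_flags <- function(path) {
  df <- readr::read_tsv(path, col_types = "clli", progress = FALSE)
  need <- c("accession", "appris_principal", "canonical_protein",
            "clinical_use_count")
  if (!all(need %in% names(df)))
    abort(paste0("flag table must have columns: ", paste(need, collapse = ", ")))
  if (any(df$clinical_use_count < 0)) abort("clinical_use_count must be >= 0.")
  out <- as_tibble(df[need])
  class(out) <- c("txh_flags", class(out))
  out
}

#' Read a stranded per-position site-count track (CAGE CTSS or poly(A))
#'
#' Five-column stranded bedGraph dialect: contig, start, end, count,
#' strand, one counted position per line (`end == start + 1`). Duplicate
#' (position, strand) lines are summed; non-positive counts are dropped
#' with a warning.
#'
#' @param path Track path.
#' @param role `"CAGE_CTSS"` or `"POLYA"`.
#' @return A tibble (`contig`, `pos`, `strand`, `count`) of class
#'   `txh_site_track`, sorted by contig/strand/pos.
#' @export
read_site_track <- function(path, role = c("CAGE_CTSS", "POLYA")) {
  role <- match.arg(role)
  df <- read_tsv_quiet(path, c("contig", "start", "end", "count", "strand"),
                       c("c", "i", "i", "d", "c"))
  if (nrow(df) && any(df$end != df$start + 1L))
    abort("site track lines must cover exactly one position (end == start + 1).")
  bad <- df$count <= 0
  if (any(bad)) {
    warn(sprintf("read_site_track: dropped %d non-positive count line(s).",
                 sum(bad)))
    df <- df[!bad, ]
  }
  out <- df |>
    group_by(.data$contig, pos = .data$start, .data$strand) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$contig, .data$strand, .data$pos)
  attr(out, "role") <- role
  class(out) <- c("txh_site_track", class(out))
  out
}

#' Build a site track from vectors (in-memory constructor)
#'
#' @param contig,pos,strand,count Parallel vectors; counts must be > 0.
#' @param role `"CAGE_CTSS"` or `"POLYA"`.
#' @return A `txh_site_track` tibble.
#' @export
site_track <- function(contig, pos, strand, count,
                       role = c("CAGE_CTSS", "POLYA")) {
  role <- match.arg(role)
  if (any(count <= 0)) abort("site counts must be positive.")
  out <- tibble(contig = contig, pos = as.integer(pos), strand = strand,
                count = count) |>
    group_by(.data$contig, .data$pos, .data$strand) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$contig, .data$strand, .data$pos)
  attr(out, "role") <- role
  class(out) <- c("txh_site_track", class(out))
  out
}

#' Read clinical variants from TSV or VCF
#'
#' TSV needs header columns `contig`, `position` (0-based), `ref`, `alt`,
#' `classification`, `id`. VCF 4.x records are converted (1-based POS to
#' 0-based) and classified from the `CLNSIG` INFO key. All records are
#' retained regardless of classification or review status; restriction to
#' P/LP happens downstream in [filter_plp()].
#'
#' Classification mapping: `Pathogenic` to `P`, `Likely_pathogenic` to
#' `LP`, anything else to `other`; comma/slash-separated multi-values take
#' the most severe.
#'
#' @param path Variant file; dialect by extension (`.vcf` vs other).
#' @return A tibble (`contig`, `position`, `ref`, `alt`, `classification`,
#'   `id`) of class `txh_variants`.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(body)) {
      df <- tibble(contig = character(), position = integer(),
                   ref = character(), alt = character(),
                   clnsig = character(), id = character())
    } else {
      f <- strsplit(body, "\t", fixed = TRUE)
      info <- map_chr(f, 8)
      cln <- map_chr(stringr::str_match(info, "CLNSIG=([^;]+)")[, 2],
                     ~ .x %||% NA_character_)
      df <- tibble(contig = map_chr(f, 1),
                   position = as.integer(map_chr(f, 2)) - 1L,
                   ref = map_chr(f, 4), alt = map_chr(f, 5),
                   clnsig = cln, id = map_chr(f, 3))
    }
    df$classification <- map_chr(df$clnsig, classify_clnsig)
    df$clnsig <- NULL
  } else {
    df <- readr::read_tsv(path, col_types = "cicccc", progress = FALSE)
    need <- c("contig", "position", "ref", "alt", "classification", "id")
    if (!all(need %in% names(df)))
      abort(paste0("variant TSV must have columns: ",
                   paste(need, collapse = ", ")))
    df <- as_tibble(df[need])
    bad <- setdiff(unique(df$classification), c("P", "LP", "other"))
    if (length(bad))
      abort(paste0("unknown variant classification(s): ",
                   paste(bad, collapse = ", ")))
  }
  if (nrow(df) && any(df$ref == df$alt))
    abort("variant with ref == alt.")
  class(df) <- c("txh_variants", class(df))
  df
}

classify_clnsig <- function(x) {
  if (is.na(x)) return("other")
  parts <- toupper(strsplit(x, "[,/|]")[[1]])
  if (any(grepl("^PATHOGENIC$", parts))) return("P")
  if (any(grepl("^LIKELY_PATHOGENIC$", parts))) return("LP")
  "other"
}
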