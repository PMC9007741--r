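#' Merge per-position site counts into clusters
#'
#' Counted positions on the same contig and strand whose successive gaps
#' are at most `cage_merge_gap` bases are transitively merged into one
#' cluster; opposite strands never merge. Each cluster records its peaks
#' (every counted position), the maximum peak, and the representative TSS
#' under the 5'-most-strong-peak rule.
#'
#' @param track A `txh_site_track` (see [read_site_track()]).
#' @param params A [txh_params()] (uses `cage_merge_gap`,
#'   `strong_peak_fraction`).
#' @return A tibble of class `txh_clusters`, one row per cluster, with
#'   columns `cluster_id`, `contig`, `strand`, `start`, `end` (half-open
#'   span over counted positions), `n_peaks`, `max_peak_pos`,
#'   `max_peak_count`, `representative_tss`, and a `peaks` list-column of
#'   (`pos`, `count`) tibbles.
#' @export
merge_clusters <- function(track, params = txh_params()) {
  empty <- tibble(cluster_id = character(), contig = character(),
                  strand = character(), start = integer(), end = integer(),
                  n_peaks = integer(), max_peak_pos = integer(),
                  max_peak_count = numeric(), representative_tss = integer(),
                  peaks = list())
  if (nrow(track) == 0) {
    class(empty) <- c("txh_clusters", class(empty))
    return(empty)
  }
  out <- track |>
    arrange(.data$contig, .data$strand, .data$pos) |>
    group_by(.data$contig, .data$strand) |>
    mutate(new_cluster = c(TRUE, diff(.data$pos) > params$cage_merge_gap),
           grp = cumsum(.data$new_cluster)) |>
    group_by(.data$contig, .data$strand, .data$grp) |>
    summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
              n_peaks = dplyr::n(),
              peaks = list(tibble(pos = pos, count = count)),
              .groups = "drop") |>
    select(-"grp")
  out <- out |>
    mutate(
      max_peak_count = map_dbl(.data$peaks, ~ max(.x$count)),
      max_peak_pos = map_int(.data$peaks,
                             ~ .x$pos[which.max(.x$count)]),
      cluster_id = sprintf("%s:%s:%d-%d", .data$contig, .data$strand,
                           .data$start, .data$end)
    )
  out$representative_tss <- map_int(seq_len(nrow(out)), function(i)
    longest_strong_site(out[i, ], end = "five_prime",
                        fraction = params$strong_peak_fraction))
  out <- select(out, "cluster_id", "contig", "strand", "start", "end",
                "n_peaks", "max_peak_pos", "max_peak_count",
                "representative_tss", "peaks")
  class(out) <- c("txh_clusters", class(out))
  out
}

#' The "longest strong" site of a cluster
#'
#' For a 5' end: the strand-aware 5'-most peak whose count is at least
#' `fraction` of the cluster's maximum peak. For a 3' end the rule is
#' mirrored (3'-most strong peak). This deliberately prefers a frequently
#' used outer site over the absolute maximum.
#'
#' @param cluster A one-row cluster (from [merge_clusters()]) or any list
#'   with `peaks` (tibble of `pos`, `count`) and `strand`.
#' @param end `"five_prime"` or `"three_prime"`.
#' @param fraction Strong-peak fraction in (0, 1].
#' @return The chosen peak position (0-based).
#' @export
#' @examples
#' cl <- list(peaks = tibble::tibble(pos = c(100L, 120L, 140L),
#'                                   count = c(10, 40, 25)),
#'            strand = "+")
#' longest_strong_site(cl, "five_prime", 0.5)  # 120: 10 < 20 is weak
longest_strong_site <- function(cluster, end = c("five_prime", "three_prime"),
                                fraction = 0.5) {
  end <- match.arg(end)
  peaks <- if (is_tibble(cluster)) cluster$peaks[[1]] else cluster$peaks
  strand <- if (is_tibble(cluster)) cluster$strand[1] else cluster$strand
  if (nrow(peaks) == 0) abort("cluster has no peaks.")
  thr <- fraction * max(peaks$count)
  strong <- peaks$pos[peaks$count >= thr]
  outermost_5 <- strand == "+"
  if (end == "three_prime") outermost_5 <- !outermost_5
  if (outermost_5) min(strong) else max(strong)
}

# Terminal exon index and outer-boundary position for one end of a model.
terminal_info <- function(t, end) {
  n <- nrow(t$exons)
  five_at_low <- t$strand == "+"
  at_low <- if (end == "five_prime") five_at_low else !five_at_low
  idx <- if (at_low) 1L else n
  pos <- if (at_low) t$exons$start[idx] else t$exons$end[idx] - 1L
  list(idx = idx, pos = pos, at_low = at_low)
}

# Move the outer boundary of the terminal exon to terminal position `pos`.
# Splice junctions and the CDS are untouched by construction; callers must
# have applied the guards first.
apply_end_update <- function(t, end, pos) {
  ti <- terminal_info(t, end)
  if (ti$at_low) t$exons$start[ti$idx] <- as.integer(pos)
  else t$exons$end[ti$idx] <- as.integer(pos) + 1L
  t
}

# Reasons an update target is inadmissible, or NULL when fine.
end_guard <- function(t, end, pos) {
  ti <- terminal_info(t, end)
  ex <- t$exons[ti$idx, ]
  if (ti$at_low) {
    if (pos >= ex$end) return("would cross a splice junction")
  } else {
    if (pos < ex$start) return("would cross a splice junction")
  }
  if (!is.null(t$cds)) {
    cds_lo <- min(t$cds$start); cds_hi <- max(t$cds$end)
    if (ti$at_low && pos > cds_lo) return("would truncate CDS")
    if (!ti$at_low && pos + 1L < cds_hi) return("would truncate CDS")
  }
  NULL
}

#' Assign an evidence-driven end to a transcript
#'
#' A cluster is eligible when it overlaps the transcript's terminal exon,
#' or lies on the outward side of the terminal nucleotide within
#' `tss_assignment_window` bases of it. Among eligible clusters the one
#' nearest the current end wins; the new boundary is its longest-strong
#' site. The update is refused (with a reason) when no cluster is
#' eligible or when the new boundary would truncate the CDS or cross a
#' splice junction.
#'
#' @param t A `txh_transcript`.
#' @param clusters A `txh_clusters` tibble (same contig/strand clusters
#'   are considered; others ignored).
#' @param end `"five_prime"` or `"three_prime"`.
#' @param params A [txh_params()].
#' @return A one-row tibble (`accession`, `end`, `old_pos`, `new_pos`,
#'   `cluster_id`, `applied`, `reason`).
#' @export
assign_end <- function(t, clusters, end = c("five_prime", "three_prime"),
                       params = txh_params()) {
  end <- match.arg(end)
  ti <- terminal_info(t, end)
  cl <- clusters[clusters$contig == t$contig & clusters$strand == t$strand, ]
  refusal <- function(reason, cid = NA_character_)
    tibble(accession = t$accession, end = end, old_pos = ti$pos,
           new_pos = ti$pos, cluster_id = cid, applied = FALSE,
           reason = reason)
  if (nrow(cl) == 0) return(refusal("no eligible cluster"))
  ex <- t$exons[ti$idx, ]
  overlaps <- pmax(cl$start, ex$start) < pmin(cl$end, ex$end)
  outward_dist <- if (ti$at_low) ti$pos - (cl$end - 1L) else cl$start - ti$pos
  eligible <- overlaps | (outward_dist > 0 &
                            outward_dist <= params$tss_assignment_window)
  if (!any(eligible)) return(refusal("no eligible cluster"))
  cl <- cl[eligible, ]
  dist <- ifelse(pmax(cl$start, ex$start) < pmin(cl$end, ex$end), 0L,
                 abs(ifelse(ti$at_low, ti$pos - (cl$end - 1L),
                            cl$start - ti$pos)))
  best <- cl[order(dist, cl$start), ][1, ]
  new_pos <- longest_strong_site(best, end, params$strong_peak_fraction)
  bad <- end_guard(t, end, new_pos)
  if (!is.null(bad)) return(refusal(bad, best$cluster_id))
  tibble(accession = t$accession, end = end, old_pos = ti$pos,
         new_pos = as.integer(new_pos), cluster_id = best$cluster_id,
         applied = new_pos != ti$pos,
         reason = if (new_pos == ti$pos) "already optimal" else NA_character_)
}

#' Standardize the 5' and 3' ends of a matched pair
#'
#' Both transcripts of an `IDENTICAL` or `END_EXTENT_ONLY` pair receive
#' the same evidence-derived terminal boundaries: the 5' end from CAGE
#' clusters and the 3' end from poly(A) clusters, each via
#' [assign_end()]. When no eligible cluster exists for an end (or the
#' cluster target is inadmissible), both transcripts adopt the
#' strand-aware outermost of their two current boundaries so the pair
#' still converges. The post-state always compares `IDENTICAL`; no CDS
#' coordinate is ever modified, and a second pass performs no further
#' changes.
#'
#' @param tA,tB The paired `txh_transcript` objects.
#' @param cage,polya `txh_site_track` objects (may be empty).
#' @param params A [txh_params()].
#' @return `list(a =, b =, updates =)` with the updated models and the
#'   per-transcript, per-end update log.
#' @export
standardize_pair <- function(tA, tB, cage, polya, params = txh_params()) {
  cat0 <- compare_pair(tA, tB)
  if (!cat0 %in% c("IDENTICAL", "END_EXTENT_ONLY"))
    abort(sprintf("standardize_pair requires an IDENTICAL or END_EXTENT_ONLY pair (got %s).",
                  cat0))
  updates <- list()
  for (end in c("five_prime", "three_prime")) {
    track <- if (end == "five_prime") cage else polya
    clusters <- merge_clusters(track, params)
    upA <- assign_end(tA, clusters, end, params)
    upB <- assign_end(tB, clusters, end, params)
    cluster_ok <- function(u) is.na(u$reason) || u$reason == "already optimal"
    if (cluster_ok(upA)) {
      target <- upA$new_pos; cid <- upA$cluster_id
    } else if (cluster_ok(upB)) {
      target <- upB$new_pos; cid <- upB$cluster_id
    } else {
      pa <- terminal_info(tA, end)$pos
      pb <- terminal_info(tB, end)$pos
      target <- if (terminal_info(tA, end)$at_low) min(pa, pb) else max(pa, pb)
      cid <- NA_character_
    }
    for (nm in c("a", "b")) {
      t <- if (nm == "a") tA else tB
      old <- terminal_info(t, end)$pos
      bad <- end_guard(t, end, target)
      if (!is.null(bad)) {
        # inadmissible fallback target: keep the current boundary
        updates[[length(updates) + 1]] <-
          tibble(accession = t$accession, end = end, old_pos = old,
                 new_pos = old, cluster_id = cid, applied = FALSE,
                 reason = bad)
        next
      }
      t2 <- apply_end_update(t, end, target)
      updates[[length(updates) + 1]] <-
        tibble(accession = t$accession, end = end, old_pos = old,
               new_pos = as.integer(target), cluster_id = cid,
               applied = old != target,
               reason = if (old == target) "already optimal" else NA_character_)
      if (nm == "a") tA <- t2 else tB <- t2
    }
  }
  list(a = tA, b = tB, updates = list_rbind(updates))
}

#' Write clusters as BED6+
#'
#' Columns: contig, span start, span end, cluster id, max peak count,
#' strand, representative TSS.
#'
#' @param clusters A `txh_clusters` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  df <- tibble(clusters$contig, clusters$start, clusters$end,
               clusters$cluster_id, clusters$max_peak_count,
               clusters$strand, clusters$representative_tss)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
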