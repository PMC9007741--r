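#' Workflow parameters
#'
#' Bundles every tunable threshold used by transcript selection, end
#' standardization and motif scanning. Defaults reflect the published
#' production settings where those are stated (cluster merge gap of 50 nt,
#' strong-peak fraction of 0.5, 500-nt assignment window, 200-nt TSS scan
#' window, motif p-value threshold of 0.01); the expression and junction
#' thresholds are unpublished and are calibrated against the bundled
#' synthetic fixtures.
#'
#' @param cage_merge_gap Maximum gap (bases) between counted positions on
#'   the same strand for CAGE/poly(A) sites to merge into one cluster.
#' @param strong_peak_fraction A peak is "strong" when its count is at least
#'   this fraction of the cluster's maximum peak. Must be in (0, 1].
#' @param tss_assignment_window Maximum distance (bases) from a transcript's
#'   terminal nucleotide to the nearest edge of an eligible cluster.
#' @param min_expression_depth Minimum mean read depth (reads/base) for a
#'   coding exon to count as expressed.
#' @param min_junction_reads Minimum spanning-read count for an intron
#'   junction to support an exon.
#' @param conservation_positive_threshold Conservation segment scores above
#'   this value count as positive signal.
#' @param conservation_min_fraction Fraction of an exon's CDS bases that
#'   must sit under positive signal for the exon to count as conserved.
#' @param scan_window Width (bases) of the TSS-centred window used for
#'   promoter-signature scanning. Must be even.
#' @param motif_p_threshold Maximum p-value for a PWM match to be reported.
#' @param weights Named numeric vector of composite-score weights over
#'   components `expression`, `conservation`, `cds_length`,
#'   `appris_concordance`, `canonical_concordance`. Non-negative.
#' @param hierarchy Character vector giving the priority order of the
#'   binary parameters used by [hierarchical_select()].
#' @param pwm_scale Integer scale applied to log-odds scores before the
#'   exact p-value convolution.
#'
#' @return A list of class `txh_params`.
#' @export
#' @examples
#' p <- txh_params(min_expression_depth = 10)
#' p$cage_merge_gap
txh_params <- function(cage_merge_gap = 50L,
                       strong_peak_fraction = 0.5,
                       tss_assignment_window = 500L,
                       min_expression_depth = 5,
                       min_junction_reads = 5,
                       conservation_positive_threshold = 0,
                       conservation_min_fraction = 0.5,
                       scan_window = 200L,
                       motif_p_threshold = 0.01,
                       weights = c(expression = 0.2,
                                   conservation = 0.2,
                                   cds_length = 0.2,
                                   appris_concordance = 0.2,
                                   canonical_concordance = 0.2),
                       hierarchy = c("clinical_use", "conservation_pass",
                                     "expression_pass", "longest_cds",
                                     "appris_principal", "canonical_protein"),
                       pwm_scale = 1000L) {
  if (strong_peak_fraction <= 0 || strong_peak_fraction > 1)
    abort("`strong_peak_fraction` must be in (0, 1].")
  if (cage_merge_gap <= 0 || tss_assignment_window <= 0 || scan_window <= 0)
    abort("window sizes must be positive.")
  if (scan_window %% 2 != 0)
    abort("`scan_window` must be even (the TSS sits at the midpoint).")
  comp <- c("expression", "conservation", "cds_length",
            "appris_concordance", "canonical_concordance")
  if (!all(comp %in% names(weights)))
    abort(paste0("`weights` must name all of: ", paste(comp, collapse = ", ")))
  if (any(weights < 0)) abort("`weights` must be non-negative.")
  known <- c("clinical_use", "conservation_pass", "expression_pass",
             "longest_cds", "appris_principal", "canonical_protein")
  if (!setequal(hierarchy, known))
    abort("`hierarchy` must be a permutation of the six binary parameters.")
  structure(list(
    cage_merge_gap = as.integer(cage_merge_gap),
    strong_peak_fraction = strong_peak_fraction,
    tss_assignment_window = as.integer(tss_assignment_window),
    min_expression_depth = min_expression_depth,
    min_junction_reads = min_junction_reads,
    conservation_positive_threshold = conservation_positive_threshold,
    conservation_min_fraction = conservation_min_fraction,
    scan_window = as.integer(scan_window),
    motif_p_threshold = motif_p_threshold,
    weights = weights[comp],
    hierarchy = hierarchy,
    pwm_scale = as.integer(pwm_scale)
  ), class = "txh_params")
}

#' @export
print.txh_params <- function(x, ...) {
  cat("<txh_params>\n")
  for (nm in setdiff(names(x), c("weights", "hierarchy")))
    cat(sprintf("  %-32s %s\n", nm, format(x[[nm]])))
  cat(sprintf("  %-32s %s\n", "weights",
              paste(sprintf("%s=%g", names(x$weights), x$weights),
                    collapse = " ")))
  cat(sprintf("  %-32s %s\n", "hierarchy",
              paste(x$hierarchy, collapse = " > ")))
  invisible(x)
}
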