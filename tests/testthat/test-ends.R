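params <- txh_params()

test_that("cluster merging respects the 50-nt same-strand rule", {
  tr <- site_track(c("chr1", "chr1"), c(100, 149), c("+", "+"), c(5, 7))
  cl <- merge_clusters(tr, params)
  expect_equal(nrow(cl), 1)  # gap 49 merges

  tr2 <- site_track(c("chr1", "chr1"), c(100, 151), c("+", "+"), c(5, 7))
  expect_equal(nrow(merge_clusters(tr2, params)), 2)  # gap 51 does not

  tr3 <- site_track(c("chr1", "chr1"), c(100, 120), c("+", "-"), c(5, 7))
  cl3 <- merge_clusters(tr3, params)
  expect_equal(nrow(cl3), 2)  # opposite strands never merge

  empty <- site_track(character(), integer(), character(), numeric())
  expect_equal(nrow(merge_clusters(empty, params)), 0)
})

test_that("longest-strong rule matches the hand-computed cases", {
  cl <- list(peaks = tibble::tibble(pos = c(100L, 120L, 140L),
                                    count = c(10, 40, 25)), strand = "+")
  expect_equal(longest_strong_site(cl, "five_prime", 0.5), 120)  # 10 < 20
  cl2 <- list(peaks = tibble::tibble(pos = c(100L, 120L),
                                     count = c(30, 40)), strand = "+")
  expect_equal(longest_strong_site(cl2, "five_prime", 0.5), 100)  # 30 >= 20
  cl3 <- list(peaks = tibble::tibble(pos = 77L, count = 3), strand = "+")
  expect_equal(longest_strong_site(cl3, "five_prime", 0.5), 77)
  # 3' mirror and minus strand
  expect_equal(longest_strong_site(cl, "three_prime", 0.5), 140)
  cl_m <- list(peaks = cl$peaks, strand = "-")
  expect_equal(longest_strong_site(cl_m, "five_prime", 0.5), 140)
  expect_equal(longest_strong_site(cl_m, "three_prime", 0.5), 120)
})

random_track <- function(n = 40) {
  site_track(rep("chr1", n),
             sort(sample(1:3000, n)),
             sample(c("+", "-"), n, TRUE),
             sample(1:50, n, TRUE))
}

test_that("cluster invariants hold on randomized tracks (exhaustive scan)", {
  set.seed(71)
  for (rep_i in 1:20) {
    tr <- random_track()
    cl <- merge_clusters(tr, params)
    # gap property between successive clusters on one contig+strand
    for (grp in split(cl, paste(cl$contig, cl$strand))) {
      grp <- dplyr::arrange(grp, start)
      if (nrow(grp) > 1)
        expect_true(all(grp$start[-1] - (grp$end[-nrow(grp)] - 1L) >
                          params$cage_merge_gap))
    }
    for (i in seq_len(nrow(cl))) {
      pk <- cl$peaks[[i]]
      thr <- params$strong_peak_fraction * max(pk$count)
      expect_true(all(pk$pos >= cl$start[i] & pk$pos < cl$end[i]))
      expect_equal(cl$max_peak_count[i], max(pk$count))
      rep_tss <- cl$representative_tss[i]
      # representative is a strong peak and nothing 5' of it is strong
      expect_true(pk$count[pk$pos == rep_tss] >= thr)
      if (cl$strand[i] == "+")
        expect_false(any(pk$pos < rep_tss & pk$count >= thr))
      else
        expect_false(any(pk$pos > rep_tss & pk$count >= thr))
    }
    # every input position lands in exactly one cluster
    covered <- purrr::map2(cl$peaks, seq_len(nrow(cl)),
                           ~ paste(cl$contig[.y], cl$strand[.y], .x$pos))
    expect_setequal(unlist(covered), paste(tr$contig, tr$strand, tr$pos))
    expect_equal(sum(purrr::map_int(cl$peaks, nrow)), nrow(tr))
  }
})

test_that("merging is idempotent when clusters are re-expressed as a track", {
  set.seed(73)
  tr <- random_track()
  cl <- merge_clusters(tr, params)
  tr2 <- site_track(rep(cl$contig, purrr::map_int(cl$peaks, nrow)),
                    unlist(purrr::map(cl$peaks, "pos")),
                    rep(cl$strand, purrr::map_int(cl$peaks, nrow)),
                    unlist(purrr::map(cl$peaks, "count")))
  cl2 <- merge_clusters(tr2, params)
  expect_equal(cl[order(cl$cluster_id), ], cl2[order(cl2$cluster_id), ])
})

# a transcript with a 100-nt 5' UTR on its first exon
std_tx <- function(acc = "T1.1", strand = "+") {
  mk_tx(acc, c(1000, 1500), c(1200, 1900),
        cds_starts = c(1100, 1500), cds_ends = c(1200, 1800),
        strand = strand)
}

test_that("assign_end extends, refuses distant clusters, and guards the CDS", {
  t <- std_tx()
  # cluster overlapping the first exon, strong site 35 nt upstream
  tr <- site_track(rep("chr1", 2), c(965, 1005), c("+", "+"), c(30, 40))
  up <- assign_end(t, merge_clusters(tr, params), "five_prime", params)
  expect_true(up$applied)
  expect_equal(up$new_pos, 965L)

  # nearest cluster 600 nt upstream: outside the 500-nt window
  tr_far <- site_track("chr1", 399, "+", 40)
  up2 <- assign_end(t, merge_clusters(tr_far, params), "five_prime", params)
  expect_false(up2$applied)
  expect_equal(up2$reason, "no eligible cluster")

  # strong site downstream of the CDS start: would truncate the CDS
  tr_in <- site_track("chr1", 1150, "+", 40)
  up3 <- assign_end(t, merge_clusters(tr_in, params), "five_prime", params)
  expect_false(up3$applied)
  expect_equal(up3$reason, "would truncate CDS")
})

test_that("end standardization converges, preserves the CDS, and is idempotent", {
  tA <- std_tx("TA.1")
  tB <- mk_tx("TB.1", c(1030, 1500), c(1200, 1930),
              cds_starts = c(1100, 1500), cds_ends = c(1200, 1800))
  expect_equal(compare_pair(tA, tB), "END_EXTENT_ONLY")

  cage <- site_track(rep("chr1", 2), c(965, 1005), c("+", "+"), c(30, 40))
  polya <- site_track(rep("chr1", 2), c(1950, 1970), c("+", "+"), c(40, 30))
  std <- standardize_pair(tA, tB, cage, polya, params)
  expect_equal(compare_pair(std$a, std$b), "IDENTICAL")
  expect_equal(std$a$exons$start[1], 965L)       # longest-strong TSS
  expect_equal(std$a$exons$end[2], 1971L)        # 3'-most strong poly(A)
  expect_true(chains_equal(std$a$cds, tA$cds))   # CDS untouched
  expect_true(chains_equal(std$b$cds, tB$cds))

  # second pass: no further changes
  std2 <- standardize_pair(std$a, std$b, cage, polya, params)
  expect_equal(sum(std2$updates$applied), 0)
  expect_true(chains_equal(std2$a$exons, std$a$exons))

  # already identical, no clusters: no-op
  empty <- site_track(character(), integer(), character(), numeric())
  std3 <- standardize_pair(std$a, std$b, empty, empty, params)
  expect_equal(sum(std3$updates$applied), 0)
  expect_true(chains_equal(std3$a$exons, std$a$exons))

  # both ends differ, CAGE at 5' only: 5' from cluster, 3' from outermost
  std4 <- standardize_pair(tA, tB, cage, empty, params)
  expect_equal(compare_pair(std4$a, std4$b), "IDENTICAL")
  expect_equal(std4$a$exons$start[1], 965L)
  expect_equal(std4$a$exons$end[2], 1930L)       # outermost of 1900/1930

  # CDS-different pairs are a contract violation
  tC <- mk_tx("TC.1", c(1000, 1500), c(1200, 1900),
              cds_starts = c(1106, 1500), cds_ends = c(1200, 1800))
  expect_error(standardize_pair(tA, tC, cage, polya, params), "IDENTICAL or")
})

test_that("minus-strand ends mirror correctly", {
  tm <- mk_tx("TM.1", c(1000, 1500), c(1200, 1900),
              cds_starts = c(1100, 1500), cds_ends = c(1200, 1800),
              strand = "-")
  # 5' end of a minus-strand transcript is the high-coordinate boundary
  tr <- site_track(rep("chr1", 2), c(1930, 1950), c("-", "-"), c(40, 30))
  up <- assign_end(tm, merge_clusters(tr, params), "five_prime", params)
  expect_true(up$applied)
  expect_equal(up$new_pos, 1950L)  # 5'-most on minus = highest coordinate
})

test_that("random end-standardization never touches CDS coordinates", {
  set.seed(83)
  for (i in 1:30) {
    t1 <- rand_tx("R1.1")
    t2 <- perturb_tx(t1, "end_jitter")
    n_cage <- sample(0:3, 1)
    lo <- max(0, t1$exons$start[1] - 300)
    cage <- if (n_cage > 0)
      site_track(rep("chr1", n_cage),
                 sample(lo:(lo + 600), n_cage),
                 rep("+", n_cage), sample(3:50, n_cage, TRUE))
    else site_track(character(), integer(), character(), numeric())
    empty <- site_track(character(), integer(), character(), numeric())
    std <- standardize_pair(t1, t2, cage, empty, params)
    expect_equal(compare_pair(std$a, std$b), "IDENTICAL")
    expect_true(chains_equal(std$a$cds, t1$cds))
    expect_true(chains_equal(std$b$cds, t2$cds))
    std2 <- standardize_pair(std$a, std$b, cage, empty, params)
    expect_equal(sum(std2$updates$applied), 0)
  }
})
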