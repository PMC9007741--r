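# PWM scanning with exact p-values, and promoter-signature profiling.

tata_pwm <- function() {
  counts <- rbind(A = c(1, 95, 1, 95, 95, 95),
                  C = c(1, 1, 1, 1, 1, 1),
                  G = c(2, 2, 2, 2, 2, 2),
                  T = c(96, 2, 96, 2, 2, 2))
  pwm_matrix(counts)
}
inr_pwm <- function() {
  counts <- rbind(A = c(2, 90, 2), C = c(90, 4, 4),
                  G = c(4, 2, 4), T = c(4, 4, 90))
  pwm_matrix(counts)  # consensus CAT around the start site
}

make_windows <- function(n, L = 200, plant = NULL, offset = NULL,
                         plus1 = NULL) {
  tssi <- L %/% 2L + 1L
  seqs <- purrr::map_chr(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (!is.null(plant)) {
      start <- tssi + offset + if (offset > 0) -1L else 0L
      s[start:(start + nchar(plant) - 1L)] <- strsplit(plant, "")[[1]]
    }
    if (!is.null(plus1)) s[tssi] <- plus1
    paste(s, collapse = "")
  })
  tss_windows(seqs)
}

test_that("nucleotide profiles count correctly and detect purine enrichment", {
  set.seed(7)
  w <- make_windows(50, plus1 = "A")
  prof <- nucleotide_profile(w)
  expect_equal(prof$purine_fraction_plus1, 1.0)

  set.seed(8)
  w2 <- make_windows(400)
  p <- nucleotide_profile(w2)$purine_fraction_plus1
  sigma <- sqrt(0.25 / 400)
  expect_lt(abs(p - 0.5), 3 * sigma + 1e-9)

  # frequencies equal a per-column counting oracle
  mat <- do.call(rbind, strsplit(w2$seq, ""))
  j <- 37
  expect_equal(p2 <- nucleotide_profile(w2)$profile$A[j],
               mean(mat[, j] == "A"))
  # each defined row sums to 1
  pr <- nucleotide_profile(w2)$profile
  expect_equal(pr$A + pr$C + pr$G + pr$T, rep(1, nrow(pr)))
})

test_that("log-odds scoring behaves at the boundaries", {
  uni <- pwm_matrix(matrix(1, 4, 3, dimnames = list(c("A", "C", "G", "T"))),
                    pseudocount = 0)
  expect_true(all(log_odds(uni) == 0))

  w1 <- pwm_matrix(matrix(c(100, 0, 0, 0), 4, 1,
                          dimnames = list(c("A", "C", "G", "T"))),
                   pseudocount = 0.25)
  lo <- log_odds(w1)
  expect_gt(lo["A", 1], 0)
  expect_true(all(lo[c("C", "G", "T"), 1] < 0))

  # integer scores match the real-valued log-odds within one scale unit
  pwm <- tata_pwm()
  lo2 <- log_odds(pwm, scale = 1000L)
  real <- 1000 * log2(sweep(pwm$probs, 1, pwm$background, "/"))
  expect_true(all(abs(lo2 - real) <= 1))
})

enumerate_pvalues <- function(lo, bg, w) {
  idx <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- rowSums(matrix(lo[cbind(as.vector(idx),
                                    rep(seq_len(w), each = nrow(idx)))],
                           nrow = nrow(idx)))
  probs <- apply(matrix(bg[as.vector(idx)], nrow = nrow(idx)), 1, prod)
  list(scores = scores, probs = probs)
}

test_that("exact p-value tables equal exhaustive enumeration (widths 1-4)", {
  set.seed(13)
  for (w in 1:4) {
    counts <- matrix(sample(1:50, 4 * w, TRUE), 4,
                     dimnames = list(c("A", "C", "G", "T")))
    bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    pwm <- pwm_matrix(counts, background = bg)
    lo <- log_odds(pwm)
    tbl <- score_pvalue_table(lo)
    en <- enumerate_pvalues(lo, bg, w)
    for (s in tbl$score)
      expect_equal(txharmony:::pwm_pvalue(tbl, s),
                   sum(en$probs[en$scores >= s]))
    # survival function properties
    expect_true(all(diff(tbl$pvalue) <= 1e-12))
    expect_equal(tbl$pvalue[1], 1)                     # minimum score
    expect_equal(sum(tbl$prob), 1)
    # closed form at the maximum: product over argmax bases (with ties)
    max_prob <- prod(purrr::map_dbl(seq_len(w), function(j) {
      col <- lo[, j]
      sum(bg[names(col)[col == max(col)]])
    }))
    expect_equal(tbl$pvalue[nrow(tbl)], max_prob)
  }
})

test_that("best-match scanning recovers planted motifs at their offsets", {
  params <- txh_params()
  set.seed(17)
  w <- make_windows(1, plant = "TATAAA", offset = -30L)
  hit <- scan_best_match(w$seq[1], tata_pwm(), params)
  expect_equal(hit$offset, -30L)
  expect_lte(hit$pvalue, 0.01)

  # a window that cannot reach the threshold yields no hit
  none <- scan_best_match(strrep("C", 200), tata_pwm(), params)
  expect_equal(nrow(none), 0)

  # equal-scoring duplicate: the 5'-most offset wins
  s <- strsplit(strrep("C", 200), "")[[1]]
  s[21:26] <- strsplit("TATAAA", "")[[1]]
  s[61:66] <- strsplit("TATAAA", "")[[1]]
  hit2 <- scan_best_match(paste(s, collapse = ""), tata_pwm(), params)
  expect_equal(hit2$start_index, 21L)

  # N in a word skips that offset but not the others
  s[21] <- "N"
  hit3 <- scan_best_match(paste(s, collapse = ""), tata_pwm(), params)
  expect_equal(hit3$start_index, 61L)
})

test_that("planted-motif recovery: modal offset over 100 windows is -30", {
  set.seed(19)
  w <- make_windows(100, plant = "TATAAA", offset = -30L)
  params <- txh_params()
  pwm <- tata_pwm()
  hits <- purrr::list_rbind(purrr::map(w$seq, scan_best_match, pwm = pwm,
                                       params = params))
  expect_gte(nrow(hits), 90)
  modal <- as.integer(names(sort(table(hits$offset), decreasing = TRUE))[1])
  expect_equal(modal, -30L)
})

test_that("signature reports quantify before/after enrichment", {
  set.seed(23)
  before <- make_windows(60)
  after <- make_windows(60, plant = "TATAAA", offset = -30L, plus1 = "A")
  pwms <- list(tata = tata_pwm(), inr = inr_pwm())
  rep <- signature_report(before, after, pwms)
  m <- tidy(rep)
  expect_gt(m$after[m$metric == "purine_fraction_plus1"],
            m$before[m$metric == "purine_fraction_plus1"])
  expect_gt(m$after[m$metric == "tata_fraction"],
            m$before[m$metric == "tata_fraction"])

  # identical sets: zero differences
  rep2 <- signature_report(before, before, pwms)
  expect_true(all(tidy(rep2)$difference == 0))

  # fractions equal a counting oracle over individual scans
  tssi <- attr(after, "tss_index")
  bg <- txharmony:::empirical_background(after$seq)
  n_in_band <- sum(purrr::map_lgl(after$seq, function(s) {
    h <- scan_best_match(s, pwms$tata, txh_params(), background = bg,
                         tss_index = tssi)
    nrow(h) == 1 && h$offset >= -35 && h$offset <= -25
  }))
  expect_equal(m$after[m$metric == "tata_fraction"], n_in_band / nrow(after))
})

test_that("JASPAR matrices round-trip through the reader", {
  f <- tempfile(fileext = ".jaspar")
  writeLines(c(">MX0001 tata_fixture",
               "A  [  1 95  1 95 95 95 ]",
               "C  [  1  1  1  1  1  1 ]",
               "G  [  2  2  2  2  2  2 ]",
               "T  [ 96  2 96  2  2  2 ]"), f)
  m <- read_jaspar(f)
  expect_named(m, "MX0001")
  expect_equal(unname(m$MX0001["T", 1]), 96)
  expect_equal(pwm_matrix(m$MX0001)$width, 6L)
})

test_that("TSS windows extract strand-normalized sequence around the cap site", {
  b <- ref_fixtures()$men1_like
  w <- extract_tss_windows(b$setA, b$genome, "NM_100")
  expect_equal(nchar(w$seq), 200)
  tssi <- attr(w, "tss_index")
  # the +1 base is the transcript's first base
  first_base <- substr(spliced_sequence(get_transcript(b$setA, "NM_100"),
                                        b$genome, "exons"), 1, 1)
  expect_equal(substr(w$seq, tssi, tssi), first_base)

  # minus-strand normalization reads in transcript orientation
  g <- mk_genome(c(chr1 = paste(rep("ACGT", 200), collapse = "")))
  tm <- mk_tx("TM.1", c(200, 400), c(300, 500), strand = "-")
  setm <- annotation_set(list(tm))
  wm <- extract_tss_windows(setm, g)
  expect_equal(substr(wm$seq, tssi, tssi),
               substr(spliced_sequence(tm, g, "exons"), 1, 1))
})
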