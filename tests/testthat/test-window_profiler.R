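test_that("count_window discerns case and routes non-ACGT to other", {
  wc <- count_window("ACGTacgt", start = 0, size = 8)
  expect_equal(wc$upper_counts, c(A = 1L, C = 1L, G = 1L, T = 1L))
  expect_equal(wc$lower_counts, c(a = 1L, c = 1L, g = 1L, t = 1L))
  expect_equal(wc$other_count, 0L)

  wn <- count_window("NNNNNNNN", 0, 8)
  expect_equal(sum(wn$upper_counts) + sum(wn$lower_counts), 0L)
  expect_equal(wn$other_count, 8L)

  expect_error(count_window("ACGT", start = 4, size = 2),
               "contract violation")
  expect_error(count_window("ACGT", start = -1, size = 2),
               "contract violation")
})

test_that("count_window matches the per-character oracle at random cuts", {
  set.seed(101)
  s <- random_mixed_sequence(100000)
  tally <- oracle_letter_tally(s)
  chars <- strsplit(s, "")[[1]]
  for (i in 1:15) {
    start <- sample(0:(nchar(s) - 1), 1)
    size <- sample(c(1, 13, 997, 50000), 1)
    wc <- count_window(s, start, size)
    span <- chars[(start + 1):min(start + size, nchar(s))]
    for (L in c("A", "C", "G", "T"))
      expect_equal(unname(wc$upper_counts[L]), sum(span == L))
    for (L in c("a", "c", "g", "t"))
      expect_equal(unname(wc$lower_counts[L]), sum(span == L))
    expect_equal(wc$other_count,
                 length(span) - sum(span %in% ORACLE_LETTERS))
  }
  # conservation against the whole-sequence tally at an exact tiling
  prof <- profile_sequence(s, 1000)
  expect_equal(sum(prof$windows$counted_bases), sum(tally[1:8]))
})

test_that("window metrics follow the counted-bases denominators", {
  m <- window_metrics(count_window("ACGTacgt", 0, 8))
  expect_equal(m$gc_pct, 50)
  expect_equal(m$rep_pct, 50)
  expect_equal(m$gc_pct_masked, 50)
  expect_equal(m$gc_pct_unmasked, 50)

  expect_equal(window_metrics(count_window("GGGGgggg", 0, 8))$gc_pct, 100)
  expect_equal(window_metrics(count_window("gggggggg", 0, 8))$rep_pct, 100)
  # half the counted G bases are soft-masked
  expect_equal(window_metrics(count_window("GGGGgggg", 0, 8))$rep_pct, 50)

  mn <- window_metrics(count_window("NNNN", 0, 4))
  expect_true(all(is.na(unlist(mn[1:4]))))
  expect_equal(mn$counted_bases, 0L)

  # repeats can carry all the GC: the fraction split observable
  ms <- window_metrics(count_window("AATTggcc", 0, 8))
  expect_equal(ms$gc_pct, 50)
  expect_equal(ms$rep_pct, 50)
  expect_equal(ms$gc_pct_unmasked, 0)
  expect_equal(ms$gc_pct_masked, 100)
})

test_that("overall GC% is the counted-bases-weighted mean of fractions", {
  set.seed(33)
  for (i in 1:20) {
    s <- random_mixed_sequence(sample(500:3000, 1))
    w <- profile_sequence(s, 250)$windows
    both <- !is.na(w$gc_pct_masked) & !is.na(w$gc_pct_unmasked)
    if (!any(both)) next
    rw <- w[both, ]
    lo <- rw$counted_bases * rw$rep_pct / 100
    up <- rw$counted_bases - lo
    expect_equal(rw$gc_pct,
                 (lo * rw$gc_pct_masked + up * rw$gc_pct_unmasked) /
                   rw$counted_bases)
  }
})

test_that("profiles tile the sequence with a trailing partial window", {
  s <- paste(rep("ACGTACGTAC", 1025), collapse = "")  # 10,250 bp
  p <- profile_sequence(s, 1000)
  expect_equal(nrow(p$windows), 11)
  expect_equal(p$windows$start_bp, (0:10) * 1000 + 1)
  expect_equal(p$windows$counted_bases[11], 250L)
  expect_profiles_equal(p$windows, oracle_profile(s, 1000))
  expect_error(profile_sequence(s, 0), "parameter error")
})

test_that("GC% is strand-symmetric (reverse complement invariant)", {
  set.seed(5)
  s <- random_mixed_sequence(1000, p_other = 0)
  comp <- chartr("ACGTacgt", "TGCAtgca", s)
  rc <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  expect_equal(profile_sequence(s, 1000)$windows$gc_pct,
               profile_sequence(rc, 1000)$windows$gc_pct)
})

test_that("window counts sum to the whole-record count (conservation)", {
  set.seed(9)
  for (i in 1:10) {
    s <- random_mixed_sequence(sample(1:20000, 1))
    w <- sample(c(1, 7, 100, 1000), 1)
    prof <- profile_sequence(s, w)$windows
    tally <- oracle_letter_tally(s)
    expect_equal(sum(prof$counted_bases), sum(tally[1:8]))
    gc_total <- sum(prof$counted_bases * prof$gc_pct / 100, na.rm = TRUE)
    expect_equal(gc_total,
                 sum(tally[c("C", "G", "c", "g")]), tolerance = 1e-9)
    masked_total <- sum(prof$counted_bases * prof$rep_pct / 100,
                        na.rm = TRUE)
    expect_equal(masked_total, sum(tally[c("a", "c", "g", "t")]),
                 tolerance = 1e-9)
  }
})

test_that("case flips move rep% to its extremes but never touch GC%", {
  set.seed(13)
  s <- random_mixed_sequence(30000)
  base <- profile_sequence(s, 1000)$windows
  up <- profile_sequence(toupper(s), 1000)$windows
  lo <- profile_sequence(tolower(s), 1000)$windows
  expect_equal(up$gc_pct, base$gc_pct)
  expect_equal(lo$gc_pct, base$gc_pct)
  expect_true(all(up$rep_pct[up$counted_bases > 0] == 0))
  expect_true(all(lo$rep_pct[lo$counted_bases > 0] == 100))
})

test_that("coarse windows aggregate fine windows by counted-base weight", {
  set.seed(17)
  s <- random_mixed_sequence(90000)
  fine <- profile_sequence(s, 1000)$windows
  coarse <- profile_sequence(s, 3000)$windows
  grp <- ((fine$index - 1) %/% 3) + 1
  agg_counted <- as.vector(rowsum(fine$counted_bases, grp))
  gc_bases <- ifelse(is.na(fine$gc_pct), 0,
                     fine$counted_bases * fine$gc_pct / 100)
  agg_gc <- as.vector(rowsum(gc_bases, grp))
  expected <- ifelse(agg_counted > 0, 100 * agg_gc / agg_counted, NA_real_)
  expect_equal(coarse$gc_pct, expected, tolerance = 1e-12)
  expect_equal(coarse$counted_bases, as.integer(agg_counted))
})

test_that("profiles match the brute-force oracle on adversarial sizes", {
  set.seed(23)
  lengths <- c(1, 2, 6, 7, 8, 999, 1000, 1001, sample(1:5000, 12))
  for (n in lengths) {
    s <- random_mixed_sequence(n, p_other = 0.15)
    for (w in c(1, 7, 1000)) {
      expect_profiles_equal(profile_sequence(s, w)$windows,
                            oracle_profile(s, w))
    }
  }
})

test_that("window means recover the generating GC probability", {
  # binomial tolerance: 4 * sqrt(p(1-p)/n) on the pooled counted bases
  for (p in c(0.35, 0.41, 0.60)) {
    gs <- genome_spec(list(chr1 = list(segment_spec(400000, p))),
                      seed = round(1000 * p))
    fa <- tempfile(fileext = ".fa")
    generate_genome(gs, fa)
    prof <- profile_sequence(read_assembly(fa), 1000)
    w <- prof$windows
    n <- sum(w$counted_bases)
    est <- sum(w$counted_bases * w$gc_pct / 100) / n
    expect_lt(abs(est - p), 4 * sqrt(p * (1 - p) / n))
  }
})
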