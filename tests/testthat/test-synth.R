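test_that("generation is deterministic in (spec, seed); seeds vary bases only", {
  spec <- genome_spec(list(
    chr1 = list(segment_spec(5000, 0.45), segment_spec(2000, 0.5, TRUE),
                segment_spec(1000, n_run = TRUE), segment_spec(3000, 0.4)),
    chr2 = list(segment_spec(4000, 0.41))), seed = 7)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  generate_genome(spec, f1)
  generate_genome(spec, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  other <- genome_spec(spec$chromosomes, seed = 8)
  f3 <- tempfile(fileext = ".fa")
  generate_genome(other, f3)
  s7 <- as.character(read_assembly(f1)$seqs[[1]])
  s8 <- as.character(read_assembly(f3)$seqs[[1]])
  expect_false(identical(s7, s8))
  # identical case/N architecture: masked and N positions coincide
  arch <- function(s) chartr("acgtACGT", "mmmmuuuu", s)
  expect_identical(arch(s7), arch(s8))
})

test_that("gzip output decompresses to the same assembly", {
  spec <- genome_spec(list(c1 = list(segment_spec(3000, 0.5))), seed = 5)
  fa <- tempfile(fileext = ".fa")
  gz <- tempfile(fileext = ".fa.gz")
  generate_genome(spec, fa)
  generate_genome(spec, gz)
  expect_identical(as.character(read_assembly(fa)$seqs),
                   as.character(read_assembly(gz)$seqs))
})

test_that("masked-base count equals the summed masked segment lengths", {
  spec <- genome_spec(list(
    chr1 = list(segment_spec(1234, 0.4), segment_spec(777, 0.5, TRUE),
                segment_spec(450, 0.6), segment_spec(1001, 0.3, TRUE))),
    seed = 11)
  fa <- tempfile(fileext = ".fa")
  generate_genome(spec, fa)
  s <- assembly_summary(read_assembly(fa))
  expect_equal(s$masked_bases, 777L + 1001L)
  expect_equal(s$length, 1234L + 777L + 450L + 1001L)
})

test_that("designed degenerate segments profile to their exact extremes", {
  spec <- genome_spec(list(c1 = list(segment_spec(1000, 1.0, TRUE))),
                      seed = 13)
  fa <- tempfile(fileext = ".fa")
  generate_genome(spec, fa)
  w <- profile_sequence(read_assembly(fa), 1000)$windows
  expect_equal(nrow(w), 1)
  expect_equal(w$gc_pct, 100)
  expect_equal(w$rep_pct, 100)

  # interstitial block: exactly one fully repetitive window among nine
  spec2 <- genome_spec(list(c1 = list(
    segment_spec(2000, 0.5), segment_spec(500, 0.5, TRUE),
    segment_spec(2000, 0.5))), seed = 13)
  fa2 <- tempfile(fileext = ".fa")
  generate_genome(spec2, fa2)
  w2 <- profile_sequence(read_assembly(fa2), 500)$windows
  expect_equal(sum(w2$rep_pct == 100), 1)
  expect_equal(sum(w2$rep_pct == 0), 8)
  expect_equal(which(w2$rep_pct == 100), 5)
})

test_that("genome-wide GC recovers gc_prob within 4 binomial SD", {
  spec <- genome_spec(list(c1 = list(segment_spec(1000000, 0.41))),
                      seed = 17)
  fa <- tempfile(fileext = ".fa")
  generate_genome(spec, fa)
  w <- profile_sequence(read_assembly(fa), 1000)$windows
  gc <- sum(w$counted_bases * w$gc_pct / 100) / sum(w$counted_bases)
  expect_lt(abs(gc - 0.41), 4 * sqrt(0.41 * 0.59 / 1e6))
})

test_that("invalid segment parameters error before generation", {
  expect_error(segment_spec(-5), "parameter error")
  expect_error(segment_spec(100, gc_prob = 1.2), "parameter error")
  expect_error(genome_spec(list(list(segment_spec(10)))), "named list")
  expect_error(preset_architectures("spiral"), "'arg' should be one of")
})

test_that("preset architectures realize their designed mask layout", {
  w <- 1000
  # telomeric: first and last windows of every chromosome fully repetitive
  acro <- preset_architectures("acrocentric_telomeric", seed = 19)
  fa <- tempfile(fileext = ".fa")
  generate_genome(acro, fa)
  profs <- profile_assembly(read_assembly(fa), w)
  for (p in profs) {
    expect_equal(p$windows$rep_pct[1], 100)
    expect_equal(p$windows$rep_pct[nrow(p$windows)], 100)
  }
  # expected composition table matches observed rep% exactly
  expected <- expected_window_composition(acro, w)
  obs <- do.call(rbind, lapply(names(profs), function(id)
    data.frame(chrom = id, index = profs[[id]]$windows$index,
               rep_pct = profs[[id]]$windows$rep_pct)))
  merged <- merge(obs, expected, by = c("chrom", "index"))
  expect_equal(merged$rep_pct, merged$expected_rep_pct)
})

test_that("compact preset stays under its repeat ceiling", {
  spec <- preset_architectures("compact_low_repeat", seed = 23)
  fa <- tempfile(fileext = ".fa")
  generate_genome(spec, fa)
  s <- assembly_summary(read_assembly(fa))
  expect_lt(sum(s$masked_bases) / sum(s$length), 0.10)
})

test_that("mammal-like preset inverts the fish GC contrast", {
  spec <- preset_architectures("mammal_like", seed = 29)
  fa <- tempfile(fileext = ".fa")
  generate_genome(spec, fa)
  profs <- profile_assembly(read_assembly(fa), 1000)
  cs <- compensation_summary(profs, assembly = "mammal_like")
  # unmasked DNA (carrying the gene-rich peaks) is GC-richer than repeats
  expect_gt(cs$mean_gc_unmasked, cs$mean_gc_masked)
  # and the high-GC peaks are unmasked: windows above 55% GC have low rep%
  w <- do.call(rbind, lapply(profs, `[[`, "windows"))
  peaks <- w[!is.na(w$gc_pct) & w$gc_pct > 55, ]
  expect_gt(nrow(peaks), 0)
  expect_true(all(peaks$rep_pct < 50))
})

test_that("fish-like presets give repeats GC at or above the background", {
  for (name in c("acrocentric_telomeric", "interstitial_blocks",
                 "dispersed")) {
    segs <- spec_segment_table(preset_architectures(name))
    expect_gte(min(segs$gc_prob[segs$masked]),
               max(segs$gc_prob[!segs$masked & !segs$n_run]))
  }
})
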