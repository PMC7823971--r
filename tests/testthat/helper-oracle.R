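# Independent brute-force oracle: per-character classification in plain R,
# no Biostrings. Classifies every residue individually, assigns it to its
# window by integer division, and computes the metrics with the textbook
# formulas. Deliberately simple and slow-ish; the implementation under
# test never calls any of this.

ORACLE_LETTERS <- c("A", "C", "G", "T", "a", "c", "g", "t")

oracle_profile <- function(seqchar, w) {
  chars <- strsplit(seqchar, "", fixed = TRUE)[[1]]
  n <- length(chars)
  nw <- ceiling(n / w)
  if (nw == 0) {
    return(data.frame(index = integer(), start_bp = numeric(),
                      gc_pct = numeric(), rep_pct = numeric(),
                      gc_pct_masked = numeric(),
                      gc_pct_unmasked = numeric(),
                      counted_bases = integer()))
  }
  win <- ((seq_along(chars) - 1) %/% w) + 1
  counts <- matrix(0, nrow = nw, ncol = length(ORACLE_LETTERS),
                   dimnames = list(NULL, ORACLE_LETTERS))
  for (L in ORACLE_LETTERS) {
    hit <- rowsum((chars == L) + 0L, win)
    counts[as.integer(rownames(hit)), L] <- hit[, 1]
  }
  n_up <- counts[, "A"] + counts[, "C"] + counts[, "G"] + counts[, "T"]
  n_lo <- counts[, "a"] + counts[, "c"] + counts[, "g"] + counts[, "t"]
  counted <- n_up + n_lo
  gc_up <- counts[, "G"] + counts[, "C"]
  gc_lo <- counts[, "g"] + counts[, "c"]
  data.frame(
    index = seq_len(nw),
    start_bp = (seq_len(nw) - 1) * w + 1,
    gc_pct = ifelse(counted > 0, 100 * (gc_up + gc_lo) / counted, NA_real_),
    rep_pct = ifelse(counted > 0, 100 * n_lo / counted, NA_real_),
    gc_pct_masked = ifelse(n_lo > 0, 100 * gc_lo / n_lo, NA_real_),
    gc_pct_unmasked = ifelse(n_up > 0, 100 * gc_up / n_up, NA_real_),
    counted_bases = as.integer(counted))
}

# whole-sequence letter tally by per-character scan
oracle_letter_tally <- function(seqchar) {
  chars <- strsplit(seqchar, "", fixed = TRUE)[[1]]
  counts <- vapply(ORACLE_LETTERS, function(L) sum(chars == L), numeric(1))
  c(counts, other = length(chars) - sum(counts))
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random mixed-case sequence incl. N and IUPAC ambiguity codes
random_mixed_sequence <- function(n, p_other = 0.05) {
  alphabet <- c(ORACLE_LETTERS, "N", "n", "R", "y", "W", "s", "-", "K")
  probs <- c(rep((1 - p_other) / 8, 8), rep(p_other / 8, 8))
  paste(sample(alphabet, n, replace = TRUE, prob = probs), collapse = "")
}

expect_profiles_equal <- function(got, want, tol = 1e-12) {
  expect_equal(nrow(got), nrow(want))
  for (col in names(want)) {
    expect_equal(got[[col]], want[[col]], tolerance = tol,
                 info = paste("column", col))
  }
}
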