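#' Case-sensitive letter counts of one window
#'
#' Counts A/C/G/T occurrences in `[start, start + size)`, discerning upper
#' (unmasked) from lower (soft-masked repeat) case. Any other character —
#' N/n, IUPAC ambiguity codes, gaps — increments `other_count` and is
#' excluded from all downstream percentages.
#'
#' @param record A [Biostrings::BString], single character string, or a
#'   one-record `masked_assembly`.
#' @param start 0-based start offset in bp; must satisfy
#'   `0 <= start < length(record)`.
#' @param size Nominal window size in bp (>= 1). The trailing window of a
#'   sequence may cover fewer residues.
#' @return A `window_counts` object: `start`, `size`, `upper_counts`
#'   (named A,C,G,T), `lower_counts` (named a,c,g,t), `other_count`,
#'   `covered` (residues actually in range).
#' @examples
#' count_window("ACGTacgt", start = 0, size = 8)
#' @export
count_window <- function(record, start, size) {
  x <- as_bstring(record)
  n <- length(x)
  if (!(is.numeric(start) && length(start) == 1 && start >= 0 && start < n))
    stop("contract violation: start must satisfy 0 <= start < record length (",
         n, "), got ", start, call. = FALSE)
  if (!(is.numeric(size) && length(size) == 1 && size >= 1))
    stop("parameter error: window size must be >= 1", call. = FALSE)
  end <- min(start + size, n)
  sub <- Biostrings::subseq(x, start = start + 1, end = end)
  counts <- Biostrings::letterFrequency(
    sub, letters = c("A", "C", "G", "T", "a", "c", "g", "t"))
  counts <- as.integer(counts)
  covered <- end - start
  structure(list(start = as.numeric(start), size = as.numeric(size),
                 upper_counts = stats::setNames(counts[1:4],
                                                c("A", "C", "G", "T")),
                 lower_counts = stats::setNames(counts[5:8],
                                                c("a", "c", "g", "t")),
                 other_count = as.integer(covered - sum(counts)),
                 covered = as.integer(covered)),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat("Window [", x$start, ", ", x$start + x$covered, ") of nominal size ",
      x$size, "\n", sep = "")
  cat("  upper:", paste(names(x$upper_counts), x$upper_counts, sep = "="),
      "\n  lower:", paste(names(x$lower_counts), x$lower_counts, sep = "="),
      "\n  other:", x$other_count, "\n")
  invisible(x)
}

#' Window metrics from letter counts
#'
#' Converts counts into the window record: overall GC%, repeat% (share of
#' counted bases that are soft-masked), and GC% computed separately inside
#' the masked and unmasked fractions. The denominator `counted_bases` is
#' A+C+G+T of either case; windows whose denominator is zero (assembly
#' gaps, N runs) yield missing percentages, not errors.
#'
#' @param counts A `window_counts` from [count_window()].
#' @return One-row `data.frame` with columns `gc_pct`, `rep_pct`,
#'   `gc_pct_masked`, `gc_pct_unmasked`, `counted_bases`.
#' @examples
#' window_metrics(count_window("AATTggcc", 0, 8))
#' @export
window_metrics <- function(counts) {
  stopifnot(inherits(counts, "window_counts"))
  up <- counts$upper_counts
  lo <- counts$lower_counts
  n_up <- sum(up)
  n_lo <- sum(lo)
  counted <- n_up + n_lo
  gc_up <- up[["G"]] + up[["C"]]
  gc_lo <- lo[["g"]] + lo[["c"]]
  data.frame(
    gc_pct = if (counted > 0) 100 * (gc_up + gc_lo) / counted else NA_real_,
    rep_pct = if (counted > 0) 100 * n_lo / counted else NA_real_,
    gc_pct_masked = if (n_lo > 0) 100 * gc_lo / n_lo else NA_real_,
    gc_pct_unmasked = if (n_up > 0) 100 * gc_up / n_up else NA_real_,
    counted_bases = as.integer(counted))
}

#' Profile a sequence in consecutive non-overlapping windows
#'
#' The core computation: partitions the sequence into `ceiling(length/w)`
#' consecutive windows of nominal size `w` (the trailing window, if the
#' length is not an exact multiple, covers its actual residues) and
#' computes per-window GC%, repeat% and per-fraction GC%.
#'
#' Counting is case-sensitive: lowercase = soft-masked repeat, uppercase =
#' unmasked. N and ambiguity codes are excluded from both numerator and
#' denominator of every percentage.
#'
#' @param record A [Biostrings::BString], character string, or one-record
#'   `masked_assembly`.
#' @param window_size Window size in bp (>= 1). The field default is
#'   1000 bp; 3000 and 10000 bp are the coarser presets for polyploid or
#'   very large genomes.
#' @param id Record identifier stored in the profile (taken from the
#'   assembly when `record` is one).
#' @return A `window_profile`: list with `record_id`, `record_length`,
#'   `window_size` and `windows`, a `data.frame` with columns `index`
#'   (1-based window ordinal), `start_bp` (1-based start), `gc_pct`,
#'   `rep_pct`, `gc_pct_masked`, `gc_pct_unmasked`, `counted_bases`.
#' @examples
#' p <- profile_sequence("ACGTacgtNNNNggcc", window_size = 4, id = "toy")
#' p$windows
#' @export
profile_sequence <- function(record, window_size = 1000, id = "seq") {
  if (!(is.numeric(window_size) && length(window_size) == 1 &&
        window_size >= 1))
    stop("parameter error: window_size must be a single integer >= 1",
         call. = FALSE)
  w <- as.numeric(window_size)
  if (inherits(record, "masked_assembly")) {
    stopifnot(length(record$ids) == 1)
    id <- record$ids[[1]]
  }
  x <- as_bstring(record)
  n <- length(x)
  nw <- as.integer(ceiling(n / w))
  if (nw == 0) {
    windows <- data.frame(index = integer(), start_bp = numeric(),
                          gc_pct = numeric(), rep_pct = numeric(),
                          gc_pct_masked = numeric(),
                          gc_pct_unmasked = numeric(),
                          counted_bases = integer())
    return(new_window_profile(id, n, w, windows))
  }
  starts <- (seq_len(nw) - 1) * w + 1
  ends <- pmin(starts + w - 1, n)
  views <- Biostrings::Views(x, start = starts, end = ends)
  m <- Biostrings::letterFrequency(
    views, letters = c("A", "C", "G", "T", "a", "c", "g", "t"))
  n_up <- m[, "A"] + m[, "C"] + m[, "G"] + m[, "T"]
  n_lo <- m[, "a"] + m[, "c"] + m[, "g"] + m[, "t"]
  counted <- n_up + n_lo
  gc_up <- m[, "G"] + m[, "C"]
  gc_lo <- m[, "g"] + m[, "c"]
  windows <- data.frame(
    index = seq_len(nw),
    start_bp = starts,
    gc_pct = ifelse(counted > 0, 100 * (gc_up + gc_lo) / counted, NA_real_),
    rep_pct = ifelse(counted > 0, 100 * n_lo / counted, NA_real_),
    gc_pct_masked = ifelse(n_lo > 0, 100 * gc_lo / n_lo, NA_real_),
    gc_pct_unmasked = ifelse(n_up > 0, 100 * gc_up / n_up, NA_real_),
    counted_bases = as.integer(counted))
  rownames(windows) <- NULL
  new_window_profile(id, n, w, windows)
}

new_window_profile <- function(id, record_length, window_size, windows) {
  structure(list(record_id = id,
                 record_length = as.numeric(record_length),
                 window_size = as.numeric(window_size),
                 windows = windows),
            class = "window_profile")
}

#' Profile every record of an assembly
#'
#' @param assembly A `masked_assembly` from [read_assembly()].
#' @param window_size Window size in bp.
#' @return Named list of `window_profile`, one per record, in file order.
#' @export
profile_assembly <- function(assembly, window_size = 1000) {
  stopifnot(inherits(assembly, "masked_assembly"))
  profiles <- lapply(seq_along(assembly$ids), function(i)
    profile_sequence(assembly$seqs[[i]], window_size, id = assembly$ids[[i]]))
  stats::setNames(profiles, assembly$ids)
}

#' @export
print.window_profile <- function(x, ...) {
  cat("Window profile of '", x$record_id, "': ",
      format(x$record_length, big.mark = ",", scientific = FALSE), " bp, w = ",
      format(x$window_size, big.mark = ",", scientific = FALSE), " bp, ",
      nrow(x$windows), " window(s)\n", sep = "")
  ok <- !is.na(x$windows$gc_pct)
  if (any(ok))
    cat(sprintf("  mean GC%% %.2f, mean rep%% %.2f (%d windows with data)\n",
                mean(x$windows$gc_pct[ok]), mean(x$windows$rep_pct[ok]),
                sum(ok)))
  invisible(x)
}

#' @export
summary.window_profile <- function(object, ...) {
  w <- object$windows
  ok <- !is.na(w$gc_pct)
  out <- list(record_id = object$record_id,
              record_length = object$record_length,
              window_size = object$window_size,
              n_windows = nrow(w),
              n_informative = sum(ok),
              gc_pct = if (any(ok)) summary(w$gc_pct[ok]) else NULL,
              rep_pct = if (any(ok)) summary(w$rep_pct[ok]) else NULL)
  class(out) <- "summary.window_profile"
  out
}

#' @export
print.summary.window_profile <- function(x, ...) {
  cat("Profile of", x$record_id, "-", x$n_informative, "of", x$n_windows,
      "windows informative\n")
  if (!is.null(x$gc_pct)) { cat("GC%:\n"); print(x$gc_pct) }
  if (!is.null(x$rep_pct)) { cat("rep%:\n"); print(x$rep_pct) }
  invisible(x)
}

as_bstring <- function(record) {
  if (inherits(record, "BString")) return(record)
  if (inherits(record, "masked_assembly")) {
    stopifnot(length(record$ids) >= 1)
    return(record$seqs[[1]])
  }
  if (is.character(record) && length(record) == 1)
    return(Biostrings::BString(record))
  stop("unsupported record type: ", paste(class(record), collapse = "/"),
       call. = FALSE)
}
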