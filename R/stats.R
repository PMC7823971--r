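#' Pooled GC% vs repeat% correlation of an assembly
#'
#' Pools the (GC%, rep%) pairs of every window across all chromosomes of
#' one assembly — pairwise-complete, i.e. windows missing either measure
#' are dropped — and computes the sample Pearson correlation coefficient
#' r with its two-sided p-value from the t transformation on
#' `n_windows - 2` degrees of freedom. One r per assembly (per species),
#' matching how the association is reported in comparative work: weak
#' positive (r about 0.1–0.225) in many fish, weak negative in mammals.
#'
#' @param profiles A `window_profile`, or a list of them (one assembly).
#' @param assembly Assembly label carried into the result.
#' @return A `gc_rep_correlation`: `assembly`, `n_windows`, `r`,
#'   `p_value`, `window_size`.
#' @examples
#' p <- profile_sequence(strrep("ACGTacgtAATT", 100), window_size = 12)
#' \dontrun{correlate_gc_rep(p)}  # constant rep% -> undefined-correlation
#' @export
correlate_gc_rep <- function(profiles, assembly = "assembly") {
  pairs <- pooled_pairs(profiles)
  if (nrow(pairs) < 3)
    stop("insufficient data: ", nrow(pairs),
         " non-missing (GC%, rep%) pairs; need >= 3", call. = FALSE)
  if (stats::sd(pairs$gc_pct) == 0 || stats::sd(pairs$rep_pct) == 0)
    stop("undefined correlation: zero variance in ",
         if (stats::sd(pairs$gc_pct) == 0) "GC%" else "rep%",
         " across windows", call. = FALSE)
  ct <- stats::cor.test(pairs$gc_pct, pairs$rep_pct, method = "pearson")
  structure(list(assembly = assembly,
                 n_windows = nrow(pairs),
                 r = unname(ct$estimate),
                 p_value = ct$p.value,
                 window_size = pairs_window_size(profiles)),
            class = "gc_rep_correlation")
}

pooled_pairs <- function(profiles) {
  if (inherits(profiles, "window_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "window_profile")))
  w <- do.call(rbind, lapply(profiles, `[[`, "windows"))
  ok <- !is.na(w$gc_pct) & !is.na(w$rep_pct)
  w[ok, c("gc_pct", "rep_pct", "gc_pct_masked", "gc_pct_unmasked")]
}

pairs_window_size <- function(profiles) {
  if (inherits(profiles, "window_profile")) profiles <- list(profiles)
  ws <- unique(vapply(profiles, `[[`, numeric(1), "window_size"))
  if (length(ws) == 1) ws else NA_real_
}

#' @export
print.gc_rep_correlation <- function(x, ...) {
  p_show <- if (x$p_value < 1e-16) "< 1e-16" else
    format(x$p_value, digits = 3)
  cat(sprintf(
    "GC%% vs rep%% (Pearson), assembly '%s':\n  r = %.4f, p %s %s, n = %d windows (w = %s bp)\n",
    x$assembly, x$r, if (x$p_value < 1e-16) "" else "=", p_show,
    x$n_windows, format(x$window_size, big.mark = ",")))
  invisible(x)
}

#' Export pooled (GC%, rep%) scatter data
#'
#' One row per window with both measures present; recomputing Pearson's r
#' from the exported file reproduces [correlate_gc_rep()]'s r exactly.
#'
#' @param profiles A `window_profile` or list of them.
#' @param path Output CSV path.
#' @return `path` invisibly; attribute `n` = rows written.
#' @export
export_scatter <- function(profiles, path) {
  pairs <- pooled_pairs(profiles)
  if (nrow(pairs) == 0)
    stop("insufficient data: no window has both GC% and rep%",
         call. = FALSE)
  utils::write.table(pairs[, c("gc_pct", "rep_pct")], path, sep = ",",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(structure(path, n = nrow(pairs)))
}

#' Repeat-GC compensation summary
#'
#' Summarises how GC% of the soft-masked (repeat) fraction relates to GC%
#' of the unmasked (unique) fraction across windows where both are
#' defined: their means and their across-window correlation. In many fish
#' genomes repeats are at least as GC-rich as unique DNA and rise where
#' unique DNA gets GC-poorer, homogenising the overall landscape; in
#' mammal-like genomes the contrast inverts. A zero-variance fraction
#' makes the correlation undefined; it is then flagged rather than
#' reported as a number.
#'
#' @param profiles A `window_profile` or list of them.
#' @param assembly Assembly label.
#' @return A `compensation_summary`: `assembly`, `n_windows`,
#'   `mean_gc_unmasked`, `mean_gc_masked`, `fraction_correlation` (NA if
#'   undefined), `correlation_defined`.
#' @export
compensation_summary <- function(profiles, assembly = "assembly") {
  pairs <- pooled_pairs(profiles)
  both <- !is.na(pairs$gc_pct_masked) & !is.na(pairs$gc_pct_unmasked)
  pairs <- pairs[both, , drop = FALSE]
  if (nrow(pairs) < 3)
    stop("insufficient data: ", nrow(pairs),
         " windows with both fraction GC% defined; need >= 3",
         call. = FALSE)
  defined <- stats::sd(pairs$gc_pct_masked) > 0 &&
    stats::sd(pairs$gc_pct_unmasked) > 0
  structure(list(
    assembly = assembly,
    n_windows = nrow(pairs),
    mean_gc_unmasked = mean(pairs$gc_pct_unmasked),
    mean_gc_masked = mean(pairs$gc_pct_masked),
    fraction_correlation = if (defined)
      stats::cor(pairs$gc_pct_masked, pairs$gc_pct_unmasked) else NA_real_,
    correlation_defined = defined),
    class = "compensation_summary")
}

#' @export
print.compensation_summary <- function(x, ...) {
  cat(sprintf(
    "Repeat-GC compensation, assembly '%s' (%d windows with both fractions):\n",
    x$assembly, x$n_windows))
  cat(sprintf("  mean GC%% unmasked %.3f, masked %.3f\n",
              x$mean_gc_unmasked, x$mean_gc_masked))
  if (x$correlation_defined)
    cat(sprintf("  fraction correlation r = %.4f\n", x$fraction_correlation))
  else
    cat("  fraction correlation undefined (zero variance in a fraction)\n")
  invisible(x)
}

#' Machine-readable row of a correlation result
#'
#' @param x A `gc_rep_correlation`.
#' @return One-row `data.frame` (`assembly`, `n_windows`, `r`, `p_value`,
#'   `window_size`).
#' @export
as.data.frame.gc_rep_correlation <- function(x, ...) {
  data.frame(assembly = x$assembly, n_windows = x$n_windows, r = x$r,
             p_value = x$p_value, window_size = x$window_size)
}
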