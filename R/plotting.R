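#' Piecewise-linear percentage-to-color scale
#'
#' A mapping from a percentage to an RGB triple, defined by ordered
#' anchors and linear interpolation per channel; percentages outside the
#' anchor span clamp to the end colors.
#'
#' Two scales carry the tool's semantics. The repeat scale colors GC%
#' points by repeat density: red = no repeats, orange = about half
#' repetitive, green = fully repetitive. The GC scale (used by the
#' swapped plot mode) mimics CMA3/CDD chromosome fluorescence: GC-rich
#' red, AT-rich green.
#'
#' @param anchors Numeric matrix with columns `pct`, `r`, `g`, `b`; rows
#'   strictly increasing in `pct`, channels in 0–255.
#' @param orientation `"repeat"` or `"gc"` — which percentage the scale is
#'   meant to color.
#' @return A `color_scale`.
#' @examples
#' default_repeat_scale()
#' @export
color_scale <- function(anchors, orientation = c("repeat", "gc")) {
  orientation <- match.arg(orientation)
  anchors <- as.matrix(anchors)
  colnames(anchors) <- c("pct", "r", "g", "b")
  if (nrow(anchors) < 2 || any(diff(anchors[, "pct"]) <= 0))
    stop("parameter error: anchors must strictly increase in percentage",
         call. = FALSE)
  if (any(anchors[, "pct"] < 0 | anchors[, "pct"] > 100))
    stop("parameter error: anchor percentages must lie in [0, 100]",
         call. = FALSE)
  if (any(anchors[, -1] < 0 | anchors[, -1] > 255))
    stop("parameter error: RGB channels must lie in 0-255", call. = FALSE)
  structure(list(anchors = anchors, orientation = orientation),
            class = "color_scale")
}

#' @rdname color_scale
#' @export
default_repeat_scale <- function() {
  color_scale(rbind(c(0, 255, 0, 0),      # red: no repeats
                    c(50, 255, 165, 0),   # orange: ~50% repetitive
                    c(100, 0, 170, 0)),   # green: fully repetitive
              orientation = "repeat")
}

#' @rdname color_scale
#' @export
default_gc_scale <- function() {
  # clamp bounds 30/60% bracket the GC range typical of fish chromosomes
  color_scale(rbind(c(30, 0, 170, 0),     # AT-rich: green
                    c(60, 255, 0, 0)),    # GC-rich: red
              orientation = "gc")
}

#' @export
print.color_scale <- function(x, ...) {
  cat("Color scale (", x$orientation, "%):\n", sep = "")
  apply(x$anchors, 1, function(a)
    cat(sprintf("  %5.1f%% -> rgb(%d, %d, %d)\n", a[1], a[2], a[3], a[4])))
  invisible(x)
}

#' Map percentages to colors
#'
#' Deterministic piecewise-linear interpolation between the scale's
#' anchors, channel by channel; exact anchor hits return the anchor
#' color, values beyond the span clamp to the end colors, and missing
#' percentages yield missing rows (no point is drawn for them).
#'
#' @param scale A [color_scale()].
#' @param pct Numeric vector of percentages in \[0, 100\] (NA allowed).
#' @return Integer matrix with columns `r`, `g`, `b`, one row per input.
#' @examples
#' map_color(default_repeat_scale(), c(0, 25, 50, 100))
#' @export
map_color <- function(scale, pct) {
  stopifnot(inherits(scale, "color_scale"))
  bad <- !is.na(pct) & (pct < 0 | pct > 100)
  if (any(bad))
    stop("contract violation: percentage outside [0, 100]: ",
         paste(utils::head(pct[bad]), collapse = ", "), call. = FALSE)
  a <- scale$anchors
  if (length(pct) == 0)
    return(matrix(integer(), ncol = 3,
                  dimnames = list(NULL, c("r", "g", "b"))))
  clamped <- pmin(pmax(pct, a[1, "pct"]), a[nrow(a), "pct"])
  out <- sapply(c("r", "g", "b"), function(ch)
    stats::approx(a[, "pct"], a[, ch], xout = clamped, rule = 2)$y)
  out <- matrix(as.integer(round(out)), ncol = 3,
                dimnames = list(NULL, c("r", "g", "b")))
  out[is.na(pct), ] <- NA_integer_
  out
}

#' Plot specification
#'
#' Geometry and color choices for chromosome-scale profile plots. In the
#' default mode (`gc_on_y`) GC% is plotted on the 0–100% y axis and each
#' point is colored by the window's rep% through the repeat scale. The
#' swapped mode (`rep_on_y`) puts rep% on the y axis and colors points by
#' GC% through the CMA3-mimicking GC scale.
#'
#' Panel width in pixels is `record_length / bp_per_pixel`, so chromosome
#' lengths stay visually comparable within one assembly; when
#' `bp_per_pixel` is `NULL` it is chosen per assembly so the longest
#' chromosome spans `max_width_px`.
#'
#' @param mode `"gc_on_y"` (default) or `"rep_on_y"` (swapped/CMA3 mode).
#' @param window_size Window size in bp (recorded for provenance).
#' @param bp_per_pixel Horizontal scale; `NULL` = derive from
#'   `max_width_px`.
#' @param max_width_px Maximum panel width in pixels (default 10000).
#' @param color_scale Optional [color_scale()] override; defaults to the
#'   mode's canonical scale.
#' @param panel_height_px Height of each chromosome panel in pixels.
#' @return A `plot_spec`.
#' @export
plot_spec <- function(mode = c("gc_on_y", "rep_on_y"), window_size = 1000,
                      bp_per_pixel = NULL, max_width_px = 10000,
                      color_scale = NULL, panel_height_px = 220) {
  mode <- match.arg(mode)
  if (!is.null(bp_per_pixel)) stopifnot(bp_per_pixel > 0)
  stopifnot(max_width_px >= 100)
  if (is.null(color_scale))
    color_scale <- if (mode == "gc_on_y") default_repeat_scale()
                   else default_gc_scale()
  stopifnot(inherits(color_scale, "color_scale"))
  structure(list(mode = mode, window_size = window_size,
                 bp_per_pixel = bp_per_pixel,
                 max_width_px = max_width_px, color_scale = color_scale,
                 panel_height_px = panel_height_px),
            class = "plot_spec")
}

# point list for one profile under a spec: x (bp), y (%), r, g, b
panel_points <- function(profile, spec) {
  w <- profile$windows
  y <- if (spec$mode == "gc_on_y") w$gc_pct else w$rep_pct
  color_by <- if (spec$mode == "gc_on_y") w$rep_pct else w$gc_pct
  ok <- !is.na(y) & !is.na(color_by)
  rgb <- map_color(spec$color_scale, color_by[ok])
  data.frame(x_bp = w$start_bp[ok], y_pct = y[ok],
             r = rgb[, "r"], g = rgb[, "g"], b = rgb[, "b"])
}

#' Render an assembly's profiles as a chromosome-scale plot
#'
#' Renders one multi-panel PNG, panels ordered by chromosome size
#' (longest first) and sized proportionally to chromosome length, plus —
#' for every panel — a machine-readable point-list sidecar
#' (`points_<record_id>.tsv`: x in bp, y in %, RGB channels). The sidecar
#' is the deterministic, testable artifact; the raster is presentation.
#' Plotting never mutates profiles. A panel with zero plottable points is
#' rendered empty with a warning.
#'
#' @param profiles List of `window_profile`s (one assembly).
#' @param spec A [plot_spec()].
#' @param outdir Output directory (created if needed).
#' @param name Basename of the PNG (`<name>.png`).
#' @return Invisible list with `png` and `sidecars` paths and the panel
#'   order used.
#' @export
render_assembly <- function(profiles, spec = plot_spec(), outdir,
                            name = "assembly") {
  if (inherits(profiles, "window_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "window_profile")))
  wsizes <- vapply(profiles, `[[`, numeric(1), "window_size")
  if (length(unique(wsizes)) != 1)
    stop("parameter error: profiles mix window sizes: ",
         paste(unique(wsizes), collapse = ", "), call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  # longest first; ties by record id
  nrows <- vapply(profiles, function(p) nrow(p$windows), numeric(1))
  ids <- vapply(profiles, `[[`, character(1), "record_id")
  profiles <- profiles[order(-nrows, ids)]
  ids <- ids[order(-nrows, ids)]
  lens <- vapply(profiles, `[[`, numeric(1), "record_length")
  bpp <- spec$bp_per_pixel
  if (is.null(bpp)) bpp <- max(lens) / spec$max_width_px
  widths_px <- pmax(1, round(lens / bpp))
  points <- lapply(profiles, panel_points, spec = spec)
  sidecars <- character(length(profiles))
  for (i in seq_along(profiles)) {
    sidecars[i] <- file.path(outdir, sprintf("points_%s.tsv", ids[i]))
    if (nrow(points[[i]]) == 0)
      warning("panel '", ids[i], "' has zero plottable points", call. = FALSE)
    utils::write.table(points[[i]], sidecars[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  }
  png_path <- file.path(outdir, paste0(name, ".png"))
  render_png(points, ids, lens, widths_px, spec, png_path)
  invisible(list(png = png_path, sidecars = sidecars, panel_order = ids,
                 bp_per_pixel = bpp, panel_widths_px = widths_px))
}

#' @rdname render_assembly
#' @param ... Passed to [plot_spec()] (e.g. `window_size`,
#'   `bp_per_pixel`); the mode is forced to `rep_on_y`, the swapped
#'   CMA3-mimicking presentation.
#' @export
render_swapped <- function(profiles, outdir, name = "assembly_cma3", ...) {
  render_assembly(profiles, spec = plot_spec(mode = "rep_on_y", ...),
                  outdir = outdir, name = name)
}

render_png <- function(points, ids, lens, widths_px, spec, png_path) {
  n <- length(points)
  dev_w <- max(widths_px) + 120   # margin for axis labels
  dev_h <- n * spec$panel_height_px + 80
  grDevices::png(png_path, width = dev_w, height = dev_h)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(n, 1), mar = c(2.5, 4, 1.5, 1), xaxs = "i")
  ylab <- if (spec$mode == "gc_on_y") "GC%" else "rep%"
  for (i in seq_len(n)) {
    p <- points[[i]]
    # panel x range fixed so width in device pixels tracks record length
    graphics::plot(NA, xlim = c(0, lens[i] * max(widths_px) /
                                  widths_px[i]),
                   ylim = c(0, 100), xlab = "", ylab = ylab,
                   main = ids[i], cex.main = 0.9)
    if (nrow(p) > 0)
      graphics::points(p$x_bp, p$y_pct, pch = ".",
                       col = grDevices::rgb(p$r, p$g, p$b,
                                            maxColorValue = 255))
  }
  invisible(png_path)
}

#' Scale legend as a data.frame
#'
#' Tabulates a color scale at regular percentage steps, for legends and
#' documentation.
#'
#' @param scale A [color_scale()].
#' @param step Percentage step (default 10).
#' @return `data.frame` with `pct`, `r`, `g`, `b`, `hex`.
#' @export
scale_legend <- function(scale, step = 10) {
  pct <- seq(0, 100, by = step)
  rgb <- map_color(scale, pct)
  data.frame(pct = pct, r = rgb[, "r"], g = rgb[, "g"], b = rgb[, "b"],
             hex = grDevices::rgb(rgb[, "r"], rgb[, "g"], rgb[, "b"],
                                  maxColorValue = 255))
}
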