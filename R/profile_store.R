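PROFILE_COLUMNS <- c("index", "start_bp", "gc_pct", "rep_pct",
                     "gc_pct_masked", "gc_pct_unmasked", "counted_bases")

# fixed-notation number formatting, element-wise so no column padding;
# NA stays NA for write.table's na= literal
fmt_num <- function(x, digits = NULL) {
  if (!is.null(digits)) x <- round(x, digits)
  vapply(x, function(v) {
    if (is.na(v)) NA_character_
    else format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
}

#' Write a window profile to a per-chromosome CSV table
#'
#' One CSV per chromosome, named `<assembly>/<record_id>.w<window>.csv`
#' under `directory`. The dialect is fixed: comma separator, '.' decimal
#' point, Unix line endings, '#'-prefixed metadata lines (record id and
#' length, window size, assembly, tool version) followed by one header
#' row. Percentages are written with 3 decimals; missing values (windows
#' with no counted bases) are the literal `NA`, never 0. The write is
#' atomic (temp file then rename).
#'
#' @param profile A `window_profile`.
#' @param directory Output directory (created if needed).
#' @param assembly Assembly label used for the subdirectory and metadata.
#' @param overwrite Overwrite an existing file? Default `FALSE`: a name
#'   collision is an error.
#' @return The file path, invisibly.
#' @export
write_profile <- function(profile, directory, assembly = "assembly",
                          overwrite = FALSE) {
  stopifnot(inherits(profile, "window_profile"))
  dir <- file.path(directory, assembly)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    stop("I/O error: cannot create directory ", dir, call. = FALSE)
  path <- file.path(dir, sprintf("%s.w%s.csv", profile$record_id,
                                 format(profile$window_size,
                                        scientific = FALSE, trim = TRUE)))
  if (file.exists(path) && !overwrite)
    stop("I/O error: ", path,
         " already exists (use overwrite = TRUE to replace)", call. = FALSE)
  df <- profile$windows
  pct <- c("gc_pct", "rep_pct", "gc_pct_masked", "gc_pct_unmasked")
  df[pct] <- lapply(df[pct], fmt_num, digits = 3)
  df$start_bp <- fmt_num(df$start_bp)
  meta <- c(sprintf("# record_id: %s", profile$record_id),
            sprintf("# record_length: %s",
                    format(profile$record_length, scientific = FALSE)),
            sprintf("# window_size: %s",
                    format(profile$window_size, scientific = FALSE)),
            sprintf("# assembly: %s", assembly),
            sprintf("# tool: gcprofiler %s",
                    as.character(utils::packageVersion("gcprofiler"))))
  tmp <- tempfile(tmpdir = dir, fileext = ".csvtmp")
  con <- file(tmp, open = "wb")  # binary: force Unix line endings
  writeLines(meta, con, sep = "\n")
  utils::write.table(df, con, sep = ",", na = "NA", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  close(con)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("I/O error: cannot write ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read a profile table written by [write_profile()]
#'
#' Reconstructs the `window_profile`, including the metadata header. The
#' row count is validated against `ceiling(record_length / window_size)`;
#' a truncated or padded file is a format error, never a silent partial
#' read.
#'
#' @param path Path to a profile CSV.
#' @return A `window_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path))
    stop("input error: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- parse_profile_meta(meta_lines)
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0)
    stop("format error: no header row in ", path, call. = FALSE)
  header <- strsplit(body[[1]], ",", fixed = TRUE)[[1]]
  if (!identical(header, PROFILE_COLUMNS))
    stop("format error: expected columns [",
         paste(PROFILE_COLUMNS, collapse = ", "), "], found [",
         paste(header, collapse = ", "), "] in ", path, call. = FALSE)
  df <- utils::read.csv(text = body, na.strings = "NA",
                        colClasses = c("integer", "numeric", "numeric",
                                       "numeric", "numeric", "numeric",
                                       "integer"))
  expected <- as.integer(ceiling(meta$record_length / meta$window_size))
  if (nrow(df) != expected)
    stop("format error: ", path, " has ", nrow(df), " data rows, expected ",
         expected, " for record_length ", meta$record_length,
         " at window_size ", meta$window_size,
         " (truncated or corrupted file)", call. = FALSE)
  new_window_profile(meta$record_id, meta$record_length, meta$window_size,
                     df)
}

parse_profile_meta <- function(meta_lines) {
  get <- function(key) {
    hit <- grep(sprintf("^#\\s*%s:", key), meta_lines, value = TRUE)
    if (length(hit) != 1)
      stop("format error: missing '# ", key, ":' metadata line",
           call. = FALSE)
    trimws(sub(sprintf("^#\\s*%s:\\s*", key), "", hit))
  }
  list(record_id = get("record_id"),
       record_length = as.numeric(get("record_length")),
       window_size = as.numeric(get("window_size")),
       assembly = get("assembly"))
}

#' Order profile tables by size (descending data-row count)
#'
#' The plotting layout presents chromosomes longest-first; this sorts
#' profile CSVs by the number of data rows, descending, with ties broken
#' by record id in lexicographic order.
#'
#' @param paths Character vector of profile CSV paths.
#' @return The paths, reordered; attributes `rows` and `record_id` carry
#'   the sort keys.
#' @export
order_by_size <- function(paths) {
  stopifnot(length(paths) >= 1)
  rows <- vapply(paths, count_data_rows, numeric(1))
  ids <- vapply(paths, function(p)
    parse_profile_meta(grep("^#", readLines(p, n = 20), value = TRUE))$record_id,
    character(1))
  ord <- order(-rows, ids)
  structure(paths[ord], rows = unname(rows[ord]),
            record_id = unname(ids[ord]))
}

# data rows = lines minus metadata minus the single header row
count_data_rows <- function(path) {
  lines <- readLines(path)
  sum(!grepl("^#", lines)) - 1
}
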