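#' Record filter for assembly reading
#'
#' A pure predicate on record identity and length used by [read_assembly()]
#' to select which FASTA records get profiled. Chromosome-level assemblies
#' typically also carry unplaced scaffolds; a minimum-length threshold (and
#' optionally an identifier pattern) excludes them without touching the
#' residues.
#'
#' @param min_length Minimum record length in bp (default 0, keep all).
#' @param id_pattern Optional regular expression the record id must match.
#' @param max_records Optional cap on the number of records kept (applied
#'   after the other predicates, in file order).
#' @return An object of class `record_filter`.
#' @examples
#' record_filter(min_length = 1e6)
#' @export
record_filter <- function(min_length = 0, id_pattern = NULL,
                          max_records = NULL) {
  stopifnot(is.numeric(min_length), length(min_length) == 1, min_length >= 0)
  if (!is.null(id_pattern)) stopifnot(is.character(id_pattern))
  if (!is.null(max_records)) stopifnot(max_records >= 1)
  structure(list(min_length = as.numeric(min_length),
                 id_pattern = id_pattern,
                 max_records = if (is.null(max_records)) NULL
                               else as.integer(max_records)),
            class = "record_filter")
}

#' @export
print.record_filter <- function(x, ...) {
  cat("Record filter: min_length =", x$min_length,
      if (!is.null(x$id_pattern)) paste0(", id ~ /", x$id_pattern, "/"),
      if (!is.null(x$max_records)) paste0(", max_records = ", x$max_records),
      "\n")
  invisible(x)
}

filter_keep <- function(filter, ids, lengths) {
  keep <- lengths >= filter$min_length
  if (!is.null(filter$id_pattern))
    keep <- keep & grepl(filter$id_pattern, ids)
  if (!is.null(filter$max_records)) {
    idx <- which(keep)
    if (length(idx) > filter$max_records)
      keep[idx[-seq_len(filter$max_records)]] <- FALSE
  }
  keep
}

#' Read a soft-masked FASTA assembly, preserving letter case
#'
#' Reads a plain or gzip-compressed FASTA file into a case-preserving
#' assembly object. Lowercase residues are the soft-masking annotation
#' (repeats); uppercase residues are unmasked DNA, so the reader never
#' normalises case. Line wrapping is ignored on read. Record identity is
#' the first whitespace-delimited token of the header, matching both
#' Ensembl and NCBI FASTA dialects.
#'
#' @param path Path to a FASTA file (`.fa`, `.fasta`, optionally `.gz`).
#' @param filter A [record_filter()]; defaults to all-pass.
#' @return A `masked_assembly`: list with `seqs` (a
#'   [Biostrings::BStringSet], case preserved), `ids` (first header
#'   tokens), `descriptions` (remainder of headers) and `source` (the
#'   input path).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "ACGTacgt", ">chr2", "NNNN"), fa)
#' asm <- read_assembly(fa)
#' record_lengths(asm)
#' @export
read_assembly <- function(path, filter = record_filter()) {
  if (!file.exists(path))
    stop("input error: no such file: ", path, call. = FALSE)
  stopifnot(inherits(filter, "record_filter"))
  check_fasta_leader(path)
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  keep <- filter_keep(filter, ids, Biostrings::width(seqs))
  structure(list(seqs = seqs[keep],
                 ids = ids[keep],
                 descriptions = descriptions[keep],
                 source = path),
            class = "masked_assembly")
}

# A FASTA stream must open with '>' (after optional blank/comment lines);
# reports the byte offset of the offending content otherwise.
check_fasta_leader <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  offset <- 0L
  repeat {
    byte <- readBin(con, "raw", n = 1L)
    if (length(byte) == 0)
      stop("format error: empty file (no FASTA records): ", path,
           call. = FALSE)
    ch <- rawToChar(byte)
    if (ch == ">") return(invisible(TRUE))
    if (ch %in% c(" ", "\t", "\n", "\r", ";")) {
      # permissive: blank space or old-style ';' comment line before '>'
      if (ch == ";") {
        repeat {
          b2 <- readBin(con, "raw", n = 1L)
          offset <- offset + 1L
          if (length(b2) == 0 || rawToChar(b2) == "\n") break
        }
      }
      offset <- offset + 1L
      next
    }
    stop("format error: not FASTA (no '>' before residues) at byte offset ",
         offset, " in ", path, call. = FALSE)
  }
}

#' @export
print.masked_assembly <- function(x, ...) {
  cat("Soft-masked assembly:", length(x$ids), "record(s),",
      format(sum(as.numeric(Biostrings::width(x$seqs))), big.mark = ","),
      "bp total\n")
  if (length(x$ids)) {
    df <- utils::head(data.frame(id = x$ids,
                                 length = Biostrings::width(x$seqs)), 10)
    print(df, row.names = FALSE)
    if (length(x$ids) > 10) cat("...", length(x$ids) - 10, "more\n")
  }
  invisible(x)
}

#' @export
length.masked_assembly <- function(x) length(x$ids)

#' Record identifiers and lengths of an assembly
#'
#' @param assembly A `masked_assembly` from [read_assembly()].
#' @return `record_ids`: character vector of ids; `record_lengths`: named
#'   integer vector of lengths in bp.
#' @export
record_ids <- function(assembly) assembly$ids

#' @rdname record_ids
#' @export
record_lengths <- function(assembly) {
  stats::setNames(Biostrings::width(assembly$seqs), assembly$ids)
}

#' Per-record summary with masked-base counts
#'
#' Counts soft-masked (lowercase) residues per record. Lowercase of any
#' letter counts as masked, including masked ambiguity codes such as `n`.
#'
#' @param assembly A `masked_assembly`.
#' @return `data.frame` with columns `id`, `length`, `masked_bases`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTacgt"), fa)
#' assembly_summary(read_assembly(fa))
#' @export
assembly_summary <- function(assembly) {
  stopifnot(inherits(assembly, "masked_assembly"))
  if (length(assembly$ids) == 0)
    return(data.frame(id = character(), length = integer(),
                      masked_bases = integer()))
  masked <- as.integer(Biostrings::letterFrequency(
    assembly$seqs, letters = paste(letters, collapse = "")))
  data.frame(id = assembly$ids,
             length = Biostrings::width(assembly$seqs),
             masked_bases = masked)
}

#' Write an assembly back to FASTA
#'
#' Case-preserving writer; lines wrapped at 60 columns. Headers are
#' reassembled as `id description`.
#'
#' @param assembly A `masked_assembly`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path) {
  stopifnot(inherits(assembly, "masked_assembly"))
  seqs <- assembly$seqs
  names(seqs) <- ifelse(nzchar(assembly$descriptions),
                        paste(assembly$ids, assembly$descriptions),
                        assembly$ids)
  Biostrings::writeXStringSet(seqs, path, width = 60L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
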