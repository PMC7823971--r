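#' Remote path templates for assembly retrieval
#'
#' Templates are configuration data, not code: each source maps a species
#' request to candidate remote paths of the soft-masked ("sm") genome
#' FASTA. Placeholders: `{base}`, `{release}`, `{species}` (lowercase,
#' underscores), `{Species}` (capitalised). Overriding `base` with a
#' `file://` URL makes any layout-compatible local directory a test
#' double for the remote repository.
#'
#' @return Named list of per-source template lists (`base`, `paths`).
#' @export
default_fetch_templates <- function() {
  list(
    ensembl = list(
      base = "https://ftp.ensembl.org/pub",
      paths = c("{base}/release-{release}/fasta/{species}/dna/{Species}.dna_sm.toplevel.fa.gz",
                "{base}/release-{release}/fasta/{species}/dna/{Species}.dna_sm.primary_assembly.fa.gz")),
    ncbi = list(
      base = "https://ftp.ncbi.nlm.nih.gov/genomes",
      paths = c("{base}/{release}/{species}/{Species}.dna_sm.fna.gz")))
}

#' Fetch a soft-masked assembly from a genome repository
#'
#' Convenience retrieval: resolves a species request to candidate remote
#' URLs from the source's path template, downloads the first one that
#' resolves into `destdir/<species>/`, verifies a non-trivial size,
#' decompresses in place (keeping the archive), and returns the local
#' FASTA path. Idempotent: an existing complete file is reused without
#' re-download. Hard-masked ("rm") artifacts are rejected — hard-masking
#' replaces repeats with N and destroys the lowercase signal this tool
#' profiles.
#'
#' Never required by the rest of the package: all analysis runs on local
#' files, and tests exercise this function only against a local
#' `file://` mock repository.
#'
#' @param species Species name, e.g. `"esox_lucius"` (case and spaces
#'   are normalised).
#' @param source `"ensembl"` or `"ncbi"` style layout.
#' @param release Release/version token substituted into the template.
#' @param destdir Destination directory; one folder per species.
#' @param base_url Optional base-URL override (e.g. `file:///...` for a
#'   local mirror).
#' @param templates Template set, by default [default_fetch_templates()].
#' @param quiet Suppress download progress.
#' @return Local path of the decompressed FASTA, invisibly.
#' @export
fetch_assembly <- function(species, source = c("ensembl", "ncbi"),
                           release = "current", destdir = ".",
                           base_url = NULL,
                           templates = default_fetch_templates(),
                           quiet = TRUE) {
  source <- match.arg(source)
  tpl <- templates[[source]]
  if (!is.null(base_url)) tpl$base <- base_url
  species_lc <- tolower(gsub("\\s+", "_", trimws(species)))
  species_cap <- sub("^(.)", "\\U\\1", species_lc, perl = TRUE)
  urls <- vapply(tpl$paths, function(p) {
    p <- gsub("{base}", tpl$base, p, fixed = TRUE)
    p <- gsub("{release}", release, p, fixed = TRUE)
    p <- gsub("{species}", species_lc, p, fixed = TRUE)
    gsub("{Species}", species_cap, p, fixed = TRUE)
  }, character(1), USE.NAMES = FALSE)
  if (any(grepl("dna_rm|_rm\\.", urls)))
    stop("parameter error: template points at a hard-masked (rm) artifact; ",
         "soft-masked (sm) FASTA is required because lowercase masking is ",
         "the tool's substrate", call. = FALSE)
  spdir <- file.path(destdir, species_lc)
  dir.create(spdir, recursive = TRUE, showWarnings = FALSE)
  for (url in urls) {
    dest_gz <- file.path(spdir, basename(url))
    dest_fa <- sub("\\.gz$", "", dest_gz)
    if (file.exists(dest_fa) && file.size(dest_fa) > 0)
      return(invisible(dest_fa))  # idempotent: complete file present
    if (!(file.exists(dest_gz) && file.size(dest_gz) > 0)) {
      ok <- tryCatch(
        utils::download.file(url, dest_gz, mode = "wb", quiet = quiet) == 0,
        error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok || !file.exists(dest_gz) || file.size(dest_gz) == 0) {
        if (file.exists(dest_gz)) {
          if (file.size(dest_gz) > 0)
            stop("partial-download error: incomplete transfer of ", url,
                 " (removed ", dest_gz, ")",
                 call. = ignore_file_remove(dest_gz))
          file.remove(dest_gz)
        }
        next
      }
    }
    gunzip_to(dest_gz, dest_fa)
    return(invisible(dest_fa))
  }
  stop("lookup error: could not resolve species '", species,
       "' at source '", source, "'; attempted:\n  ",
       paste(urls, collapse = "\n  "), call. = FALSE)
}

ignore_file_remove <- function(path) { file.remove(path); FALSE }

# stream-decompress .gz to path (binary-safe); plain files are copied
gunzip_to <- function(gz, out) {
  if (!grepl("\\.gz$", gz)) {
    if (gz != out) file.copy(gz, out, overwrite = TRUE)
    return(invisible(out))
  }
  inc <- gzfile(gz, "rb")
  on.exit(close(inc), add = TRUE)
  outc <- file(out, "wb")
  on.exit(close(outc), add = TRUE)
  repeat {
    chunk <- readBin(inc, "raw", n = 1024L * 1024L)
    if (length(chunk) == 0) break
    writeBin(chunk, outc)
  }
  invisible(out)
}
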