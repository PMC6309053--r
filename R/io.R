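#' Write a proteome database as FASTA
#'
#' Standard FASTA wrapped at 60 columns (via Biostrings).
#'
#' @param db Named character vector of sequences.
#' @param path Output file.
#' @export
write_proteome_fasta <- function(db, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(db), path, width = 60L)
  invisible(path)
}

#' Read a proteome database from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_proteome_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write deconvoluted spectra to a block-format text file
#'
#' One block per spectrum: `BEGIN IONS`, `ID=<spectrum_id>`,
#' `PRECURSOR_MASS=<Da, 5 dp>`, one neutral fragment mass per line (5 dp),
#' `END IONS`. Ground truth is never written here (see
#' [write_truth_tsv()]), so the search stage stays blind.
#'
#' @param spectra List of `deconv_spectrum` objects.
#' @param path Output file.
#' @export
write_spectra <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    paste(c("BEGIN IONS",
            paste0("ID=", s$spectrum_id),
            sprintf("PRECURSOR_MASS=%.5f", s$precursor_mass),
            sprintf("%.5f", s$fragment_masses),
            "END IONS", ""), collapse = "\n")
  }, "")
  writeLines(blocks, path, sep = "\n")
  invisible(path)
}

#' Read deconvoluted spectra from a block-format text file
#'
#' Tolerates blank lines and `#` comments between and inside blocks.
#'
#' @param path Spectrum file written by [write_spectra()] (or compatible).
#' @return List of `deconv_spectrum` objects (without ground truth).
#' @export
read_spectra <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed spectrum file: unbalanced BEGIN/END IONS", call. = FALSE)
  lapply(seq_along(starts), function(i) {
    body <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    id_line <- grep("^ID=", body, value = TRUE)
    prec_line <- grep("^PRECURSOR_MASS=", body, value = TRUE)
    if (length(id_line) != 1L || length(prec_line) != 1L)
      stop("malformed spectrum block ", i, call. = FALSE)
    frag <- body[!grepl("^[A-Z_]+=", body)]
    structure(list(spectrum_id = sub("^ID=", "", id_line),
                   precursor_mass = as.numeric(sub("^PRECURSOR_MASS=", "", prec_line)),
                   fragment_masses = sort(as.numeric(frag)),
                   truth = NULL),
              class = "deconv_spectrum")
  })
}

#' Write the ground-truth sidecar table
#'
#' @param spectra List of `deconv_spectrum` objects carrying `truth`.
#' @param path Output TSV.
#' @export
write_truth_tsv <- function(spectra, path) {
  df <- do.call(rbind, lapply(spectra, function(s) {
    tr <- s$truth
    data.frame(spectrum_id = s$spectrum_id, protein_id = tr$protein_id,
               start = tr$start, end = tr$end, mod_site = tr$mod_site,
               mod_mass = tr$mod_mass, stringsAsFactors = FALSE)
  }))
  write_tsv(df, path)
}

#' Read the ground-truth sidecar table
#'
#' @param path TSV written by [write_truth_tsv()].
#' @return Data frame.
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# all tabular outputs: tab-separated, single header row, no quoting
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
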