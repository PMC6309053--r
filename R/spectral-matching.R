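#' N-terminal prefix-mass ladder of a segment
#'
#' Cumulative residue masses at the internal cleavage sites 1..L-1 of an
#' unmodified segment (the N-terminal theoretical fragment ladder).
#'
#' @param segment Amino-acid string.
#' @return Strictly increasing numeric vector of length `nchar(segment) - 1`.
#' @export
#' @examples
#' prefix_masses("GG")
prefix_masses <- function(segment) {
  m <- residue_mass_vector(segment)
  L <- length(m)
  if (L < 2L) return(numeric(0))
  cumsum(m)[seq_len(L - 1L)]
}

#' Theoretical fragment masses of a (possibly modified) proteoform segment
#'
#' N-terminal ladder masses carry the modification shift at cleavage sites at
#' or after the modified residue; C-terminal ladder masses carry it at sites
#' before the modified residue (where the residue lies in the C-terminal
#' fragment). C-terminal fragments are neutral suffix masses (residues plus
#' one water).
#'
#' @param segment Amino-acid string.
#' @param modification Optional `list(site =, mass =)` with `site` a 1-based
#'   position within the segment.
#' @param ion_series Subset of `c("N", "C")`.
#' @return Sorted numeric vector of fragment masses; length `L - 1` per
#'   series.
#' @export
#' @examples
#' theoretical_fragments("EPPLSQETFS", list(site = 5, mass = 79.96633), "N")
theoretical_fragments <- function(segment, modification = NULL,
                                  ion_series = c("N", "C")) {
  ion_series <- match.arg(ion_series, c("N", "C"), several.ok = TRUE)
  pre <- prefix_masses(segment)
  L <- nchar(segment)
  M <- segment_mass(segment)
  site <- if (is.null(modification)) 0L else as.integer(modification$site)
  shift <- if (is.null(modification)) 0 else modification$mass
  if (site != 0L && (site < 1L || site > L))
    stop("modification site outside segment", call. = FALSE)
  out <- numeric(0)
  sites <- seq_len(L - 1L)
  if ("N" %in% ion_series && L > 1L)
    out <- c(out, pre + ifelse(site != 0L & sites >= site, shift, 0))
  if ("C" %in% ion_series && L > 1L)
    out <- c(out, (M - pre) + ifelse(site != 0L & sites < site, shift, 0))
  sort(out)
}

#' Count matched fragment masses at a ppm tolerance
#'
#' Number of theoretical masses with an observed mass within relative
#' tolerance, each observed mass consumed at most once (greedy left-to-right
#' pairing over the sorted lists).
#'
#' @param spectrum_fragments Observed neutral masses (sorted ascending).
#' @param theoretical Theoretical masses (sorted ascending).
#' @param tol_ppm Relative tolerance in parts per million.
#' @return Integer match count.
#' @export
match_count <- function(spectrum_fragments, theoretical, tol_ppm = 15) {
  if (tol_ppm < 0) stop("tol_ppm must be >= 0", call. = FALSE)
  cpp_greedy_match(sort(theoretical), sort(spectrum_fragments), tol_ppm)
}

#' Score a spectrum against a segment allowing one unknown mass shift
#'
#' The unknown shift is `delta = precursor mass - unmodified segment mass`.
#' If `delta` lies within the precursor tolerance the segment is scored as an
#' unmodified match. Otherwise every split site is tried: fragments on the
#' N-terminal side of the split are matched unshifted and fragments spanning
#' the split carry `+delta`; the reported score is the best split's greedy
#' match count. The localization interval brackets the shift between the
#' rightmost matched cleavage site bounding it from the left and the
#' leftmost matched site bounding it from the right (extended to the segment
#' termini when a bounding match is absent).
#'
#' @param spectrum A `deconv_spectrum` (or list with `precursor_mass` and
#'   `fragment_masses`).
#' @param segment Candidate unmodified segment string.
#' @param tol_ppm Fragment and precursor tolerance (ppm).
#' @param ion_series Subset of `c("N", "C")`.
#' @return List with `score`, `delta` and `shift_interval` (integer
#'   `c(first, last)` in segment coordinates, or `NULL` for an unmodified
#'   match).
#' @export
one_shift_align <- function(spectrum, segment, tol_ppm = 15,
                            ion_series = c("N", "C")) {
  if (!nzchar(segment)) stop("empty segment", call. = FALSE)
  ion_series <- match.arg(ion_series, c("N", "C"), several.ok = TRUE)
  obs <- sort(spectrum$fragment_masses)
  M <- segment_mass(segment)
  delta <- spectrum$precursor_mass - M
  pre <- prefix_masses(segment)
  theoN <- if ("N" %in% ion_series) pre else numeric(0)
  theoC <- if ("C" %in% ion_series) M - pre else numeric(0)
  if (abs(delta) <= tol_ppm * 1e-6 * spectrum$precursor_mass) {
    score <- cpp_greedy_match(sort(c(theoN, theoC)), obs, tol_ppm)
    return(list(score = score, delta = delta, shift_interval = NULL))
  }
  r <- cpp_one_shift(theoN, theoC, nchar(segment), obs, delta, tol_ppm)
  list(score = r$score, delta = delta,
       shift_interval = c(r$first, r$last))
}

# cumulative residue-mass vectors (leading 0) for a database sorted by id
db_prefix_masses <- function(db) {
  db <- db[order(names(db))]
  list(ids = names(db),
       seqs = db,
       prefixes = lapply(db, function(s) c(0, cumsum(residue_mass_vector(s)))))
}

prsm_row <- function(spectrum_id, protein_id, start, end, score, delta,
                     shift_first, shift_last) {
  data.frame(spectrum_id = spectrum_id, protein_id = protein_id,
             start = as.integer(start), end = as.integer(end),
             score = as.integer(score), delta = delta,
             shift_first = as.integer(shift_first),
             shift_last = as.integer(shift_last),
             is_decoy = startsWith(protein_id, "DECOY_"),
             stringsAsFactors = FALSE)
}

#' Search a spectrum against a protein database
#'
#' Enumerates every terminally truncated segment of every database protein
#' whose unmodified mass lies within `max_delta` of the precursor mass,
#' scores each with [one_shift_align()] semantics, and returns the best
#' proteoform-spectrum match (PrSM). Ties break deterministically: higher
#' score, then smaller `|delta|`, then lexicographically smallest
#' `(protein_id, start)`. When no candidate exists a score-0 sentinel row is
#' returned.
#'
#' @param spectrum A `deconv_spectrum`.
#' @param db Protein database (named character vector), typically
#'   target+decoy.
#' @param tol_ppm Precursor and fragment tolerance (ppm).
#' @param max_delta Maximal absolute unknown shift (Da) and truncation
#'   enumeration bound.
#' @param min_segment_length Minimal candidate segment length.
#' @param ion_series Subset of `c("N", "C")`.
#' @return One-row data frame: spectrum_id, protein_id, start, end, score,
#'   delta, shift_first, shift_last (0 when no interval), is_decoy.
#' @export
search_database <- function(spectrum, db, tol_ppm = 15, max_delta = 500,
                            min_segment_length = 10,
                            ion_series = c("N", "C")) {
  idx <- db_prefix_masses(db)
  search_one(spectrum, idx, tol_ppm, max_delta, min_segment_length,
             ion_series)
}

search_one <- function(spectrum, idx, tol_ppm, max_delta,
                       min_segment_length, ion_series) {
  r <- cpp_search_db(idx$prefixes, sort(spectrum$fragment_masses),
                     spectrum$precursor_mass, tol_ppm, max_delta,
                     as.integer(min_segment_length), .WATER,
                     "N" %in% ion_series, "C" %in% ion_series)
  if (r$iprot == 0L)
    return(prsm_row(spectrum$spectrum_id, "", 0L, 0L, 0L, 0, 0L, 0L))
  prsm_row(spectrum$spectrum_id, idx$ids[r$iprot], r$start, r$end, r$score,
           r$delta, r$first, r$last)
}

#' Search many spectra against a protein database
#'
#' @param spectra List of `deconv_spectrum` objects.
#' @inheritParams search_database
#' @return Data frame with one best PrSM per spectrum.
#' @export
search_spectra <- function(spectra, db, tol_ppm = 15, max_delta = 500,
                           min_segment_length = 10,
                           ion_series = c("N", "C")) {
  idx <- db_prefix_masses(db)
  do.call(rbind, lapply(spectra, search_one, idx = idx, tol_ppm = tol_ppm,
                        max_delta = max_delta,
                        min_segment_length = min_segment_length,
                        ion_series = ion_series))
}

#' Build a shuffled decoy database
#'
#' One decoy per target protein: the residues of each sequence are randomly
#' permuted (residue multiset preserved) and the id is prefixed `DECOY_`.
#'
#' @param db Target database.
#' @param seed Integer seed; deterministic per seed.
#' @return Named character vector of decoy sequences.
#' @export
build_decoy_db <- function(db, seed = 1) {
  if (any(startsWith(names(db), "DECOY_")))
    stop("target database already contains DECOY_ ids", call. = FALSE)
  set.seed(as.integer(seed))
  out <- vapply(db, function(s)
    paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), "")
  names(out) <- paste0("DECOY_", names(db))
  out
}

#' Filter best-per-spectrum PrSMs at a spectrum-level FDR
#'
#' Finds the smallest score threshold `tau` such that
#' `#decoy(score >= tau) / max(1, #target(score >= tau)) <= fdr_level`,
#' accepts all target PrSMs with `score >= tau` (and score > 0), and marks
#' decoy PrSMs as not accepted (decoys compete in the search but are removed
#' from the accepted set).
#'
#' @param prsms Data frame of best-per-spectrum PrSMs (columns `score`,
#'   `is_decoy`).
#' @param fdr_level Proportion in (0, 1].
#' @return `prsms` with a logical `accepted` column; the chosen threshold is
#'   attached as attribute `fdr_threshold` (`Inf` when nothing passes).
#' @export
filter_fdr <- function(prsms, fdr_level = 0.01) {
  if (fdr_level <= 0 || fdr_level > 1)
    stop("fdr_level must be in (0, 1]", call. = FALSE)
  taus <- sort(unique(prsms$score))
  threshold <- Inf
  for (tau in taus) {
    nd <- sum(prsms$is_decoy & prsms$score >= tau)
    nt <- sum(!prsms$is_decoy & prsms$score >= tau)
    if (nd / max(1, nt) <= fdr_level) { threshold <- tau; break }
  }
  prsms$accepted <- !prsms$is_decoy & prsms$score >= threshold &
    prsms$score > 0
  attr(prsms, "fdr_threshold") <- threshold
  prsms
}
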