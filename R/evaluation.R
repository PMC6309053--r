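#' Judge a homolog-database identification against its expected mapping
#'
#' The protein is correct when the reported homolog protein id equals the
#' mapped homologous protein; the segment is additionally correct when the
#' reported unmodified segment string equals the homologous protein segment
#' (string equality, so coordinate off-by-ones with identical strings still
#' count).
#'
#' @param reported_protein_id Protein id reported by the homolog search.
#' @param reported_segment Unmodified segment string reported by the
#'   homolog search.
#' @param expected Mapping row (or list) with `homolog_protein_id` and
#'   `homolog_segment`.
#' @return `list(correct_protein =, correct_segment =)`.
#' @export
assess_identification <- function(reported_protein_id, reported_segment,
                                  expected) {
  cp <- identical(reported_protein_id, expected$homolog_protein_id)
  cs <- cp && identical(reported_segment, expected$homolog_segment)
  list(correct_protein = cp, correct_segment = cs)
}

#' Assign a spectrum to a mutation-count subgroup
#'
#' Perfect-group spectra (reference proteoform without a mass shift) with
#' `i <= 4` mutations go to `Gi`; mass-shift-group spectra to `Hi`; spectra
#' with 5 or more mutations are excluded.
#'
#' @param group `"perfect"` or `"mass_shift"`.
#' @param mutation_count Number of mutations between the reference segment
#'   and its homologous segment.
#' @return Label `"G0"`..`"G4"`, `"H0"`..`"H4"`, or `"excluded"`.
#' @export
assign_subgroup <- function(group, mutation_count) {
  group <- match.arg(group, c("perfect", "mass_shift"))
  if (mutation_count > 4) return("excluded")
  paste0(if (group == "perfect") "G" else "H", mutation_count)
}

#' Correct-protein and correct-segment rates per subgroup
#'
#' For each subgroup, `n_t` is the number of spectra in the subgroup, `n_p`
#' and `n_s` count the spectra among them that the homolog-database search
#' accepted with the correct protein / the correct protein segment. The CP
#' and CS rates are `100 * n_p / n_t` and `100 * n_s / n_t`. Empty subgroups
#' are absent from the table.
#'
#' @param records Data frame with columns `spectrum_id`, `subgroup`,
#'   `correct_protein`, `correct_segment` (rows with subgroup
#'   `"excluded"` are ignored).
#' @param accepted_ids Spectrum ids accepted by the homolog-database search.
#' @return Data frame: subgroup, n_t, n_p, n_s, cp_rate, cs_rate (percent,
#'   2 decimal places).
#' @export
compute_rates <- function(records, accepted_ids) {
  labels <- c(paste0("G", 0:4), paste0("H", 0:4))
  rows <- lapply(labels, function(lab) {
    r <- records[records$subgroup == lab, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    acc <- r$spectrum_id %in% accepted_ids
    n_t <- nrow(r)
    n_p <- sum(acc & r$correct_protein)
    n_s <- sum(acc & r$correct_segment)
    data.frame(subgroup = lab, n_t = n_t, n_p = n_p, n_s = n_s,
               cp_rate = round(100 * n_p / n_t, 2),
               cs_rate = round(100 * n_s / n_t, 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(subgroup = character(0), n_t = integer(0),
                      n_p = integer(0), n_s = integer(0),
                      cp_rate = numeric(0), cs_rate = numeric(0),
                      stringsAsFactors = FALSE)
  out
}

#' Judge a reported mass-shift localization interval
#'
#' The reported interval (segment coordinates) is correct when it covers
#' every required position: the positions of all substitutions, insertions
#' and deletions, plus the modification site for mass-shift-group spectra.
#' An empty required set is vacuously correct.
#'
#' @param reported_interval Integer `c(first, last)` or `NULL` (no interval
#'   reported).
#' @param required_positions Integer positions that must be covered.
#' @return Logical.
#' @export
assess_localization <- function(reported_interval, required_positions) {
  if (length(required_positions) == 0L) return(TRUE)
  if (is.null(reported_interval)) return(FALSE)
  all(required_positions >= reported_interval[1] &
        required_positions <= reported_interval[2])
}

#' Histogram of sequence identities
#'
#' Half-open bins `[lo, lo + width)` over \[0, 100\]; the top bin is closed
#' at 100. Counts sum to the number of identities.
#'
#' @param identities Numeric vector of percent identities in \[0, 100\], or
#'   a mapping data frame with an `identity_pct` column.
#' @param bin_width Bin width in percent (must divide 100).
#' @return Data frame: lower, upper, count.
#' @export
identity_histogram <- function(identities, bin_width = 5) {
  if (is.data.frame(identities)) identities <- identities$identity_pct
  if (100 %% bin_width != 0) stop("bin_width must divide 100", call. = FALSE)
  nb <- as.integer(100 / bin_width)
  lower <- (seq_len(nb) - 1) * bin_width
  idx <- pmin(floor(identities / bin_width), nb - 1) + 1
  data.frame(lower = lower, upper = lower + bin_width,
             count = tabulate(idx, nbins = nb))
}

#' Evaluate homolog-search identifications against the reference mapping
#'
#' Assembles one evaluation record per mapped spectrum: its group (perfect
#' when the true reference proteoform is unmodified, mass-shift otherwise),
#' the mutation count and subgroup, correctness of the homolog-search
#' protein and segment, and - for correct-segment identifications with at
#' least one mutation - whether the reported shift interval covers all
#' mutation positions (plus the modification site for the mass-shift
#' group, projected through the reference-to-homolog alignment).
#'
#' @param truth Ground-truth data frame (see [write_truth_tsv()]).
#' @param ref_prsms Reference-search PrSMs with an `accepted` column.
#' @param hom_prsms Homolog-search PrSMs with an `accepted` column.
#' @param mapping Output of [map_identifications()] (with its `alignments`
#'   attribute).
#' @param homolog_db Homologous proteome.
#' @return List: `records` (evaluation data frame), `rates`
#'   (per-subgroup table from [compute_rates()]), `localization`
#'   (per-group assessed/correct counts and accuracy).
#' @export
evaluate_identifications <- function(truth, ref_prsms, hom_prsms, mapping,
                                     homolog_db) {
  alns <- attr(mapping, "alignments")
  hom_by_id <- split(hom_prsms, hom_prsms$spectrum_id)
  truth_by_id <- split(truth, truth$spectrum_id)
  ref_by_id <- split(ref_prsms, ref_prsms$spectrum_id)
  recs <- vector("list", nrow(mapping))
  for (i in seq_len(nrow(mapping))) {
    sid <- mapping$spectrum_id[i]
    tr <- truth_by_id[[sid]]
    group <- if (tr$mod_site != 0) "mass_shift" else "perfect"
    mc <- mapping$mutation_count[i]
    subgroup <- assign_subgroup(group, mc)
    hp <- hom_by_id[[sid]]
    accepted <- !is.null(hp) && isTRUE(hp$accepted)
    cp <- FALSE; cs <- FALSE
    loc_assessed <- FALSE; loc_correct <- NA
    if (accepted) {
      seg <- substr(homolog_db[[hp$protein_id]], hp$start, hp$end)
      ok <- assess_identification(hp$protein_id, seg, mapping[i, ])
      cp <- ok$correct_protein; cs <- ok$correct_segment
      if (cs && mc >= 1 && subgroup != "excluded") {
        loc_assessed <- TRUE
        a <- alns[[sid]]
        required <- a$mutation_positions - a$subject_start + 1L
        if (group == "mass_shift") {
          # project the true modification site (reference protein
          # coordinates) through the reference segment into the homologous
          # segment
          rp <- ref_by_id[[sid]]
          qpos <- tr$mod_site - rp$start + 1L
          qpos <- min(max(qpos, 1L), rp$end - rp$start + 1L)
          required <- c(required,
                        project_query_position(a, qpos) - a$subject_start + 1L)
        }
        interval <- if (hp$shift_first > 0) c(hp$shift_first, hp$shift_last)
                    else NULL
        loc_correct <- assess_localization(interval, required)
      }
    }
    recs[[i]] <- data.frame(spectrum_id = sid, group = group,
                            mutation_count = mc, subgroup = subgroup,
                            accepted_homolog = accepted,
                            correct_protein = cp, correct_segment = cs,
                            localization_assessed = loc_assessed,
                            localization_correct = loc_correct,
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  accepted_ids <- records$spectrum_id[records$accepted_homolog]
  rates <- compute_rates(records, accepted_ids)
  loc <- do.call(rbind, lapply(c("perfect", "mass_shift"), function(g) {
    r <- records[records$group == g & records$localization_assessed, ,
                 drop = FALSE]
    data.frame(group = g, n_assessed = nrow(r),
               n_correct = sum(r$localization_correct),
               accuracy = if (nrow(r)) round(100 * mean(r$localization_correct), 2)
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(records = records, rates = rates, localization = loc)
}
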