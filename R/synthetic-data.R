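#' Generate a random reference proteome
#'
#' Creates a database of random protein sequences that plays the role of the
#' proteome of the species under study (the database a reference search would
#' use). Residues are drawn i.i.d. from `composition` (default uniform over
#' the 20 standard amino acids).
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer vector `c(min, max)` of sequence lengths,
#'   within \[20, 1000\].
#' @param seed Integer seed; the output is deterministic for a fixed seed.
#' @param composition Optional named numeric vector of residue weights
#'   (names must be the 20 standard letters); default uniform.
#' @param id_prefix Prefix for generated protein ids.
#' @return A named character vector of sequences (a proteome database);
#'   names are unique protein ids.
#' @export
#' @examples
#' db <- generate_reference_proteome(3, c(30, 40), seed = 1)
generate_reference_proteome <- function(n_proteins, length_range, seed,
                                        composition = NULL,
                                        id_prefix = "REF") {
  if (!is.numeric(n_proteins) || n_proteins < 1)
    stop("n_proteins must be >= 1", call. = FALSE)
  length_range <- as.integer(round(length_range))
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 20L || length_range[2] > 1000L)
    stop("length_range must be c(min, max) within [20, 1000]", call. = FALSE)
  aa <- amino_acids()
  if (is.null(composition)) {
    prob <- rep(1 / 20, 20)
  } else {
    if (!all(sort(names(composition)) == sort(aa)))
      stop("composition must be named by the 20 standard residues",
           call. = FALSE)
    prob <- as.numeric(composition[aa]) / sum(composition)
  }
  set.seed(as.integer(seed))
  n_proteins <- as.integer(n_proteins)
  lenspace <- seq.int(length_range[1], length_range[2])
  lens <- lenspace[sample.int(length(lenspace), n_proteins, replace = TRUE)]
  seqs <- vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE, prob = prob), collapse = ""), "")
  names(seqs) <- sprintf("%s%04d", id_prefix, seq_len(n_proteins))
  seqs
}

#' Apply a mutation-event log to a reference sequence
#'
#' Replays substitution, insertion and deletion events (addressed in
#' reference coordinates) over a reference sequence, reconstructing the
#' mutated sequence exactly. Insertions insert `alt_aa` before `ref_pos`
#' (`ref_pos = length + 1` appends at the C terminus).
#'
#' @param sequence Reference amino-acid string.
#' @param events Data frame with columns `kind` (`"substitution"`,
#'   `"insertion"`, `"deletion"`), `ref_pos`, `ref_aa`, `alt_aa`.
#' @return The mutated sequence string.
#' @export
apply_mutations <- function(sequence, events) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (nrow(events) == 0L) return(sequence)
  # apply right-to-left so reference positions stay valid
  events <- events[order(events$ref_pos, decreasing = TRUE), , drop = FALSE]
  out <- as.list(chars)
  for (i in seq_len(nrow(events))) {
    kind <- events$kind[i]
    p <- events$ref_pos[i]
    if (kind == "substitution") {
      if (out[[p]] != events$ref_aa[i])
        stop("event log inconsistent with sequence at position ", p,
             call. = FALSE)
      out[[p]] <- events$alt_aa[i]
    } else if (kind == "deletion") {
      out[[p]] <- character(0)
    } else if (kind == "insertion") {
      if (p > length(chars)) {
        out[[length(chars)]] <- c(out[[length(chars)]], events$alt_aa[i])
      } else {
        out[[p]] <- c(events$alt_aa[i], out[[p]])
      }
    } else stop("unknown mutation kind: ", kind, call. = FALSE)
  }
  paste(unlist(out), collapse = "")
}

#' Derive a homologous proteome by planting mutations
#'
#' Produces, for each reference protein, a homolog carrying exactly the
#' requested number of mutation events (per-residue counting: a one-residue
#' insertion or deletion is one event), together with a replayable event log.
#' Event positions are distinct; substitutions draw the alternative residue
#' uniformly from the 19 others.
#'
#' @param ref Reference proteome (named character vector).
#' @param mutations_per_protein Single count applied to every protein, or a
#'   named vector keyed by protein id.
#' @param indel_fraction Probability that an event is an indel (then
#'   insertion or deletion with equal probability); the rest are
#'   substitutions.
#' @param seed Integer seed.
#' @param position_window Fractional interval `c(lo, hi)` of each sequence
#'   within which mutation positions are sampled (default the whole
#'   sequence). Restricting the window keeps planted mutations inside
#'   segments that survive terminal truncation.
#' @return List with `db` (homolog proteome, same ids as `ref`) and
#'   `events` (data frame: protein_id, kind, ref_pos, ref_aa, alt_aa).
#' @export
mutate_proteome <- function(ref, mutations_per_protein, indel_fraction = 0.2,
                            seed = 1, position_window = c(0, 1)) {
  if (any(mutations_per_protein < 0))
    stop("mutations_per_protein must be >= 0", call. = FALSE)
  if (indel_fraction < 0 || indel_fraction > 1)
    stop("indel_fraction must be in [0, 1]", call. = FALSE)
  ids <- names(ref)
  k_by_id <- if (length(mutations_per_protein) == 1L && is.null(names(mutations_per_protein))) {
    stats::setNames(rep(as.integer(mutations_per_protein), length(ids)), ids)
  } else {
    if (!all(ids %in% names(mutations_per_protein)))
      stop("mutations_per_protein must cover every protein id", call. = FALSE)
    stats::setNames(as.integer(mutations_per_protein[ids]), ids)
  }
  set.seed(as.integer(seed))
  aa <- amino_acids()
  hom <- character(length(ref))
  names(hom) <- ids
  ev_list <- vector("list", length(ref))
  for (idx in seq_along(ref)) {
    id <- ids[idx]
    s <- ref[[idx]]
    L <- nchar(s)
    k <- k_by_id[[id]]
    if (k > L)
      stop("requested ", k, " mutations for ", id, " of length ", L,
           call. = FALSE)
    lo <- max(1L, ceiling(position_window[1] * L))
    hi <- min(L, floor(position_window[2] * L))
    allowed <- seq.int(lo, hi)
    if (k > length(allowed))
      stop("position window too narrow for ", k, " mutations in ", id,
           call. = FALSE)
    if (k == 0L) {
      hom[idx] <- s
      ev_list[[idx]] <- NULL
      next
    }
    pos <- sort(allowed[sample.int(length(allowed), k)])
    is_indel <- stats::runif(k) < indel_fraction
    is_ins <- is_indel & (stats::runif(k) < 0.5)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    kind <- ifelse(!is_indel, "substitution",
                   ifelse(is_ins, "insertion", "deletion"))
    ref_aa <- ifelse(kind == "insertion", "", chars[pos])
    alt_aa <- vapply(seq_len(k), function(i) {
      switch(kind[i],
        substitution = sample(setdiff(aa, chars[pos[i]]), 1L),
        insertion = sample(aa, 1L),
        deletion = "")
    }, "")
    ev <- data.frame(protein_id = id, kind = kind, ref_pos = pos,
                     ref_aa = ref_aa, alt_aa = alt_aa,
                     stringsAsFactors = FALSE)
    hom[idx] <- apply_mutations(s, ev)
    ev_list[[idx]] <- ev
  }
  events <- do.call(rbind, ev_list[!vapply(ev_list, is.null, TRUE)])
  if (is.null(events))
    events <- data.frame(protein_id = character(0), kind = character(0),
                         ref_pos = integer(0), ref_aa = character(0),
                         alt_aa = character(0), stringsAsFactors = FALSE)
  list(db = hom, events = events)
}

#' Sample proteoforms from a proteome
#'
#' Draws proteoforms (protein segment plus at most one localized
#' modification) emulating intact-protein species with terminal truncations.
#' With probability `ptm_probability` exactly one modification from
#' `ptm_menu` is placed at a uniformly random site inside the segment.
#'
#' @param db Proteome database (named character vector).
#' @param n Number of proteoforms.
#' @param truncation_model `c(max_n_trim, max_c_trim)` maximal fractions of
#'   the sequence removable from the N and C terminus.
#' @param min_length Minimal segment length (trims are reduced to honour it).
#' @param ptm_menu List of `list(name=, mass=)` candidate modifications;
#'   required when `ptm_probability > 0`.
#' @param ptm_probability Probability a proteoform carries one modification.
#' @param seed Integer seed.
#' @param protein_ids Optional vector of source protein ids (recycled to
#'   length `n`); default: sampled uniformly from `db`.
#' @return Data frame with columns protein_id, start, end, mod_site (0 when
#'   unmodified, otherwise a 1-based protein coordinate inside
#'   \[start, end\]), mod_mass, mod_name.
#' @export
sample_proteoforms <- function(db, n, truncation_model = c(0.1, 0.1),
                               min_length = 15, ptm_menu = NULL,
                               ptm_probability = 0, seed = 1,
                               protein_ids = NULL) {
  if (length(db) == 0L) stop("empty proteome database", call. = FALSE)
  if (ptm_probability > 0 && (is.null(ptm_menu) || length(ptm_menu) == 0L))
    stop("ptm_menu must be non-empty when ptm_probability > 0", call. = FALSE)
  set.seed(as.integer(seed))
  ids <- if (is.null(protein_ids)) sample(names(db), n, replace = TRUE)
         else rep_len(protein_ids, n)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    id <- ids[i]
    L <- nchar(db[[id]])
    ntrim <- sample.int(floor(truncation_model[1] * L) + 1L, 1L) - 1L
    ctrim <- sample.int(floor(truncation_model[2] * L) + 1L, 1L) - 1L
    # honour the minimal segment length by giving residues back, C side first
    deficit <- min_length - (L - ntrim - ctrim)
    if (deficit > 0) {
      give <- min(ctrim, deficit)
      ctrim <- ctrim - give
      deficit <- deficit - give
      ntrim <- ntrim - min(ntrim, max(0, deficit))
    }
    start <- ntrim + 1L
    end <- L - ctrim
    mod_site <- 0L; mod_mass <- 0; mod_name <- ""
    if (ptm_probability > 0 && stats::runif(1) < ptm_probability) {
      m <- ptm_menu[[sample.int(length(ptm_menu), 1L)]]
      mod_site <- sample(seq.int(start, end), 1L)
      mod_mass <- m$mass
      mod_name <- m$name
    }
    res[[i]] <- data.frame(protein_id = id, start = start, end = end,
                           mod_site = mod_site, mod_mass = mod_mass,
                           mod_name = mod_name, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

# fetch and validate the unmodified segment string of a proteoform row
proteoform_segment <- function(pf, db) {
  pf <- as.list(pf)
  if (!pf$protein_id %in% names(db))
    stop("proteoform references unknown protein ", pf$protein_id,
         call. = FALSE)
  L <- nchar(db[[pf$protein_id]])
  if (pf$start < 1 || pf$end > L || pf$start > pf$end)
    stop("proteoform bounds [", pf$start, ",", pf$end,
         "] invalid for protein of length ", L, call. = FALSE)
  if (pf$mod_site != 0 && (pf$mod_site < pf$start || pf$mod_site > pf$end))
    stop("modification site outside proteoform segment", call. = FALSE)
  substr(db[[pf$protein_id]], pf$start, pf$end)
}

#' Simulate a deconvoluted MS/MS spectrum of a proteoform
#'
#' Builds the theoretical fragment-mass ladder of the proteoform (shifting
#' fragments that contain the modification), retains each fragment
#' independently with `peak_keep_probability`, and perturbs all masses with
#' Gaussian relative error of scale `mass_error_ppm` ppm. The precursor mass
#' is the unmodified segment mass plus the modification shift, perturbed the
#' same way.
#'
#' @param pf One proteoform (one-row data frame or list as produced by
#'   [sample_proteoforms()]).
#' @param db The proteome the proteoform refers to.
#' @param ion_series Subset of `c("N", "C")`: which fragment ladders to emit.
#' @param peak_keep_probability Per-fragment retention probability in (0, 1].
#' @param mass_error_ppm Standard deviation of the relative mass error, ppm.
#' @param seed Optional integer seed.
#' @param spectrum_id Spectrum identifier.
#' @return A `deconv_spectrum`: list with `spectrum_id`, `precursor_mass`,
#'   `fragment_masses` (sorted ascending), and `truth` (the proteoform).
#' @export
simulate_spectrum <- function(pf, db, ion_series = c("N", "C"),
                              peak_keep_probability = 1, mass_error_ppm = 0,
                              seed = NULL, spectrum_id = "spec_1") {
  if (peak_keep_probability <= 0 || peak_keep_probability > 1)
    stop("peak_keep_probability must be in (0, 1]", call. = FALSE)
  if (mass_error_ppm < 0) stop("mass_error_ppm must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pf <- as.list(pf)
  segment <- proteoform_segment(pf, db)
  modification <- NULL
  if (pf$mod_site != 0)
    modification <- list(site = pf$mod_site - pf$start + 1L,
                         mass = pf$mod_mass)
  theo <- theoretical_fragments(segment, modification, ion_series)
  precursor <- segment_mass(segment) + (if (is.null(modification)) 0 else pf$mod_mass)
  perturb <- function(m) m * (1 + stats::rnorm(length(m), 0, mass_error_ppm) * 1e-6)
  keep <- stats::runif(length(theo)) <= peak_keep_probability
  frag <- sort(perturb(theo[keep]))
  precursor <- perturb(precursor)
  frag <- frag[frag > 0 & frag < precursor]
  if (length(frag) > 1L) {
    # drop near-duplicates (within 1 ppm), e.g. coinciding N/C ladder masses
    dup <- c(FALSE, diff(frag) <= frag[-length(frag)] * 1e-6)
    frag <- frag[!dup]
  }
  structure(list(spectrum_id = spectrum_id,
                 precursor_mass = precursor,
                 fragment_masses = frag,
                 truth = pf),
            class = "deconv_spectrum")
}

#' Simulate spectra for a set of proteoforms
#'
#' @param proteoforms Data frame from [sample_proteoforms()].
#' @param db Proteome database.
#' @param seed Integer seed (one stream across all spectra).
#' @param id_prefix Prefix for spectrum ids.
#' @inheritParams simulate_spectrum
#' @return List of `deconv_spectrum` objects.
#' @export
simulate_spectra <- function(proteoforms, db, ion_series = c("N", "C"),
                             peak_keep_probability = 1, mass_error_ppm = 0,
                             seed = 1, id_prefix = "spec") {
  set.seed(as.integer(seed))
  lapply(seq_len(nrow(proteoforms)), function(i)
    simulate_spectrum(proteoforms[i, ], db, ion_series,
                      peak_keep_probability, mass_error_ppm, seed = NULL,
                      spectrum_id = sprintf("%s_%04d", id_prefix, i)))
}

#' @export
print.deconv_spectrum <- function(x, ...) {
  cat("Deconvoluted spectrum", x$spectrum_id, "\n")
  cat(sprintf("  precursor mass: %.5f Da\n", x$precursor_mass))
  cat(sprintf("  fragments: %d\n", length(x$fragment_masses)))
  invisible(x)
}
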