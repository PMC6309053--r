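#' Default modification menu
#'
#' Common monoisotopic modification masses used when simulating the
#' mass-shift group: phosphorylation (+HPO3), acetylation (+C2H2O) and
#' methylation (+CH2).
#'
#' @return List of `list(name =, mass =)`.
#' @export
default_ptm_menu <- function() {
  list(list(name = "phospho", mass = 79.96633),
       list(name = "acetyl", mass = 42.01057),
       list(name = "methyl", mass = 14.01565))
}

#' Build a pipeline configuration
#'
#' Assembles and validates the full parameter set of the two-database
#' experiment. Defaults are the benchmark study conditions: 10 subgroup
#' cells (perfect / mass-shift crossed with 0-4 planted mutations), 10
#' proteins and 200 spectra per cell, both fragment-ion series, 30% peak
#' dropout, exact fragment masses, 15 ppm tolerances, 1% spectrum-level
#' FDR, E-value cutoff 0.01, local-search gaps 11/1 and global-local gaps
#' 10/4.
#'
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @param n_proteins_per_cell Reference proteins per subgroup cell.
#' @param spectra_per_subgroup Spectra per subgroup cell.
#' @param groups Proteoform groups to simulate (subset of `"perfect"`,
#'   `"mass_shift"`).
#' @param mutation_counts Planted mutation counts defining the subgroup
#'   cells.
#' @param length_range Protein length range (residues).
#' @param indel_fraction Fraction of planted mutations that are indels.
#' @param position_window Fractional sequence window for planted mutations
#'   (kept inside segments that survive truncation).
#' @param truncation_model Maximal N-/C-terminal trim fractions.
#' @param min_proteoform_length Minimal proteoform segment length.
#' @param ptm_menu Modification menu for the mass-shift group.
#' @param tol_ppm Precursor and fragment mass tolerance (ppm).
#' @param fdr_level Spectrum-level FDR for accepting PrSMs.
#' @param max_delta Maximal absolute unknown mass shift (Da).
#' @param min_segment_length Minimal candidate segment length in the search.
#' @param local_gap_open,local_gap_extend Gap costs of the local search.
#' @param gap_open,gap_extend Gap costs of the global-local alignment.
#' @param evalue_cutoff E-value cutoff of the local search.
#' @param ion_series Fragment ladders to simulate and search.
#' @param peak_keep_probability Per-fragment retention probability.
#' @param mass_error_ppm Mass-error scale (ppm standard deviation).
#' @param lambda,K Karlin-Altschul constants.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            n_proteins_per_cell = 10,
                            spectra_per_subgroup = 200,
                            groups = c("perfect", "mass_shift"),
                            mutation_counts = 0:4,
                            length_range = c(40, 60),
                            indel_fraction = 0.2,
                            position_window = c(0.15, 0.85),
                            truncation_model = c(0.1, 0.1),
                            min_proteoform_length = 15,
                            ptm_menu = default_ptm_menu(),
                            tol_ppm = 15,
                            fdr_level = 0.01,
                            max_delta = 500,
                            min_segment_length = 10,
                            local_gap_open = 11, local_gap_extend = 1,
                            gap_open = 10, gap_extend = 4,
                            evalue_cutoff = 0.01,
                            ion_series = c("N", "C"),
                            peak_keep_probability = 0.7,
                            mass_error_ppm = 0,
                            lambda = 0.267, K = 0.041) {
  cfg <- list(seed = as.integer(seed),
              n_proteins_per_cell = as.integer(n_proteins_per_cell),
              spectra_per_subgroup = as.integer(spectra_per_subgroup),
              groups = groups,
              mutation_counts = as.integer(mutation_counts),
              length_range = as.numeric(length_range),
              indel_fraction = indel_fraction,
              position_window = as.numeric(position_window),
              truncation_model = as.numeric(truncation_model),
              min_proteoform_length = as.integer(min_proteoform_length),
              ptm_menu = ptm_menu,
              tol_ppm = tol_ppm, fdr_level = fdr_level,
              max_delta = max_delta,
              min_segment_length = as.integer(min_segment_length),
              local_gap_open = local_gap_open,
              local_gap_extend = local_gap_extend,
              gap_open = gap_open, gap_extend = gap_extend,
              evalue_cutoff = evalue_cutoff,
              ion_series = ion_series,
              peak_keep_probability = peak_keep_probability,
              mass_error_ppm = mass_error_ppm,
              lambda = lambda, K = K)
  stopifnot(cfg$tol_ppm > 0, cfg$fdr_level > 0, cfg$fdr_level <= 1,
            cfg$max_delta > 0, cfg$evalue_cutoff > 0,
            cfg$gap_open >= 0, cfg$gap_extend > 0,
            cfg$local_gap_open >= 0, cfg$local_gap_extend > 0,
            cfg$peak_keep_probability > 0, cfg$peak_keep_probability <= 1,
            cfg$mass_error_ppm >= 0,
            all(cfg$ion_series %in% c("N", "C")),
            all(cfg$groups %in% c("perfect", "mass_shift")),
            all(cfg$mutation_counts >= 0))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration snapshot
#'
#' @param path YAML file written by [run_experiment()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Derive a per-stage child seed from the global seed
#'
#' Deterministic fan-out of one global seed to independent stage seeds,
#' keyed by the stage name, so stages stay reproducible when rerun in
#' isolation.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Number of possible substitution types
#'
#' Ordered pairs of distinct residues: each letter can mutate to any other,
#' giving `n * (n - 1)` types (380 for the 20 standard amino acids).
#'
#' @param alphabet Character vector of distinct residue letters.
#' @return Integer count.
#' @export
mutation_type_count <- function(alphabet = amino_acids()) {
  if (anyDuplicated(alphabet)) stop("alphabet letters must be distinct",
                                    call. = FALSE)
  length(alphabet) * (length(alphabet) - 1L)
}

format_prsms <- function(prsms) {
  prsms$delta <- sprintf("%.5f", prsms$delta)
  prsms
}

#' Run the two-database evaluation experiment end to end
#'
#' Simulates the reference and homologous proteomes and the spectra,
#' searches the spectra against both (target+decoy) databases, filters at
#' the spectrum-level FDR, maps accepted reference identifications to
#' homologous segments, and computes the per-subgroup CP/CS rate table,
#' localization accuracy and identity histogram. All artifacts are written
#' under `outdir`; rerunning with the same configuration reproduces them
#' bit for bit.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory (created if needed). On failure, files
#'   written by the partial run are removed.
#' @return A `tdhomolog_experiment` object (list with `config`, `counts`,
#'   `rates`, `localization`, `records`, `mapping`, `histogram`, `ref_prsms`,
#'   `hom_prsms`, `outdir`); see `summary()` and `plot()` methods.
#' @export
run_experiment <- function(cfg = pipeline_config(), outdir = tempfile("tdh_")) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- file.path(outdir, c(
    "reference.fasta", "homolog.fasta", "spectra.txt", "truth.tsv",
    "prsm_reference.tsv", "prsm_homolog.tsv", "mapping.tsv",
    "evaluation.tsv", "rates.tsv", "identity_histogram.tsv", "config.yaml",
    "pipeline.log"))
  tryCatch(
    run_experiment_impl(cfg, outdir),
    error = function(e) {
      unlink(paths[file.exists(paths)])
      stop("pipeline failed (partial outputs removed): ",
           conditionMessage(e), call. = FALSE)
    })
}

run_experiment_impl <- function(cfg, outdir) {
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0("INFO ", sprintf(...)))
  }
  cells <- expand.grid(group = cfg$groups, k = cfg$mutation_counts,
                       stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  npc <- cfg$n_proteins_per_cell

  ref <- generate_reference_proteome(n_cells * npc, cfg$length_range,
                                     stage_seed(cfg$seed, "reference"))
  cell_of_protein <- rep(seq_len(n_cells), each = npc)
  k_by_id <- stats::setNames(cells$k[cell_of_protein], names(ref))
  hom <- mutate_proteome(ref, k_by_id, cfg$indel_fraction,
                         stage_seed(cfg$seed, "mutate"),
                         cfg$position_window)
  say("simulate: %d reference proteins, %d homologs (%d mutation events)",
      length(ref), length(hom$db), nrow(hom$events))

  pfs <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    ids <- names(ref)[cell_of_protein == ci]
    pfs[[ci]] <- sample_proteoforms(
      ref, cfg$spectra_per_subgroup, cfg$truncation_model,
      cfg$min_proteoform_length, cfg$ptm_menu,
      ptm_probability = if (cells$group[ci] == "mass_shift") 1 else 0,
      seed = stage_seed(cfg$seed, paste0("proteoforms", ci)),
      protein_ids = rep_len(ids, cfg$spectra_per_subgroup))
  }
  pfs <- do.call(rbind, pfs)
  spectra <- simulate_spectra(pfs, ref, cfg$ion_series,
                              cfg$peak_keep_probability, cfg$mass_error_ppm,
                              seed = stage_seed(cfg$seed, "spectra"))
  say("simulate: %d spectra (%d with a modification)", length(spectra),
      sum(pfs$mod_site != 0))

  write_proteome_fasta(ref, file.path(outdir, "reference.fasta"))
  write_proteome_fasta(hom$db, file.path(outdir, "homolog.fasta"))
  write_spectra(spectra, file.path(outdir, "spectra.txt"))
  write_truth_tsv(spectra, file.path(outdir, "truth.tsv"))
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))

  truth <- read_truth_tsv(file.path(outdir, "truth.tsv"))

  search_stage <- function(db, decoy_stage, label) {
    full <- c(db, build_decoy_db(db, stage_seed(cfg$seed, decoy_stage)))
    prsms <- search_spectra(spectra, full, cfg$tol_ppm, cfg$max_delta,
                            cfg$min_segment_length, cfg$ion_series)
    prsms <- filter_fdr(prsms, cfg$fdr_level)
    say("search %s: %d spectra, %d accepted at %.2g FDR (threshold %s)",
        label, nrow(prsms), sum(prsms$accepted), cfg$fdr_level,
        format(attr(prsms, "fdr_threshold")))
    prsms
  }
  ref_prsms <- search_stage(ref, "decoy_ref", "reference")
  hom_prsms <- search_stage(hom$db, "decoy_hom", "homolog")
  write_tsv(format_prsms(ref_prsms), file.path(outdir, "prsm_reference.tsv"))
  write_tsv(format_prsms(hom_prsms), file.path(outdir, "prsm_homolog.tsv"))

  accepted_ref <- ref_prsms[ref_prsms$accepted, , drop = FALSE]
  mapping <- map_identifications(accepted_ref, ref, hom$db,
                                 cfg$evalue_cutoff, cfg$local_gap_open,
                                 cfg$local_gap_extend, cfg$gap_open,
                                 cfg$gap_extend, cfg$lambda, cfg$K)
  say("map: %d of %d accepted reference PrSMs mapped to a homolog (%d unmapped)",
      nrow(mapping), nrow(accepted_ref), attr(mapping, "n_unmapped"))
  map_out <- mapping
  map_out$identity_pct <- sprintf("%.1f", map_out$identity_pct)
  map_out$evalue <- formatC(map_out$evalue, format = "e", digits = 1)
  write_tsv(map_out, file.path(outdir, "mapping.tsv"))

  ev <- evaluate_identifications(truth, ref_prsms, hom_prsms, mapping,
                                 hom$db)
  n_excluded <- sum(ev$records$subgroup == "excluded")
  say("evaluate: %d records, %d excluded (more than 4 mutations)",
      nrow(ev$records), n_excluded)
  hist_df <- identity_histogram(mapping, bin_width = 5)
  write_tsv(ev$records, file.path(outdir, "evaluation.tsv"))
  write_tsv(ev$rates, file.path(outdir, "rates.tsv"))
  write_tsv(hist_df, file.path(outdir, "identity_histogram.tsv"))

  counts <- list(n_proteins = length(ref), n_spectra = length(spectra),
                 n_accepted_reference = sum(ref_prsms$accepted),
                 n_accepted_homolog = sum(hom_prsms$accepted),
                 n_mapped = nrow(mapping),
                 n_unmapped = attr(mapping, "n_unmapped"),
                 n_excluded = n_excluded)
  writeLines(log_lines, file.path(outdir, "pipeline.log"))
  structure(list(config = cfg, counts = counts, rates = ev$rates,
                 localization = ev$localization, records = ev$records,
                 mapping = mapping, histogram = hist_df,
                 ref_prsms = ref_prsms, hom_prsms = hom_prsms,
                 outdir = outdir),
            class = "tdhomolog_experiment")
}

#' @export
print.tdhomolog_experiment <- function(x, ...) {
  cat("Two-database proteoform identification experiment\n")
  cat(sprintf("  %d spectra against %d reference proteins (seed %d)\n",
              x$counts$n_spectra, x$counts$n_proteins, x$config$seed))
  cat(sprintf("  accepted: %d (reference search), %d (homolog search)\n",
              x$counts$n_accepted_reference, x$counts$n_accepted_homolog))
  cat("  CP/CS rates per subgroup:\n")
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' @export
summary.tdhomolog_experiment <- function(object, ...) {
  print(object)
  cat("  mass-shift localization accuracy:\n")
  print(object$localization, row.names = FALSE)
  cat(sprintf("  mapped %d, unmapped %d, excluded (>4 mutations) %d\n",
              object$counts$n_mapped, object$counts$n_unmapped,
              object$counts$n_excluded))
  invisible(object)
}

#' Plot the subgroup rates and the identity histogram
#'
#' Left panel: CP and CS rates per mutation-count subgroup; right panel:
#' histogram of reference-to-homolog sequence identities.
#'
#' @param x A `tdhomolog_experiment`.
#' @param ... Unused.
#' @export
plot.tdhomolog_experiment <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  m <- t(as.matrix(x$rates[, c("cp_rate", "cs_rate")]))
  colnames(m) <- x$rates$subgroup
  graphics::barplot(m, beside = TRUE, ylim = c(0, 100),
                    ylab = "rate (%)", legend.text = c("CP", "CS"),
                    main = "CP/CS rates by subgroup")
  graphics::barplot(x$histogram$count,
                    names.arg = paste0(x$histogram$lower, "-"),
                    ylab = "count", xlab = "identity (%)",
                    main = "Sequence identity")
  invisible(x)
}
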