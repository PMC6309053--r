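# BLOSUM62 is loaded once from Biostrings' data store
.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

encode_seq <- function(s, mat = blosum62()) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], rownames(mat))
  if (anyNA(idx)) stop("sequence contains letters outside the scoring matrix",
                       call. = FALSE)
  idx
}

#' Local-alignment search of a segment against a protein database
#'
#' Smith-Waterman local alignment with BLOSUM62 and affine gap costs
#' against every database protein, ranked by Karlin-Altschul E-value
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' total number of database residues. The default gap costs (open 11,
#' extend 1) are the classic protein-search defaults.
#'
#' @param query_segment Query amino-acid string.
#' @param db Protein database (named character vector).
#' @param evalue_cutoff Report nothing when the best E-value exceeds this.
#' @param gap_open,gap_extend Affine gap costs (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param lambda,K Karlin-Altschul constants for gapped BLOSUM62 scores.
#' @return `list(subject_id, score, evalue)` for the best subject (ties
#'   broken by lexicographic id), or `NULL` when the cutoff is not met.
#' @export
local_search <- function(query_segment, db, evalue_cutoff = 0.01,
                         gap_open = 11, gap_extend = 1,
                         lambda = 0.267, K = 0.041) {
  if (!nzchar(query_segment)) stop("empty query segment", call. = FALSE)
  if (length(db) == 0L) stop("empty database", call. = FALSE)
  db <- db[order(names(db))]
  mat <- blosum62()
  q <- encode_seq(query_segment, mat)
  subjects <- lapply(db, encode_seq, mat = mat)
  scores <- cpp_sw_scores(q, subjects, mat, gap_open, gap_extend)
  best <- which.max(scores)  # first (lexicographically smallest) id on ties
  n_total <- sum(nchar(db))
  evalue <- K * length(q) * n_total * exp(-lambda * scores[best])
  if (evalue > evalue_cutoff) return(NULL)
  list(subject_id = names(db)[best], score = scores[best], evalue = evalue)
}

#' Global-local (semi-global) alignment of a segment to a protein
#'
#' The query is aligned end to end; entry and exit in the subject are free
#' (no cost for unaligned subject ends). BLOSUM62 scoring with affine gaps;
#' a gap of length L costs `gap_open + L * gap_extend`. Traceback prefers
#' diagonal over up over left, making the alignment deterministic.
#'
#' @param query_segment Query string (aligned globally).
#' @param subject Subject string (aligned locally).
#' @param gap_open,gap_extend Gap costs (defaults 10 and 4).
#' @return An `alignment_result`: list with `aligned_query`,
#'   `aligned_subject` (equal-length gapped strings), `subject_start`,
#'   `subject_end`, `score`, `identity_pct`, `mutation_count`,
#'   `mutation_positions` (1-based subject positions; a gap event maps to
#'   its flanking subject position).
#' @export
global_local_align <- function(query_segment, subject, gap_open = 10,
                               gap_extend = 4) {
  if (!nzchar(query_segment) || !nzchar(subject))
    stop("query and subject must be non-empty", call. = FALSE)
  mat <- blosum62()
  r <- cpp_semiglobal(encode_seq(query_segment, mat),
                      encode_seq(subject, mat), mat, gap_open, gap_extend)
  qc <- strsplit(query_segment, "", fixed = TRUE)[[1]]
  sc <- strsplit(subject, "", fixed = TRUE)[[1]]
  qpos <- 0L
  spos <- r$subject_start - 1L
  aq <- character(length(r$ops))
  as_ <- character(length(r$ops))
  mut_pos <- integer(0)
  for (k in seq_along(r$ops)) {
    op <- r$ops[k]
    if (op == 0L) {
      qpos <- qpos + 1L; spos <- spos + 1L
      aq[k] <- qc[qpos]; as_[k] <- sc[spos]
      if (qc[qpos] != sc[spos]) mut_pos <- c(mut_pos, spos)
    } else if (op == 1L) {
      # query residue vs subject gap: insertion relative to the subject,
      # charged to the flanking subject position
      qpos <- qpos + 1L
      aq[k] <- qc[qpos]; as_[k] <- "-"
      mut_pos <- c(mut_pos, max(spos, r$subject_start))
    } else {
      spos <- spos + 1L
      aq[k] <- "-"; as_[k] <- sc[spos]
      mut_pos <- c(mut_pos, spos)
    }
  }
  out <- list(query_id = "", subject_id = "",
              aligned_query = paste(aq, collapse = ""),
              aligned_subject = paste(as_, collapse = ""),
              subject_start = r$subject_start,
              subject_end = r$subject_end,
              score = r$score,
              identity_pct = NA_real_,
              mutation_count = NA_integer_,
              mutation_positions = mut_pos)
  class(out) <- "alignment_result"
  out$identity_pct <- sequence_identity(out)
  out$mutation_count <- count_mutations(out)
  out
}

alignment_columns <- function(a) {
  q <- strsplit(a$aligned_query, "", fixed = TRUE)[[1]]
  s <- strsplit(a$aligned_subject, "", fixed = TRUE)[[1]]
  if (length(q) != length(s))
    stop("aligned strings differ in length", call. = FALSE)
  list(q = q, s = s)
}

#' Count mutations in an alignment
#'
#' Substitution columns (both residues present, unequal) plus gap columns,
#' each column counted once (per-residue counting: a length-2 indel is two
#' mutations).
#'
#' @param a An `alignment_result` (or any list with `aligned_query` and
#'   `aligned_subject`).
#' @return Integer count.
#' @export
count_mutations <- function(a) {
  col <- alignment_columns(a)
  sum(col$q == "-" | col$s == "-" |
        (col$q != col$s & col$q != "-" & col$s != "-"))
}

#' Percent sequence identity of an alignment
#'
#' Identical matches over the entire alignment length (gap columns counted
#' in the denominator).
#'
#' @inheritParams count_mutations
#' @return Percent in \[0, 100\].
#' @export
sequence_identity <- function(a) {
  col <- alignment_columns(a)
  100 * sum(col$q == col$s & col$q != "-") / length(col$q)
}

#' Project a query position through an alignment onto the subject
#'
#' Returns the subject position aligned to `query_pos` (1-based within the
#' aligned query). A query position aligned to a gap maps to its flanking
#' subject position (the last subject position consumed before it, clamped
#' to the aligned subject span).
#'
#' @param a An `alignment_result`.
#' @param query_pos 1-based query position.
#' @return 1-based subject position.
#' @export
project_query_position <- function(a, query_pos) {
  col <- alignment_columns(a)
  qpos <- 0L
  spos <- a$subject_start - 1L
  for (k in seq_along(col$q)) {
    if (col$s[k] != "-") spos <- spos + 1L
    if (col$q[k] != "-") {
      qpos <- qpos + 1L
      if (qpos == query_pos) return(max(spos, a$subject_start))
    }
  }
  stop("query_pos beyond aligned query", call. = FALSE)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Global-local alignment (score %.0f, identity %.1f%%, %d mutation%s)\n",
              x$score, x$identity_pct, x$mutation_count,
              if (x$mutation_count == 1) "" else "s"))
  cat("  query:   ", x$aligned_query, "\n")
  cat("  subject: ", x$aligned_subject, sprintf("  [%d-%d]\n",
      x$subject_start, x$subject_end))
  invisible(x)
}

#' Map accepted reference identifications onto homologous protein segments
#'
#' The two-step mapping: (1) local-alignment search of each reference
#' protein segment against the homolog database with an E-value cutoff;
#' (2) global-local alignment of the segment to the best homologous protein,
#' whose aligned subject span defines the homologous protein segment.
#' Spectra whose segment finds no homolog under the cutoff are dropped and
#' counted in the `n_unmapped` attribute.
#'
#' @param prsms Data frame of accepted reference-database PrSMs.
#' @param ref_db Reference proteome.
#' @param homolog_db Homologous proteome.
#' @param evalue_cutoff E-value cutoff for the local search.
#' @param local_gap_open,local_gap_extend Gap costs of the local search.
#' @param gap_open,gap_extend Gap costs of the global-local alignment.
#' @param lambda,K Karlin-Altschul constants.
#' @return Data frame (one row per mapped spectrum): spectrum_id,
#'   ref_protein_id, homolog_protein_id, homolog_start, homolog_end,
#'   homolog_segment, identity_pct, mutation_count, mutation_positions
#'   (comma-joined), evalue. The `alignment_result` objects are attached as
#'   attribute `alignments` (named by spectrum id), the number of unmapped
#'   spectra as `n_unmapped`.
#' @export
map_identifications <- function(prsms, ref_db, homolog_db,
                                evalue_cutoff = 0.01,
                                local_gap_open = 11, local_gap_extend = 1,
                                gap_open = 10, gap_extend = 4,
                                lambda = 0.267, K = 0.041) {
  memo <- new.env(parent = emptyenv())  # identical segments map identically
  rows <- vector("list", nrow(prsms))
  alns <- vector("list", nrow(prsms))
  n_unmapped <- 0L
  for (i in seq_len(nrow(prsms))) {
    seg <- substr(ref_db[[prsms$protein_id[i]]], prsms$start[i],
                  prsms$end[i])
    hit <- memo[[seg]]
    if (is.null(hit)) {
      ls <- local_search(seg, homolog_db, evalue_cutoff, local_gap_open,
                         local_gap_extend, lambda, K)
      if (is.null(ls)) {
        hit <- list(unmapped = TRUE)
      } else {
        a <- global_local_align(seg, homolog_db[[ls$subject_id]],
                                gap_open, gap_extend)
        a$subject_id <- ls$subject_id
        hit <- list(unmapped = FALSE, ls = ls, a = a)
      }
      memo[[seg]] <- hit
    }
    if (hit$unmapped) { n_unmapped <- n_unmapped + 1L; next }
    a <- hit$a
    a$query_id <- prsms$spectrum_id[i]
    alns[[i]] <- a
    rows[[i]] <- data.frame(
      spectrum_id = prsms$spectrum_id[i],
      ref_protein_id = prsms$protein_id[i],
      homolog_protein_id = a$subject_id,
      homolog_start = a$subject_start,
      homolog_end = a$subject_end,
      homolog_segment = substr(homolog_db[[a$subject_id]], a$subject_start,
                               a$subject_end),
      identity_pct = a$identity_pct,
      mutation_count = a$mutation_count,
      mutation_positions = paste(a$mutation_positions, collapse = ","),
      evalue = hit$ls$evalue,
      stringsAsFactors = FALSE)
  }
  keep <- !vapply(rows, is.null, TRUE)
  out <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(spectrum_id = character(0), ref_protein_id = character(0),
               homolog_protein_id = character(0), homolog_start = integer(0),
               homolog_end = integer(0), homolog_segment = character(0),
               identity_pct = numeric(0), mutation_count = integer(0),
               mutation_positions = character(0), evalue = numeric(0),
               stringsAsFactors = FALSE)
  alns <- alns[keep]
  names(alns) <- out$spectrum_id
  attr(out, "alignments") <- alns
  attr(out, "n_unmapped") <- n_unmapped
  out
}
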