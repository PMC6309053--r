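# Independent reference implementations used to freeze expected values.
# These deliberately share no code with the package internals.

# monoisotopic atomic masses, for deriving expected residue/modification
# masses from element counts
ATOM <- c(H = 1.0078250319, C = 12, N = 14.0030740052, O = 15.9949146221,
          S = 31.97207069, P = 30.97376151)

mass_from_formula <- function(counts) sum(ATOM[names(counts)] * counts)

# greedy one-to-one matching, written as an explicit consumed-flag scan
oracle_greedy_match <- function(theo, obs, tol_ppm) {
  theo <- sort(theo[theo > 0])
  obs <- sort(obs)
  used <- rep(FALSE, length(obs))
  n <- 0L
  for (t in theo) {
    w <- tol_ppm * 1e-6 * t
    ok <- which(!used & obs >= t - w & obs <= t + w)
    if (length(ok)) {
      used[ok[1]] <- TRUE
      n <- n + 1L
    }
  }
  n
}

# greedy matching returning which theoretical entries matched
oracle_greedy_match_flags <- function(theo_df, obs, tol_ppm) {
  ord <- order(theo_df$mass)
  theo_df <- theo_df[ord, , drop = FALSE]
  used <- rep(FALSE, length(obs))
  matched <- rep(FALSE, nrow(theo_df))
  for (i in seq_len(nrow(theo_df))) {
    t <- theo_df$mass[i]
    if (t <= 0) next
    w <- tol_ppm * 1e-6 * t
    ok <- which(!used & obs >= t - w & obs <= t + w)
    if (length(ok)) {
      used[ok[1]] <- TRUE
      matched[i] <- TRUE
    }
  }
  theo_df$matched <- matched
  theo_df
}

# exhaustive split-site enumeration for the one-unknown-shift score and the
# localization interval
oracle_one_shift <- function(segment, precursor, obs, tol_ppm,
                             ion_series = c("N", "C")) {
  rm <- residue_masses()[strsplit(segment, "")[[1]]]
  L <- length(rm)
  M <- sum(rm) + 18.010565
  delta <- precursor - M
  pre <- cumsum(rm)[seq_len(max(L - 1, 0))]
  obs <- sort(obs)
  best <- list(score = -1L)
  for (s in 0:(L - 1)) {
    rows <- NULL
    if ("N" %in% ion_series && L > 1)
      rows <- rbind(rows, data.frame(
        mass = pre + ifelse(seq_len(L - 1) > s, delta, 0),
        site = seq_len(L - 1), shifted = seq_len(L - 1) > s, nterm = TRUE))
    if ("C" %in% ion_series && L > 1)
      rows <- rbind(rows, data.frame(
        mass = (M - pre) + ifelse(seq_len(L - 1) <= s, delta, 0),
        site = seq_len(L - 1), shifted = seq_len(L - 1) <= s, nterm = FALSE))
    if (is.null(rows)) rows <- data.frame(mass = numeric(0), site = integer(0),
                                          shifted = logical(0), nterm = logical(0))
    res <- oracle_greedy_match_flags(rows, obs, tol_ppm)
    score <- sum(res$matched)
    if (score > best$score) {
      lower <- res$matched & ((res$nterm & !res$shifted) |
                                (!res$nterm & res$shifted))
      upper <- res$matched & ((res$nterm & res$shifted) |
                                (!res$nterm & !res$shifted))
      r <- if (any(lower)) max(res$site[lower]) else 0L
      t <- if (any(upper)) min(res$site[upper]) else L
      best <- list(score = score, first = r + 1L, last = t)
    }
  }
  best
}

# plain global (Needleman-Wunsch) affine-gap alignment score; gap of length
# L costs open + L * extend
oracle_global_affine_score <- function(q, s, mat, go, ge) {
  qi <- strsplit(q, "")[[1]]
  si <- strsplit(s, "")[[1]]
  m <- length(qi); n <- length(si)
  NEG <- -1e15
  H <- matrix(NEG, m + 1, n + 1); E <- H; F <- H
  H[1, 1] <- 0
  for (i in seq_len(m)) { F[i + 1, 1] <- -(go + i * ge); H[i + 1, 1] <- F[i + 1, 1] }
  for (j in seq_len(n)) { E[1, j + 1] <- -(go + j * ge); H[1, j + 1] <- E[1, j + 1] }
  for (i in seq_len(m)) for (j in seq_len(n)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - go - ge, E[i + 1, j] - ge)
    F[i + 1, j + 1] <- max(H[i, j + 1] - go - ge, F[i, j + 1] - ge)
    H[i + 1, j + 1] <- max(H[i, j] + mat[qi[i], si[j]],
                           E[i + 1, j + 1], F[i + 1, j + 1])
  }
  H[m + 1, n + 1]
}

# global-local score by brute force: best global alignment of the query
# against every subject substring (empty substring = all-gap query)
oracle_semiglobal_score <- function(q, s, mat, go, ge) {
  n <- nchar(s)
  m <- nchar(q)
  best <- -(go + m * ge)  # align query entirely to gaps
  for (a in seq_len(n)) for (b in a:n) {
    best <- max(best,
                oracle_global_affine_score(q, substr(s, a, b), mat, go, ge))
  }
  best
}

oracle_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_segment <- function(len) {
  paste(sample(amino_acids(), len, replace = TRUE), collapse = "")
}
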