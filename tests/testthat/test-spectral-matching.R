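test_that("prefix ladders reproduce residue-mass sums", {
  gly <- mass_from_formula(c(C = 2, H = 3, N = 1, O = 1))
  expect_equal(prefix_masses("GG"), gly, tolerance = 1e-5)

  p <- prefix_masses("EPPLSQETFS")
  expect_length(p, 9)
  ser <- mass_from_formula(c(C = 3, H = 5, N = 1, O = 2))
  expect_equal(p[5] - p[4], ser, tolerance = 1e-5)
  expect_true(all(diff(p) > 0))

  expect_length(prefix_masses("A"), 0)
  expect_error(prefix_masses("AXB"), "unknown")
})

test_that("theoretical ladders shift at and beyond the modified residue", {
  un <- theoretical_fragments("EPPLSQETFS", NULL, "N")
  mo <- theoretical_fragments("EPPLSQETFS", list(site = 5, mass = 79.96633),
                              "N")
  expect_equal(round(mo - un, 2), c(rep(0, 4), rep(79.97, 5)))

  expect_equal(theoretical_fragments("EPPLSQETFS"),
               sort(c(prefix_masses("EPPLSQETFS"),
                      segment_mass("EPPLSQETFS") -
                        prefix_masses("EPPLSQETFS"))))
  expect_length(theoretical_fragments("EPPLSQETFS", NULL, "N"), 9)
  expect_length(theoretical_fragments("EPPLSQETFS"), 18)

  # C-terminal ladder shifts where the modified residue sits C-terminal of
  # the cleavage site
  unc <- theoretical_fragments("EPPLSQETFS", NULL, "C")
  moc <- theoretical_fragments("EPPLSQETFS", list(site = 5, mass = 79.96633),
                               "C")
  expect_equal(sum(abs(sort(moc) - sort(unc + 79.96633)) < 1e-6 |
                     abs(sort(moc) - sort(unc)) < 1e-6), 9)
})

test_that("match counting respects the ppm boundary and greedy consumption", {
  expect_equal(match_count(numeric(0), c(100, 200)), 0)
  theo <- prefix_masses("EPPLSQETFS")
  expect_equal(match_count(theo, theo, 15), length(theo))
  expect_equal(match_count(1000.016, 1000.0, 15), 0)
  expect_equal(match_count(1000.014, 1000.0, 15), 1)
  # one observed mass cannot match two theoretical masses
  expect_equal(match_count(1000.0, c(1000.0, 1000.001), 15), 1)
  expect_error(match_count(1, 1, -5), "tol_ppm")

  # agreement with an independently coded greedy matcher
  set.seed(42)
  for (i in 1:50) {
    theo <- sort(runif(sample(1:20, 1), 100, 2000))
    obs <- sort(theo[runif(length(theo)) < 0.7] *
                  (1 + rnorm(sum(runif(length(theo)) < 2), 0, 10e-6)[1]))
    obs <- sort(c(obs, runif(5, 100, 2000)))
    expect_equal(match_count(obs, theo, 15),
                 oracle_greedy_match(theo, obs, 15))
  }
})

test_that("one-shift alignment localizes a planted modification", {
  db <- c(P1 = "EPPLSQETFS")
  pfm <- data.frame(protein_id = "P1", start = 1, end = 10, mod_site = 5,
                    mod_mass = 79.96633, mod_name = "phospho")
  sp <- simulate_spectrum(pfm, db, "N", 1, 0, seed = 1)
  r <- one_shift_align(sp, "EPPLSQETFS", 15, "N")
  expect_equal(r$score, 9)
  expect_equal(round(r$delta, 2), 79.97)
  expect_equal(r$shift_interval, c(5, 5))

  # zero-shift case: no interval, score equals the plain match count
  pf <- data.frame(protein_id = "P1", start = 1, end = 10, mod_site = 0,
                   mod_mass = 0, mod_name = "")
  sp0 <- simulate_spectrum(pf, db, c("N", "C"), 1, 0, seed = 2)
  r0 <- one_shift_align(sp0, "EPPLSQETFS", 15)
  expect_null(r0$shift_interval)
  expect_equal(r0$score,
               match_count(sp0$fragment_masses,
                           theoretical_fragments("EPPLSQETFS"), 15))

  # only sites 1-2 matched unshifted, nothing shifted: the shift can sit
  # anywhere from site 3 to the segment end
  seg <- "ACDEFGHIKL"
  sp2 <- list(precursor_mass = segment_mass(seg) + 50,
              fragment_masses = prefix_masses(seg)[1:2])
  r2 <- one_shift_align(sp2, seg, 15, "N")
  expect_equal(r2$score, 2)
  expect_equal(r2$shift_interval, c(3, 10))

  expect_error(one_shift_align(sp2, "", 15), "empty")
})

test_that("one-shift scoring agrees with exhaustive split enumeration", {
  set.seed(101)
  for (i in 1:150) {
    L <- sample(2:8, 1)
    seg <- random_segment(L)
    delta <- sample(c(-120, -17, 0.5, 42.01057, 79.96633, 150), 1)
    site <- sample(seq_len(L), 1)
    series <- list("N", "C", c("N", "C"))[[sample(3, 1)]]
    theo <- theoretical_fragments(seg, list(site = site, mass = delta),
                                  series)
    keep <- runif(length(theo)) < 0.8
    noise <- runif(sample(0:3, 1), 100, 1500)
    obs <- sort(c(theo[keep], noise))
    prec <- segment_mass(seg) + delta
    got <- one_shift_align(list(precursor_mass = prec,
                                fragment_masses = obs), seg, 15, series)
    want <- oracle_one_shift(seg, prec, obs, 15, series)
    expect_equal(got$score, want$score,
                 info = sprintf("case %d seg %s", i, seg))
    if (!is.null(got$shift_interval))
      expect_equal(got$shift_interval, c(want$first, want$last),
                   info = sprintf("case %d seg %s", i, seg))
  }
})

test_that("a forced zero shift reduces to plain ladder matching", {
  set.seed(77)
  for (i in 1:500) {
    seg <- random_segment(sample(5:20, 1))
    theo <- theoretical_fragments(seg)
    obs <- sort(c(theo[runif(length(theo)) < 0.6],
                  runif(3, 100, 2000)))
    r <- one_shift_align(list(precursor_mass = segment_mass(seg),
                              fragment_masses = obs), seg, 15)
    expect_null(r$shift_interval)
    expect_equal(r$score, match_count(obs, theo, 15))
  }
})

test_that("match scores never increase when the tolerance shrinks", {
  set.seed(5)
  seg <- random_segment(30)
  theo <- theoretical_fragments(seg)
  obs <- sort(theo * (1 + rnorm(length(theo), 0, 8e-6)))
  tols <- c(30, 15, 10, 5, 2, 1, 0.1)
  scores <- vapply(tols, function(t) match_count(obs, theo, t), 0L)
  expect_true(all(diff(scores) <= 0))
})

test_that("database search recovers true segments and breaks ties stably", {
  db <- generate_reference_proteome(20, c(40, 60), seed = 21)
  pfs <- sample_proteoforms(db, 200, ptm_menu = default_ptm_menu(),
                            ptm_probability = 0.5, seed = 22)
  sps <- simulate_spectra(pfs, db, peak_keep_probability = 1,
                          mass_error_ppm = 0, seed = 23)
  prsms <- search_spectra(sps, db)
  hit <- prsms$protein_id == pfs$protein_id & prsms$start == pfs$start &
    prsms$end == pfs$end
  expect_gte(mean(hit), 0.99)

  # searches via the exhaustive one-shift scorer applied to every candidate
  # must agree with the indexed search on a small database
  small <- db[1:3]
  for (i in 1:10) {
    sp <- sps[[i]]
    best <- NULL
    for (id in sort(names(small))) {
      s <- small[[id]]
      L <- nchar(s)
      for (a in 1:(L - 9)) for (b in (a + 9):L) {
        seg <- substr(s, a, b)
        if (abs(sp$precursor_mass - segment_mass(seg)) > 500) next
        r <- one_shift_align(sp, seg, 15)
        cand <- list(id = id, start = a, end = b, score = r$score,
                     delta = r$delta)
        if (is.null(best) || cand$score > best$score ||
            (cand$score == best$score && abs(cand$delta) < abs(best$delta)))
          best <- cand
      }
    }
    got <- search_database(sp, small)
    if (is.null(best)) {
      expect_equal(got$score, 0)  # no mass-compatible candidate: sentinel
      next
    }
    expect_equal(got$score, best$score)
    expect_equal(abs(got$delta), abs(best$delta), tolerance = 1e-9)
    if (got$score > 0)
      expect_identical(list(got$protein_id, got$start, got$end),
                       list(best$id, best$start, best$end))
  }

  # no mass-compatible candidate: score-0 sentinel
  tiny <- list(precursor_mass = 99999, fragment_masses = c(500, 600))
  tiny$spectrum_id <- "s"
  sent <- search_database(tiny, db[1])
  expect_equal(sent$score, 0)
  expect_identical(sent$protein_id, "")

  # identical proteins under two ids: the lexicographically smaller wins
  twin <- c(B_COPY = db[[1]], A_COPY = db[[1]])
  sp1 <- sps[[which(pfs$protein_id == names(db)[1])[1]]]
  expect_identical(search_database(sp1, twin)$protein_id, "A_COPY")
})

test_that("decoy construction permutes residues deterministically", {
  db <- generate_reference_proteome(10, c(30, 50), seed = 31)
  d1 <- build_decoy_db(db, seed = 1)
  expect_identical(d1, build_decoy_db(db, seed = 1))
  expect_true(all(startsWith(names(d1), "DECOY_")))
  for (i in seq_along(db)) {
    expect_identical(sort(strsplit(d1[[i]], "")[[1]]),
                     sort(strsplit(db[[i]], "")[[1]]))
  }
  expect_identical(unname(build_decoy_db(c(A = "AAAA"), 1)), "AAAA")
  expect_error(build_decoy_db(d1, 1), "DECOY_")
})

test_that("FDR filtering picks the smallest admissible threshold", {
  mk <- function(scores, decoy) data.frame(
    spectrum_id = paste0("s", seq_along(scores)), protein_id = "p",
    start = 1, end = 2, score = scores, delta = 0, shift_first = 0,
    shift_last = 0, is_decoy = decoy)

  # scan-all-thresholds example: one decoy at 9 forces tau down to 8 where
  # 1 decoy / 3 targets passes a 34% level
  x <- filter_fdr(mk(c(10, 9, 8, 9), c(FALSE, FALSE, FALSE, TRUE)), 0.34)
  expect_equal(attr(x, "fdr_threshold"), 8)
  expect_equal(sum(x$accepted), 3)
  expect_false(any(x$accepted & x$is_decoy))

  # no decoys: everything with a positive score is accepted
  y <- filter_fdr(mk(c(5, 3, 0), rep(FALSE, 3)), 0.01)
  expect_equal(sum(y$accepted), 2)

  # level 1: everything scoring above zero passes
  z <- filter_fdr(mk(c(5, 1, 0, 4), c(FALSE, FALSE, FALSE, TRUE)), 1)
  expect_equal(sum(z$accepted), 2)

  # independent threshold-scan oracle on random score sets
  set.seed(13)
  for (i in 1:25) {
    scores <- sample(0:30, 40, replace = TRUE)
    decoy <- runif(40) < 0.3
    lvl <- sample(c(0.01, 0.05, 0.2, 0.5), 1)
    got <- filter_fdr(mk(scores, decoy), lvl)
    taus <- sort(unique(scores))
    ok <- vapply(taus, function(tau)
      sum(decoy & scores >= tau) / max(1, sum(!decoy & scores >= tau)) <= lvl,
      TRUE)
    want_tau <- if (any(ok)) min(taus[ok]) else Inf
    expect_equal(attr(got, "fdr_threshold"), want_tau)
    expect_equal(got$accepted, !decoy & scores >= want_tau & scores > 0)
  }

  expect_error(filter_fdr(mk(1, FALSE), 0), "fdr_level")
  expect_error(filter_fdr(mk(1, FALSE), 1.5), "fdr_level")
})
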