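test_that("reference proteome generation is deterministic and well-formed", {
  a <- generate_reference_proteome(1, c(50, 50), seed = 7)
  b <- generate_reference_proteome(1, c(50, 50), seed = 7)
  expect_identical(a, b)
  expect_equal(nchar(a[[1]]), 50)

  db <- generate_reference_proteome(100, c(30, 300), seed = 1)
  expect_length(db, 100)
  expect_false(anyDuplicated(names(db)) > 0)
  expect_true(all(strsplit(paste(db, collapse = ""), "")[[1]] %in%
                    amino_acids()))

  s2 <- generate_reference_proteome(3, c(20, 20), seed = 2)
  s3 <- generate_reference_proteome(3, c(20, 20), seed = 3)
  expect_false(identical(unname(s2), unname(s3)))

  expect_error(generate_reference_proteome(2, c(5, 10), seed = 1), "range")
})

test_that("planted mutations are counted, logged and replayable", {
  ref <- generate_reference_proteome(20, c(40, 60), seed = 3)

  none <- mutate_proteome(ref, 0, seed = 1)
  expect_identical(none$db, ref)
  expect_equal(nrow(none$events), 0)

  two <- mutate_proteome(ref, 2, indel_fraction = 0, seed = 5)
  expect_true(all(two$events$kind == "substitution"))
  expect_equal(unname(table(two$events$protein_id)[names(ref)]),
               rep(2L, length(ref)), ignore_attr = TRUE)
  for (id in names(ref)) {
    ev <- two$events[two$events$protein_id == id, ]
    expect_identical(apply_mutations(ref[[id]], ev), two$db[[id]])
  }

  indel <- mutate_proteome(ref, 1, indel_fraction = 1, seed = 9)
  expect_true(all(abs(nchar(indel$db) - nchar(ref)) == 1))

  expect_error(mutate_proteome(c(A = paste(rep("G", 20), collapse = "")), 30,
                               seed = 1), "mutations")
})

test_that("mutation logs replay byte-for-byte across many random cases", {
  # seed-indexed stress of the event-log contract
  ref <- generate_reference_proteome(50, c(30, 80), seed = 11)
  for (seed in 1:20) {
    k <- seed %% 5
    mut <- mutate_proteome(ref, k, indel_fraction = 0.4, seed = seed)
    expect_equal(sum(mut$events$ref_pos > 0), k * length(ref))
    replayed <- vapply(names(ref), function(id)
      apply_mutations(ref[[id]],
                      mut$events[mut$events$protein_id == id, , drop = FALSE]),
      "")
    expect_identical(unname(replayed), unname(mut$db))
  }
})

test_that("proteoform sampling honours truncation, length and PTM settings", {
  db <- generate_reference_proteome(10, c(40, 60), seed = 2)

  plain <- sample_proteoforms(db, 50, ptm_probability = 0, seed = 1)
  expect_true(all(plain$mod_site == 0))
  expect_true(all(plain$end - plain$start + 1 >= 15))

  hpo3 <- mass_from_formula(c(H = 1, P = 1, O = 3))
  expect_equal(hpo3, 79.96633, tolerance = 1e-5)
  menu <- list(list(name = "phospho", mass = 79.96633))
  modded <- sample_proteoforms(db, 50, ptm_menu = menu, ptm_probability = 1,
                               seed = 2)
  expect_true(all(modded$mod_mass == 79.96633))
  expect_true(all(modded$mod_site >= modded$start &
                    modded$mod_site <= modded$end))

  full <- sample_proteoforms(db, 20, truncation_model = c(0, 0), seed = 3)
  expect_true(all(full$start == 1))
  expect_equal(full$end, unname(nchar(db[full$protein_id])))

  expect_error(sample_proteoforms(character(0), 5, seed = 1), "empty")
  expect_error(sample_proteoforms(db, 5, ptm_probability = 0.5, seed = 1),
               "ptm_menu")
})

test_that("simulated spectra carry the theoretical ladder and precursor", {
  db <- c(P1 = "EPPLSQETFS")
  pf <- data.frame(protein_id = "P1", start = 1, end = 10, mod_site = 0,
                   mod_mass = 0, mod_name = "")
  sp <- simulate_spectrum(pf, db, "N", 1, 0, seed = 1)
  expect_length(sp$fragment_masses, 9)
  ser <- mass_from_formula(c(C = 3, H = 5, N = 1, O = 2))
  expect_equal(sp$fragment_masses[5] - sp$fragment_masses[4], ser,
               tolerance = 1e-5)

  pfm <- data.frame(protein_id = "P1", start = 1, end = 10, mod_site = 5,
                    mod_mass = 79.96633, mod_name = "phospho")
  spm <- simulate_spectrum(pfm, db, "N", 1, 0, seed = 1)
  expect_equal(round(spm$fragment_masses[5:9] - sp$fragment_masses[5:9], 2),
               rep(79.97, 5))

  # precursor closure: residues + water + shift
  expect_equal(spm$precursor_mass,
               sum(residue_masses()[strsplit("EPPLSQETFS", "")[[1]]]) +
                 18.010565 + 79.96633,
               tolerance = 1e-9)

  # vanishing keep probability: empty fragment list, precursor still set
  sp0 <- simulate_spectrum(pf, db, "N", 1e-12, 0, seed = 4)
  expect_length(sp0$fragment_masses, 0)
  expect_gt(sp0$precursor_mass, 0)

  bad <- data.frame(protein_id = "P1", start = 1, end = 99, mod_site = 0,
                    mod_mass = 0, mod_name = "")
  expect_error(simulate_spectrum(bad, db, seed = 1), "bounds")
})

test_that("spectrum fragments are sorted, positive and below the precursor", {
  db <- generate_reference_proteome(5, c(40, 60), seed = 6)
  pfs <- sample_proteoforms(db, 10, ptm_menu = default_ptm_menu(),
                            ptm_probability = 0.5, seed = 7)
  sps <- simulate_spectra(pfs, db, peak_keep_probability = 0.7,
                          mass_error_ppm = 5, seed = 8)
  for (sp in sps) {
    f <- sp$fragment_masses
    expect_true(all(diff(f) > 0))
    expect_true(all(f > 0 & f < sp$precursor_mass))
  }
})

test_that("FASTA and spectrum files round-trip and are bit-identical per seed", {
  db <- generate_reference_proteome(8, c(40, 120), seed = 4)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_proteome_fasta(db, f1)
  write_proteome_fasta(generate_reference_proteome(8, c(40, 120), seed = 4), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(read_proteome_fasta(f1), db)

  pfs <- sample_proteoforms(db, 5, seed = 5)
  sps <- simulate_spectra(pfs, db, peak_keep_probability = 0.8, seed = 6)
  s1 <- tempfile(); s2 <- tempfile()
  write_spectra(sps, s1)
  write_spectra(simulate_spectra(pfs, db, peak_keep_probability = 0.8,
                                 seed = 6), s2)
  expect_identical(unname(tools::md5sum(s1)), unname(tools::md5sum(s2)))

  back <- read_spectra(s1)
  expect_equal(vapply(back, `[[`, "", "spectrum_id"),
               vapply(sps, `[[`, "", "spectrum_id"))
  expect_equal(back[[1]]$precursor_mass, sps[[1]]$precursor_mass,
               tolerance = 1e-5)
  expect_equal(back[[1]]$fragment_masses, sps[[1]]$fragment_masses,
               tolerance = 1e-4)

  # the parser tolerates comments and blank lines
  lines <- readLines(s1)
  messy <- tempfile()
  writeLines(c("# comment", "", lines[1:3], "# inside", lines[-(1:3)]), messy)
  expect_equal(length(read_spectra(messy)), length(sps))

  t1 <- tempfile()
  write_truth_tsv(sps, t1)
  tr <- read_truth_tsv(t1)
  expect_equal(nrow(tr), 5)
  expect_identical(tr$protein_id, pfs$protein_id)
})
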