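test_that("the generator is byte-deterministic under its seed", {
  cfg <- sim_config(seed = 5, n_proteins = 10, n_sites = 10,
                    n_background = 5, n_noise_spectra = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, out_dir = d1)
  simulate_dataset(cfg, out_dir = d2)
  for (f in c("proteins.fasta", "spectra.mgf", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("precursor masses carry the configured adduct forms", {
  cfg <- sim_config(seed = 6, n_proteins = 15, n_sites = 25,
                    nucleoside_fraction = 0.5, n_background = 0,
                    n_noise_spectra = 0, insource_fraction = 0)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  # true neutral mass equals peptide + form-specific delta, exactly
  for (i in sample(nrow(tr), 10)) {
    expect_equal(tr$true_neutral[i],
                 peptide_neutral_mass(tr$peptide[i], tr$site_pep[i],
                                      "4SU", tr$form[i]),
                 tolerance = 1e-9)
  }
  # nucleoside vs base of the same peptide/site differ by the ribose mass
  nuc <- tr[tr$form == "nucleoside", ]
  expect_gt(nrow(nuc), 0)
  base_equiv <- peptide_neutral_mass(nuc$peptide[1], nuc$site_pep[1],
                                     "4SU", "base")
  expect_equal(nuc$true_neutral[1] - base_equiv, ribose_mass(),
               tolerance = 1e-9)
  # observed precursor is within mass-error of truth
  sp <- sim$spectra[[1]]
  obs <- (sp$premz - proton_mass()) * sp$charge
  expect_lt(abs(obs - tr$true_neutral[1]) / tr$true_neutral[1] * 1e6, 20)
  # nucleoside fraction 0 plants only base forms
  all_base <- simulate_dataset(sim_config(seed = 6, n_proteins = 15,
                                          n_sites = 20,
                                          nucleoside_fraction = 0,
                                          n_background = 0,
                                          n_noise_spectra = 0))
  expect_true(all(all_base$truth$form == "base"))
})

test_that("MS2 site fragments are base-form even for nucleoside precursors", {
  cfg <- sim_config(seed = 8, n_proteins = 15, n_sites = 10,
                    nucleoside_fraction = 1, fragment_efficiency = 1,
                    noise_peaks = 0, frag_mz_sd = 0, n_background = 0,
                    n_noise_spectra = 0, insource_fraction = 0)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth[1, ]
  sp <- sim$spectra[[1]]
  want <- theoretical_fragments(tr$peptide, tr$site_pep, "4SU",
                                "nucleoside", mode = "prbs")
  expect_equal(sort(sp$mz), sort(want$mz), tolerance = 1e-9)
})

test_that("impossible crosslink requests are rejected", {
  cfg <- sim_config(seed = 9, n_proteins = 2, protein_length = c(30L, 40L),
                    n_sites = 500)
  expect_error(simulate_dataset(cfg), "eligible")
})

test_that("recovery metrics follow their conventions", {
  truth <- data.frame(scan = c("s1", "s2"), kind = "crosslink",
                      peptide = c("GWK", "AYR"), accession = c("P1", "P2"),
                      pep_start = c(10L, 5L), site_pep = c(2L, 2L),
                      site_protein = c(11L, 6L), residue = c("W", "Y"),
                      form = c("base", "nucleoside"),
                      true_neutral = c(500, 600), rt = c(100, 200),
                      charge = 2L, stringsAsFactors = FALSE)
  perfect <- data.frame(accession = c("P1", "P2"), position = c(11L, 6L))
  m <- evaluate_recovery(perfect, truth)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  # empty output: recall 0, precision reported 1 with the defined-flag down
  m0 <- evaluate_recovery(perfect[0, ], truth)
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 1)
  expect_false(m0$precision_defined)
  # off-by-one site counts as false localization, not recovery
  off <- data.frame(accession = "P1", position = 12L)
  m1 <- evaluate_recovery(off, truth)
  expect_equal(m1$recall, 0)
  expect_equal(m1$false_localization_rate, 1)
})
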