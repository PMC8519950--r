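test_that("tryptic digestion follows the K/R rule with Pro suppression", {
  d <- digest(mini_db("MKR"), missed_cleavages = 0, length_range = c(1, 40))
  expect_setequal(d$sequence, c("MK", "R"))
  # K-P suppresses cleavage, trailing R ends the protein
  d2 <- digest(mini_db("MKPR"), missed_cleavages = 0, length_range = c(1, 40))
  expect_setequal(d2$sequence, "MKPR")
  # missed cleavages only add peptides
  sim <- small_sim()
  d0 <- digest(sim$database[1:5, ], 0, c(6, 40))
  d1 <- digest(sim$database[1:5, ], 1, c(6, 40))
  expect_true(all(d0$sequence %in% d1$sequence))
  # shared peptides merge with multi-protein provenance
  d3 <- digest(mini_db(c("AAAWDKR", "AAAWDKK")), 0, c(6, 40))
  row <- d3[d3$sequence == "AAAWDK", ]
  expect_equal(row$proteins, "P1;P2")
  expect_match(row$starts, "P1:1;P2:1")
})

test_that("scan correction subtracts ribose/charge once and only once", {
  sp <- mk_spec(c(200, 300), premz = 800, charge = 2L)
  cs <- correct_scan(sp)
  expect_equal((sp$premz - cs$premz) * 2, 132.0423, tolerance = 1e-3)
  expect_identical(cs$mz, sp$mz)
  expect_identical(cs$intensity, sp$intensity)
  expect_identical(cs$rt, sp$rt)
  expect_true(cs$corrected)
  expect_error(correct_scan(cs), "already corrected")
  sp$charge <- NA_integer_
  expect_error(correct_scan(sp), "charge")
})

test_that("theoretical fragments carry the base-form delta at the site", {
  # y1 of GK = K residue + water + proton, from the composition table
  fr <- theoretical_fragments("GK")
  y1 <- fr$mz[fr$ion == "y1"]
  expect_equal(y1, mass_of("C6H12N2O1") + mass_of("H2O1") + proton_mass(),
               tolerance = 1e-9)
  # every y-ion containing the site is shifted; y1 is not
  un <- theoretical_fragments("GWK")
  mod <- theoretical_fragments("GWK", mod_site = 2, par_type = "4SU",
                               form = "base")
  d <- adduct_delta("4SU", "base", "W")
  expect_equal(mod$mz[mod$ion == "y1"], un$mz[un$ion == "y1"])
  expect_equal(mod$mz[mod$ion == "y2"], un$mz[un$ion == "y2"] + d)
  expect_equal(mod$mz[mod$ion == "b2"], un$mz[un$ion == "b2"] + d)
  # prbs mode: nucleoside form yields base-form fragments (ribose lost in MS2)
  nuc <- theoretical_fragments("GWK", 2, "4SU", "nucleoside", mode = "prbs")
  expect_equal(nuc$mz, mod$mz)
  # conventional mode applies the searched delta as-is
  conv <- theoretical_fragments("GWK", 2, "4SU", "nucleoside",
                                mode = "conventional")
  expect_equal(conv$mz[conv$ion == "y2"] - un$mz[un$ion == "y2"],
               adduct_delta("4SU", "nucleoside", "W"))
  expect_error(theoretical_fragments("GWK", mod_site = 9), "out of range")
})

test_that("binomial-tail significance equals a brute-force tail sum", {
  pep <- "SAMPLEK"
  fr <- theoretical_fragments(pep)
  # spectrum containing 4 of the 12 fragments plus unrelated peaks
  sp <- mk_spec(sort(c(fr$mz[c(1, 3, 5, 8)], 111.11, 222.22, 333.33)),
                intensity = rep(100, 7))
  got <- score_match(sp, pep, frag_tol = 0.02)
  expect_equal(got$n_matched, 4L)
  n <- nrow(fr)
  p <- 2 * 0.02 * length(sp$mz) / diff(range(sp$mz))
  tail_sum <- sum(vapply(4:n, function(i)
    choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
  expect_equal(got$significance, tail_sum, tolerance = 1e-10)
  # zero matches and empty spectra give significance 1
  expect_equal(score_match(mk_spec(c(55.5, 66.6)), pep)$significance, 1)
  expect_equal(score_match(mk_spec(numeric(0)), pep)$significance, 1)
  # full fragment evidence scores better than partial
  full <- score_match(ideal_spectrum(pep), pep)
  expect_lt(full$significance, got$significance)
})

test_that("search recovers base and nucleoside forms through scan duplication", {
  db <- build_target_decoy(mini_db(c("AAAWDLNKSSR", "MGGFEYHDKAAR")))
  params <- search_params("4SU", "prbs")
  idx <- build_search_index(digest(db, 2, c(6, 40)), params)

  base_sp <- ideal_spectrum("AAAWDLNK", site = 4, form = "base")
  psm <- search_scan(base_sp, idx)
  expect_equal(psm$peptide, "AAAWDLNK")
  expect_equal(psm$site, 4L)
  expect_equal(psm$form, "base")
  expect_false(psm$corrected)

  nuc_sp <- ideal_spectrum("AAAWDLNK", site = 4, form = "nucleoside")
  psm2 <- search_scan(nuc_sp, idx)
  expect_equal(psm2$peptide, "AAAWDLNK")
  expect_equal(psm2$site, 4L)
  expect_equal(psm2$form, "nucleoside")
  expect_true(psm2$corrected)

  # conventional mode scores the nucleoside candidate worse: site-covering
  # fragments mismatch by the ribose mass
  conv <- search_params("4SU", "conventional")
  idxc <- build_search_index(digest(db, 2, c(6, 40)), conv)
  psm3 <- search_scan(nuc_sp, idxc)
  expect_gt(psm3$significance, psm2$significance)
  # base-form spectra: both modes agree
  psm4 <- search_scan(base_sp, idxc)
  expect_equal(psm4[, c("peptide", "site", "form")],
               psm[, c("peptide", "site", "form")])

  # nothing within tolerance -> no PSM
  far <- mk_spec(c(300, 400), premz = 499.777, charge = 2L)
  expect_null(search_scan(far, idx))
})

test_that("run_search yields at most one PSM per scan, deterministically", {
  sim <- small_sim()
  db <- build_target_decoy(sim$database)
  params <- search_params("4SU", "prbs")
  psms <- run_search(sim$spectra[1:40], db, params)
  expect_lte(nrow(psms), 40L)
  expect_false(any(duplicated(psms$scan)))
  again <- run_search(sim$spectra[1:40], db, params)
  expect_identical(psms, again)
  expect_equal(nrow(run_search(list(), db, params)), 0L)
})

test_that("search_scan agrees with exhaustive enumeration on a tiny database", {
  db <- build_target_decoy(mini_db(c("AAAWDLNKSSYHRTTGMK",
                                     "MGGFEYHDKAACRLLWDER",
                                     "QTSNVWAHKDDFYGR")))
  for (mode in c("prbs", "conventional")) {
    params <- search_params("4SU", mode)
    peps <- digest(db, params$missed_cleavages, params$length_range)
    expect_lte(nrow(peps), 50L)
    idx <- build_search_index(peps, params)
    # ideal spectra for several (peptide, site, form) combinations, plus
    # perturbed and unmatchable precursors
    set.seed(31)
    specs <- list(
      ideal_spectrum("AAAWDLNK", 4, form = "base"),
      ideal_spectrum("AAAWDLNK", 4, form = "nucleoside"),
      ideal_spectrum("SSYHR", 3, form = "nucleoside"),
      ideal_spectrum("AACRLLWDER", 3, form = "base"),
      ideal_spectrum("QTSNVWAHK", 6, form = "base"),
      ideal_spectrum("MGGFEYHDK"),
      mk_spec(sort(runif(30, 150, 1200)), premz = 700.123, charge = 2L),
      mk_spec(c(300, 400), premz = 499.777, charge = 2L)
    )
    checked <- 0L
    for (sp in specs) {
      got <- search_scan(sp, idx)
      ora <- enumerate_best(sp, peps, params)
      if (is.null(ora)) {
        expect_null(got)
      } else {
        checked <- checked + 1L
        expect_equal(got$peptide, ora$peptide)
        expect_equal(got$form, ora$form)
        expect_equal(got$corrected, ora$corrected)
        expect_equal(got$significance, ora$sig, tolerance = 1e-12)
        if (!is.na(ora$site)) expect_equal(got$site, ora$site)
      }
    }
    expect_gte(checked, 5L)
  }
})
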