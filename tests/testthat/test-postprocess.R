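# A minimal PSM row with sensible defaults, overridable per test.
mk_psm <- function(scan = "s1", peptide = "GWK", site = 2L, residue = "W",
                   form = "base", sig = 1e-6, ppm = 0, decoy = FALSE,
                   mass = 500, rt = 100, inten = NA_real_,
                   ambiguous = FALSE, proteins = "P1", starts = "P1:1") {
  data.frame(scan = scan, peptide = peptide, proteins = proteins,
             starts = starts, is_decoy = decoy, site = site,
             residue = residue, par_type = "4SU", form = form,
             corrected = FALSE, n_matched = 5L, raw_score = 1,
             significance = sig, prec_error_ppm = ppm,
             site_ambiguous = ambiguous, obs_neutral_mass = mass,
             precursor_mz = mass / 2, charge = 2L, rt = rt,
             precursor_intensity = inten, stringsAsFactors = FALSE)
}

test_that("recalibration keeps PSMs within the window around the shifted center", {
  # high-confidence errors at +3 ppm shift the center: +7.9 is retained,
  # -2.1 (5.1 away from center) is not
  psms <- rbind(mk_psm("a", sig = 1e-12, ppm = 3), mk_psm("b", sig = 1e-12, ppm = 3),
                mk_psm("c", sig = 0.01, ppm = 7.9), mk_psm("d", sig = 0.01, ppm = -2.1))
  out <- recalibration_filter(psms, ppm_window = 5, high_conf_quantile = 0.5)
  expect_equal(attr(out, "center_ppm"), 3)
  expect_setequal(out$scan, c("a", "b", "c"))
  # centered errors: +/-4.9 in, +/-5.1 out
  psms2 <- rbind(mk_psm("a", sig = 1e-12, ppm = 0), mk_psm("b", sig = 0.01, ppm = 4.9),
                 mk_psm("c", sig = 0.01, ppm = 5.1))
  out2 <- recalibration_filter(psms2, 5, 0.1)
  expect_setequal(out2$scan, c("a", "b"))
  expect_warning(recalibration_filter(mk_psm(decoy = TRUE)), "high-confidence")
})

test_that("exclusion rules drop unmodified, C-terminal K/R and ambiguous PSMs", {
  psms <- rbind(
    mk_psm("keep", peptide = "GWK", site = 2L, residue = "W"),
    mk_psm("cterm", peptide = "GWK", site = 3L, residue = "K"),
    mk_psm("unmod", form = "none", site = NA_integer_, residue = NA_character_),
    mk_psm("tie", ambiguous = TRUE))
  expect_equal(apply_exclusions(psms)$scan, "keep")
})

test_that("UMC clustering chains by mass ppm and RT gap", {
  base <- rbind(mk_psm("a", rt = 100), mk_psm("b", rt = 160))
  expect_equal(length(unique(assign_umcs(base, 10, 120)$umc_id)), 1L)
  apart <- rbind(mk_psm("a", rt = 100), mk_psm("b", rt = 400))
  expect_equal(length(unique(assign_umcs(apart, 10, 120)$umc_id)), 2L)
  # a ribose-mass gap is orders of magnitude beyond ppm tolerance
  forms <- rbind(mk_psm("a", mass = 1500), mk_psm("b", mass = 1500 + 132.0423))
  expect_equal(length(unique(assign_umcs(forms, 10, 60)$umc_id)), 2L)
  # transitive chain: 100 - 160 - 220 all join even though ends are 120 apart
  chain <- rbind(mk_psm("a", rt = 100), mk_psm("b", rt = 160), mk_psm("c", rt = 220))
  expect_equal(length(unique(assign_umcs(chain, 10, 70)$umc_id)), 1L)
})

test_that("localization scores follow the -log10 significance ratio", {
  one <- mk_psm("a")
  expect_equal(localize(one)$score, 1)
  two_same <- rbind(mk_psm("a"), mk_psm("b"))
  expect_equal(localize(two_same)$score, 1)
  # sites F5 vs Y3 with significances 1e-10 and 1e-5: score 10/15
  two <- rbind(mk_psm("a", peptide = "AAYAFK", site = 5L, residue = "F", sig = 1e-10),
               mk_psm("b", peptide = "AAYAFK", site = 3L, residue = "Y", sig = 1e-5))
  loc <- localize(two)
  expect_equal(loc$site, 5L)
  expect_equal(loc$score, 10 / 15)
  # scores over observed sites sum to 1
  w <- -log10(two$significance)
  shares <- tapply(w, two$site, sum) / sum(w)
  expect_equal(sum(shares), 1)
  # undefined when every significance is 1
  expect_null(localize(mk_psm("a", sig = 1)))
})

test_that("UMC q-values match a brute-force target-decoy oracle", {
  set.seed(9)
  sig <- sort(10^-runif(20, 0, 12))
  decoy <- c(FALSE, FALSE, TRUE, FALSE, TRUE, rep(c(FALSE, TRUE), length.out = 15))
  psms <- do.call(rbind, lapply(seq_along(sig), function(i)
    mk_psm(sprintf("s%02d", i), sig = sig[i], decoy = decoy[i],
           mass = 400 + 10 * i)))
  umcs <- umc_fdr(summarize_umcs(assign_umcs(psms, 10, 60)), alpha = 0.01)
  expect_equal(umcs$q_value, brute_force_qvalues(umcs$best_significance,
                                                 umcs$is_decoy))
  # decoy ranked first forces q >= 1/1 for it
  psms2 <- rbind(mk_psm("a", sig = 1e-12, decoy = TRUE, mass = 400),
                 mk_psm("b", sig = 1e-6, mass = 500))
  u2 <- umc_fdr(summarize_umcs(assign_umcs(psms2, 10, 60)), 0.01)
  expect_gte(u2$q_value[u2$is_decoy], 1)
  expect_equal(u2$q_value, brute_force_qvalues(u2$best_significance,
                                               u2$is_decoy))
  # no decoys: everything accepted at q = 0; alpha = 0 accepts nothing
  clean <- do.call(rbind, lapply(1:10, function(i)
    mk_psm(sprintf("t%d", i), sig = 10^-i, mass = 400 + 10 * i)))
  uc <- umc_fdr(summarize_umcs(assign_umcs(clean, 10, 60)), 0.01)
  expect_true(all(uc$accepted))
  expect_true(all(uc$q_value == 0))
  u0 <- umc_fdr(summarize_umcs(assign_umcs(clean, 10, 60)), 0)
  expect_false(any(u0$accepted))
})

test_that("quantification takes the most abundant member, flagging absences", {
  members <- rbind(mk_psm("a", inten = 100), mk_psm("b", inten = 300),
                   mk_psm("c", inten = 200))
  expect_equal(as.numeric(quantify(members)), 300)
  expect_equal(as.numeric(quantify(mk_psm("a", inten = 42))), 42)
  q <- quantify(rbind(mk_psm("a"), mk_psm("b")))
  expect_equal(as.numeric(q), 0)
  expect_true(attr(q, "all_missing"))
})

test_that("accepted UMCs collapse into protein-coordinate site records", {
  db <- data.frame(accession = c("P1", "P2"), description = "",
                   sequence = c("AAAAAAAAAGWKAAAA", "GWKAAAA"),
                   is_decoy = FALSE, stringsAsFactors = FALSE)
  psms <- rbind(
    mk_psm("a", starts = "P1:10", sig = 1e-9, mass = 600, rt = 100, inten = 10),
    mk_psm("b", starts = "P1:10", sig = 1e-7, mass = 734, rt = 100, inten = 20))
  umcs <- umc_fdr(summarize_umcs(assign_umcs(psms, 10, 60)), 0.01)
  rbs <- collapse_to_rbs(umcs, db)
  # site 2 of the peptide at protein start 10 -> residue 11; two UMCs merge
  expect_equal(nrow(rbs$sites), 1L)
  expect_equal(rbs$sites$position, 11L)
  expect_equal(rbs$sites$residue, "W")
  expect_equal(rbs$sites$n_umcs, 2L)
  expect_equal(rbs$sites$quant, 20)
  # shared peptide expands to both proteins under one group id
  shared <- mk_psm("c", starts = "P1:10;P2:1", proteins = "P1;P2",
                   sig = 1e-9, inten = 5)
  u2 <- umc_fdr(summarize_umcs(assign_umcs(shared, 10, 60)), 0.01)
  r2 <- collapse_to_rbs(u2, db)
  expect_equal(nrow(r2$sites), 2L)
  expect_equal(unique(r2$sites$protein_group), "P1;P2")
  expect_setequal(paste(r2$sites$accession, r2$sites$position),
                  c("P1 11", "P2 2"))
  # a peptide that does not sit at its claimed coordinates is rejected
  wrong <- mk_psm("d", starts = "P2:4", sig = 1e-9)
  uw <- umc_fdr(summarize_umcs(assign_umcs(wrong, 10, 60)), 0.01)
  expect_error(collapse_to_rbs(uw, db), "GWK")
})

test_that("the postprocess chain is idempotent on its own output", {
  res <- small_result()
  kept <- apply_exclusions(recalibration_filter(res$psms))
  again <- apply_exclusions(kept)
  expect_identical(kept[order(kept$scan), ], again[order(again$scan), ])
  clustered <- assign_umcs(kept, 10, 60)
  re <- assign_umcs(clustered, 10, 60)
  # cluster labels may be renumbered but the partition is identical
  expect_equal(length(unique(clustered$umc_id)), length(unique(re$umc_id)))
  expect_true(all(tapply(re$umc_id, clustered$umc_id,
                         function(x) length(unique(x))) == 1L))
  umcs <- umc_fdr(summarize_umcs(clustered), 0.01)
  expect_identical(umc_fdr(umcs[, setdiff(names(umcs), c("q_value", "accepted"))],
                           0.01)$q_value, umcs$q_value)
})
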