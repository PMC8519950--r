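# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(seed = 42, n_proteins = 30, n_sites = 40,
                      n_background = 20, n_noise_spectra = 30)
    .fixture_env$sim <- simulate_dataset(cfg)
  }
  .fixture_env$sim
}

small_result <- function() {
  if (is.null(.fixture_env$res)) {
    sim <- small_sim()
    .fixture_env$res <- prbs_id(sim$spectra, sim$database,
                                search_params("4SU", "prbs"))
  }
  .fixture_env$res
}

mini_db <- function(seqs, acc = sprintf("P%d", seq_along(seqs))) {
  data.frame(accession = acc, description = "", sequence = seqs,
             is_decoy = FALSE, stringsAsFactors = FALSE)
}

# A tiny hand-made spectrum from explicit peaks.
mk_spec <- function(mz, intensity = rep(1000, length(mz)), premz = 500,
                    charge = 2L, rt = 100, scan = "s1", prec_int = NA_real_) {
  spectrum(scan = scan, premz = premz, charge = charge, rt = rt,
           prec_intensity = prec_int, mz = mz, intensity = intensity)
}

# Noise-free synthetic spectrum of a peptide (all b/y ions present), used
# where tests need full fragment evidence without RNG.
ideal_spectrum <- function(pep, site = NULL, par_type = "4SU",
                           form = "base", charge = 2L, rt = 100,
                           scan = "ideal", prec_int = 1e6) {
  fr <- theoretical_fragments(pep, mod_site = site, par_type = par_type,
                              form = form, mode = "prbs")
  neutral <- peptide_neutral_mass(pep, mod_site = site, par_type = par_type,
                                  form = form)
  spectrum(scan = scan, premz = neutral / charge + proton_mass(),
           charge = charge, rt = rt, prec_intensity = prec_int,
           mz = fr$mz, intensity = rep(1e4, nrow(fr)))
}
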