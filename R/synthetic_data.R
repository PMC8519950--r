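# Seeded generator of FASTA + MGF + ground-truth fixtures carrying the
# statistical structure the search method assumes: tryptic peptides with
# exactly one PAR adduct in base or nucleoside form (both minus H2S), HCD
# MS2 fragments in which nucleoside adducts have lost the ribose (appearing
# base-form), multiple XIC-like precursor occurrences per site, in-source
# fragmented co-eluting base-form precursors, noise peaks, uncrosslinked
# background peptides and pure-noise scans.

# Approximate human proteome amino-acid background frequencies used to draw
# synthetic protein sequences.
.AA_BACKGROUND <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, Q = 0.048,
  E = 0.071, G = 0.066, H = 0.026, I = 0.043, L = 0.100, K = 0.057,
  M = 0.021, F = 0.037, P = 0.063, S = 0.083, T = 0.053, W = 0.012,
  Y = 0.027, V = 0.060
)

#' Default crosslink residue propensity weights
#'
#' Site selection favors the aromatic residues Trp/Tyr/Phe/His and the
#' thiol-bearing Cys, the residue classes most frequently captured as
#' PAR-crosslinked sites; every other residue keeps a small non-zero weight
#' so rarer sites occur too.
#'
#' @return Named numeric weight vector over the 20 residues.
#' @export
default_residue_weights <- function() {
  w <- stats::setNames(rep(0.3, 20), names(.AA_BACKGROUND))
  w[c("W", "Y", "F", "H", "C")] <- c(6, 5, 4, 4, 4)
  w[c("K", "R")] <- 0.1
  w
}

#' Simulation configuration
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_proteins Number of synthetic proteins (default 200).
#' @param protein_length Length bounds for protein sequences (default
#'   60-120).
#' @param n_sites Number of planted crosslink sites (default 300).
#' @param par_type `"4SU"` or `"6SG"`.
#' @param nucleoside_fraction Fraction of planted sites whose precursor
#'   retains the ribose (default 0.4).
#' @param insource_fraction Probability that a nucleoside-form site
#'   additionally emits a co-eluting base-form precursor via in-source
#'   fragmentation (default 0.3).
#' @param residue_weights Site propensity weights, see
#'   [default_residue_weights()].
#' @param fragment_efficiency Probability that each theoretical b/y ion is
#'   observed (default 0.9).
#' @param noise_peaks Noise peaks added to each peptide spectrum (default 5).
#' @param n_background Uncrosslinked background peptide spectra (default
#'   100).
#' @param n_noise_spectra Pure-noise scans with no underlying peptide
#'   (default 150); these exercise the target-decoy FDR machinery.
#' @param noise_spectrum_peaks Peaks per pure-noise scan (default 45).
#' @param mass_error_ppm Gaussian precursor mass error s.d. in ppm (default
#'   3).
#' @param frag_mz_sd Gaussian fragment m/z jitter s.d. in Da (default
#'   0.004).
#' @param rt_range Elution window in seconds (default 300-5700).
#' @param rt_jitter Half-width of the RT jitter between XIC-like occurrences
#'   of one site, seconds (default 20).
#' @param mean_occurrences Mean number of precursor occurrences (spectra)
#'   per planted site (default 2; minimum 1).
#' @param charge_range Charges sampled for peptide precursors (default 2-3).
#' @param spectrum_seed Optional separate seed for the spectrum-level noise
#'   (intensities, mass errors, noise peaks).  Two simulations sharing
#'   `seed` but differing in `spectrum_seed` are technical replicates: same
#'   proteins, sites, forms and abundances, independent measurement noise.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 200L,
                       protein_length = c(60L, 120L), n_sites = 300L,
                       par_type = "4SU", nucleoside_fraction = 0.4,
                       insource_fraction = 0.3,
                       residue_weights = default_residue_weights(),
                       fragment_efficiency = 0.9, noise_peaks = 5L,
                       n_background = 100L, n_noise_spectra = 150L,
                       noise_spectrum_peaks = 45L, mass_error_ppm = 3,
                       frag_mz_sd = 0.004, rt_range = c(300, 5700),
                       rt_jitter = 20, mean_occurrences = 2,
                       charge_range = 2:3, spectrum_seed = NULL) {
  stopifnot(nucleoside_fraction >= 0, nucleoside_fraction <= 1,
            insource_fraction >= 0, insource_fraction <= 1,
            fragment_efficiency > 0, fragment_efficiency <= 1,
            mean_occurrences >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Internal: one synthetic MS2 spectrum.  `site`/`form` NULL for background
# peptides.  MS2 site-covering fragments always carry the BASE-form delta
# (ribose is lost during HCD); only the precursor mass distinguishes the
# forms.
.sim_peptide_spectrum <- function(scan, pep, site, form, par_type, abundance,
                                  rt, cfg) {
  res <- strsplit(pep, "", fixed = TRUE)[[1]]
  L <- length(res)
  resm <- .residue_mass_vector(res, TRUE)
  neutral <- sum(resm) + .WATER
  dbase <- 0
  if (!is.null(site)) {
    dbase <- adduct_delta(par_type, "base", res[site])
    neutral <- neutral + adduct_delta(par_type, form, res[site])
  }
  charge <- if (length(cfg$charge_range) > 1L) {
    sample(cfg$charge_range, 1L)
  } else cfg$charge_range
  obs <- neutral * (1 + stats::rnorm(1, 0, cfg$mass_error_ppm) / 1e6)
  premz <- obs / charge + .PROTON
  prec_int <- abundance * stats::rlnorm(1, 0, 0.25)
  i <- seq_len(L - 1L)
  b <- cumsum(resm)[-L] + .PROTON
  y <- cumsum(rev(resm))[-L] + .WATER + .PROTON
  if (!is.null(site)) {
    b <- b + (i >= site) * dbase
    y <- y + (i >= L - site + 1L) * dbase
  }
  frag <- c(b, y)
  keep <- stats::runif(length(frag)) < cfg$fragment_efficiency
  frag <- frag[keep]
  fmz <- frag + stats::rnorm(length(frag), 0, cfg$frag_mz_sd)
  fint <- stats::rlnorm(length(frag), log(5e3), 0.8)
  if (cfg$noise_peaks > 0L) {
    nmz <- stats::runif(cfg$noise_peaks, 100, max(c(fmz, 800)) + 100)
    nint <- stats::rlnorm(cfg$noise_peaks, log(500), 0.8)
    fmz <- c(fmz, nmz)
    fint <- c(fint, nint)
  }
  list(spectrum = spectrum(scan = scan, premz = premz, charge = charge,
                           rt = rt, prec_intensity = prec_int,
                           mz = fmz, intensity = fint),
       neutral = neutral, charge = charge)
}

#' Simulate a crosslinking LC-MS/MS dataset
#'
#' Generates a synthetic protein FASTA, an MGF of centroided MS2 scans and a
#' per-spectrum ground-truth table, deterministically under
#' `config$seed`.  Crosslinked precursors carry the base-form delta, or the
#' base-form delta plus the ribose mass for nucleoside forms; MS2
#' site-covering b/y ions carry the base-form delta in both cases.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional directory; when given, `proteins.fasta`,
#'   `spectra.mgf` and `truth.tsv` are written there.
#' @return List with `database` (targets only), `spectra`, `truth`
#'   data.frame and the `config`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  aa <- names(.AA_BACKGROUND)
  lens <- sample(seq.int(cfg$protein_length[1], cfg$protein_length[2]),
                 cfg$n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(n)
    paste(sample(aa, n, replace = TRUE, prob = .AA_BACKGROUND),
          collapse = ""), character(1))
  db <- data.frame(accession = sprintf("SYN%04d", seq_len(cfg$n_proteins)),
                   description = "synthetic protein",
                   sequence = seqs, is_decoy = FALSE, stringsAsFactors = FALSE)
  peptides <- digest(db, missed_cleavages = 0, length_range = c(7, 30))
  peptides <- peptides[!grepl(";", peptides$proteins), , drop = FALSE]
  w <- cfg$residue_weights
  eligible <- lapply(strsplit(peptides$sequence, "", fixed = TRUE),
                     function(r) {
                       # crosslink planted anywhere except the C-terminal
                       # K/R, which the localization rules exclude
                       pos <- seq_len(length(r) - 1L)
                       pos[w[r[pos]] > 0]
                     })
  has_site <- lengths(eligible) > 0L
  peptides <- peptides[has_site, , drop = FALSE]
  eligible <- eligible[has_site]
  if (nrow(peptides) < cfg$n_sites) {
    stop("configuration requests ", cfg$n_sites, " crosslink sites but only ",
         nrow(peptides), " eligible peptides exist")
  }
  sel <- sample(nrow(peptides), cfg$n_sites)
  sites <- vapply(sel, function(i) {
    pos <- eligible[[i]]
    r <- strsplit(peptides$sequence[i], "", fixed = TRUE)[[1]]
    if (length(pos) == 1L) pos else sample(pos, 1L, prob = w[r[pos]])
  }, integer(1))
  forms <- ifelse(stats::runif(cfg$n_sites) < cfg$nucleoside_fraction,
                  "nucleoside", "base")
  abundance <- stats::rlnorm(cfg$n_sites, log(1e6), 1.2)
  rts <- stats::runif(cfg$n_sites, cfg$rt_range[1], cfg$rt_range[2])
  occ <- 1L + stats::rpois(cfg$n_sites, cfg$mean_occurrences - 1)
  insource <- forms == "nucleoside" &
    stats::runif(cfg$n_sites) < cfg$insource_fraction
  bg_pool <- setdiff(seq_len(nrow(peptides)), sel)
  bg_sel <- if (cfg$n_background > 0L) {
    sample(bg_pool, min(cfg$n_background, length(bg_pool)))
  } else integer(0)
  bg_abundance <- stats::rlnorm(length(bg_sel), log(1e6), 1.2)
  bg_rts <- stats::runif(length(bg_sel), cfg$rt_range[1], cfg$rt_range[2])

  # task list is fixed by the planting seed; measurement noise may use its
  # own stream so that technical replicates share the plant
  set.seed(if (is.null(cfg$spectrum_seed)) cfg$seed else cfg$spectrum_seed)

  spectra <- list()
  truth <- list()
  scan_no <- 0L
  emit <- function(kind, pep_i, site, form, abund, rt) {
    scan_no <<- scan_no + 1L
    id <- sprintf("synth.%05d", scan_no)
    pep <- peptides$sequence[pep_i]
    gen <- .sim_peptide_spectrum(id, pep, site, form, cfg$par_type, abund,
                                 rt, cfg)
    spectra[[length(spectra) + 1L]] <<- gen$spectrum
    prov <- .parse_starts(peptides$starts[pep_i])
    truth[[length(truth) + 1L]] <<- data.frame(
      scan = id, kind = kind, peptide = pep,
      accession = prov$accession[1L], pep_start = prov$start[1L],
      site_pep = if (is.null(site)) NA_integer_ else site,
      site_protein = if (is.null(site)) NA_integer_ else
        prov$start[1L] + site - 1L,
      residue = if (is.null(site)) NA_character_ else
        substr(pep, site, site),
      form = if (is.null(form)) "none" else form,
      true_neutral = gen$neutral, rt = rt, charge = gen$charge,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(cfg$n_sites)) {
    for (o in seq_len(occ[k])) {
      rt_o <- rts[k] + stats::runif(1, -cfg$rt_jitter, cfg$rt_jitter)
      emit("crosslink", sel[k], sites[k], forms[k], abundance[k], rt_o)
    }
    if (insource[k]) {
      emit("insource", sel[k], sites[k], "base", abundance[k] * 0.5, rts[k])
    }
  }
  for (k in seq_along(bg_sel)) {
    emit("background", bg_sel[k], NULL, NULL, bg_abundance[k], bg_rts[k])
  }
  for (k in seq_len(cfg$n_noise_spectra)) {
    scan_no <- scan_no + 1L
    id <- sprintf("synth.%05d", scan_no)
    mz <- stats::runif(cfg$noise_spectrum_peaks, 150, 1500)
    spectra[[length(spectra) + 1L]] <- spectrum(
      scan = id, premz = stats::runif(1, 400, 1200), charge = 2L,
      rt = stats::runif(1, cfg$rt_range[1], cfg$rt_range[2]),
      prec_intensity = stats::rlnorm(1, log(1e5), 1),
      mz = mz, intensity = stats::rlnorm(length(mz), log(1e3), 1))
    truth[[length(truth) + 1L]] <- data.frame(
      scan = id, kind = "noise", peptide = NA_character_,
      accession = NA_character_, pep_start = NA_integer_,
      site_pep = NA_integer_, site_protein = NA_integer_,
      residue = NA_character_, form = "none", true_neutral = NA_real_,
      rt = NA_real_, charge = 2L, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  out <- list(database = db, spectra = spectra, truth = truth, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(db, file.path(out_dir, "proteins.fasta"))
    write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
    write_results(truth, file.path(out_dir, "truth.tsv"))
  }
  out
}

#' Compare pipeline output with the simulation ground truth
#'
#' Site-level precision and recall use exact (protein, position) matching;
#' an off-by-one localization counts as a false localization, not a
#' recovery.  When the UMC table is supplied, form-assignment accuracy and
#' the realized false-discovery proportion (accepted UMCs whose best PSM
#' does not reproduce the generating peptide) are evaluated via the scan
#' identifiers.
#'
#' @param sites Site table from [collapse_to_rbs()] / [prbs_id()].
#' @param truth Ground-truth table from [simulate_dataset()].
#' @param umcs Optional accepted/filtered UMC table from [umc_fdr()].
#' @return List of metrics: `recall`, `precision` (reported as 1 with
#'   `precision_defined = FALSE` when nothing was reported),
#'   `false_localization_rate`, `n_true_sites`, `n_reported`, and - when
#'   `umcs` is given - `form_accuracy` and `realized_fdp`.
#' @export
evaluate_recovery <- function(sites, truth, umcs = NULL) {
  xt <- truth[truth$kind %in% c("crosslink", "insource"), , drop = FALSE]
  true_keys <- unique(paste(xt$accession, xt$site_protein))
  rep_keys <- paste(sites$accession, sites$position)
  hit <- rep_keys %in% true_keys
  recall <- sum(unique(rep_keys[hit]) %in% true_keys) / length(true_keys)
  precision_defined <- length(rep_keys) > 0L
  precision <- if (precision_defined) mean(hit) else 1
  true_prot <- unique(xt$accession)
  false_loc <- !hit & sites$accession %in% true_prot
  out <- list(recall = recall, precision = precision,
              precision_defined = precision_defined,
              false_localization_rate = if (length(rep_keys)) {
                mean(false_loc)
              } else 0,
              n_true_sites = length(true_keys),
              n_reported = length(rep_keys))
  if (!is.null(umcs)) {
    acc <- umcs[umcs$accepted, , drop = FALSE]
    ti <- match(acc$best_scan, truth$scan)
    genuine <- !is.na(ti) & !is.na(truth$peptide[ti]) &
      truth$peptide[ti] == acc$peptide
    out$realized_fdp <- if (nrow(acc)) mean(!genuine) else 0
    xl <- genuine & truth$kind[ti] %in% c("crosslink", "insource")
    out$form_accuracy <- if (any(xl)) {
      mean(acc$form[xl] == truth$form[ti][xl])
    } else NA_real_
    out$n_accepted_umcs <- nrow(acc)
  }
  out
}
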