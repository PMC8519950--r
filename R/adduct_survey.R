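# Adduct-characterization analytics: a simplified MS1 precursor-delta
# profile (open-offset surrogate) and the y-ion nominal-mass MS2 scan that
# together reveal the base/nucleoside adduct pair and the ribose neutral
# loss.

#' MS1 precursor-delta profile
#'
#' For each spectrum, the best candidate peptide is found by counting matched
#' unmodified b/y fragments while ignoring the precursor mass (an
#' open-search surrogate); the offset between observed neutral mass and the
#' candidate's unmodified mass is histogrammed into 1-Da nominal bins over
#' `range`, count-weighted, and max-normalized.
#'
#' @param spectra List of [spectrum()] objects.
#' @param database Protein database; only target entries are used.
#' @param params [search_params()] (digestion settings and fragment
#'   tolerance).
#' @param range Nominal offset range in Da (default `c(0, 400)`).
#' @param min_fragments Minimum matched fragments for a spectrum to
#'   contribute (default 3).
#' @return data.frame (`nominal_mass`, `intensity`) covering `range`, with
#'   maximum exactly 1 when any spectrum contributed; attribute `"source"`
#'   is `"MS1"`.
#' @export
precursor_delta_profile <- function(spectra, database,
                                    params = search_params(),
                                    range = c(0, 400), min_fragments = 3L) {
  nominal <- seq.int(range[1], range[2])
  acc <- stats::setNames(numeric(length(nominal)), nominal)
  if (length(spectra) > 0L) {
    targets <- database[!database$is_decoy, , drop = FALSE]
    peptides <- digest(targets, params$missed_cleavages, params$length_range)
    resm_list <- lapply(strsplit(peptides$sequence, "", fixed = TRUE),
                        .residue_mass_vector, params$carbamidomethyl)
    mass0 <- vapply(resm_list, sum, numeric(1)) + .WATER
    frag <- lapply(seq_along(resm_list), function(i) {
      resm <- resm_list[[i]]
      L <- length(resm)
      c(cumsum(resm)[-L] + .PROTON, cumsum(rev(resm))[-L] + .WATER + .PROTON)
    })
    pep_id <- rep(seq_along(frag), lengths(frag))
    fragv <- unlist(frag)
    o <- order(fragv)
    fragv <- fragv[o]
    pep_id <- pep_id[o]
    for (sp in spectra) {
      if (length(sp$mz) == 0L || is.na(sp$charge)) next
      m <- .match_peaks(fragv, sp$mz, rep(0, length(sp$mz)), params$frag_tol)
      counts <- tabulate(pep_id[m$matched], nbins = nrow(peptides))
      best <- which.max(counts)
      if (counts[best] < min_fragments) next
      offset <- (sp$premz - .PROTON) * sp$charge - mass0[best]
      bin <- round(offset)
      if (bin >= range[1] && bin <= range[2]) {
        acc[as.character(bin)] <- acc[as.character(bin)] + 1
      }
    }
  }
  if (max(acc) > 0) acc <- acc / max(acc)
  structure(data.frame(nominal_mass = nominal, intensity = unname(acc)),
            source = "MS1", window = 1)
}

#' MS2 y-ion nominal-mass modification profile
#'
#' For every PSM, y-ions covering the assigned modification site are taken
#' at their unmodified masses; nominal masses 1-400 Da (by default) are
#' iteratively added and matched against the MS2 peaks of the corresponding
#' scan within a total `window` of 0.5 Da.  Relative peak intensities
#' (peak / base peak of its scan) of matched ions are summed per nominal
#' mass and the profile is max-normalized.
#'
#' @param psms PSM table (modified PSMs with `peptide` and `site`).
#' @param spectra List of [spectrum()] objects containing every PSM scan.
#' @param range Nominal mass range (default `c(1, 400)`).
#' @param window Total matching window width in Da (default 0.5, i.e.
#'   +/- 0.25).
#' @param include_b Also use b-ions covering the site (default FALSE; the
#'   survey is y-ion based).
#' @param carbamidomethyl Fixed Cys modification.
#' @return data.frame (`nominal_mass`, `intensity`); attribute `"source"`
#'   is `"MS2"`.
#' @export
ms2_delta_profile <- function(psms, spectra, range = c(1, 400), window = 0.5,
                              include_b = FALSE, carbamidomethyl = TRUE) {
  nominal <- seq.int(range[1], range[2])
  acc <- stats::setNames(numeric(length(nominal)), nominal)
  scan_map <- stats::setNames(seq_along(spectra),
                              vapply(spectra, function(s) s$scan,
                                     character(1)))
  mod <- psms[!is.na(psms$site), , drop = FALSE]
  for (r in seq_len(nrow(mod))) {
    i <- scan_map[mod$scan[r]]
    if (is.na(i)) stop("no spectrum for scan '", mod$scan[r], "'")
    sp <- spectra[[i]]
    if (length(sp$mz) == 0L) next
    res <- strsplit(mod$peptide[r], "", fixed = TRUE)[[1]]
    L <- length(res)
    s <- mod$site[r]
    resm <- .residue_mass_vector(res, carbamidomethyl)
    yi <- seq_len(L - 1L)
    ions <- (cumsum(rev(resm))[-L] + .WATER + .PROTON)[yi >= L - s + 1L]
    if (include_b) {
      bi <- seq_len(L - 1L)
      ions <- c(ions, (cumsum(resm)[-L] + .PROTON)[bi >= s])
    }
    if (length(ions) == 0L) next
    rel <- sp$intensity / max(sp$intensity)
    delta <- outer(sp$mz, ions, "-")
    nom <- round(delta)
    ok <- abs(delta - nom) <= window / 2 & nom >= range[1] & nom <= range[2]
    if (!any(ok)) next
    hit_nom <- nom[ok]
    hit_rel <- rel[row(delta)[ok]]
    add <- tapply(hit_rel, hit_nom, sum)
    acc[names(add)] <- acc[names(add)] + add
  }
  if (max(acc) > 0) acc <- acc / max(acc)
  structure(data.frame(nominal_mass = nominal, intensity = unname(acc)),
            source = "MS2", window = window)
}

#' Mode (argmax nominal mass) of a delta profile
#' @param profile Output of [precursor_delta_profile()] or
#'   [ms2_delta_profile()].
#' @return The nominal mass with the highest normalized intensity.
#' @export
profile_mode <- function(profile) {
  profile$nominal_mass[which.max(profile$intensity)]
}
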