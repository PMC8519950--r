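# In-silico tryptic digestion, candidate indexing, scan duplication with
# ribose-loss precursor correction, fragment generation, scoring and
# best-PSM-per-scan selection.  The "conventional" baseline mode (no
# precursor correction, base AND nucleoside variable modifications) shares
# the same machinery.

#' Search parameter set
#'
#' @param par_type `"4SU"` or `"6SG"`.
#' @param mode `"prbs"` (scan duplication with ribose-loss precursor
#'   correction, single base-form variable modification) or `"conventional"`
#'   (uncorrected precursors only, base and nucleoside variable
#'   modifications).
#' @param prec_ppm Precursor mass tolerance in ppm (default 10).
#' @param frag_tol Fragment matching tolerance in Da (default 0.02,
#'   appropriate for 15k-resolution HCD MS2).
#' @param missed_cleavages Maximum tryptic missed cleavages (default 2).
#' @param length_range Peptide length bounds (default 6-40).
#' @param charge_range Precursor charges searched (default 2-7).
#' @param carbamidomethyl Fixed Cys carbamidomethylation (default TRUE).
#' @param adducts Adduct definition table, see [default_adducts()].
#' @return List of class `"prbs_params"`.
#' @export
search_params <- function(par_type = "4SU", mode = c("prbs", "conventional"),
                          prec_ppm = 10, frag_tol = 0.02,
                          missed_cleavages = 2, length_range = c(6, 40),
                          charge_range = c(2L, 7L), carbamidomethyl = TRUE,
                          adducts = default_adducts()) {
  mode <- match.arg(mode)
  stopifnot(prec_ppm > 0, frag_tol > 0, missed_cleavages >= 0)
  structure(list(par_type = par_type, mode = mode, prec_ppm = prec_ppm,
                 frag_tol = frag_tol, missed_cleavages = missed_cleavages,
                 length_range = length_range,
                 charge_range = as.integer(charge_range),
                 carbamidomethyl = carbamidomethyl, adducts = adducts),
            class = "prbs_params")
}

#' Tryptic in-silico digestion
#'
#' Cleaves C-terminal to K/R, suppressed before Pro.  Peptides containing
#' nonstandard residues (X, B, U, ...) are dropped, matching common search
#' engine behavior.  Duplicate sequences across proteins are merged with
#' multi-protein provenance.
#'
#' @param db Protein database data.frame (see [read_fasta()]).
#' @param missed_cleavages Maximum number of missed cleavages.
#' @param length_range Length bounds `c(min, max)`, inclusive.
#' @return data.frame with columns `sequence`, `proteins` (`;`-collapsed
#'   accessions), `starts` (`;`-collapsed `accession:start` pairs, 1-based),
#'   `n_missed` (minimum over occurrences), `is_decoy` (TRUE iff every parent
#'   protein is a decoy).
#' @export
digest <- function(db, missed_cleavages = 2, length_range = c(6, 40)) {
  stopifnot(missed_cleavages >= 0)
  seq_l <- list()
  acc_l <- list()
  start_l <- list()
  mc_l <- list()
  dec_l <- list()
  for (r in seq_len(nrow(db))) {
    s <- db$sequence[r]
    n <- nchar(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    kr <- which(chars %in% c("K", "R"))
    kr <- kr[kr == n | chars[pmin(kr + 1L, n)] != "P"]
    ends <- sort(unique(c(kr, n)))
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    nseg <- length(ends)
    for (j in seq_len(nseg)) {
      for (mc in 0:missed_cleavages) {
        if (j + mc > nseg) break
        from <- starts[j]
        to <- ends[j + mc]
        len <- to - from + 1L
        if (len < length_range[1] || len > length_range[2]) next
        pep <- substr(s, from, to)
        seq_l[[length(seq_l) + 1L]] <- pep
        acc_l[[length(acc_l) + 1L]] <- db$accession[r]
        start_l[[length(start_l) + 1L]] <- from
        mc_l[[length(mc_l) + 1L]] <- mc
        dec_l[[length(dec_l) + 1L]] <- isTRUE(db$is_decoy[r])
      }
    }
  }
  if (length(seq_l) == 0L) {
    return(data.frame(sequence = character(0), proteins = character(0),
                      starts = character(0), n_missed = integer(0),
                      is_decoy = logical(0), stringsAsFactors = FALSE))
  }
  flat <- data.frame(sequence = unlist(seq_l), accession = unlist(acc_l),
                     start = unlist(start_l), n_missed = unlist(mc_l),
                     is_decoy = unlist(dec_l), stringsAsFactors = FALSE)
  ok <- !grepl("[^ACDEFGHIKLMNPQRSTVWY]", flat$sequence)
  flat <- flat[ok, , drop = FALSE]
  sp <- split(flat, flat$sequence)
  out <- data.frame(
    sequence = names(sp),
    proteins = vapply(sp, function(d) paste(unique(d$accession),
                                            collapse = ";"), character(1)),
    starts = vapply(sp, function(d)
      paste(paste0(d$accession, ":", d$start), collapse = ";"), character(1)),
    n_missed = vapply(sp, function(d) min(d$n_missed), integer(1)),
    is_decoy = vapply(sp, function(d) all(d$is_decoy), logical(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Duplicate a scan with ribose-loss precursor correction
#'
#' Returns a copy of the spectrum whose precursor m/z has been lowered by the
#' ribose mass divided by the charge, so that a nucleoside-form precursor is
#' reinterpreted as its base form.  The MS2 peak list and retention time are
#' unchanged.  A scan can be corrected only once.
#'
#' @param sp A [spectrum()] object with known charge.
#' @return Corrected copy with the `corrected` flag set.
#' @export
correct_scan <- function(sp) {
  if (isTRUE(sp$corrected)) stop("scan '", sp$scan, "' is already corrected")
  if (is.na(sp$charge) || sp$charge < 1) {
    stop("cannot correct scan '", sp$scan, "': unknown or zero charge")
  }
  sp$premz <- sp$premz - .RIBOSE_MASS / sp$charge
  sp$corrected <- TRUE
  sp
}

# Internal: nearest-peak matching of a vector of theoretical m/z values
# against a sorted peak list.  Returns matched flags and per-fragment
# intensity weights log10(1 + relative intensity).
.match_peaks <- function(mzv, peak_mz, peak_w, tol) {
  n <- length(peak_mz)
  idx <- findInterval(mzv, peak_mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, n)
  dlo <- abs(mzv - peak_mz[lo])
  dhi <- abs(mzv - peak_mz[hi])
  use_hi <- dhi < dlo
  d <- pmin(dlo, dhi)
  best <- ifelse(use_hi, hi, lo)
  matched <- d <= tol
  w <- numeric(length(mzv))
  w[matched] <- peak_w[best[matched]]
  list(matched = matched, w = w)
}

# Internal vectorized scorer: one peptide (residue-mass vector `resm`),
# several candidate modification sites at once.  `sites = integer(0)` scores
# the unmodified peptide.  `deltas` gives the fragment-level mass delta per
# site (scalar or vector parallel to `sites`).
# Returns data.frame(site, k, raw, sig).
.score_sites <- function(sp, resm, sites, deltas, frag_tol) {
  L <- length(resm)
  nf <- 2L * (L - 1L)
  unmod <- length(sites) == 0L
  ncand <- if (unmod) 1L else length(sites)
  if (length(sp$mz) == 0L || L < 2L) {
    return(data.frame(site = if (unmod) NA_integer_ else sites,
                      k = 0L, raw = 0, sig = 1))
  }
  b <- cumsum(resm)[-L] + .PROTON
  y <- cumsum(rev(resm))[-L] + .WATER + .PROTON
  i <- seq_len(L - 1L)
  if (unmod) {
    fr <- c(b, y)
  } else {
    if (length(deltas) == 1L) deltas <- rep(deltas, length(sites))
    bm <- matrix(b, L - 1L, ncand) +
      outer(i, sites, ">=") * rep(deltas, each = L - 1L)
    ym <- matrix(y, L - 1L, ncand) +
      outer(i, L - sites + 1L, ">=") * rep(deltas, each = L - 1L)
    fr <- rbind(bm, ym)
  }
  peak_w <- log10(1 + sp$intensity / max(sp$intensity))
  p <- min(0.999, 2 * frag_tol * length(sp$mz) /
             max(1, diff(range(sp$mz))))
  m <- .match_peaks(as.vector(fr), sp$mz, peak_w, frag_tol)
  k <- colSums(matrix(m$matched, nrow = nf))
  raw <- colSums(matrix(m$w, nrow = nf))
  sig <- ifelse(k == 0L, 1,
                pmax(1e-300, stats::pbinom(k - 1L, nf, p, lower.tail = FALSE)))
  data.frame(site = if (unmod) NA_integer_ else sites,
             k = as.integer(k), raw = raw, sig = sig)
}

#' Theoretical b/y fragment ions of a peptide candidate
#'
#' In `"prbs"` mode, fragments covering the modification site always carry
#' the base-form adduct delta regardless of the precursor form, reflecting
#' the near-complete ribose neutral loss of nucleoside adducts during HCD;
#' in `"conventional"` mode the searched variable modification is applied to
#' the fragments as-is.
#'
#' @param sequence Peptide sequence.
#' @param mod_site Optional 1-based modification site.
#' @param par_type,form Adduct identity when `mod_site` is given.
#' @param max_charge Highest fragment charge generated (default 1).
#' @param mode `"prbs"` or `"conventional"` (see above).
#' @param carbamidomethyl Fixed Cys modification.
#' @param adducts Adduct definition table.
#' @return data.frame with columns `ion` (e.g. `"y3"`, `"b2^2"`) and `mz`.
#' @export
theoretical_fragments <- function(sequence, mod_site = NULL, par_type = "4SU",
                                  form = "base", max_charge = 1L,
                                  mode = c("prbs", "conventional"),
                                  carbamidomethyl = TRUE,
                                  adducts = default_adducts()) {
  mode <- match.arg(mode)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(res)
  if (!is.null(mod_site) && (mod_site < 1L || mod_site > L)) {
    stop("modification site out of range for peptide '", sequence, "'")
  }
  resm <- .residue_mass_vector(res, carbamidomethyl)
  b <- cumsum(resm)[-L] + .PROTON
  y <- cumsum(rev(resm))[-L] + .WATER + .PROTON
  i <- seq_len(L - 1L)
  if (!is.null(mod_site)) {
    frag_form <- if (mode == "prbs") "base" else form
    d <- adduct_delta(par_type, frag_form, res[mod_site], adducts)
    b <- b + (i >= mod_site) * d
    y <- y + (i >= L - mod_site + 1L) * d
  }
  out <- data.frame(ion = c(paste0("b", i), paste0("y", i)), mz = c(b, y),
                    stringsAsFactors = FALSE)
  if (max_charge > 1L) {
    extra <- lapply(2:max_charge, function(z) {
      data.frame(ion = paste0(out$ion, "^", z),
                 mz = (out$mz + (z - 1L) * .PROTON) / z,
                 stringsAsFactors = FALSE)
    })
    out <- rbind(out, do.call(rbind, extra))
  }
  out
}

#' Score one peptide candidate against a spectrum
#'
#' The raw score is the count of matched theoretical b/y fragments weighted
#' by `log10(1 + relative intensity)`; the significance is the exact
#' binomial tail probability of matching at least `k` of `n` fragments by
#' chance, with per-fragment match probability
#' `p = 2 * frag_tol * n_peaks / usable m/z range` (floored at 1e-300 and
#' capped below 1).  Smaller significance is better.  An empty peak list or
#' zero matched fragments gives significance 1.
#'
#' @inheritParams theoretical_fragments
#' @param sp A [spectrum()] object.
#' @param frag_tol Fragment tolerance in Da.
#' @return List with `raw_score`, `significance` and `n_matched`.
#' @export
score_match <- function(sp, sequence, mod_site = NULL, par_type = "4SU",
                        form = "base", frag_tol = 0.02,
                        mode = c("prbs", "conventional"),
                        carbamidomethyl = TRUE, adducts = default_adducts()) {
  mode <- match.arg(mode)
  stopifnot(frag_tol > 0)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  resm <- .residue_mass_vector(res, carbamidomethyl)
  if (is.null(mod_site)) {
    sc <- .score_sites(sp, resm, integer(0), 0, frag_tol)
  } else {
    if (mod_site < 1L || mod_site > length(res)) {
      stop("modification site out of range for peptide '", sequence, "'")
    }
    frag_form <- if (mode == "prbs") "base" else form
    d <- adduct_delta(par_type, frag_form, res[mod_site], adducts)
    sc <- .score_sites(sp, resm, as.integer(mod_site), d, frag_tol)
  }
  list(raw_score = sc$raw, significance = sc$sig, n_matched = sc$k)
}

#' Build a precursor-mass candidate index over digested peptides
#'
#' Each peptide contributes up to five index entries: unmodified, base-form
#' adduct on a non-Cys residue, base-form on Cys, and the two nucleoside
#' counterparts (used only by the conventional mode).
#'
#' @param peptides Digestion table from [digest()].
#' @param params [search_params()] object.
#' @return List of class `"prbs_index"`.
#' @export
build_search_index <- function(peptides, params = search_params()) {
  res_list <- strsplit(peptides$sequence, "", fixed = TRUE)
  resm_list <- lapply(res_list, .residue_mass_vector, params$carbamidomethyl)
  mass0 <- vapply(resm_list, sum, numeric(1)) + .WATER
  lens <- lengths(res_list)
  ncys <- vapply(res_list, function(r) sum(r == "C"), integer(1))
  d <- c(
    base_x = adduct_delta(params$par_type, "base", "G", params$adducts),
    base_c = adduct_delta(params$par_type, "base", "C", params$adducts),
    nucl_x = adduct_delta(params$par_type, "nucleoside", "G", params$adducts),
    nucl_c = adduct_delta(params$par_type, "nucleoside", "C", params$adducts)
  )
  np <- nrow(peptides)
  has_x <- lens > ncys
  has_c <- ncys > 0L
  entry <- function(pep, type, mass) {
    data.frame(pep = pep, type = rep_len(type, length(pep)), mass = mass,
               stringsAsFactors = FALSE)
  }
  entries <- rbind(
    entry(seq_len(np), "none", mass0),
    entry(which(has_x), "base_x", mass0[has_x] + d[["base_x"]]),
    entry(which(has_c), "base_c", mass0[has_c] + d[["base_c"]]),
    entry(which(has_x), "nucl_x", mass0[has_x] + d[["nucl_x"]]),
    entry(which(has_c), "nucl_c", mass0[has_c] + d[["nucl_c"]])
  )
  entries <- entries[order(entries$mass), , drop = FALSE]
  structure(list(peptides = peptides, res = res_list, resm = resm_list,
                 mass0 = mass0, deltas = d, entries = entries,
                 params = params),
            class = "prbs_index")
}

# Internal: index entries whose mass is within ppm of `m`, restricted to
# allowed entry types.
.index_query <- function(index, m, ppm, types) {
  e <- index$entries
  lo <- findInterval(m * (1 - ppm * 1e-6), e$mass)
  hi <- findInterval(m * (1 + ppm * 1e-6), e$mass)
  if (hi <= lo) return(e[0, , drop = FALSE])
  hit <- e[(lo + 1L):hi, , drop = FALSE]
  hit[hit$type %in% types, , drop = FALSE]
}

#' Search one MS2 scan and return the single best PSM
#'
#' In `"prbs"` mode the scan is evaluated twice - against its uncorrected
#' precursor mass and against the ribose-corrected mass - with the single
#' base-form variable modification (plus unmodified candidates on the
#' uncorrected version); a best match from the corrected version is reported
#' as the nucleoside form.  In `"conventional"` mode only the uncorrected
#' mass is used, with both base and nucleoside variable modifications whose
#' deltas are applied to the fragments as-is.  Exactly one PSM (lowest
#' significance) or `NULL` is returned; ties are broken deterministically:
#' target before decoy, unmodified before modified, lexicographically
#' smallest peptide, smallest site, uncorrected before corrected.
#'
#' @param sp A [spectrum()] object.
#' @param index A [build_search_index()] object.
#' @param params [search_params()]; defaults to the index's own parameters.
#' @return One-row data.frame (PSM) or `NULL`.
#' @export
search_scan <- function(sp, index, params = index$params) {
  if (is.na(sp$charge)) return(NULL)
  M <- (sp$premz - .PROTON) * sp$charge
  versions <- list(list(corrected = FALSE, M = M))
  if (params$mode == "prbs") {
    versions <- c(versions, list(list(corrected = TRUE, M = M - .RIBOSE_MASS)))
  }
  rows <- list()
  for (v in versions) {
    types <- if (params$mode == "prbs") {
      if (v$corrected) c("base_x", "base_c") else c("none", "base_x", "base_c")
    } else {
      c("none", "base_x", "base_c", "nucl_x", "nucl_c")
    }
    hits <- .index_query(index, v$M, params$prec_ppm, types)
    if (nrow(hits) == 0L) next
    for (h in seq_len(nrow(hits))) {
      pi <- hits$pep[h]
      type <- hits$type[h]
      res <- index$res[[pi]]
      resm <- index$resm[[pi]]
      if (type == "none") {
        sc <- .score_sites(sp, resm, integer(0), 0, params$frag_tol)
        form <- "none"
      } else {
        cys_type <- endsWith(type, "_c")
        sites <- if (cys_type) which(res == "C") else which(res != "C")
        # fragment-level delta: always base form in prbs mode; as-searched in
        # conventional mode
        dname <- if (params$mode == "prbs") {
          if (cys_type) "base_c" else "base_x"
        } else type
        sc <- .score_sites(sp, resm, sites, index$deltas[[dname]],
                           params$frag_tol)
        form <- if (params$mode == "prbs") {
          if (v$corrected) "nucleoside" else "base"
        } else if (startsWith(type, "nucl")) "nucleoside" else "base"
      }
      sc$pep <- pi
      sc$form <- form
      sc$corrected <- v$corrected
      sc$prec_error_ppm <- (v$M - hits$mass[h]) / hits$mass[h] * 1e6
      rows[[length(rows) + 1L]] <- sc
    }
  }
  if (length(rows) == 0L) return(NULL)
  cand <- do.call(rbind, rows)
  cand <- cand[cand$k > 0L | cand$form == "none", , drop = FALSE]
  if (nrow(cand) == 0L || min(cand$sig) >= 1) return(NULL)
  peps <- index$peptides
  ord <- order(cand$sig, peps$is_decoy[cand$pep], cand$form != "none",
               peps$sequence[cand$pep], cand$site, cand$corrected)
  best <- cand[ord[1L], , drop = FALSE]
  # localization ambiguity: another site of the same peptide/form/version at
  # identical significance
  same <- cand$pep == best$pep & cand$form == best$form &
    cand$corrected == best$corrected & cand$sig == best$sig &
    !is.na(cand$site)
  ambiguous <- !is.na(best$site) &&
    length(unique(cand$site[same])) > 1L
  pi <- best$pep
  res <- index$res[[pi]]
  data.frame(
    scan = sp$scan,
    peptide = peps$sequence[pi],
    proteins = peps$proteins[pi],
    starts = peps$starts[pi],
    is_decoy = peps$is_decoy[pi],
    site = best$site,
    residue = if (is.na(best$site)) NA_character_ else res[best$site],
    par_type = params$par_type,
    form = best$form,
    corrected = best$corrected,
    n_matched = best$k,
    raw_score = best$raw,
    significance = best$sig,
    prec_error_ppm = best$prec_error_ppm,
    site_ambiguous = ambiguous,
    obs_neutral_mass = M,
    precursor_mz = sp$premz,
    charge = sp$charge,
    rt = sp$rt,
    precursor_intensity = sp$prec_intensity,
    stringsAsFactors = FALSE
  )
}

#' Run a database search over a set of spectra
#'
#' Digests the database, builds the candidate index and searches every scan
#' whose charge lies within the configured range, returning at most one PSM
#' per scan.  Deterministic given inputs and parameters.
#'
#' @param spectra List of [spectrum()] objects.
#' @param database Protein database including decoys (see
#'   [build_target_decoy()]).
#' @param params [search_params()] object.
#' @return PSM data.frame, one row per identified scan.
#' @export
run_search <- function(spectra, database, params = search_params()) {
  peptides <- digest(database, params$missed_cleavages, params$length_range)
  index <- build_search_index(peptides, params)
  search_spectra(spectra, index, params)
}

#' Search spectra against a prebuilt index
#'
#' @inheritParams run_search
#' @param index A [build_search_index()] object.
#' @return PSM data.frame.
#' @export
search_spectra <- function(spectra, index, params = index$params) {
  out <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (is.na(sp$charge) || sp$charge < params$charge_range[1] ||
        sp$charge > params$charge_range[2]) next
    out[[i]] <- search_scan(sp, index, params)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(search_scan_empty())
  }
  do.call(rbind, out)
}

# Internal: zero-row PSM table with the full column set.
search_scan_empty <- function() {
  data.frame(scan = character(0), peptide = character(0),
             proteins = character(0), starts = character(0),
             is_decoy = logical(0), site = integer(0), residue = character(0),
             par_type = character(0), form = character(0),
             corrected = logical(0), n_matched = integer(0),
             raw_score = numeric(0), significance = numeric(0),
             prec_error_ppm = numeric(0), site_ambiguous = logical(0),
             obs_neutral_mass = numeric(0), precursor_mz = numeric(0),
             charge = integer(0), rt = numeric(0),
             precursor_intensity = numeric(0), stringsAsFactors = FALSE)
}
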