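# Further-processing chain: precursor recalibration filtering, ambiguity
# exclusions, UMC (unique mass class) clustering, site localization scoring,
# UMC-level target-decoy FDR, label-free quantification, and collapse of
# accepted UMCs to RNA-binding-site records in protein coordinates.

#' Precursor recalibration filter
#'
#' Centers the precursor ppm error distribution on the mean error of a
#' high-confidence PSM subset and retains PSMs within `ppm_window` of that
#' center.  When no explicit q-values are available yet, "high-confidence"
#' means target PSMs in the best `high_conf_quantile` fraction of
#' significance.
#'
#' @param psms PSM table from [run_search()].
#' @param ppm_window Half-width of the retained window in ppm (default 5).
#' @param high_conf_quantile Fraction of best-significance target PSMs used
#'   to estimate the center (default 0.1).
#' @return Filtered PSM table; the center used is attached as attribute
#'   `"center_ppm"`.
#' @export
recalibration_filter <- function(psms, ppm_window = 5,
                                 high_conf_quantile = 0.1) {
  if (nrow(psms) == 0L) {
    attr(psms, "center_ppm") <- 0
    return(psms)
  }
  hc <- psms[!psms$is_decoy, , drop = FALSE]
  if (nrow(hc) > 0L) {
    cut <- stats::quantile(hc$significance, high_conf_quantile, names = FALSE)
    hc <- hc[hc$significance <= cut, , drop = FALSE]
  }
  if (nrow(hc) == 0L) {
    warning("no high-confidence PSMs for recalibration; centering at 0 ppm")
    center <- 0
  } else {
    center <- mean(hc$prec_error_ppm)
  }
  keep <- abs(psms$prec_error_ppm - center) <= ppm_window
  out <- psms[keep, , drop = FALSE]
  attr(out, "center_ppm") <- center
  out
}

#' Ambiguity exclusion rules
#'
#' Removes unmodified PSMs, PSMs whose modification site is the peptide
#' C-terminal residue when that residue is Lys or Arg, and PSMs whose site
#' assignment is non-unique (another site of the same peptide scored at equal
#' significance).
#'
#' @param psms PSM table.
#' @return Filtered PSM table.
#' @export
apply_exclusions <- function(psms) {
  if (nrow(psms) == 0L) return(psms)
  keep <- psms$form != "none"
  plen <- nchar(psms$peptide)
  cterm_kr <- !is.na(psms$site) & psms$site == plen &
    psms$residue %in% c("K", "R")
  keep <- keep & !cterm_kr & !psms$site_ambiguous
  psms[keep, , drop = FALSE]
}

#' Cluster PSMs into unique mass classes (UMCs)
#'
#' Single-linkage clustering of PSM precursor features: two PSMs join one UMC
#' iff their (uncorrected) observed neutral masses agree within `mass_ppm`
#' AND their retention times differ by at most `rt_gap` seconds, chained
#' transitively.  Base- and nucleoside-form precursors of the same peptide
#' differ by the ribose mass and therefore never co-cluster at ppm scale.
#'
#' @param psms PSM table with `obs_neutral_mass` and `rt` columns.
#' @param mass_ppm Mass tolerance in ppm (default 10).
#' @param rt_gap Maximum retention-time gap in seconds (default 60).
#' @return PSM table with an added integer `umc_id` column.
#' @export
assign_umcs <- function(psms, mass_ppm = 10, rt_gap = 60) {
  n <- nrow(psms)
  psms$umc_id <- integer(n)
  if (n == 0L) return(psms)
  o <- order(psms$obs_neutral_mass)
  m <- psms$obs_neutral_mass[o]
  rt <- psms$rt[o]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)[-1]) {
    j <- i - 1L
    while (j >= 1L && (m[i] - m[j]) <= m[i] * mass_ppm * 1e-6) {
      if (is.na(rt[i]) || is.na(rt[j]) || abs(rt[i] - rt[j]) <= rt_gap) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      j <- j - 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  psms$umc_id[o] <- ids
  psms
}

#' Localization score of one UMC
#'
#' For each candidate localization (peptide, site) within the UMC, the score
#' is the sum of `-log10(significance)` of PSMs supporting that site divided
#' by the same sum over all PSMs in the UMC; scores over observed sites sum
#' to 1.  The argmax site is assigned (ties: smallest site index).
#'
#' @param members PSM table subset belonging to one UMC (modified PSMs).
#' @return List with `peptide`, `site`, `score`, or `NULL` when every member
#'   significance equals 1 (score undefined).
#' @export
localize <- function(members) {
  stopifnot(nrow(members) > 0L)
  w <- -log10(members$significance)
  total <- sum(w)
  if (total <= 0) return(NULL)
  key <- paste(members$peptide, members$site, sep = "@")
  scores <- tapply(w, key, sum) / total
  best <- names(scores)[order(-scores, names(scores))][1L]
  i <- match(best, key)
  list(peptide = members$peptide[i], site = members$site[i],
       score = unname(scores[best]))
}

#' Summarize UMC clusters into a UMC-level table
#'
#' One row per UMC: representative mass and RT span, the best-significance
#' member PSM (which donates the decoy status, form and peptide), the
#' assigned localization with its score, and the MostAbundant-style
#' label-free quant value (maximum member precursor intensity; missing
#' intensities count as 0 and are flagged).
#'
#' UMCs whose members all have significance 1 carry no localization
#' information and are dropped with a warning.
#'
#' @param psms PSM table with `umc_id` (see [assign_umcs()]).
#' @return UMC data.frame.
#' @export
summarize_umcs <- function(psms) {
  if (nrow(psms) == 0L || !"umc_id" %in% names(psms)) {
    stop("PSM table lacks umc_id; run assign_umcs() first")
  }
  sp <- split(psms, psms$umc_id)
  rows <- lapply(sp, function(d) {
    loc <- localize(d)
    if (is.null(loc)) return(NULL)
    b <- order(d$significance, d$is_decoy)[1L]
    quant_missing <- all(is.na(d$precursor_intensity))
    quant <- if (quant_missing) 0 else
      max(d$precursor_intensity, na.rm = TRUE)
    data.frame(
      umc_id = d$umc_id[1L],
      rep_mass = stats::median(d$obs_neutral_mass),
      rt_start = suppressWarnings(min(d$rt, na.rm = TRUE)),
      rt_end = suppressWarnings(max(d$rt, na.rm = TRUE)),
      n_psms = nrow(d),
      peptide = loc$peptide,
      site = loc$site,
      residue = d$residue[match(paste(loc$peptide, loc$site),
                                paste(d$peptide, d$site))],
      loc_score = loc$score,
      par_type = d$par_type[b],
      form = d$form[b],
      proteins = d$proteins[b],
      starts = d$starts[b],
      is_decoy = d$is_decoy[b],
      best_significance = d$significance[b],
      best_scan = d$scan[b],
      scans = paste(d$scan, collapse = ";"),
      quant = quant,
      quant_missing = quant_missing,
      stringsAsFactors = FALSE
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warning(dropped, " UMC(s) dropped: all member significances equal 1")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no UMC retained a defined localization")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' UMC-level target-decoy FDR
#'
#' UMCs are ranked by best member significance (targets before decoys on
#' ties).  The FDR estimate at rank r is `(#decoys <= r) / (#targets <= r)`;
#' q-values are the running minimum taken from the worst rank upward.
#' Accepted UMCs are targets with `q < alpha`.
#'
#' @param umcs UMC table from [summarize_umcs()].
#' @param alpha FDR level (default 0.01).
#' @return UMC table with added `q_value` and `accepted` columns.
#' @export
umc_fdr <- function(umcs, alpha = 0.01) {
  n <- nrow(umcs)
  if (n == 0L || !any(!umcs$is_decoy)) {
    umcs$q_value <- numeric(n)
    umcs$accepted <- logical(n)
    return(umcs[0, , drop = FALSE])
  }
  o <- order(umcs$best_significance, umcs$is_decoy)
  dec <- cumsum(umcs$is_decoy[o])
  tgt <- cumsum(!umcs$is_decoy[o])
  fdr <- ifelse(tgt == 0, Inf, dec / tgt)
  q <- rev(cummin(rev(fdr)))
  umcs$q_value[o] <- q
  umcs$accepted <- !umcs$is_decoy & umcs$q_value < alpha
  umcs
}

#' Label-free quantification value of one UMC
#'
#' MostAbundant surrogate: the maximum precursor intensity among member
#' PSMs; absent intensities are treated as 0.
#'
#' @param members PSM table subset of one UMC.
#' @return Intensity (flag attribute `"all_missing"` when no member carried
#'   an intensity).
#' @export
quantify <- function(members) {
  v <- members$precursor_intensity
  if (all(is.na(v))) {
    return(structure(0, all_missing = TRUE))
  }
  structure(max(v, na.rm = TRUE), all_missing = FALSE)
}

# Internal: parse ";"-collapsed "accession:start" provenance strings.
.parse_starts <- function(starts) {
  parts <- strsplit(starts, ";", fixed = TRUE)[[1]]
  acc <- sub(":[0-9]+$", "", parts)
  pos <- as.integer(sub("^.*:", "", parts))
  data.frame(accession = acc, start = pos, stringsAsFactors = FALSE)
}

#' Collapse accepted UMCs into RNA-binding-site records
#'
#' Maps each UMC's peptide-level site into protein coordinates (1-based) and
#' merges records per (protein, residue).  Peptides shared by several
#' proteins expand to every member of the protein group, with the group id
#' (sorted accessions) noted.  Site-level quant is the maximum over
#' supporting UMCs.  A peptide-level table is returned alongside.
#'
#' @param umcs UMC table from [umc_fdr()]; only accepted rows are used
#'   (unless the table has no `accepted` column, in which case all rows are).
#' @param database Protein database used for the search (target entries are
#'   used to validate residue letters).
#' @return List with data.frames `sites` and `peptides`.
#' @export
collapse_to_rbs <- function(umcs, database) {
  if ("accepted" %in% names(umcs)) {
    umcs <- umcs[umcs$accepted, , drop = FALSE]
  }
  site_rows <- list()
  for (r in seq_len(nrow(umcs))) {
    prov <- .parse_starts(umcs$starts[r])
    group <- paste(sort(prov$accession), collapse = ";")
    for (k in seq_len(nrow(prov))) {
      acc <- prov$accession[k]
      dbrow <- match(acc, database$accession)
      if (is.na(dbrow)) {
        stop("peptide '", umcs$peptide[r], "' maps to unknown protein ", acc)
      }
      pos <- prov$start[k] + umcs$site[r] - 1L
      letter <- substr(database$sequence[dbrow], pos, pos)
      if (!nzchar(letter) || letter != umcs$residue[r] ||
          substr(database$sequence[dbrow], prov$start[k],
                 prov$start[k] + nchar(umcs$peptide[r]) - 1L) !=
            umcs$peptide[r]) {
        stop("peptide '", umcs$peptide[r], "' not found at ", acc, ":",
             prov$start[k])
      }
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        accession = acc, position = pos, residue = letter,
        par_type = umcs$par_type[r], form = umcs$form[r],
        peptide = umcs$peptide[r], umc_id = umcs$umc_id[r],
        loc_score = umcs$loc_score[r], quant = umcs$quant[r],
        q_value = umcs$q_value[r], protein_group = group,
        stringsAsFactors = FALSE)
    }
  }
  if (length(site_rows) == 0L) {
    sites <- data.frame(accession = character(0), position = integer(0),
                        residue = character(0), par_type = character(0),
                        umc_ids = character(0), n_umcs = integer(0),
                        peptides = character(0), loc_score = numeric(0),
                        quant = numeric(0), q_value = numeric(0),
                        protein_group = character(0), stringsAsFactors = FALSE)
    peptides <- data.frame(peptide = character(0), site = integer(0),
                           form = character(0), par_type = character(0),
                           proteins = character(0), n_umcs = integer(0),
                           quant = numeric(0), q_value = numeric(0),
                           stringsAsFactors = FALSE)
    return(list(sites = sites, peptides = peptides))
  }
  flat <- do.call(rbind, site_rows)
  key <- paste(flat$accession, flat$position)
  sp <- split(flat, key)
  sites <- do.call(rbind, lapply(sp, function(d) data.frame(
    accession = d$accession[1L], position = d$position[1L],
    residue = d$residue[1L], par_type = d$par_type[1L],
    umc_ids = paste(unique(d$umc_id), collapse = ";"),
    n_umcs = length(unique(d$umc_id)),
    peptides = paste(unique(d$peptide), collapse = ";"),
    loc_score = max(d$loc_score), quant = max(d$quant),
    q_value = min(d$q_value), protein_group = d$protein_group[1L],
    stringsAsFactors = FALSE)))
  sites <- sites[order(sites$accession, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  pkey <- paste(umcs$peptide, umcs$site, umcs$form)
  pp <- split(umcs, pkey)
  peptides <- do.call(rbind, lapply(pp, function(d) data.frame(
    peptide = d$peptide[1L], site = d$site[1L], form = d$form[1L],
    par_type = d$par_type[1L], proteins = d$proteins[1L],
    n_umcs = nrow(d), quant = max(d$quant), q_value = min(d$q_value),
    stringsAsFactors = FALSE)))
  rownames(peptides) <- NULL
  list(sites = sites, peptides = peptides)
}

#' Full pRBS-ID analysis of a spectra set
#'
#' Convenience wrapper chaining target-decoy construction (when the database
#' has no decoys yet), the database search, recalibration filtering,
#' ambiguity exclusions, UMC clustering, UMC-level FDR and the collapse to
#' RNA-binding-site records.
#'
#' @param spectra List of [spectrum()] objects (e.g. from [read_mgf()]).
#' @param database Protein database (targets only, or targets + decoys).
#' @param params [search_params()] object.
#' @param fdr UMC-level FDR cutoff (default 0.01).
#' @param ppm_window Recalibration window in ppm (default 5).
#' @param mass_ppm,rt_gap UMC clustering parameters (defaults 10 ppm, 60 s).
#' @return List with `psms`, `umcs`, `sites`, `peptides` and the search
#'   `database` (including decoys).
#' @export
prbs_id <- function(spectra, database, params = search_params(), fdr = 0.01,
                    ppm_window = 5, mass_ppm = 10, rt_gap = 60) {
  if (!any(database$is_decoy)) {
    database <- build_target_decoy(database)
  }
  psms <- run_search(spectra, database, params)
  filtered <- recalibration_filter(psms, ppm_window)
  filtered <- apply_exclusions(filtered)
  if (nrow(filtered) == 0L) {
    return(list(psms = psms, umcs = NULL,
                sites = collapse_to_rbs(
                  cbind(summarize_umcs_empty(), accepted = logical(0)),
                  database)$sites,
                peptides = NULL, database = database))
  }
  clustered <- assign_umcs(filtered, mass_ppm, rt_gap)
  umcs <- umc_fdr(summarize_umcs(clustered), fdr)
  rbs <- collapse_to_rbs(umcs, database)
  list(psms = psms, umcs = umcs, sites = rbs$sites, peptides = rbs$peptides,
       database = database)
}

# Internal: zero-row UMC table (column set of summarize_umcs()).
summarize_umcs_empty <- function() {
  data.frame(umc_id = integer(0), rep_mass = numeric(0),
             rt_start = numeric(0), rt_end = numeric(0), n_psms = integer(0),
             peptide = character(0), site = integer(0), residue = character(0),
             loc_score = numeric(0), par_type = character(0),
             form = character(0), proteins = character(0),
             starts = character(0), is_decoy = logical(0),
             best_significance = numeric(0), best_scan = character(0),
             scans = character(0), quant = numeric(0),
             quant_missing = logical(0), q_value = numeric(0),
             stringsAsFactors = FALSE)
}
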