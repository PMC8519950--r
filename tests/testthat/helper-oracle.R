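# Independent brute-force oracles used by the equivalence tests.

# Exhaustive enumeration of every (peptide, site, form, corrected)
# combination via the public scoring surface, with the documented
# deterministic tie-break.  Stays independent of the indexed search path.
enumerate_best <- function(sp, peps, params) {
  if (is.na(sp$charge) || sp$charge < params$charge_range[1] ||
      sp$charge > params$charge_range[2]) {
    return(NULL)
  }
  M <- (sp$premz - proton_mass()) * sp$charge
  versions <- list(list(corrected = FALSE, M = M))
  if (params$mode == "prbs") {
    versions <- c(versions,
                  list(list(corrected = TRUE, M = M - ribose_mass())))
  }
  ppm_ok <- function(obs, theo) abs(obs - theo) / theo * 1e6 <= params$prec_ppm
  rows <- list()
  add <- function(pep, site, form, corrected, sig, k, dec) {
    rows[[length(rows) + 1L]] <<- data.frame(
      peptide = pep, site = site, form = form, corrected = corrected,
      sig = sig, k = k, dec = dec, stringsAsFactors = FALSE)
  }
  for (v in versions) {
    for (i in seq_len(nrow(peps))) {
      pep <- peps$sequence[i]
      res <- strsplit(pep, "", fixed = TRUE)[[1]]
      if (!v$corrected && ppm_ok(v$M, peptide_neutral_mass(pep))) {
        sc <- score_match(sp, pep, frag_tol = params$frag_tol)
        add(pep, NA_integer_, "none", v$corrected, sc$significance,
            sc$n_matched, peps$is_decoy[i])
      }
      search_forms <- if (params$mode == "prbs") "base" else
        c("base", "nucleoside")
      for (fm in search_forms) {
        for (s in seq_along(res)) {
          mt <- peptide_neutral_mass(pep, s, params$par_type, fm)
          if (!ppm_ok(v$M, mt)) next
          sc <- score_match(sp, pep, s, params$par_type, fm,
                            params$frag_tol, mode = params$mode)
          form_out <- if (params$mode == "prbs") {
            if (v$corrected) "nucleoside" else "base"
          } else fm
          add(pep, s, form_out, v$corrected, sc$significance, sc$n_matched,
              peps$is_decoy[i])
        }
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  cand <- do.call(rbind, rows)
  cand <- cand[cand$k > 0L | cand$form == "none", , drop = FALSE]
  if (nrow(cand) == 0L || min(cand$sig) >= 1) return(NULL)
  cand[order(cand$sig, cand$dec, cand$form != "none", cand$peptide,
             cand$site, cand$corrected)[1L], , drop = FALSE]
}

# Brute-force target-decoy q-values (distinct scores): for each observation,
# scan every possible score cutoff at or beyond it and take the minimum
# decoy/target ratio achievable while still including it.
brute_force_qvalues <- function(sig, is_decoy) {
  stopifnot(!anyDuplicated(sig))
  vapply(sig, function(s) {
    fdrs <- vapply(sig[sig >= s], function(thr) {
      inc <- sig <= thr
      t <- sum(!is_decoy & inc)
      if (t == 0) Inf else sum(is_decoy & inc) / t
    }, numeric(1))
    min(fdrs)
  }, numeric(1))
}
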