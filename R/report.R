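# Dataset-level summaries: normalized amino-acid frequencies of identified
# sites, overlap between site tables, and replicate quantification
# correlation.

#' Normalized amino-acid frequencies of RNA-binding sites
#'
#' For each amino acid a, the raw frequency is (number of sites on residue
#' type a) divided by (occurrences of a across the full sequences of the
#' proteins carrying at least one site); raw frequencies are then normalized
#' to sum to 1.  Residue types absent from those proteins are omitted rather
#' than zero-divided.
#'
#' @param sites Site table with `accession` and `residue` columns.
#' @param database Protein database containing every site-bearing protein.
#' @return data.frame (`residue`, `frequency`) sorted by decreasing
#'   frequency; frequencies sum to 1.
#' @export
aa_frequency <- function(sites, database) {
  miss <- setdiff(unique(sites$accession), database$accession)
  if (length(miss)) {
    stop("site protein absent from database: ", paste(miss, collapse = ", "))
  }
  prot <- unique(sites$accession)
  seqs <- database$sequence[match(prot, database$accession)]
  aa_counts <- table(strsplit(paste(seqs, collapse = ""), "")[[1]])
  site_counts <- table(sites$residue)
  common <- names(site_counts)
  denom <- as.numeric(aa_counts[common])
  if (any(is.na(denom) | denom == 0)) {
    stop("site residue type absent from site-bearing proteins")
  }
  raw <- as.numeric(site_counts) / denom
  freq <- raw / sum(raw)
  out <- data.frame(residue = common, frequency = freq,
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$residue), , drop = FALSE]
}

#' Overlap counts between site tables
#'
#' Sites are keyed by (protein accession, position); protein-group level
#' counts key on the accession alone.
#'
#' @param ... Two or more site tables (named arguments name the sets).
#' @return List with `site` and `protein` components, each containing
#'   per-set sizes, per-set exclusive counts, the pairwise intersection
#'   matrix and the count common to all sets.
#' @export
dataset_overlap <- function(...) {
  tabs <- list(...)
  if (length(tabs) < 2L) stop("need at least two site tables")
  if (is.null(names(tabs)) || any(!nzchar(names(tabs)))) {
    names(tabs) <- paste0("set", seq_along(tabs))
  }
  level_counts <- function(keysets) {
    n <- length(keysets)
    pair <- matrix(0L, n, n, dimnames = list(names(keysets), names(keysets)))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        pair[i, j] <- length(intersect(keysets[[i]], keysets[[j]]))
      }
    }
    exclusive <- vapply(seq_len(n), function(i) {
      length(setdiff(keysets[[i]], unlist(keysets[-i])))
    }, integer(1))
    list(sizes = lengths(keysets),
         exclusive = stats::setNames(exclusive, names(keysets)),
         pairwise = pair,
         common = length(Reduce(intersect, keysets)))
  }
  site_keys <- lapply(tabs, function(t) unique(paste(t$accession, t$position)))
  prot_keys <- lapply(tabs, function(t) unique(t$accession))
  list(site = level_counts(site_keys), protein = level_counts(prot_keys))
}

#' Replicate label-free quantification correlation
#'
#' Spearman rank correlation of log10 intensities over peptide-site entries
#' co-identified in two runs; co-identification is keyed by (peptide, site,
#' form).  Ties receive average ranks (the `stats::cor` convention).
#'
#' @param pep_a,pep_b Peptide-level tables from [collapse_to_rbs()].
#' @param min_shared Minimum number of co-identified entries (default 3);
#'   below this the correlation is undefined and `NA` is returned.
#' @return List with `spearman`, `n_shared`.
#' @export
quant_correlation <- function(pep_a, pep_b, min_shared = 3L) {
  key_a <- paste(pep_a$peptide, pep_a$site, pep_a$form)
  key_b <- paste(pep_b$peptide, pep_b$site, pep_b$form)
  shared <- intersect(key_a, key_b)
  qa <- pep_a$quant[match(shared, key_a)]
  qb <- pep_b$quant[match(shared, key_b)]
  ok <- qa > 0 & qb > 0
  if (sum(ok) < min_shared) {
    return(list(spearman = NA_real_, n_shared = sum(ok)))
  }
  list(spearman = stats::cor(log10(qa[ok]), log10(qb[ok]),
                             method = "spearman"),
       n_shared = sum(ok))
}
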