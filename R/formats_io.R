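# FASTA / MGF readers and writers, target-decoy database construction, and
# TSV results output.  FASTA goes through seqinr; MGF (Matrix-Science
# dialect) is parsed here.

#' Read a protein FASTA file
#'
#' UniProt-style headers are tolerated: the accession is the first
#' whitespace-delimited token of the header, the rest is kept as description.
#' Sequences are uppercased and trailing/leading `*` stop characters stripped.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `accession`, `description`, `sequence`,
#'   `is_decoy` (all `FALSE`; see [build_target_decoy()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA header at line ", nonblank[1], " of ", path)
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             whole.header = TRUE)
  headers <- vapply(recs, function(r) attr(r, "Annot"), character(1))
  headers <- sub("^>", "", headers)
  accession <- sub("[[:space:]].*$", "", headers)
  description <- sub("^[^[:space:]]+[[:space:]]*", "", headers)
  sequence <- toupper(vapply(recs, as.character, character(1)))
  sequence <- gsub("^\\*+|\\*+$", "", sequence)
  empty <- !nzchar(sequence)
  if (any(empty)) {
    stop("FASTA record with empty sequence: ", accession[which(empty)[1]])
  }
  data.frame(accession = unname(accession), description = unname(description),
             sequence = unname(sequence), is_decoy = FALSE,
             stringsAsFactors = FALSE)
}

#' Write a protein database to FASTA
#'
#' @param db data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @export
write_fasta <- function(db, path) {
  nm <- ifelse(nzchar(db$description),
               paste(db$accession, db$description), db$accession)
  seqinr::write.fasta(as.list(db$sequence), names = nm, file.out = path,
                      nbchar = 60)
  invisible(path)
}

#' Append reversed-sequence decoys to a target database
#'
#' For every target protein one decoy is added whose sequence is the full
#' reversal of the target and whose accession carries the reserved decoy
#' prefix, mirroring the default decoy construction of standard search
#' engines.  Reversal is a permutation, so the amino-acid composition of each
#' entry is preserved.
#'
#' @param targets Target database data.frame.
#' @param prefix Reserved decoy accession prefix (default `"XXX_"`).
#' @return Combined data.frame of `2 * nrow(targets)` entries.
#' @export
build_target_decoy <- function(targets, prefix = "XXX_") {
  clash <- startsWith(targets$accession, prefix)
  if (any(clash)) {
    stop("target accession already carries the decoy prefix: ",
         targets$accession[which(clash)[1]])
  }
  rev_seq <- vapply(strsplit(targets$sequence, "", fixed = TRUE),
                    function(x) paste(rev(x), collapse = ""), character(1))
  decoys <- data.frame(accession = paste0(prefix, targets$accession),
                       description = targets$description,
                       sequence = rev_seq, is_decoy = TRUE,
                       stringsAsFactors = FALSE)
  targets$is_decoy <- FALSE
  rbind(targets, decoys)
}

#' Construct a single MS2 spectrum object
#'
#' @param scan Scan identifier (MGF TITLE).
#' @param premz Precursor m/z.
#' @param charge Precursor charge (integer >= 1).
#' @param rt Retention time in seconds (NA if unknown).
#' @param prec_intensity Precursor intensity (NA if absent).
#' @param mz,intensity Centroided peak list; re-sorted by m/z if needed.
#' @param corrected Whether the precursor has had the ribose mass subtracted.
#' @return Object of class `"prbs_spectrum"`.
#' @export
spectrum <- function(scan, premz, charge, rt = NA_real_,
                     prec_intensity = NA_real_, mz = numeric(0),
                     intensity = numeric(0), corrected = FALSE) {
  stopifnot(length(mz) == length(intensity))
  if (!is.na(charge) && charge < 1) stop("charge must be >= 1")
  if (any(intensity < 0)) stop("negative peak intensity")
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  structure(list(scan = as.character(scan), premz = as.numeric(premz),
                 charge = as.integer(charge), rt = as.numeric(rt),
                 prec_intensity = as.numeric(prec_intensity),
                 mz = as.numeric(mz), intensity = as.numeric(intensity),
                 corrected = isTRUE(corrected)),
            class = "prbs_spectrum")
}

#' @export
print.prbs_spectrum <- function(x, ...) {
  cat(sprintf("<MS2 scan '%s': m/z %.4f, %d+, rt %.1f s, %d peaks%s>\n",
              x$scan, x$premz, x$charge, x$rt, length(x$mz),
              if (x$corrected) ", ribose-corrected" else ""))
  invisible(x)
}

#' Read centroided MS2 spectra from an MGF file
#'
#' Honors `TITLE`, `PEPMASS` (m/z and optional precursor intensity),
#' `CHARGE` (`"2+"` style) and `RTINSECONDS` inside `BEGIN IONS`/`END IONS`
#' blocks.  Peaks are re-sorted by m/z if needed.
#'
#' @param path Path to the MGF file.
#' @param rt_from_index If TRUE, blocks lacking `RTINSECONDS` get their
#'   1-based block index as a surrogate retention time (useful for MGFs
#'   exported without RT); otherwise the RT is NA.
#' @return List of [spectrum()] objects, in file order.
#' @export
read_mgf <- function(path, rt_from_index = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("unbalanced BEGIN IONS/END IONS blocks in ", path)
  }
  spectra <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    block <- block[nzchar(block)]
    is_kv <- grepl("^[A-Z][A-Z0-9]*=", block)
    keys <- sub("=.*$", "", block[is_kv])
    vals <- sub("^[A-Z][A-Z0-9]*=", "", block[is_kv])
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      sprintf("index=%d", i)
    if (!"PEPMASS" %in% keys) {
      stop("MGF block without PEPMASS: '", title, "'")
    }
    pm <- strsplit(trimws(vals[match("PEPMASS", keys)]), "[ \t]+")[[1]]
    premz <- as.numeric(pm[1])
    prec_int <- if (length(pm) > 1L) as.numeric(pm[2]) else NA_real_
    charge <- NA_integer_
    if ("CHARGE" %in% keys) {
      charge <- as.integer(gsub("[+ ]", "", vals[match("CHARGE", keys)]))
    }
    rt <- if ("RTINSECONDS" %in% keys) {
      as.numeric(vals[match("RTINSECONDS", keys)])
    } else if (rt_from_index) as.numeric(i) else NA_real_
    peak_lines <- block[!is_kv]
    if (length(peak_lines)) {
      pk <- scan(text = paste(peak_lines, collapse = "\n"), quiet = TRUE)
      pk <- matrix(pk, ncol = 2, byrow = TRUE)
    } else {
      pk <- matrix(numeric(0), ncol = 2)
    }
    spectra[[i]] <- spectrum(scan = title, premz = premz, charge = charge,
                             rt = rt, prec_intensity = prec_int,
                             mz = pk[, 1], intensity = pk[, 2])
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    lines <- c("BEGIN IONS", paste0("TITLE=", sp$scan))
    if (!is.na(sp$rt)) lines <- c(lines, sprintf("RTINSECONDS=%.3f", sp$rt))
    pep <- if (is.na(sp$prec_intensity)) sprintf("PEPMASS=%.6f", sp$premz) else
      sprintf("PEPMASS=%.6f %.6g", sp$premz, sp$prec_intensity)
    lines <- c(lines, pep)
    if (!is.na(sp$charge)) lines <- c(lines, sprintf("CHARGE=%d+", sp$charge))
    if (length(sp$mz)) {
      lines <- c(lines, sprintf("%.5f %.6g", sp$mz, sp$intensity))
    }
    lines <- c(lines, "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}

# Versioned TSV results IO ---------------------------------------------------

.RESULTS_VERSION <- "parlock-results\tv1"

#' Write a results table as tab-separated text
#'
#' The first line is a `#`-prefixed format/version stamp; [read_results()]
#' skips it.
#'
#' @param tab data.frame to write.
#' @param path Output path.
#' @export
write_results <- function(tab, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", .RESULTS_VERSION), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
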