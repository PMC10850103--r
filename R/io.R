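# File-format adapters. Tabular files are TSV: tab-separated, header row,
# UTF-8, '.' decimal. All writers round-trip losslessly through the readers.

#' Read substrates from a FASTA file
#'
#' @param path FASTA file path.
#' @return List of [substrate()] objects.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (any(duplicated(names(set)))) stop("duplicate FASTA identifiers in ", path)
  lapply(seq_along(set), function(i) {
    nm <- names(set)[i]
    id <- sub("\\s.*$", "", nm)
    desc <- sub("^\\S+\\s*", "", nm)
    substrate(id, as.character(set[[i]]), desc)
  })
}

#' Write substrates to a FASTA file
#'
#' @param substrates List of [substrate()] objects.
#' @param path Output path.
#' @export
write_fasta <- function(substrates, path) {
  seqs <- Biostrings::AAStringSet(vapply(substrates, `[[`, "", "sequence"))
  names(seqs) <- vapply(substrates, function(s) {
    if (nzchar(s$description)) paste(s$id, s$description) else s$id
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an MGF peak-list file
#'
#' Minimal Mascot Generic Format reader covering BEGIN/END IONS blocks with
#' TITLE, PEPMASS, CHARGE and RTINSECONDS headers. Unsorted peak lists are
#' sorted with a warning (via the [spectrum()] constructor).
#'
#' @param path MGF file path.
#' @return Named list of [spectrum()] objects keyed by spectrum id.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) stop("malformed MGF: unbalanced blocks in ", path)
  out <- list()
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[[`, "", 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    peaks <- block[!hdr & nzchar(block)]
    pm <- do.call(rbind, strsplit(trimws(peaks), "[ \t]+"))
    if (is.null(pm) || ncol(pm) < 2L)
      stop("malformed MGF block ", b, " in ", path, ": no peaks")
    id <- getv("TITLE")
    if (is.na(id)) id <- paste0("spectrum_", b)
    charge <- getv("CHARGE")
    charge <- if (is.na(charge)) 2L else as.integer(gsub("[^0-9]", "", charge))
    rt <- getv("RTINSECONDS")
    rt <- if (is.na(rt)) NA_real_ else as.numeric(rt) / 60
    pepmass <- as.numeric(strsplit(getv("PEPMASS"), "[ \t]+")[[1]][1])
    out[[id]] <- spectrum(id, pepmass, charge, rt,
                          mz = as.numeric(pm[, 1]),
                          intensity = as.numeric(pm[, 2]))
  }
  if (any(duplicated(names(out)))) stop("duplicate spectrum ids in ", path)
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      paste0("PEPMASS=", format(sp$precursor_mz, digits = 12)),
      paste0("CHARGE=", sp$charge, "+"),
      paste0("RTINSECONDS=", format(sp$retention_time * 60, digits = 10)),
      paste(format(sp$mz, digits = 12, trim = TRUE),
            format(sp$intensity, digits = 10, trim = TRUE)),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read a candidate PSM table
#'
#' Expected columns: `spectrum_id`, `peptide`, `base_score`, `is_decoy`,
#' `origin_flag`, `precursor_mz`, `charge`, `retention_time`; optional
#' `mods`.
#'
#' @param path TSV path.
#' @return Data.frame of PSM records.
#' @export
read_psm_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "peptide", "base_score", "is_decoy", "origin_flag",
            "precursor_mz", "charge", "retention_time")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("PSM table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  df$is_decoy <- as.logical(df$is_decoy)
  if (!"mods" %in% names(df)) df$mods <- ""
  df$mods[is.na(df$mods)] <- ""
  df
}

#' Write a PSM or product table as TSV
#'
#' @param df Data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinetics table
#'
#' Expected columns: `peptide`, `time_h`, `bio_rep`, `tech_rep`,
#' `intensity`. Negative intensities or duplicate
#' (peptide, time, bio, tech) keys are rejected.
#'
#' @param path TSV path.
#' @return Data.frame kinetics table.
#' @export
read_kinetics_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "time_h", "bio_rep", "tech_rep", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("kinetics table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$intensity < 0, na.rm = TRUE))
    stop("kinetics table ", path, " contains negative intensities")
  key <- paste(df$peptide, df$time_h, df$bio_rep, df$tech_rep)
  if (any(duplicated(key)))
    stop("kinetics table ", path,
         " has duplicate (peptide, time, bio, tech) entries")
  df
}
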