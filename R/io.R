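# Package-level I/O: FASTA in/out (via Biostrings), BED6/bedGraph/TSV
# export with the package's 0-based half-open convention, and provenance
# headers on tabular output.

.provenanceHeader <- function() {
  sprintf("# hoxcrm v%s", as.character(utils::packageVersion("hoxcrm")))
}

#' Read a FASTA file
#'
#' Reads (multi-record) FASTA via Biostrings; sequences are uppercased
#' (lowercase input is accepted, with a notice) and names preserved.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("format error reading FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("format error: no FASTA records in ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  if (any(grepl("[acgt]", raw[!startsWith(raw, ">")])))
    message("lowercase bases in ", path, " were uppercased")
  setNames(toupper(as.character(set)), names(set))
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector of DNA strings.
#' @param path Output path.
#' @export
writeFasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write binding sites as BED6
#'
#' One line per site: chrom (= sequence name), 0-based half-open start/end,
#' name (`model[:class]`), score (`round(1000 * affinity)`, capped at 1000),
#' strand. A track header line is always written, so an empty site list
#' yields a header-only file. Ordering follows the input (which
#' [scanSites()] returns deterministically ranked).
#'
#' @param sites Site data.frame from [scanSites()].
#' @param path Output path.
#' @param seqname Sequence name for the chrom column.
#' @param trackName Track header name.
#' @export
writeBed <- function(sites, path, seqname = "seq", trackName = "hoxcrm_sites") {
  stopifnot(is.data.frame(sites))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf('track name="%s"', trackName), con)
  if (nrow(sites) > 0L) {
    nm <- ifelse(is.na(sites$class_label) | sites$class_label == "none",
                 sites$model, paste0(sites$model, ":", sites$class_label))
    df <- data.frame(chrom = seqname, start = sites$start, end = sites$end,
                     name = nm,
                     score = pmin(1000L, as.integer(round(1000 * sites$affinity))),
                     strand = sites$strand)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Write an affinity profile as bedGraph
#'
#' Each window start becomes a 1-bp interval carrying the profile value.
#'
#' @param profile data.frame from [affinityProfile()].
#' @param path Output path.
#' @param seqname Sequence name.
#' @param trackName Track header name.
#' @export
writeBedGraph <- function(profile, path, seqname = "seq",
                          trackName = "hoxcrm_profile") {
  stopifnot(is.data.frame(profile),
            all(c("start", "affinity") %in% names(profile)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', trackName), con)
  if (nrow(profile) > 0L)
    write.table(data.frame(seqname, profile$start, profile$start + 1L,
                           profile$affinity),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Write a table as TSV with a provenance header
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param header Write the `# hoxcrm v...` provenance comment line?
#' @export
writeTsv <- function(df, path, header = TRUE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (header) writeLines(.provenanceHeader(), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
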