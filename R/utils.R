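# Internal helpers shared across modules. Package-wide conventions:
# DNA is uppercase ACGT, coordinates are 0-based half-open, energies are
# dimensionless (RT = 1).

.DNA_BASES <- c("A", "C", "G", "T")

.checkDna <- function(x, arg = "sequence", allowOther = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single character string of DNA", arg),
         call. = FALSE)
  x <- toupper(x)
  if (!allowOther && grepl("[^ACGT]", x))
    stop(sprintf("'%s' contains characters outside the A/C/G/T alphabet", arg),
         call. = FALSE)
  x
}

# Reverse complement for plain character vectors; non-ACGT characters are
# tolerated only when the caller has already flagged them.
.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

.complementBase <- function(b) chartr("ACGT", "TGCA", b)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL means "use current stream".
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# All (possibly overlapping) occurrences of fixed k-mers on both strands of
# `sequence`, reported in plus-strand 0-based half-open coordinates.
# `kmers` may be named (e.g. by class label); names are carried through.
.findKmers <- function(sequence, kmers) {
  n <- nchar(sequence)
  out <- list()
  labs <- names(kmers)
  if (is.null(labs)) labs <- kmers
  for (i in seq_along(kmers)) {
    k <- kmers[[i]]
    w <- nchar(k)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") k else .revcomp(k)
      m <- gregexpr(paste0("(?=", pat, ")"), sequence, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      start0 <- as.integer(m) - 1L
      out[[length(out) + 1L]] <- data.frame(
        label = labs[[i]], kmer = k, start = start0, end = start0 + w,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(label = character(0), kmer = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand, res$label), , drop = FALSE]
  rownames(res) <- NULL
  res
}
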