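# Both-strand scanning of sequences with energy models: ranked site calls,
# per-position affinity profiles, exact-core localisation, and overlap
# relationships between sites.

.emptySites <- function() {
  data.frame(model = character(0), start = integer(0), end = integer(0),
             strand = character(0), window = character(0),
             affinity = numeric(0), type = character(0),
             class_label = character(0), core_offset = integer(0),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for binding sites on both strands
#'
#' Slides the model over every window of both strands and reports all
#' windows with relative affinity at or above `threshold`, sorted by
#' descending affinity, then ascending start, then strand (+ before -).
#' Coordinates are plus-strand 0-based half-open; a minus-strand site's
#' `window` is the reverse complement of the plus-strand substring, i.e. the
#' string that was actually scored.
#'
#' For dimer models built around a designated core, `class_label` names the
#' Hox-Exd class whose core exactly matches the scored window's core
#' positions (near-cores are reported with label `"none"` but full graded
#' affinity, because exact core identity decides the class while flanks
#' grade the affinity). Monomer-model sites carry `type = "monomer"`.
#'
#' @param sequence DNA string (non-ACGT characters are tolerated; windows
#'   containing them score 0 and are excluded, with a logged notice).
#' @param model An [EnergyModel-class].
#' @param threshold Minimum relative affinity, >= 0. The default 0.05
#'   retains weak sites, which matter for Hox regulation. Thresholds above
#'   the attainable maximum simply return an empty site list.
#' @param registry Registry used for core classification.
#' @return A data.frame of binding sites: `model`, `start`, `end` (0-based
#'   half-open), `strand`, `window`, `affinity`, `type`
#'   (`"dimer"`/`"monomer"`), `class_label`, `core_offset`.
#' @seealso [affinityProfile()], [findSiteOverlaps()], [siteGRanges()]
#' @export
#' @examples
#' m <- modelFromCore("TGATTAAT", siteArchitecture("TGATTAAT", 0L, 0L))
#' scanSites(paste0("CCCC", "TGATTAAT", "CCCC"), m, threshold = 0.5)
scanSites <- function(sequence, model, threshold = 0.05,
                      registry = hoxRegistry()) {
  stopifnot(is(model, "EnergyModel"))
  sequence <- .checkDna(sequence, "sequence", allowOther = TRUE)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("'threshold' must be a single number >= 0", call. = FALSE)
  L <- model@footprint
  n <- nchar(sequence)
  if (n < L) {
    message("sequence shorter than the model footprint (", n, " < ", L,
            "): no windows to scan")
    return(.emptySites())
  }
  plus <- .windowScoresRaw(sequence, model) / model@normMax
  minus <- rev(.windowScoresRaw(.revcomp(sequence), model)) / model@normMax
  nskip <- sum(plus == 0) + sum(minus == 0)
  if (nskip > 0L)
    message(nskip, " window(s) containing non-ACGT bases were skipped")

  starts <- 0:(n - L)
  rows <- list()
  for (strand in c("+", "-")) {
    aff <- if (strand == "+") plus else minus
    keep <- which(aff >= threshold & aff > 0)
    if (length(keep) == 0L) next
    s0 <- starts[keep]
    win <- substring(sequence, s0 + 1L, s0 + L)
    if (strand == "-") win <- .revcomp(win)
    rows[[strand]] <- data.frame(
      model = model@name, start = s0, end = s0 + L, strand = strand,
      window = win, affinity = aff[keep], type = model@mode,
      class_label = NA_character_, core_offset = model@coreOffset,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(.emptySites())
  sites <- do.call(rbind, rows)
  if (model@mode == "dimer" && !is.na(model@coreOffset) &&
      identical(model@coreWidth, 8L)) {
    corestr <- substring(sites$window, model@coreOffset + 1L,
                         model@coreOffset + 8L)
    sites$class_label <- vapply(corestr, function(cs) {
      if (grepl("[^ACGT]", cs)) "none" else classifyWindow(cs, registry)
    }, character(1L), USE.NAMES = FALSE)
  }
  ord <- order(-sites$affinity, sites$start, match(sites$strand, c("+", "-")))
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Per-position affinity profile
#'
#' For each window start, the maximum of the plus- and minus-strand relative
#' affinities; the in-silico affinity track plotted along an enhancer.
#'
#' @inheritParams scanSites
#' @return data.frame with `start` (0-based window start) and `affinity`.
#'   Exportable with [writeBedGraph()].
#' @export
affinityProfile <- function(sequence, model) {
  stopifnot(is(model, "EnergyModel"))
  sequence <- .checkDna(sequence, "sequence", allowOther = TRUE)
  L <- model@footprint
  n <- nchar(sequence)
  if (n < L) {
    message("sequence shorter than the model footprint (", n, " < ", L,
            "): empty profile")
    return(data.frame(start = integer(0), affinity = numeric(0)))
  }
  plus <- .windowScoresRaw(sequence, model) / model@normMax
  minus <- rev(.windowScoresRaw(.revcomp(sequence), model)) / model@normMax
  data.frame(start = 0:(n - L), affinity = pmax(plus, minus))
}

#' Locate exact Hox-Exd class cores (and optionally monomer cores)
#'
#' Reports every exact occurrence of the registered 8-bp class cores on
#' either strand, in plus-strand 0-based half-open coordinates. With
#' `monomers = TRUE` the generic TAAT and Abd-B TTAT/TTAG monomer cores are
#' included (labelled `"monomer"`/`"monomer_abdb"`).
#'
#' @param sequence DNA string.
#' @param registry Registry supplying the cores.
#' @param monomers Also report monomer cores?
#' @return data.frame: `label`, `kmer`, `start`, `end`, `strand`.
#' @export
scanCores <- function(sequence, registry = hoxRegistry(), monomers = FALSE) {
  sequence <- .checkDna(sequence, "sequence", allowOther = TRUE)
  kmers <- as.list(classCores(registry))
  if (monomers) {
    mc <- monomerCores()
    kmers <- c(kmers, setNames(as.list(c(mc$generic, mc$abdb)),
                               c("monomer", rep("monomer_abdb",
                                                length(mc$abdb)))))
  }
  .findKmers(sequence, kmers)
}

#' Overlap relationships between two site lists
#'
#' All cross pairs of sites whose [start, end) intervals on the same
#' sequence intersect in at least `minSharedBp` bases - the configuration of
#' a main site and an overlapping site occupying shared sequence. Symmetric
#' in the a/b swap up to pair order.
#'
#' @param sitesA,sitesB Site data.frames from [scanSites()] (or any frame
#'   with 0-based half-open `start`/`end` columns) referring to the same
#'   sequence.
#' @param minSharedBp Minimum shared bases, >= 1.
#' @return data.frame with one row per overlapping pair: indices `a` and
#'   `b` into the inputs, the pair's coordinates, and `shared_start`,
#'   `shared_end`, `shared_bp`.
#' @export
findSiteOverlaps <- function(sitesA, sitesB, minSharedBp = 1L) {
  stopifnot(is.data.frame(sitesA), is.data.frame(sitesB), minSharedBp >= 1L)
  empty <- data.frame(a = integer(0), b = integer(0),
                      a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      shared_start = integer(0), shared_end = integer(0),
                      shared_bp = integer(0))
  if (nrow(sitesA) == 0L || nrow(sitesB) == 0L) return(empty)
  ra <- IRanges::IRanges(start = sitesA$start + 1L, end = sitesA$end)
  rb <- IRanges::IRanges(start = sitesB$start + 1L, end = sitesB$end)
  hits <- IRanges::findOverlaps(ra, rb, minoverlap = as.integer(minSharedBp))
  if (length(hits) == 0L) return(empty)
  qa <- S4Vectors::queryHits(hits)
  qb <- S4Vectors::subjectHits(hits)
  inter <- IRanges::pintersect(ra[qa], rb[qb])
  out <- data.frame(
    a = qa, b = qb,
    a_start = sitesA$start[qa], a_end = sitesA$end[qa],
    b_start = sitesB$start[qb], b_end = sitesB$end[qb],
    shared_start = IRanges::start(inter) - 1L,
    shared_end = IRanges::end(inter),
    shared_bp = IRanges::width(inter))
  out[order(out$a, out$b), , drop = FALSE]
}

#' Convert a site table to GRanges
#'
#' @param sites Site data.frame from [scanSites()].
#' @param seqname Sequence (chromosome) name for the ranges.
#' @return A [GenomicRanges::GRanges] (1-based, closed, per Bioconductor
#'   convention) with `affinity`, `model` and `class_label` metadata
#'   columns.
#' @export
siteGRanges <- function(sites, seqname = "seq") {
  stopifnot(is.data.frame(sites))
  GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = if (nrow(sites)) sites$strand else character(0),
    affinity = sites$affinity, model = sites$model,
    class_label = sites$class_label)
}
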