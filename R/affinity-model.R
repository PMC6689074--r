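# Mononucleotide free-energy binding models (monomer and Hox-Exd dimer
# modes) and their relative-affinity normalization.

#' EnergyModel: a position-specific free-energy binding model
#'
#' An `EnergyModel` stores per-position, per-base free-energy penalties (in
#' dimensionless RT units) over a binding footprint of `footprint` bases.
#' A window's raw relative affinity is `exp(-sum of penalties) / normMax`.
#' Models are *anchored*: at every position the minimum penalty over the
#' four bases is exactly 0, so the optimal window has total penalty 0 and
#' raw relative affinity 1 (with `normMax = 1`).
#'
#' The normalization constant `normMax` corresponds to a different and
#' unknown dissociation constant for each factor; affinities are therefore
#' comparable only within one model, never across models. No function in
#' this package arithmetically combines affinities from different models;
#' cross-model results are only ever reported side by side.
#'
#' @slot name Model name.
#' @slot factor Name of the transcription factor the model describes.
#' @slot mode `"monomer"` or `"dimer"`.
#' @slot footprint Window length L (bases). Dimer models default to the
#'   12-bp Hox-Exd architecture, monomer models to 6 bp.
#' @slot penalties L x 4 numeric matrix (columns A, C, G, T) of non-negative
#'   free-energy increments; each row minimum is exactly 0.
#' @slot normMax Positive normalization scalar (default 1).
#' @slot coreOffset 0-based offset of the classifiable core within the
#'   window, or `NA` when the model has no designated core.
#' @slot coreWidth Width of that core, or `NA`.
#'
#' @seealso [windowAffinity()], [modelFromCore()], [normalizeToReference()]
#' @export
setClass("EnergyModel",
  representation(name = "character", factor = "character", mode = "character",
                 footprint = "integer", penalties = "matrix",
                 normMax = "numeric", coreOffset = "integer",
                 coreWidth = "integer"))

setValidity("EnergyModel", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("monomer", "dimer"))
    msg <- c(msg, "mode must be 'monomer' or 'dimer'")
  p <- object@penalties
  if (!is.numeric(p) || !identical(colnames(p), .DNA_BASES))
    msg <- c(msg, "penalties must be a numeric matrix with columns A,C,G,T")
  else {
    if (nrow(p) != object@footprint)
      msg <- c(msg, "penalties must have one row per footprint position")
    if (any(!is.finite(p)) || any(p < 0))
      msg <- c(msg, "penalties must be finite and >= 0")
    else {
      rowmin <- apply(p, 1L, min)
      badrow <- which(rowmin > 1e-9)
      if (length(badrow) > 0L)
        msg <- c(msg, paste0("model not anchored: no zero-penalty base at ",
                             "position(s) ", paste(badrow - 1L, collapse = ", "),
                             " (0-based)"))
    }
  }
  if (length(object@normMax) != 1L || !is.finite(object@normMax) ||
      object@normMax <= 0)
    msg <- c(msg, "normMax must be a positive finite scalar")
  if (!is.na(object@coreOffset)) {
    if (is.na(object@coreWidth) ||
        object@coreOffset < 0L ||
        object@coreOffset + object@coreWidth > object@footprint)
      msg <- c(msg, "core offset/width outside the footprint")
  }
  if (length(msg) == 0L) TRUE else msg
})

#' Construct an EnergyModel
#'
#' @param name,factor,mode,penalties,normMax,coreOffset,coreWidth See the
#'   class slots of [EnergyModel-class].
#' @return A validated `EnergyModel`.
#' @export
energyModel <- function(name, factor = "", mode = c("dimer", "monomer"),
                        penalties, normMax = 1,
                        coreOffset = NA_integer_, coreWidth = NA_integer_) {
  mode <- match.arg(mode)
  penalties <- as.matrix(penalties)
  colnames(penalties) <- .DNA_BASES
  new("EnergyModel", name = name, factor = factor, mode = mode,
      footprint = nrow(penalties), penalties = penalties,
      normMax = as.numeric(normMax),
      coreOffset = as.integer(coreOffset), coreWidth = as.integer(coreWidth))
}

#' EnergyModel accessors
#'
#' `footprint()` returns the window length, `penalties()` the L x 4 penalty
#' matrix, `normMax()` the normalization constant and `modelName()` the
#' model's name.
#'
#' @param x An [EnergyModel-class].
#' @return See individual accessors.
#' @name energy-model-accessors
#' @export
setGeneric("footprint", function(x) standardGeneric("footprint"))

#' @rdname energy-model-accessors
#' @export
setGeneric("penalties", function(x) standardGeneric("penalties"))

#' @rdname energy-model-accessors
#' @export
setGeneric("normMax", function(x) standardGeneric("normMax"))

#' @rdname energy-model-accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

setMethod("footprint", "EnergyModel", function(x) x@footprint)
setMethod("penalties", "EnergyModel", function(x) x@penalties)
setMethod("normMax", "EnergyModel", function(x) x@normMax)
setMethod("modelName", "EnergyModel", function(x) x@name)

setMethod("show", "EnergyModel", function(object) {
  cat(sprintf("EnergyModel '%s' (%s, %s mode, footprint %d bp, normMax %.4g)\n",
              object@name, object@factor, object@mode, object@footprint,
              object@normMax))
  if (!is.na(object@coreOffset))
    cat(sprintf("  core: window positions %d-%d (0-based)\n",
                object@coreOffset, object@coreOffset + object@coreWidth - 1L))
  invisible(NULL)
})

# Raw (pre-normalization) plus-strand scores for every window of `sequence`;
# windows containing non-ACGT bases score 0 and are counted by the caller.
.windowScoresRaw <- function(sequence, model) {
  codes <- match(strsplit(sequence, "")[[1L]], .DNA_BASES)
  L <- model@footprint
  n <- length(codes)
  nw <- n - L + 1L
  if (nw < 1L) return(numeric(0))
  total <- numeric(nw)
  bad <- logical(nw)
  pen <- model@penalties
  for (i in seq_len(L)) {
    b <- codes[i:(i + nw - 1L)]
    nab <- is.na(b)
    bad <- bad | nab
    add <- pen[i, ifelse(nab, 1L, b)]
    add[nab] <- 0
    total <- total + add
  }
  aff <- exp(-total)
  aff[bad] <- 0
  aff
}

#' Relative affinity of windows under a model
#'
#' Scores each window as `exp(-sum of per-position penalties) / normMax`.
#' Deterministic; log-affinity is exactly additive over positions. Windows
#' containing non-ACGT characters score 0 and a notice is emitted.
#'
#' @param model An [EnergyModel-class].
#' @param windows Character vector of DNA windows, each exactly
#'   `footprint(model)` bases.
#' @return Numeric vector of relative affinities in (0, 1] (0 only for
#'   flagged non-ACGT windows).
#' @export
#' @examples
#' m <- modelFromCore("TGATTAAT")
#' windowAffinity(m, "ATGATTAATAAA")
windowAffinity <- function(model, windows) {
  stopifnot(is(model, "EnergyModel"))
  if (!is.character(windows) || length(windows) == 0L)
    stop("'windows' must be a non-empty character vector", call. = FALSE)
  windows <- toupper(windows)
  if (any(nchar(windows) != model@footprint))
    stop(sprintf("all windows must be exactly %d bases (model footprint)",
                 model@footprint), call. = FALSE)
  res <- vapply(windows, function(w) .windowScoresRaw(w, model), numeric(1L),
                USE.NAMES = FALSE)
  nbad <- sum(res == 0)
  if (nbad > 0L)
    message(nbad, " window(s) contained non-ACGT bases and were scored 0")
  res / model@normMax
}

#' Normalize a model to a reference sequence set
#'
#' Returns a copy of the model whose `normMax` equals the maximum raw window
#' affinity over both strands of all reference sequences, so that the best
#' reference window thereafter scores exactly 1. This mirrors reporting
#' affinities relative to a genomic maximum; the reference set is explicit
#' because the appropriate universe (genome-wide, per-scaffold, ...) is a
#' choice the caller must make.
#'
#' @param model An [EnergyModel-class].
#' @param referenceSequences Character vector of DNA sequences, at least one
#'   of which must be at least `footprint(model)` long.
#' @return A renormalized `EnergyModel`.
#' @export
normalizeToReference <- function(model, referenceSequences) {
  stopifnot(is(model, "EnergyModel"))
  if (!is.character(referenceSequences) || length(referenceSequences) == 0L)
    stop("normalization error: empty reference sequence list", call. = FALSE)
  best <- 0
  for (s in toupper(referenceSequences)) {
    for (strand in c("+", "-")) {
      seqs <- if (strand == "+") s else .revcomp(s)
      sc <- .windowScoresRaw(seqs, model)
      if (length(sc) > 0L) best <- max(best, sc)
    }
  }
  if (best <= 0)
    stop("normalization error: no valid window of length >= ",
         model@footprint, " in the reference set", call. = FALSE)
  model@normMax <- best
  validObject(model)
  model
}

#' Synthesize a class-anchored model from a core sequence
#'
#' Builds an `EnergyModel` whose unique zero-penalty core equals `core`
#' (every other base at a core position carries `corePenalty`) and whose
#' flank positions carry the smaller `flankPenalty` for every base other
#' than the position's optimal flank base. Such models emulate the
#' qualitative class 1/2/3 Hox-Exd preferences - exact core identity decides
#' the class, graded flank matches modulate affinity - without claiming
#' fitted parameters.
#'
#' @param core Core sequence, or a vector of equal-length alternatives that
#'   are all zero-penalty (used for Abd-B's TTAT/TTAG monomer preference).
#' @param architecture A [siteArchitecture()]; defaults to the architecture
#'   implied by `core` with the canonical 1 + core + 3 dimer layout.
#' @param corePenalty Penalty (RT units) for any non-core base at a core
#'   position. Default `log(10)`.
#' @param flankPenalty Penalty for a non-optimal base at a flank position;
#'   scalar or one value per flank position. Default `log(2)`.
#' @param flankOptimal Character vector of optimal flank bases, one per
#'   flank position in window order (5' flanks then 3' flanks). Default all
#'   "A".
#' @param name,factor,mode Passed to the model; `mode` defaults to dimer
#'   for 8-bp cores and monomer for 4-bp cores.
#' @return An [EnergyModel-class] with `coreOffset`/`coreWidth` set from the
#'   architecture.
#' @export
#' @examples
#' m <- modelFromCore("TGATTAAT", corePenalty = log(10))
#' # one core mismatch -> factor 10 affinity drop
modelFromCore <- function(core, architecture = NULL,
                          corePenalty = log(10), flankPenalty = log(2),
                          flankOptimal = NULL,
                          name = NULL, factor = "", mode = NULL) {
  core <- vapply(core, .checkDna, character(1L), arg = "core",
                 USE.NAMES = FALSE)
  w <- unique(nchar(core))
  if (length(w) != 1L)
    stop("all core alternatives must have equal length", call. = FALSE)
  if (is.null(architecture))
    architecture <- if (w == 4L) siteArchitecture(core, 1L, 1L)
                    else siteArchitecture(core, 1L, 3L)
  if (!inherits(architecture, "SiteArchitecture"))
    stop("'architecture' must be a SiteArchitecture", call. = FALSE)
  if (length(architecture$corePositions) != w)
    stop("core width does not match the architecture core width",
         call. = FALSE)
  if (corePenalty < 0 || any(flankPenalty < 0))
    stop("penalties must be >= 0", call. = FALSE)
  L <- architecture$length
  flankPos <- sort(c(architecture$exdFlankPositions,
                     architecture$hoxFlankPositions))
  if (is.null(flankOptimal)) flankOptimal <- rep("A", length(flankPos))
  flankOptimal <- toupper(flankOptimal)
  if (length(flankOptimal) != length(flankPos) ||
      !all(flankOptimal %in% .DNA_BASES))
    stop("'flankOptimal' must give one A/C/G/T base per flank position",
         call. = FALSE)
  flankPenalty <- rep_len(flankPenalty, length(flankPos))

  pen <- matrix(0, nrow = L, ncol = 4L,
                dimnames = list(NULL, .DNA_BASES))
  coreMat <- do.call(rbind, strsplit(core, ""))
  for (j in seq_len(w)) {
    pos <- architecture$corePositions[j] + 1L      # 1-based row
    allowed <- unique(coreMat[, j])
    pen[pos, setdiff(.DNA_BASES, allowed)] <- corePenalty
  }
  for (j in seq_along(flankPos)) {
    pos <- flankPos[j] + 1L
    pen[pos, setdiff(.DNA_BASES, flankOptimal[j])] <- flankPenalty[j]
  }
  if (is.null(mode)) mode <- if (w >= 8L) "dimer" else "monomer"
  if (is.null(name))
    name <- paste0(if (nzchar(factor)) paste0(factor, "-") else "",
                   core[[1L]], "-", mode)
  energyModel(name = name, factor = factor, mode = mode, penalties = pen,
              coreOffset = architecture$coreStart, coreWidth = w)
}

#' Read / write an EnergyModel as schema-validated JSON
#'
#' The on-disk format is versioned JSON: `{schema, name, factor, mode,
#' footprint, penalties (L x 4 rows in A,C,G,T column order), norm_max,
#' core_offset, core_width}`. Round trips are lossless; files violating the
#' model invariants (negative or unanchored penalties) are rejected with the
#' offending field named.
#'
#' @param model An [EnergyModel-class].
#' @param path File path.
#' @return `readModel()` returns the validated `EnergyModel`.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "EnergyModel"))
  doc <- list(
    schema = "hoxcrm-energy-model-1",
    name = model@name, factor = model@factor, mode = model@mode,
    footprint = model@footprint,
    penalties = unname(lapply(seq_len(model@footprint),
                              function(i) unname(model@penalties[i, ]))),
    norm_max = model@normMax,
    core_offset = if (is.na(model@coreOffset)) NULL else model@coreOffset,
    core_width = if (is.na(model@coreWidth)) NULL else model@coreWidth)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "hoxcrm-energy-model-1"))
    stop("format error at 'schema': not a hoxcrm energy-model file",
         call. = FALSE)
  for (field in c("name", "factor", "mode", "footprint", "penalties",
                  "norm_max"))
    if (is.null(doc[[field]]))
      stop("format error at '", field, "': missing required field",
           call. = FALSE)
  L <- as.integer(doc$footprint)
  if (length(doc$penalties) != L)
    stop("format error at 'penalties': expected ", L, " rows", call. = FALSE)
  pen <- matrix(NA_real_, nrow = L, ncol = 4L,
                dimnames = list(NULL, .DNA_BASES))
  for (i in seq_len(L)) {
    row <- unlist(doc$penalties[[i]])
    if (length(row) != 4L || !is.numeric(row))
      stop("format error at 'penalties[", i - 1L,
           "]': expected 4 numeric values (A,C,G,T)", call. = FALSE)
    if (any(!is.finite(row)) || any(row < 0))
      stop("format error at 'penalties[", i - 1L,
           "]': penalties must be finite and >= 0", call. = FALSE)
    pen[i, ] <- row
  }
  rowmin <- apply(pen, 1L, min)
  badrow <- which(rowmin > 1e-9)
  if (length(badrow) > 0L)
    stop("format error at 'penalties[", badrow[[1L]] - 1L,
         "]': position not anchored (no zero-penalty base); ",
         "unanchored input is rejected rather than silently re-anchored",
         call. = FALSE)
  energyModel(name = doc$name, factor = doc$factor, mode = doc$mode,
              penalties = pen, normMax = doc$norm_max,
              coreOffset = if (is.null(doc$core_offset)) NA_integer_
                           else as.integer(doc$core_offset),
              coreWidth = if (is.null(doc$core_width)) NA_integer_
                          else as.integer(doc$core_width))
}
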