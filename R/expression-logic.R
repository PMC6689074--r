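# Segment-level activation model: additive Hox + STAT input gated by WNT
# repression and cofactor availability, with genotype emulation.

#' GenotypeSpec: which inputs a simulated genotype retains
#'
#' Encodes the genetic perturbations the expression model can emulate:
#' removal of individual Hox factors, loss of the Exd/Hth cofactors
#' (`cofactorsAvailable = FALSE`, emulating a strong hth allele in which Exd
#' stays cytoplasmic), silencing of the WNT repressor or the JAK/STAT
#' activator pathways, and ectopic per-segment addition of factors.
#'
#' @slot removedFactors Character vector of removed Hox factors.
#' @slot cofactorsAvailable Can Hox-cofactor (dimer) sites act?
#' @slot wntActive Is WNT repression present?
#' @slot statActive Is JAK/STAT activation present?
#' @slot ectopicFactors Named list: segment id -> factors added there.
#' @export
setClass("GenotypeSpec",
  representation(removedFactors = "character",
                 cofactorsAvailable = "logical", wntActive = "logical",
                 statActive = "logical", ectopicFactors = "list"))

setValidity("GenotypeSpec", function(object) {
  msg <- character(0)
  for (seg in names(object@ectopicFactors)) {
    clash <- intersect(object@ectopicFactors[[seg]], object@removedFactors)
    if (length(clash) > 0L)
      msg <- c(msg, paste0("factor(s) both removed and ectopic in ", seg,
                           ": ", paste(clash, collapse = ", ")))
  }
  if (length(msg) == 0L) TRUE else msg
})

#' Construct a GenotypeSpec
#'
#' @param removedFactors,cofactorsAvailable,wntActive,statActive,ectopicFactors
#'   See [GenotypeSpec-class]. Defaults describe wild type.
#' @return A validated [GenotypeSpec-class].
#' @export
#' @examples
#' genotypeSpec()                                   # wild type
#' genotypeSpec(cofactorsAvailable = FALSE)         # hth/exd loss
#' genotypeSpec(removedFactors = c("Scr", "Antp", "Ubx"), wntActive = FALSE)
genotypeSpec <- function(removedFactors = character(0),
                         cofactorsAvailable = TRUE, wntActive = TRUE,
                         statActive = TRUE, ectopicFactors = list()) {
  new("GenotypeSpec", removedFactors = removedFactors,
      cofactorsAvailable = cofactorsAvailable, wntActive = wntActive,
      statActive = statActive, ectopicFactors = ectopicFactors)
}

setMethod("show", "GenotypeSpec", function(object) {
  cat("GenotypeSpec:",
      if (length(object@removedFactors)) paste("removed",
        paste(object@removedFactors, collapse = ",")) else "all factors",
      "| cofactors", if (object@cofactorsAvailable) "available" else "lost",
      "| WNT", if (object@wntActive) "on" else "off",
      "| STAT", if (object@statActive) "on" else "off", "\n")
  if (length(object@ectopicFactors) > 0L)
    cat("  ectopic:", paste(names(object@ectopicFactors),
        vapply(object@ectopicFactors, paste, character(1L), collapse = "+"),
        sep = "=", collapse = "; "), "\n")
  invisible(NULL)
})

#' Segment map: ordered segments with collaborator inputs
#'
#' Describes the spatial scaffold the expression model runs over: the
#' ordered embryo segments, the Hox factors occupying each (from the
#' registry), a per-segment STAT activator level, and a WNT mask over
#' intra-segment positions. The default mask has two positions per segment -
#' a WNT-on (segment-polarity stripe) and a WNT-off position - the minimal
#' structure that distinguishes repeated patches from a continuous stripe.
#'
#' @param registry Hox registry supplying segments and occupancy.
#' @param statLevel Per-segment STAT input level (scalar recycled, or named
#'   vector over segments); site-level STAT scanning is out of scope.
#' @param wntMask Named numeric over intra-segment positions; 1 = repressed.
#' @return List with `segments`, `factors` (named list per segment), `stat`
#'   (named numeric) and `wntMask`; class `"SegmentMap"`.
#' @export
segmentMap <- function(registry = hoxRegistry(), statLevel = 1,
                       wntMask = c(wnt_on = 1, wnt_off = 0)) {
  segs <- registry$segments
  stat <- if (length(statLevel) == 1L) setNames(rep(statLevel, length(segs)),
                                                segs)
          else statLevel[segs]
  if (any(!is.finite(stat)) || any(stat < 0))
    stop("STAT levels must be finite and >= 0", call. = FALSE)
  structure(list(
    segments = segs,
    factors = setNames(lapply(segs, factorsInSegment, registry = registry),
                       segs),
    stat = stat,
    wntMask = wntMask), class = "SegmentMap")
}

#' @export
print.SegmentMap <- function(x, ...) {
  cat("SegmentMap:", length(x$segments), "segments,",
      length(x$wntMask), "intra-segment position(s)\n")
  occ <- vapply(x$factors, function(f)
    if (length(f)) paste(f, collapse = "+") else "-", character(1L))
  cat(paste0("  ", format(x$segments, width = 3), " ", occ, collapse = "\n"),
      "\n")
  invisible(x)
}

#' Default per-factor binding models
#'
#' Builds the synthetic class-anchored energy models the expression logic
#' and the fixture suite use: for every Hox factor a 12-bp dimer model
#' anchored on its class core, and a 6-bp monomer model anchored on TAAT
#' (TTAT/TTAG for Abd-B). Fitted model parameters are not available, so
#' these models encode the qualitative structure - exact core identity
#' decides the class, flank matches grade the affinity - with a core
#' mismatch penalty of `log(50)` (a single core mismatch scores 0.02, below
#' the default 0.05 site threshold) and a flank mismatch penalty of
#' `log(3)`. Flank preferences differ between classes, for dimers and for
#' monomers, reflecting that flanking bases contribute class-specific
#' affinity.
#'
#' @param registry Hox registry.
#' @param corePenalty,flankPenalty Mismatch penalties (RT units).
#' @return Named list (one element per factor) of lists with `dimer` and
#'   `monomer` [EnergyModel-class] objects.
#' @export
defaultHoxModels <- function(registry = hoxRegistry(),
                             corePenalty = log(50), flankPenalty = log(3)) {
  dimerFlanks <- list(class1 = c("C", "G", "A", "A"),
                      class2 = c("C", "G", "C", "C"),
                      class3 = c("C", "G", "C", "C"))
  monomerFlanks <- list(class1 = c("A", "A"),
                        class2 = c("A", "A"),
                        class3 = c("G", "C"))
  mc <- monomerCores()
  out <- list()
  for (i in seq_len(nrow(registry$factors))) {
    f <- registry$factors$name[i]
    cl <- registry$factors$hox_class[i]
    dimer <- modelFromCore(classCore(cl, registry),
                           corePenalty = corePenalty,
                           flankPenalty = flankPenalty,
                           flankOptimal = dimerFlanks[[cl]],
                           name = paste0(f, "-Exd"), factor = f,
                           mode = "dimer")
    monomerCore <- if (f == "Abd-B") mc$abdb else mc$generic
    monFlank <- if (f == "Abd-B") c("A", "A") else monomerFlanks[[cl]]
    monomer <- modelFromCore(monomerCore,
                             architecture = siteArchitecture(monomerCore,
                                                             1L, 1L),
                             corePenalty = corePenalty,
                             flankPenalty = flankPenalty,
                             flankOptimal = monFlank,
                             name = paste0(f, "-monomer"), factor = f,
                             mode = "monomer")
    out[[f]] <- list(dimer = dimer, monomer = monomer)
  }
  out
}

# Per-factor construct-level inputs: best dimer-site affinity (or 0 without
# cofactors) and the capped monomer aggregate.
.factorInputs <- function(sequence, models, genotype, registry,
                          dimerThreshold, monomerThreshold) {
  comp <- setNames(registry$factors$monomer_competence,
                   registry$factors$name)
  res <- list()
  for (f in names(models)) {
    mm <- models[[f]]
    dimer <- 0
    if (genotype@cofactorsAvailable && !is.null(mm$dimer)) {
      prof <- affinityProfile(sequence, mm$dimer)
      best <- if (nrow(prof)) max(prof$affinity) else 0
      dimer <- if (best >= dimerThreshold) best else 0
    }
    monomer <- 0
    if (!is.null(mm$monomer)) {
      sites <- scanSites(sequence, mm$monomer, threshold = monomerThreshold,
                         registry = registry)
      # many weak monomer sites act cumulatively; cap avoids unbounded drive
      monomer <- min(1, sum(sites$affinity))
    }
    res[[f]] <- data.frame(factor = f, dimer = dimer, monomer = monomer,
                           input = dimer + (comp[[f]] %||% 0.3) * monomer,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.occupyingFactors <- function(segment, map, genotype) {
  occ <- union(map$factors[[segment]],
               genotype@ectopicFactors[[segment]] %||% character(0))
  setdiff(occ, genotype@removedFactors)
}

#' Hox drive of a construct in one segment
#'
#' The summed Hox input a construct receives in a segment under a genotype:
#' over every factor occupying the segment (registry occupancy, minus
#' removed, plus ectopic factors), the best Hox-cofactor (dimer) site
#' affinity - zero when cofactors are unavailable - plus the factor's
#' monomer competence times its monomer-site aggregate (sum of monomer-site
#' affinities at or above `monomerThreshold`, capped at 1). Activation of a
#' Hox-regulated enhancer can thus be carried either by a Hox-cofactor site
#' or by monomer sites alone.
#'
#' @param sequence Construct DNA string.
#' @param segment Registered segment id.
#' @param models Named per-factor model list as from [defaultHoxModels()];
#'   a factor occupying the segment without a model is a configuration
#'   error.
#' @param genotype A [GenotypeSpec-class].
#' @param dimerThreshold Minimum dimer site affinity that counts (default
#'   0.05).
#' @param monomerThreshold Minimum monomer site affinity that counts
#'   (default 0.5; only moderately strong monomer sites contribute).
#' @param registry Hox registry.
#' @return Non-negative scalar Hox drive. Deterministic; invariant under
#'   reordering of the model list.
#' @export
hoxInput <- function(sequence, segment, models, genotype = genotypeSpec(),
                     dimerThreshold = 0.05, monomerThreshold = 0.5,
                     registry = hoxRegistry()) {
  map <- segmentMap(registry)
  occ <- .occupyingFactors(segment, map, genotype)
  missing <- setdiff(occ, names(models))
  if (length(missing) > 0L)
    stop("configuration error: no model for factor(s) present in ", segment,
         ": ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(occ) == 0L) return(0)
  inputs <- .factorInputs(sequence, models[occ], genotype, registry,
                          dimerThreshold, monomerThreshold)
  sum(inputs$input)
}

#' Predict segment-level reporter activity
#'
#' Scores every (segment, intra-segment position) cell as
#' `w_hox * HoxInput + w_stat * STAT - w_wnt * WNT`, floored at zero, and
#' quantizes the score into an off / weak / strong call via two ordered
#' thresholds. STAT contributes the segment's level when the pathway is
#' active; WNT subtracts at masked positions when active. The reporter
#' output is thus the additive combination of (weak) Hox and STAT inputs,
#' balanced against the negative WNT collaborator.
#'
#' The default weights and thresholds (`w_hox = 1`, `w_stat = 0.2`,
#' `w_wnt = 2`, thresholds 0.3 / 0.7 on a score scale of roughly 0-2) are a
#' frozen calibration chosen so that the qualitative genotype behaviour of
#' the modelled enhancer family holds; the underlying biology constrains
#' signs and orderings, not magnitudes.
#'
#' @inheritParams hoxInput
#' @param map A [segmentMap()].
#' @param weights Named numeric: `hox`, `stat`, `wnt`; all >= 0.
#' @param thresholds Named numeric `c(weak =, strong =)`, ordered.
#' @return data.frame (one row per segment x position): `segment`,
#'   `position`, `hox`, `stat`, `wnt`, `score`, `call` (ordered factor
#'   off < weak < strong; calls are monotone in score).
#' @export
predictExpression <- function(sequence, models, map = segmentMap(),
                              genotype = genotypeSpec(),
                              weights = c(hox = 1, stat = 0.2, wnt = 2),
                              thresholds = c(weak = 0.3, strong = 0.7),
                              dimerThreshold = 0.05, monomerThreshold = 0.5,
                              registry = hoxRegistry()) {
  stopifnot(all(c("hox", "stat", "wnt") %in% names(weights)),
            all(weights >= 0),
            all(c("weak", "strong") %in% names(thresholds)),
            thresholds[["weak"]] < thresholds[["strong"]])
  allFactors <- unique(unlist(c(map$factors, genotype@ectopicFactors)))
  allFactors <- setdiff(allFactors, genotype@removedFactors)
  missing <- setdiff(allFactors, names(models))
  if (length(missing) > 0L)
    stop("configuration error: no model for factor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  inputs <- .factorInputs(sequence, models[allFactors], genotype, registry,
                          dimerThreshold, monomerThreshold)
  perFactor <- setNames(inputs$input, inputs$factor)

  rows <- list()
  for (seg in map$segments) {
    occ <- .occupyingFactors(seg, map, genotype)
    hox <- sum(perFactor[occ])
    stat <- if (genotype@statActive) map$stat[[seg]] else 0
    for (p in names(map$wntMask)) {
      wnt <- if (genotype@wntActive) map$wntMask[[p]] else 0
      score <- max(0, weights[["hox"]] * hox + weights[["stat"]] * stat -
                     weights[["wnt"]] * wnt)
      rows[[length(rows) + 1L]] <- data.frame(
        segment = seg, position = p, hox = hox, stat = stat, wnt = wnt,
        score = score, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$call <- cut(out$score,
                  breaks = c(-Inf, thresholds[["weak"]],
                             thresholds[["strong"]], Inf),
                  labels = c("off", "weak", "strong"),
                  right = FALSE, ordered_result = TRUE)
  out$segment <- factor(out$segment, levels = map$segments)
  rownames(out) <- NULL
  out
}

#' Serialize / load a genotype configuration
#'
#' @param genotype A [GenotypeSpec-class].
#' @param path File path (YAML).
#' @return `readGenotype()` returns a validated `GenotypeSpec`.
#' @export
writeGenotype <- function(genotype, path) {
  stopifnot(is(genotype, "GenotypeSpec"))
  yaml::write_yaml(list(
    schema = "hoxcrm-genotype-1",
    removed_factors = as.list(genotype@removedFactors),
    cofactors_available = genotype@cofactorsAvailable,
    wnt_active = genotype@wntActive,
    stat_active = genotype@statActive,
    ectopic_factors = lapply(genotype@ectopicFactors, as.list)), path)
  invisible(path)
}

#' @rdname writeGenotype
#' @export
readGenotype <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.list(doc) || !identical(doc$schema, "hoxcrm-genotype-1"))
    stop("not a hoxcrm genotype file: ", path, call. = FALSE)
  genotypeSpec(
    removedFactors = as.character(unlist(doc$removed_factors)),
    cofactorsAvailable = isTRUE(doc$cofactors_available),
    wntActive = isTRUE(doc$wnt_active),
    statActive = isTRUE(doc$stat_active),
    ectopicFactors = lapply(doc$ectopic_factors, function(x)
      as.character(unlist(x))))
}
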