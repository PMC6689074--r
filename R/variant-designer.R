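# Rational site engineering: class conversion, optimal-flank design,
# minimal-edit knockout, restoration, and overlap-aware side-effect audits.

#' EditPlan: an ordered set of single-base substitutions
#'
#' An `EditPlan` records where a designed sequence change comes from: the
#' substitutions themselves (0-based position, reference base, alternate
#' base), the operation and parameters that produced them, and optionally an
#' [AuditReport-class] of predicted effects. Applying then reverting a plan
#' returns the original sequence exactly.
#'
#' @slot substitutions data.frame with columns `pos` (0-based), `ref`,
#'   `alt`; positions unique, `alt != ref`.
#' @slot provenance list with `op` (operation name) and `params`.
#' @slot predictedEffects An `AuditReport`, or `NULL`.
#' @export
setClass("EditPlan",
  representation(substitutions = "data.frame", provenance = "list",
                 predictedEffects = "ANY"))

setValidity("EditPlan", function(object) {
  s <- object@substitutions
  msg <- character(0)
  need <- c("pos", "ref", "alt")
  if (!all(need %in% names(s)))
    return("substitutions must have columns pos, ref, alt")
  if (nrow(s) > 0L) {
    if (anyDuplicated(s$pos)) msg <- c(msg, "substitution positions must be unique")
    if (any(s$pos < 0L)) msg <- c(msg, "substitution positions must be >= 0")
    if (any(s$ref == s$alt)) msg <- c(msg, "alt base must differ from ref base")
    if (!all(c(s$ref, s$alt) %in% .DNA_BASES))
      msg <- c(msg, "ref/alt must be A, C, G or T")
  }
  if (is.null(object@provenance$op)) msg <- c(msg, "provenance must name the operation")
  if (length(msg) == 0L) TRUE else msg
})

.editPlan <- function(pos = integer(0), ref = character(0),
                      alt = character(0), op, params = list(),
                      predictedEffects = NULL) {
  o <- order(pos)
  new("EditPlan",
      substitutions = data.frame(pos = as.integer(pos)[o], ref = ref[o],
                                 alt = alt[o], stringsAsFactors = FALSE),
      provenance = list(op = op, params = params),
      predictedEffects = predictedEffects)
}

#' EditPlan accessors
#'
#' `substitutions()` returns the substitution table, `planProvenance()` the
#' producing operation and its parameters, `predictedEffects()` the attached
#' audit (or `NULL`), and `nEdits()` the number of substitutions.
#'
#' @param x An [EditPlan-class].
#' @name edit-plan-accessors
#' @export
setGeneric("substitutions", function(x) standardGeneric("substitutions"))

#' @rdname edit-plan-accessors
#' @export
setGeneric("planProvenance", function(x) standardGeneric("planProvenance"))

#' @rdname edit-plan-accessors
#' @export
setGeneric("predictedEffects", function(x) standardGeneric("predictedEffects"))

#' @rdname edit-plan-accessors
#' @export
setGeneric("nEdits", function(x) standardGeneric("nEdits"))

setMethod("substitutions", "EditPlan", function(x) x@substitutions)
setMethod("planProvenance", "EditPlan", function(x) x@provenance)
setMethod("predictedEffects", "EditPlan", function(x) x@predictedEffects)
setMethod("nEdits", "EditPlan", function(x) nrow(x@substitutions))

setMethod("show", "EditPlan", function(object) {
  s <- object@substitutions
  cat(sprintf("EditPlan (%s): %d substitution(s)\n",
              object@provenance$op, nrow(s)))
  if (nrow(s) > 0L)
    cat(paste0("  ", s$pos, " ", s$ref, ">", s$alt, collapse = "\n"), "\n")
  invisible(NULL)
})

#' Apply or revert an edit plan
#'
#' `applyEditPlan()` substitutes each `alt` base at its position after
#' checking that the sequence carries the recorded `ref` base there;
#' `revertEditPlan()` applies the inverse substitutions. Reverting an
#' applied plan restores the input exactly.
#'
#' @param sequence DNA string.
#' @param plan An [EditPlan-class].
#' @return The edited sequence.
#' @export
applyEditPlan <- function(sequence, plan) {
  stopifnot(is(plan, "EditPlan"))
  sequence <- .checkDna(sequence, "sequence", allowOther = TRUE)
  s <- plan@substitutions
  if (nrow(s) == 0L) return(sequence)
  if (any(s$pos >= nchar(sequence)))
    stop("edit position outside the sequence", call. = FALSE)
  chars <- strsplit(sequence, "")[[1L]]
  have <- chars[s$pos + 1L]
  if (!all(have == s$ref))
    stop("reference base mismatch at position(s) ",
         paste(s$pos[have != s$ref], collapse = ", "),
         ": plan does not belong to this sequence", call. = FALSE)
  chars[s$pos + 1L] <- s$alt
  paste(chars, collapse = "")
}

#' @rdname applyEditPlan
#' @export
revertEditPlan <- function(sequence, plan) {
  stopifnot(is(plan, "EditPlan"))
  s <- plan@substitutions
  inv <- .editPlan(s$pos, ref = s$alt, alt = s$ref,
                   op = paste0("revert:", plan@provenance$op),
                   params = plan@provenance$params)
  applyEditPlan(sequence, inv)
}

# Map a window-coordinate edit (0-based offset within the scored window) to
# a plus-strand sequence edit, complementing the alternate base on "-".
.windowEditToSeq <- function(sequence, siteStart, siteStrand, L, wpos, alt) {
  if (siteStrand == "+") {
    pos <- siteStart + wpos
    altp <- alt
  } else {
    pos <- siteStart + (L - 1L - wpos)
    altp <- .complementBase(alt)
  }
  ref <- substring(sequence, pos + 1L, pos + 1L)
  list(pos = pos, ref = ref, alt = altp)
}

.siteFields <- function(site) {
  # Accept a one-row data.frame from scanSites() or a plain list.
  if (is.data.frame(site)) {
    if (nrow(site) != 1L)
      stop("'site' must be a single site (one row)", call. = FALSE)
    site <- as.list(site)
  }
  need <- c("start", "strand", "window")
  if (!all(need %in% names(site)))
    stop("'site' must carry start, strand and window fields", call. = FALSE)
  site
}

#' Convert a Hox-Exd site from one specificity class to another
#'
#' Produces the minimal set of substitutions mapping the site's current
#' class core to the target class core at the core positions, leaving the
#' flanks untouched. Minimality is certified by the Hamming distance of the
#' cores: the three registered cores differ only at core position 5, so any
#' class conversion is a single-base change (an identity conversion is an
#' empty plan). Core positions are taken from the site's `core_offset`
#' (window coordinates); edits are mapped back to plus-strand sequence
#' coordinates, complementing bases for minus-strand sites.
#'
#' @param sequence DNA string the site was called on.
#' @param site One row of a [scanSites()] result (dimer model) whose core
#'   matches a registered class.
#' @param targetClass Target class label.
#' @param models Optional named list of [EnergyModel-class] objects; when
#'   given, the plan's `predictedEffects` audit includes per-model site
#'   diffs in addition to the always-computed core diff.
#' @param registry Hox registry.
#' @return An [EditPlan-class] with attached predicted-effects audit.
#' @export
#' @examples
#' seqs <- "CCCCTGATTAATGGGG"
#' m <- modelFromCore("TGATTAAT")
#' site <- scanSites(seqs, m, threshold = 0.01)[1, ]
#' convertClass(seqs, site, "class3")  # single edit: core A -> T
convertClass <- function(sequence, site, targetClass, models = list(),
                         registry = hoxRegistry()) {
  sequence <- .checkDna(sequence, "sequence")
  site <- .siteFields(site)
  target <- classCore(targetClass, registry)
  co <- site$core_offset
  if (is.null(co) || is.na(co))
    stop("design error: site carries no core offset (monomer-mode site?)",
         call. = FALSE)
  L <- nchar(site$window)
  current <- substring(site$window, co + 1L, co + 8L)
  if (classifyWindow(current, registry) == "none")
    stop("design error: site core ", current,
         " is not a registered class core", call. = FALSE)
  diffs <- which(strsplit(current, "")[[1L]] != strsplit(target, "")[[1L]])
  pos <- integer(0); ref <- character(0); alt <- character(0)
  for (d in diffs) {
    wpos <- co + d - 1L
    e <- .windowEditToSeq(sequence, site$start, site$strand, L, wpos,
                          substring(target, d, d))
    pos <- c(pos, e$pos); ref <- c(ref, e$ref); alt <- c(alt, e$alt)
  }
  plan <- .editPlan(pos, ref, alt, op = "convert_class",
                    params = list(from = classifyWindow(current, registry),
                                  to = targetClass,
                                  site_start = site$start,
                                  strand = site$strand))
  plan@predictedEffects <- sideEffectAudit(sequence,
                                           applyEditPlan(sequence, plan),
                                           models = models,
                                           registry = registry)
  plan
}

#' Optimize the flanking bases of a site for a model
#'
#' With the core positions locked, chooses at every flank position the base
#' with the lowest penalty under `model`. Because the energy model is
#' additive over positions, independent per-position choice is exact: the
#' edited window attains the model's maximum affinity achievable with the
#' core fixed. Already-optimal flanks yield an empty plan; core positions
#' are never touched. Ties between zero-penalty bases keep the current base
#' if optimal, otherwise take the first optimal base in A,C,G,T order.
#'
#' @inheritParams convertClass
#' @param model The dimer [EnergyModel-class] to optimize for; its footprint
#'   must match the site's window.
#' @return An [EditPlan-class] confined to flank positions.
#' @export
optimizeFlanks <- function(sequence, site, model, models = list(),
                           registry = hoxRegistry()) {
  stopifnot(is(model, "EnergyModel"))
  if (model@mode != "dimer")
    stop("'model' must be a dimer-mode model", call. = FALSE)
  sequence <- .checkDna(sequence, "sequence")
  site <- .siteFields(site)
  L <- model@footprint
  if (nchar(site$window) != L)
    stop("site window and model footprint disagree", call. = FALSE)
  co <- model@coreOffset
  if (is.na(co))
    stop("model has no designated core; flank optimization undefined",
         call. = FALSE)
  corePos <- co + seq_len(model@coreWidth) - 1L
  flankPos <- setdiff(0:(L - 1L), corePos)
  wchars <- strsplit(site$window, "")[[1L]]
  pos <- integer(0); ref <- character(0); alt <- character(0)
  for (wp in flankPos) {
    row <- model@penalties[wp + 1L, ]
    cur <- wchars[wp + 1L]
    if (row[[cur]] <= min(row) + 1e-12) next   # current base already optimal
    best <- .DNA_BASES[which.min(row)]
    e <- .windowEditToSeq(sequence, site$start, site$strand, L, wp, best)
    pos <- c(pos, e$pos); ref <- c(ref, e$ref); alt <- c(alt, e$alt)
  }
  plan <- .editPlan(pos, ref, alt, op = "optimize_flanks",
                    params = list(model = model@name,
                                  site_start = site$start,
                                  strand = site$strand))
  plan@predictedEffects <- sideEffectAudit(sequence,
                                           applyEditPlan(sequence, plan),
                                           models = models,
                                           registry = registry)
  plan
}

# ---- knockout ---------------------------------------------------------------

# Predicate factories: return function(sequence) -> TRUE when knocked out,
# plus a candidate-position function for the search.
.koCorePredicate <- function(cores) {
  function(sequence) nrow(.findKmers(sequence, cores)) == 0L
}

.koCoreResidual <- function(sequence, cores) .findKmers(sequence, cores)

.koAffinityResidual <- function(sequence, models, ceiling) {
  out <- list()
  for (m in models) {
    sc <- scanSites(sequence, m, threshold = ceiling)
    if (nrow(sc) > 0L) out[[length(out) + 1L]] <- sc
  }
  if (length(out) == 0L) .emptySites() else do.call(rbind, out)
}

#' Minimal-edit knockout of Hox input
#'
#' Finds a small set of single-base substitutions after which no Hox site
#' survives, mirroring the design of constructs that remove predicted Hox
#' input with the fewest possible base changes.
#'
#' Two modes:
#' * `mode = "core"` (default): destroy every exact occurrence of the
#'   forbidden cores (default: the registered class cores) on both strands,
#'   without any edit creating a new forbidden core. This mirrors
#'   mutagenesis designed against predicted cores.
#' * `mode = "affinity"`: after editing, every window of every supplied
#'   model on both strands must score below `ceiling`.
#'
#' For sequences up to `certifyLen` bases and plans up to `certifyEdits`
#' substitutions the search is exhaustive over edit counts 0, 1, 2, ... so
#' the returned plan is certified minimal; single-edit searches enumerate
#' every position, multi-edit searches restrict candidate positions to bases
#' covered by a current site. Beyond those limits an iterative greedy search
#' is used (each step applies the substitution that best reduces the
#' residual, never one that creates a new forbidden core). Among equal-size
#' plans the lexicographically smallest (position, then alternate base in
#' A,C,G,T order) is returned, for determinism.
#'
#' @param sequence DNA string.
#' @param models List of [EnergyModel-class] objects (required for
#'   `mode = "affinity"`; optional for the audit in core mode).
#' @param mode `"core"` or `"affinity"`.
#' @param cores Named character vector of forbidden cores for core mode;
#'   default the registry class cores. Add [monomerCores()] strings to also
#'   knock out monomer input.
#' @param ceiling Affinity bound in (0, 1) for affinity mode (also the audit
#'   threshold).
#' @param maxEdits Maximum substitutions to attempt.
#' @param certifyLen,certifyEdits Exhaustive-search limits.
#' @param registry Hox registry.
#' @return An [EditPlan-class]; its provenance records whether minimality
#'   was `certified`. If no plan within `maxEdits` exists the search stops
#'   with an error reporting the best residual sites.
#' @export
knockoutSites <- function(sequence, models = list(),
                          mode = c("core", "affinity"),
                          cores = NULL, ceiling = 0.05, maxEdits = 3L,
                          certifyLen = 60L, certifyEdits = 3L,
                          registry = hoxRegistry()) {
  mode <- match.arg(mode)
  sequence <- .checkDna(sequence, "sequence")
  if (mode == "affinity" && length(models) == 0L)
    stop("affinity-mode knockout needs at least one model", call. = FALSE)
  if (ceiling <= 0 || ceiling >= 1)
    stop("'ceiling' must be in (0, 1)", call. = FALSE)
  if (mode == "core" && is.null(cores)) cores <- classCores(registry)

  residual <- function(s) {
    if (mode == "core") .koCoreResidual(s, cores)
    else .koAffinityResidual(s, models, ceiling)
  }
  done <- function(s) nrow(residual(s)) == 0L

  finishedPlan <- function(pos, ref, alt, certified) {
    plan <- .editPlan(pos, ref, alt, op = "knockout",
                      params = list(mode = mode, ceiling = ceiling,
                                    certified = certified))
    plan@predictedEffects <- sideEffectAudit(sequence,
                                             applyEditPlan(sequence, plan),
                                             models = models,
                                             threshold = ceiling,
                                             registry = registry)
    plan
  }

  if (done(sequence))
    return(finishedPlan(integer(0), character(0), character(0),
                        certified = TRUE))

  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1L]]
  exhaustive <- n <= certifyLen && maxEdits <= certifyEdits

  if (exhaustive) {
    res0 <- residual(sequence)
    covered <- sort(unique(unlist(Map(function(s, e) s:(e - 1L),
                                      res0$start, res0$end))))
    for (k in seq_len(maxEdits)) {
      cand <- if (k == 1L) 0:(n - 1L) else covered
      if (length(cand) < k) next
      combos <- combn(cand, k)
      altsets <- expand.grid(rep(list(1:3), k))
      # rows in lexicographic order (first position's alternate slowest):
      altsets <- altsets[do.call(order, altsets), , drop = FALSE]
      for (ci in seq_len(ncol(combos))) {
        pos <- combos[, ci]
        refs <- chars[pos + 1L]
        altchoices <- lapply(refs, function(r) setdiff(.DNA_BASES, r))
        for (ai in seq_len(nrow(altsets))) {
          alts <- vapply(seq_len(k), function(j)
            altchoices[[j]][altsets[ai, j]], character(1L))
          trial <- chars
          trial[pos + 1L] <- alts
          if (done(paste(trial, collapse = "")))
            return(finishedPlan(pos, refs, alts, certified = TRUE))
        }
      }
    }
    stop("design failure: no knockout plan within ", maxEdits,
         " edit(s); residual sites remain:\n",
         paste(utils::capture.output(print(residual(sequence))),
               collapse = "\n"), call. = FALSE)
  }

  # Greedy: per step, the substitution minimizing the residual site count
  # (ties: fewest new forbidden cores impossible by construction - edits
  # creating forbidden cores are rejected; then lexicographic order).
  cur <- sequence
  pos <- integer(0); ref <- character(0); alt <- character(0)
  for (step in seq_len(maxEdits)) {
    res <- residual(cur)
    if (nrow(res) == 0L) break
    covered <- sort(unique(unlist(Map(function(s, e) s:(e - 1L),
                                      res$start, res$end))))
    bestCount <- nrow(res)
    bestEdit <- NULL
    curChars <- strsplit(cur, "")[[1L]]
    for (p in covered) {
      for (a in setdiff(.DNA_BASES, curChars[p + 1L])) {
        trial <- curChars
        trial[p + 1L] <- a
        trialSeq <- paste(trial, collapse = "")
        cnt <- nrow(residual(trialSeq))
        if (cnt < bestCount) {
          bestCount <- cnt
          bestEdit <- list(pos = p, ref = curChars[p + 1L], alt = a)
        }
      }
    }
    if (is.null(bestEdit))
      stop("design failure: greedy knockout cannot reduce the residual; ",
           "sites remain:\n",
           paste(utils::capture.output(print(res)), collapse = "\n"),
           call. = FALSE)
    pos <- c(pos, bestEdit$pos); ref <- c(ref, bestEdit$ref)
    alt <- c(alt, bestEdit$alt)
    curChars[bestEdit$pos + 1L] <- bestEdit$alt
    cur <- paste(curChars, collapse = "")
  }
  if (!done(cur))
    stop("design failure: no knockout plan within ", maxEdits,
         " edit(s); best residual sites:\n",
         paste(utils::capture.output(print(residual(cur))),
               collapse = "\n"), call. = FALSE)
  finishedPlan(pos, ref, alt, certified = FALSE)
}

#' Restore regions of a sequence to their original state
#'
#' Returns a sequence equal to `original` within the given regions and to
#' `current` elsewhere - e.g. restoring knocked-out Hox-cofactor sites back
#' to wild type inside an otherwise mutated construct.
#'
#' @param current,original Equal-length DNA strings.
#' @param regions List of 0-based half-open `c(start, end)` intervals (or a
#'   2-column matrix).
#' @return The hybrid sequence.
#' @export
restoreRegions <- function(current, original, regions) {
  current <- .checkDna(current, "current", allowOther = TRUE)
  original <- .checkDna(original, "original", allowOther = TRUE)
  if (nchar(current) != nchar(original))
    stop("'current' and 'original' must have equal length", call. = FALSE)
  if (is.matrix(regions))
    regions <- lapply(seq_len(nrow(regions)), function(i) regions[i, ])
  chars <- strsplit(current, "")[[1L]]
  orig <- strsplit(original, "")[[1L]]
  for (r in regions) {
    s <- as.integer(r[[1L]]); e <- as.integer(r[[2L]])
    if (s < 0L || e > length(chars) || s > e)
      stop("region [", s, ", ", e, ") out of bounds", call. = FALSE)
    if (e > s) chars[(s + 1L):e] <- orig[(s + 1L):e]
  }
  paste(chars, collapse = "")
}

# ---- audits -----------------------------------------------------------------

#' AuditReport: complete diff of site content between two sequences
#'
#' Captures what an edit did to the binding-site landscape: exact class
#' cores gained and lost (always computed), and per energy model the sites
#' gained, lost and affinity-changed above a threshold. An identity edit
#' yields an empty report. Use [S4Vectors::isEmpty()] to test emptiness.
#'
#' @slot cores list with `gained` and `lost` core data.frames
#'   (see [scanCores()]).
#' @slot models Named list (one per audited model) of lists with `gained`,
#'   `lost` and `changed` site data.frames; `changed` carries
#'   `affinity_before`/`affinity_after`.
#' @slot threshold Site threshold the model diffs used.
#' @export
setClass("AuditReport",
  representation(cores = "list", models = "list", threshold = "numeric"))

setMethod("show", "AuditReport", function(object) {
  cat(sprintf("AuditReport: %d core(s) gained, %d lost",
              nrow(object@cores$gained), nrow(object@cores$lost)))
  if (length(object@models) > 0L) {
    cat("; per-model site diffs:\n")
    for (nm in names(object@models)) {
      d <- object@models[[nm]]
      cat(sprintf("  %s: +%d / -%d / ~%d\n", nm, nrow(d$gained),
                  nrow(d$lost), nrow(d$changed)))
    }
  } else cat("\n")
  invisible(NULL)
})

#' @rdname AuditReport-class
#' @param x An `AuditReport`.
#' @export
setMethod("isEmpty", "AuditReport", function(x) {
  coreEmpty <- nrow(x@cores$gained) == 0L && nrow(x@cores$lost) == 0L
  modelEmpty <- all(vapply(x@models, function(d) {
    nrow(d$gained) == 0L && nrow(d$lost) == 0L && nrow(d$changed) == 0L
  }, logical(1L)))
  coreEmpty && modelEmpty
})

#' Audit accessors
#'
#' `coreChanges()` returns the gained/lost exact-core diff; `modelChanges()`
#' the per-model site diffs.
#'
#' @param x An [AuditReport-class].
#' @name audit-accessors
#' @export
setGeneric("coreChanges", function(x) standardGeneric("coreChanges"))

#' @rdname audit-accessors
#' @export
setGeneric("modelChanges", function(x) standardGeneric("modelChanges"))

setMethod("coreChanges", "AuditReport", function(x) x@cores)
setMethod("modelChanges", "AuditReport", function(x) x@models)

#' Side-effect audit of a sequence edit
#'
#' Diffs the complete binding-site content of two equal-length sequences:
#' exact class-core occurrences (both strands) gained and lost, and - for
#' each supplied model - scan results gained, lost, or changed in affinity.
#' Sites are matched by (start, strand). This catches collateral effects of
#' rational edits, such as a class conversion that simultaneously creates or
#' strengthens an overlapping core of a different class.
#'
#' @param sequenceBefore,sequenceAfter Equal-length DNA strings.
#' @param models Named list of [EnergyModel-class] objects to diff with.
#' @param threshold Site threshold for the model scans.
#' @param registry Hox registry.
#' @return An [AuditReport-class]. Deterministic.
#' @export
#' @examples
#' # class2 -> class1 core edit that also creates an overlapping class3 core
#' before <- "CCTGATTAATTTATCC"
#' after  <- "CCTGATTGATTTATCC"
#' coreChanges(sideEffectAudit(before, after))
sideEffectAudit <- function(sequenceBefore, sequenceAfter, models = list(),
                            threshold = 0.05, registry = hoxRegistry()) {
  sequenceBefore <- .checkDna(sequenceBefore, "sequenceBefore")
  sequenceAfter <- .checkDna(sequenceAfter, "sequenceAfter")
  if (nchar(sequenceBefore) != nchar(sequenceAfter))
    stop("sequences must have equal length", call. = FALSE)

  key <- function(df) paste(df$label, df$start, df$strand)
  cb <- scanCores(sequenceBefore, registry)
  ca <- scanCores(sequenceAfter, registry)
  cores <- list(gained = ca[!key(ca) %in% key(cb), , drop = FALSE],
                lost = cb[!key(cb) %in% key(ca), , drop = FALSE])
  rownames(cores$gained) <- rownames(cores$lost) <- NULL

  if (length(models) > 0L && is.null(names(models)))
    names(models) <- vapply(models, modelName, character(1L))
  mdiff <- lapply(models, function(m) {
    sb <- scanSites(sequenceBefore, m, threshold, registry)
    sa <- scanSites(sequenceAfter, m, threshold, registry)
    kb <- paste(sb$start, sb$strand)
    ka <- paste(sa$start, sa$strand)
    shared <- intersect(kb, ka)
    ib <- match(shared, kb); ia <- match(shared, ka)
    chg <- abs(sb$affinity[ib] - sa$affinity[ia]) > 1e-12
    changed <- data.frame(sa[ia[chg], c("model", "start", "end", "strand"),
                             drop = FALSE],
                          affinity_before = sb$affinity[ib[chg]],
                          affinity_after = sa$affinity[ia[chg]])
    rownames(changed) <- NULL
    g <- sa[!ka %in% kb, , drop = FALSE]; rownames(g) <- NULL
    l <- sb[!kb %in% ka, , drop = FALSE]; rownames(l) <- NULL
    list(gained = g, lost = l, changed = changed)
  })
  new("AuditReport", cores = cores, models = mdiff,
      threshold = as.numeric(threshold))
}

#' Serialize / load an edit plan
#'
#' Plans are written either as a small VCF-like tab table (sequence name,
#' 0-based position, ref, alt, provenance) or as JSON carrying the full
#' provenance parameters.
#'
#' @param plan An [EditPlan-class].
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @param seqname Sequence name recorded in the table.
#' @return `readEditPlan()` returns an `EditPlan` (without predicted
#'   effects, which are recomputable).
#' @export
writeEditPlan <- function(plan, path, format = c("tsv", "json"),
                          seqname = "seq") {
  stopifnot(is(plan, "EditPlan"))
  format <- match.arg(format)
  s <- plan@substitutions
  if (format == "tsv") {
    df <- data.frame(seqname = rep(seqname, nrow(s)), pos = s$pos,
                     ref = s$ref, alt = s$alt,
                     provenance = rep(plan@provenance$op, nrow(s)),
                     stringsAsFactors = FALSE)
    writeTsv(df, path)
  } else {
    doc <- list(schema = "hoxcrm-edit-plan-1", seqname = seqname,
                provenance = plan@provenance,
                substitutions = unname(lapply(seq_len(nrow(s)), function(i)
                  list(pos = s$pos[i], ref = s$ref[i], alt = s$alt[i]))))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeEditPlan
#' @export
readEditPlan <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    op <- if (nrow(df) > 0L) df$provenance[[1L]] else "unknown"
    .editPlan(df$pos, df$ref, df$alt, op = op)
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!identical(doc$schema, "hoxcrm-edit-plan-1"))
      stop("format error at 'schema': not a hoxcrm edit-plan file",
           call. = FALSE)
    s <- doc$substitutions
    .editPlan(vapply(s, function(x) as.integer(x$pos), integer(1L)),
              vapply(s, `[[`, character(1L), "ref"),
              vapply(s, `[[`, character(1L), "alt"),
              op = doc$provenance$op,
              params = doc$provenance$params)
  }
}
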