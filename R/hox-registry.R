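# Fixed biological constants: Hox factors, Hox-Exd specificity classes,
# monomer cores, site architecture and segment expression domains.

#' The default Hox registry
#'
#' Returns the registry of biological constants the package operates with:
#' the three Hox-Exd specificity classes and their 8-bp cores, the eight
#' Drosophila Hox factors with class membership and monomer competence
#' weights, per-factor segment expression domains, and the ordered
#' (anterior to posterior) segment list.
#'
#' Monomer competence expresses the relative capacity of a factor to act
#' through Hox-monomer sites without Exd/Hth; Abd-B is markedly more
#' competent as a monomer than the other Hox proteins, so it carries weight
#' 1 against a default of 0.3. The magnitudes are tunable model parameters,
#' not measured constants. Pb has no registered expression segments in this
#' system and is unused downstream.
#'
#' @return A list with elements `classes` (data.frame: label, core),
#'   `members` (list of factor names per class), `factors` (data.frame:
#'   name, hox_class, monomer_competence), `expression_segments` (named
#'   list of segment ids per factor) and `segments` (ordered character
#'   vector of segment ids).
#' @seealso [classCore()], [factorsInSegment()], [writeRegistry()]
#' @export
#' @examples
#' reg <- hoxRegistry()
#' reg$classes
hoxRegistry <- function() {
  list(
    classes = data.frame(
      label = c("class1", "class2", "class3"),
      core  = c("TGATTGAT", "TGATTAAT", "TGATTTAT"),
      stringsAsFactors = FALSE),
    members = list(
      class1 = c("Lab", "Pb"),
      class2 = c("Dfd", "Scr"),
      class3 = c("Antp", "Ubx", "Abd-A", "Abd-B")),
    factors = data.frame(
      name = c("Lab", "Pb", "Dfd", "Scr", "Antp", "Ubx", "Abd-A", "Abd-B"),
      hox_class = c("class1", "class1", "class2", "class2",
                    "class3", "class3", "class3", "class3"),
      monomer_competence = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 1.0),
      stringsAsFactors = FALSE),
    expression_segments = list(
      Lab = "ic",
      Pb = character(0),
      Dfd = c("md", "mx"),
      Scr = c("lb", "T1"),
      Antp = c("T1", "T2", "T3"),
      Ubx = c("T3", paste0("A", 1:7)),
      `Abd-A` = paste0("A", 2:8),
      `Abd-B` = c("A8", "A9")),
    segments = c("ic", "md", "mx", "lb", "T1", "T2", "T3", paste0("A", 1:9))
  )
}

#' Class core sequences
#'
#' `classCores()` returns the named vector of all registered 8-bp Hox-Exd
#' core sequences; `classCore()` looks up a single class label.
#'
#' @param registry A registry as returned by [hoxRegistry()].
#' @param label One of `"class1"`, `"class2"`, `"class3"`.
#' @return `classCores()`: named character vector; `classCore()`: a single
#'   8-base string.
#' @export
#' @examples
#' classCore("class2")  # "TGATTAAT"
classCores <- function(registry = hoxRegistry()) {
  setNames(registry$classes$core, registry$classes$label)
}

#' @rdname classCores
#' @export
classCore <- function(label, registry = hoxRegistry()) {
  cores <- classCores(registry)
  if (!is.character(label) || length(label) != 1L || !label %in% names(cores))
    stop("unknown Hox-Exd class label: ", paste(label, collapse = ", "),
         call. = FALSE)
  unname(cores[[label]])
}

#' Classify an 8-bp window against the registered Hox-Exd cores
#'
#' Returns the class label whose core equals the window, or `"none"`.
#' The registry is strand-naive: the caller is responsible for strand
#' (score the reverse complement to classify minus-strand windows).
#'
#' @param window An 8-base ACGT string.
#' @inheritParams classCores
#' @return `"class1"`, `"class2"`, `"class3"` or `"none"`.
#' @export
#' @examples
#' classifyWindow("TGATTAAT")   # class2
#' classifyWindow("AAAAAAAA")   # none
classifyWindow <- function(window, registry = hoxRegistry()) {
  window <- .checkDna(window, "window")
  if (nchar(window) != 8L)
    stop("'window' must be exactly 8 bases long", call. = FALSE)
  cores <- classCores(registry)
  hit <- names(cores)[cores == window]
  if (length(hit) == 0L) "none" else hit[[1L]]
}

#' Hox-monomer core constants
#'
#' All Hox proteins except Abd-B bind a TAAT monomer core; Abd-B, with its
#' divergent homeodomain, prefers TTAT or TTAG. Monomer recognition covers a
#' short 6-bp AT-rich footprint.
#'
#' @return A list with `generic` ("TAAT"), `abdb` (c("TTAT", "TTAG")) and
#'   `footprint` (6).
#' @export
monomerCores <- function() {
  list(generic = "TAAT", abdb = c("TTAT", "TTAG"), footprint = 6L)
}

#' Hox factor table
#'
#' @inheritParams classCores
#' @return The registry factor data.frame (name, hox_class,
#'   monomer_competence) with an added list column `expression_segments`.
#' @export
hoxFactors <- function(registry = hoxRegistry()) {
  df <- registry$factors
  df$expression_segments <- unname(registry$expression_segments[df$name])
  df
}

#' Ordered segment registry
#'
#' @inheritParams classCores
#' @return Character vector of segment ids, anterior to posterior:
#'   ic, md, mx, lb, T1-T3, A1-A9.
#' @export
hoxSegments <- function(registry = hoxRegistry()) registry$segments

#' Hox factors expressed in a segment
#'
#' @param segment A registered segment id.
#' @inheritParams classCores
#' @return Factor names occupying the segment, in the registry's
#'   anterior-to-posterior factor order. Deterministic.
#' @export
#' @examples
#' factorsInSegment("ic")  # Lab
#' factorsInSegment("lb")  # Scr
factorsInSegment <- function(segment, registry = hoxRegistry()) {
  if (!is.character(segment) || length(segment) != 1L ||
      !segment %in% registry$segments)
    stop("unknown segment id: ", paste(segment, collapse = ", "),
         call. = FALSE)
  present <- vapply(registry$factors$name, function(f) {
    segment %in% registry$expression_segments[[f]]
  }, logical(1L))
  registry$factors$name[present]
}

#' Canonical Hox-Exd / Hox-monomer site architecture
#'
#' Describes the layout of a binding-site window: wildcard flank positions
#' around a fixed core. The default dimer architecture is the canonical
#' 12-bp Hox-Exd site, one Exd-side flank base, the 8-bp core bound by both
#' proteins, and three Hox-side flank bases (template `nTGATTAATnnn`).
#' Positions are 0-based within the window.
#'
#' @param core Core sequence (8 bp for Hox-Exd dimers, 4 bp for monomer
#'   cores). May be a vector of equal-length cores when a position tolerates
#'   more than one base (Abd-B's TTAT/TTAG); the template shows the first.
#' @param leftFlank,rightFlank Number of wildcard flank positions on each
#'   side of the core.
#' @return An object of class `"SiteArchitecture"`: list with `template`,
#'   `length`, `coreStart`, `corePositions`, `exdFlankPositions` (5' side)
#'   and `hoxFlankPositions` (3' side), all 0-based.
#' @export
#' @examples
#' siteArchitecture()                       # nTGATTAATnnn, length 12
#' siteArchitecture("TAAT", 1L, 1L)         # nTAATn, monomer footprint 6
siteArchitecture <- function(core = "TGATTAAT", leftFlank = 1L,
                             rightFlank = 3L) {
  core <- vapply(core, .checkDna, character(1L), arg = "core",
                 USE.NAMES = FALSE)
  w <- unique(nchar(core))
  if (length(w) != 1L)
    stop("all core alternatives must have equal length", call. = FALSE)
  leftFlank <- as.integer(leftFlank); rightFlank <- as.integer(rightFlank)
  if (leftFlank < 0L || rightFlank < 0L)
    stop("flank widths must be non-negative", call. = FALSE)
  len <- leftFlank + w + rightFlank
  structure(list(
    template = paste0(strrep("n", leftFlank), core[[1L]],
                      strrep("n", rightFlank)),
    length = len,
    core = core,
    coreStart = leftFlank,
    corePositions = leftFlank + seq_len(w) - 1L,
    exdFlankPositions = if (leftFlank > 0L) 0:(leftFlank - 1L) else integer(0),
    hoxFlankPositions = if (rightFlank > 0L) (leftFlank + w):(len - 1L)
                        else integer(0)
  ), class = "SiteArchitecture")
}

#' @export
print.SiteArchitecture <- function(x, ...) {
  cat("SiteArchitecture: template", x$template, "(length", x$length, "bp)\n")
  cat("  core positions:", paste(x$corePositions, collapse = ","),
      " flanks 5':", length(x$exdFlankPositions),
      " 3':", length(x$hoxFlankPositions), "\n")
  invisible(x)
}

#' Serialize / load a Hox registry
#'
#' The registry is written as a YAML document with `classes`, `factors`
#' (including monomer competence and expression segments) and `segments`
#' tables, so segment domains and competence weights can be reconfigured
#' without code changes.
#'
#' @param registry A registry list (see [hoxRegistry()]).
#' @param path File path.
#' @return `readRegistry()` returns a validated registry list.
#' @export
writeRegistry <- function(registry, path) {
  doc <- list(
    schema = "hoxcrm-registry-1",
    classes = Map(function(l, c) list(label = l, core = c),
                  registry$classes$label, registry$classes$core),
    factors = lapply(seq_len(nrow(registry$factors)), function(i) {
      nm <- registry$factors$name[i]
      list(name = nm,
           hox_class = registry$factors$hox_class[i],
           monomer_competence = registry$factors$monomer_competence[i],
           expression_segments = as.list(registry$expression_segments[[nm]]))
    }),
    segments = as.list(registry$segments))
  names(doc$classes) <- NULL
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname writeRegistry
#' @export
readRegistry <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.list(doc) || !identical(doc$schema, "hoxcrm-registry-1"))
    stop("not a hoxcrm registry file (missing/unknown 'schema' key): ", path,
         call. = FALSE)
  classes <- data.frame(
    label = vapply(doc$classes, `[[`, character(1L), "label"),
    core = vapply(doc$classes, `[[`, character(1L), "core"),
    stringsAsFactors = FALSE)
  if (any(nchar(classes$core) != 8L) || any(grepl("[^ACGT]", classes$core)))
    stop("registry class cores must be 8-bp ACGT strings", call. = FALSE)
  if (anyDuplicated(classes$core))
    stop("registry class cores must be pairwise distinct", call. = FALSE)
  factors <- data.frame(
    name = vapply(doc$factors, `[[`, character(1L), "name"),
    hox_class = vapply(doc$factors, `[[`, character(1L), "hox_class"),
    monomer_competence = vapply(doc$factors, `[[`, numeric(1L),
                                "monomer_competence"),
    stringsAsFactors = FALSE)
  segments <- unlist(doc$segments)
  expr <- lapply(doc$factors, function(f)
    as.character(unlist(f$expression_segments)))
  names(expr) <- factors$name
  bad <- setdiff(unlist(expr), segments)
  if (length(bad) > 0L)
    stop("registry expression segments not in the segment table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  members <- split(factors$name, factors$hox_class)[classes$label]
  names(members) <- classes$label
  list(classes = classes, members = members, factors = factors,
       expression_segments = expr, segments = segments)
}
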