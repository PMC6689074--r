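# Synthetic inputs with the structure the analysis assumes: background
# sequences free of registered cores, planted class/monomer sites, an
# enhancer-like fixture family with a 55-bp dual-core cassette, and noisy
# pseudo-measurements for recovery tests.

#' Random background sequence free of forbidden cores
#'
#' Draws an i.i.d. sequence at the requested GC fraction and, when `forbid`
#' is non-empty, repairs it until no forbidden k-mer occurs on either strand
#' (each repair step resamples one base inside the first remaining
#' occurrence). Reproducible for a fixed seed.
#'
#' @param length Sequence length, >= 1.
#' @param gc GC fraction in [0, 1] (`gc = 0` gives an AT-only sequence).
#' @param forbid Character vector of k-mers that must not occur on either
#'   strand (e.g. `classCores()`).
#' @param seed Optional integer seed; the caller's RNG stream is preserved.
#' @param maxAttempts Repair-step cap; exceeding it is a generation error.
#' @return A DNA string.
#' @export
randomBackground <- function(length, gc = 0.5, forbid = character(0),
                             seed = NULL, maxAttempts = 10000L) {
  if (length < 1L) stop("'length' must be >= 1", call. = FALSE)
  if (gc < 0 || gc > 1) stop("'gc' must be in [0, 1]", call. = FALSE)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  .withSeed(seed, {
    chars <- sample(.DNA_BASES, length, replace = TRUE, prob = probs)
    if (length(forbid) > 0L) {
      attempt <- 0L
      repeat {
        hits <- .findKmers(paste(chars, collapse = ""), forbid)
        if (nrow(hits) == 0L) break
        attempt <- attempt + 1L
        if (attempt > maxAttempts)
          stop("generation error: could not purge forbidden cores within ",
               maxAttempts, " repair steps", call. = FALSE)
        p <- sample(hits$start[1L]:(hits$end[1L] - 1L), 1L)
        chars[p + 1L] <- sample(.DNA_BASES, 1L, prob = probs)
      }
    }
    paste(chars, collapse = "")
  })
}

#' Plant an insert into a sequence
#'
#' Replaces the substring at `[position, position + nchar(insert))` with the
#' insert (its reverse complement for `strand = "-"`); sequence length is
#' preserved.
#'
#' @param sequence DNA string.
#' @param insert DNA string to plant.
#' @param position 0-based start of the replaced substring.
#' @param strand `"+"` or `"-"`.
#' @return The edited sequence.
#' @export
#' @examples
#' plantSite(strrep("C", 16), "TGATTAAT", 4)
plantSite <- function(sequence, insert, position, strand = "+") {
  sequence <- .checkDna(sequence, "sequence", allowOther = TRUE)
  insert <- .checkDna(insert, "insert")
  position <- as.integer(position)
  w <- nchar(insert)
  if (position < 0L || position + w > nchar(sequence))
    stop("insert does not fit at position ", position, call. = FALSE)
  if (strand == "-") insert <- .revcomp(insert)
  paste0(substring(sequence, 1L, position), insert,
         substring(sequence, position + w + 1L, nchar(sequence)))
}

# ---- fixture suite ----------------------------------------------------------

# Geometry constants of the dual-core cassette (all 0-based offsets within
# the 55-bp cassette): 18 bp inert pad | 'C' left flank | 15 bp dual core
# (class 2 at 19, class 3 at 26, sharing position 26) | 'TGT' | 18 bp pad.
# The fixed flanking bases are chosen so the only monomer cores in the
# cassette are the ones inherent to the dual core itself.
.CASSETTE_PAD <- 18L
.DUAL_CORE <- "TGATTAATGATTTAT"
.CASSETTE_MAIN <- .CASSETTE_PAD + 1L          # class 2 core start (19)
.CASSETTE_OL <- .CASSETTE_MAIN + 7L           # class 3 core start (26)

.allForbidden <- function(registry) {
  mc <- monomerCores()
  c(unname(classCores(registry)), mc$generic, mc$abdb)
}

# Expected exact-core content (plus incidental monomer cores inside planted
# elements), as (kmer, start, strand) keys.
.coreKey <- function(df) paste(df$kmer, df$start, df$strand)

.expectedCassetteHits <- function() {
  p <- .CASSETTE_MAIN
  data.frame(
    kmer = c("TGATTAAT", "TGATTTAT", "TAAT", "TAAT", "TTAT"),
    start = c(p, p + 7L, p + 4L, p + 2L, p + 11L),
    strand = c("+", "+", "+", "-", "+"),
    stringsAsFactors = FALSE)
}

.shiftHits <- function(df, by) { df$start <- df$start + as.integer(by); df }

.expectedInsertHits <- function(insert, at) {
  if (insert == "GATTATA")       # Abd-B monomer site: A-TTAT-A with lead G
    data.frame(kmer = c("TTAT", "TAAT"), start = at + c(2L, 1L),
               strand = c("+", "-"), stringsAsFactors = FALSE)
  else if (insert == "GTAATC")   # generic monomer site: G-TAAT-C
    data.frame(kmer = "TAAT", start = at + 1L, strand = "+",
               stringsAsFactors = FALSE)
  else stop("unknown insert")
}

.hitsMatch <- function(sequence, expected, registry) {
  got <- .findKmers(sequence, .allForbidden(registry))
  setequal(.coreKey(got), .coreKey(expected))
}

#' Generate the enhancer-like fixture suite
#'
#' Builds, reproducibly from a seed, the family of synthetic constructs the
#' package's validation rests on. No real enhancer sequence is available as
#' text, so the suite emulates its documented structure (every sequence here
#' is synthetic):
#'
#' * `S1`: a 300-bp inert fragment carrying no registered class or monomer
#'   core on either strand (rejection-sampled).
#' * `cassette`: a 55-bp element containing exactly one class 2 core (the
#'   "main" site) and one class 3 core (the "overlapping" site) that share
#'   one base pair, so a single shared-position substitution can destroy
#'   both.
#' * `S2` (250 bp): the cassette followed by background carrying three
#'   planted Abd-B-type monomer sites (TTAT with optimal flanks).
#' * `S3` (130 bp): background with three planted generic TAAT monomer
#'   sites with trunk-class-optimal flanks.
#' * `vvl` (680 bp): the S1 + S2 + S3 concatenation.
#' * `S1p55` (355 bp): S1 plus the cassette - the minimal active construct.
#' * Seven variant constructs derived from `S1p55` by the variant-designer
#'   operations: `cl1`/`cl2`/`cl3` (main-site class conversions; cl2 is the
#'   identity), `mut` (minimal-edit dual-core knockout) and `cl1OF` /
#'   `cl2OF` / `cl3OF` (conversions with model-optimal flanks).
#'
#' Fragment lengths (300/250/130, total 680) sit inside the 200-680 bp range
#' of the enhancer fragments this family emulates. The manifest records all
#' engineered feature coordinates and agrees with [scanCores()] output on
#' the generated sequences; byte-identical regeneration from (version, seed)
#' is guaranteed.
#'
#' @param seed Integer seed.
#' @param registry Hox registry.
#' @param models Per-factor models used to derive the variant constructs;
#'   defaults to [defaultHoxModels()].
#' @return A list of class `"FixtureSuite"`: `sequences` (named character),
#'   `plans` (the [EditPlan-class]s that produced the variants), `manifest`
#'   (data.frame: sequence, feature, start, end, strand), `seed`, `version`.
#' @export
makeFixtureSuite <- function(seed = 1L, registry = hoxRegistry(),
                             models = defaultHoxModels(registry)) {
  forbid <- .allForbidden(registry)
  mid <- paste0("C", .DUAL_CORE, "TGT")

  .withSeed(seed, {
    cassette <- s1 <- s2 <- s3 <- NULL
    for (attempt in 1:200) {
      s1try <- randomBackground(300L, 0.5, forbid)
      pad1 <- randomBackground(.CASSETTE_PAD, 0.5, forbid)
      pad2 <- randomBackground(.CASSETTE_PAD, 0.5, forbid)
      cass <- paste0(pad1, mid, pad2)
      s2bg <- randomBackground(195L, 0.5, forbid)
      s2rest <- s2bg
      for (o in c(40L, 100L, 160L))
        s2rest <- plantSite(s2rest, "GATTATA", o)
      s3try <- randomBackground(130L, 0.5, forbid)
      for (o in c(20L, 60L, 100L))
        s3try <- plantSite(s3try, "GTAATC", o)

      expCass <- .expectedCassetteHits()
      expS2 <- rbind(expCass,
                     do.call(rbind, lapply(c(40L, 100L, 160L), function(o)
                       .expectedInsertHits("GATTATA", o + 55L))))
      expS3 <- do.call(rbind, lapply(c(20L, 60L, 100L), function(o)
        .expectedInsertHits("GTAATC", o)))
      s2try <- paste0(cass, s2rest)
      vvlTry <- paste0(s1try, s2try, s3try)
      expVvl <- rbind(.shiftHits(expS2, 300L), .shiftHits(expS3, 550L))
      s1p55Try <- paste0(s1try, cass)

      ok <- .hitsMatch(s1try, expCass[0, ], registry) &&
        .hitsMatch(cass, expCass, registry) &&
        .hitsMatch(s2try, expS2, registry) &&
        .hitsMatch(s3try, expS3, registry) &&
        .hitsMatch(vvlTry, expVvl, registry) &&
        .hitsMatch(s1p55Try, .shiftHits(expCass, 300L), registry)
      if (ok) {
        s1 <- s1try; cassette <- cass; s2 <- s2try; s3 <- s3try
        break
      }
    }
    if (is.null(s1))
      stop("generation error: could not assemble a conforming fixture ",
           "suite in 200 attempts", call. = FALSE)

    s1p55 <- paste0(s1, cassette)
    vvl <- paste0(s1, s2, s3)

    # Variant constructs via the designer operations, anchored on the main
    # class 2 site of S1p55.
    mainSite <- scanSites(s1p55, models$Dfd$dimer, threshold = 0.05,
                          registry = registry)[1L, ]
    planCl3 <- convertClass(s1p55, mainSite, "class3", registry = registry)
    planCl1 <- convertClass(s1p55, mainSite, "class1", registry = registry)
    planMut <- knockoutSites(s1p55, mode = "core", registry = registry)
    cl3 <- applyEditPlan(s1p55, planCl3)
    cl1 <- applyEditPlan(s1p55, planCl1)
    mut <- applyEditPlan(s1p55, planMut)
    planCl2OF <- optimizeFlanks(s1p55, mainSite, models$Dfd$dimer,
                                registry = registry)
    cl2OF <- applyEditPlan(s1p55, planCl2OF)
    cl1Site <- scanSites(cl1, models$Lab$dimer, threshold = 0.05,
                         registry = registry)[1L, ]
    planCl1OF <- optimizeFlanks(cl1, cl1Site, models$Lab$dimer,
                                registry = registry)
    cl1OF <- applyEditPlan(cl1, planCl1OF)
    cl3Site <- scanSites(cl3, models$Ubx$dimer, threshold = 0.05,
                         registry = registry)[1L, ]
    planCl3OF <- optimizeFlanks(cl3, cl3Site, models$Ubx$dimer,
                                registry = registry)
    cl3OF <- applyEditPlan(cl3, planCl3OF)

    p <- .CASSETTE_MAIN
    manifest <- rbind(
      data.frame(sequence = "cassette", feature = c("main_core",
                 "overlapping_core"), start = c(p, p + 7L),
                 end = c(p + 8L, p + 15L), strand = "+",
                 stringsAsFactors = FALSE),
      data.frame(sequence = "S1p55",
                 feature = c("cassette", "main_core", "overlapping_core"),
                 start = c(300L, 300L + p, 300L + p + 7L),
                 end = c(355L, 300L + p + 8L, 300L + p + 15L),
                 strand = "+", stringsAsFactors = FALSE),
      data.frame(sequence = "S2",
                 feature = c("main_core", "overlapping_core",
                             rep("abdb_monomer", 3L)),
                 start = c(p, p + 7L, 55L + c(40L, 100L, 160L) + 2L),
                 end = c(p + 8L, p + 15L, 55L + c(40L, 100L, 160L) + 6L),
                 strand = "+", stringsAsFactors = FALSE),
      data.frame(sequence = "S3", feature = rep("generic_monomer", 3L),
                 start = c(20L, 60L, 100L) + 1L,
                 end = c(20L, 60L, 100L) + 5L, strand = "+",
                 stringsAsFactors = FALSE),
      data.frame(sequence = "vvl",
                 feature = c("cassette", "main_core", "overlapping_core",
                             rep("abdb_monomer", 3L),
                             rep("generic_monomer", 3L)),
                 start = c(300L, 300L + p, 300L + p + 7L,
                           355L + c(40L, 100L, 160L) + 2L,
                           550L + c(20L, 60L, 100L) + 1L),
                 end = c(355L, 300L + p + 8L, 300L + p + 15L,
                         355L + c(40L, 100L, 160L) + 6L,
                         550L + c(20L, 60L, 100L) + 5L),
                 strand = "+", stringsAsFactors = FALSE))

    structure(list(
      sequences = c(S1 = s1, cassette = cassette, S2 = s2, S3 = s3,
                    S1p55 = s1p55, vvl = vvl,
                    S1p55_cl1 = cl1, S1p55_cl2 = s1p55, S1p55_cl3 = cl3,
                    S1p55_mut = mut, S1p55_cl1OF = cl1OF,
                    S1p55_cl2OF = cl2OF, S1p55_cl3OF = cl3OF),
      plans = list(cl1 = planCl1, cl3 = planCl3, mut = planMut,
                   cl1OF = planCl1OF, cl2OF = planCl2OF, cl3OF = planCl3OF),
      manifest = manifest,
      seed = seed,
      version = "1"), class = "FixtureSuite")
  })
}

#' @export
print.FixtureSuite <- function(x, ...) {
  cat("FixtureSuite v", x$version, " (seed ", x$seed, "): ",
      length(x$sequences), " sequences\n", sep = "")
  cat(paste0("  ", format(names(x$sequences), width = 12), " ",
             nchar(x$sequences), " bp", collapse = "\n"), "\n")
  invisible(x)
}

#' Noisy pseudo-measurements of window binding
#'
#' Multiplicative lognormal noise around the true window affinities of a
#' model, standing in for quantified relative band intensities. The noise
#' has unit mean and the requested coefficient of variation; `cv = 0`
#' returns the exact affinities. Reproducible for a fixed seed.
#'
#' @param model An [EnergyModel-class].
#' @param windows Character vector of footprint-length windows.
#' @param cv Coefficient of variation, >= 0.
#' @param seed Optional integer seed.
#' @return Numeric vector of pseudo-measured relative binding values.
#' @export
noisyMeasurements <- function(model, windows, cv = 0, seed = NULL) {
  if (cv < 0) stop("'cv' must be >= 0", call. = FALSE)
  true <- windowAffinity(model, windows)
  if (cv == 0) return(true)
  sigma <- sqrt(log1p(cv^2))
  .withSeed(seed,
            true * rlnorm(length(true), meanlog = -sigma^2 / 2,
                          sdlog = sigma))
}

#' Recover model penalties from noisy window measurements
#'
#' Linear regression of `-log(measurement)` on per-position base indicator
#' variables. Because log affinity is additive over positions, the
#' coefficient for base b at position i estimates the penalty contrast
#' `penalty[i, b] - penalty[i, A]` (base A is the reference level). Used to
#' verify that synthetic-model penalties are recoverable from noisy
#' pseudo-measurements.
#'
#' @param windows Character vector of equal-length windows.
#' @param measurements Positive measurements, one per window.
#' @return data.frame with `position` (0-based), `base`, `estimate`, `se`
#'   for every non-reference base at every position.
#' @export
recoverModelPenalties <- function(windows, measurements) {
  if (length(windows) != length(measurements))
    stop("windows and measurements must have equal length", call. = FALSE)
  if (any(measurements <= 0))
    stop("measurements must be positive", call. = FALSE)
  L <- unique(nchar(windows))
  if (length(L) != 1L)
    stop("all windows must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(windows), ""))
  df <- as.data.frame(lapply(seq_len(L), function(i)
    factor(mat[, i], levels = .DNA_BASES)))
  names(df) <- paste0("p", seq_len(L))
  df$y <- -log(measurements)
  fit <- lm(y ~ ., data = df)
  cf <- summary(fit)$coefficients
  keep <- grepl("^p[0-9]+", rownames(cf))
  nm <- rownames(cf)[keep]
  data.frame(
    position = as.integer(sub("^p([0-9]+).*$", "\\1", nm)) - 1L,
    base = sub("^p[0-9]+", "", nm),
    estimate = cf[keep, "Estimate"],
    se = cf[keep, "Std. Error"],
    row.names = NULL)
}
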