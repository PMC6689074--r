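# Shared fixtures and independent oracles for the test suite. The oracles
# deliberately avoid the package's scanning code paths: reverse complements
# are built by hand and windows are scored one by one from the penalty
# matrix.

test_registry <- hoxRegistry()
test_models <- defaultHoxModels(test_registry)
test_suite <- makeFixtureSuite(seed = 1, registry = test_registry,
                               models = test_models)

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

oracle_window_affinity <- function(model, window) {
  chars <- strsplit(window, "")[[1L]]
  pen <- penalties(model)
  total <- 0
  for (i in seq_along(chars)) total <- total + pen[i, chars[i]]
  exp(-total) / normMax(model)
}

# Exhaustive both-strand enumeration of every window, scored independently,
# with the package's documented ranking applied afterwards.
oracle_scan <- function(sequence, model, threshold) {
  L <- footprint(model)
  n <- nchar(sequence)
  rows <- list()
  for (s0 in 0:(n - L)) {
    sub <- substring(sequence, s0 + 1L, s0 + L)
    for (strand in c("+", "-")) {
      w <- if (strand == "+") sub else oracle_revcomp(sub)
      aff <- oracle_window_affinity(model, w)
      if (aff >= threshold && aff > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          start = s0, end = s0 + L, strand = strand, window = w,
          affinity = aff, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), window = character(0),
                      affinity = numeric(0)))
  df <- do.call(rbind, rows)
  df <- df[order(-df$affinity, df$start, match(df$strand, c("+", "-"))), ]
  rownames(df) <- NULL
  df
}

# A random anchored model for property tests.
random_model <- function(L = 8L, maxPenalty = 2) {
  pen <- matrix(runif(L * 4L, 0, maxPenalty), nrow = L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  pen <- pen - apply(pen, 1L, min)
  energyModel(name = "random", mode = "dimer", penalties = pen)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force Kendall tau (no ties): pair counting.
oracle_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / choose(n, 2)
}
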