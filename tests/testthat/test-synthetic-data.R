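test_that("random backgrounds are reproducible and respect constraints", {
  a <- randomBackground(120L, 0.5, seed = 5L)
  b <- randomBackground(120L, 0.5, seed = 5L)
  expect_identical(a, b)
  expect_identical(nchar(a), 120L)
  clean <- randomBackground(200L, 0.5, forbid = unname(classCores()),
                            seed = 6L)
  expect_identical(nrow(scanCores(clean)), 0L)
  atOnly <- randomBackground(50L, gc = 0, seed = 7L)
  expect_false(grepl("[GC]", atOnly))
})

test_that("plantSite places inserts on either strand, length-preserving", {
  planted <- plantSite(strrep("C", 16L), "TGATTAAT", 4L)
  expect_identical(nchar(planted), 16L)
  expect_identical(classifyWindow(substring(planted, 5L, 12L)), "class2")
  minus <- plantSite(strrep("C", 16L), "TGATTAAT", 4L, strand = "-")
  m <- modelFromCore("TGATTAAT",
                     architecture = siteArchitecture("TGATTAAT", 0L, 0L))
  hit <- scanSites(minus, m, threshold = 0.5)
  expect_identical(hit$strand, "-")
  expect_identical(hit$start, 4L)
  # overlapping plants reproduce the dual-core geometry
  dual <- plantSite(plantSite(strrep("C", 15L), "TGATTAAT", 0L),
                    "TGATTTAT", 7L)
  expect_identical(dual, "TGATTAATGATTTAT")
  expect_error(plantSite("ACGT", "TGATTAAT", 2L), "fit")
})

test_that("the fixture suite satisfies its structural invariants", {
  s <- test_suite$sequences
  expect_identical(nchar(s[["cassette"]]), 55L)
  expect_identical(nchar(s[["S1"]]), 300L)
  expect_identical(nchar(s[["S2"]]), 250L)
  expect_identical(nchar(s[["S3"]]), 130L)
  expect_identical(nchar(s[["vvl"]]), 680L)
  # fragments sit inside the 200-680 bp family range
  expect_true(all(nchar(s[c("S1", "S2", "vvl")]) >= 200L))
  expect_true(all(nchar(s) <= 680L))

  # cassette: exactly one class 2 and one class 3 core, mutually overlapping
  cores <- scanCores(s[["cassette"]])
  expect_identical(nrow(cores), 2L)
  expect_setequal(cores$label, c("class2", "class3"))
  ov <- findSiteOverlaps(cores[cores$label == "class2", ],
                         cores[cores$label == "class3", ])
  expect_gte(ov$shared_bp, 1L)

  # the S1-like fragment is inert: no class core on either strand
  expect_identical(nrow(scanCores(s[["S1"]])), 0L)
  # and no monomer core either (rejection-sampled)
  expect_identical(nrow(scanCores(s[["S1"]], monomers = TRUE)), 0L)
})

test_that("the manifest agrees with scanner output on every fixture", {
  man <- test_suite$manifest
  for (seqname in unique(man$sequence)) {
    seqs <- test_suite$sequences[[seqname]]
    hits <- scanCores(seqs, monomers = TRUE)
    rows <- man[man$sequence == seqname & man$feature != "cassette", ]
    for (i in seq_len(nrow(rows))) {
      match <- hits[hits$start == rows$start[i] &
                    hits$strand == rows$strand[i], ]
      expect_gte(nrow(match), 1L)
    }
    # the two engineered class cores are the only class cores anywhere
    classHits <- hits[grepl("^class", hits$label), ]
    expected <- rows[rows$feature %in% c("main_core", "overlapping_core"), ]
    expect_identical(nrow(classHits), nrow(expected))
  }
})

test_that("fixtures regenerate byte-identically from (version, seed)", {
  again <- makeFixtureSuite(seed = 1, registry = test_registry,
                            models = test_models)
  expect_identical(again$sequences, test_suite$sequences)
  expect_identical(again$manifest, test_suite$manifest)
  expect_identical(again$version, test_suite$version)
  different <- makeFixtureSuite(seed = 2, registry = test_registry,
                                models = test_models)
  expect_false(identical(different$sequences[["S1"]],
                         test_suite$sequences[["S1"]]))
})

test_that("variant constructs differ from the base as designed", {
  s <- test_suite$sequences
  base <- s[["S1p55"]]
  hamming <- function(a, b)
    sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  expect_identical(s[["S1p55_cl2"]], base)
  expect_identical(hamming(s[["S1p55_cl3"]], base), 1L)
  expect_identical(hamming(s[["S1p55_cl1"]], base), 1L)
  expect_identical(hamming(s[["S1p55_mut"]], base), 1L)
  # mut carries no registered class core anywhere (cassette included)
  expect_identical(nrow(scanCores(s[["S1p55_mut"]])), 0L)
  # OF variants keep their class core and reach affinity 1 for their model
  expect_equal(max(affinityProfile(s[["S1p55_cl2OF"]],
                                   test_models$Dfd$dimer)$affinity), 1.0)
  expect_equal(max(affinityProfile(s[["S1p55_cl1OF"]],
                                   test_models$Lab$dimer)$affinity), 1.0)
  expect_equal(max(affinityProfile(s[["S1p55_cl3OF"]],
                                   test_models$Ubx$dimer)$affinity), 1.0)
})

test_that("pseudo-measurements are exact at cv 0 and noisy above", {
  m <- test_models$Ubx$dimer
  windows <- c("CTGATTTATGCC", "CTGATTTATGAT", "ATGATTTATGCC")
  expect_identical(noisyMeasurements(m, windows, cv = 0),
                   windowAffinity(m, windows))
  n1 <- noisyMeasurements(m, windows, cv = 0.3, seed = 9L)
  n2 <- noisyMeasurements(m, windows, cv = 0.3, seed = 9L)
  expect_identical(n1, n2)
  expect_false(identical(n1, windowAffinity(m, windows)))
})

test_that("low-cv noise keeps a 2-fold affinity ladder perfectly ranked", {
  # 7 windows spanning a 64-fold range; at cv 0.05 the ranking must be
  # preserved in at least 95% of 200 seeded replicates
  m <- modelFromCore("TAAT", architecture = siteArchitecture("TAAT", 1L, 1L),
                     corePenalty = log(2), flankPenalty = log(2),
                     flankOptimal = c("A", "A"))
  # 0..6 mismatches against the optimal window ATAATA, each costing ln 2
  windows <- c("ATAATA", "CTAATA", "CTAATC", "CGAATC", "CGCATC",
               "CGCCTC", "CGCCGC")
  pred <- windowAffinity(m, windows)
  expect_identical(anyDuplicated(pred), 0L)
  expect_gte(max(pred) / min(pred), 10)
  hits <- vapply(1:200, function(i) {
    meas <- noisyMeasurements(m, windows, cv = 0.05, seed = 1000L + i)
    rankConcordance(pred, measured = meas) == 1
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
  # heavy noise degrades the ranking
  heavy <- vapply(1:50, function(i) {
    meas <- noisyMeasurements(m, windows, cv = 2, seed = 2000L + i)
    rankConcordance(pred, measured = meas)
  }, numeric(1L))
  expect_lt(mean(heavy), 1)
})

test_that("penalties are recoverable from 500 noisy windows at cv 0.1", {
  set.seed(20190809 %% 10000L)
  pen <- matrix(runif(24L, 0, 1.5), nrow = 6L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  pen <- pen - apply(pen, 1L, min)
  m <- energyModel("recovery", mode = "monomer", penalties = pen)
  windows <- vapply(1:500, function(i) random_dna(6L), character(1L))
  meas <- noisyMeasurements(m, windows, cv = 0.1)
  est <- recoverModelPenalties(windows, meas)
  truth <- apply(est, 1L, function(r) {
    pen[as.integer(r[["position"]]) + 1L, r[["base"]]] -
      pen[as.integer(r[["position"]]) + 1L, "A"]
  })
  z <- abs(est$estimate - truth) / est$se
  expect_true(all(z <= 3))
})
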