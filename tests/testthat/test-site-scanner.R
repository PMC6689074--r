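core_only <- function(core) {
  modelFromCore(core, architecture = siteArchitecture(core, 0L, 0L),
                corePenalty = log(10))
}

test_that("a planted core is called once, on the right strand", {
  seqs <- paste0("CCCC", "TGATTAAT", "CCCC")
  sites <- scanSites(seqs, core_only("TGATTAAT"), threshold = 0.5)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$start, 4L)
  expect_identical(sites$end, 12L)
  expect_identical(sites$strand, "+")
  expect_equal(sites$affinity, 1.0)
  expect_identical(sites$class_label, "class2")
  # thresholds above the attainable maximum give an empty list
  expect_identical(nrow(scanSites(seqs, core_only("TGATTAAT"),
                                  threshold = 1.1)), 0L)
})

test_that("minus-strand cores are reported with plus-strand coordinates", {
  seqs <- paste0("CC", "ATAAATCA", "CC")  # revcomp(TGATTTAT) planted at 2
  sites <- scanSites(seqs, core_only("TGATTTAT"), threshold = 0.5)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$start, 2L)
  expect_identical(sites$strand, "-")
  expect_identical(sites$window, "TGATTTAT")
  expect_identical(sites$class_label, "class3")
})

test_that("sequences shorter than the footprint scan to an empty list", {
  expect_message(sites <- scanSites("ACGT", core_only("TGATTAAT")),
                 "shorter")
  expect_identical(nrow(sites), 0L)
})

test_that("scan equals exhaustive both-strand enumeration", {
  set.seed(21)
  for (rep in 1:20) {
    m <- random_model(L = sample(4:10, 1L))
    seqs <- random_dna(sample(footprint(m):200, 1L))
    thr <- runif(1L, 0, 0.5)
    got <- scanSites(seqs, m, threshold = thr)
    exp <- oracle_scan(seqs, m, thr)
    expect_identical(nrow(got), nrow(exp))
    expect_identical(got$start, exp$start)
    expect_identical(got$strand, exp$strand)
    expect_identical(got$window, exp$window)
    expect_equal(got$affinity, exp$affinity, tolerance = 1e-12)
  }
})

test_that("scanning the reverse complement mirrors the site list", {
  set.seed(22)
  for (rep in 1:10) {
    m <- random_model(L = 6L)
    seqs <- random_dna(80L)
    fwd <- scanSites(seqs, m, threshold = 0.1)
    rev <- scanSites(oracle_revcomp(seqs), m, threshold = 0.1)
    expect_identical(nrow(fwd), nrow(rev))
    key <- function(df, n) {
      k <- paste(n - df$end, n - df$start, ifelse(df$strand == "+", "-", "+"),
                 signif(df$affinity, 12))
      sort(k)
    }
    expect_identical(key(rev, nchar(seqs)),
                     sort(paste(fwd$start, fwd$end, fwd$strand,
                                signif(fwd$affinity, 12))))
  }
})

test_that("raising the threshold only removes sites", {
  set.seed(23)
  m <- random_model(L = 8L)
  seqs <- random_dna(150L)
  loose <- scanSites(seqs, m, threshold = 0.05)
  tight <- scanSites(seqs, m, threshold = 0.3)
  keyL <- paste(loose$start, loose$strand)
  keyT <- paste(tight$start, tight$strand)
  expect_true(all(keyT %in% keyL))
  expect_true(all(tight$affinity >= 0.3))
})

test_that("the profile is the per-start strand maximum, consistent with scan", {
  set.seed(24)
  m <- random_model(L = 6L)
  seqs <- random_dna(100L)
  prof <- affinityProfile(seqs, m)
  expect_identical(nrow(prof), 95L)
  all_sites <- scanSites(seqs, m, threshold = 0)
  expect_equal(max(prof$affinity), max(all_sites$affinity))
  # per start the profile is the better of the two strands
  for (s0 in c(0L, 40L, 94L)) {
    both <- all_sites$affinity[all_sites$start == s0]
    expect_equal(prof$affinity[prof$start == s0], max(both))
  }
})

test_that("a uniform model gives a flat profile; a planted site gives a peak", {
  flat <- energyModel("flat", mode = "monomer",
                      penalties = matrix(0, 4L, 4L,
                                         dimnames = list(NULL,
                                                         c("A", "C", "G", "T"))))
  prof <- affinityProfile(strrep("A", 30L), flat)
  expect_true(all(prof$affinity == 1))
  m <- core_only("TGATTAAT")
  planted <- plantSite(strrep("C", 40L), "TGATTAAT", 16L)
  prof2 <- affinityProfile(planted, m)
  expect_identical(prof2$start[which.max(prof2$affinity)], 16L)
})

test_that("interval overlap follows half-open arithmetic", {
  a <- data.frame(start = 10L, end = 22L)
  b <- data.frame(start = 14L, end = 26L)
  ov <- findSiteOverlaps(a, b, minSharedBp = 1L)
  expect_identical(nrow(ov), 1L)
  expect_identical(ov$shared_bp, 8L)
  expect_identical(ov$shared_start, 14L)
  expect_identical(ov$shared_end, 22L)
  # abutting half-open intervals do not overlap
  expect_identical(nrow(findSiteOverlaps(data.frame(start = 0L, end = 12L),
                                         data.frame(start = 12L, end = 24L))),
                   0L)
  # swap symmetry
  ov2 <- findSiteOverlaps(b, a)
  expect_identical(ov2$shared_bp, ov$shared_bp)
})

test_that("the dual-core geometry shares exactly one base pair", {
  cores <- scanCores("TGATTAATGATTTAT")
  expect_identical(cores$label, c("class2", "class3"))
  expect_identical(cores$kmer, c("TGATTAAT", "TGATTTAT"))
  expect_identical(cores$start, c(0L, 7L))
  ov <- findSiteOverlaps(cores[1L, ], cores[2L, ], minSharedBp = 1L)
  expect_identical(ov$shared_bp, 1L)
  expect_identical(ov$shared_start, 7L)
})

test_that("scanCores sees both strands and optionally monomer cores", {
  seqs <- paste0("CC", "ATTAATCA", "CC")  # minus-strand class2 core at 2
  hits <- scanCores(seqs)
  expect_identical(hits$kmer, "TGATTAAT")
  expect_identical(hits$strand, "-")
  expect_identical(hits$start, 2L)
  withMono <- scanCores(paste0("GG", "TAAT", "GG"), monomers = TRUE)
  expect_true("monomer" %in% withMono$label)
})

test_that("siteGRanges converts to 1-based closed Bioconductor ranges", {
  sites <- scanSites(paste0("CCCC", "TGATTAAT", "CCCC"),
                     core_only("TGATTAAT"), threshold = 0.5)
  gr <- siteGRanges(sites, "fixture")
  expect_s4_class(gr, "GRanges")
  expect_identical(GenomicRanges::start(gr), 5L)
  expect_identical(GenomicRanges::end(gr), 12L)
})
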