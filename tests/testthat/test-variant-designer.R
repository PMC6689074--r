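dfd_dimer <- test_models$Dfd$dimer

site_on <- function(seqs, model = dfd_dimer, thr = 0.01) {
  scanSites(seqs, model, threshold = thr)[1L, ]
}

test_that("class conversion is a certified single-base core edit", {
  seqs <- paste0("CCCC", "CTGATTAATAAA", "CCCC")
  site <- site_on(seqs)
  to3 <- convertClass(seqs, site, "class3")
  expect_identical(nEdits(to3), 1L)
  s <- substitutions(to3)
  expect_identical(s$pos, site$start + 1L + 5L)  # core index 5 in the window
  expect_identical(s$ref, "A"); expect_identical(s$alt, "T")
  to1 <- convertClass(seqs, site, "class1")
  expect_identical(substitutions(to1)$alt, "G")
  expect_identical(nEdits(convertClass(seqs, site, "class2")), 0L)
  # edit count equals the Hamming distance of the printed cores
  expect_identical(nEdits(to3),
                   sum(strsplit(classCore("class2"), "")[[1L]] !=
                       strsplit(classCore("class3"), "")[[1L]]))
})

test_that("conversion round trip restores the original sequence", {
  seqs <- paste0("GG", "CTGATTAATAAA", "GG")
  site <- site_on(seqs)
  as1 <- applyEditPlan(seqs, convertClass(seqs, site, "class1"))
  site1 <- site_on(as1, test_models$Lab$dimer)
  back <- applyEditPlan(as1, convertClass(as1, site1, "class2"))
  expect_identical(back, seqs)
})

test_that("minus-strand sites convert through plus-strand edits", {
  seqs <- paste0("GG", oracle_revcomp("CTGATTAATAAA"), "GG")
  site <- site_on(seqs)
  expect_identical(site$strand, "-")
  plan <- convertClass(seqs, site, "class3")
  expect_identical(nEdits(plan), 1L)
  edited <- applyEditPlan(seqs, plan)
  newSite <- site_on(edited, test_models$Ubx$dimer)
  expect_identical(newSite$class_label, "class3")
  expect_identical(newSite$strand, "-")
})

test_that("flank optimization attains the core-constrained optimum exactly", {
  arch <- siteArchitecture("TGATTAAT", 1L, 3L)
  m <- modelFromCore("TGATTAAT", arch, corePenalty = log(10),
                     flankPenalty = 0.5, flankOptimal = c("A", "A", "A", "A"))
  seqs <- paste0("GGGG", "CTGATTAATAAA", "GGGG")  # left flank C, pen 0.5
  site <- site_on(seqs, m)
  pre <- site$affinity
  plan <- optimizeFlanks(seqs, site, m)
  expect_identical(nEdits(plan), 1L)
  expect_identical(substitutions(plan)$ref, "C")
  expect_identical(substitutions(plan)$alt, "A")
  post <- site_on(applyEditPlan(seqs, plan), m)$affinity
  expect_equal(post, pre * exp(0.5))
  expect_equal(post, 1.0)
  # already-optimal flanks: empty plan
  expect_identical(nEdits(optimizeFlanks(applyEditPlan(seqs, plan),
                                         site_on(applyEditPlan(seqs, plan), m),
                                         m)), 0L)
})

test_that("flank optimization never touches core positions", {
  set.seed(31)
  for (rep in 1:10) {
    flanks <- sample(c("A", "C", "G", "T"), 4L, replace = TRUE)
    m <- modelFromCore("TGATTAAT", corePenalty = log(10),
                       flankPenalty = runif(4L, 0.1, 1),
                       flankOptimal = flanks)
    seqs <- paste0(random_dna(6L), "ATGATTAATCGT", random_dna(6L))
    site <- scanSites(seqs, m, threshold = 0.001)
    site <- site[site$class_label %in% "class2", ][1L, ]
    plan <- optimizeFlanks(seqs, site, m)
    corePos <- site$start + 1L + 0:7  # plus-strand site: core window pos 1-8
    expect_length(intersect(substitutions(plan)$pos, corePos), 0L)
    expect_equal(site_on(applyEditPlan(seqs, plan), m, 0.001)$affinity, 1.0)
  }
})

test_that("single planted core knocks out with one certified edit", {
  seqs <- plantSite(strrep("C", 30L), "TGATTAAT", 10L)
  plan <- knockoutSites(seqs, mode = "core")
  expect_identical(nEdits(plan), 1L)
  expect_true(planProvenance(plan)$params$certified)
  after <- applyEditPlan(seqs, plan)
  expect_identical(nrow(scanCores(after)), 0L)
})

test_that("the shared base of overlapping cores allows a dual knockout", {
  seqs <- paste0("CCCC", "TGATTAATGATTTAT", "CCCC")
  plan <- knockoutSites(seqs, mode = "core")
  expect_identical(nEdits(plan), 1L)
  s <- substitutions(plan)
  expect_identical(s$pos, 11L)   # the 1-bp overlap of the two cores
  after <- applyEditPlan(seqs, plan)
  expect_identical(nrow(scanCores(after)), 0L)
  # certified: no 0-edit plan existed, and no new core was created
  expect_true(planProvenance(plan)$params$certified)
})

test_that("a sequence with no forbidden core yields an empty plan", {
  plan <- knockoutSites(strrep("C", 40L), mode = "core")
  expect_identical(nEdits(plan), 0L)
  expect_true(isEmpty(predictedEffects(plan)))
})

test_that("affinity-ceiling knockout drives all windows below the bound", {
  m <- test_models$Dfd$dimer
  seqs <- paste0("CCCC", "CTGATTAATGCC", "CCCC")  # optimal-flank site
  plan <- knockoutSites(seqs, models = list(m), mode = "affinity",
                        ceiling = 0.05)
  after <- applyEditPlan(seqs, plan)
  expect_identical(nrow(scanSites(after, m, threshold = 0.05)), 0L)
  expect_gt(nEdits(plan), 0L)
})

test_that("greedy knockout matches the certified exhaustive minimum", {
  set.seed(32)
  cores <- classCores()
  for (rep in 1:8) {
    seqs <- randomBackground(sample(25:40, 1L), 0.5,
                             forbid = unname(cores))
    n1 <- sample(cores, 1L)
    seqs <- plantSite(seqs, n1, 2L)
    if (rep %% 2 == 0)
      seqs <- plantSite(seqs, sample(cores, 1L), 14L)
    exh <- knockoutSites(seqs, mode = "core")
    grd <- knockoutSites(seqs, mode = "core", certifyLen = 0L)
    expect_true(planProvenance(exh)$params$certified)
    expect_false(planProvenance(grd)$params$certified)
    expect_gte(nEdits(grd), nEdits(exh))
    expect_identical(nEdits(grd), nEdits(exh))
    for (p in list(exh, grd))
      expect_identical(nrow(scanCores(applyEditPlan(seqs, p))), 0L)
  }
})

test_that("restore returns the original inside regions, current elsewhere", {
  orig <- "AAAACCCCGGGGTTTT"
  curr <- "TTTTCCCCAAAAGGGG"
  expect_identical(restoreRegions(curr, orig, list(c(0L, 16L))), orig)
  expect_identical(restoreRegions(curr, orig, list()), curr)
  mix <- restoreRegions(curr, orig, list(c(0L, 4L), c(12L, 16L)))
  expect_identical(mix, "AAAACCCCAAAATTTT")
  expect_error(restoreRegions(curr, "AAAA", list(c(0L, 4L))), "equal length")
})

test_that("knockout then restore brings site affinity back exactly", {
  m <- dfd_dimer
  seqs <- paste0("GGGG", "CTGATTAATAAA", "GGGG")
  pre <- site_on(seqs, m)$affinity
  ko <- knockoutSites(seqs, mode = "core")
  mutated <- applyEditPlan(seqs, ko)
  restored <- restoreRegions(mutated, seqs, list(c(4L, 16L)))
  expect_identical(restored, seqs)
  expect_equal(site_on(restored, m)$affinity, pre)
})

test_that("identity edits audit empty; the class1 conversion artifact is caught", {
  seqs <- "CCTGATTAATTTATCC"
  expect_true(isEmpty(sideEffectAudit(seqs, seqs,
                                      models = list(dfd_dimer))))
  # class2 -> class1 core edit (window core index 5: A -> G)
  edited <- "CCTGATTGATTTATCC"
  audit <- sideEffectAudit(seqs, edited)
  cc <- coreChanges(audit)
  expect_identical(cc$lost$label, "class2")
  expect_identical(cc$lost$start, 2L)
  expect_setequal(cc$gained$label, c("class1", "class3"))
  g3 <- cc$gained[cc$gained$label == "class3", ]
  expect_identical(g3$kmer, "TGATTTAT")
  expect_identical(g3$start, 6L)
  expect_identical(g3$strand, "+")
})

test_that("designed plans carry a self-consistent predicted-effects audit", {
  for (nm in c("cl1", "cl3", "mut", "cl2OF")) {
    plan <- test_suite$plans[[nm]]
    before <- test_suite$sequences[["S1p55"]]
    if (nm %in% c("cl1OF")) next
    after <- applyEditPlan(before, plan)
    indep <- sideEffectAudit(before, after)
    expect_identical(coreChanges(predictedEffects(plan)),
                     coreChanges(indep))
  }
})

test_that("applying and reverting a plan is exact; foreign plans are refused", {
  seqs <- paste0("GG", "CTGATTAATAAA", "GG")
  site <- site_on(seqs)
  plan <- convertClass(seqs, site, "class3")
  edited <- applyEditPlan(seqs, plan)
  expect_identical(revertEditPlan(edited, plan), seqs)
  expect_error(applyEditPlan(strrep("G", 16L), plan), "reference base")
})

test_that("edit plans round trip through TSV and JSON", {
  seqs <- paste0("GG", "CTGATTAATAAA", "GG")
  plan <- convertClass(seqs, site_on(seqs), "class1")
  for (fmt in c("tsv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeEditPlan(plan, path, format = fmt)
    back <- readEditPlan(path, format = fmt)
    expect_identical(substitutions(back), substitutions(plan))
    expect_identical(applyEditPlan(seqs, back), applyEditPlan(seqs, plan))
  }
})
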