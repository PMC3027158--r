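test_that("generated genomes are deterministic in the seed", {
  cfg <- GenomeConfig(nChromosomes = 1, chromLength = 60000, nGenes = 8,
    seed = 5)
  g1 <- makeGenome(cfg)
  g2 <- makeGenome(cfg)
  expect_identical(as.character(genomeSeq(g1)), as.character(genomeSeq(g2)))
  expect_identical(as.data.frame(geneRanges(g1)), as.data.frame(geneRanges(g2)))
  expect_identical(as.data.frame(truthIslands(g1)), as.data.frame(truthIslands(g2)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeGenome(g1, d1)
  writeGenome(g2, d2)
  for (f in c("genome.fa", "genes.gff3", "truth_islands.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  g3 <- makeGenome(GenomeConfig(nChromosomes = 1, chromLength = 60000,
    nGenes = 8, seed = 6))
  expect_false(identical(as.character(genomeSeq(g1)),
    as.character(genomeSeq(g3))))
})

test_that("planted islands sit in their promoter windows and pass thresholds", {
  cfg <- GenomeConfig(nChromosomes = 1, chromLength = 200000, nGenes = 20,
    repeatFraction = 0, seed = 13)
  ga <- makeGenome(cfg)
  truth <- truthIslands(ga)
  expect_length(truth, 20L)
  win <- promoterWindows(ga)
  ov <- GenomicRanges::findOverlaps(truth, win, type = "within")
  keep <- truth$gene_id[S4Vectors::queryHits(ov)] ==
    win$gene_id[S4Vectors::subjectHits(ov)]
  expect_setequal(S4Vectors::queryHits(ov)[keep], seq_along(truth))
  # whole-span stats of every planted island pass the default criteria
  p <- CgiParams()
  expect_true(all(truth$gc >= p@gcMin))
  expect_true(all(truth$oe >= p@oeMin))
  expect_true(all(GenomicRanges::width(truth) >= p@minIslandLen))
})

test_that("infeasible gene packing fails loudly", {
  expect_error(
    makeGenome(GenomeConfig(nChromosomes = 1, chromLength = 10000,
      nGenes = 10, seed = 1)),
    "cannot place"
  )
})

test_that("background masking respects the configured repeat fraction", {
  cfg <- GenomeConfig(nChromosomes = 1, chromLength = 100000, nGenes = 5,
    repeatFraction = 0.15, seed = 21)
  ga <- makeGenome(cfg)
  ch <- strsplit(as.character(genomeSeq(ga))[[1]], "")[[1]]
  frac <- mean(ch %in% c("a", "c", "g", "t"))
  expect_gt(frac, 0.10)
  expect_lt(frac, 0.20)
  # islands stay unmasked
  for (i in seq_along(truthIslands(ga))) {
    tr <- truthIslands(ga)[i]
    span <- ch[GenomicRanges::start(tr):GenomicRanges::end(tr)]
    expect_true(all(span %in% c("A", "C", "G", "T")))
  }
})

test_that("methylation truth honors mixtures, effects and control overrides", {
  ids <- sprintf("r%02d", 1:30)
  groups <- c(
    stats::setNames(rep("control", 3), c("C1", "C2", "C3")),
    stats::setNames(rep("tumor", 3), c("T1", "T2", "T3")),
    P1 = "positive", N1 = "negative"
  )
  tr <- makeMethylation(ids, groups, baselineHighProb = 0.5, nHypo = 4,
    nHyper = 3, effectFold = 2.5, replicateSd = 0, seed = 2)
  m <- methLevels(tr)
  expect_true(all(m[, "P1"] == 1))
  expect_true(all(m[, "N1"] == 0))
  eff <- effectLedger(tr)
  expect_equal(sum(eff$direction == "hypo"), 4L)
  expect_equal(sum(eff$direction == "hyper"), 3L)
  expect_length(intersect(
    eff$region_id[eff$direction == "hypo"],
    eff$region_id[eff$direction == "hyper"]
  ), 0L)
  # with no effects, tumor and control means agree region by region
  tr0 <- makeMethylation(ids, groups, nHypo = 0, nHyper = 0,
    replicateSd = 0, seed = 2)
  m0 <- methLevels(tr0)
  expect_equal(m0[, "T1"], m0[, "C1"])
  # the odds-scale shift matches its closed form: 0.9 hypo by 2.5
  expect_equal(
    logitFoldShift(0.9, 2.5, "hypo"),
    0.9 / (0.9 + 2.5 * 0.1)
  )
  expect_equal(logitFoldShift(0.2, 3, "hyper"), 0.6 / (0.6 + 0.8))
  expect_equal(logitFoldShift(c(0, 1), 2, "hypo"), c(0, 1))
  expect_error(makeMethylation(ids, groups, nHypo = 20, nHyper = 15),
    "exceeds")
})

test_that("array simulation obeys the affine signal model", {
  st <- makeExampleStudy(nProbes = 60, nHypo = 5, nHyper = 2, nTumor = 3,
    nControl = 3, model = SignalModel(noiseCv = 0, affinitySigma = 0),
    seed = 4)
  cy5 <- SummarizedExperiment::assay(st$channels, "cy5")
  cy3 <- SummarizedExperiment::assay(st$channels, "cy3")
  model <- SignalModel()
  # negative control: uniform Cy5 = alpha for all probes
  expect_true(all(cy5[, "N1"] == model@alphaNonspecific))
  # positive/negative ratio = (alpha + beta) / alpha everywhere
  expect_equal(
    unname(cy5[, "P1"] / cy5[, "N1"]),
    rep((model@alphaNonspecific + model@betaEnrichment) /
      model@alphaNonspecific, 60L)
  )
  # calibration: truth is recoverable from noise-free ratios
  r <- cy5 / cy3
  mHat <- (r - model@alphaNonspecific) / model@betaEnrichment
  expect_equal(unname(mHat), unname(methLevels(st$truth)), tolerance = 1e-12)
  # presence flags follow the detection threshold ordering
  present <- SummarizedExperiment::assay(st$channels, "present")
  expect_false(any(present[, "N1"])) # alpha below threshold
  expect_true(all(present[, "P1"])) # alpha + beta above threshold
})

test_that("array simulation demands a complete probe-to-region mapping", {
  st <- makeExampleStudy(nProbes = 10, nHypo = 0, nHyper = 0, nTumor = 2,
    nControl = 2, seed = 4)
  pr <- probes(st$design)
  pr$island_id[3] <- "unmapped_region"
  badDesign <- buildDesign(pr)
  expect_error(simulateArray(badDesign, st$truth), "without a truth region")
})

test_that("simulated traces encode methylation and conversion as peak areas", {
  s <- strrep("CGAAT", 10) # 10 CpGs, no other C
  tr0 <- simulateTraces(s, m = 0, noiseSd = 0, conversionRate = 1, seed = 1)
  s0 <- traceSites(tr0)
  expect_true(all(s0$c_area[s0$site_type == "cpg"] == 0))
  tr1 <- simulateTraces(s, m = 1, noiseSd = 0, seed = 1)
  s1 <- traceSites(tr1)
  expect_true(all(s1$t_area[s1$site_type == "cpg"] == 0))
  tr5 <- simulateTraces(s, m = 0.5, noiseSd = 0, seed = 1)
  s5 <- traceSites(tr5)
  expect_equal(s5$c_area[s5$site_type == "cpg"],
    s5$t_area[s5$site_type == "cpg"])
  # non-CpG cytosines follow the conversion rate
  tr <- simulateTraces("CCGAT", m = 1, noiseSd = 0, conversionRate = 0.9,
    seed = 1)
  st <- traceSites(tr)
  nc <- st[st$site_type == "non_cpg_c", ]
  expect_equal(nc$t_area, 0.9)
  expect_equal(nc$c_area, 0.1, tolerance = 1e-12)
  # positions come in sequence order
  expect_false(is.unsorted(st$position, strictly = TRUE))
  expect_error(simulateTraces("ATTA", 0.5), "no CpG")
})

test_that("simulated HPLC profiles split the cytosine share correctly", {
  p0 <- simulateHplc(0, noiseSd = 0)
  expect_equal(peakAreas(p0)[["m5dC"]], 0)
  # 10 units of cytosine share at 10% methylation: dC = 9, 5mdC = 1
  p <- simulateHplc(10, totalArea = 50, noiseSd = 0, gcFractionGenome = 0.4)
  a <- peakAreas(p)
  expect_equal(a[["dC"]] + a[["m5dC"]], 10)
  expect_equal(a[["dC"]], 9)
  expect_equal(a[["m5dC"]], 1)
  expect_equal(a[["U"]], 0)
  pr <- simulateHplc(10, rnaContamination = TRUE)
  expect_gt(peakAreas(pr)[["U"]], 0)
})

test_that("channel tables round-trip through TSV", {
  st <- makeExampleStudy(nProbes = 25, nHypo = 2, nHyper = 1, nTumor = 2,
    nControl = 2, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeChannelTable(st$channels, f)
  ch2 <- readChannelTable(f)
  for (a in c("cy5", "cy3")) {
    expect_equal(
      SummarizedExperiment::assay(st$channels, a),
      SummarizedExperiment::assay(ch2, a),
      tolerance = 1e-6
    )
  }
  expect_equal(
    SummarizedExperiment::assay(st$channels, "present"),
    SummarizedExperiment::assay(ch2, "present")
  )
  expect_equal(sampleGroups(st$channels), sampleGroups(ch2))
})

test_that("trace tables round-trip through TSV", {
  traces <- list(
    simulateTraces(strrep("CGAAT", 5), 0.3, regionId = "rA", sampleId = "s1",
      group = "control", seed = 1),
    simulateTraces(strrep("CGAAT", 5), 0.8, regionId = "rA", sampleId = "s2",
      group = "tumor", seed = 2)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTraceTable(traces, f)
  back <- readTraceTable(f)
  expect_length(back, 2L)
  expect_equal(traceSites(back[[1]]), traceSites(traces[[1]]))
  expect_equal(back[[2]]@group, "tumor")
})
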