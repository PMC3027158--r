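test_that("ratio computation guards the reference channel", {
  groups <- c(C1 = "control", C2 = "control")
  cy5 <- matrix(c(100, 50, 30, 40), 2, 2,
    dimnames = list(c("p1", "p2"), names(groups)))
  cy3 <- matrix(c(50, 50, 0, 40), 2, 2, dimnames = dimnames(cy5))
  ch <- ChannelSet(cy5, cy3, present = cy5 > 0, groups = groups)
  r <- computeRatios(ch)
  expect_equal(r["p1", "C1"], 2)
  expect_equal(r["p2", "C2"], 1)
  expect_true(is.na(r["p1", "C2"])) # zero reference marked invalid
})

test_that("control-mean normalization leaves control means at exactly 1", {
  set.seed(1)
  groups <- c(
    stats::setNames(rep("control", 4), paste0("C", 1:4)),
    stats::setNames(rep("tumor", 4), paste0("T", 1:4)),
    P1 = "positive"
  )
  raw <- matrix(stats::rlnorm(9 * 200), 200, 9,
    dimnames = list(sprintf("p%03d", 1:200), names(groups)))
  nm <- normalizeToControl(raw, groups)
  ctrlMeans <- rowMeans(normalizedRatios(nm)[, paste0("C", 1:4)])
  expect_equal(unname(ctrlMeans), rep(1, 200))
  # a known fold survives: tumor 4 against control mean 2
  raw2 <- raw
  raw2[1, paste0("C", 1:4)] <- 2
  raw2[1, "T1"] <- 4
  nm2 <- normalizeToControl(raw2, groups)
  expect_equal(normalizedRatios(nm2)[1, "T1"], 2)
  # positive control samples are excluded from the reference mean
  raw3 <- raw2
  raw3[1, "P1"] <- 1e6
  nm3 <- normalizeToControl(raw3, groups)
  expect_equal(normalizedRatios(nm3)[1, "T1"], 2)
})

test_that("presence, intensity and sd filters remove with recorded reasons", {
  st <- smallStudy()
  groups <- sampleGroups(st$channels)
  cy5 <- SummarizedExperiment::assay(st$channels, "cy5")
  cy3 <- SummarizedExperiment::assay(st$channels, "cy3")
  present <- SummarizedExperiment::assay(st$channels, "present")
  # rig three probes for targeted failures
  present[1, ] <- c(rep(TRUE, 3), rep(FALSE, ncol(present) - 3)) # 3 present
  present[2, ] <- TRUE
  cy5[2, ] <- 24 # mean raw below 25
  present[3, ] <- TRUE
  cy5[3, ] <- 100
  bio <- names(groups)[groups %in% c("control", "tumor")]
  ch <- ChannelSet(cy5, cy3, present, groups)
  nm <- normalizeToControl(computeRatios(ch), groups)
  rat <- normalizedRatios(nm)
  rat[3, names(groups)[groups == "tumor"]] <- c(0.1, 6, 0.1, 6) # sd >> 1.4
  nm2 <- new("NormalizedMatrix", ratios = rat, rawRatios = rawRatios(nm),
    groups = groups, filterStatus = filterStatus(nm))
  fl <- filterProbes(nm2, ch)
  status <- filterStatus(fl)
  expect_equal(status$reason[1], "presence")
  expect_equal(status$reason[2], "intensity")
  expect_equal(status$reason[3], "sd")
  expect_false(any(status$retained[1:3]))
  # audit counts reconcile with the status table
  audit <- attr(status, "audit")
  expect_equal(sum(audit$removed), sum(!status$retained))
  # retained probes survive every rule
  kept <- status$probe_id[status$retained]
  expect_true(all(rowSums(present[kept, , drop = FALSE]) >= 4))
  expect_true(all(rowMeans(cy5[kept, bio, drop = FALSE]) >= 25))
})

test_that("the Welch test matches the closed-form oracle and t.test", {
  set.seed(2)
  for (i in 1:250) {
    a <- stats::rnorm(sample(2:8, 1), sd = stats::runif(1, 0.5, 2))
    b <- stats::rnorm(sample(2:8, 1), mean = stats::runif(1, -1, 1))
    w <- welchTest(a, b)
    o <- oracleWelch(a, b)
    expect_equal(w$t, o$t, tolerance = 1e-10)
    expect_equal(w$df, o$df, tolerance = 1e-10)
    expect_equal(w$p, o$p, tolerance = 1e-10)
    tt <- stats::t.test(a, b)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
    # antisymmetry
    w2 <- welchTest(b, a)
    expect_equal(w2$t, -w$t)
    expect_equal(w2$p, w$p)
  }
  # identical constant groups degenerate to t = 0, p = 1
  expect_equal(welchTest(c(1, 1), c(1, 1)), list(t = 0, df = 2, p = 1))
  w <- welchTest(1:4, 1:4)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  expect_error(welchTest(1, 1:3), "at least 2")
})

test_that("differential calling respects the joint fold and p thresholds", {
  st <- smallStudy()
  nm <- normalizeToControl(computeRatios(st$channels),
    sampleGroups(st$channels))
  fl <- filterProbes(nm, st$channels)
  dr <- differentialProbes(fl)
  hyper <- dr[dr$direction == "hyper", ]
  hypo <- dr[dr$direction == "hypo", ]
  expect_true(all(hyper$fc >= 1.5 & hyper$p < 0.05))
  expect_true(all(hypo$fc <= 1 / 1.5 & hypo$p < 0.05))
  expect_length(intersect(hyper$probe_id, hypo$probe_id), 0L)
  # a small fold with a tiny p stays non-significant
  expect_true(all(dr$direction[dr$fc > 1 / 1.4 & dr$fc < 1.4] == "ns"))
  expect_false(is.unsorted(dr$p))
  # row-wise statistics agree with the scalar Welch test
  rat <- normalizedRatios(fl)
  groups <- sampleGroups(fl)
  i <- match(dr$probe_id[1], rownames(rat))
  w <- welchTest(
    rat[i, names(groups)[groups == "tumor"]],
    rat[i, names(groups)[groups == "control"]]
  )
  expect_equal(dr$t[1], w$t, tolerance = 1e-12)
  expect_equal(dr$p[1], w$p, tolerance = 1e-12)
})

test_that("planted effects are recovered with correct directions", {
  st <- makeExampleStudy(nProbes = 2000, nHypo = 100, nHyper = 25, seed = 7)
  nm <- normalizeToControl(computeRatios(st$channels),
    sampleGroups(st$channels))
  fl <- filterProbes(nm, st$channels)
  dr <- differentialProbes(fl)
  eff <- effectLedger(st$truth)
  truthDir <- stats::setNames(eff$direction, paste0(eff$region_id, "_p01"))
  called <- dr[dr$direction != "ns", ]
  hit <- called$probe_id %in% names(truthDir)
  tp <- sum(hit & called$direction == truthDir[called$probe_id])
  expect_gte(tp / nrow(eff), 0.8)
  expect_lte(sum(!hit) / max(1L, nrow(called)), 0.1)
  expect_gt(sum(called$direction == "hypo"), sum(called$direction == "hyper"))
})

test_that("gene aggregation preserves probes with discordant directions", {
  dr <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    gene_ids = c("gA", "gA", "gB", "gB", "gC"),
    mean_tumor = 1, mean_control = 1,
    fc = c(0.5, 0.6, 0.4, 2.1, 1.1),
    t = 0, df = 6,
    p = c(0.01, 0.02, 0.01, 0.01, 0.5),
    direction = c("hypo", "hypo", "hypo", "hyper", "ns")
  )
  res <- probeToGene(dr)
  genes <- res$genes[order(res$genes$gene_id), ]
  expect_equal(genes$direction[genes$gene_id == "gA"], "hypo")
  expect_equal(genes$direction[genes$gene_id == "gB"], "mixed")
  expect_false("gC" %in% genes$gene_id) # no significant probe
  expect_equal(sum(res$probes$gene_id == "gB"), 2L) # both rows preserved
})

test_that("median classes include the two-fold boundaries", {
  x <- stats::setNames(c(1, 1, 1, 1, 4), paste0("g", 1:5))
  mc <- medianClasses(x)
  expect_equal(mc$median, 1)
  expect_equal(mc$higher, "g5")
  x2 <- stats::setNames(c(1, 1, 1, 1, 0.25), paste0("g", 1:5))
  expect_equal(medianClasses(x2)$lower, "g5")
  # all equal: both sets empty is impossible since boundaries are inclusive
  # of exact 2-fold; equal values sit at the median itself
  x3 <- stats::setNames(rep(3, 4), paste0("g", 1:4))
  mc3 <- medianClasses(x3)
  expect_length(mc3$higher, 0L)
  expect_length(mc3$lower, 0L)
  expect_error(medianClasses(c(g1 = 1)), "at least 2")
})

test_that("PCA scores match a direct eigendecomposition on a tiny case", {
  mat <- matrix(c(1, 2, 3, 1, 2.5, 2), nrow = 2, byrow = TRUE,
    dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  pc <- pcaScores(mat)
  x <- scale(t(mat), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x))
  scoresRef <- x %*% ev$vectors
  # compare up to sign per component
  for (j in 1:2) {
    expect_true(
      isTRUE(all.equal(unname(pc$scores[, j]), unname(scoresRef[, j]),
        tolerance = 1e-8)) ||
        isTRUE(all.equal(unname(pc$scores[, j]), -unname(scoresRef[, j]),
          tolerance = 1e-8))
    )
  }
  expect_equal(sum(pc$varExplained), 1, tolerance = 1e-12)
  # identical samples collapse to identical scores
  m2 <- matrix(c(1, 2, 1, 2), 2, 2,
    dimnames = list(c("p1", "p2"), c("s1", "s2")))
  pc2 <- pcaScores(m2)
  expect_equal(pc2$scores["s1", ], pc2$scores["s2", ])
  # sign convention is deterministic across calls
  expect_identical(pcaScores(mat)$scores, pc$scores)
})

test_that("four sample groups separate on the first two components", {
  st <- makeExampleStudy(nProbes = 2000, nHypo = 100, nHyper = 20,
    nTumor = 4, nControl = 4, seed = 303)
  nm <- normalizeToControl(computeRatios(st$channels),
    sampleGroups(st$channels))
  fl <- filterProbes(nm, st$channels)
  dr <- differentialProbes(fl)
  sig <- dr$probe_id[dr$direction != "ns"]
  pc <- pcaScores(normalizedRatios(fl)[sig, , drop = FALSE])
  sw <- silhouetteWidth(pc$scores, sampleGroups(fl))
  expect_gt(sw, 0.5)
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(4)
  coords <- rbind(
    matrix(stats::rnorm(10, 0), 5, 2),
    matrix(stats::rnorm(10, 4), 5, 2)
  )
  labels <- rep(c("a", "b"), each = 5)
  ref <- mean(cluster::silhouette(
    as.integer(factor(labels)), stats::dist(coords)
  )[, "sil_width"])
  expect_equal(silhouetteWidth(coords, labels), ref, tolerance = 1e-12)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  set.seed(6)
  universe <- sprintf("g%02d", 1:20)
  termMap <- list(tA = universe[1:5], tB = universe[3:12], tAll = universe)
  res <- termEnrichment(universe[1:5], universe, termMap)
  # a term annotating the whole universe is never enriched
  expect_equal(res$p[res$term_id == "tAll"], 1)
  # all 5 drawn from the 5 annotated: p = 1 / choose(20, 5)
  expect_equal(res$p[res$term_id == "tA"], 1 / choose(20, 5))
  # randomized instances against the combinatorial oracle
  for (i in 1:50) {
    N <- sample(10:40, 1)
    uni <- sprintf("u%03d", seq_len(N))
    K <- sample(2:N, 1)
    n <- sample(2:N, 1)
    tm <- list(t1 = sample(uni, K))
    lst <- sample(uni, n)
    r <- termEnrichment(lst, uni, tm)
    k <- length(intersect(lst, tm$t1))
    expect_equal(r$p, oracleHyper(k, K, n, N), tolerance = 1e-10)
  }
  expect_true(all(res$q >= res$p))
  expect_error(termEnrichment(character(), universe, termMap), "non-empty")
})

test_that("permuted labels yield almost no significant terms", {
  set.seed(8)
  universe <- sprintf("g%03d", 1:200)
  termMap <- lapply(1:20, function(i) sample(universe, 25))
  names(termMap) <- sprintf("t%02d", 1:20)
  hits <- 0L
  for (i in 1:20) {
    lst <- sample(universe, 30) # no association by construction
    r <- termEnrichment(lst, universe, termMap)
    hits <- hits + sum(r$significant)
  }
  expect_lte(hits / 20, 0.5)
})

test_that("audit and funnel reports serialize to JSON", {
  st <- smallStudy()
  nm <- normalizeToControl(computeRatios(st$channels),
    sampleGroups(st$channels))
  fl <- filterProbes(nm, st$channels)
  f1 <- withr::local_tempfile(fileext = ".json")
  writeAuditJson(fl, f1)
  audit <- jsonlite::read_json(f1)
  expect_equal(audit$n_probes, 400)
  expect_equal(
    audit$n_retained + Reduce(`+`, audit$removed_by_rule),
    400
  )
  dr <- differentialProbes(fl)
  gm <- probeToGene(dr, st$design)
  pr <- probes(st$design)
  ov <- expressionOverlap(
    gm$genes,
    data.frame(gene_id = pr$gene_ids[1:50], direction = "up"),
    st$design,
    data.frame(gene_id = unique(pr$gene_ids))
  )
  f2 <- withr::local_tempfile(fileext = ".json")
  writeFunnelJson(ov, f2)
  funnel <- jsonlite::read_json(f2)
  expect_equal(funnel$funnel$expression_significant, 50)
  expect_equal(
    funnel$percent_both_significant,
    ov$percent_both_significant
  )
})

test_that("the expression-methylation funnel books every stage", {
  # bookkeeping oracle: plant methylation effects inside the expression set
  st <- makeExampleStudy(nProbes = 300, nHypo = 15, nHyper = 5, seed = 12)
  nm <- normalizeToControl(computeRatios(st$channels),
    sampleGroups(st$channels))
  fl <- filterProbes(nm, st$channels)
  dr <- differentialProbes(fl)
  gm <- probeToGene(dr, st$design)
  pr <- probes(st$design)
  geneOf <- stats::setNames(pr$gene_ids, pr$island_id)
  eff <- effectLedger(st$truth)
  effGenes <- unname(geneOf[eff$region_id])
  exprDf <- data.frame(
    gene_id = c(effGenes, "gene_absent1", "gene_absent2"),
    direction = "up"
  )
  islands <- data.frame(gene_id = unique(pr$gene_ids))
  ov <- expressionOverlap(gm$genes, exprDf, st$design, islands)
  expect_equal(unname(ov$funnel["expression_significant"]), nrow(eff) + 2L)
  expect_equal(unname(ov$funnel["with_promoter_cgi"]), nrow(eff))
  expect_equal(unname(ov$funnel["on_array"]), nrow(eff))
  expect_equal(
    unname(ov$funnel["both_significant"]),
    length(intersect(effGenes, gm$genes$gene_id))
  )
  expect_equal(
    ov$percent_both_significant,
    100 * ov$funnel[["both_significant"]] / ov$funnel[["on_array"]]
  )
  # empty expression table: all funnel counts zero
  ov0 <- expressionOverlap(gm$genes,
    data.frame(gene_id = character(), direction = character()),
    st$design, islands)
  expect_true(all(ov0$funnel == 0))
})
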