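## Two-channel MeDIP-chip analysis: ratio computation, control-mean
## normalization, presence/intensity/variability filtering, Welch testing
## with fold-change cut-offs, median-relative methylation classes, PCA QC,
## hypergeometric term enrichment and expression concordance.

.bioGroups <- c("control", "tumor")

#' Raw Cy5/Cy3 ratios
#'
#' Divides the immunoprecipitated test signal by the genomic reference
#' signal per probe and sample. Entries with a non-positive reference are
#' marked invalid (NA) and drop out of presence counting.
#'
#' @param channels A \code{\link{ChannelSet}}.
#' @return numeric matrix of ratios (probes x samples) with NA for invalid
#'   entries.
#' @export
computeRatios <- function(channels) {
  cy5 <- SummarizedExperiment::assay(channels, "cy5")
  cy3 <- SummarizedExperiment::assay(channels, "cy3")
  r <- cy5 / cy3
  r[cy3 <= 0] <- NA_real_
  r
}

#' Normalize ratios to the control-group mean
#'
#' Every sample's raw ratio at a probe is divided by the mean raw ratio of
#' the control-group biological samples at that probe, so retained probes
#' have a control mean of exactly 1 and fold changes read directly off the
#' normalized values. Positive/negative control samples are excluded from
#' the reference mean (but stay in the matrix). Probes whose control mean
#' is zero or undefined are flagged unusable.
#'
#' @param rawRatios matrix from \code{\link{computeRatios}}.
#' @param groups named character vector of sample groups.
#' @return A \code{\link{NormalizedMatrix}} (unfiltered; see
#'   \code{\link{filterProbes}}).
#' @export
normalizeToControl <- function(rawRatios, groups) {
  groups <- groups[colnames(rawRatios)]
  ctrl <- names(groups)[groups == "control"]
  if (!length(ctrl)) stop("need at least one control-group sample")
  ctrlMean <- rowMeans(rawRatios[, ctrl, drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(ctrlMean) | ctrlMean <= 0
  norm <- rawRatios / ctrlMean
  norm[bad, ] <- NA_real_
  status <- data.frame(
    probe_id = rownames(rawRatios),
    retained = !bad,
    reason = ifelse(bad, "control_mean", "")
  )
  new("NormalizedMatrix",
    ratios = norm, rawRatios = rawRatios,
    groups = stats::setNames(as.character(groups), names(groups)),
    filterStatus = status
  )
}

#' Apply the presence, intensity and variability filters
#'
#' A probe is retained iff (a) its present flag is set in at least
#' \code{presentMin} samples, (b) its mean raw Cy5 intensity over
#' biological (control and tumor) samples is at least \code{intensityMin},
#' and (c) the standard deviation of its normalized ratios within each
#' biological group is at most \code{sdMax}. Removal reasons are recorded
#' in filter order (presence, then intensity, then sd) and summarized in an
#' audit table.
#'
#' @param normMatrix A \code{\link{NormalizedMatrix}}.
#' @param channels the \code{\link{ChannelSet}} the ratios came from
#'   (presence flags and raw intensities).
#' @param params An \code{\link{AnalysisParams}}.
#' @return The filtered \code{NormalizedMatrix} (rows of failing probes are
#'   dropped from the ratio matrix) with \code{\link{filterStatus}} covering
#'   every input probe, plus an \code{audit} element in the status
#'   attributes; see \code{attr(filterStatus(x), "audit")}.
#' @export
filterProbes <- function(normMatrix, channels, params = AnalysisParams()) {
  groups <- sampleGroups(normMatrix)
  present <- SummarizedExperiment::assay(channels, "present")
  cy5 <- SummarizedExperiment::assay(channels, "cy5")
  raw <- rawRatios(normMatrix)
  present[is.na(raw)] <- FALSE # invalid entries cannot count as present
  bio <- names(groups)[groups %in% .bioGroups]
  nm <- normalizedRatios(normMatrix)

  nPresent <- rowSums(present, na.rm = TRUE)
  meanRaw <- rowMeans(cy5[, bio, drop = FALSE], na.rm = TRUE)
  sdBad <- rep(FALSE, nrow(nm))
  for (g in .bioGroups) {
    gs <- names(groups)[groups == g]
    if (length(gs) >= 2L) {
      sds <- apply(nm[, gs, drop = FALSE], 1L, stats::sd, na.rm = TRUE)
      sdBad <- sdBad | (!is.na(sds) & sds > params@sdMax)
    }
  }
  prior <- filterStatus(normMatrix)
  reason <- prior$reason
  failPresence <- nPresent < params@presentMin
  failIntensity <- !is.finite(meanRaw) | meanRaw < params@intensityMin
  reason[reason == "" & failPresence] <- "presence"
  reason[reason == "" & failIntensity] <- "intensity"
  reason[reason == "" & sdBad] <- "sd"
  retained <- reason == ""
  status <- data.frame(
    probe_id = prior$probe_id, retained = retained, reason = reason
  )
  audit <- as.data.frame(table(
    reason = factor(reason[!retained],
      levels = c("control_mean", "presence", "intensity", "sd")
    )
  ))
  names(audit) <- c("reason", "removed")
  attr(status, "audit") <- audit
  new("NormalizedMatrix",
    ratios = nm[retained, , drop = FALSE],
    rawRatios = raw[retained, , drop = FALSE],
    groups = groups, filterStatus = status
  )
}

#' Welch two-sample t-test
#'
#' The unequal-variance t statistic
#' \code{t = (mean(a) - mean(b)) / sqrt(var(a)/na + var(b)/nb)} with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. When
#' both groups are constant and equal the test degenerates to \code{t = 0,
#' p = 1} by convention.
#'
#' @param a,b numeric vectors of length >= 2 (NAs dropped).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welchTest <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  va <- stats::var(a)
  vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Row-wise vectorized Welch test (same formulas as welchTest).
.rowWelch <- function(x, y) {
  na <- rowSums(!is.na(x))
  nb <- rowSums(!is.na(y))
  ma <- rowMeans(x, na.rm = TRUE)
  mb <- rowMeans(y, na.rm = TRUE)
  va <- rowSums((x - ma)^2, na.rm = TRUE) / (na - 1)
  vb <- rowSums((y - mb)^2, na.rm = TRUE) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  t[zero] <- 0
  p[zero & ma == mb] <- 1
  p[zero & ma != mb] <- 0
  df[zero] <- na[zero] + nb[zero] - 2
  list(t = t, df = df, p = p, meanA = ma, meanB = mb)
}

#' Call differentially methylated probes
#'
#' Per retained probe, the fold change \code{mean(tumor)/mean(control)} of
#' normalized ratios and a Welch test between the tumor and control groups.
#' Probes with \code{fc >= fcCut} and \code{p < alpha} are called
#' hypermethylated; \code{fc <= 1/fcCut} with \code{p < alpha}
#' hypomethylated; everything else is not significant. Set
#' \code{log2scale = TRUE} to test log2 ratios instead (fold changes are
#' still reported on the linear scale).
#'
#' @param normMatrix a filtered \code{\link{NormalizedMatrix}}.
#' @param params An \code{\link{AnalysisParams}}.
#' @param geneIds optional named character vector probe_id -> gene ids
#'   (comma-separated) carried into the result.
#' @param log2scale logical; test on the log2 scale.
#' @return data.frame sorted by p with columns \code{probe_id},
#'   \code{gene_ids}, \code{mean_tumor}, \code{mean_control}, \code{fc},
#'   \code{t}, \code{df}, \code{p}, \code{direction}.
#' @export
differentialProbes <- function(normMatrix, params = AnalysisParams(),
                               geneIds = NULL, log2scale = FALSE) {
  groups <- sampleGroups(normMatrix)
  nm <- normalizedRatios(normMatrix)
  tum <- names(groups)[groups == "tumor"]
  ctl <- names(groups)[groups == "control"]
  if (length(tum) < 2L || length(ctl) < 2L) {
    stop("need >= 2 samples per biological group")
  }
  x <- nm[, tum, drop = FALSE]
  y <- nm[, ctl, drop = FALSE]
  w <- if (log2scale) .rowWelch(log2(x), log2(y)) else .rowWelch(x, y)
  meanT <- rowMeans(x, na.rm = TRUE)
  meanC <- rowMeans(y, na.rm = TRUE)
  fc <- meanT / meanC
  direction <- rep("ns", nrow(nm))
  direction[fc >= params@fcCut & w$p < params@alpha] <- "hyper"
  direction[fc <= 1 / params@fcCut & w$p < params@alpha] <- "hypo"
  res <- data.frame(
    probe_id = rownames(nm),
    gene_ids = if (is.null(geneIds)) "" else unname(geneIds[rownames(nm)]),
    mean_tumor = meanT, mean_control = meanC, fc = fc,
    t = w$t, df = w$df, p = w$p, direction = direction,
    row.names = NULL
  )
  res[order(res$p), , drop = FALSE]
}

#' Summarize significant probes per gene
#'
#' Genes keep every significant probe row with its direction; a gene-level
#' direction is assigned only when all its probes agree, otherwise it is
#' \code{mixed}. Genes without significant probes are absent.
#'
#' @param diffResults data.frame from \code{\link{differentialProbes}}.
#' @param design optional \code{\link{ArrayDesign}} used to resolve probe
#'   gene ids when \code{diffResults$gene_ids} is empty.
#' @return list with \code{probes} (significant probe rows, one per probe
#'   and gene) and \code{genes} (data.frame \code{gene_id},
#'   \code{direction}, \code{n_probes}).
#' @export
probeToGene <- function(diffResults, design = NULL) {
  sig <- diffResults[diffResults$direction %in% c("hypo", "hyper"), ,
    drop = FALSE
  ]
  if (!is.null(design)) {
    pr <- probes(design)
    map <- stats::setNames(pr$gene_ids, pr$probe_id)
    blank <- !nzchar(sig$gene_ids)
    sig$gene_ids[blank] <- unname(map[sig$probe_id[blank]])
  }
  rows <- sig[rep(seq_len(nrow(sig)),
    vapply(strsplit(sig$gene_ids, ","), length, integer(1))
  ), , drop = FALSE]
  rows$gene_id <- unlist(strsplit(sig$gene_ids, ","), use.names = FALSE)
  genes <- do.call(rbind, lapply(split(rows, rows$gene_id), function(d) {
    dirs <- unique(d$direction)
    data.frame(
      gene_id = d$gene_id[1L],
      direction = if (length(dirs) == 1L) dirs else "mixed",
      n_probes = nrow(d)
    )
  }))
  rownames(genes) <- NULL
  list(probes = rows, genes = genes)
}

#' Median-relative methylation classes in control samples
#'
#' Computes the per-gene mean signal across control biological samples,
#' takes the median over genes, and classes genes at least
#' \code{medianFold}-fold above it as higher-methylated and at most
#' \code{1/medianFold} of it as lower-methylated (boundaries included).
#'
#' @param geneSignal named numeric vector of per-gene mean control signals
#'   (e.g. mean raw ratios).
#' @param params An \code{\link{AnalysisParams}}.
#' @return list with \code{median}, \code{higher}, \code{lower} (character
#'   vectors of gene ids).
#' @export
medianClasses <- function(geneSignal, params = AnalysisParams()) {
  if (length(geneSignal) < 2L) stop("need at least 2 genes")
  M <- stats::median(geneSignal, na.rm = TRUE)
  list(
    median = M,
    higher = names(geneSignal)[geneSignal >= params@medianFold * M],
    lower = names(geneSignal)[geneSignal <= M / params@medianFold]
  )
}

#' Per-gene mean control signal
#'
#' Aggregates raw Cy5/Cy3 ratios to one methylation-level signal per gene:
#' the mean over control-group biological samples per probe, averaged over
#' the probes of each gene. Feed the result to \code{\link{medianClasses}}.
#'
#' @param normMatrix A \code{\link{NormalizedMatrix}}.
#' @param design An \code{\link{ArrayDesign}} mapping probes to genes.
#' @return named numeric vector, one signal per gene.
#' @export
controlGeneSignal <- function(normMatrix, design) {
  groups <- sampleGroups(normMatrix)
  ctrl <- names(groups)[groups == "control"]
  raw <- rawRatios(normMatrix)
  probeMean <- rowMeans(raw[, ctrl, drop = FALSE], na.rm = TRUE)
  pr <- probes(design)
  gid <- stats::setNames(pr$gene_ids, pr$probe_id)[names(probeMean)]
  expand <- strsplit(gid, ",")
  df <- data.frame(
    gene = unlist(expand, use.names = FALSE),
    signal = rep(probeMean, lengths(expand))
  )
  vapply(split(df$signal, df$gene), mean, numeric(1))
}

#' PCA sample scores for quality control
#'
#' Samples are observations and probes variables; columns are mean-centered
#' and not scaled, and scores come from the singular value decomposition.
#' Signs are fixed deterministically: within each component the loading of
#' largest magnitude is made positive.
#'
#' @param mat numeric matrix, probes x samples (e.g. normalized ratios
#'   restricted to differential probes).
#' @param nComponents number of components to return.
#' @return list with \code{scores} (samples x components),
#'   \code{varExplained} (fraction per component).
#' @export
pcaScores <- function(mat, nComponents = 2L) {
  x <- t(mat) # samples x probes
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 samples and >= 2 probes")
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  k <- min(nComponents, length(sv$d))
  tot <- sum(sv$d^2)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  load <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (tot == 0) scores[] <- 0
  dimnames(scores) <- list(colnames(mat), paste0("PC", seq_len(k)))
  list(
    scores = scores,
    varExplained = if (tot > 0) sv$d[seq_len(k)]^2 / tot else rep(0, k)
  )
}

#' Hypergeometric term over-representation
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least \code{k} annotated genes in a list of \code{n} drawn from a
#' universe of \code{N} containing \code{K} annotated genes, with
#' Benjamini-Hochberg adjustment across terms.
#'
#' @param geneList character vector (subset of \code{universe}).
#' @param universe character vector of all testable genes.
#' @param termMap data.frame with columns \code{gene_id}, \code{term_id}
#'   (or a named list term -> genes).
#' @param params An \code{\link{AnalysisParams}} (uses
#'   \code{enrichmentFdr}).
#' @return data.frame with \code{term_id}, \code{k}, \code{K}, \code{n},
#'   \code{N}, \code{p}, \code{q}, \code{significant}, sorted by p.
#' @export
termEnrichment <- function(geneList, universe, termMap,
                           params = AnalysisParams()) {
  if (!length(geneList) || !length(universe)) {
    stop("gene list and universe must be non-empty")
  }
  geneList <- unique(geneList)
  universe <- unique(universe)
  if (!all(geneList %in% universe)) stop("geneList must be within universe")
  if (is.data.frame(termMap)) {
    termMap <- split(termMap$gene_id, termMap$term_id)
  }
  N <- length(universe)
  n <- length(geneList)
  rows <- lapply(names(termMap), function(tm) {
    ann <- intersect(unique(termMap[[tm]]), universe)
    K <- length(ann)
    k <- length(intersect(ann, geneList))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, k = k, K = K, n = n, N = N, p = p)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < params@enrichmentFdr
  res[order(res$p), , drop = FALSE]
}

#' Expression-methylation concordance funnel
#'
#' Intersects expression-significant genes with promoter CGI predictions,
#' array representation and methylation significance, reproducing the
#' funnel expression-significant -> has promoter CGI -> represented by at
#' least one probe -> methylation-significant, and joins per-gene
#' expression and methylation directions.
#'
#' @param geneMeth data.frame from \code{\link{probeToGene}}'s \code{genes}
#'   element (methylation-significant genes with direction).
#' @param expression data.frame with columns \code{gene_id},
#'   \code{direction} (\code{up}/\code{down}).
#' @param design An \code{\link{ArrayDesign}} (probe gene ids define array
#'   representation).
#' @param islands \code{GRanges} (or data.frame) of promoter islands with a
#'   \code{gene_id} column.
#' @return list with \code{funnel} (named counts), \code{table} (per-gene
#'   joined rows for co-represented genes) and
#'   \code{percent_both_significant} (of co-represented genes).
#' @export
expressionOverlap <- function(geneMeth, expression, design, islands) {
  exprGenes <- unique(expression$gene_id)
  islGenes <- unique(
    if (is(islands, "GRanges")) islands$gene_id else islands$gene_id
  )
  probeGenes <- unique(unlist(
    strsplit(probes(design)$gene_ids, ","),
    use.names = FALSE
  ))
  withCgi <- intersect(exprGenes, islGenes)
  onArray <- intersect(withCgi, probeGenes)
  methGenes <- if (nrow(geneMeth)) unique(geneMeth$gene_id) else character()
  both <- intersect(onArray, methGenes)
  tab <- data.frame(
    gene_id = onArray,
    expression = expression$direction[match(onArray, expression$gene_id)],
    methylation = ifelse(
      onArray %in% both,
      geneMeth$direction[match(onArray, geneMeth$gene_id)],
      "ns"
    )
  )
  list(
    funnel = c(
      expression_significant = length(exprGenes),
      with_promoter_cgi = length(withCgi),
      on_array = length(onArray),
      both_significant = length(both)
    ),
    table = tab,
    percent_both_significant = if (length(onArray)) {
      100 * length(both) / length(onArray)
    } else {
      0
    }
  )
}

#' Write analysis reports as JSON
#'
#' \code{writeAuditJson} saves the per-rule removal counts of
#' \code{\link{filterProbes}}; \code{writeFunnelJson} saves the funnel and
#' concordance percentage of \code{\link{expressionOverlap}}.
#'
#' @param normMatrix a filtered \code{\link{NormalizedMatrix}}.
#' @param overlap result of \code{\link{expressionOverlap}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeAuditJson <- function(normMatrix, path) {
  status <- filterStatus(normMatrix)
  audit <- attr(status, "audit")
  out <- list(
    n_probes = nrow(status),
    n_retained = sum(status$retained),
    removed_by_rule = stats::setNames(
      as.list(audit$removed), as.character(audit$reason)
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAuditJson
#' @export
writeFunnelJson <- function(overlap, path) {
  out <- list(
    funnel = as.list(overlap$funnel),
    percent_both_significant = overlap$percent_both_significant
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mean silhouette width of labelled points
#'
#' Average silhouette over all points for a labelling of low-dimensional
#' coordinates (Euclidean distance); singleton clusters contribute zero.
#' Used to quantify group separation on the first two PCA axes.
#'
#' @param coords numeric matrix (points x dimensions).
#' @param labels group labels, one per row.
#' @return mean silhouette width.
#' @export
silhouetteWidth <- function(coords, labels) {
  labels <- as.character(labels)
  n <- nrow(coords)
  stopifnot(length(labels) == n, n >= 2L)
  d <- as.matrix(stats::dist(coords))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (!length(own)) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, own])
    b <- min(vapply(
      setdiff(unique(labels), labels[i]),
      function(g) mean(d[i, labels == g]),
      numeric(1)
    ))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
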