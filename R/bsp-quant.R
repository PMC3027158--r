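## Quantification of methylation from direct bisulfite-sequencing traces
## (per-site C/T peak areas) and of global 5-methylcytosine from HPLC
## mononucleotide peak areas.

#' Percent methylation at one CpG site
#'
#' \code{100 * c / (c + t)} from the C and T peak areas of a bisulfite
#' trace. Sites where both areas are zero carry no signal and are treated
#' as missing (NA); callers exclude them from region means.
#'
#' @param cArea,tArea non-negative peak areas (vectorized).
#' @return percent methylation, NA where both areas are zero.
#' @examples
#' siteMethylation(3, 1) # 75
#' @export
siteMethylation <- function(cArea, tArea) {
  stopifnot(all(cArea >= 0), all(tArea >= 0))
  tot <- cArea + tArea
  ifelse(tot > 0, 100 * cArea / tot, NA_real_)
}

#' Percent methylation of a region
#'
#' Unweighted mean of per-site percentages over the non-missing CpG sites
#' of a trace.
#'
#' @param trace A \code{\link{BisulfiteTrace}}.
#' @return percent methylation of the region.
#' @export
regionMethylation <- function(trace) {
  s <- traceSites(trace)
  s <- s[s$site_type == "cpg", , drop = FALSE]
  pct <- siteMethylation(s$c_area, s$t_area)
  pct <- pct[!is.na(pct)]
  if (!length(pct)) stop("all CpG sites missing (zero total area)")
  mean(pct)
}

#' Bisulfite conversion quality control
#'
#' Non-CpG cytosines should read fully as T after complete conversion. The
#' rate is the pooled \code{sum(t) / (sum(c) + sum(t))} over non-CpG
#' cytosine sites; the check passes when the rate reaches the threshold.
#'
#' @param trace A \code{\link{BisulfiteTrace}}.
#' @param threshold minimum acceptable conversion rate.
#' @return list with \code{rate}, \code{pass}, and \code{available}
#'   (FALSE, with NA rate and pass, when the trace has no non-CpG cytosine
#'   site -- unavailable QC never reports a pass).
#' @export
conversionQc <- function(trace, threshold = 0.98) {
  s <- traceSites(trace)
  s <- s[s$site_type == "non_cpg_c", , drop = FALSE]
  if (!nrow(s)) {
    return(list(rate = NA_real_, pass = NA, available = FALSE))
  }
  rate <- sum(s$t_area) / (sum(s$c_area) + sum(s$t_area))
  list(rate = rate, pass = rate >= threshold, available = TRUE)
}

#' Compare region methylation between tumor and control traces
#'
#' Pools per-site percentages across replicate samples within each group
#' (all measured CpGs combined) and compares the groups with the Welch
#' test. Note the pseudoreplication caveat: sites within a molecule are
#' not independent, so the p-value is optimistic.
#'
#' @param tumorTraces,controlTraces lists of \code{\link{BisulfiteTrace}}
#'   objects.
#' @return list with \code{mean_difference} (tumor - control, percentage
#'   points), \code{t}, \code{df}, \code{p}, \code{direction}
#'   (\code{hyper}/\code{hypo}/\code{none} as seen in tumor), and the
#'   pooled site percentages per group.
#' @export
compareRegions <- function(tumorTraces, controlTraces) {
  poolSites <- function(traces) {
    unlist(lapply(traces, function(tr) {
      s <- traceSites(tr)
      s <- s[s$site_type == "cpg", , drop = FALSE]
      pct <- siteMethylation(s$c_area, s$t_area)
      pct[!is.na(pct)]
    }), use.names = FALSE)
  }
  tum <- poolSites(tumorTraces)
  ctl <- poolSites(controlTraces)
  if (length(tum) < 2L || length(ctl) < 2L) {
    stop("need >= 2 site measurements per group")
  }
  w <- welchTest(tum, ctl)
  diff <- mean(tum) - mean(ctl)
  list(
    mean_difference = diff, t = w$t, df = w$df, p = w$p,
    direction = if (w$p < 0.05 && diff > 0) {
      "hyper"
    } else if (w$p < 0.05 && diff < 0) {
      "hypo"
    } else {
      "none"
    },
    tumor_sites = tum, control_sites = ctl
  )
}

#' Classify a region's methylation level
#'
#' Threshold classification of a region percentage: at most \code{lowCut}
#' is called unmethylated, at least \code{highCut} methylated, anything in
#' between partial. The defaults operationalize "completely un-methylated"
#' and "completely methylated" calls from trace data.
#'
#' @param percent region methylation percentage in [0, 100] (vectorized).
#' @param lowCut,highCut class boundaries in percent.
#' @return character vector in \code{{unmethylated, partial, methylated}}.
#' @export
classifyRegion <- function(percent, lowCut = 10, highCut = 90) {
  stopifnot(all(percent >= 0), all(percent <= 100), lowCut < highCut)
  ifelse(percent <= lowCut, "unmethylated",
    ifelse(percent >= highCut, "methylated", "partial")
  )
}

#' Global percent 5-methylcytosine from an HPLC profile
#'
#' \code{100 * A(5mdC) / (A(5mdC) + A(dC))} after dividing each peak area
#' by its molar response factor. A nonzero uracil peak triggers an RNA
#' contamination warning (the result is still returned).
#'
#' @param profile An \code{\link{HplcProfile}}.
#' @return percent of cytosines methylated.
#' @export
globalMethylationPercent <- function(profile) {
  a <- peakAreas(profile) / profile@responseFactors
  tot <- a[["dC"]] + a[["m5dC"]]
  if (tot <= 0) stop("zero cytosine signal")
  if (a[["U"]] > 0) {
    warning("nonzero uracil peak: possible RNA contamination")
  }
  100 * a[["m5dC"]] / tot
}

#' Fold difference between two methylation percentages
#'
#' @param a,b percentages; \code{b} must be positive.
#' @return \code{a / b}.
#' @examples
#' foldDifference(8.56, 4) # 2.14
#' @export
foldDifference <- function(a, b) {
  if (any(b == 0)) stop("denominator must be nonzero")
  a / b
}

#' Read / write bisulfite-trace tables
#'
#' Long-format TSV with header \code{region_id, sample_id, group,
#' position, site_type, c_area, t_area}; one \code{BisulfiteTrace} per
#' (region, sample) pair.
#'
#' @param traces list of \code{\link{BisulfiteTrace}} objects.
#' @param path file path.
#' @return \code{writeTraceTable}: invisibly, \code{path};
#'   \code{readTraceTable}: a list of \code{BisulfiteTrace}.
#' @export
writeTraceTable <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    s <- traceSites(tr)
    data.frame(
      region_id = tr@regionId, sample_id = tr@sampleId, group = tr@group,
      position = s$position, site_type = s$site_type,
      c_area = s$c_area, t_area = s$t_area
    )
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceTable
#' @export
readTraceTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
    stringsAsFactors = FALSE)
  keys <- unique(df[, c("region_id", "sample_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    d <- df[df$region_id == keys$region_id[i] &
      df$sample_id == keys$sample_id[i], , drop = FALSE]
    BisulfiteTrace(
      regionId = keys$region_id[i], sampleId = keys$sample_id[i],
      group = d$group[1L],
      sites = data.frame(
        position = d$position, site_type = d$site_type,
        c_area = d$c_area, t_area = d$t_area
      )
    )
  })
}

#' Read an HPLC peak-area table
#'
#' TSV with columns \code{peak, area} and optionally
#' \code{response_factor}.
#'
#' @param path file path.
#' @return An \code{\link{HplcProfile}}.
#' @export
readHplcTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
    stringsAsFactors = FALSE)
  areas <- stats::setNames(df$area, df$peak)
  rf <- if ("response_factor" %in% colnames(df)) {
    stats::setNames(df$response_factor, df$peak)
  } else {
    NULL
  }
  HplcProfile(areas, rf)
}
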