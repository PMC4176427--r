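#' Per-sample median channel intensities
#'
#' Extracts, for each sample, the log2 median methylated and unmethylated
#' intensity over all autosomal probes (read from the stored p = 0.5
#' quantiles) plus the combined mean NEGATIVE-control intensity when control
#' summaries are present. These are the coordinates of the classic
#' median-M-vs-median-U QC scatter: degraded samples drift towards the low
#' corner.
#'
#' A median of zero has no log2; a floor of 1 intensity unit is applied first
#' and such samples are flagged immediately with reason `"zero_median"`.
#'
#' @param summary A raw-labelled [QCSummary-class] with a non-empty autosomal
#'   stratum.
#' @return Data frame with columns `sample_id`, `median_log2_meth`,
#'   `median_log2_unmeth`, `mean_negative_control`, `flagged`, `flag_reason`.
#' @seealso [flagLowQuality()] to apply the intensity cutoff.
#' @export
medianChannelIntensities <- function(summary) {
    stopifnot(is(summary, "QCSummary"))
    if (summary@label != "raw")
        stop("median channel intensities require a raw summary (normalized data have no channels)")
    if (summary@strataCounts[["autosomal"]] == 0)
        stop("autosomal stratum is empty")
    probs <- summary@probs
    i50 <- which(probs == 0.5)
    if (length(i50) != 1)
        stop("quantile grid does not contain p = 0.5")
    medM <- unname(summary@quantiles$autosomal$M[i50, ])
    medU <- unname(summary@quantiles$autosomal$U[i50, ])
    zero <- medM < 1 | medU < 1
    negCtrl <- rep(NA_real_, length(summary@sampleIds))
    ctl <- summary@controls
    if (!is.null(ctl) && any(ctl$control_type == "NEGATIVE")) {
        neg <- ctl[ctl$control_type == "NEGATIVE", ]
        negCtrl <- neg$mean_combined[match(summary@sampleIds, neg$sample_id)]
    }
    data.frame(sample_id = summary@sampleIds,
               median_log2_meth = log2(pmax(medM, 1)),
               median_log2_unmeth = log2(pmax(medU, 1)),
               mean_negative_control = negCtrl,
               flagged = zero,
               flag_reason = ifelse(zero, "zero_median", ""),
               stringsAsFactors = FALSE)
}

#' Flag low-quality samples by median intensity
#'
#' A sample is flagged when the mean of its two log2 median channel
#' intensities falls below `cutoff`: flagged iff
#' (median_log2_meth + median_log2_unmeth) / 2 < cutoff, reason
#' `"low_median_intensity"`. Existing flags (e.g. `"zero_median"`) are kept;
#' reasons accumulate separated by `";"`. Flagging is monotone in the cutoff.
#'
#' @param qc Data frame from [medianChannelIntensities()].
#' @param cutoff Log2-intensity threshold (default 10.5, a conventional 450k
#'   working value).
#' @return The `qc` data frame with `flagged`/`flag_reason` updated.
#' @export
flagLowQuality <- function(qc, cutoff = 10.5) {
    need <- c("sample_id", "median_log2_meth", "median_log2_unmeth")
    if (!all(need %in% names(qc)))
        stop("'qc' must come from medianChannelIntensities()")
    low <- (qc$median_log2_meth + qc$median_log2_unmeth) / 2 < cutoff
    qc$flag_reason <- ifelse(
        low & nzchar(qc$flag_reason),
        paste(qc$flag_reason, "low_median_intensity", sep = ";"),
        ifelse(low, "low_median_intensity", qc$flag_reason))
    qc$flagged <- qc$flagged | low
    qc
}

## Silverman's rule-of-thumb bandwidth, with the sample-size factor taken from
## the number of probes the quantile vector summarizes (nEff) rather than the
## grid length: the stored quantiles are a size-independent sketch of the
## probe distribution, and matching the full-data KDE requires the full-data n.
.silvermanBw <- function(x, nEff = length(x)) {
    s <- stats::sd(x)
    iqr <- stats::IQR(x)
    spread <- if (iqr > 0) min(s, iqr / 1.34) else s
    bw <- 0.9 * spread * nEff^(-1 / 5)
    if (!is.finite(bw) || bw <= 0)
        bw <- 1e-6 * max(1, abs(x[1]))  # constant pseudo-sample: spike at c
    bw
}

#' Density curves reconstructed from stored quantiles
#'
#' Gaussian kernel density estimates of the per-sample Beta or M-value
#' distribution in a stratum, computed from the stored quantile vector treated
#' as an equal-weight pseudo-sample. All samples share one abscissa grid
#' spanning the pooled range, so curves overlay directly. The bandwidth is
#' Silverman's rule with spread statistics from the pseudo-sample and the
#' sample-size factor from the stratum's true probe count, which makes the
#' reconstruction track a KDE of the full underlying matrix closely.
#'
#' @param summary A [QCSummary-class].
#' @param measure `"Beta"` or `"MValue"`.
#' @param stratum Stratum name (see [quantileTable()]).
#' @param nGrid Number of grid points (default 512).
#' @return A list with elements `measure`, `stratum`, `grid` (length `nGrid`)
#'   and `density`, an `nGrid` x samples matrix of non-negative ordinates,
#'   each column integrating to ~1.
#' @export
densityCurves <- function(summary, measure = c("Beta", "MValue"),
                          stratum = "autosomal", nGrid = 512) {
    stopifnot(is(summary, "QCSummary"))
    measure <- match.arg(measure)
    stratum <- match.arg(stratum, .STRATA)
    q <- summary@quantiles[[stratum]][[measure]]
    if (is.null(q))
        stop(sprintf("stratum '%s' is empty; no %s densities available",
                     stratum, measure))
    nEff <- summary@strataCounts[[stratum]]
    if (is.na(nEff) || nEff <= 0) nEff <- nrow(q)
    bws <- apply(q, 2, .silvermanBw, nEff = nEff)
    lo <- min(q) - 3 * max(bws)
    hi <- max(q) + 3 * max(bws)
    dens <- vapply(seq_len(ncol(q)), function(j)
        stats::density(q[, j], bw = bws[j], from = lo, to = hi, n = nGrid)$y,
        numeric(nGrid))
    colnames(dens) <- colnames(q)
    list(measure = measure, stratum = stratum,
         grid = seq(lo, hi, length.out = nGrid), density = dens)
}
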