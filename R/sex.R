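#' Per-sample sex-chromosome copy-number difference
#'
#' The sex predictor's one-dimensional statistic: log2 of the median total
#' copy number (CN = M + U) over chrY probes minus the same over chrX probes,
#' both read from the stored p = 0.5 quantiles. Two X chromosomes and no Y
#' push the difference down (females); one of each pushes it up (males), so
#' samples separate into two clusters along this axis.
#'
#' @param summary A raw-labelled [QCSummary-class] with non-empty chrX and
#'   chrY strata.
#' @return Named numeric vector (one value per sample).
#' @export
sexDifference <- function(summary) {
    stopifnot(is(summary, "QCSummary"))
    if (!"CN" %in% names(summary@quantiles$chrX) ||
        is.null(summary@quantiles$chrX$CN))
        stop("chrX stratum is empty or carries no CN quantiles")
    if (is.null(summary@quantiles$chrY$CN))
        stop("chrY stratum is empty or carries no CN quantiles")
    i50 <- which(summary@probs == 0.5)
    if (length(i50) != 1)
        stop("quantile grid does not contain p = 0.5")
    d <- log2(summary@quantiles$chrY$CN[i50, ]) -
         log2(summary@quantiles$chrX$CN[i50, ])
    stats::setNames(as.numeric(d), summary@sampleIds)
}

## Deterministic one-dimensional 2-means: centres initialised at min and max,
## points assigned to the nearer centre, iterated to convergence.
.twoMeans1d <- function(x, maxIter = 100) {
    c1 <- min(x); c2 <- max(x)
    if (c1 == c2)
        stop("cannot separate clusters: all differences identical")
    assign <- x >= (c1 + c2) / 2
    for (i in seq_len(maxIter)) {
        c1 <- mean(x[!assign]); c2 <- mean(x[assign])
        newAssign <- x >= (c1 + c2) / 2
        if (identical(newAssign, assign)) break
        assign <- newAssign
        if (!any(assign) || all(assign))
            stop("cannot separate clusters: all differences identical")
    }
    c(lower = c1, upper = c2)
}

#' Predict sample sex from the X/Y difference
#'
#' Thresholds the [sexDifference()] statistic: samples at or above the cutoff
#' are called male (`"M"`), below it female (`"F"`). With `cutoff = "auto"`
#' the cutoff is found by a deterministic one-dimensional 2-means (centres
#' initialised at the minimum and maximum, iterated to convergence) and set to
#' the midpoint of the two final centres; the cluster with the larger centre
#' is labelled male. The tie-break at the cutoff (>= is male) is deliberate
#' and tested.
#'
#' @param diffs Named numeric vector from [sexDifference()].
#' @param cutoff Numeric cutoff, or `"auto"` (requires >= 2 samples and at
#'   least two distinct values).
#' @param reportedSex Optional vector of reported sexes (`"M"`, `"F"`, NA),
#'   recycled against `diffs` by name when named, else by position.
#' @return Data frame (one row per sample) with columns `sample_id`,
#'   `xy_diff`, `predicted_sex`, `cutoff_used`, `reported_sex`, `mismatch`.
#' @export
predictSex <- function(diffs, cutoff = "auto", reportedSex = NULL) {
    if (anyNA(diffs) || any(!is.finite(diffs)))
        stop("'diffs' must be finite")
    if (is.character(cutoff)) {
        if (!identical(tolower(cutoff), "auto"))
            stop("'cutoff' must be numeric or \"auto\"")
        if (length(diffs) < 2)
            stop("automatic cutoff requires at least 2 samples")
        centres <- .twoMeans1d(as.numeric(diffs))
        cutoff <- mean(centres)
    } else {
        stopifnot(is.numeric(cutoff), length(cutoff) == 1)
    }
    ids <- if (!is.null(names(diffs))) names(diffs)
           else sprintf("sample_%d", seq_along(diffs))
    predicted <- ifelse(diffs >= cutoff, "M", "F")
    reported <- rep(NA_character_, length(diffs))
    if (!is.null(reportedSex)) {
        reported <- if (!is.null(names(reportedSex)))
            as.character(reportedSex[ids]) else as.character(reportedSex)
        if (length(reported) != length(diffs))
            stop("'reportedSex' must match 'diffs' in length")
    }
    data.frame(sample_id = ids,
               xy_diff = as.numeric(diffs),
               predicted_sex = predicted,
               cutoff_used = cutoff,
               reported_sex = reported,
               mismatch = !is.na(reported) & reported != predicted,
               stringsAsFactors = FALSE)
}

#' Samples whose predicted sex contradicts the reported sex
#'
#' Filters [predictSex()] calls down to the rows where a non-missing reported
#' sex disagrees with the prediction — candidate sample swaps or labelling
#' errors. Export with [exportSampleList()] (reason `"sex_mismatch"`).
#'
#' @param calls Data frame from [predictSex()].
#' @return The mismatching subset, same columns.
#' @export
sexMismatches <- function(calls) {
    need <- c("sample_id", "predicted_sex", "reported_sex", "mismatch")
    if (!all(need %in% names(calls)))
        stop("'calls' must come from predictSex()")
    out <- calls[calls$mismatch, , drop = FALSE]
    rownames(out) <- NULL
    out
}
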