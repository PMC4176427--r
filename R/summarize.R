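## Partition manifest rows (restricted to the probes present in the data)
## into the six strata. Autosomal type I probes are split by colour channel;
## chrX/chrY pool both chemistries; "autosomal" pools all autosomal probes.
.strataIndex <- function(manifest, probeIds) {
    miss <- setdiff(probeIds, manifest$probe_id)
    if (length(miss))
        stop(sprintf("%d probe(s) missing from the manifest, e.g.: %s",
                     length(miss),
                     paste(utils::head(miss, 10), collapse = ", ")))
    man <- manifest[match(probeIds, manifest$probe_id), ]
    auto <- !(man$chromosome %in% c("chrX", "chrY"))
    list(IGrn = which(auto & man$infinium_type == "I" & man$channel == "Grn"),
         IRed = which(auto & man$infinium_type == "I" & man$channel == "Red"),
         II   = which(auto & man$infinium_type == "II"),
         chrX = which(man$chromosome == "chrX"),
         chrY = which(man$chromosome == "chrY"),
         autosomal = which(auto))
}

.quantileMatrix <- function(mat, idx, probs) {
    if (length(idx) == 0) return(NULL)
    out <- apply(mat[idx, , drop = FALSE], 2, quantileSummary, probs = probs)
    if (!is.matrix(out)) out <- matrix(out, nrow = length(probs))
    colnames(out) <- colnames(mat)
    rownames(out) <- NULL
    out
}

.emptyStrataWarning <- function(counts) {
    empty <- names(counts)[counts == 0]
    if (length(empty))
        warning(sprintf("empty stratum(s) recorded with no quantiles: %s",
                        paste(empty, collapse = ", ")), call. = FALSE)
}

.resolvePhenotypes <- function(phenotypes, sampleIds) {
    if (is.null(phenotypes))
        return(data.frame(sample_id = sampleIds, stringsAsFactors = FALSE))
    if (!"sample_id" %in% names(phenotypes))
        stop("phenotype table must have a 'sample_id' column")
    extra <- setdiff(sampleIds, phenotypes$sample_id)
    if (length(extra))
        stop(sprintf("samples missing from phenotype table: %s",
                     paste(extra, collapse = ", ")))
    out <- phenotypes[match(sampleIds, phenotypes$sample_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Summarize raw methylation signals into a compact QCSummary
#'
#' Reduces the full probes x samples intensity matrices to per-sample quantile
#' tables of the five measures (M, U, CN = M + U, Beta, M-value), stratified by
#' probe chemistry and chromosome; summarizes control probes; and runs a PCA on
#' the most variable autosomal Beta values. The result is a [QCSummary-class]
#' whose size is independent of the probe count, so it can be shipped from a
#' compute server to a laptop for interactive-style exploration.
#'
#' @param signals A [SignalSet-class].
#' @param manifest Probe manifest data frame as returned by [readManifest()];
#'   every probe in `signals` must be present.
#' @param controls Optional control-probe table from [readControls()];
#'   summarized via [summarizeControls()].
#' @param phenotypes Optional phenotype data frame with a `sample_id` column
#'   covering all samples; reordered to the signal sample order.
#' @param params A [transformParams()] record.
#' @param nTop Number of most-variable autosomal probes for the PCA
#'   (default 20000; all autosomal probes when fewer exist).
#' @return A [QCSummary-class] with label `"raw"`.
#' @details A stratum with zero probes is recorded as empty with a warning, not
#'   an error, so partial manifests stay usable; downstream operations that
#'   need the missing stratum fail at their own call site.
#' @export
summarizeRaw <- function(signals, manifest, controls = NULL, phenotypes = NULL,
                         params = transformParams(), nTop = 20000) {
    stopifnot(is(signals, "SignalSet"))
    meth <- getMeth(signals)
    unmeth <- getUnmeth(signals)
    sampleIds <- colnames(meth)
    idx <- .strataIndex(manifest, rownames(meth))
    counts <- vapply(idx, length, integer(1))
    .emptyStrataWarning(counts)

    measures <- list(
        M = meth,
        U = unmeth,
        CN = computeCN(meth, unmeth),
        Beta = computeBeta(meth, unmeth, params$betaOffset),
        MValue = computeMValue(meth, unmeth, params$mvalueEpsilon))
    quantiles <- lapply(idx, function(ii)
        lapply(measures, .quantileMatrix, idx = ii, probs = params$quantileProbs))

    controlTab <- if (!is.null(controls)) {
        .checkControlSamples(controls, sampleIds)
        summarizeControls(controls)
    }

    pca <- NULL
    if (length(idx$autosomal) > 0 && length(sampleIds) >= 2) {
        sel <- selectTopVariable(measures$Beta[idx$autosomal, , drop = FALSE],
                                 nTop = nTop)
        pca <- runPCA(measures$Beta[sel, , drop = FALSE], nTop = nTop)
    }

    new("QCSummary",
        sampleIds = sampleIds,
        probs = params$quantileProbs,
        quantiles = quantiles,
        strataCounts = counts,
        controls = controlTab,
        pca = pca,
        phenotypes = .resolvePhenotypes(phenotypes, sampleIds),
        label = "raw",
        params = list(betaOffset = as.numeric(params$betaOffset),
                      mvalueEpsilon = as.numeric(params$mvalueEpsilon),
                      logitEpsilon = as.numeric(params$logitEpsilon),
                      nTop = as.integer(nTop)))
}

.checkControlSamples <- function(controls, sampleIds) {
    have <- setdiff(sampleIds, unique(controls$sample_id))
    if (length(have))
        stop(sprintf("control table lacks samples: %s",
                     paste(have, collapse = ", ")))
    invisible(TRUE)
}

#' Summarize a normalized Beta matrix
#'
#' Builds the stratified quantile summary of externally normalized Beta values
#' (e.g. after functional normalization) for side-by-side comparison with the
#' raw-data summary. Only Beta and M-value tables are stored; M-values are
#' derived as logit2 of Beta with clipping (see [logit2Beta()]). Raw channels
#' and control probes do not exist at this stage, so those tables are absent.
#'
#' @param betaNorm Numeric matrix of normalized Beta values in [0, 1], probes
#'   x samples, with probe/sample dimnames.
#' @inheritParams summarizeRaw
#' @return A [QCSummary-class] with label `"normalized"`.
#' @export
summarizeNormalized <- function(betaNorm, manifest, phenotypes = NULL,
                                params = transformParams(), nTop = 20000) {
    betaNorm <- as.matrix(betaNorm)
    if (is.null(rownames(betaNorm)) || is.null(colnames(betaNorm)))
        stop("'betaNorm' must carry probe and sample IDs as dimnames")
    if (anyNA(betaNorm) || any(betaNorm < 0) || any(betaNorm > 1))
        stop("normalized Beta values must lie in [0, 1] with no missing values")
    sampleIds <- colnames(betaNorm)
    idx <- .strataIndex(manifest, rownames(betaNorm))
    counts <- vapply(idx, length, integer(1))
    .emptyStrataWarning(counts)

    measures <- list(Beta = betaNorm,
                     MValue = logit2Beta(betaNorm, params$logitEpsilon))
    quantiles <- lapply(idx, function(ii)
        lapply(measures, .quantileMatrix, idx = ii, probs = params$quantileProbs))

    pca <- NULL
    if (length(idx$autosomal) > 0 && length(sampleIds) >= 2) {
        sel <- selectTopVariable(betaNorm[idx$autosomal, , drop = FALSE],
                                 nTop = nTop)
        pca <- runPCA(betaNorm[sel, , drop = FALSE], nTop = nTop)
    }

    new("QCSummary",
        sampleIds = sampleIds,
        probs = params$quantileProbs,
        quantiles = quantiles,
        strataCounts = counts,
        controls = NULL,
        pca = pca,
        phenotypes = .resolvePhenotypes(phenotypes, sampleIds),
        label = "normalized",
        params = list(betaOffset = as.numeric(params$betaOffset),
                      mvalueEpsilon = as.numeric(params$mvalueEpsilon),
                      logitEpsilon = as.numeric(params$logitEpsilon),
                      nTop = as.integer(nTop)))
}

#' Per-sample control-probe summaries
#'
#' Averages the green and red channel intensities of the control probes within
#' each control type, per sample — the numbers behind the "average negative
#' control intensities" QC panel.
#'
#' @param controls Control table data frame with columns `control_id`,
#'   `control_type`, `sample_id`, `green`, `red`.
#' @return Data frame with one row per (sample, control type): columns
#'   `sample_id`, `control_type`, `mean_green`, `mean_red`, `mean_combined`
#'   where `mean_combined = (mean_green + mean_red) / 2`.
#' @export
summarizeControls <- function(controls) {
    need <- c("control_id", "control_type", "sample_id", "green", "red")
    if (!all(need %in% names(controls)))
        stop("control table must have columns: ", paste(need, collapse = ", "))
    if (nrow(controls) == 0)
        stop("control table must contain at least one row")
    out <- stats::aggregate(cbind(mean_green = green, mean_red = red) ~
                                sample_id + control_type,
                            data = controls, FUN = mean)
    out$mean_combined <- (out$mean_green + out$mean_red) / 2
    out <- out[order(out$sample_id, out$control_type), ]
    rownames(out) <- NULL
    out
}
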