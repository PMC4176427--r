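#' Accessors for SignalSet
#'
#' `getMeth()` and `getUnmeth()` return the methylated / unmethylated
#' intensity matrices (probes x samples).
#'
#' @param object A [SignalSet-class].
#' @return A numeric matrix.
#' @name SignalSet-accessors
NULL

#' @rdname SignalSet-accessors
#' @export
setMethod("getMeth", "SignalSet", function(object)
    SummarizedExperiment::assay(object, "meth"))

#' @rdname SignalSet-accessors
#' @export
setMethod("getUnmeth", "SignalSet", function(object)
    SummarizedExperiment::assay(object, "unmeth"))

setMethod("show", "SignalSet", function(object) {
    cat("SignalSet with", nrow(object), "probes and", ncol(object), "samples\n")
    cat("  assays: meth, unmeth\n")
})

#' Accessors for QCSummary
#'
#' Read-only access to the slots of a [QCSummary-class]: sample IDs, the
#' provenance label ("raw"/"normalized") and parameter record, the shared
#' quantile probability grid, individual quantile tables, per-stratum probe
#' counts, control-probe summaries, the PCA result and the phenotype table.
#'
#' @param object A [QCSummary-class].
#' @param stratum One of `"IGrn"`, `"IRed"`, `"II"`, `"chrX"`, `"chrY"`,
#'   `"autosomal"`.
#' @param measure One of `"M"`, `"U"`, `"CN"`, `"Beta"`, `"MValue"`.
#' @return `quantileTable` returns a probs x samples matrix or NULL for an
#'   empty stratum; the others return the corresponding slot.
#' @name QCSummary-accessors
NULL

#' @rdname QCSummary-accessors
#' @export
setMethod("sampleIDs", "QCSummary", function(object) object@sampleIds)

#' @rdname QCSummary-accessors
#' @export
setMethod("summaryLabel", "QCSummary", function(object) object@label)

#' @rdname QCSummary-accessors
#' @export
setMethod("summaryParams", "QCSummary", function(object) object@params)

#' @rdname QCSummary-accessors
#' @export
setMethod("quantileProbs", "QCSummary", function(object) object@probs)

#' @rdname QCSummary-accessors
#' @export
setMethod("quantileTable", "QCSummary", function(object, stratum, measure) {
    stratum <- match.arg(stratum, .STRATA)
    if (!stratum %in% names(object@quantiles))
        stop(sprintf("stratum '%s' not present in this summary", stratum))
    tabs <- object@quantiles[[stratum]]
    measure <- match.arg(measure, .RAW_MEASURES)
    if (!measure %in% names(tabs))
        stop(sprintf("measure '%s' not stored for a '%s' summary",
                     measure, object@label))
    tabs[[measure]]
})

#' @rdname QCSummary-accessors
#' @export
setMethod("strataCounts", "QCSummary", function(object) object@strataCounts)

#' @rdname QCSummary-accessors
#' @export
setMethod("controlSummary", "QCSummary", function(object) object@controls)

#' @rdname QCSummary-accessors
#' @export
setMethod("pcaResult", "QCSummary", function(object) object@pca)

#' @rdname QCSummary-accessors
#' @export
setMethod("phenotypes", "QCSummary", function(object) object@phenotypes)

setMethod("show", "QCSummary", function(object) {
    cat(sprintf("QCSummary (%s) of %d samples\n",
                object@label, length(object@sampleIds)))
    cat(sprintf("  quantile grid: %d probabilities in [0, 1]\n",
                length(object@probs)))
    nonEmpty <- names(object@strataCounts)[object@strataCounts > 0]
    cat("  strata:", paste(sprintf("%s(%d)", nonEmpty,
                                   object@strataCounts[nonEmpty]),
                           collapse = ", "), "\n")
    cat("  measures:", paste(names(object@quantiles[[nonEmpty[1]]]),
                             collapse = ", "), "\n")
    cat("  controls:", if (is.null(object@controls)) "absent" else
        sprintf("%d control types", length(unique(object@controls$control_type))),
        "| pca:", if (is.null(object@pca)) "absent" else
        sprintf("%d components", ncol(object@pca@scores)), "\n")
})

#' Accessors for PCAResult
#'
#' `pcaScores()` returns the samples x components score matrix,
#' `varianceRatio()` the per-component explained-variance fractions and
#' `selectedProbes()` the IDs of the variance-selected probes.
#'
#' @param object A [PCAResult-class].
#' @name PCAResult-accessors
NULL

#' @rdname PCAResult-accessors
#' @export
setMethod("pcaScores", "PCAResult", function(object) object@scores)

#' @rdname PCAResult-accessors
#' @export
setMethod("varianceRatio", "PCAResult", function(object) object@varianceRatio)

#' @rdname PCAResult-accessors
#' @export
setMethod("selectedProbes", "PCAResult", function(object) object@selectedProbes)

setMethod("show", "PCAResult", function(object) {
    cat(sprintf("PCAResult: %d samples, %d components, %d/%d probes selected\n",
                length(object@sampleIds), ncol(object@scores),
                length(object@selectedProbes), object@nTop))
    if (length(object@varianceRatio))
        cat("  variance explained:",
            paste(sprintf("%.1f%%", 100 * object@varianceRatio), collapse = " "),
            "\n")
})
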