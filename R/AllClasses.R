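#' @import methods
#' @importFrom S4Vectors SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Fixed stratum / measure vocabularies. Autosomal probes are split by
## chemistry (type I by colour channel, type II), sex chromosomes pool both
## chemistries, and "autosomal" pools every autosomal probe for downstream
## QC metrics.
.STRATA <- c("IGrn", "IRed", "II", "chrX", "chrY", "autosomal")
.RAW_MEASURES <- c("M", "U", "CN", "Beta", "MValue")
.NORM_MEASURES <- c("Beta", "MValue")
.CHROMOSOMES <- c(paste0("chr", 1:22), "chrX", "chrY")

#' SignalSet: paired methylated/unmethylated intensity matrices
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding the two raw
#' signal channels of an Infinium methylation array as assays \code{meth} and
#' \code{unmeth} (probes in rows, samples in columns). Row names are probe IDs,
#' column names are sample IDs; both must be unique and all intensities must be
#' finite and non-negative. Missing values are not supported.
#'
#' @seealso [SignalSet()] for the constructor, [readSignalSet()] to build one
#'   from delimited files, [getMeth()] and [getUnmeth()] for the assays.
#' @exportClass SignalSet
setClass("SignalSet", contains = "SummarizedExperiment")

.validSignalSet <- function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("meth", "unmeth") %in% an))
        return("assays 'meth' and 'unmeth' are required")
    m <- SummarizedExperiment::assay(object, "meth")
    u <- SummarizedExperiment::assay(object, "unmeth")
    if (!identical(dim(m), dim(u)))
        msg <- c(msg, "'meth' and 'unmeth' must have identical dimensions")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "probe IDs (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample IDs (colnames) must be present and unique")
    for (nm in c("meth", "unmeth")) {
        a <- SummarizedExperiment::assay(object, nm)
        if (!is.numeric(a) || anyNA(a) || any(!is.finite(a)))
            msg <- c(msg, sprintf("assay '%s' must be numeric, finite and non-missing", nm))
        else if (any(a < 0))
            msg <- c(msg, sprintf("assay '%s' contains negative intensities", nm))
    }
    if (length(msg)) msg else TRUE
}
setValidity("SignalSet", .validSignalSet)

#' Construct a SignalSet
#'
#' @param meth,unmeth Numeric matrices (probes x samples) of methylated and
#'   unmethylated intensities with identical dimnames. `unmeth` rows/columns
#'   are reindexed to `meth`'s order when the ID sets agree.
#' @return A validated [SignalSet-class] object.
#' @examples
#' m <- matrix(1:6 * 100, 3, 2, dimnames = list(paste0("cg", 1:3), c("S1", "S2")))
#' SignalSet(meth = m, unmeth = m / 2)
#' @export
SignalSet <- function(meth, unmeth) {
    meth <- as.matrix(meth)
    unmeth <- as.matrix(unmeth)
    if (is.null(rownames(meth)) || is.null(colnames(meth)))
        stop("'meth' must carry probe IDs as rownames and sample IDs as colnames")
    .checkIdSets(rownames(meth), rownames(unmeth), "probe")
    .checkIdSets(colnames(meth), colnames(unmeth), "sample")
    unmeth <- unmeth[rownames(meth), colnames(meth), drop = FALSE]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(meth = meth, unmeth = unmeth))
    new("SignalSet", se)
}

.checkIdSets <- function(a, b, what) {
    if (anyDuplicated(a) || anyDuplicated(b))
        stop(sprintf("duplicate %s IDs are not allowed", what))
    extraA <- setdiff(a, b)
    extraB <- setdiff(b, a)
    if (length(extraA) || length(extraB))
        stop(sprintf("%s ID mismatch between meth and unmeth; symmetric difference: %s",
                     what, paste(c(extraA, extraB), collapse = ", ")))
    invisible(TRUE)
}

#' PCAResult: principal component scores of the most variable probes
#'
#' Holds PCA output computed on autosomal Beta values: per-sample scores of the
#' retained components, the fraction of variance each retained component
#' explains, and the IDs of the probes selected by variance ranking.
#'
#' @slot sampleIds Character vector of sample IDs (score row order).
#' @slot scores Numeric matrix, samples x retained components.
#' @slot varianceRatio Fraction of total variance per retained component;
#'   non-increasing, sums to at most 1.
#' @slot selectedProbes IDs of the probes the PCA ran on (at most `nTop`).
#' @slot nTop The requested number of most-variable probes.
#' @exportClass PCAResult
setClass("PCAResult", representation(
    sampleIds = "character",
    scores = "matrix",
    varianceRatio = "numeric",
    selectedProbes = "character",
    nTop = "integer"))

.validPCAResult <- function(object) {
    msg <- character()
    if (nrow(object@scores) != length(object@sampleIds))
        msg <- c(msg, "score rows must match sampleIds")
    if (ncol(object@scores) != length(object@varianceRatio))
        msg <- c(msg, "one varianceRatio entry per score column required")
    vr <- object@varianceRatio
    if (length(vr)) {
        if (any(vr < -1e-12) || sum(vr) > 1 + 1e-8)
            msg <- c(msg, "varianceRatio entries must lie in [0,1] and sum to <= 1")
        if (is.unsorted(rev(vr), strictly = FALSE))
            msg <- c(msg, "varianceRatio must be non-increasing")
    }
    if (length(object@selectedProbes) > object@nTop)
        msg <- c(msg, "more selected probes than nTop")
    if (length(msg)) msg else TRUE
}
setValidity("PCAResult", .validPCAResult)

setClassUnion("PCAResultOrNULL", c("PCAResult", "NULL"))
setClassUnion("dataframeOrNULL", c("data.frame", "NULL"))

#' QCSummary: compact stratified quantile summary of a methylation experiment
#'
#' The central container of the package: for each probe stratum (type I green
#' autosomal, type I red autosomal, type II autosomal, pooled chrX, pooled
#' chrY, and all-autosomal) and each measure (M, U, CN, Beta, MValue for raw
#' data; Beta and MValue for normalized data) it stores a quantile table with
#' one column per sample on a shared probability grid. Size therefore grows
#' with sample count and grid size, never with probe count. Control-probe
#' summaries, PCA results and the phenotype table ride along, together with a
#' provenance record of the transformation parameters.
#'
#' @slot sampleIds Ordered sample IDs; every table column follows this order.
#' @slot probs Shared quantile probability grid (strictly increasing, 0 to 1).
#' @slot quantiles Named list, stratum -> measure -> matrix (probs x samples);
#'   an empty stratum holds NULL entries.
#' @slot strataCounts Named integer vector: probes per stratum in the data the
#'   summary was computed from (used e.g. for density bandwidth selection).
#' @slot controls Per (sample, control type) mean green/red/combined control
#'   intensities, or NULL for normalized summaries.
#' @slot pca A [PCAResult-class] or NULL.
#' @slot phenotypes The phenotype table (one row per sample).
#' @slot label "raw" or "normalized".
#' @slot params Provenance list: betaOffset, mvalueEpsilon, logitEpsilon,
#'   nTop, seed and friends.
#' @seealso [summarizeRaw()], [summarizeNormalized()], [writeSummary()].
#' @exportClass QCSummary
setClass("QCSummary", representation(
    sampleIds = "character",
    probs = "numeric",
    quantiles = "list",
    strataCounts = "integer",
    controls = "dataframeOrNULL",
    pca = "PCAResultOrNULL",
    phenotypes = "data.frame",
    label = "character",
    params = "list"))

.validQCSummary <- function(object) {
    msg <- character()
    p <- object@probs
    if (length(p) < 2 || p[1] != 0 || p[length(p)] != 1 || is.unsorted(p, strictly = TRUE))
        msg <- c(msg, "probs must be strictly increasing from 0 to 1")
    if (!object@label %in% c("raw", "normalized"))
        msg <- c(msg, "label must be 'raw' or 'normalized'")
    if (!all(names(object@quantiles) %in% .STRATA))
        msg <- c(msg, "unknown stratum name in quantiles")
    for (st in names(object@quantiles)) {
        for (me in names(object@quantiles[[st]])) {
            q <- object@quantiles[[st]][[me]]
            if (is.null(q)) next
            if (nrow(q) != length(p))
                msg <- c(msg, sprintf("%s/%s: rows must match the probability grid", st, me))
            if (!identical(colnames(q), object@sampleIds))
                msg <- c(msg, sprintf("%s/%s: columns must match sampleIds", st, me))
            if (anyNA(q) || any(!is.finite(q)))
                msg <- c(msg, sprintf("%s/%s: non-finite quantiles", st, me))
            else {
                if (ncol(q) && any(apply(q, 2, is.unsorted)))
                    msg <- c(msg, sprintf("%s/%s: quantile columns must be non-decreasing", st, me))
                if (me == "Beta" && (any(q < 0) || any(q > 1)))
                    msg <- c(msg, sprintf("%s/Beta quantiles must lie in [0, 1]", st))
                if (me %in% c("M", "U", "CN") && any(q < 0))
                    msg <- c(msg, sprintf("%s/%s quantiles must be non-negative", st, me))
            }
        }
    }
    if (nrow(object@phenotypes) && !identical(object@phenotypes$sample_id, object@sampleIds))
        msg <- c(msg, "phenotypes$sample_id must equal sampleIds in order")
    if (length(msg)) msg else TRUE
}
setValidity("QCSummary", .validQCSummary)
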