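#' Transformation parameters for methylation summaries
#'
#' Bundles the constants used when deriving Beta values, M-values and quantile
#' summaries from raw channel intensities.
#'
#' @param betaOffset Non-negative offset in the Beta denominator,
#'   Beta = M / (M + U + offset). Default 100, the platform-standard value that
#'   shrinks Beta towards 0 at low total intensity.
#' @param mvalueEpsilon Positive count added to both channels before the log
#'   ratio, M-value = log2((M + eps) / (U + eps)). Default 1.
#' @param logitEpsilon Clipping bound used when converting normalized Beta
#'   values to M-values via logit2; Beta is clipped to
#'   [logitEpsilon, 1 - logitEpsilon]. Default 1e-6.
#' @param quantileProbs Probability grid for all quantile tables. Strictly
#'   increasing, starting at 0 and ending at 1. Default 501 evenly spaced
#'   points, which contains 0, 0.5 and 1 exactly so stored medians are exact.
#' @return A list of class `TransformParams`.
#' @examples
#' transformParams()$betaOffset
#' @export
transformParams <- function(betaOffset = 100, mvalueEpsilon = 1,
                            logitEpsilon = 1e-6,
                            quantileProbs = seq(0, 1, length.out = 501)) {
    if (!is.numeric(betaOffset) || length(betaOffset) != 1 || betaOffset < 0)
        stop("'betaOffset' must be a single non-negative number")
    if (!is.numeric(mvalueEpsilon) || length(mvalueEpsilon) != 1 ||
        mvalueEpsilon <= 0)
        stop("'mvalueEpsilon' must be a single positive number")
    if (!is.numeric(logitEpsilon) || length(logitEpsilon) != 1 ||
        logitEpsilon <= 0 || logitEpsilon >= 0.5)
        stop("'logitEpsilon' must lie in (0, 0.5)")
    .checkProbs(quantileProbs)
    structure(list(betaOffset = betaOffset, mvalueEpsilon = mvalueEpsilon,
                   logitEpsilon = logitEpsilon, quantileProbs = quantileProbs),
              class = "TransformParams")
}

.checkProbs <- function(probs) {
    if (!is.numeric(probs) || length(probs) < 2 || anyNA(probs))
        stop("'quantileProbs' must be a numeric grid of at least 2 probabilities")
    if (probs[1] != 0 || probs[length(probs)] != 1)
        stop("'quantileProbs' must start at 0 and end at 1")
    if (is.unsorted(probs, strictly = TRUE))
        stop("'quantileProbs' must be strictly increasing")
    invisible(probs)
}

.checkShapes <- function(meth, unmeth) {
    if (!identical(dim(meth), dim(unmeth)))
        stop("'meth' and 'unmeth' must have identical dimensions")
    invisible(TRUE)
}

#' Copy-number, Beta-value and M-value transforms
#'
#' Elementwise transforms of paired methylated (M) and unmethylated (U)
#' intensities: total copy number CN = M + U; methylation proportion
#' Beta = M / (M + U + offset); log ratio M-value = log2((M + eps)/(U + eps)).
#'
#' @param meth,unmeth Numeric matrices or vectors of identical shape.
#' @param betaOffset Non-negative denominator offset (default 100). With
#'   offset 0 and M = U = 0 the Beta value is defined as 0.
#' @param mvalueEpsilon Positive stabilising count (default 1).
#' @return An object of the same shape as the inputs.
#' @examples
#' computeCN(500, 300)                   # 800
#' computeBeta(1000, 1000)               # 1000/2100
#' computeMValue(100, 400)               # log2(101/401)
#' @export
computeCN <- function(meth, unmeth) {
    .checkShapes(meth, unmeth)
    meth + unmeth
}

#' @rdname computeCN
#' @export
computeBeta <- function(meth, unmeth, betaOffset = 100) {
    .checkShapes(meth, unmeth)
    if (!is.numeric(betaOffset) || length(betaOffset) != 1 || betaOffset < 0)
        stop("'betaOffset' must be a single non-negative number")
    denom <- meth + unmeth + betaOffset
    beta <- meth / denom
    beta[denom == 0] <- 0  # only reachable when betaOffset == 0 and M = U = 0
    beta
}

#' @rdname computeCN
#' @export
computeMValue <- function(meth, unmeth, mvalueEpsilon = 1) {
    .checkShapes(meth, unmeth)
    if (!is.numeric(mvalueEpsilon) || length(mvalueEpsilon) != 1 ||
        mvalueEpsilon <= 0)
        stop("'mvalueEpsilon' must be a single positive number")
    log2((meth + mvalueEpsilon) / (unmeth + mvalueEpsilon))
}

#' M-values from normalized Beta values
#'
#' logit2 transform used for normalized data where raw channels are no longer
#' available: M-value = log2(Beta / (1 - Beta)) with Beta clipped to
#' [eps, 1 - eps] to avoid infinities.
#'
#' @param beta Numeric in [0, 1].
#' @param logitEpsilon Clipping bound in (0, 0.5).
#' @return Same shape as `beta`.
#' @export
logit2Beta <- function(beta, logitEpsilon = 1e-6) {
    if (anyNA(beta) || any(beta < 0) || any(beta > 1))
        stop("Beta values must lie in [0, 1] with no missing values")
    b <- pmin(pmax(beta, logitEpsilon), 1 - logitEpsilon)
    out <- log2(b / (1 - b))
    if (is.matrix(beta)) dim(out) <- dim(beta)
    dimnames(out) <- dimnames(beta)
    out
}

#' Quantile summary of a vector
#'
#' Linear-interpolation sample quantiles (type 7: h = (n - 1) p + 1) of a
#' vector of finite values on a probability grid. The backbone of every
#' quantile table stored in a [QCSummary-class].
#'
#' @param values Non-empty numeric vector, all finite.
#' @param probs Probability grid as in [transformParams()].
#' @return Numeric vector of quantiles, non-decreasing; the minimum at p = 0
#'   and the maximum at p = 1.
#' @examples
#' quantileSummary(1:5, c(0, 0.5, 1))  # 1 3 5
#' @export
quantileSummary <- function(values, probs = seq(0, 1, length.out = 501)) {
    if (length(values) == 0)
        stop("'values' must be non-empty")
    if (anyNA(values) || any(!is.finite(values)))
        stop("'values' must be finite with no missing values")
    .checkProbs(probs)
    stats::quantile(values, probs = probs, type = 7, names = FALSE)
}
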