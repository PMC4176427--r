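#' Select the most variable probes
#'
#' Ranks probes by across-sample population variance (denominator n) and
#' returns the IDs of the top `nTop`; ties at the boundary are broken by
#' lexicographic probe ID so the selection is deterministic. When fewer than
#' `nTop` probes exist, all are returned.
#'
#' @param beta Numeric matrix (probes x samples) with probe IDs as rownames.
#' @param nTop Number of probes to keep (default 20000).
#' @return Character vector of selected probe IDs, in decreasing-variance
#'   order.
#' @export
selectTopVariable <- function(beta, nTop = 20000) {
    if (!is.matrix(beta) || nrow(beta) == 0)
        stop("'beta' must be a non-empty matrix")
    if (is.null(rownames(beta)))
        stop("'beta' must carry probe IDs as rownames")
    mu <- rowMeans(beta)
    v <- rowMeans((beta - mu)^2)  # population variance
    ord <- order(-v, rownames(beta), method = "radix")
    rownames(beta)[ord[seq_len(min(nTop, nrow(beta)))]]
}

#' Principal component analysis of Beta values
#'
#' PCA of the samples on the given probe subset: probes are mean-centred (no
#' unit-variance scaling, since Beta values already share a scale) and the
#' centred samples x probes matrix is decomposed by SVD. Scores are the left
#' singular vectors scaled by their singular values; each score column's sign
#' is fixed so its largest-magnitude entry is positive, making stored
#' summaries reproducible bit-for-bit. The explained-variance ratio is
#' computed over all components, of which the first
#' `min(maxComponents, samples - 1)` are retained.
#'
#' @param betaSubset Numeric matrix (probes x samples), typically the output
#'   of [selectTopVariable()] rows; at least 2 samples.
#' @param maxComponents Maximum number of components to retain (default 10).
#' @param nTop Recorded in the result as the selection size that produced
#'   `betaSubset`.
#' @return A [PCAResult-class].
#' @export
runPCA <- function(betaSubset, maxComponents = 10, nTop = nrow(betaSubset)) {
    if (!is.matrix(betaSubset)) betaSubset <- as.matrix(betaSubset)
    n <- ncol(betaSubset)
    if (n < 2)
        stop("PCA requires at least 2 samples")
    x <- t(betaSubset)                      # samples x probes
    x <- sweep(x, 2, colMeans(x), "-")      # centre each probe
    sv <- svd(x)
    total <- sum(sv$d^2)
    keep <- seq_len(min(maxComponents, n - 1))
    ratio <- if (total > 0) sv$d[keep]^2 / total else rep(0, length(keep))
    scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], nrow = length(keep))
    for (j in seq_len(ncol(scores))) {
        i <- which.max(abs(scores[, j]))
        if (scores[i, j] < 0) scores[, j] <- -scores[, j]
    }
    dimnames(scores) <- NULL
    new("PCAResult",
        sampleIds = colnames(betaSubset),
        scores = scores,
        varianceRatio = ratio,
        selectedProbes = rownames(betaSubset),
        nTop = as.integer(nTop))
}

#' Association of principal components with a covariate
#'
#' One-way ANOVA of each retained score column on a categorical covariate — a
#' numeric counterpart of eyeballing coloured score plots for batch or
#' phenotype structure. Perfect separation with zero within-group variance is
#' reported as `F = Inf`, `p = 0` with `degenerate = TRUE`.
#'
#' @param pca A [PCAResult-class].
#' @param covariate Vector (coerced to factor) with one value per sample, at
#'   least two levels, each level with at least two samples.
#' @return Data frame with columns `component`, `F`, `p`, `degenerate`.
#' @export
pcAssociation <- function(pca, covariate) {
    stopifnot(is(pca, "PCAResult"))
    g <- factor(covariate)
    n <- length(pca@sampleIds)
    if (length(g) != n)
        stop("'covariate' must have one value per sample")
    if (anyNA(g))
        stop("'covariate' must not contain missing values")
    if (nlevels(g) < 2)
        stop("'covariate' must have at least 2 levels")
    if (any(table(g) < 2))
        stop("every covariate level needs at least 2 samples")
    k <- nlevels(g)
    out <- data.frame(component = seq_len(ncol(pca@scores)),
                      F = NA_real_, p = NA_real_, degenerate = FALSE)
    for (j in seq_len(ncol(pca@scores))) {
        y <- pca@scores[, j]
        gm <- tapply(y, g, mean)
        ssb <- sum(table(g) * (gm - mean(y))^2)
        ssw <- sum((y - gm[g])^2)
        if (ssw <= .Machine$double.eps * sum(y^2)) {
            if (ssb > 0) {
                out$F[j] <- Inf; out$p[j] <- 0; out$degenerate[j] <- TRUE
            } else {
                out$F[j] <- 0; out$p[j] <- 1
            }
        } else {
            f <- (ssb / (k - 1)) / (ssw / (n - k))
            out$F[j] <- f
            out$p[j] <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
        }
    }
    out
}

#' Physical slide layout of the samples
#'
#' Parses Sentrix-style positions (`R01C01` .. `R06C02`, the 6 x 2 grid of a
#' 450k 12-sample slide) from the phenotype table and attaches a covariate for
#' colouring, so physical placement can be checked for confounding with the
#' study design.
#'
#' @param phenotypes Phenotype data frame with `slide` and `array_position`
#'   columns.
#' @param covariate Name of the phenotype column used for colouring.
#' @param nRows,nCols Slide geometry (defaults: 6 rows x 2 columns).
#' @return Data frame with columns `sample_id`, `slide`, `row`, `col`,
#'   `covariate`.
#' @export
arrayLayout <- function(phenotypes, covariate, nRows = 6, nCols = 2) {
    need <- c("sample_id", "slide", "array_position")
    if (!all(need %in% names(phenotypes)))
        stop("phenotype table must have columns: ", paste(need, collapse = ", "))
    if (!covariate %in% names(phenotypes))
        stop(sprintf("covariate '%s' not found; available: %s", covariate,
                     paste(setdiff(names(phenotypes), "sample_id"),
                           collapse = ", ")))
    pos <- as.character(phenotypes$array_position)
    ok <- grepl("^R[0-9]{2}C[0-9]{2}$", pos)
    if (any(!ok))
        stop("malformed array_position for sample(s): ",
             paste(phenotypes$sample_id[!ok], collapse = ", "))
    row <- as.integer(substr(pos, 2, 3))
    col <- as.integer(substr(pos, 5, 6))
    bad <- row < 1 | row > nRows | col < 1 | col > nCols
    if (any(bad))
        stop(sprintf("array_position outside the %d x %d slide grid for sample(s): %s",
                     nRows, nCols,
                     paste(phenotypes$sample_id[bad], collapse = ", ")))
    key <- paste(phenotypes$slide, pos)
    if (anyDuplicated(key))
        stop("duplicate (slide, position) pairs: ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
    data.frame(sample_id = phenotypes$sample_id,
               slide = as.character(phenotypes$slide),
               row = row, col = col,
               covariate = phenotypes[[covariate]],
               stringsAsFactors = FALSE)
}
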