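# Independent oracles and small fixture builders shared across test files.

# Type-7 sample quantile by explicit sort-and-interpolate:
# h = (n - 1) p + 1, linear interpolation between order statistics.
oracleQuantile <- function(x, probs) {
    xs <- sort(x)
    n <- length(xs)
    vapply(probs, function(p) {
        h <- (n - 1) * p + 1
        lo <- floor(h)
        hi <- ceiling(h)
        xs[lo] + (h - lo) * (xs[hi] - xs[lo])
    }, numeric(1))
}

# Grouped means over the control table by explicit loops.
oracleControlMeans <- function(controls) {
    out <- NULL
    for (s in sort(unique(controls$sample_id))) {
        for (tp in sort(unique(controls$control_type[controls$sample_id == s]))) {
            sub <- controls[controls$sample_id == s & controls$control_type == tp, ]
            out <- rbind(out, data.frame(
                sample_id = s, control_type = tp,
                mean_green = mean(sub$green), mean_red = mean(sub$red),
                mean_combined = (mean(sub$green) + mean(sub$red)) / 2,
                stringsAsFactors = FALSE))
        }
    }
    rownames(out) <- NULL
    out
}

# Minimal handmade inputs --------------------------------------------------

tinySignalMatrices <- function(nProbes = 6, nSamples = 3, seed = 7) {
    set.seed(seed)
    dn <- list(sprintf("cg%03d", seq_len(nProbes)),
               sprintf("S%d", seq_len(nSamples)))
    list(meth = matrix(rexp(nProbes * nSamples, 1 / 3000), nProbes, nSamples,
                       dimnames = dn),
         unmeth = matrix(rexp(nProbes * nSamples, 1 / 3000), nProbes, nSamples,
                         dimnames = dn))
}

tinyManifest <- function(probeIds) {
    n <- length(probeIds)
    type <- rep(c("I", "I", "II"), length.out = n)
    data.frame(probe_id = probeIds,
               infinium_type = type,
               channel = ifelse(type == "I",
                                rep(c("Grn", "Red"), length.out = n), NA),
               chromosome = rep(c("chr1", "chr2", "chrX", "chrY"),
                                length.out = n),
               stringsAsFactors = FALSE)
}

writeSignalFile <- function(mat, path, sep = "\t") {
    df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    path
}

# A small summarized clean dataset reused by several files (computed once).
cleanSummaryFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            d <- generateDataset(simPreset("clean_small"))
            s <- summarizeRaw(d$signals, d$manifest, d$controls, d$phenotypes)
            cache <<- list(data = d, summary = s)
        }
        cache
    }
})
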