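test_that("median channel intensities are log2 of brute-force autosomal medians", {
    d <- generateDataset(simParams(nProbesAutosomal = 500, nProbesX = 60,
                                   nProbesY = 60, nSamples = 6, seed = 21))
    s <- summarizeRaw(d$signals, d$manifest, d$controls, d$phenotypes)
    qc <- medianChannelIntensities(s)
    man <- d$manifest
    auto <- man$probe_id[!man$chromosome %in% c("chrX", "chrY")]
    expect_equal(qc$median_log2_meth,
                 log2(apply(getMeth(d$signals)[auto, ], 2, median)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(qc$median_log2_unmeth,
                 log2(apply(getUnmeth(d$signals)[auto, ], 2, median)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    ## NEGATIVE control means ride along
    ctl <- controlSummary(s)
    neg <- ctl[ctl$control_type == "NEGATIVE", ]
    expect_equal(qc$mean_negative_control,
                 neg$mean_combined[match(qc$sample_id, neg$sample_id)])
    ## invariant to probe permutation within the matrices
    perm <- sample(nrow(getMeth(d$signals)))
    s2 <- summarizeRaw(SignalSet(getMeth(d$signals)[perm, ],
                                 getUnmeth(d$signals)[perm, ]),
                       d$manifest)
    expect_equal(medianChannelIntensities(s2)$median_log2_meth,
                 qc$median_log2_meth, tolerance = 1e-12)
})

test_that("powers of two and zero medians are handled as documented", {
    m <- matrix(1024, 20, 2, dimnames = list(sprintf("cg%03d", 1:20),
                                             c("A", "B")))
    u <- m
    u[, 2] <- 0  # all-zero unmethylated channel for sample B
    s <- summarizeRaw(SignalSet(m, u), tinyManifest(rownames(m)))
    qc <- medianChannelIntensities(s)
    expect_equal(qc$median_log2_meth, c(10, 10))
    expect_equal(qc$median_log2_unmeth[1], 10)
    ## zero median: floored to 1 (log2 = 0) and flagged immediately
    expect_equal(qc$median_log2_unmeth[2], 0)
    expect_true(qc$flagged[2])
    expect_match(qc$flag_reason[2], "zero_median")
    expect_false(qc$flagged[1])
})

test_that("flagging applies the mean-log2-median rule and is monotone in the cutoff", {
    qc <- data.frame(sample_id = c("A", "B"),
                     median_log2_meth = c(12, 9),
                     median_log2_unmeth = c(12, 9),
                     mean_negative_control = NA_real_,
                     flagged = FALSE, flag_reason = "",
                     stringsAsFactors = FALSE)
    out <- flagLowQuality(qc, cutoff = 10.5)
    expect_identical(out$flagged, c(FALSE, TRUE))
    expect_identical(out$flag_reason, c("", "low_median_intensity"))

    ## monotone: raising the cutoff never unflags
    set.seed(22)
    rqc <- data.frame(sample_id = sprintf("S%02d", 1:30),
                      median_log2_meth = runif(30, 8, 13),
                      median_log2_unmeth = runif(30, 8, 13),
                      mean_negative_control = NA_real_,
                      flagged = FALSE, flag_reason = "",
                      stringsAsFactors = FALSE)
    prev <- rep(FALSE, 30)
    for (cut in seq(8, 13, by = 0.5)) {
        cur <- flagLowQuality(rqc, cutoff = cut)$flagged
        expect_true(all(cur[prev]))  # once flagged, stays flagged
        prev <- cur
    }
})

test_that("normalized summaries have no channel medians", {
    d <- generateDataset(simParams(nProbesAutosomal = 100, nProbesX = 20,
                                   nProbesY = 20, nSamples = 3, seed = 23))
    beta <- computeBeta(getMeth(d$signals), getUnmeth(d$signals))
    sn <- summarizeNormalized(beta, d$manifest)
    expect_error(medianChannelIntensities(sn), "raw summary")
})

test_that("density curves integrate to ~1, share a grid, and respect symmetry", {
    d <- generateDataset(simParams(nProbesAutosomal = 2000, nProbesX = 100,
                                   nProbesY = 100, nSamples = 5, seed = 24))
    s <- summarizeRaw(d$signals, d$manifest)
    dc <- densityCurves(s, "Beta", "autosomal")
    expect_equal(length(dc$grid), 512)
    expect_true(all(dc$density >= 0))
    dx <- diff(dc$grid)
    for (j in seq_len(ncol(dc$density))) {
        integral <- sum((dc$density[-1, j] + dc$density[-512, j]) / 2 * dx)
        expect_gt(integral, 0.97)
        expect_lt(integral, 1.03)
    }
    expect_error(densityCurves(s, "Beta", "nope"), "arg")

    ## symmetric bimodal quantile input -> density symmetric about 0.5
    set.seed(241)
    probs <- seq(0, 1, length.out = 501)
    qsym <- oracleQuantile(c(rbeta(5000, 8, 30), 1 - rbeta(5000, 8, 30)), probs)
    half <- (qsym + rev(1 - qsym)) / 2         # enforce exact symmetry
    ssym <- new("QCSummary", sampleIds = "A", probs = probs,
                quantiles = list(autosomal = list(Beta = matrix(half, ncol = 1,
                    dimnames = list(NULL, "A")))),
                strataCounts = c(IGrn = 0L, IRed = 0L, II = 0L, chrX = 0L,
                                 chrY = 0L, autosomal = 10000L),
                controls = NULL, pca = NULL,
                phenotypes = data.frame(sample_id = "A"),
                label = "raw", params = list())
    dsym <- densityCurves(ssym, "Beta", "autosomal", nGrid = 401)
    mid <- (dsym$grid + rev(dsym$grid)) / 2
    expect_equal(mean(mid), 0.5, tolerance = 1e-9)
    expect_equal(dsym$density[, 1], rev(dsym$density[, 1]), tolerance = 1e-6)
})

test_that("a constant pseudo-sample produces a finite spike at the constant", {
    probs <- seq(0, 1, length.out = 501)
    s <- new("QCSummary", sampleIds = "A", probs = probs,
             quantiles = list(autosomal = list(Beta = matrix(0.42, 501, 1,
                 dimnames = list(NULL, "A")))),
             strataCounts = c(IGrn = 0L, IRed = 0L, II = 0L, chrX = 0L,
                              chrY = 0L, autosomal = 100L),
             controls = NULL, pca = NULL,
             phenotypes = data.frame(sample_id = "A"),
             label = "raw", params = list())
    dc <- densityCurves(s, "Beta", "autosomal")
    expect_true(all(is.finite(dc$density)))
    expect_equal(dc$grid[which.max(dc$density[, 1])], 0.42, tolerance = 1e-3)
})

test_that("quantile-reconstructed densities track the full-matrix KDE", {
    d <- generateDataset(simParams(nProbesAutosomal = 10000, nProbesX = 100,
                                   nProbesY = 100, nSamples = 4, seed = 25))
    s <- summarizeRaw(d$signals, d$manifest)
    dc <- densityCurves(s, "Beta", "autosomal")
    beta <- computeBeta(getMeth(d$signals), getUnmeth(d$signals))
    man <- d$manifest
    auto <- man$probe_id[!man$chromosome %in% c("chrX", "chrY")]
    for (j in seq_along(sampleIDs(s))) {
        full <- density(beta[auto, j], bw = "nrd0",
                        from = dc$grid[1], to = dc$grid[512], n = 512)$y
        peak <- max(full)
        expect_lt(max(abs(dc$density[, j] - full)), 0.05 * peak)
    }
})
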