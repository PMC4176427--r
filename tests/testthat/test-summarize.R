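test_that("stratification partitions the probes and quantiles match a brute-force oracle", {
    set.seed(11)
    d <- generateDataset(simParams(nProbesAutosomal = 800, nProbesX = 100,
                                   nProbesY = 100, nSamples = 8, seed = 11))
    s <- summarizeRaw(d$signals, d$manifest, d$controls, d$phenotypes)
    counts <- strataCounts(s)
    expect_identical(counts[["IGrn"]] + counts[["IRed"]] + counts[["II"]] +
                     counts[["chrX"]] + counts[["chrY"]],
                     nrow(d$manifest))
    expect_identical(counts[["autosomal"]],
                     counts[["IGrn"]] + counts[["IRed"]] + counts[["II"]])

    ## brute-force: filter the manifest by hand, recompute Beta, take oracle
    ## quantiles of the IGrn subset for every sample
    man <- d$manifest
    keep <- man$probe_id[man$infinium_type == "I" & !is.na(man$channel) &
                         man$channel == "Grn" &
                         !man$chromosome %in% c("chrX", "chrY")]
    beta <- computeBeta(getMeth(d$signals), getUnmeth(d$signals), 100)
    probs <- quantileProbs(s)
    for (j in sampleIDs(s)) {
        expect_equal(quantileTable(s, "IGrn", "Beta")[, j],
                     oracleQuantile(beta[keep, j], probs), tolerance = 1e-12)
    }
    ## chrY pools both chemistries
    yprobes <- man$probe_id[man$chromosome == "chrY"]
    cn <- computeCN(getMeth(d$signals), getUnmeth(d$signals))
    expect_equal(quantileTable(s, "chrY", "CN")[, 3],
                 oracleQuantile(cn[yprobes, 3], probs), tolerance = 1e-12)
})

test_that("a probe missing from the manifest is a hard error listing offenders", {
    sig <- tinySignalMatrices(6, 3)
    ss <- SignalSet(sig$meth, sig$unmeth)
    man <- tinyManifest(rownames(sig$meth)[1:4])
    expect_error(summarizeRaw(ss, man), "cg005")
})

test_that("an empty stratum warns, records zero probes, and blocks sex prediction", {
    sig <- tinySignalMatrices(6, 3)
    ss <- SignalSet(sig$meth, sig$unmeth)
    man <- tinyManifest(rownames(sig$meth))
    man$chromosome[man$chromosome == "chrY"] <- "chr5"  # no chrY anywhere
    expect_warning(s <- summarizeRaw(ss, man), "chrY")
    expect_identical(strataCounts(s)[["chrY"]], 0L)
    expect_null(quantileTable(s, "chrY", "CN"))
    expect_error(sexDifference(s), "chrY")
})

test_that("identical sample columns give identical quantile columns", {
    sig <- tinySignalMatrices(12, 1)
    m <- cbind(S1 = sig$meth[, 1], S2 = sig$meth[, 1], S3 = sig$meth[, 1])
    u <- cbind(S1 = sig$unmeth[, 1], S2 = sig$unmeth[, 1], S3 = sig$unmeth[, 1])
    rownames(m) <- rownames(u) <- rownames(sig$meth)
    s <- summarizeRaw(SignalSet(m, u), tinyManifest(rownames(m)))
    for (st in names(strataCounts(s))) {
        q <- quantileTable(s, st, "MValue")
        if (is.null(q)) next
        expect_identical(q[, "S1"], q[, "S2"])
        expect_identical(q[, "S1"], q[, "S3"])
    }
})

test_that("summaries are scale-equivariant in the raw intensities", {
    d <- generateDataset(simParams(nProbesAutosomal = 300, nProbesX = 50,
                                   nProbesY = 50, nSamples = 4, seed = 12))
    cfac <- 3.7
    s1 <- summarizeRaw(d$signals, d$manifest)
    scaled <- SignalSet(getMeth(d$signals) * cfac, getUnmeth(d$signals) * cfac)
    s2 <- summarizeRaw(scaled, d$manifest,
                       params = transformParams(betaOffset = 100 * cfac,
                                                mvalueEpsilon = 1 * cfac))
    for (me in c("M", "U", "CN"))
        expect_equal(quantileTable(s2, "autosomal", me),
                     cfac * quantileTable(s1, "autosomal", me),
                     tolerance = 1e-12)
    expect_equal(quantileTable(s2, "autosomal", "Beta"),
                 quantileTable(s1, "autosomal", "Beta"), tolerance = 1e-12)
    expect_equal(quantileTable(s2, "II", "MValue"),
                 quantileTable(s1, "II", "MValue"), tolerance = 1e-12)
})

test_that("permuting sample columns permutes summary columns with no leakage", {
    d <- generateDataset(simParams(nProbesAutosomal = 200, nProbesX = 40,
                                   nProbesY = 40, nSamples = 5, seed = 13))
    perm <- c(4, 2, 5, 1, 3)
    m <- getMeth(d$signals)[, perm]
    u <- getUnmeth(d$signals)[, perm]
    s1 <- summarizeRaw(d$signals, d$manifest)
    s2 <- summarizeRaw(SignalSet(m, u), d$manifest)
    expect_identical(sampleIDs(s2), sampleIDs(s1)[perm])
    expect_identical(unname(quantileTable(s2, "autosomal", "Beta")),
                     unname(quantileTable(s1, "autosomal", "Beta")[, perm]))
})

test_that("normalized summaries store Beta and logit2 M-values on the shared grid", {
    d <- generateDataset(simParams(nProbesAutosomal = 300, nProbesX = 50,
                                   nProbesY = 50, nSamples = 4, seed = 14))
    beta <- computeBeta(getMeth(d$signals), getUnmeth(d$signals))
    sr <- summarizeRaw(d$signals, d$manifest)
    sn <- summarizeNormalized(beta, d$manifest)
    expect_identical(summaryLabel(sn), "normalized")
    expect_null(controlSummary(sn))
    expect_identical(quantileProbs(sn), quantileProbs(sr))
    expect_error(quantileTable(sn, "autosomal", "M"), "not stored")

    half <- matrix(0.5, 20, 3,
                   dimnames = list(sprintf("cg%03d", 1:20), c("A", "B", "C")))
    s05 <- suppressWarnings(summarizeNormalized(half, tinyManifest(rownames(half))))
    expect_true(all(quantileTable(s05, "autosomal", "MValue") == 0))

    probs <- quantileProbs(sn)
    man <- d$manifest
    auto <- man$probe_id[!man$chromosome %in% c("chrX", "chrY")]
    expect_equal(quantileTable(sn, "autosomal", "Beta")[, 2],
                 oracleQuantile(beta[auto, 2], probs), tolerance = 1e-12)

    bad <- beta; bad[1, 1] <- 1.4
    expect_error(summarizeNormalized(bad, d$manifest), "\\[0, 1\\]")
})

test_that("control summaries equal a grouped-loop oracle", {
    one <- data.frame(control_id = "c1", control_type = "NEGATIVE",
                      sample_id = "S1", green = 100, red = 200)
    expect_equal(summarizeControls(one)[, c("mean_green", "mean_red", "mean_combined")],
                 data.frame(mean_green = 100, mean_red = 200, mean_combined = 150))
    two <- rbind(one, data.frame(control_id = "c2", control_type = "NEGATIVE",
                                 sample_id = "S1", green = 300, red = 220))
    expect_equal(summarizeControls(two)$mean_green, 200)

    set.seed(15)
    tab <- data.frame(
        control_id = rep(sprintf("c%02d", 1:8), each = 3),
        control_type = rep(c("NEGATIVE", "STAINING"), each = 12),
        sample_id = rep(c("S1", "S2", "S3"), 8),
        green = rexp(24, 1 / 100), red = rexp(24, 1 / 100),
        stringsAsFactors = FALSE)
    got <- summarizeControls(tab)
    want <- oracleControlMeans(tab)
    expect_equal(got[order(got$sample_id, got$control_type), ], want,
                 ignore_attr = TRUE)
})
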