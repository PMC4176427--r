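#' Simulation parameters for 450k-like synthetic datasets
#'
#' Bundles and validates the knobs of [generateDataset()]. Defaults describe a
#' clean, realistic array: total intensity (CN) lognormal around 5000 units,
#' multiplicative intensity noise of 0.3 on the log2 scale, a 1.5 log2-unit
#' chrY copy-number separation between the sexes, and low-quality samples at
#' 15% of normal intensity.
#'
#' @param nProbesAutosomal,nProbesX,nProbesY Probe counts per compartment.
#' @param fractionType1 Fraction of probes on the type I chemistry (split
#'   evenly between the Grn and Red channels); default 0.3, close to the
#'   platform's 28%.
#' @param nSamples Number of samples.
#' @param sexVector Optional explicit vector of true sexes ("M"/"F"); when
#'   NULL, sexes are drawn with `sexRatio` males.
#' @param sexRatio Fraction of male samples when `sexVector` is NULL.
#' @param batchLabels Optional explicit per-sample batch labels; when NULL and
#'   `batchShiftBeta > 0`, samples split into two equal batches.
#' @param batchShiftBeta Additive Beta shift applied to affected probes in the
#'   second batch (clipped to [0, 1]).
#' @param batchProbeFraction Fraction of autosomal probes carrying the batch
#'   shift.
#' @param sexLog2Shift chrY copy-number increase in log2 units for male
#'   samples (their chrX copy number is halved); default 1.5.
#' @param noiseSdLog2 SD of the multiplicative intensity noise, log2 scale;
#'   default 0.3.
#' @param baselineIntensity Median total intensity per probe; default 5000.
#' @param nLowQuality Number of injected degraded samples.
#' @param lowQualityFactor Intensity multiplier for degraded samples, in
#'   (0, 1); default 0.15.
#' @param nSexFlips Number of samples whose *reported* sex is deliberately
#'   mislabelled.
#' @param seed RNG seed; the whole dataset is drawn from one stream seeded
#'   once (probes, then samples, then controls), so equal seeds give
#'   bit-identical datasets.
#' @return A list of class `SimParams`.
#' @export
simParams <- function(nProbesAutosomal = 2000, nProbesX = 200, nProbesY = 200,
                      fractionType1 = 0.3, nSamples = 8,
                      sexVector = NULL, sexRatio = 0.5,
                      batchLabels = NULL, batchShiftBeta = 0,
                      batchProbeFraction = 0,
                      sexLog2Shift = 1.5, noiseSdLog2 = 0.3,
                      baselineIntensity = 5000,
                      nLowQuality = 0, lowQualityFactor = 0.15,
                      nSexFlips = 0, seed = 1) {
    stopifnot(nProbesAutosomal >= 0, nProbesX >= 0, nProbesY >= 0,
              nSamples >= 1,
              fractionType1 >= 0, fractionType1 <= 1,
              sexRatio >= 0, sexRatio <= 1,
              batchShiftBeta >= 0, batchProbeFraction >= 0,
              batchProbeFraction <= 1,
              noiseSdLog2 >= 0, baselineIntensity > 0,
              nLowQuality >= 0, lowQualityFactor > 0, lowQualityFactor < 1,
              nSexFlips >= 0)
    if (nSexFlips > nSamples)
        stop("'nSexFlips' cannot exceed 'nSamples'")
    if (!is.null(sexVector)) {
        if (length(sexVector) != nSamples || !all(sexVector %in% c("M", "F")))
            stop("'sexVector' must give 'M'/'F' for every sample")
    }
    if (!is.null(batchLabels) && length(batchLabels) != nSamples)
        stop("'batchLabels' must give a label for every sample")
    structure(as.list(environment()), class = "SimParams")
}

#' Generate a synthetic 450k-like dataset
#'
#' Draws a complete, seeded dataset in the formats the rest of the package
#' consumes. Per-probe methylation states come from a trimodal mixture
#' (unmethylated ~ Beta 0.1, methylated ~ 0.9, hemimethylated ~ 0.5, weights
#' 0.45 / 0.45 / 0.10); intensities are `M = CN * beta * exp(e1)`,
#' `U = CN * (1 - beta) * exp(e2)` with CN lognormal around the baseline and
#' independent multiplicative noise per channel (a shared noise term would
#' cancel out of Beta entirely). Males get chrY copy number scaled by
#' `2^sexLog2Shift` and chrX halved; batch 2 samples get `batchShiftBeta`
#' added to the Beta of the affected probes; low-quality samples have *all*
#' intensities (controls included) multiplied by `lowQualityFactor`. NEGATIVE
#' control probes sit at 2% of the baseline, BISULFITE_CONVERSION_I controls
#' at 80%.
#'
#' @param params A [simParams()] record.
#' @return A list with elements `signals` ([SignalSet-class]), `manifest`,
#'   `controls`, `phenotypes` (data frames as the io readers return) and
#'   `truth`, a record of the generating ground truth (true sexes, flipped
#'   labels, low-quality IDs, batch labels, batch-affected probes).
#' @export
generateDataset <- function(params = simParams()) {
    stopifnot(inherits(params, "SimParams"))
    set.seed(params$seed)
    nA <- params$nProbesAutosomal; nX <- params$nProbesX; nY <- params$nProbesY
    nP <- nA + nX + nY
    n <- params$nSamples
    if (nP == 0) stop("at least one probe is required")

    ## --- probes ---------------------------------------------------------
    probeIds <- sprintf("cg%07d", seq_len(nP))
    chrom <- c(if (nA) rep_len(paste0("chr", 1:22), nA),
               rep("chrX", nX), rep("chrY", nY))
    nType1 <- round(params$fractionType1 * nP)
    type1Idx <- if (nType1) sort(sample.int(nP, nType1)) else integer()
    infType <- rep("II", nP); infType[type1Idx] <- "I"
    channel <- rep(NA_character_, nP)
    channel[type1Idx] <- rep_len(c("Grn", "Red"), length(type1Idx))
    manifest <- data.frame(probe_id = probeIds, infinium_type = infType,
                           channel = channel, chromosome = chrom,
                           stringsAsFactors = FALSE)

    mode <- sample(c(0.1, 0.9, 0.5), nP, replace = TRUE,
                   prob = c(0.45, 0.45, 0.10))
    baseBeta <- pmin(pmax(mode + stats::rnorm(nP, 0, 0.03), 0.005), 0.995)

    nAffected <- round(params$batchProbeFraction * nA)
    affected <- if (nAffected) sort(sample.int(nA, nAffected)) else integer()

    ## --- samples --------------------------------------------------------
    sampleIds <- sprintf("S%03d", seq_len(n))
    sex <- if (!is.null(params$sexVector)) as.character(params$sexVector)
           else {
               nM <- round(params$sexRatio * n)
               sample(rep(c("M", "F"), c(nM, n - nM)))
           }
    batch <- if (!is.null(params$batchLabels)) as.character(params$batchLabels)
             else if (params$batchShiftBeta > 0 && n >= 2)
                 rep(c("batch1", "batch2"), c(ceiling(n / 2), floor(n / 2)))
             else rep("batch1", n)
    flipped <- if (params$nSexFlips) sort(sample.int(n, params$nSexFlips)) else integer()
    lowQ <- if (params$nLowQuality) sort(sample.int(n, params$nLowQuality)) else integer()

    beta <- matrix(baseBeta, nP, n)
    inBatch2 <- batch == unique(batch)[min(2, length(unique(batch)))] &
                length(unique(batch)) > 1
    if (length(affected) && any(inBatch2))
        beta[affected, inBatch2] <- pmin(pmax(
            beta[affected, inBatch2] + params$batchShiftBeta, 0), 1)

    sdLog <- params$noiseSdLog2 * log(2)
    cn <- params$baselineIntensity * exp(matrix(stats::rnorm(nP * n, 0, sdLog), nP, n))
    male <- sex == "M"
    if (any(male)) {
        if (nX) cn[chrom == "chrX", male] <- cn[chrom == "chrX", male] * 0.5
        if (nY) cn[chrom == "chrY", male] <-
            cn[chrom == "chrY", male] * 2^params$sexLog2Shift
    }
    meth <- cn * beta * exp(matrix(stats::rnorm(nP * n, 0, sdLog), nP, n))
    unmeth <- cn * (1 - beta) * exp(matrix(stats::rnorm(nP * n, 0, sdLog), nP, n))
    if (length(lowQ)) {
        meth[, lowQ] <- meth[, lowQ] * params$lowQualityFactor
        unmeth[, lowQ] <- unmeth[, lowQ] * params$lowQualityFactor
    }
    dimnames(meth) <- dimnames(unmeth) <- list(probeIds, sampleIds)

    ## --- controls -------------------------------------------------------
    ctrlSpec <- data.frame(
        control_type = rep(c("NEGATIVE", "BISULFITE_CONVERSION_I"), c(30, 10)),
        level = rep(c(0.02, 0.8) * params$baselineIntensity, c(30, 10)))
    nC <- nrow(ctrlSpec)
    controls <- data.frame(
        control_id = rep(sprintf("ctl%03d", seq_len(nC)), each = n),
        control_type = rep(ctrlSpec$control_type, each = n),
        sample_id = rep(sampleIds, nC),
        green = rep(ctrlSpec$level, each = n) *
            exp(stats::rnorm(nC * n, 0, sdLog)),
        red = rep(ctrlSpec$level, each = n) *
            exp(stats::rnorm(nC * n, 0, sdLog)),
        stringsAsFactors = FALSE)
    if (length(lowQ)) {
        isLowQ <- controls$sample_id %in% sampleIds[lowQ]
        controls$green[isLowQ] <- controls$green[isLowQ] * params$lowQualityFactor
        controls$red[isLowQ] <- controls$red[isLowQ] * params$lowQualityFactor
    }

    ## --- phenotypes -----------------------------------------------------
    reported <- sex
    if (length(flipped))
        reported[flipped] <- ifelse(sex[flipped] == "M", "F", "M")
    posIdx <- (seq_len(n) - 1) %% 12
    phenotypes <- data.frame(
        sample_id = sampleIds,
        reported_sex = reported,
        plate = batch,
        slide = sprintf("SL%03d", (seq_len(n) - 1) %/% 12 + 1),
        array_position = sprintf("R%02dC%02d", posIdx %% 6 + 1, posIdx %/% 6 + 1),
        stringsAsFactors = FALSE)

    list(signals = SignalSet(meth = meth, unmeth = unmeth),
         manifest = manifest,
         controls = controls,
         phenotypes = phenotypes,
         truth = list(sex = stats::setNames(sex, sampleIds),
                      flippedSamples = sampleIds[flipped],
                      lowQualitySamples = sampleIds[lowQ],
                      batch = stats::setNames(batch, sampleIds),
                      affectedProbes = probeIds[affected],
                      baseBeta = stats::setNames(baseBeta, probeIds)))
}

#' Named simulation presets
#'
#' Three documented parameter bundles matching the package's demonstration
#' scenarios: `"clean_small"` (2,000 probes, 8 samples, nothing injected),
#' `"fig2_batch"` (two batches with a 0.1 Beta shift on 30% of autosomal
#' probes, for PCA batch detection) and `"fig4_sex"` (40 samples with one
#' deliberately mislabelled reported sex, for the mismatch report).
#'
#' @param name Preset name.
#' @param seed Optional seed overriding the preset's documented default.
#' @return A [simParams()] record.
#' @export
simPreset <- function(name = c("clean_small", "fig2_batch", "fig4_sex"),
                      seed = NULL) {
    if (!is.character(name) || length(name) != 1 ||
        !name %in% c("clean_small", "fig2_batch", "fig4_sex"))
        stop("unknown preset; available: clean_small, fig2_batch, fig4_sex")
    p <- switch(name,
        clean_small = simParams(nProbesAutosomal = 1600, nProbesX = 200,
                                nProbesY = 200, nSamples = 8, seed = 100),
        fig2_batch = simParams(nProbesAutosomal = 2000, nProbesX = 150,
                               nProbesY = 150, nSamples = 20,
                               batchShiftBeta = 0.1,
                               batchProbeFraction = 0.3, seed = 200),
        fig4_sex = simParams(nProbesAutosomal = 2000, nProbesX = 200,
                             nProbesY = 200, nSamples = 40,
                             nSexFlips = 1, seed = 300))
    if (!is.null(seed)) p$seed <- seed
    p
}

#' Write a generated dataset to disk
#'
#' Writes the five files the io readers consume (`meth.tsv`, `unmeth.tsv`,
#' `manifest.tsv`, `controls.tsv`, `phenotypes.tsv`) plus the ground-truth
#' record as `truth.json`.
#'
#' @param dataset Output of [generateDataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    m <- getMeth(dataset$signals)
    u <- getUnmeth(dataset$signals)
    .writeTsv(data.frame(probe_id = rownames(m), m, check.names = FALSE),
              file.path(dir, "meth.tsv"))
    .writeTsv(data.frame(probe_id = rownames(u), u, check.names = FALSE),
              file.path(dir, "unmeth.tsv"))
    .writeTsv(dataset$manifest, file.path(dir, "manifest.tsv"))
    .writeTsv(dataset$controls, file.path(dir, "controls.tsv"))
    .writeTsv(dataset$phenotypes, file.path(dir, "phenotypes.tsv"))
    jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
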