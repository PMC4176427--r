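.covColours <- function(values) {
    f <- factor(values)
    pal <- grDevices::hcl.colors(max(nlevels(f), 2), palette = "Dark 3")
    list(col = pal[as.integer(f)], levels = levels(f),
         palette = pal[seq_len(nlevels(f))])
}

.pngPanel <- function(path, expr, width = 900, height = 600) {
    grDevices::png(path, width = width, height = height, res = 110)
    on.exit(grDevices::dev.off())
    force(expr)
    invisible(path)
}

.plotControls <- function(summary, colours) {
    ctl <- controlSummary(summary)
    neg <- ctl[ctl$control_type == "NEGATIVE", ]
    neg <- neg[match(sampleIDs(summary), neg$sample_id), ]
    graphics::plot(seq_len(nrow(neg)), neg$mean_combined, col = colours$col,
                   pch = 19, xlab = "sample index",
                   ylab = "mean NEGATIVE control intensity",
                   main = "Negative control probes")
    graphics::legend("topright", legend = colours$levels,
                     col = colours$palette, pch = 19, bty = "n", cex = 0.8)
}

.plotMedianScatter <- function(qc, colours, cutoff) {
    graphics::plot(qc$median_log2_unmeth, qc$median_log2_meth,
                   col = colours$col, pch = 19,
                   xlab = "median log2 unmethylated",
                   ylab = "median log2 methylated",
                   main = sprintf("QC plot (cutoff %.1f)", cutoff))
    graphics::abline(a = 2 * cutoff, b = -1, lty = 2)
    if (any(qc$flagged))
        graphics::points(qc$median_log2_unmeth[qc$flagged],
                         qc$median_log2_meth[qc$flagged],
                         pch = 4, cex = 2, lwd = 2)
}

.plotDensities <- function(summary, measure, stratum, colours, label) {
    dc <- densityCurves(summary, measure = measure, stratum = stratum)
    graphics::matplot(dc$grid, dc$density, type = "l", lty = 1,
                      col = colours$col,
                      xlab = measure, ylab = "density",
                      main = sprintf("%s densities, %s probes (%s)",
                                     measure, stratum, label))
}

.plotSexPanel <- function(calls) {
    sexCol <- ifelse(calls$predicted_sex == "M", "#2c7fb8", "#e6550d")
    graphics::stripchart(calls$xy_diff, method = "jitter", jitter = 0.15,
                         vertical = FALSE, pch = 19, col = sexCol,
                         xlab = "log2 median CN: chrY - chrX",
                         main = "Sex prediction")
    graphics::abline(v = calls$cutoff_used[1], lty = 2)
    graphics::legend("topleft", legend = c("predicted M", "predicted F"),
                     col = c("#2c7fb8", "#e6550d"), pch = 19, bty = "n")
}

.plotPCA <- function(pca, colours, covName) {
    sc <- pcaScores(pca)
    vr <- varianceRatio(pca)
    if (ncol(sc) < 2) return(invisible())
    graphics::plot(sc[, 1], sc[, 2], col = colours$col, pch = 19,
                   xlab = sprintf("PC1 (%.1f%%)", 100 * vr[1]),
                   ylab = sprintf("PC2 (%.1f%%)", 100 * vr[2]),
                   main = sprintf("PCA of top %d variable autosomal Beta values",
                                  length(selectedProbes(pca))))
    graphics::legend("topright", legend = colours$levels, title = covName,
                     col = colours$palette, pch = 19, bty = "n", cex = 0.8)
}

.plotArrayLayout <- function(layout, covName) {
    colours <- .covColours(layout$covariate)
    slides <- unique(layout$slide)
    graphics::par(mfrow = c(1, max(length(slides), 1)), mar = c(2, 2, 3, 1))
    for (sl in slides) {
        sub <- layout[layout$slide == sl, ]
        graphics::plot(NA, xlim = c(0.5, 2.5), ylim = c(6.5, 0.5),
                       xlab = "", ylab = "", xaxt = "n", yaxt = "n",
                       main = sprintf("%s (%s)", sl, covName))
        graphics::axis(1, at = 1:2, labels = c("C01", "C02"))
        graphics::axis(2, at = 1:6, labels = sprintf("R%02d", 1:6), las = 1)
        graphics::points(sub$col, sub$row, pch = 15, cex = 4,
                         col = colours$col[layout$slide == sl])
    }
}

.htmlSection <- function(title, img) {
    sprintf("<section><h2>%s</h2><img src=\"%s\" alt=\"%s\"/></section>",
            title, img, title)
}

#' Build a static quality-control report
#'
#' The batch counterpart of an interactive QC session: renders every
#' diagnostic panel (negative controls, median-intensity QC scatter, density
#' panels per stratum for raw and — when supplied — normalized data, the sex
#' panel, PCA score plots and the physical array layout) to PNG files, writes
#' the flagged-sample / sex CSVs, and ties everything together in a single
#' `index.html`. The report runs entirely from summary archives; the full
#' signal matrices are never touched.
#'
#' @param rawSummary A raw [QCSummary-class] or path to its archive.
#' @param normalizedSummary Optional normalized [QCSummary-class] or archive
#'   path; must cover exactly the same samples.
#' @param outputDir Report directory (created if needed).
#' @param colorBy Phenotype column used for colouring; default `"plate"` when
#'   present, else the first non-ID column, else sample index.
#' @param qcCutoff Passed to [flagLowQuality()] (default 10.5).
#' @param sexCutoff Passed to [predictSex()] (default `"auto"`).
#' @return `outputDir`, invisibly. Files written: `index.html`, PNG panels,
#'   `flagged_samples.csv`, `sex_predictions.csv`, `sex_mismatches.csv`.
#' @export
buildReport <- function(rawSummary, normalizedSummary = NULL,
                        outputDir, colorBy = NULL,
                        qcCutoff = 10.5, sexCutoff = "auto") {
    if (is.character(rawSummary)) rawSummary <- readSummary(rawSummary)
    stopifnot(is(rawSummary, "QCSummary"))
    if (summaryLabel(rawSummary) != "raw")
        stop("'rawSummary' must be a raw-labelled summary")
    if (!is.null(normalizedSummary)) {
        if (is.character(normalizedSummary))
            normalizedSummary <- readSummary(normalizedSummary)
        if (!setequal(sampleIDs(normalizedSummary), sampleIDs(rawSummary)))
            stop("raw and normalized summaries cover different sample sets")
    }
    if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)

    pheno <- phenotypes(rawSummary)
    if (is.null(colorBy)) {
        cand <- setdiff(names(pheno), "sample_id")
        colorBy <- if ("plate" %in% cand) "plate"
                   else if (length(cand)) cand[1] else NULL
    } else if (!colorBy %in% names(pheno)) {
        stop(sprintf("covariate '%s' not in phenotypes; available: %s",
                     colorBy,
                     paste(setdiff(names(pheno), "sample_id"), collapse = ", ")))
    }
    colours <- .covColours(if (is.null(colorBy)) seq_len(nrow(pheno))
                           else pheno[[colorBy]])
    covName <- if (is.null(colorBy)) "sample" else colorBy

    sections <- character()
    addPanel <- function(file, title, expr, ...) {
        .pngPanel(file.path(outputDir, file), expr, ...)
        sections <<- c(sections, .htmlSection(title, file))
    }

    ## QC metrics + flagged-sample export
    qc <- flagLowQuality(medianChannelIntensities(rawSummary),
                         cutoff = qcCutoff)
    flagged <- qc$sample_id[qc$flagged]
    exportSampleList(flagged, "low_median_intensity",
                     file.path(outputDir, "flagged_samples.csv"),
                     knownSamples = sampleIDs(rawSummary))

    if (!is.null(controlSummary(rawSummary)) &&
        any(controlSummary(rawSummary)$control_type == "NEGATIVE"))
        addPanel("controls.png", "Average negative control intensities",
                 .plotControls(rawSummary, colours))
    addPanel("qc_scatter.png", "Median channel intensities",
             .plotMedianScatter(qc, colours, qcCutoff))

    counts <- strataCounts(rawSummary)
    for (st in c("IGrn", "IRed", "II")) {
        if (counts[[st]] == 0) next
        for (me in c("Beta", "MValue"))
            addPanel(sprintf("density_%s_%s_raw.png", me, st),
                     sprintf("%s densities, %s probes (raw)", me, st),
                     .plotDensities(rawSummary, me, st, colours, "raw"))
        if (!is.null(normalizedSummary) &&
            strataCounts(normalizedSummary)[[st]] > 0)
            for (me in c("Beta", "MValue"))
                addPanel(sprintf("density_%s_%s_normalized.png", me, st),
                         sprintf("%s densities, %s probes (normalized)", me, st),
                         .plotDensities(normalizedSummary, me, st, colours,
                                        "normalized"))
    }

    ## Sex prediction
    if (counts[["chrX"] ] > 0 && counts[["chrY"]] > 0) {
        diffs <- sexDifference(rawSummary)
        reported <- if ("reported_sex" %in% names(pheno))
            stats::setNames(pheno$reported_sex, pheno$sample_id) else NULL
        calls <- predictSex(diffs, cutoff = sexCutoff, reportedSex = reported)
        .writeCsv(calls[, c("sample_id", "xy_diff", "predicted_sex",
                            "reported_sex", "mismatch")],
                  file.path(outputDir, "sex_predictions.csv"))
        mm <- sexMismatches(calls)
        .writeCsv(mm[, c("sample_id", "xy_diff", "predicted_sex",
                         "reported_sex", "mismatch")],
                  file.path(outputDir, "sex_mismatches.csv"))
        addPanel("sex_panel.png", "Sex prediction", .plotSexPanel(calls))
    } else {
        .writeCsv(data.frame(sample_id = character(), xy_diff = numeric(),
                             predicted_sex = character(),
                             reported_sex = character(), mismatch = logical()),
                  file.path(outputDir, "sex_predictions.csv"))
        .writeCsv(data.frame(sample_id = character(), xy_diff = numeric(),
                             predicted_sex = character(),
                             reported_sex = character(), mismatch = logical()),
                  file.path(outputDir, "sex_mismatches.csv"))
    }

    ## PCA + array layout
    if (!is.null(pcaResult(rawSummary)))
        addPanel("pca_raw.png", "PCA (raw)",
                 .plotPCA(pcaResult(rawSummary), colours, covName))
    if (!is.null(normalizedSummary) && !is.null(pcaResult(normalizedSummary)))
        addPanel("pca_normalized.png", "PCA (normalized)",
                 .plotPCA(pcaResult(normalizedSummary), colours, covName))
    if (all(c("slide", "array_position") %in% names(pheno)) &&
        !is.null(colorBy))
        addPanel("array_layout.png", "Array layout",
                 .plotArrayLayout(arrayLayout(pheno, colorBy), covName),
                 width = 1100)

    html <- c("<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
              "<title>Methylation array QC report</title>",
              "<style>body{font-family:sans-serif;max-width:1000px;margin:auto}",
              "img{max-width:100%}section{margin-bottom:2em}</style></head><body>",
              "<h1>Methylation array QC report</h1>",
              sprintf("<p>%d samples; coloured by <b>%s</b>; QC cutoff %.2f; %d sample(s) flagged.</p>",
                      length(sampleIDs(rawSummary)), covName, qcCutoff,
                      length(flagged)),
              sections,
              "</body></html>")
    writeLines(html, file.path(outputDir, "index.html"), useBytes = TRUE)
    invisible(outputDir)
}

.writeCsv <- function(df, path) {
    cols <- lapply(df, .fmtColumn)
    lines <- c(paste(names(df), collapse = ","),
               if (nrow(df)) do.call(paste, c(cols, sep = ",")))
    writeLines(lines, path, useBytes = TRUE)
}
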