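## Delimited-file dialect: RFC-4180 CSV or TSV, UTF-8, mandatory header,
## "." or empty string as the NA token. The delimiter is sniffed from the
## header line (a tab wins over a comma).

.sniffSep <- function(path) {
    header <- readLines(path, n = 1L, warn = FALSE)
    if (length(header) == 0) stop(sprintf("'%s' is empty", path))
    if (grepl("\t", header)) "\t" else ","
}

.readTable <- function(path, check.names = FALSE) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    utils::read.table(path, sep = .sniffSep(path), header = TRUE,
                      na.strings = c(".", "", "NA"), check.names = check.names,
                      stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

.fmtColumn <- function(x) {
    out <- if (is.integer(x)) as.character(x)
           else if (is.numeric(x)) sprintf("%.17g", x)
           else as.character(x)
    out[is.na(x)] <- "."
    out
}

.writeTsv <- function(df, path) {
    cols <- lapply(df, .fmtColumn)
    lines <- c(paste(names(df), collapse = "\t"),
               if (nrow(df)) do.call(paste, c(cols, sep = "\t")))
    writeLines(lines, path, useBytes = TRUE)
}

.readSignalMatrix <- function(path) {
    tab <- .readTable(path)
    if (ncol(tab) < 2)
        stop(sprintf("'%s' needs a probe-ID column plus at least one sample", path))
    ids <- as.character(tab[[1]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop(sprintf("duplicate probe IDs in '%s': %s", path,
                     paste(unique(dup), collapse = ", ")))
    for (j in 2:ncol(tab)) {
        col <- tab[[j]]
        if (!is.numeric(col) || anyNA(col))
            stop(sprintf("non-numeric or missing intensity in '%s', column '%s', first at row %d",
                         path, names(tab)[j],
                         which(!is.finite(suppressWarnings(as.numeric(col))))[1]))
        if (any(col < 0))
            stop(sprintf("negative intensity in '%s', column '%s', row %d",
                         path, names(tab)[j], which(col < 0)[1]))
    }
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- ids
    mat
}

#' Read a SignalSet from methylated/unmethylated signal files
#'
#' Each file is CSV or TSV with a probe-ID first column and one numeric column
#' per sample. Probe and sample order is taken from the methylated file; the
#' unmethylated matrix is reindexed by ID to match, so permuted columns are
#' fine but any ID present on one side only is a hard error naming the
#' symmetric difference.
#'
#' @param methPath,unmethPath Paths to the two signal tables.
#' @return A [SignalSet-class].
#' @export
readSignalSet <- function(methPath, unmethPath) {
    meth <- .readSignalMatrix(methPath)
    unmeth <- .readSignalMatrix(unmethPath)
    SignalSet(meth = meth, unmeth = unmeth)
}

#' Read and validate a probe manifest
#'
#' Expects columns `probe_id`, `infinium_type` (I or II), `channel` (Grn or
#' Red for type I, NA for type II) and `chromosome`. Chromosome tokens are
#' normalized to the chr-prefixed vocabulary chr1..chr22, chrX, chrY ("X" ->
#' "chrX" etc.); anything else is a hard error, as are duplicate probe IDs and
#' chemistry/channel combinations that violate the platform design.
#'
#' @param path Path to the manifest table.
#' @return A validated data frame with the four columns above.
#' @export
readManifest <- function(path) {
    man <- .readTable(path)
    need <- c("probe_id", "infinium_type", "channel", "chromosome")
    if (!all(need %in% names(man)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    man <- man[, need]
    validateManifest(man)
}

#' @rdname readManifest
#' @param manifest A manifest data frame to validate/normalize in memory.
#' @export
validateManifest <- function(manifest) {
    dup <- manifest$probe_id[duplicated(manifest$probe_id)]
    if (length(dup))
        stop("duplicate probe IDs in manifest: ",
             paste(unique(dup), collapse = ", "))
    if (!all(manifest$infinium_type %in% c("I", "II")))
        stop("infinium_type must be 'I' or 'II'")
    chr <- as.character(manifest$chromosome)
    plain <- !startsWith(chr, "chr") & !is.na(chr)
    chr[plain] <- paste0("chr", chr[plain])
    bad <- setdiff(chr, .CHROMOSOMES)
    if (length(bad) || anyNA(chr))
        stop("unknown chromosome token(s): ",
             paste(unique(bad), collapse = ", "))
    manifest$chromosome <- chr
    typeI <- manifest$infinium_type == "I"
    if (any(typeI & is.na(manifest$channel)))
        stop("type I probes must have a channel (Grn or Red); first offender: ",
             manifest$probe_id[which(typeI & is.na(manifest$channel))[1]])
    if (any(typeI & !manifest$channel %in% c("Grn", "Red")))
        stop("type I channel must be 'Grn' or 'Red'")
    if (any(!typeI & !is.na(manifest$channel)))
        stop("type II probes must have channel NA; first offender: ",
             manifest$probe_id[which(!typeI & !is.na(manifest$channel))[1]])
    rownames(manifest) <- NULL
    manifest
}

#' Read a control-probe intensity table
#'
#' Long format: one row per (control probe, sample) with columns `control_id`,
#' `control_type`, `sample_id`, `green`, `red`. Intensities must be finite and
#' non-negative; (control_id, sample_id) pairs must be unique.
#'
#' @param path Path to the control table.
#' @return A validated data frame.
#' @export
readControls <- function(path) {
    tab <- .readTable(path)
    need <- c("control_id", "control_type", "sample_id", "green", "red")
    if (!all(need %in% names(tab)))
        stop("control table must have columns: ", paste(need, collapse = ", "))
    for (ch in c("green", "red")) {
        v <- tab[[ch]]
        if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v < 0))
            stop(sprintf("control '%s' intensities must be finite and >= 0", ch))
    }
    if (anyDuplicated(tab[, c("control_id", "sample_id")]))
        stop("duplicate (control_id, sample_id) pairs in control table")
    tab[, need]
}

#' Read a phenotype table
#'
#' One row per sample; `sample_id` is the only mandatory column and must be
#' unique. Reserved optional columns: `reported_sex` (M/F/NA), `slide`,
#' `array_position` (RnnCnn). All other columns are free covariates.
#'
#' @param path Path to the phenotype table.
#' @return A data frame.
#' @export
readPhenotypes <- function(path) {
    tab <- .readTable(path)
    if (!"sample_id" %in% names(tab))
        stop("phenotype table must have a 'sample_id' column")
    tab$sample_id <- as.character(tab$sample_id)
    dup <- tab$sample_id[duplicated(tab$sample_id)]
    if (length(dup))
        stop("duplicate sample IDs in phenotype table: ",
             paste(unique(dup), collapse = ", "))
    if ("reported_sex" %in% names(tab) &&
        !all(tab$reported_sex %in% c("M", "F") | is.na(tab$reported_sex)))
        stop("reported_sex must be 'M', 'F' or NA")
    tab
}

## ---- summary archive -------------------------------------------------------
## An uncompressed POSIX tar holding metadata.json plus one TSV per
## (stratum, measure) quantile table, controls/phenotypes tables and the PCA
## payload. Doubles are written as %.17g so the round trip is bit-identical;
## member mtimes are pinned so rewriting an identical summary yields an
## identical archive byte-for-byte.

.SCHEMA_VERSION <- 1L
.ARCHIVE_EPOCH <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

.colClass <- function(x) {
    if (is.integer(x)) "integer"
    else if (is.numeric(x)) "numeric"
    else if (is.logical(x)) "logical"
    else "character"
}

.coerceClass <- function(x, cls) {
    switch(cls,
           integer = as.integer(x),
           numeric = as.numeric(x),
           logical = as.logical(x),
           character = as.character(x))
}

#' Write / read a QCSummary archive
#'
#' `writeSummary()` serializes a [QCSummary-class] to a single
#' platform-independent archive (uncompressed tar of a JSON metadata document
#' plus TSV payload tables, one per stored stratum/measure). All floating
#' point payload uses 17 significant digits, so
#' `readSummary(writeSummary(s))` reproduces `s` bit-for-bit and re-writing
#' the result yields a byte-identical archive.
#'
#' @param summary A [QCSummary-class].
#' @param path Output archive path (conventionally `.qcsummary.tar`).
#' @return `writeSummary` returns `path` invisibly; `readSummary` returns the
#'   [QCSummary-class].
#' @export
writeSummary <- function(summary, path) {
    stopifnot(is(summary, "QCSummary"))
    stage <- tempfile("qcsummary_stage")
    dir.create(stage)
    on.exit(unlink(stage, recursive = TRUE), add = TRUE)

    strataMeasures <- lapply(summary@quantiles, function(tabs)
        names(tabs)[!vapply(tabs, is.null, logical(1))])
    meta <- list(
        schema_version = .SCHEMA_VERSION,
        label = summary@label,
        parameters = summary@params,
        sample_ids = summary@sampleIds,
        ## %.17g strings: JSON number serialization loses the last ulp
        quantile_probs = sprintf("%.17g", summary@probs),
        strata_counts = as.list(summary@strataCounts),
        strata_measures = strataMeasures,
        has_controls = !is.null(summary@controls),
        has_pca = !is.null(summary@pca),
        phenotype_classes = lapply(summary@phenotypes, .colClass))
    jsonlite::write_json(meta, file.path(stage, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)

    for (st in names(summary@quantiles)) {
        for (me in names(summary@quantiles[[st]])) {
            q <- summary@quantiles[[st]][[me]]
            if (is.null(q)) next
            df <- data.frame(prob = summary@probs, q, check.names = FALSE)
            .writeTsv(df, file.path(stage, sprintf("%s__%s.tsv", st, me)))
        }
    }
    if (!is.null(summary@controls))
        .writeTsv(summary@controls, file.path(stage, "controls.tsv"))
    .writeTsv(summary@phenotypes, file.path(stage, "phenotypes.tsv"))
    if (!is.null(summary@pca)) {
        pca <- summary@pca
        sc <- data.frame(sample_id = pca@sampleIds, pca@scores,
                         check.names = FALSE)
        colnames(sc) <- c("sample_id", paste0("PC", seq_len(ncol(pca@scores))))
        .writeTsv(sc, file.path(stage, "pca__scores.tsv"))
        .writeTsv(data.frame(component = seq_along(pca@varianceRatio),
                             variance_ratio = pca@varianceRatio),
                  file.path(stage, "pca__variance.tsv"))
        writeLines(pca@selectedProbes,
                   file.path(stage, "pca__selected_probes.txt"))
    }

    members <- sort(list.files(stage))
    Sys.setFileTime(file.path(stage, members), .ARCHIVE_EPOCH)
    Sys.setFileTime(stage, .ARCHIVE_EPOCH)
    ## anchor relative paths before the setwd into the staging directory
    path <- file.path(normalizePath(dirname(path), mustWork = TRUE),
                      basename(path))
    owd <- setwd(stage)
    on.exit(setwd(owd), add = TRUE, after = FALSE)
    utils::tar(path, files = members, tar = "internal")
    invisible(path)
}

.readArchiveTsv <- function(dir, name, colClasses = NA) {
    p <- file.path(dir, name)
    if (!file.exists(p))
        stop(sprintf("summary archive is missing required table '%s'", name))
    utils::read.table(p, sep = "\t", header = TRUE, check.names = FALSE,
                      na.strings = ".", colClasses = colClasses,
                      stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' @rdname writeSummary
#' @export
readSummary <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    exdir <- tempfile("qcsummary_read")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
    utils::untar(path, exdir = exdir, tar = "internal")

    metaPath <- file.path(exdir, "metadata.json")
    if (!file.exists(metaPath))
        stop("summary archive is missing required table 'metadata.json'")
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    if (!identical(as.integer(meta$schema_version), .SCHEMA_VERSION))
        stop(sprintf("summary archive schema version %s is not supported (expected %d)",
                     meta$schema_version, .SCHEMA_VERSION))

    sampleIds <- as.character(meta$sample_ids)
    probs <- as.numeric(meta$quantile_probs)
    quantiles <- list()
    for (st in .STRATA) {
        measures <- meta$strata_measures[[st]]
        expected <- if (meta$label == "raw") .RAW_MEASURES else .NORM_MEASURES
        tabs <- stats::setNames(vector("list", length(expected)), expected)
        for (me in measures) {
            tab <- .readArchiveTsv(exdir, sprintf("%s__%s.tsv", st, me),
                                   colClasses = "numeric")
            q <- as.matrix(tab[, -1, drop = FALSE])
            rownames(q) <- NULL
            tabs[[me]] <- q
        }
        quantiles[[st]] <- tabs
    }

    controls <- NULL
    if (isTRUE(meta$has_controls)) {
        controls <- .readArchiveTsv(exdir, "controls.tsv",
                                    colClasses = c("character", "character",
                                                   "numeric", "numeric",
                                                   "numeric"))
    }

    phenoClasses <- meta$phenotype_classes
    pheno <- .readArchiveTsv(exdir, "phenotypes.tsv",
                             colClasses = "character")
    for (nm in names(pheno))
        pheno[[nm]] <- .coerceClass(pheno[[nm]], phenoClasses[[nm]])

    pca <- NULL
    if (isTRUE(meta$has_pca)) {
        sc <- .readArchiveTsv(exdir, "pca__scores.tsv")
        scores <- as.matrix(sc[, -1, drop = FALSE])
        dimnames(scores) <- NULL
        vr <- .readArchiveTsv(exdir, "pca__variance.tsv",
                              colClasses = c("integer", "numeric"))
        spPath <- file.path(exdir, "pca__selected_probes.txt")
        if (!file.exists(spPath))
            stop("summary archive is missing required table 'pca__selected_probes.txt'")
        pca <- new("PCAResult",
                   sampleIds = as.character(sc[[1]]),
                   scores = scores,
                   varianceRatio = vr$variance_ratio,
                   selectedProbes = readLines(spPath),
                   nTop = as.integer(meta$parameters$nTop))
    }

    params <- meta$parameters
    for (nm in c("betaOffset", "mvalueEpsilon", "logitEpsilon"))
        if (!is.null(params[[nm]])) params[[nm]] <- as.numeric(params[[nm]])
    if (!is.null(params$nTop)) params$nTop <- as.integer(params$nTop)

    counts <- unlist(meta$strata_counts)
    new("QCSummary",
        sampleIds = sampleIds,
        probs = probs,
        quantiles = quantiles,
        strataCounts = stats::setNames(as.integer(counts), names(counts)),
        controls = controls,
        pca = pca,
        phenotypes = pheno,
        label = meta$label,
        params = params)
}

#' Export a sample list as CSV
#'
#' Writes the two-column CSV (`sample_id,reason`) used to hand excluded or
#' mismatched samples to downstream analyses. Input order is preserved.
#'
#' @param sampleIds Character vector (may be empty).
#' @param reason Single string recorded for every row.
#' @param path Output CSV path.
#' @param knownSamples Optional universe of valid sample IDs; any `sampleIds`
#'   entry outside it is a hard error.
#' @return `path`, invisibly.
#' @export
exportSampleList <- function(sampleIds, reason, path, knownSamples = NULL) {
    if (!is.null(knownSamples)) {
        bad <- setdiff(sampleIds, knownSamples)
        if (length(bad))
            stop("unknown sample ID(s): ", paste(bad, collapse = ", "))
    }
    stopifnot(is.character(reason), length(reason) == 1)
    lines <- c("sample_id,reason",
               if (length(sampleIds)) paste(sampleIds, reason, sep = ","))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}
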