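test_that("variance-based probe selection matches a full-sort oracle", {
    set.seed(41)
    beta <- matrix(runif(500 * 8), 500, 8,
                   dimnames = list(sprintf("cg%04d", 1:500), NULL))
    sel <- selectTopVariable(beta, nTop = 50)
    mu <- rowMeans(beta)
    v <- rowMeans((beta - mu)^2)
    want <- names(sort(v, decreasing = TRUE))[1:50]
    expect_setequal(sel, want)

    expect_length(selectTopVariable(beta[1:10, ], nTop = 20000), 10)

    bc <- beta[1:11, ]
    bc[1, ] <- 0.5  # constant probe has zero variance, excluded at nTop = 10
    expect_false("cg0001" %in% selectTopVariable(bc, nTop = 10))
})

test_that("PCA has the stated algebraic structure", {
    set.seed(42)
    ids <- sprintf("cg%03d", 1:40)
    sm <- sprintf("S%d", 1:6)
    ## rank-1: only one probe varies
    b1 <- matrix(0.4, 40, 6, dimnames = list(ids, sm))
    b1[7, ] <- seq(0.1, 0.9, length.out = 6)
    p1 <- runPCA(b1)
    expect_equal(varianceRatio(p1)[1], 1)

    ## duplicated sample columns -> identical score rows
    b2 <- matrix(runif(40 * 5), 40, 5, dimnames = list(ids, sprintf("S%d", 1:5)))
    b2[, 5] <- b2[, 4]
    p2 <- runPCA(b2)
    expect_equal(pcaScores(p2)[4, ], pcaScores(p2)[5, ], tolerance = 1e-10)

    ## orthogonality + reconstruction bound with full retention
    b3 <- matrix(runif(40 * 6), 40, 6, dimnames = list(ids, sm))
    p3 <- runPCA(b3)
    sc <- pcaScores(p3)
    g <- crossprod(sc)
    expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
    expect_equal(sum(varianceRatio(p3)), 1, tolerance = 1e-12)  # 5 = n-1 comps
    expect_lte(sum(varianceRatio(p2)), 1)

    ## sign convention: largest-|entry| of each column is positive
    expect_true(all(apply(sc, 2, function(x) x[which.max(abs(x))] >= 0)))

    ## probe-order invariance and sample-permutation equivariance
    perm <- sample(40)
    expect_equal(pcaScores(runPCA(b3[perm, ])), sc, tolerance = 1e-10)
    sp <- c(3, 1, 6, 2, 5, 4)
    p4 <- runPCA(b3[, sp])
    expect_equal(abs(pcaScores(p4)), abs(sc[sp, ]), tolerance = 1e-10)

    expect_error(runPCA(b3[, 1, drop = FALSE]), "2 samples")
})

test_that("PC1 tracks a constructed batch effect", {
    d <- generateDataset(simPreset("fig2_batch"))
    s <- summarizeRaw(d$signals, d$manifest, d$controls, d$phenotypes)
    pc1 <- pcaScores(pcaResult(s))[, 1]
    r <- cor(pc1, as.numeric(factor(d$truth$batch)))
    expect_gte(abs(r), 0.9)
})

test_that("component-covariate ANOVA agrees with stats::anova and handles degeneracy", {
    set.seed(43)
    beta <- matrix(runif(60 * 12), 60, 12,
                   dimnames = list(sprintf("cg%03d", 1:60), sprintf("S%d", 1:12)))
    pca <- runPCA(beta)
    g <- rep(c("a", "b", "c"), each = 4)
    got <- pcAssociation(pca, g)
    for (j in 1:3) {
        ref <- anova(lm(pcaScores(pca)[, j] ~ factor(g)))
        expect_equal(got$F[j], ref$`F value`[1], tolerance = 1e-10)
        expect_equal(got$p[j], ref$`Pr(>F)`[1], tolerance = 1e-10)
    }

    ## identical scores across groups -> F = 0
    pcaFlat <- pca
    pcaFlat@scores[] <- rep(c(-1, 1, 0), each = 4)
    flat <- pcAssociation(pcaFlat, rep(c("x", "y"), 6))
    expect_equal(flat$F[1], 0)

    ## perfect separation with zero within-variance -> p = 0 with a flag
    pcaSep <- pca
    pcaSep@scores[, 1] <- rep(c(0, 1), each = 6)
    sep <- pcAssociation(pcaSep, rep(c("x", "y"), each = 6))
    expect_identical(sep$p[1], 0)
    expect_true(sep$degenerate[1])

    expect_error(pcAssociation(pca, rep("a", 12)), "2 levels")
    expect_error(pcAssociation(pca, c(rep("a", 11), "b")), "at least 2 samples")
})

test_that("nested batch and phenotype flag the same leading component", {
    set.seed(44)
    n <- 16
    beta <- matrix(runif(400 * n, 0.3, 0.7), 400, n,
                   dimnames = list(sprintf("cg%04d", 1:400), sprintf("S%d", 1:n)))
    batch <- rep(c("b1", "b2"), each = n / 2)
    pheno <- rep(c("ctl", "case"), each = n / 2)  # perfectly nested
    beta[1:120, batch == "b2"] <- beta[1:120, batch == "b2"] + 0.15
    pca <- runPCA(beta)
    pb <- pcAssociation(pca, batch)
    pp <- pcAssociation(pca, pheno)
    expect_identical(which.min(pb$p), which.min(pp$p))
    expect_lt(pb$p[which.min(pb$p)], 0.01)
    expect_lt(pp$p[which.min(pp$p)], 0.01)
})

test_that("array layout parses Sentrix positions and rejects bad ones", {
    ph <- data.frame(sample_id = c("S1", "S2"),
                     slide = "SL001",
                     array_position = c("R03C02", "R01C01"),
                     plate = c("p1", "p2"),
                     stringsAsFactors = FALSE)
    lay <- arrayLayout(ph, "plate")
    expect_equal(lay$row, c(3L, 1L))
    expect_equal(lay$col, c(2L, 1L))

    bad <- ph; bad$array_position[1] <- "R07C01"
    expect_error(arrayLayout(bad, "plate"), "outside the 6 x 2")
    bad2 <- ph; bad2$array_position[1] <- "3-2"
    expect_error(arrayLayout(bad2, "plate"), "malformed.*S1")
    dup <- ph; dup$array_position[2] <- "R03C02"
    expect_error(arrayLayout(dup, "plate"), "duplicate")
    expect_error(arrayLayout(ph, "nope"), "available")
})
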