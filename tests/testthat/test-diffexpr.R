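test_that("median-of-ratios size factors match the hand-computed case", {
    sheet <- data.frame(sample_id = c("s1", "s2"), cell_type = "IMAdC",
                        culture = c("mono", "co"), replicate = 1L)
    cts <- matrix(c(10L, 50L, 20L, 100L), 2, 2,
                  dimnames = list(c("GA", "GB"), c("s1", "s2")))
    x <- CocultureExperiment(cts, sheet)
    sf <- sizeFactorsMOR(x)
    # second sample = 2x first: factors (1/sqrt(2), sqrt(2)) after
    # geometric-mean rescaling
    expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

    same <- CocultureExperiment(cbind(s1 = c(10L, 50L), s2 = c(10L, 50L)) |>
        (\(m) {rownames(m) <- c("GA", "GB"); m})(), sheet)
    expect_equal(unname(sizeFactorsMOR(same)), c(1, 1))
})

test_that("size factors agree with DESeq2 on random data up to rescaling", {
    skip_if_not_installed("DESeq2")
    set.seed(14)
    cts <- matrix(rnbinom(600, mu = 50, size = 5), 100, 6)
    dimnames(cts) <- list(sprintf("G%03d", 1:100), paste0("s", 1:6))
    ours <- sizeFactorsMOR(cts)
    theirs <- DESeq2::estimateSizeFactorsForMatrix(cts)
    ratio <- ours / theirs
    expect_lt(max(ratio) / min(ratio) - 1, 1e-8)
})

test_that("size factor estimator is equivariant to sample scaling", {
    set.seed(15)
    cts <- matrix(rnbinom(400, mu = 100, size = 10), 100, 4)
    dimnames(cts) <- list(sprintf("G%03d", 1:100), paste0("s", 1:4))
    sf1 <- sizeFactorsMOR(cts)
    cts2 <- cts
    cts2[, 2] <- cts[, 2] * 3L
    sf2 <- sizeFactorsMOR(cts2)
    # sample 2's factor triples relative to the others, up to the global
    # geometric-mean rescale
    expect_equal(unname((sf2[2] / sf2[1]) / (sf1[2] / sf1[1])), 3,
                 tolerance = 1e-8)
})

test_that("bhAdjust equals the step-up oracle on short grids", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

    grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 0.9, 1)
    set.seed(33)
    for (len in 1:8) {
        for (rep in 1:25) {
            p <- sample(grid, len, replace = TRUE)
            expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
        }
    }
})

test_that("dispersion estimation: Poisson data floors, MoM is consistent", {
    cfg <- simConfig(nGenes = 1000, nRepsPerGroup = 3,
                     baselineLog2Mean = c(6, 1), dispersion = 1e-12,
                     seed = 51)
    x <- simulateCounts(cfg)$experiment
    disp <- estimateDispersionsMoM(x)
    expect_lte(stats::median(disp), 0.01)

    # constant-count gene -> floor
    sheet <- sampleSheet(tinyExperiment())
    cts <- matrix(7L, 2, 8,
                  dimnames = list(c("GA", "GB"), sheet$sample_id))
    flat <- CocultureExperiment(cts, sheet)
    expect_equal(unname(estimateDispersionsMoM(flat)["GA"]), 1e-8)

    # alpha = 0.5, 50 reps per group: estimates recover the truth
    cfg2 <- simConfig(nGenes = 300, nRepsPerGroup = 50,
                      baselineLog2Mean = c(7, 0), dispersion = 0.5,
                      seed = 52)
    x2 <- simulateCounts(cfg2)$experiment
    d2 <- estimateDispersionsMoM(x2)
    expect_gt(mean(d2), 0.35)
    expect_lt(mean(d2), 0.65)
})

test_that("Wald contrast is antisymmetric and null on identical groups", {
    cfg <- simConfig(nGenes = 200, nRepsPerGroup = 3,
                     baselineLog2Mean = c(6, 1), dispersion = 0.1,
                     seed = 61)
    x <- simulateCounts(cfg)$experiment
    fwd <- nbWaldContrast(x, contrastSpec("f", c("IMAdC", "mono"),
                                          c("IMAdC", "co")))
    rev <- nbWaldContrast(x, contrastSpec("r", c("IMAdC", "co"),
                                          c("IMAdC", "mono")))
    tf <- resultTable(fwd); tr <- resultTable(rev)
    expect_equal(tf$log2fc, -tr$log2fc)
    expect_equal(tf$wald_z, -tr$wald_z)
    expect_equal(tf$p, tr$p)

    # a group compared against itself: duplicate the mono samples as a
    # fake second condition
    cts <- countsMatrix(x)
    sheet <- sampleSheet(x)
    mono <- sheet$sample_id[sheet$cell_type == "IMAdC" &
                            sheet$culture == "mono"]
    dup <- cts[, c(mono, mono)]
    colnames(dup) <- paste0("s", 1:6)
    sheet2 <- data.frame(sample_id = colnames(dup), cell_type = "IMAdC",
                         culture = rep(c("mono", "co"), each = 3),
                         replicate = rep(1:3, 2))
    x2 <- CocultureExperiment(dup, sheet2)
    same <- nbWaldContrast(x2, contrastSpec("s", c("IMAdC", "mono"),
                                            c("IMAdC", "co")))
    expect_true(all(resultTable(same)$log2fc == 0))
    expect_true(all(resultTable(same)$p == 1))
})

test_that("planted log2fc = 2 is recovered without material bias", {
    genes <- sprintf("G%04d", 1:200)
    pd <- data.frame(gene = genes, contrast = "IMAdC_mono_vs_co",
                     log2fc = 2)
    cfg <- simConfig(nGenes = 2000, nRepsPerGroup = 3,
                     baselineLog2Mean = c(7, 0.5), dispersion = 0.05,
                     plantedDE = pd, seed = 71)
    x <- simulateCounts(cfg)$experiment
    res <- nbWaldContrast(x, contrastSpec("IMAdC_mono_vs_co",
                                          c("IMAdC", "mono"),
                                          c("IMAdC", "co")))
    tb <- resultTable(res)
    est <- tb$log2fc[tb$gene %in% genes]
    expect_gt(mean(est), 1.6)
    expect_lt(mean(est), 2.4)
})

test_that("DEG classification honors the strict thresholds", {
    # log2 fold changes as printed for the validated genes: PPARG 1.0485
    # (UP), FYN 0.9934 (fails |log2FC| > 1 -> NS), ATF3 -3.0771 (DOWN)
    tb <- data.frame(gene = c("PPARG", "FYN", "ATF3", "EDGE"),
                     mean_first = 10, mean_second = 10,
                     log2fc = c(1.0485, 0.9934, -3.0771, 1.0),
                     se = 0.2, wald_z = 1, p = c(0.001, 0.001, 1e-4, 0.001),
                     padj = c(0.01, 0.01, 0.001, 0.01), status = "NS")
    res <- new("ContrastResult", contrast = "c",
               groupFirst = c("IMAdC", "mono"),
               groupSecond = c("IMAdC", "co"), table = tb,
               alpha = 0.05, lfcMin = 1)
    out <- resultTable(classifyDEGs(res))
    expect_identical(out$status,
                     c("UP", "NS", "DOWN", "NS"))
    expect_identical(unname(degSummary(classifyDEGs(res))[c("n_up",
                                                            "n_down")]),
                     c(1L, 1L))

    # raw-p thresholding flag
    tb$padj <- c(0.2, 0.2, 0.2, 0.2)
    res2 <- new("ContrastResult", contrast = "c",
                groupFirst = c("IMAdC", "mono"),
                groupSecond = c("IMAdC", "co"), table = tb,
                alpha = 0.05, lfcMin = 1)
    out2 <- resultTable(classifyDEGs(res2, thresholdOn = "p"))
    expect_identical(out2$status, c("UP", "NS", "DOWN", "NS"))
})

test_that("classification counts are invariant to gene order", {
    res <- randomContrastResult(sprintf("G%03d", 1:50), "c", seed = 81)
    tb <- resultTable(res)
    perm <- tb[sample(nrow(tb)), ]
    res2 <- new("ContrastResult", contrast = "c",
                groupFirst = c("IMAdC", "mono"),
                groupSecond = c("IMAdC", "co"), table = perm,
                alpha = 0.05, lfcMin = 1)
    expect_identical(degSummary(classifyDEGs(res2)),
                     degSummary(classifyDEGs(res)))
})

test_that("overlap partition categorizes UP/DOWN/CONFLICT correctly", {
    genes <- c("A", "B", "C", "D")
    mk <- function(name, statuses) {
        tb <- data.frame(gene = genes, mean_first = 10, mean_second = 10,
                         log2fc = ifelse(statuses == "UP", 2,
                                  ifelse(statuses == "DOWN", -2, 0)),
                         se = 0.3, wald_z = 0,
                         p = ifelse(statuses == "NS", 0.9, 0.001),
                         padj = ifelse(statuses == "NS", 0.9, 0.01),
                         status = statuses)
        new("ContrastResult", contrast = name,
            groupFirst = c("IMAdC", "mono"),
            groupSecond = c("IMAdC", "co"), table = tb,
            alpha = 0.05, lfcMin = 1)
    }
    r1 <- mk("c1", c("UP", "UP", "NS", "NS"))
    r2 <- mk("c2", c("UP", "DOWN", "NS", "DOWN"))
    part <- partitionOverlap(list(r1, r2))
    g <- part$genes
    expect_identical(g$category[g$gene == "A"], "UP")
    expect_identical(g$category[g$gene == "B"], "CONFLICT")
    expect_identical(g$category[g$gene == "C"], "NS")
    expect_identical(g$category[g$gene == "D"], "DOWN")
    expect_identical(g$region[g$gene == "A"], "c1,c2")
    expect_identical(g$region[g$gene == "C"], "")
    expect_false("C" %in% part$region_counts$gene)

    r3 <- mk("c3", c("UP", "UP", "NS", "NS"))
    bad <- mk("bad", c("UP", "UP", "NS", "NS"))
    bad@table$gene <- c("A", "B", "C", "ZZ")
    expect_error(partitionOverlap(list(r1, bad)), "universe")
})

test_that("contrast with a 1-replicate group is rejected", {
    x <- tinyExperiment()
    keep <- sampleSheet(x)$sample_id != "ia_m2"
    x1 <- x[, keep]
    expect_error(
        nbWaldContrast(x1, contrastSpec("c", c("IMAdC", "mono"),
                                        c("IMAdC", "co")),
                       minTotal = 0L),
        "fewer than 2")
})
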