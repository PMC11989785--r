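test_that("same seed gives bit-identical count matrices", {
    cfg <- simConfig(nGenes = 100, seed = 11)
    a <- simulateCounts(cfg)
    b <- simulateCounts(cfg)
    expect_identical(countsMatrix(a$experiment), countsMatrix(b$experiment))
    c2 <- simulateCounts(simConfig(nGenes = 100, seed = 12))
    expect_false(identical(countsMatrix(a$experiment),
                           countsMatrix(c2$experiment)))
})

test_that("dispersion -> 0 limit approaches Poisson variance/mean of 1", {
    # one gene, 2500 replicates per group = 10,000 draws, equal library
    # sizes, constant mean
    cfg <- simConfig(nGenes = 1, nRepsPerGroup = 2500,
                     baselineLog2Mean = c(6, 0), dispersion = 1e-12,
                     seed = 5)
    cts <- as.numeric(countsMatrix(simulateCounts(cfg)$experiment))
    ratio <- stats::var(cts) / mean(cts)
    expect_gt(ratio, 0.95)
    expect_lt(ratio, 1.05)
})

test_that("NB moments match mu + alpha * mu^2 at scale", {
    alpha <- 0.3
    cfg <- simConfig(nGenes = 1, nRepsPerGroup = 2500,
                     baselineLog2Mean = c(7, 0), dispersion = alpha,
                     seed = 8)
    cts <- as.numeric(countsMatrix(simulateCounts(cfg)$experiment))
    m <- mean(cts)
    expected <- m + alpha * m^2
    expect_gt(stats::var(cts) / expected, 0.9)
    expect_lt(stats::var(cts) / expected, 1.1)
})

test_that("null simulation has near-zero empirical log2 ratios", {
    cfg <- simConfig(nGenes = 200, nRepsPerGroup = 3,
                     baselineLog2Mean = c(7, 0), dispersion = 0.05,
                     seed = 21)
    sim <- simulateCounts(cfg)
    cts <- countsMatrix(sim$experiment)
    sheet <- sampleSheet(sim$experiment)
    g1 <- sheet$sample_id[sheet$cell_type == "IMAdC" &
                          sheet$culture == "mono"]
    g2 <- sheet$sample_id[sheet$cell_type == "IMAdC" &
                          sheet$culture == "co"]
    lfc <- log2(rowMeans(cts[, g1]) / rowMeans(cts[, g2]))
    # mean lfc over genes ~ N(0, sd/sqrt(n)); 3 SE band
    se <- stats::sd(lfc) / sqrt(length(lfc))
    expect_lt(abs(mean(lfc)), 3 * se + 1e-3)
})

test_that("planted effects shift the intended group only", {
    pd <- data.frame(gene = "G0001", contrast = "SMSC_mono_vs_co",
                     log2fc = 3)
    cfg <- simConfig(nGenes = 50, nRepsPerGroup = 50,
                     baselineLog2Mean = c(6, 0), dispersion = 0.01,
                     plantedDE = pd, seed = 31)
    sim <- simulateCounts(cfg)
    cts <- countsMatrix(sim$experiment)
    sheet <- sampleSheet(sim$experiment)
    gm <- function(ct, cu) rowMeans(cts[, sheet$sample_id[
        sheet$cell_type == ct & sheet$culture == cu], drop = FALSE])
    lfc_smsc <- log2(gm("SMSC", "mono")["G0001"] / gm("SMSC", "co")["G0001"])
    lfc_imadc <- log2(gm("IMAdC", "mono")["G0001"] /
                      gm("IMAdC", "co")["G0001"])
    expect_gt(lfc_smsc, 2.5)
    expect_lt(abs(lfc_imadc), 0.5)
})

test_that("contradictory planted effects are rejected", {
    pd <- data.frame(gene = c("G0001", "G0001"),
                     contrast = "IMAdC_mono_vs_co", log2fc = c(1, 2))
    expect_error(simConfig(nGenes = 10, plantedDE = pd, seed = 1),
                 "contradictory")
})

test_that("LR scenario plants pairs satisfying the rule, plus decoys", {
    cfg <- simConfig(nGenes = 100, seed = 41)
    scen <- simulateLRScenario(cfg, nTruePairs = 2, nDecoys = 5)
    expect_identical(nrow(lrPairs(scen$db)), 7L)
    expect_identical(nrow(scen$truth@trueLRPairs), 2L)
    expect_identical(unique(scen$truth@trueLRPairs$mode), "paracrine")

    # truth consistency: planted ligand/receptor genes carry the effects
    # the rule's direction requires
    tl <- scen$truth@trueLog2FC
    for (i in seq_len(2)) {
        lig <- scen$truth@trueLRPairs$ligand[i]
        rec <- scen$truth@trueLRPairs$receptor[i]
        expect_identical(
            tl$log2fc[tl$gene == lig & tl$contrast == "SMSC_mono_vs_co"], 2)
        expect_identical(
            tl$log2fc[tl$gene == rec & tl$contrast == "IMAdC_mono_vs_co"],
            -2)
    }
})

test_that("LR scenario rejects configs with too few genes", {
    cfg <- simConfig(nGenes = 5, seed = 1)
    expect_error(simulateLRScenario(cfg, nTruePairs = 5, nDecoys = 5),
                 "too few")
})

test_that("block network generator matches closed-form edge counts", {
    net <- simulateBlockNetwork(c(4, 4, 4), 1, 0, seed = 3)
    expect_identical(nrow(networkEdges(net$network)), 18L)  # 3 * C(4,2)
    e <- networkEdges(net$network)
    mods <- net$truth@trueModules
    expect_true(all(mods[e$from] == mods[e$to]))  # no cross-module edge

    again <- simulateBlockNetwork(c(4, 4, 4), 1, 0, seed = 3)
    expect_identical(networkEdges(again$network), e)

    expect_error(simulateBlockNetwork(c(4, 4), 0.2, 0.5, seed = 1),
                 "exceed")
    expect_error(simulateBlockNetwork(c(4, 4), 1.2, 0, seed = 1),
                 "\\[0, 1\\]")
})
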