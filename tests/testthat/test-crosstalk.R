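test_that("candidate screening respects database membership", {
    db <- LRDatabase(data.frame(ligand = "GCG", receptor = "DPP4"))
    tb <- data.frame(gene = c("GCG", "DPP4", "ACTB"),
                     mean_first = 10, mean_second = 10,
                     log2fc = c(2, 2, 2), se = 0.3, wald_z = 5,
                     p = 0.001, padj = 0.01, status = "UP")
    res <- new("ContrastResult", contrast = "c",
               groupFirst = c("IMAdC", "mono"),
               groupSecond = c("IMAdC", "co"), table = tb,
               alpha = 0.05, lfcMin = 1)
    cand <- selectLRCandidates(res, db)
    expect_identical(cand$ligands$gene, "GCG")
    expect_identical(cand$receptors$gene, "DPP4")
    expect_identical(cand$n_ligands, 1L)

    # empty DEG set -> empty candidates
    tb$status <- "NS"
    res2 <- new("ContrastResult", contrast = "c",
                groupFirst = c("IMAdC", "mono"),
                groupSecond = c("IMAdC", "co"), table = tb,
                alpha = 0.05, lfcMin = 1)
    cand2 <- selectLRCandidates(res2, db)
    expect_identical(cand2$n_ligands, 0L)

    # gene annotated as both ligand and receptor appears in both sets
    db2 <- LRDatabase(data.frame(ligand = c("GCG", "DPP4"),
                                 receptor = c("DPP4", "GCG")))
    cand3 <- selectLRCandidates(res, db2)
    expect_true("DPP4" %in% cand3$ligands$gene)
    expect_true("GCG" %in% cand3$receptors$gene)
})

test_that("buildPairs applies the direction rule exactly", {
    db <- LRDatabase(data.frame(ligand = c("L1", "L2"),
                                receptor = c("R1", "R2")))
    candidates <- list(
        cL = list(ligands = data.frame(gene = "L1", log2fc = 2,
                                       padj = 0.01, status = "UP"),
                  receptors = data.frame(gene = character(),
                                         log2fc = numeric(),
                                         padj = numeric(),
                                         status = character())),
        cR = list(ligands = data.frame(gene = character(),
                                       log2fc = numeric(),
                                       padj = numeric(),
                                       status = character()),
                  receptors = data.frame(gene = c("R1", "R2"),
                                         log2fc = c(-2, -1.5),
                                         padj = 0.01, status = "DOWN")))
    rule <- data.frame(rule = "test", mode = "paracrine", method = 1L,
                       ligand_contrast = "cL", ligand_status = "UP",
                       receptor_contrast = "cR",
                       receptor_status = "DOWN",
                       source_cell = "SMSC", target_cell = "IMAdC")
    pairs <- buildPairs(rule, candidates, db)
    expect_identical(nrow(pairs), 1L)
    expect_identical(pairs$ligand, "L1")
    expect_identical(pairs$receptor, "R1")
    expect_identical(pairs$mode, "paracrine")

    rule$ligand_status <- "DOWN"
    expect_identical(nrow(buildPairs(rule, candidates, db)), 0L)

    rule$ligand_contrast <- "nope"
    expect_error(buildPairs(rule, candidates, db), "nope")
})

test_that("buildPairs equals the brute-force oracle on random instances", {
    rules <- defaultDirectionRules()
    contrasts <- names(studyContrasts())
    set.seed(101)
    for (i in 1:100) {
        genes <- sprintf("X%02d", seq_len(sample(10:50, 1)))
        nDb <- sample(5:20, 1)
        db <- LRDatabase(data.frame(
            ligand = sample(genes, nDb, replace = TRUE),
            receptor = sample(genes, nDb, replace = TRUE)))
        candidates <- lapply(stats::setNames(contrasts, contrasts),
                             function(cn) selectLRCandidates(
                                 randomContrastResult(genes, cn,
                                                      seed = i * 7 +
                                                          match(cn,
                                                                contrasts)),
                                 db))
        rule <- rules[sample(nrow(rules), 1), , drop = FALSE]
        got <- buildPairs(rule, candidates, db)
        want <- buildPairsOracle(rule, candidates, db)
        expect_identical(nrow(got), nrow(want))
        if (nrow(got))
            expect_setequal(paste(got$ligand, got$receptor),
                            paste(want$ligand, want$receptor))
    }
})

test_that("communication score is the product of magnitude fold changes", {
    expect_equal(communicationScore(1, 2)$cs, 8)
    expect_equal(communicationScore(0, 0)$cs, 1)
    # magnitudes as printed for PPARG (1.0485) and IGF1R (-0.4761)
    sc <- communicationScore(1.0485, -0.4761)
    expect_equal(sc$cs, 2^1.5246, tolerance = 1e-12)
    expect_equal(sc$fc_ligand, 2^1.0485)
    expect_equal(sc$fc_receptor, 2^0.4761)
    # sign-insensitive: down- and upregulation score alike
    expect_equal(communicationScore(-3, 1)$cs, communicationScore(3, 1)$cs)
    expect_error(communicationScore(NA, 1), "finite")
})

test_that("cs is monotone in either member's |log2fc|", {
    base <- communicationScore(1, 1)$cs
    for (d in c(0.5, 1, 2))
        expect_gt(communicationScore(1 + d, 1)$cs, base)
    expect_gt(communicationScore(1, -3)$cs, base)
})

test_that("rankPairs orders by cs then lexicographic and is stable", {
    pairs <- data.frame(ligand = c("B", "A", "C"),
                        receptor = c("R", "R", "R"),
                        cs = c(2, 2, 8))
    r <- rankPairs(pairs)
    expect_identical(r$ligand, c("C", "A", "B"))
    expect_identical(r$rank, 1:3)
    perm <- rankPairs(pairs[c(3, 1, 2), ])
    expect_identical(perm$ligand, r$ligand)

    single <- rankPairs(data.frame(ligand = "L", receptor = "R", cs = 1))
    expect_identical(single$rank, 1L)
})

test_that("planted LR pairs are recovered with no decoy discoveries", {
    cfg <- simConfig(nGenes = 300, nRepsPerGroup = 3,
                     baselineLog2Mean = c(7, 0.5), dispersion = 0.05,
                     seed = 111)
    scen <- simulateLRScenario(cfg, nTruePairs = 2, nDecoys = 5)
    results <- lapply(studyContrasts(), function(cs)
        nbWaldContrast(scen$experiment,
                       contrastSpec(cs$name, cs$first, cs$second)))
    pairs <- runCrosstalk(results, scen$db)
    stratum <- pairs[pairs$rule == "m1_para_SMSC_to_IMAdC", ]
    expect_setequal(paste(stratum$ligand, stratum$receptor),
                    paste(scen$truth@trueLRPairs$ligand,
                          scen$truth@trueLRPairs$receptor))
    decoys <- setdiff(paste(lrPairs(scen$db)$ligand,
                            lrPairs(scen$db)$receptor),
                      paste(scen$truth@trueLRPairs$ligand,
                            scen$truth@trueLRPairs$receptor))
    expect_false(any(paste(pairs$ligand, pairs$receptor) %in% decoys))
})

test_that("all-null data yields an empty crosstalk table", {
    cfg <- simConfig(nGenes = 150, nRepsPerGroup = 3,
                     baselineLog2Mean = c(6, 0.5), dispersion = 0.05,
                     seed = 121)
    sim <- simulateCounts(cfg)
    db <- LRDatabase(data.frame(ligand = c("G0001", "G0002"),
                                receptor = c("G0003", "G0004")))
    results <- lapply(studyContrasts(), function(cs)
        nbWaldContrast(sim$experiment,
                       contrastSpec(cs$name, cs$first, cs$second)))
    pairs <- runCrosstalk(results, db)
    expect_identical(nrow(pairs), 0L)
})

test_that("runCrosstalk reports missing contrasts by name", {
    db <- LRDatabase(data.frame(ligand = "L1", receptor = "R1"))
    res <- list(IMAdC_mono_vs_co =
                    randomContrastResult(c("L1", "R1"),
                                         "IMAdC_mono_vs_co", seed = 1))
    expect_error(runCrosstalk(res, db), "SMSC_mono_vs_co")
})
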