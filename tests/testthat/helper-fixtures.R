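# Shared fixtures and independent oracles used across the suite.

# Tiny fixed experiment: 2 cell types x {mono, co} x 2 replicates.
tinyExperiment <- function(counts = NULL, nGenes = 4L) {
    sheet <- data.frame(
        sample_id = c("ia_m1", "ia_m2", "ia_c1", "ia_c2",
                      "sm_m1", "sm_m2", "sm_c1", "sm_c2"),
        cell_type = rep(c("IMAdC", "SMSC"), each = 4L),
        culture = rep(c("mono", "mono", "co", "co"), 2L),
        replicate = rep(1:2, 4L))
    if (is.null(counts)) {
        counts <- matrix(seq_len(nGenes * 8L), nGenes, 8L)
        dimnames(counts) <- list(sprintf("G%02d", seq_len(nGenes)),
                                 sheet$sample_id)
    }
    CocultureExperiment(counts, sheet)
}

writeTempTSV <- function(df, dir = withr::local_tempdir(.local_envir =
                                                        parent.frame())) {
    path <- tempfile(tmpdir = dir, fileext = ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

# Step-up BH definition, evaluated literally: padj_(i) = min over j >= i
# of min(1, p_(j) * m / j), restored to input order.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    po <- p[o]
    adj <- vapply(seq_len(m), function(i)
        min(1, min(po[i:m] * m / (i:m))), numeric(1))
    out <- numeric(m)
    out[o] <- adj
    out
}

# Upper-tail hypergeometric probability by direct enumeration of the
# counting formula, independent of phyper.
hyperTailOracle <- function(k, K, N, n) {
    hi <- min(K, n)
    if (k > hi) return(0)
    kk <- max(k, max(0, n - (N - K))):hi
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Brute-force pairing: for each database pair, test the rule's status
# requirements against the candidate tables directly.
buildPairsOracle <- function(rule, candidates, db) {
    lig <- candidates[[rule$ligand_contrast]]$ligands
    rec <- candidates[[rule$receptor_contrast]]$receptors
    ok <- function(tab, gene, status)
        gene %in% tab$gene &&
            (status == "ANY" || tab$status[tab$gene == gene] == status)
    p <- lrPairs(db)
    keep <- vapply(seq_len(nrow(p)), function(i)
        ok(lig, p$ligand[i], rule$ligand_status) &&
        ok(rec, p$receptor[i], rule$receptor_status), logical(1))
    p[keep, , drop = FALSE]
}

# Random classified ContrastResult over a small gene universe, for
# property-style crosstalk tests.
randomContrastResult <- function(genes, name, seed) {
    set.seed(seed)
    n <- length(genes)
    lfc <- stats::rnorm(n, 0, 2)
    padj <- stats::runif(n)
    tb <- data.frame(gene = genes, mean_first = 10, mean_second = 10,
                     log2fc = lfc, se = 0.3, wald_z = lfc / 0.3,
                     p = padj, padj = padj, status = "NS",
                     stringsAsFactors = FALSE)
    res <- new("ContrastResult", contrast = name,
               groupFirst = c("IMAdC", "mono"),
               groupSecond = c("IMAdC", "co"),
               table = tb, alpha = 0.05, lfcMin = 1)
    classifyDEGs(res)
}
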