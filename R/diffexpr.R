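## Negative-binomial Wald differential expression between two sample
## groups, with median-of-ratios normalization, method-of-moments
## dispersion estimation shrunk toward a fitted mean-dispersion trend,
## Benjamini-Hochberg correction and threshold-based DEG classification
## (|log2FC| > 1, adjusted p < 0.05 by default).

#' Contrast specification
#'
#' @param name contrast name.
#' @param first,second character(2): (cell_type, culture) of the numerator
#'   and denominator groups. \code{"UP"} means higher in \code{first}.
#' @return list of class \code{"contrastSpec"}.
#' @export
contrastSpec <- function(name, first, second) {
    stopifnot(length(first) == 2L, length(second) == 2L)
    if (identical(first, second)) stop("contrast groups must be disjoint")
    structure(list(name = name, first = first, second = second),
              class = "contrastSpec")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median across all-positive genes of the ratio of
#' its count to the gene's geometric mean across samples; factors are then
#' rescaled to have geometric mean 1.
#'
#' @param x a \linkS4class{CocultureExperiment} or a count matrix.
#' @return named numeric vector of positive size factors.
#' @export
sizeFactorsMOR <- function(x) {
    cts <- if (is(x, "CocultureExperiment")) countsMatrix(x) else as.matrix(x)
    pos <- rowSums(cts > 0) == ncol(cts)
    if (!any(pos))
        stop("no gene with positive counts in every sample; ",
             "filter empty genes or samples first")
    lc <- log(cts[pos, , drop = FALSE])
    ref <- rowMeans(lc)
    sf <- apply(lc, 2L, function(col) exp(stats::median(col - ref)))
    sf <- sf / exp(mean(log(sf)))
    sf
}

#' Filter genes with too few total counts
#'
#' @param x a \linkS4class{CocultureExperiment}.
#' @param minTotal minimum summed count across samples (default 10).
#' @return the filtered \code{CocultureExperiment}.
#' @export
filterLowCounts <- function(x, minTotal = 10L) {
    keep <- rowSums(countsMatrix(x)) >= minTotal
    x[keep, ]
}

#' Method-of-moments NB dispersion with trend shrinkage
#'
#' Per-gene raw dispersions are estimated on size-factor-normalized counts
#' by pooling the within-group method-of-moments estimate
#' \eqn{(s^2 - \bar y)/\bar y^2} across the sample-sheet groups (weighted
#' by within-group degrees of freedom), then shrunk halfway toward a
#' mean-dispersion trend fitted by loess on log mean. Degenerate genes
#' (zero variance, or raw estimates at or below zero) fall to
#' \code{alphaFloor}.
#'
#' @param x a \linkS4class{CocultureExperiment}.
#' @param sizeFactors optional precomputed size factors.
#' @param alphaFloor lower bound on the returned dispersion.
#' @return named numeric vector of per-gene dispersions.
#' @export
estimateDispersionsMoM <- function(x, sizeFactors = NULL,
                                   alphaFloor = 1e-8) {
    stopifnot(is(x, "CocultureExperiment"))
    sheet <- sampleSheet(x)
    grp <- interaction(sheet$cell_type, sheet$culture, drop = TRUE)
    if (any(table(grp) < 2L))
        stop("every group needs >= 2 replicates for dispersion estimation")
    if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMOR(x)
    y <- sweep(countsMatrix(x), 2L, sizeFactors, `/`)

    num <- 0; den <- 0
    for (g in levels(grp)) {
        cols <- grp == g
        n <- sum(cols)
        m <- rowMeans(y[, cols, drop = FALSE])
        v <- apply(y[, cols, drop = FALSE], 1L, stats::var)
        ## per-group MoM: (variance - mean)/mean^2, df-weighted
        a <- ifelse(m > 0, (v - m) / m^2, 0)
        num <- num + (n - 1L) * a
        den <- den + (n - 1L)
    }
    raw <- num / den
    mu <- rowMeans(y)

    ok <- is.finite(raw) & mu > 0
    trend <- rep(stats::median(pmax(raw[ok], alphaFloor)), length(raw))
    if (sum(ok) >= 20L) {
        fit <- tryCatch(
            stats::loess(raw ~ lmu, data = data.frame(raw = raw[ok],
                                                      lmu = log(mu[ok])),
                         span = 0.75, degree = 1L,
                         family = "symmetric"),
            error = function(e) NULL)
        if (!is.null(fit)) {
            pr <- rep(NA_real_, length(raw))
            pr[ok] <- stats::predict(fit, newdata = data.frame(
                lmu = log(mu[ok])))
            trend <- ifelse(is.finite(pr), pr, trend)
        }
    }
    trend <- pmax(trend, alphaFloor)
    alpha <- pmax(alphaFloor, 0.5 * (pmax(raw, alphaFloor) + trend))
    alpha[!is.finite(alpha)] <- alphaFloor
    stats::setNames(alpha, rownames(x))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with order statistics \eqn{p_{(1)} \le \dots
#' \le p_{(m)}}, \eqn{padj_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)},
#' returned in the original order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
    if (anyNA(p) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test for one two-group contrast
#'
#' Normalized group means are compared on the log2 scale; the standard
#' error of the log2 fold change comes from the delta method applied to
#' the NB variance \eqn{\mu + \alpha\mu^2} of each replicate (accounting
#' for size factors), giving a Wald z statistic with a two-sided normal
#' p-value. A pseudocount of 0.5 is added to both group means only when
#' either falls below 0.5, keeping the fold change finite without biasing
#' well-expressed genes. Genes with fewer than \code{minTotal} summed raw
#' counts are removed before testing.
#'
#' @param x a \linkS4class{CocultureExperiment}.
#' @param spec a [contrastSpec()]; each group needs >= 2 replicates.
#' @param dispersions optional per-gene dispersions (estimated via
#'   [estimateDispersionsMoM()] when NULL).
#' @param sizeFactors optional size factors ([sizeFactorsMOR()] when NULL).
#' @param alpha,lfcMin significance and fold-change thresholds passed to
#'   [classifyDEGs()].
#' @param minTotal low-count filter threshold (default 10).
#' @param thresholdOn classify on \code{"padj"} (default) or raw
#'   \code{"p"}.
#' @return A classified \linkS4class{ContrastResult}.
#' @export
nbWaldContrast <- function(x, spec, dispersions = NULL, sizeFactors = NULL,
                           alpha = 0.05, lfcMin = 1, minTotal = 10L,
                           thresholdOn = c("padj", "p")) {
    stopifnot(is(x, "CocultureExperiment"),
              inherits(spec, "contrastSpec"))
    thresholdOn <- match.arg(thresholdOn)
    x <- filterLowCounts(x, minTotal)
    sheet <- sampleSheet(x)
    g1 <- .group_samples(sheet, spec$first)
    g2 <- .group_samples(sheet, spec$second)
    if (length(g1) < 2L || length(g2) < 2L)
        stop("contrast '", spec$name, "': group ",
             if (length(g1) < 2L) paste(spec$first, collapse = "/")
             else paste(spec$second, collapse = "/"),
             " has fewer than 2 replicates")
    if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMOR(x)
    if (is.null(dispersions))
        dispersions <- estimateDispersionsMoM(x, sizeFactors)
    dispersions <- dispersions[rownames(x)]
    y <- sweep(countsMatrix(x), 2L, sizeFactors[colnames(x)], `/`)

    m1 <- rowMeans(y[, g1, drop = FALSE])
    m2 <- rowMeans(y[, g2, drop = FALSE])
    c0 <- 0.5
    use0 <- m1 < c0 | m2 < c0
    a1 <- m1 + c0 * use0
    a2 <- m2 + c0 * use0
    log2fc <- log2(a1 / a2)

    ## delta method: Var(mean of normalized counts) for group k,
    ## each replicate j contributing mu/s_j + alpha mu^2
    varMean <- function(mu, samples) {
        s <- sizeFactors[samples]
        n <- length(s)
        (mu * sum(1 / s) + n * dispersions * mu^2) / n^2
    }
    v1 <- varMean(a1, g1)
    v2 <- varMean(a2, g2)
    se <- sqrt((v1 / a1^2 + v2 / a2^2)) / log(2)
    se <- pmax(se, 1e-12)
    z <- log2fc / se
    p <- 2 * stats::pnorm(-abs(z))
    padj <- bhAdjust(p)

    tb <- data.frame(gene = rownames(x), mean_first = m1, mean_second = m2,
                     log2fc = log2fc, se = se, wald_z = z, p = p,
                     padj = padj, status = "NS",
                     row.names = NULL, stringsAsFactors = FALSE)
    res <- new("ContrastResult", contrast = spec$name,
               groupFirst = spec$first, groupSecond = spec$second,
               table = tb, alpha = alpha, lfcMin = lfcMin)
    classifyDEGs(res, lfcMin = lfcMin, alpha = alpha,
                 thresholdOn = thresholdOn)
}

#' Classify genes as UP / DOWN / NS
#'
#' \code{UP} iff adjusted p (or raw p, see \code{thresholdOn}) is below
#' \code{alpha} and log2FC strictly exceeds \code{lfcMin}; \code{DOWN}
#' symmetric; everything else \code{NS}. The inequality on the fold
#' change is strict, so a gene at exactly the threshold is NS.
#'
#' @param result a \linkS4class{ContrastResult}.
#' @param lfcMin minimum |log2FC| (strict; default 1).
#' @param alpha significance threshold (default 0.05).
#' @param thresholdOn \code{"padj"} (default) or \code{"p"}.
#' @return the \code{ContrastResult} with statuses filled and a
#'   \code{summary} in its show output.
#' @export
classifyDEGs <- function(result, lfcMin = 1, alpha = 0.05,
                         thresholdOn = c("padj", "p")) {
    stopifnot(is(result, "ContrastResult"))
    thresholdOn <- match.arg(thresholdOn)
    tb <- result@table
    sig <- tb[[thresholdOn]] < alpha
    tb$status <- ifelse(sig & tb$log2fc > lfcMin, "UP",
                 ifelse(sig & tb$log2fc < -lfcMin, "DOWN", "NS"))
    result@table <- tb
    result@alpha <- alpha
    result@lfcMin <- lfcMin
    validObject(result)
    result
}

#' DEG summary counts for a contrast
#'
#' @param result a classified \linkS4class{ContrastResult}.
#' @return named integer vector: n_up, n_down, n_total_de, n_genes.
#' @export
degSummary <- function(result) {
    st <- resultTable(result)$status
    c(n_up = sum(st == "UP"), n_down = sum(st == "DOWN"),
      n_total_de = sum(st != "NS"), n_genes = length(st))
}

#' Multi-contrast UP/DOWN/CONFLICT partition
#'
#' Combines two or more classified contrasts on a shared gene universe
#' into per-gene categories: \code{CONFLICT} when a gene is UP in at
#' least one contrast and DOWN in at least one other, \code{UP}/\code{DOWN}
#' when all its DE calls agree, \code{NS} when it is DE nowhere. Venn
#' region membership (which subset of contrasts calls the gene DE) is
#' returned per gene for overlap counting.
#'
#' @param results list of classified \linkS4class{ContrastResult}s over
#'   the same genes.
#' @return list with \code{genes} (data.frame: gene, category, region —
#'   comma-joined contrast names where the gene is DE) and
#'   \code{region_counts} (data.frame: region, category, n).
#' @export
partitionOverlap <- function(results) {
    if (length(results) < 2L) stop("need >= 2 contrasts")
    genes <- resultTable(results[[1L]])$gene
    for (r in results[-1L])
        if (!setequal(resultTable(r)$gene, genes))
            stop("contrasts must share one gene universe")
    nm <- vapply(results, contrastName, "")
    if (anyDuplicated(nm)) stop("duplicate contrast names")
    status <- vapply(results, function(r) {
        tb <- resultTable(r)
        tb$status[match(genes, tb$gene)]
    }, character(length(genes)))
    if (is.null(dim(status))) status <- matrix(status, nrow = 1L)
    colnames(status) <- nm

    anyUp <- rowSums(status == "UP") > 0
    anyDown <- rowSums(status == "DOWN") > 0
    category <- ifelse(anyUp & anyDown, "CONFLICT",
                ifelse(anyUp, "UP", ifelse(anyDown, "DOWN", "NS")))
    region <- apply(status != "NS", 1L, function(m)
        paste(nm[m], collapse = ","))
    df <- data.frame(gene = genes, category = category, region = region,
                     stringsAsFactors = FALSE)
    de <- df[df$category != "NS", , drop = FALSE]
    counts <- if (nrow(de))
        stats::aggregate(list(n = de$gene),
                         by = list(region = de$region,
                                   category = de$category), FUN = length)
    else data.frame(region = character(), category = character(),
                    n = integer())
    counts <- counts[order(counts$region, counts$category), , drop = FALSE]
    rownames(counts) <- NULL
    list(genes = df, region_counts = counts)
}

#' Write a ContrastResult as a volcano-ready TSV
#'
#' Rows sorted by adjusted p then gene.
#'
#' @param result a \linkS4class{ContrastResult}.
#' @param path output path.
#' @export
writeContrastResult <- function(result, path) {
    tb <- resultTable(result)
    tb <- tb[order(tb$padj, tb$gene), , drop = FALSE]
    .write_tsv(tb, path)
}
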