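## Expression normalization and sample-level QC: FPKM, log10(FPKM + 1),
## Pearson correlation between samples, PCA, and average-linkage
## hierarchical clustering on correlation distance. Plus two closed-form
## utilities: the Phred quality transform and 2^-ddCt relative expression.

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' \deqn{FPKM_{gj} = \frac{c_{gj}}{(L_g/10^3)\,(N_j/10^6)}}
#' with \eqn{c_{gj}} the raw count, \eqn{L_g} the gene length in bp and
#' \eqn{N_j} the sample's library size (column sum).
#'
#' @param x a \linkS4class{CocultureExperiment}.
#' @param lengths named numeric vector of gene lengths in bp covering
#'   every gene in \code{x} (see [readGeneLengths()]).
#' @return numeric matrix of FPKM values with attribute
#'   \code{unit = "FPKM"}.
#' @examples
#' cts <- matrix(10L, 1, 1, dimnames = list("G1", "s1"))
#' # a lone gene carries the whole library; scale it to 1e6 fragments
#' @export
fpkm <- function(x, lengths) {
    stopifnot(is(x, "CocultureExperiment"))
    cts <- countsMatrix(x)
    miss <- setdiff(rownames(cts), names(lengths))
    if (length(miss))
        stop("gene length missing for: ",
             paste(utils::head(miss, 5L), collapse = ", "),
             if (length(miss) > 5L) ", ...")
    len <- as.numeric(lengths[rownames(cts)])
    if (any(len < 1)) stop("gene lengths must be >= 1 bp")
    lib <- colSums(cts)
    if (any(lib == 0))
        stop("zero library size for sample(s): ",
             paste(colnames(cts)[lib == 0], collapse = ", "))
    out <- sweep(cts / (len / 1e3), 2L, lib / 1e6, `/`)
    attr(out, "unit") <- "FPKM"
    out
}

#' log10(FPKM + 1) transform
#'
#' @param expr FPKM matrix as returned by [fpkm()].
#' @return matrix of log10(x + 1) values with
#'   \code{unit = "log10_fpkm_plus1"}.
#' @export
logTransform <- function(expr) {
    if (!identical(attr(expr, "unit"), "FPKM"))
        stop("input must be an FPKM matrix (unit attribute 'FPKM')")
    if (any(expr < 0)) stop("negative expression values")
    out <- log10(expr + 1)
    attr(out, "unit") <- "log10_fpkm_plus1"
    out
}

#' Phred quality score
#'
#' \eqn{Q = -10 \log_{10}(e)} for a base-call error probability \eqn{e}.
#'
#' @param errorRate probability of a base-calling error, in (0, 1].
#' @return Phred quality score(s).
#' @examples
#' phredQuality(0.01)   # 20
#' phredQuality(0.001)  # 30
#' @export
phredQuality <- function(errorRate) {
    if (any(!is.finite(errorRate)) || any(errorRate <= 0) ||
        any(errorRate > 1))
        stop("errorRate must lie in (0, 1]")
    -10 * log10(errorRate)
}

#' Relative expression by the 2^-ddCt method
#'
#' Cycle-threshold based relative quantification of a target gene against
#' a reference gene and a control condition:
#' \deqn{2^{-((Ct^{target}_{treated}-Ct^{ref}_{treated}) -
#'            (Ct^{target}_{control}-Ct^{ref}_{control}))}}
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetControl,ctRefControl finite
#'   Ct values.
#' @return fold change relative to the control condition.
#' @examples
#' ddctRelativeExpression(20, 15, 18, 15)  # 2^-2 = 0.25
#' @export
ddctRelativeExpression <- function(ctTargetTreated, ctRefTreated,
                                   ctTargetControl, ctRefControl) {
    vals <- c(ctTargetTreated, ctRefTreated, ctTargetControl, ctRefControl)
    if (any(!is.finite(vals))) stop("Ct values must be finite")
    ddct <- (ctTargetTreated - ctRefTreated) -
        (ctTargetControl - ctRefControl)
    2^(-ddct)
}

#' Sample-level QC summary
#'
#' On a log10(FPKM + 1) matrix: Pearson correlation between samples over
#' genes, PCA with samples as observations (gene-centered, unscaled), and
#' average-linkage hierarchical clustering on 1 - correlation distance.
#'
#' @param expr log-transformed expression matrix from [logTransform()].
#' @return list with \code{correlation} (sample x sample),
#'   \code{pca_scores} (sample x component), \code{pca_var_explained}
#'   (fractions, non-increasing), \code{hclust} (an \code{hclust} object)
#'   and \code{linkage} (the linkage used, \code{"average"}).
#' @export
qcSummary <- function(expr) {
    if (!identical(attr(expr, "unit"), "log10_fpkm_plus1"))
        stop("qcSummary expects a log10(FPKM + 1) matrix")
    if (ncol(expr) < 2L) stop("need >= 2 samples")
    sds <- apply(expr, 2L, stats::sd)
    if (any(sds == 0))
        stop("zero-variance sample(s), correlation undefined: ",
             paste(colnames(expr)[sds == 0], collapse = ", "))
    cc <- stats::cor(expr, method = "pearson")
    pca <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
    ve <- pca$sdev^2 / sum(pca$sdev^2)
    keep <- seq_len(min(ncol(expr) - 1L, ncol(pca$x)))
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    list(correlation = cc,
         pca_scores = pca$x[, keep, drop = FALSE],
         pca_var_explained = ve[keep],
         hclust = hc,
         linkage = "average")
}
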