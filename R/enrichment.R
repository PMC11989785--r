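## Hypergeometric over-representation analysis of DEG lists against a
## gene-set collection, with BH correction across all tested terms.
## Up- and down-regulated lists are intended to be tested separately,
## each forming its own BH family.

#' Over-representation analysis
#'
#' For each term with \eqn{K} universe genes, the upper-tail exact
#' hypergeometric probability of observing at least \eqn{k} of the
#' \eqn{n} DEGs in the term, drawing from a universe of size \eqn{N}:
#' \deqn{p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n).}
#' Terms are intersected with the universe first; terms with no universe
#' gene are dropped. BH adjustment runs across all tested terms.
#'
#' @param degGenes character vector of DEG symbols (must be a subset of
#'   \code{universe}).
#' @param universe character vector of background symbols (typically all
#'   genes surviving the low-count filter).
#' @param gsc a \linkS4class{GeneSetCollection2}.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame with one row per tested term: term_id, term_name,
#'   k, K, n, N, p, padj, significant, genes (comma-joined sorted DEG
#'   members); sorted by p then term_id.
#' @examples
#' gsc <- GeneSetCollection2(list(S1 = c("A", "B", "C")))
#' ora(c("A", "B"), c("A", "B", "C", "D", "E"), gsc)
#' @export
ora <- function(degGenes, universe, gsc, alpha = 0.05) {
    degGenes <- unique(toupper(degGenes))
    universe <- unique(toupper(universe))
    bad <- setdiff(degGenes, universe)
    if (length(bad))
        stop("DEG gene(s) outside the universe: ",
             paste(utils::head(bad, 10L), collapse = ", "))
    N <- length(universe)
    n <- length(degGenes)
    rows <- lapply(names(geneSets(gsc)), function(id) {
        members <- intersect(geneSets(gsc)[[id]], universe)
        K <- length(members)
        if (K == 0L) return(NULL)
        hits <- intersect(members, degGenes)
        k <- length(hits)
        p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(term_id = id, term_name = gsc@termNames[[id]],
                   k = k, K = K, n = n, N = N, p = p,
                   genes = paste(sort(hits), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term_id = character(), term_name = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = numeric(), padj = numeric(),
                          significant = logical(), genes = character()))
    out$padj <- bhAdjust(out$p)
    out$significant <- out$padj < alpha
    out <- out[order(out$p, out$term_id),
               c("term_id", "term_name", "k", "K", "n", "N", "p", "padj",
                 "significant", "genes")]
    rownames(out) <- NULL
    out
}

#' Report top enriched terms with gene-term incidence
#'
#' Tabular analogue of a Sankey/bubble plot: the top \code{topM}
#' significant terms plus the gene-to-term incidence pairs needed to draw
#' the ribbons.
#'
#' @param rows output of [ora()].
#' @param topM maximum number of significant terms to keep.
#' @return list with \code{terms} (the selected rows) and
#'   \code{incidence} (data.frame: gene, term_id), with one incidence row
#'   per DEG-in-term membership.
#' @export
enrichmentReport <- function(rows, topM = 10L) {
    sig <- rows[rows$significant, , drop = FALSE]
    sig <- utils::head(sig, topM)
    inc <- if (nrow(sig)) {
        do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
            g <- strsplit(sig$genes[i], ",", fixed = TRUE)[[1L]]
            g <- g[nzchar(g)]
            if (!length(g)) return(NULL)
            data.frame(gene = g, term_id = sig$term_id[i],
                       stringsAsFactors = FALSE)
        }))
    } else NULL
    if (is.null(inc))
        inc <- data.frame(gene = character(), term_id = character())
    rownames(inc) <- NULL
    list(terms = sig, incidence = inc)
}
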