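## DEG-induced subnetworks, degree-based hub ranking, and module
## detection by spectral embedding + k-means (k = 3 by default, the
## number of subnetworks reported per DEG direction in the study design
## this pipeline mirrors).

#' Subgraph induced by a gene set
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param genes character vector of symbols (case-insensitive).
#' @return the induced \linkS4class{InteractionNetwork}: nodes present in
#'   both, edges with both ends retained.
#' @export
inducedSubgraph <- function(net, genes) {
    stopifnot(is(net, "InteractionNetwork"))
    genes <- toupper(genes)
    keep <- intersect(networkNodes(net), genes)
    e <- networkEdges(net)
    e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
    InteractionNetwork(e, nodes = keep)
}

#' Degree-based hub ranking
#'
#' Nodes sorted by degree descending; ties broken by gene symbol
#' ascending; ranks run 1..n.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param topN how many hubs to return (default 10; capped at the node
#'   count).
#' @return data.frame: gene, degree, rank.
#' @export
hubRanking <- function(net, topN = 10L) {
    stopifnot(is(net, "InteractionNetwork"))
    nodes <- networkNodes(net)
    e <- networkEdges(net)
    deg <- table(factor(c(e$from, e$to), levels = nodes))
    df <- data.frame(gene = nodes, degree = as.integer(deg),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$degree, df$gene), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    utils::head(df, topN)
}

#' Network modules by spectral embedding + k-means
#'
#' Non-isolated nodes are embedded using the first \code{k} eigenvectors
#' (smallest eigenvalues) of the symmetric normalized Laplacian
#' \eqn{L = I - D^{-1/2} A D^{-1/2}} of the (optionally weighted)
#' adjacency matrix — connected components are handled jointly, since
#' each contributes a zero eigenvalue — then row-normalized and clustered
#' with \code{kmeans} (\code{nstart = 20}) under a fixed seed. Isolated
#' nodes are excluded and reported separately.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param k number of modules (default 3).
#' @param seed integer seed for the k-means restarts.
#' @param weighted use edge weights in the adjacency (default TRUE; all
#'   weights are 1 unless the input carried confidence values).
#' @return list with \code{modules} (named integer vector: gene ->
#'   module id in 1..k), \code{isolated} (character vector) and \code{k}.
#' @export
kmeansModules <- function(net, k = 3L, seed, weighted = TRUE) {
    stopifnot(is(net, "InteractionNetwork"))
    if (missing(seed)) stop("a seed is mandatory")
    e <- networkEdges(net)
    connected <- sort(unique(c(e$from, e$to)))
    isolated <- setdiff(networkNodes(net), connected)
    n <- length(connected)
    if (n < k)
        stop("only ", n, " non-isolated node(s); reduce k (", k, ")")
    if (k == 1L)
        return(list(modules = stats::setNames(rep(1L, n), connected),
                    isolated = isolated, k = 1L))
    if (k == n)  # each node its own module; kmeans needs k < n points
        return(list(modules = stats::setNames(seq_len(n), connected),
                    isolated = isolated, k = as.integer(k)))
    A <- matrix(0, n, n, dimnames = list(connected, connected))
    w <- if (weighted) e$weight else rep(1, nrow(e))
    A[cbind(e$from, e$to)] <- w
    A[cbind(e$to, e$from)] <- w
    d <- rowSums(A)
    Dinv <- 1 / sqrt(d)
    L <- diag(n) - (Dinv %o% Dinv) * A
    dec <- eigen(L, symmetric = TRUE)
    ## smallest k eigenvalues = last k columns
    U <- dec$vectors[, n - seq_len(k) + 1L, drop = FALSE]
    rn <- sqrt(rowSums(U^2))
    rn[rn == 0] <- 1
    U <- U / rn
    set.seed(.substream(seed, 5L))
    km <- stats::kmeans(U, centers = k, nstart = 20L, iter.max = 100L)
    list(modules = stats::setNames(as.integer(km$cluster), connected),
         isolated = isolated, k = as.integer(k))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length (matched by names when both
#'   are named).
#' @return numeric scalar.
#' @export
adjustedRandIndex2 <- function(a, b) {
    if (!is.null(names(a)) && !is.null(names(b))) {
        common <- intersect(names(a), names(b))
        a <- a[common]; b <- b[common]
    }
    stopifnot(length(a) == length(b), length(a) > 0L)
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sumIJ <- sum(comb2(tab))
    sumI <- sum(comb2(rowSums(tab)))
    sumJ <- sum(comb2(colSums(tab)))
    nC2 <- comb2(sum(tab))
    expected <- sumI * sumJ / nC2
    maxIdx <- (sumI + sumJ) / 2
    if (maxIdx == expected) return(1)
    (sumIJ - expected) / (maxIdx - expected)
}

#' Pathway-gene incidence and co-membership network
#'
#' For the top \code{nPathways} significant enrichment terms, builds the
#' bipartite gene-to-pathway incidence table (annotated with each gene's
#' log2 fold change) and the gene co-membership edge list linking genes
#' that share at least one selected pathway.
#'
#' @param rows output of [ora()].
#' @param result the \linkS4class{ContrastResult} providing log2 fold
#'   changes.
#' @param nPathways how many top significant pathways to use (default 10;
#'   if fewer are significant, all are used with a message).
#' @return list with \code{incidence} (gene, term_id, log2fc) and
#'   \code{edges} (data.frame from, to) of co-membership links.
#' @export
pathwayGeneNetwork <- function(rows, result, nPathways = 10L) {
    sig <- rows[rows$significant, , drop = FALSE]
    if (nrow(sig) < nPathways)
        message("only ", nrow(sig), " significant pathway(s); using all")
    sel <- utils::head(sig, nPathways)
    rep <- enrichmentReport(rows, topM = nPathways)
    inc <- rep$incidence
    tb <- resultTable(result)
    inc$log2fc <- tb$log2fc[match(inc$gene, tb$gene)]
    edges <- NULL
    for (id in unique(inc$term_id)) {
        g <- sort(unique(inc$gene[inc$term_id == id]))
        if (length(g) >= 2L) {
            cmb <- t(utils::combn(g, 2L))
            edges <- rbind(edges, data.frame(from = cmb[, 1L],
                                             to = cmb[, 2L],
                                             stringsAsFactors = FALSE))
        }
    }
    if (is.null(edges))
        edges <- data.frame(from = character(), to = character())
    edges <- unique(edges)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    list(incidence = inc, edges = edges, terms = sel)
}
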