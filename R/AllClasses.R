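#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

CELL_TYPES <- c("IMAdC", "SMSC")
CULTURES <- c("mono", "co")
DEG_STATUSES <- c("UP", "DOWN", "NS")

#' Co-culture RNA-seq experiment container
#'
#' Extends \linkS4class{SummarizedExperiment} with the two-cell-type,
#' mono/co-culture sample sheet used throughout the pipeline. The single
#' assay \code{"counts"} holds non-negative integer gene-level counts
#' (genes x samples); \code{colData} carries \code{cell_type}
#' (\code{"IMAdC"} or \code{"SMSC"}), \code{culture} (\code{"mono"} or
#' \code{"co"}) and \code{replicate}.
#'
#' @seealso [CocultureExperiment()] for the constructor, [readCounts()] to
#'   build one from TSV files.
#' @name CocultureExperiment-class
#' @aliases CocultureExperiment-class
#' @exportClass CocultureExperiment
setClass("CocultureExperiment", contains = "SummarizedExperiment")

.validCocultureExperiment <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (anyNA(cts) || any(!is.finite(cts)))
            msg <- c(msg, "counts must be finite and non-missing")
        else {
            if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
            if (any(cts != round(cts)))
                msg <- c(msg, "counts must be integers")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    need <- c("cell_type", "culture", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        if (!all(cd$cell_type %in% CELL_TYPES))
            msg <- c(msg, "cell_type must be 'IMAdC' or 'SMSC'")
        if (!all(cd$culture %in% CULTURES))
            msg <- c(msg, "culture must be 'mono' or 'co'")
        rep <- cd$replicate
        if (anyNA(rep) || any(rep != round(rep)) || any(rep < 1))
            msg <- c(msg, "replicate must be a positive integer")
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
}
setValidity("CocultureExperiment", .validCocultureExperiment)

#' Construct a CocultureExperiment
#'
#' @param counts integer matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param sampleSheet data.frame with columns \code{sample_id},
#'   \code{cell_type}, \code{culture}, \code{replicate}; rows are matched to
#'   the columns of \code{counts} by \code{sample_id}.
#' @return A \linkS4class{CocultureExperiment}.
#' @examples
#' cts <- matrix(0:3, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"),
#'                     cell_type = "IMAdC",
#'                     culture = c("mono", "co"), replicate = 1L)
#' CocultureExperiment(cts, sheet)
#' @export
CocultureExperiment <- function(counts, sampleSheet) {
    counts <- as.matrix(counts)
    sampleSheet <- as.data.frame(sampleSheet)
    if (!"sample_id" %in% colnames(sampleSheet))
        stop("sample sheet must have a 'sample_id' column")
    if (anyDuplicated(sampleSheet$sample_id))
        stop("duplicate sample_id in sample sheet: ",
             paste(unique(sampleSheet$sample_id[
                 duplicated(sampleSheet$sample_id)]), collapse = ", "))
    unmatched <- c(setdiff(colnames(counts), sampleSheet$sample_id),
                   setdiff(sampleSheet$sample_id, colnames(counts)))
    if (length(unmatched))
        stop("sample ids in counts and sample sheet do not match: ",
             paste(unmatched, collapse = ", "))
    sampleSheet <- sampleSheet[match(colnames(counts),
                                     sampleSheet$sample_id), , drop = FALSE]
    cd <- S4Vectors::DataFrame(sampleSheet[setdiff(colnames(sampleSheet),
                                                   "sample_id")],
                               row.names = sampleSheet$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("CocultureExperiment", se)
}

#' @describeIn CocultureExperiment-class the raw count matrix.
#' @param object,x a \code{CocultureExperiment}.
#' @export
setGeneric("countsMatrix", function(object) standardGeneric("countsMatrix"))

#' @rdname CocultureExperiment-class
#' @export
setMethod("countsMatrix", "CocultureExperiment", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @describeIn CocultureExperiment-class the sample sheet as a data.frame
#'   with a \code{sample_id} column.
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))

#' @rdname CocultureExperiment-class
#' @export
setMethod("sampleSheet", "CocultureExperiment", function(object) {
    cd <- as.data.frame(SummarizedExperiment::colData(object))
    data.frame(sample_id = rownames(cd), cd, row.names = NULL,
               stringsAsFactors = FALSE)
})

#' Ligand-receptor reference database
#'
#' Curated ligand -> receptor gene-symbol pairs (human symbols, CellTalkDB
#' dialect). Symbols are uppercased at construction and duplicate pairs
#' collapsed, so membership tests are case-insensitive.
#'
#' @slot pairs data.frame with character columns \code{ligand} and
#'   \code{receptor}; unique rows, sorted.
#' @slot provenance character scalar describing the source.
#' @export
setClass("LRDatabase",
         representation(pairs = "data.frame", provenance = "character"))

setValidity("LRDatabase", function(object) {
    p <- object@pairs
    msg <- character()
    if (!all(c("ligand", "receptor") %in% colnames(p)))
        return("pairs must have 'ligand' and 'receptor' columns")
    if (any(!nzchar(p$ligand)) || any(!nzchar(p$receptor)) ||
        anyNA(p$ligand) || anyNA(p$receptor))
        msg <- c(msg, "empty or missing gene symbols are not allowed")
    if (any(p$ligand != toupper(p$ligand)) ||
        any(p$receptor != toupper(p$receptor)))
        msg <- c(msg, "symbols must be uppercase")
    if (anyDuplicated(paste(p$ligand, p$receptor, sep = "\r")))
        msg <- c(msg, "duplicate ligand-receptor pairs")
    if (length(msg)) msg else TRUE
})

#' @rdname LRDatabase-class
#' @param pairs data.frame with columns \code{ligand}, \code{receptor}
#'   (any case; uppercased and deduplicated).
#' @param provenance character scalar.
#' @export
LRDatabase <- function(pairs, provenance = "user") {
    pairs <- data.frame(ligand = toupper(as.character(pairs$ligand)),
                        receptor = toupper(as.character(pairs$receptor)),
                        stringsAsFactors = FALSE)
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs$ligand, pairs$receptor), , drop = FALSE]
    rownames(pairs) <- NULL
    new("LRDatabase", pairs = pairs, provenance = provenance)
}

#' @describeIn LRDatabase-class the pair table.
#' @param object an \code{LRDatabase}.
#' @export
setGeneric("lrPairs", function(object) standardGeneric("lrPairs"))

#' @rdname LRDatabase-class
#' @export
setMethod("lrPairs", "LRDatabase", function(object) object@pairs)

#' @describeIn LRDatabase-class distinct ligand symbols.
#' @export
setGeneric("ligands", function(object) standardGeneric("ligands"))

#' @rdname LRDatabase-class
#' @export
setMethod("ligands", "LRDatabase", function(object)
    sort(unique(object@pairs$ligand)))

#' @describeIn LRDatabase-class distinct receptor symbols.
#' @export
setGeneric("receptors", function(object) standardGeneric("receptors"))

#' @rdname LRDatabase-class
#' @export
setMethod("receptors", "LRDatabase", function(object)
    sort(unique(object@pairs$receptor)))

setMethod("show", "LRDatabase", function(object) {
    cat("LRDatabase:", nrow(object@pairs), "pairs,",
        length(ligands(object)), "ligands,",
        length(receptors(object)), "receptors\n")
    cat("provenance:", object@provenance, "\n")
})

#' Gene-set collection (GMT-style)
#'
#' @slot sets named list of character vectors (term id -> member symbols).
#' @slot termNames named character vector of term descriptions.
#' @export
setClass("GeneSetCollection2",
         representation(sets = "list", termNames = "character"))

setValidity("GeneSetCollection2", function(object) {
    msg <- character()
    ids <- names(object@sets)
    if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
        msg <- c(msg, "term ids must be unique non-empty names")
    if (any(vapply(object@sets, length, 1L) == 0L))
        msg <- c(msg, "member sets must be non-empty")
    if (!identical(sort(names(object@termNames)), sort(ids)))
        msg <- c(msg, "termNames must be named by the same term ids")
    if (length(msg)) msg else TRUE
})

#' @rdname GeneSetCollection2-class
#' @param sets named list of character vectors.
#' @param termNames named character vector; defaults to the ids.
#' @export
GeneSetCollection2 <- function(sets, termNames = NULL) {
    sets <- lapply(sets, function(s) sort(unique(toupper(s))))
    if (is.null(termNames))
        termNames <- stats::setNames(names(sets), names(sets))
    new("GeneSetCollection2", sets = sets,
        termNames = termNames[names(sets)])
}

#' @describeIn GeneSetCollection2-class the member list.
#' @param object a \code{GeneSetCollection2}.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname GeneSetCollection2-class
#' @export
setMethod("geneSets", "GeneSetCollection2", function(object) object@sets)

setMethod("show", "GeneSetCollection2", function(object) {
    sz <- vapply(object@sets, length, 1L)
    cat("GeneSetCollection2:", length(object@sets), "terms; set sizes",
        min(sz), "-", max(sz), "\n")
})

#' Undirected gene interaction network
#'
#' A light container for an undirected, simple (no self-loops, no
#' multi-edges) interaction network over gene symbols, with optional edge
#' confidence weights in [0, 1].
#'
#' @slot nodes character vector of node symbols (sorted, unique).
#' @slot edges data.frame with columns \code{from}, \code{to} (with
#'   \code{from < to} lexicographically) and \code{weight}.
#' @export
setClass("InteractionNetwork",
         representation(nodes = "character", edges = "data.frame"))

setValidity("InteractionNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("from", "to", "weight") %in% colnames(e)))
        return("edges must have 'from', 'to', 'weight' columns")
    if (nrow(e)) {
        if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
        if (!all(c(e$from, e$to) %in% object@nodes))
            msg <- c(msg, "edges reference unknown nodes")
        if (any(e$from > e$to))
            msg <- c(msg, "edges must be stored with from < to")
        if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
            msg <- c(msg, "duplicate edges")
        if (any(e$weight < 0 | e$weight > 1))
            msg <- c(msg, "weights must lie in [0, 1]")
    }
    if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate nodes")
    if (length(msg)) msg else TRUE
})

#' @rdname InteractionNetwork-class
#' @param edges data.frame with columns \code{from}, \code{to} and
#'   optionally \code{weight}; undirected duplicates are collapsed and
#'   self-loops dropped with a warning.
#' @param nodes optional extra (possibly isolated) nodes.
#' @export
InteractionNetwork <- function(edges = NULL, nodes = character()) {
    if (is.null(edges) || nrow(edges) == 0L) {
        e <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
    } else {
        from <- toupper(as.character(edges$from))
        to <- toupper(as.character(edges$to))
        w <- if ("weight" %in% colnames(edges))
            as.numeric(edges$weight) else rep(1, length(from))
        loops <- from == to
        if (any(loops)) {
            warning(sum(loops), " self-loop edge(s) dropped")
            from <- from[!loops]; to <- to[!loops]; w <- w[!loops]
        }
        a <- pmin(from, to); b <- pmax(from, to)
        key <- paste(a, b, sep = "\r")
        keep <- !duplicated(key)
        e <- data.frame(from = a[keep], to = b[keep], weight = w[keep],
                        stringsAsFactors = FALSE)
        e <- e[order(e$from, e$to), , drop = FALSE]
        rownames(e) <- NULL
    }
    nodes <- sort(unique(c(toupper(nodes), e$from, e$to)))
    new("InteractionNetwork", nodes = nodes, edges = e)
}

#' @describeIn InteractionNetwork-class node symbols.
#' @param object an \code{InteractionNetwork}.
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkNodes", "InteractionNetwork",
          function(object) object@nodes)

#' @describeIn InteractionNetwork-class the edge table.
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkEdges", "InteractionNetwork",
          function(object) object@edges)

setMethod("show", "InteractionNetwork", function(object) {
    cat("InteractionNetwork:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges\n")
})

#' Result of one two-group differential-expression contrast
#'
#' Per-gene normalized group means, log2 fold change (first-listed group as
#' numerator), delta-method standard error, Wald z, p, BH-adjusted p, and a
#' DEG status in \code{UP}/\code{DOWN}/\code{NS} at the thresholds recorded
#' in \code{alpha} and \code{lfcMin}.
#'
#' @slot contrast character name of the contrast.
#' @slot groupFirst,groupSecond character(2): (cell_type, culture).
#' @slot table data.frame with columns gene, mean_first, mean_second,
#'   log2fc, se, wald_z, p, padj, status.
#' @slot alpha,lfcMin numeric thresholds used by the classification.
#' @export
setClass("ContrastResult",
         representation(contrast = "character", groupFirst = "character",
                        groupSecond = "character", table = "data.frame",
                        alpha = "numeric", lfcMin = "numeric"))

setValidity("ContrastResult", function(object) {
    tb <- object@table
    need <- c("gene", "mean_first", "mean_second", "log2fc", "se",
              "wald_z", "p", "padj", "status")
    miss <- setdiff(need, colnames(tb))
    if (length(miss))
        return(paste0("result table lacks column(s): ",
                      paste(miss, collapse = ", ")))
    msg <- character()
    if (anyDuplicated(tb$gene)) msg <- c(msg, "duplicate genes")
    if (nrow(tb)) {
        if (any(tb$p < 0 | tb$p > 1, na.rm = TRUE) ||
            any(tb$padj < 0 | tb$padj > 1, na.rm = TRUE))
            msg <- c(msg, "p and padj must lie in [0, 1]")
        if (any(tb$padj + 1e-12 < tb$p, na.rm = TRUE))
            msg <- c(msg, "padj must be >= p")
        if (!all(tb$status %in% DEG_STATUSES))
            msg <- c(msg, "status must be UP, DOWN or NS")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn ContrastResult-class the per-gene result table.
#' @param object a \code{ContrastResult}.
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname ContrastResult-class
#' @export
setMethod("resultTable", "ContrastResult", function(object) object@table)

#' @describeIn ContrastResult-class the contrast name.
#' @export
setGeneric("contrastName", function(object) standardGeneric("contrastName"))

#' @rdname ContrastResult-class
#' @export
setMethod("contrastName", "ContrastResult",
          function(object) object@contrast)

#' @describeIn ContrastResult-class genes with a given status.
#' @param status one of "UP", "DOWN", "NS".
#' @export
setGeneric("degGenes", function(object, status = c("UP", "DOWN"))
    standardGeneric("degGenes"))

#' @rdname ContrastResult-class
#' @export
setMethod("degGenes", "ContrastResult", function(object, status) {
    status <- match.arg(status, DEG_STATUSES, several.ok = TRUE)
    sort(object@table$gene[object@table$status %in% status])
})

setMethod("show", "ContrastResult", function(object) {
    tb <- object@table
    cat("ContrastResult '", object@contrast, "': ",
        paste(object@groupFirst, collapse = "/"), " vs ",
        paste(object@groupSecond, collapse = "/"), "\n", sep = "")
    cat(" ", nrow(tb), "genes;", sum(tb$status == "UP"), "UP,",
        sum(tb$status == "DOWN"), "DOWN at padj <", object@alpha,
        "and |log2FC| >", object@lfcMin, "\n")
})

#' Planted ground truth accompanying synthetic data
#'
#' @slot trueLog2FC data.frame(gene, contrast, log2fc) of planted effects.
#' @slot trueLRPairs data.frame of planted crosstalk pairs (ligand,
#'   receptor, mode, method, source_cell, target_cell).
#' @slot trueModules named integer vector: gene -> planted module id.
#' @export
setClass("SyntheticTruth",
         representation(trueLog2FC = "data.frame", trueLRPairs = "data.frame",
                        trueModules = "integer"))

#' @rdname SyntheticTruth-class
#' @param trueLog2FC,trueLRPairs,trueModules see slots.
#' @export
SyntheticTruth <- function(trueLog2FC = NULL, trueLRPairs = NULL,
                           trueModules = NULL) {
    if (is.null(trueLog2FC))
        trueLog2FC <- data.frame(gene = character(), contrast = character(),
                                 log2fc = numeric())
    if (is.null(trueLRPairs))
        trueLRPairs <- data.frame(ligand = character(),
                                  receptor = character(), mode = character(),
                                  method = integer(),
                                  source_cell = character(),
                                  target_cell = character())
    if (is.null(trueModules)) trueModules <- integer()
    new("SyntheticTruth", trueLog2FC = trueLog2FC,
        trueLRPairs = trueLRPairs,
        trueModules = if (is.null(trueModules)) integer() else trueModules)
}

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", nrow(object@trueLog2FC), "planted effects,",
        nrow(object@trueLRPairs), "planted LR pairs,",
        length(object@trueModules), "module labels\n")
})
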