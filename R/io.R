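## Readers and writers for the plain-text formats the pipeline exchanges.
## Everything is TSV (UTF-8, header row, no quoting of numeric fields) or
## GMT; readers validate aggressively so malformed inputs fail at the door.

.read_tsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = "")
}

.write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a count matrix and sample sheet into a CocultureExperiment
#'
#' The count file is a TSV whose first column holds gene ids and whose
#' header row holds sample ids; all remaining cells must be non-negative
#' integers. The sample sheet is a TSV with columns \code{sample_id},
#' \code{cell_type}, \code{culture}, \code{replicate} covering exactly the
#' samples in the count header.
#'
#' @param countsPath path to the counts TSV.
#' @param sheetPath path to the sample-sheet TSV.
#' @return A \linkS4class{CocultureExperiment}.
#' @export
readCounts <- function(countsPath, sheetPath) {
    raw <- .read_tsv(countsPath)
    if (ncol(raw) < 2L)
        stop("counts file needs a gene-id column plus >=1 sample column")
    genes <- as.character(raw[[1L]])
    if (anyDuplicated(genes))
        stop("duplicate gene id(s) in ", countsPath, ": ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    m <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(apply(m, 2L, as.numeric))
    num <- matrix(num, nrow = nrow(raw),
                  dimnames = list(genes, colnames(raw)[-1L]))
    bad <- which(is.na(num) | !is.finite(num) | num < 0 |
                 num != round(num), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-integer or invalid count at gene '",
             genes[bad[1L, 1L]], "', sample '",
             colnames(num)[bad[1L, 2L]], "' in ", countsPath)
    storage.mode(num) <- "integer"
    sheet <- .read_tsv(sheetPath)
    need <- c("sample_id", "cell_type", "culture", "replicate")
    miss <- setdiff(need, colnames(sheet))
    if (length(miss))
        stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
    CocultureExperiment(num, sheet)
}

#' Write a CocultureExperiment back to counts + sample-sheet TSVs
#'
#' @param x a \linkS4class{CocultureExperiment}.
#' @param countsPath,sheetPath output paths.
#' @return Invisibly, \code{countsPath}.
#' @export
writeCounts <- function(x, countsPath, sheetPath) {
    stopifnot(is(x, "CocultureExperiment"))
    cts <- countsMatrix(x)
    df <- data.frame(gene_id = rownames(cts), cts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .write_tsv(df, countsPath)
    .write_tsv(sampleSheet(x), sheetPath)
    invisible(countsPath)
}

#' Read a per-gene length table
#'
#' TSV with columns \code{gene_id} and \code{length_bp} (positive
#' integers), as used by [fpkm()].
#'
#' @param path path to the TSV.
#' @return Named numeric vector of lengths in bp.
#' @export
readGeneLengths <- function(path) {
    df <- .read_tsv(path)
    miss <- setdiff(c("gene_id", "length_bp"), colnames(df))
    if (length(miss))
        stop("gene-length table lacks column(s): ",
             paste(miss, collapse = ", "))
    len <- as.numeric(df$length_bp)
    if (anyNA(len) || any(len < 1) || any(len != round(len)))
        stop("length_bp must be positive integers")
    if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in ", path)
    stats::setNames(len, as.character(df$gene_id))
}

#' Read a CellTalkDB-dialect ligand-receptor table
#'
#' Requires columns \code{ligand_gene_symbol} and
#' \code{receptor_gene_symbol}; all other columns are ignored. Symbols are
#' uppercased and duplicate pairs collapsed (a message reports how many).
#'
#' @param path path to the TSV.
#' @param provenance provenance string stored on the database.
#' @return An \linkS4class{LRDatabase}.
#' @export
readLRDatabase <- function(path, provenance = path) {
    df <- .read_tsv(path)
    need <- c("ligand_gene_symbol", "receptor_gene_symbol")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("ligand-receptor table lacks column(s): ",
             paste(miss, collapse = ", "))
    lig <- toupper(as.character(df$ligand_gene_symbol))
    rec <- toupper(as.character(df$receptor_gene_symbol))
    if (any(!nzchar(lig)) || any(!nzchar(rec)) || anyNA(lig) || anyNA(rec))
        stop("empty ligand or receptor symbol in ", path)
    db <- LRDatabase(data.frame(ligand = lig, receptor = rec),
                     provenance = provenance)
    dropped <- length(lig) - nrow(lrPairs(db))
    if (dropped > 0)
        message(dropped, " duplicate pair row(s) collapsed")
    db
}

#' Write an LRDatabase as a CellTalkDB-dialect TSV
#'
#' @param db an \linkS4class{LRDatabase}.
#' @param path output path.
#' @export
writeLRDatabase <- function(db, path) {
    p <- lrPairs(db)
    .write_tsv(data.frame(lr_pair = paste(p$ligand, p$receptor, sep = "_"),
                          ligand_gene_symbol = p$ligand,
                          receptor_gene_symbol = p$receptor), path)
}

#' Read a GMT gene-set file
#'
#' Each line: term id, description, then one or more member symbols, all
#' tab-separated.
#'
#' @param path path to the GMT file.
#' @return A \linkS4class{GeneSetCollection2}.
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- vapply(fields, length, 1L)
    if (any(nf < 3L))
        stop("GMT line ", which(nf < 3L)[1L],
             " has fewer than 3 fields in ", path)
    ids <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicate term id(s) in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sets <- lapply(fields, function(f) f[-c(1L, 2L)])
    names(sets) <- ids
    nms <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
    GeneSetCollection2(sets, nms)
}

#' Write a GeneSetCollection2 as GMT
#'
#' @param gsc a \linkS4class{GeneSetCollection2}.
#' @param path output path.
#' @export
writeGMT <- function(gsc, path) {
    sets <- geneSets(gsc)
    lines <- vapply(names(sets), function(id)
        paste(c(id, gsc@termNames[[id]], sets[[id]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read an interaction edge list
#'
#' TSV with two symbol columns (\code{from}, \code{to}) and an optional
#' \code{weight} column in [0, 1]. Undirected duplicates are collapsed;
#' self-loops are dropped with a warning.
#'
#' @param path path to the TSV.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
readEdgeList <- function(path) {
    df <- .read_tsv(path)
    if (ncol(df) < 2L)
        stop("edge list needs at least two columns in ", path)
    colnames(df)[1:2] <- c("from", "to")
    InteractionNetwork(df)
}

#' Write an InteractionNetwork as an edge-list TSV
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param path output path.
#' @export
writeEdgeList <- function(net, path) {
    .write_tsv(networkEdges(net), path)
}
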