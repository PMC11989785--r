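## Ligand-receptor crosstalk inference. Differentially expressed ligands
## and receptors are screened per contrast against a curated LR database,
## paired under direction rules describing two methods (mono-vs-co
## comparison; co-vs-co comparison) and two modes (autocrine within a
## cell population, paracrine across populations), and ranked within each
## (mode, method, source, target) stratum by communication score — the
## product of the two members' fold-change magnitudes.

#' Screen differentially expressed ligand and receptor candidates
#'
#' DEGs of a contrast whose symbol appears in the database's ligand
#' (resp. receptor) universe. A gene annotated as both may appear in both
#' sets.
#'
#' @param result a classified \linkS4class{ContrastResult}.
#' @param db an \linkS4class{LRDatabase}.
#' @return list with \code{contrast}, \code{ligands} and \code{receptors}
#'   (each a data.frame: gene, log2fc, padj, status) and counts
#'   \code{n_ligands}, \code{n_receptors}.
#' @export
selectLRCandidates <- function(result, db) {
    stopifnot(is(result, "ContrastResult"), is(db, "LRDatabase"))
    tb <- resultTable(result)
    de <- tb[tb$status %in% c("UP", "DOWN"), , drop = FALSE]
    pick <- function(universe) {
        out <- de[toupper(de$gene) %in% universe,
                  c("gene", "log2fc", "padj", "status"), drop = FALSE]
        out$gene <- toupper(out$gene)
        out <- out[order(out$gene), , drop = FALSE]
        rownames(out) <- NULL
        out
    }
    lig <- pick(ligands(db))
    rec <- pick(receptors(db))
    list(contrast = contrastName(result), ligands = lig, receptors = rec,
         n_ligands = nrow(lig), n_receptors = nrow(rec))
}

#' Build ligand-receptor pairs under one direction rule
#'
#' Emits every database pair whose ligand is a DE ligand candidate in the
#' rule's ligand contrast with the required status (\code{"ANY"} accepts
#' UP or DOWN), and whose receptor analogously passes in the receptor
#' contrast; stamps mode, method, source and target cells from the rule.
#'
#' @param rule single-row data.frame in the [defaultDirectionRules()]
#'   layout.
#' @param candidates named list of [selectLRCandidates()] outputs, keyed
#'   by contrast name.
#' @param db an \linkS4class{LRDatabase}.
#' @return data.frame of pairs: ligand, receptor, mode, method,
#'   source_cell, target_cell, ligand_log2fc, receptor_log2fc.
#' @export
buildPairs <- function(rule, candidates, db) {
    stopifnot(nrow(rule) == 1L, is(db, "LRDatabase"))
    for (cn in c(rule$ligand_contrast, rule$receptor_contrast))
        if (!cn %in% names(candidates))
            stop("unknown contrast in rule: ", cn)
    passes <- function(cand, status)
        cand[status == "ANY" | cand$status == status, , drop = FALSE]
    lig <- passes(candidates[[rule$ligand_contrast]]$ligands,
                  rule$ligand_status)
    rec <- passes(candidates[[rule$receptor_contrast]]$receptors,
                  rule$receptor_status)
    p <- lrPairs(db)
    hit <- p$ligand %in% lig$gene & p$receptor %in% rec$gene
    p <- p[hit, , drop = FALSE]
    if (!nrow(p))
        return(data.frame(ligand = character(), receptor = character(),
                          mode = character(), method = integer(),
                          source_cell = character(),
                          target_cell = character(),
                          ligand_log2fc = numeric(),
                          receptor_log2fc = numeric()))
    out <- data.frame(ligand = p$ligand, receptor = p$receptor,
                      mode = rule$mode, method = rule$method,
                      source_cell = rule$source_cell,
                      target_cell = rule$target_cell,
                      ligand_log2fc = lig$log2fc[match(p$ligand, lig$gene)],
                      receptor_log2fc =
                          rec$log2fc[match(p$receptor, rec$gene)],
                      stringsAsFactors = FALSE)
    out <- unique(out)
    rownames(out) <- NULL
    out
}

#' Communication score of a ligand-receptor pair
#'
#' The product of the two members' fold-change magnitudes:
#' \deqn{CS = 2^{|log2FC_L|} \cdot 2^{|log2FC_R|}.}
#' Magnitudes are used so that a strongly downregulated member raises the
#' score exactly as an upregulated one; the signed log2 fold changes are
#' preserved alongside for transparency.
#'
#' @param ligandLog2FC,receptorLog2FC finite log2 fold changes.
#' @return list with \code{fc_ligand}, \code{fc_receptor}, \code{cs}.
#' @examples
#' communicationScore(1, 2)$cs  # 2 * 4 = 8
#' @export
communicationScore <- function(ligandLog2FC, receptorLog2FC) {
    if (any(!is.finite(c(ligandLog2FC, receptorLog2FC))))
        stop("log2 fold changes must be finite")
    fcL <- 2^abs(ligandLog2FC)
    fcR <- 2^abs(receptorLog2FC)
    list(fc_ligand = fcL, fc_receptor = fcR, cs = fcL * fcR)
}

#' Rank scored pairs by communication score
#'
#' Descending by \code{cs}; ties broken by (ligand, receptor)
#' lexicographically; ranks 1..n.
#'
#' @param pairs data.frame with at least ligand, receptor, cs.
#' @return the data.frame sorted with a \code{rank} column.
#' @export
rankPairs <- function(pairs) {
    o <- order(-pairs$cs, pairs$ligand, pairs$receptor)
    out <- pairs[o, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Run the full two-method crosstalk inference
#'
#' Applies every direction rule to the classified study contrasts, scores
#' the resulting pairs, and ranks them within each
#' (mode, method, source, target) stratum.
#'
#' @param results named list of classified \linkS4class{ContrastResult}s
#'   covering every contrast referenced by the rules (by default the
#'   three of [studyContrasts()]).
#' @param db an \linkS4class{LRDatabase}.
#' @param rules rule table (default [defaultDirectionRules()]).
#' @return data.frame: rule, mode, method, source_cell, target_cell,
#'   ligand, receptor, ligand_log2fc, receptor_log2fc, fc_ligand,
#'   fc_receptor, cs, rank (within stratum).
#' @export
runCrosstalk <- function(results, db, rules = defaultDirectionRules()) {
    needed <- unique(c(rules$ligand_contrast, rules$receptor_contrast))
    miss <- setdiff(needed, names(results))
    if (length(miss))
        stop("missing contrast result(s): ", paste(miss, collapse = ", "))
    candidates <- lapply(results[needed], selectLRCandidates, db = db)
    out <- NULL
    for (i in seq_len(nrow(rules))) {
        rule <- rules[i, , drop = FALSE]
        p <- buildPairs(rule, candidates, db)
        if (!nrow(p)) next
        sc <- communicationScore(p$ligand_log2fc, p$receptor_log2fc)
        p$fc_ligand <- sc$fc_ligand
        p$fc_receptor <- sc$fc_receptor
        p$cs <- sc$cs
        p <- rankPairs(p)
        p <- cbind(rule = rule$rule, p, stringsAsFactors = FALSE)
        out <- rbind(out, p)
    }
    if (is.null(out))
        out <- data.frame(rule = character(), ligand = character(),
                          receptor = character(), mode = character(),
                          method = integer(), source_cell = character(),
                          target_cell = character(),
                          ligand_log2fc = numeric(),
                          receptor_log2fc = numeric(),
                          fc_ligand = numeric(), fc_receptor = numeric(),
                          cs = numeric(), rank = integer())
    ## soundness: every emitted pair must be in the database with DE
    ## members — asserted on every run
    if (nrow(out)) {
        key <- paste(out$ligand, out$receptor)
        dbkey <- paste(lrPairs(db)$ligand, lrPairs(db)$receptor)
        stopifnot(all(key %in% dbkey))
    }
    rownames(out) <- NULL
    out
}

#' Write a crosstalk table plus per-stratum link files
#'
#' @param pairs output of [runCrosstalk()].
#' @param path output TSV path; per-stratum two-column link files are
#'   written next to it as \code{<path>.<rule>.links.tsv}.
#' @export
writeCrosstalk <- function(pairs, path) {
    cols <- c("rule", "mode", "method", "source_cell", "target_cell",
              "ligand", "receptor", "ligand_log2fc", "receptor_log2fc",
              "fc_ligand", "fc_receptor", "cs", "rank")
    .write_tsv(pairs[, intersect(cols, colnames(pairs)), drop = FALSE],
               path)
    for (r in unique(pairs$rule)) {
        sub <- pairs[pairs$rule == r, c("ligand", "receptor")]
        .write_tsv(sub, paste0(path, ".", r, ".links.tsv"))
    }
    invisible(path)
}
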