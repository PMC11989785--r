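## Seeded synthetic-data generators. These stand in for the (unreleased)
## four-group co-culture RNA-seq data: two cell types x {mono, co}, three
## biological replicates each, negative-binomial counts with planted
## differential expression, planted ligand-receptor pairs satisfying a
## direction rule, and planted network modules. Every generator returns its
## ground truth so recovery can be measured.

#' Simulation configuration for four-group NB count data
#'
#' Counts for gene g in sample j are drawn
#' NB(mean = s_j * 2^(b_g + effects), variance = mu + alpha_g * mu^2),
#' where b_g is a normal baseline log2 mean, s_j a per-sample library size
#' factor and alpha_g the gene dispersion. Planted effects are specified
#' per (gene, contrast): the effect is added to the log2 mean of the
#' contrast's first-listed group, so the gene's expected log2 fold change
#' in that contrast equals the planted value.
#'
#' @param nGenes number of genes (default 2000, the desk-scale analogue of
#'   a full transcriptome).
#' @param nRepsPerGroup biological replicates per group (default 3).
#' @param baselineLog2Mean length-2 numeric (mean, sd) of the normal
#'   baseline log2 expression (default c(5, 2)).
#' @param dispersion NB dispersion alpha: a scalar, a length-\code{nGenes}
#'   vector, or a length-2 numeric \code{c(shape, rate)} interpreted as a
#'   gamma distribution over genes.
#' @param plantedDE data.frame with columns \code{gene}, \code{contrast},
#'   \code{log2fc}; contrast names must come from [studyContrasts()].
#' @param sizeFactorsTrue per-sample positive library size factors
#'   (default all 1); length 4 * nRepsPerGroup, ordered as the generated
#'   samples.
#' @param seed integer seed (mandatory).
#' @return A validated config list of class \code{"simConfig"}.
#' @export
simConfig <- function(nGenes = 2000L, nRepsPerGroup = 3L,
                      baselineLog2Mean = c(5, 2), dispersion = 0.1,
                      plantedDE = NULL, sizeFactorsTrue = NULL,
                      seed) {
    if (missing(seed)) stop("a seed is mandatory")
    if (nGenes < 1L || nRepsPerGroup < 2L)
        stop("need >=1 gene and >=2 replicates per group")
    if (length(baselineLog2Mean) != 2L || baselineLog2Mean[2L] < 0)
        stop("baselineLog2Mean must be c(mean, sd) with sd >= 0")
    if (any(dispersion <= 0)) stop("dispersion parameters must be positive")
    nSamples <- 4L * nRepsPerGroup
    if (is.null(sizeFactorsTrue)) sizeFactorsTrue <- rep(1, nSamples)
    if (length(sizeFactorsTrue) != nSamples || any(sizeFactorsTrue <= 0))
        stop("sizeFactorsTrue must be ", nSamples, " positive values")
    if (is.null(plantedDE))
        plantedDE <- data.frame(gene = character(), contrast = character(),
                                log2fc = numeric())
    plantedDE <- as.data.frame(plantedDE)
    stopifnot(all(c("gene", "contrast", "log2fc") %in% colnames(plantedDE)))
    if (anyDuplicated(plantedDE[c("gene", "contrast")]))
        stop("contradictory planted effects: same gene and contrast twice")
    if (!all(plantedDE$contrast %in% names(studyContrasts())))
        stop("unknown contrast in plantedDE: ",
             paste(setdiff(plantedDE$contrast, names(studyContrasts())),
                   collapse = ", "))
    structure(list(nGenes = as.integer(nGenes),
                   nRepsPerGroup = as.integer(nRepsPerGroup),
                   baselineLog2Mean = as.numeric(baselineLog2Mean),
                   dispersion = dispersion, plantedDE = plantedDE,
                   sizeFactorsTrue = as.numeric(sizeFactorsTrue),
                   seed = as.integer(seed)),
              class = "simConfig")
}

.sim_gene_ids <- function(n)
    sprintf("G%0*d", max(4L, nchar(n)), seq_len(n))

.sim_sheet <- function(nReps) {
    groups <- expand.grid(culture = c("mono", "co"),
                          cell_type = c("IMAdC", "SMSC"),
                          stringsAsFactors = FALSE)[, c(2, 1)]
    sheet <- groups[rep(seq_len(4L), each = nReps), ]
    sheet$replicate <- rep(seq_len(nReps), times = 4L)
    sheet$sample_id <- paste(sheet$cell_type, sheet$culture,
                             sheet$replicate, sep = "_")
    rownames(sheet) <- NULL
    sheet[, c("sample_id", "cell_type", "culture", "replicate")]
}

.sim_dispersions <- function(config) {
    d <- config$dispersion
    if (length(d) == config$nGenes) return(as.numeric(d))
    if (length(d) == 1L) return(rep(as.numeric(d), config$nGenes))
    if (length(d) == 2L)  # gamma(shape, rate) across genes
        return(stats::rgamma(config$nGenes, shape = d[1L], rate = d[2L]))
    stop("dispersion must be scalar, per-gene, or c(shape, rate)")
}

#' Generate four-group NB counts with planted differential expression
#'
#' @param config a [simConfig()].
#' @return A list with elements \code{experiment}
#'   (\linkS4class{CocultureExperiment}) and \code{truth}
#'   (\linkS4class{SyntheticTruth} carrying the planted log2 fold changes).
#' @examples
#' sim <- simulateCounts(simConfig(nGenes = 50, seed = 1))
#' dim(countsMatrix(sim$experiment))
#' @export
simulateCounts <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(.substream(config$seed, 1L))
    nG <- config$nGenes
    sheet <- .sim_sheet(config$nRepsPerGroup)
    nS <- nrow(sheet)
    genes <- .sim_gene_ids(nG)

    baseline <- stats::rnorm(nG, config$baselineLog2Mean[1L],
                             config$baselineLog2Mean[2L])
    alpha <- .sim_dispersions(config)

    log2mu <- matrix(baseline, nG, nS)
    rownames(log2mu) <- genes
    specs <- studyContrasts()
    pd <- config$plantedDE
    if (nrow(pd)) {
        unknown <- setdiff(pd$gene, genes)
        if (length(unknown))
            stop("planted gene(s) not in the matrix: ",
                 paste(unknown, collapse = ", "))
        for (i in seq_len(nrow(pd))) {
            first <- specs[[pd$contrast[i]]]$first
            cols <- sheet$cell_type == first[1L] & sheet$culture == first[2L]
            log2mu[pd$gene[i], cols] <- log2mu[pd$gene[i], cols] +
                pd$log2fc[i]
        }
    }
    mu <- sweep(2^log2mu, 2L, config$sizeFactorsTrue, `*`)
    counts <- matrix(stats::rnbinom(nG * nS, mu = mu,
                                    size = rep(1 / alpha, nS)),
                     nG, nS, dimnames = list(genes, sheet$sample_id))
    storage.mode(counts) <- "integer"
    list(experiment = CocultureExperiment(counts, sheet),
         truth = SyntheticTruth(trueLog2FC = pd))
}

#' Default direction rules for ligand-receptor pair construction
#'
#' Encodes the two pairing methods over the study's three contrasts.
#' Method 1 compares mono- vs co-cultured cells of each type; method 2
#' uses the co-culture vs co-culture contrast. Autocrine rules pair a
#' ligand and receptor from the same cell population; paracrine rules
#' match a ligand from the source cell to a receptor in the target cell:
#' \itemize{
#'   \item method 1, autocrine (per cell type): any DE ligand with any DE
#'     receptor within that cell's mono-vs-co contrast;
#'   \item method 2, autocrine IMAdC: ligand UP and receptor UP in
#'     co-IMAdC vs co-SMSC (genes higher in co-cultured IMAdCs); the
#'     SMSC rule is the DOWN/DOWN mirror;
#'   \item method 1, paracrine SMSC to IMAdC: ligand UP in SMSC mono-vs-co
#'     and receptor DOWN in IMAdC mono-vs-co; mirrored for the opposite
#'     direction;
#'   \item method 2, paracrine SMSC to IMAdC: ligand DOWN and receptor UP
#'     in co-IMAdC vs co-SMSC; mirrored for the opposite direction.
#' }
#' Rules are data, not code: supply a modified table to [runCrosstalk()]
#' to change the semantics.
#'
#' @return data.frame with columns \code{rule}, \code{mode}, \code{method},
#'   \code{ligand_contrast}, \code{ligand_status}, \code{receptor_contrast},
#'   \code{receptor_status}, \code{source_cell}, \code{target_cell}.
#' @export
defaultDirectionRules <- function() {
    data.frame(
        rule = c("m1_auto_IMAdC", "m1_auto_SMSC",
                 "m2_auto_IMAdC", "m2_auto_SMSC",
                 "m1_para_SMSC_to_IMAdC", "m1_para_IMAdC_to_SMSC",
                 "m2_para_SMSC_to_IMAdC", "m2_para_IMAdC_to_SMSC"),
        mode = c("autocrine", "autocrine", "autocrine", "autocrine",
                 "paracrine", "paracrine", "paracrine", "paracrine"),
        method = c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L),
        ligand_contrast = c("IMAdC_mono_vs_co", "SMSC_mono_vs_co",
                            "co_IMAdC_vs_co_SMSC", "co_IMAdC_vs_co_SMSC",
                            "SMSC_mono_vs_co", "IMAdC_mono_vs_co",
                            "co_IMAdC_vs_co_SMSC", "co_IMAdC_vs_co_SMSC"),
        ligand_status = c("ANY", "ANY", "UP", "DOWN",
                          "UP", "UP", "DOWN", "UP"),
        receptor_contrast = c("IMAdC_mono_vs_co", "SMSC_mono_vs_co",
                              "co_IMAdC_vs_co_SMSC", "co_IMAdC_vs_co_SMSC",
                              "IMAdC_mono_vs_co", "SMSC_mono_vs_co",
                              "co_IMAdC_vs_co_SMSC", "co_IMAdC_vs_co_SMSC"),
        receptor_status = c("ANY", "ANY", "UP", "DOWN",
                            "DOWN", "DOWN", "UP", "DOWN"),
        source_cell = c("IMAdC", "SMSC", "IMAdC", "SMSC",
                        "SMSC", "IMAdC", "SMSC", "IMAdC"),
        target_cell = c("IMAdC", "SMSC", "IMAdC", "SMSC",
                        "IMAdC", "IMAdC", "IMAdC", "SMSC"),
        stringsAsFactors = FALSE)
}

#' Generate a ligand-receptor recovery scenario with planted truth
#'
#' Takes a base count-simulation config, plants differential-expression
#' effects on fresh ligand/receptor genes so that \code{nTruePairs} pairs
#' satisfy the given direction rule, adds \code{nDecoys} database pairs
#' whose members carry no effect, simulates counts, and returns everything
#' plus the ground truth. Planted effect signs follow the rule's required
#' statuses (\code{ANY} plants UP).
#'
#' @param config a [simConfig()]; its existing \code{plantedDE} rows are
#'   kept and the scenario's effects appended.
#' @param nTruePairs number of planted ligand-receptor pairs.
#' @param nDecoys number of decoy database pairs on non-DE genes.
#' @param rule single row of [defaultDirectionRules()] (default: the
#'   method-1 paracrine SMSC-to-IMAdC rule).
#' @param effectSize absolute planted log2 fold change (default 2).
#' @return list(experiment, db, truth): the simulated
#'   \linkS4class{CocultureExperiment}, the \linkS4class{LRDatabase} of
#'   planted plus decoy pairs, and a \linkS4class{SyntheticTruth} whose
#'   \code{trueLRPairs} hold the planted pairs stamped with the rule's
#'   mode/method/source/target.
#' @export
simulateLRScenario <- function(config, nTruePairs = 2L, nDecoys = 5L,
                               rule = NULL, effectSize = 2) {
    stopifnot(inherits(config, "simConfig"))
    if (is.null(rule)) {
        rules <- defaultDirectionRules()
        rule <- rules[rules$rule == "m1_para_SMSC_to_IMAdC", ]
    }
    stopifnot(nrow(rule) == 1L)
    genes <- .sim_gene_ids(config$nGenes)
    used <- unique(config$plantedDE$gene)
    avail <- setdiff(genes, used)
    need <- 2L * nTruePairs + 2L * nDecoys
    if (length(avail) < need)
        stop("config has too few unplanted genes (need ", need, ")")
    pick <- avail[seq_len(need)]
    ligs <- pick[seq_len(nTruePairs)]
    recs <- pick[nTruePairs + seq_len(nTruePairs)]
    decoy <- pick[2L * nTruePairs + seq_len(2L * nDecoys)]

    sgn <- function(status) if (status == "DOWN") -1 else 1
    extra <- data.frame(
        gene = c(ligs, recs),
        contrast = c(rep(rule$ligand_contrast, nTruePairs),
                     rep(rule$receptor_contrast, nTruePairs)),
        log2fc = c(rep(sgn(rule$ligand_status) * effectSize, nTruePairs),
                   rep(sgn(rule$receptor_status) * effectSize, nTruePairs)))
    ## same gene may host a ligand in one contrast and nothing elsewhere;
    ## merge with any pre-existing planted effects
    config$plantedDE <- rbind(config$plantedDE, extra)
    if (anyDuplicated(config$plantedDE[c("gene", "contrast")]))
        stop("planted LR genes collide with existing planted effects")

    sim <- simulateCounts(config)
    dbPairs <- data.frame(
        ligand = c(ligs, decoy[seq_len(nDecoys)]),
        receptor = c(recs, decoy[nDecoys + seq_len(nDecoys)]))
    db <- LRDatabase(dbPairs, provenance = "synthetic LR scenario")
    truePairs <- data.frame(ligand = toupper(ligs), receptor = toupper(recs),
                            mode = rule$mode, method = rule$method,
                            source_cell = rule$source_cell,
                            target_cell = rule$target_cell,
                            stringsAsFactors = FALSE)
    truth <- SyntheticTruth(trueLog2FC = config$plantedDE,
                            trueLRPairs = truePairs)
    list(experiment = sim$experiment, db = db, truth = truth)
}

#' Generate a stochastic-block-model interaction network
#'
#' Planted-partition benchmark for module detection: nodes fall into
#' blocks of the given sizes, with independent edge probabilities
#' \code{pWithin} inside a block and \code{pBetween} across blocks.
#'
#' @param moduleSizes integer vector of block sizes.
#' @param pWithin,pBetween edge probabilities; \code{pWithin > pBetween}.
#' @param seed integer seed.
#' @param genePrefix prefix for generated node names.
#' @param nodeNames optional explicit node names (length
#'   \code{sum(moduleSizes)}), overriding \code{genePrefix}.
#' @return list(network = \linkS4class{InteractionNetwork},
#'   truth = \linkS4class{SyntheticTruth} with \code{trueModules}).
#' @examples
#' net <- simulateBlockNetwork(c(4, 4, 4), 1, 0, seed = 1)
#' nrow(networkEdges(net$network))  # 3 * choose(4, 2) = 18
#' @export
simulateBlockNetwork <- function(moduleSizes, pWithin, pBetween, seed,
                                 genePrefix = "N", nodeNames = NULL) {
    .stopifnot_prob(c(pWithin, pBetween), "edge probabilities")
    if (pWithin <= pBetween) stop("pWithin must exceed pBetween")
    if (missing(seed)) stop("a seed is mandatory")
    n <- sum(moduleSizes)
    labels <- rep(seq_along(moduleSizes), times = moduleSizes)
    nodes <- if (!is.null(nodeNames)) {
        stopifnot(length(nodeNames) == n)
        toupper(nodeNames)
    } else sprintf("%s%0*d", genePrefix, max(3L, nchar(n)), seq_len(n))
    set.seed(.substream(seed, 3L))
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pEdge <- ifelse(labels[idx[, 1L]] == labels[idx[, 2L]],
                    pWithin, pBetween)
    keep <- stats::runif(nrow(idx)) < pEdge
    edges <- data.frame(from = nodes[idx[keep, 1L]],
                        to = nodes[idx[keep, 2L]])
    net <- InteractionNetwork(edges, nodes = nodes)
    truth <- SyntheticTruth(trueModules = stats::setNames(labels,
                                                          toupper(nodes)))
    list(network = net, truth = truth)
}

#' Generate a random gene-set collection over a gene universe
#'
#' Utility for exercising over-representation analysis on synthetic data:
#' draws term memberships uniformly from the universe, optionally spiking
#' one term with a supplied gene list so enrichment is planted.
#'
#' @param universe character vector of gene symbols.
#' @param nTerms number of random terms.
#' @param setSize length-2 range of member counts per term.
#' @param spike optional character vector; if given, an extra term
#'   \code{"SPIKE"} containing exactly these genes is added.
#' @param seed integer seed.
#' @return A \linkS4class{GeneSetCollection2}.
#' @export
simulateGeneSets <- function(universe, nTerms = 20L, setSize = c(10L, 50L),
                             spike = NULL, seed) {
    if (missing(seed)) stop("a seed is mandatory")
    set.seed(.substream(seed, 4L))
    sizes <- sample(setSize[1L]:setSize[2L], nTerms, replace = TRUE)
    sets <- lapply(sizes, function(k)
        sample(universe, min(k, length(universe))))
    names(sets) <- sprintf("T%03d", seq_len(nTerms))
    if (!is.null(spike)) sets[["SPIKE"]] <- spike
    GeneSetCollection2(sets)
}
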