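## End-to-end orchestration: qc -> differential expression (all three
## study contrasts) -> overlap partition -> enrichment (UP and DOWN lists
## per contrast) -> network hubs/modules -> crosstalk. One config, one
## seed, a deterministic output tree and a JSON manifest sufficient to
## re-execute the run.

#' Pipeline configuration
#'
#' Exactly one of real-input mode (all file paths supplied) or synthetic
#' mode (\code{synthetic} a [simConfig()]) must be used. In synthetic
#' mode gene lengths, the LR database (planted pairs plus decoys), gene
#' sets and a module-structured interaction network are generated from
#' the same seed.
#'
#' @param countsPath,sheetPath,lengthsPath,lrDbPath,gmtPath,edgeListPath
#'   input file paths (real mode).
#' @param synthetic a [simConfig()] (synthetic mode).
#' @param contrasts named list of contrast specs as in [studyContrasts()].
#' @param alpha,lfcMin DEG thresholds (defaults 0.05 and 1).
#' @param kModules number of network modules (default 3).
#' @param topNHubs,topMTerms report sizes.
#' @param seed integer seed (synthetic mode and module detection).
#' @param outDir output directory.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(countsPath = NULL, sheetPath = NULL,
                           lengthsPath = NULL, lrDbPath = NULL,
                           gmtPath = NULL, edgeListPath = NULL,
                           synthetic = NULL,
                           contrasts = studyContrasts(),
                           alpha = 0.05, lfcMin = 1, kModules = 3L,
                           topNHubs = 10L, topMTerms = 10L,
                           seed, outDir) {
    if (missing(seed) || missing(outDir))
        stop("seed and outDir are mandatory")
    structure(list(countsPath = countsPath, sheetPath = sheetPath,
                   lengthsPath = lengthsPath, lrDbPath = lrDbPath,
                   gmtPath = gmtPath, edgeListPath = edgeListPath,
                   synthetic = synthetic, contrasts = contrasts,
                   alpha = alpha, lfcMin = lfcMin,
                   kModules = as.integer(kModules),
                   topNHubs = as.integer(topNHubs),
                   topMTerms = as.integer(topMTerms),
                   seed = as.integer(seed), outDir = outDir),
              class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; a \code{synthetic}
#' block holds [simConfig()] arguments.
#'
#' @param path YAML file.
#' @return a \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    syn <- NULL
    if (!is.null(y$synthetic)) {
        sa <- y$synthetic
        syn <- simConfig(
            nGenes = sa$nGenes %||% 2000L,
            nRepsPerGroup = sa$nRepsPerGroup %||% 3L,
            baselineLog2Mean = unlist(sa$baselineLog2Mean %||% c(5, 2)),
            dispersion = unlist(sa$dispersion %||% 0.1),
            seed = sa$seed %||% y$seed)
    }
    pipelineConfig(countsPath = y$countsPath, sheetPath = y$sheetPath,
                   lengthsPath = y$lengthsPath, lrDbPath = y$lrDbPath,
                   gmtPath = y$gmtPath, edgeListPath = y$edgeListPath,
                   synthetic = syn,
                   alpha = y$alpha %||% 0.05, lfcMin = y$lfcMin %||% 1,
                   kModules = y$kModules %||% 3L,
                   topNHubs = y$topNHubs %||% 10L,
                   topMTerms = y$topMTerms %||% 10L,
                   seed = y$seed, outDir = y$outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pipeline configuration without computing
#'
#' Structural dry run: mode exclusivity, file existence, required
#' columns, and >= 2 replicates per contrast group. All failures are
#' collected and reported together.
#'
#' @param config a [pipelineConfig()].
#' @return character vector of failure messages (empty when valid).
#' @export
validateConfig <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    fail <- character()
    pathKeys <- c("countsPath", "sheetPath", "lengthsPath", "lrDbPath",
                  "gmtPath", "edgeListPath")
    paths <- unlist(config[pathKeys])
    real <- length(paths) > 0L
    syn <- !is.null(config$synthetic)
    if (real && syn)
        fail <- c(fail, "config mixes real-input and synthetic modes")
    if (!real && !syn)
        fail <- c(fail, "config has neither input paths nor synthetic mode")
    if (real) {
        for (k in pathKeys) {
            if (is.null(config[[k]]))
                fail <- c(fail, paste0("missing input path: ", k))
            else if (!file.exists(config[[k]]))
                fail <- c(fail, paste0(k, " does not exist: ",
                                       config[[k]]))
        }
        if (!is.null(config$countsPath) && file.exists(config$countsPath) &&
            !is.null(config$sheetPath) && file.exists(config$sheetPath)) {
            x <- tryCatch(readCounts(config$countsPath, config$sheetPath),
                          error = function(e) conditionMessage(e))
            if (is.character(x)) fail <- c(fail, x)
            else {
                sheet <- sampleSheet(x)
                for (cs in config$contrasts)
                    for (grp in list(cs$first, cs$second)) {
                        n <- length(.group_samples(sheet, grp))
                        if (n < 2L)
                            fail <- c(fail, paste0(
                                "group ", paste(grp, collapse = "/"),
                                " has ", n, " replicate(s); need >= 2"))
                    }
            }
        }
    }
    fail
}

.load_inputs <- function(config) {
    if (!is.null(config$synthetic)) {
        sc <- config$synthetic
        scen <- simulateLRScenario(sc, nTruePairs = 3L, nDecoys = 10L)
        genes <- rownames(scen$experiment)
        set.seed(.substream(config$seed, 2L))
        lengths <- stats::setNames(
            sample(200:10000, length(genes), replace = TRUE), genes)
        gsc <- simulateGeneSets(genes, nTerms = 20L,
                                spike = utils::head(
                                    unique(scen$truth@trueLog2FC$gene), 20L),
                                seed = config$seed)
        sizes <- rep(15L, 3L)
        net <- simulateBlockNetwork(sizes, 0.45, 0.02, seed = config$seed,
                                    nodeNames = utils::head(genes,
                                                            sum(sizes)))
        list(experiment = scen$experiment, lengths = lengths,
             db = scen$db, gsc = gsc, network = net$network,
             truth = scen$truth, networkTruth = net$truth)
    } else {
        list(experiment = readCounts(config$countsPath, config$sheetPath),
             lengths = readGeneLengths(config$lengthsPath),
             db = readLRDatabase(config$lrDbPath),
             gsc = readGMT(config$gmtPath),
             network = readEdgeList(config$edgeListPath),
             truth = NULL, networkTruth = NULL)
    }
}

#' Run the pipeline end-to-end
#'
#' Executes qc, differential expression for every configured contrast,
#' the multi-contrast overlap partition, over-representation of UP and
#' DOWN DEG lists per contrast, DEG-induced network hub ranking and
#' module detection, and two-method crosstalk inference; writes each
#' stage's TSVs under \code{outDir} (\code{qc/}, \code{de/<contrast>/},
#' \code{enrichment/<contrast>/<direction>/}, \code{network/},
#' \code{crosstalk/}) and a JSON \code{manifest.json}. Identical config
#' and seed give a byte-identical output tree.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
    fail <- validateConfig(config)
    if (length(fail))
        stop("invalid configuration:\n  ", paste(fail, collapse = "\n  "))
    inp <- .load_inputs(config)
    out <- config$outDir
    for (d in c("qc", "network", "crosstalk"))
        dir.create(file.path(out, d), recursive = TRUE,
                   showWarnings = FALSE)
    manifest <- list(seed = config$seed,
                     alpha = config$alpha, lfcMin = config$lfcMin,
                     kModules = config$kModules,
                     mode = if (is.null(config$synthetic)) "real"
                            else "synthetic",
                     package_version =
                         as.character(utils::packageVersion("cocultalk")),
                     stages = list())

    ## qc
    fp <- fpkm(inp$experiment, inp$lengths)
    lg <- logTransform(fp)
    qc <- qcSummary(lg)
    .write_tsv(data.frame(sample = rownames(qc$correlation),
                          round(qc$correlation, 10)),
               file.path(out, "qc", "correlation.tsv"))
    .write_tsv(data.frame(sample = rownames(qc$pca_scores),
                          round(qc$pca_scores, 10)),
               file.path(out, "qc", "pca_scores.tsv"))
    jsonlite::write_json(
        list(linkage = qc$linkage,
             var_explained = round(qc$pca_var_explained, 12),
             merge_order = qc$hclust$order,
             labels = qc$hclust$labels),
        file.path(out, "qc", "clustering.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$stages$qc <- list(n_samples = ncol(lg), n_genes = nrow(lg))

    ## differential expression
    filtered <- filterLowCounts(inp$experiment)
    sf <- sizeFactorsMOR(filtered)
    disp <- estimateDispersionsMoM(filtered, sf)
    results <- list()
    for (cs in config$contrasts) {
        res <- nbWaldContrast(inp$experiment, contrastSpec(
            cs$name, cs$first, cs$second),
            dispersions = disp, sizeFactors = sf,
            alpha = config$alpha, lfcMin = config$lfcMin)
        results[[cs$name]] <- res
        d <- file.path(out, "de", cs$name)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        writeContrastResult(res, file.path(d, "results.tsv"))
        manifest$stages$de[[cs$name]] <- as.list(degSummary(res))
    }
    part <- partitionOverlap(results)
    .write_tsv(part$genes, file.path(out, "de", "partition.tsv"))
    .write_tsv(part$region_counts,
               file.path(out, "de", "partition_counts.tsv"))

    ## enrichment per contrast and direction
    universe <- resultTable(results[[1L]])$gene
    for (cn in names(results)) {
        for (dir in c("UP", "DOWN")) {
            degs <- degGenes(results[[cn]], dir)
            d <- file.path(out, "enrichment", cn, dir)
            dir.create(d, recursive = TRUE, showWarnings = FALSE)
            rows <- ora(degs, universe, inp$gsc, alpha = config$alpha)
            .write_tsv(rows, file.path(d, "ora.tsv"))
            rep <- enrichmentReport(rows, config$topMTerms)
            .write_tsv(rep$incidence, file.path(d, "incidence.tsv"))
            manifest$stages$enrichment[[paste(cn, dir, sep = ".")]] <-
                list(n_deg = length(degs),
                     n_significant = sum(rows$significant))
        }
    }

    ## network on the DEGs of the first contrast
    degAll <- degGenes(results[[1L]], c("UP", "DOWN"))
    sub <- inducedSubgraph(inp$network, degAll)
    hubs <- hubRanking(sub, config$topNHubs)
    .write_tsv(hubs, file.path(out, "network", "hubs.tsv"))
    nConn <- length(unique(unlist(networkEdges(sub)[c("from", "to")])))
    if (nConn >= config$kModules) {
        mods <- kmeansModules(sub, config$kModules, seed = config$seed)
        .write_tsv(data.frame(gene = names(mods$modules),
                              module = as.integer(mods$modules)),
                   file.path(out, "network", "modules.tsv"))
        manifest$stages$network <- list(n_nodes = length(networkNodes(sub)),
                                        n_edges = nrow(networkEdges(sub)),
                                        n_modules = mods$k)
    } else {
        manifest$stages$network <- list(n_nodes = length(networkNodes(sub)),
                                        n_edges = nrow(networkEdges(sub)),
                                        n_modules = 0L)
    }

    ## crosstalk
    pairs <- runCrosstalk(results, inp$db)
    writeCrosstalk(pairs, file.path(out, "crosstalk", "pairs.tsv"))
    manifest$stages$crosstalk <- list(n_pairs = nrow(pairs))

    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
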