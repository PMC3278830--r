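# High-level run modes mirroring the three applications of the method:
# whole-network enrichment, sub-network enrichment, and merge comparison.
# Each accepts in-memory objects or file paths and optionally writes a TSV
# plus a JSON manifest.

.loadNetwork <- function(x, weightThreshold = NULL) {
    if (is(x, "GeneNetwork")) return(x)
    readNetwork(x, weightThreshold = weightThreshold)
}

.loadAnnotations <- function(x, dag = NULL) {
    ann <- if (is(x, "AnnotationSet")) x
           else if (grepl("\\.gmt$", x, ignore.case = TRUE)) readGMT(x)
           else readAnnotationPairs(x)
    if (!is.null(dag)) {
        dm <- if (is.character(dag) && length(dag) == 1L) {
            if (grepl("\\.obo$", dag, ignore.case = TRUE)) readOboDag(dag)
            else readDagPairs(dag)
        } else dag
        ann <- annotationSet(termGenes(ann), dag = dm)
    }
    if (hasDag(ann)) ann <- propagateTruePath(ann)
    ann
}

.finishRun <- function(res, config, outputPath) {
    if (!is.null(outputPath)) {
        writeEnrichmentResults(res, outputPath)
        writeRunManifest(config, paste0(outputPath, ".manifest.json"))
    }
    res
}

#' Whole-network enrichment
#'
#' Which functions are coherent in a single network?  The network serves as
#' both universe and interesting collection, so the set-based Fisher
#' baseline is 1 for every term while the permutation p-values remain
#' informative.
#'
#' @param network a [GeneNetwork-class] or path to an edge-list/SIF file.
#' @param annotations an [AnnotationSet-class] or path to a GMT /
#'   two-column annotation file.
#' @param dag optional ontology for true-path propagation: a (child,
#'   parent) matrix or a path to a two-column TSV or OBO file.
#' @param iterations,k Monte-Carlo iterations and swap multiplier.
#' @param minUniversal,maxInteresting term filters (counts against the
#'   corresponding node sets).
#' @param weightThreshold optional minimum edge weight when reading the
#'   network from a weighted file.
#' @param seed integer run seed.
#' @param outputPath optional TSV output path; a `.manifest.json` is
#'   written beside it.
#' @return the [enrich()] results `data.frame`.
#' @export
runEnrichNetwork <- function(network, annotations, dag = NULL,
                             iterations = 100000L, k = 10,
                             minUniversal = 5L, maxInteresting = 100L,
                             weightThreshold = NULL, seed = 1L,
                             outputPath = NULL) {
    G <- .loadNetwork(network, weightThreshold)
    ann <- .loadAnnotations(annotations, dag)
    ann <- filterFunctions(ann, G, G, minUniversal, maxInteresting)
    message(numNodes(G), " nodes, ", numEdges(G), " edges; ",
            numTerms(ann), " terms after filtering; p-value resolution ",
            signif(1 / iterations, 3L))
    res <- enrich(G, G, ann, iterations = iterations, k = k, seed = seed)
    .finishRun(res, list(mode = "enrich-network",
                         iterations = iterations, k = k,
                         min_universal = minUniversal,
                         max_interesting = maxInteresting,
                         weight_threshold = weightThreshold, seed = seed),
               outputPath)
}

#' Sub-network enrichment
#'
#' Which functions are coherent in an interesting sub-network of a
#' universal network?  The interesting part may be given as an edge list
#' (a subgraph, possibly missing some universal edges among its nodes) or
#' as a node list / gene vector, in which case the subgraph of the
#' universal network induced by those nodes is used.
#'
#' @inheritParams runEnrichNetwork
#' @param interesting a [GeneNetwork-class], a path to an edge-list/SIF
#'   file, a character vector of genes, or (with
#'   `interestingType = "nodes"`) a path to a node-list file.
#' @param interestingType `"edges"` or `"nodes"`; controls how a path in
#'   `interesting` is read.
#' @return the [enrich()] results `data.frame`.
#' @export
runEnrichSubnetwork <- function(network, interesting,
                                interestingType = c("edges", "nodes"),
                                annotations, dag = NULL,
                                iterations = 100000L, k = 10,
                                minUniversal = 5L, maxInteresting = 100L,
                                weightThreshold = NULL, seed = 1L,
                                outputPath = NULL) {
    interestingType <- match.arg(interestingType)
    G <- .loadNetwork(network, weightThreshold)
    H <- if (is(interesting, "GeneNetwork")) {
        interesting
    } else if (interestingType == "nodes" ||
               (is.character(interesting) && length(interesting) > 1L)) {
        genes <- if (length(interesting) == 1L && file.exists(interesting))
            readNodeList(interesting) else as.character(interesting)
        inducedSubgraph(G, genes)
    } else {
        readNetwork(interesting)
    }
    ann <- .loadAnnotations(annotations, dag)
    ann <- filterFunctions(ann, G, H, minUniversal, maxInteresting)
    message(numNodes(G), "/", numNodes(H), " universal/interesting nodes; ",
            numTerms(ann), " terms after filtering; p-value resolution ",
            signif(1 / iterations, 3L))
    res <- enrich(G, H, ann, iterations = iterations, k = k, seed = seed)
    .finishRun(res, list(mode = "enrich-subnetwork",
                         interesting_type = interestingType,
                         iterations = iterations, k = k,
                         min_universal = minUniversal,
                         max_interesting = maxInteresting,
                         weight_threshold = weightThreshold, seed = seed),
               outputPath)
}

#' Merge comparison: does an edge set improve functional coherence?
#'
#' Runs the enrichment twice against the same universal network `G` (which
#' already contains the removable edges): once with the interesting network
#' equal to `G`, and once with the interesting network equal to `G` minus
#' the removable edges — except removable edges with independent support,
#' which are retained.  Each function is scored by
#' `s = log10(p_without / p_with)` on the combined p-values, with zeros
#' floored at `1/iterations`.
#'
#' Independent support for a removable pair means, depending on
#' `supportMode`: the pair appears in an explicit keep-list
#' (`"keep-list"`, the default), appears more than once in the raw
#' universal edge file (`"duplicates"`, requires `network` to be a path),
#' or either (`"either"`).
#'
#' @inheritParams runEnrichNetwork
#' @param removableEdges two-column matrix/data frame of gene pairs, or a
#'   path to a two-column file.
#' @param keepList optional edge pairs (matrix or path) with independent
#'   evidence, retained even when removable.
#' @param supportMode `"keep-list"`, `"duplicates"`, or `"either"`.
#' @return a `data.frame` with columns `term`, `u_f`, `c_f`, `p_with`
#'   (all edges), `p_without` (edge set removed), and `score`, sorted by
#'   decreasing score.
#' @export
runMergeCompare <- function(network, removableEdges, keepList = NULL,
                            supportMode = c("keep-list", "duplicates",
                                            "either"),
                            annotations, dag = NULL,
                            iterations = 100000L, k = 10,
                            minUniversal = 5L, maxInteresting = 100L,
                            weightThreshold = NULL, seed = 1L,
                            outputPath = NULL) {
    supportMode <- match.arg(supportMode)
    G <- .loadNetwork(network, weightThreshold)
    rem <- if (is.character(removableEdges) && length(removableEdges) == 1L)
        .readPairs(removableEdges, "removable-edge") else
        as.matrix(removableEdges)
    remKey <- .pairKey(rem)
    supported <- character()
    if (supportMode %in% c("keep-list", "either") && !is.null(keepList)) {
        kl <- if (is.character(keepList) && length(keepList) == 1L)
            .readPairs(keepList, "keep-list") else as.matrix(keepList)
        supported <- c(supported, .pairKey(kl))
    }
    if (supportMode %in% c("duplicates", "either")) {
        if (!is.character(network) || length(network) != 1L)
            stop("supportMode '", supportMode,
                 "' needs the universal network as a file path")
        raw <- .readPairs(network, "network")
        rawKey <- .pairKey(raw)
        supported <- c(supported, unique(rawKey[duplicated(rawKey)]))
    }
    dropKey <- setdiff(unique(remKey), supported)
    ge <- edgeMatrix(G)
    keepEdge <- !(.pairKey(ge) %in% dropKey)
    message("removing ", sum(!keepEdge), " of ", nrow(ge),
            " universal edges (", length(unique(remKey)),
            " removable pairs, ",
            sum(unique(remKey) %in% supported),
            " independently supported)")
    H2 <- new("GeneNetwork", nodes = nodeIds(G),
              edges = ge[keepEdge, , drop = FALSE])
    ann <- .loadAnnotations(annotations, dag)
    ann <- filterFunctions(ann, G, G, minUniversal, maxInteresting)
    withRes <- enrich(G, G, ann, iterations = iterations, k = k,
                      seed = seed)
    withoutRes <- enrich(G, H2, ann, iterations = iterations, k = k,
                         seed = seed)
    m <- match(withRes$term, withoutRes$term)
    res <- data.frame(
        term = withRes$term,
        u_f = withRes$u_f,
        c_f = withRes$c_f,
        p_with = withRes$p_combined,
        p_without = withoutRes$p_combined[m],
        stringsAsFactors = FALSE)
    res$score <- mergeScore(res$p_without, res$p_with,
                            floor = 1 / iterations)
    res <- res[order(-res$score, res$term), , drop = FALSE]
    rownames(res) <- NULL
    .finishRun(res, list(mode = "merge-compare",
                         support_mode = supportMode,
                         iterations = iterations, k = k,
                         min_universal = minUniversal,
                         max_interesting = maxInteresting, seed = seed),
               outputPath)
}

# canonical unordered-pair keys for edge matrices
.pairKey <- function(m) {
    if (!NROW(m)) return(character())
    mode(m) <- "character"
    paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]), sep = "\r")
}
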