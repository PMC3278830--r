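# Deterministic synthetic inputs.  Every statistic in the package is
# testable on these generators without downloading an interactome; the
# preferential-attachment family exercises the heavy-tailed degree
# distributions the swap null is designed to preserve.

#' Generate a synthetic gene network
#'
#' @param generator one of `"complete"`, `"path"`, `"disjoint-cliques"`
#'   (`param` = clique size, must divide `n`), `"erdos-renyi"`
#'   (`param` = edge probability), `"preferential-attachment"`
#'   (`param` = edges added per node).
#' @param n number of nodes; node identifiers are `g001`, `g002`, ...
#' @param param generator-specific parameter (see `generator`).
#' @param seed integer seed; the same spec and seed always produce the
#'   same network.
#' @return a [GeneNetwork-class].
#' @examples
#' componentSizeSeq(fixtureNetwork("disjoint-cliques", 12, 4))  # 4 4 4
#' @export
fixtureNetwork <- function(generator = c("complete", "path",
                                         "disjoint-cliques", "erdos-renyi",
                                         "preferential-attachment"),
                           n, param = NULL, seed = 1L) {
    generator <- match.arg(generator)
    stopifnot(n >= 1L)
    g <- .withSeed(seed, switch(generator,
        "complete" = igraph::make_full_graph(n),
        "path" = igraph::make_ring(n, circular = FALSE),
        "disjoint-cliques" = {
            stopifnot(!is.null(param), param >= 1L)
            if (n %% param != 0L)
                stop("clique size ", param, " does not divide n = ", n)
            do.call(igraph::disjoint_union,
                    replicate(n %/% param, igraph::make_full_graph(param),
                              simplify = FALSE))
        },
        "erdos-renyi" = {
            stopifnot(!is.null(param), param >= 0, param <= 1)
            igraph::sample_gnp(n, param, directed = FALSE)
        },
        "preferential-attachment" = {
            stopifnot(!is.null(param), param >= 1L)
            igraph::sample_pa(n, m = param, directed = FALSE)
        }))
    ids <- sprintf("g%03d", seq_len(n))
    e <- igraph::as_edgelist(g, names = FALSE)
    geneNetwork(nodes = ids,
                edges = cbind(ids[e[, 1L]], ids[e[, 2L]]))
}

# random connected induced subset of `size` genes (grown from a random
# start inside a sufficiently large component)
.plantConnected <- function(net, size, adj) {
    comps <- igraph::components(.asIgraph(net))
    ok <- which(comps$csize >= size)
    if (!length(ok))
        stop("infeasible planted term: no component with at least ",
             size, " nodes")
    comp <- if (length(ok) == 1L) ok else sample(ok, 1L)
    pool <- nodeIds(net)[comps$membership == comp]
    cur <- sample(pool, 1L)
    while (length(cur) < size) {
        frontier <- setdiff(unique(unlist(adj[cur], use.names = FALSE)), cur)
        nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
        cur <- c(cur, nxt)
    }
    cur
}

# random independent set of `size` genes: the induced subgraph is all
# singletons, i.e. `size` components, comfortably >= ceiling(size/2)
.plantFragmented <- function(net, size, adj) {
    chosen <- character()
    for (v in sample(nodeIds(net))) {
        if (!any(adj[[v]] %in% chosen)) {
            chosen <- c(chosen, v)
            if (length(chosen) == size) break
        }
    }
    if (length(chosen) < size)
        stop("infeasible planted term: no independent set of size ", size)
    chosen
}

#' Generate a network with planted annotated terms
#'
#' Plants terms whose induced subgraphs are connected (a single component,
#' by construction) or fragmented (an independent set, hence at least
#' `ceiling(size/2)` components — asserted after construction).  Optional
#' random background terms draw genes uniformly.
#'
#' @inheritParams fixtureNetwork
#' @param plantedTerms list of `list(id =, size =, mode =)` entries with
#'   `mode` either `"connected"` or `"fragmented"`.
#' @param nRandomTerms number of additional uniform background terms.
#' @param randomTermSize length-2 range of background term sizes.
#' @return `list(network = GeneNetwork, annotations = AnnotationSet)`.
#' @export
generateFixture <- function(generator = "erdos-renyi", n = 50L,
                            param = 0.08, plantedTerms = list(),
                            nRandomTerms = 0L, randomTermSize = c(5L, 15L),
                            seed = 1L) {
    net <- fixtureNetwork(generator, n, param, seed = seed)
    adj <- .adjacencyList(net)
    terms <- .withSeed(seed + 1L, {
        out <- list()
        for (pt in plantedTerms) {
            stopifnot(!is.null(pt$id), !is.null(pt$size))
            mode <- match.arg(pt$mode, c("connected", "fragmented"))
            genes <- if (mode == "connected")
                .plantConnected(net, pt$size, adj)
            else .plantFragmented(net, pt$size, adj)
            cs <- componentSizeSeq(inducedSubgraph(net, genes))
            if (mode == "connected" && length(cs) != 1L)
                stop("planted connected term is not connected")
            if (mode == "fragmented" && length(cs) < ceiling(pt$size / 2))
                stop("planted fragmented term has too few components")
            out[[pt$id]] <- genes
        }
        if (nRandomTerms > 0L) {
            for (i in seq_len(nRandomTerms)) {
                sz <- sample(randomTermSize[1L]:randomTermSize[2L], 1L)
                sz <- min(sz, numNodes(net))
                out[[sprintf("rand%03d", i)]] <- sample(nodeIds(net), sz)
            }
        }
        out
    })
    list(network = net, annotations = annotationSet(terms))
}

.adjacencyList <- function(net) {
    adj <- setNames(vector("list", numNodes(net)), nodeIds(net))
    e <- edgeMatrix(net)
    if (nrow(e)) {
        half <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
        adj[names(half)] <- half
    }
    adj
}

#' Write a fixture to disk in the package's file formats
#'
#' Produces `network.tsv` (edge list), `nodes.txt` (full node list,
#' including isolated nodes) and `annotations.gmt` under `dir`, suitable
#' for end-to-end runs through the file-based interface.
#'
#' @param fixture a `list(network =, annotations =)` as returned by
#'   [generateFixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
writeFixture <- function(fixture, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    np <- file.path(dir, "network.tsv")
    suppressWarnings(writeNetwork(fixture$network, np))
    lp <- file.path(dir, "nodes.txt")
    writeLines(nodeIds(fixture$network), lp)
    ap <- file.path(dir, "annotations.gmt")
    writeGMT(fixture$annotations, ap)
    c(network = np, nodes = lp, annotations = ap)
}
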