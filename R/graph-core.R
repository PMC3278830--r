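#' Construct a simple undirected gene network
#'
#' Normalizes arbitrary edge input into the canonical simple undirected form:
#' edge direction and repetition are collapsed to a single unordered pair,
#' and self-loops are dropped.  The counts of dropped self-loops and
#' collapsed duplicates are reported via [message()] when `verbose = TRUE`.
#'
#' @param nodes character vector of gene identifiers (isolated nodes are
#'   kept); endpoints appearing in `edges` are added automatically.
#' @param edges a two-column character matrix or data frame of endpoint
#'   pairs, or `NULL` for an edgeless network.
#' @param verbose report normalization counts (dropped self-loops and
#'   duplicate edges).
#' @return a [GeneNetwork-class] object.
#' @examples
#' net <- geneNetwork(edges = cbind(c("a", "b", "a"), c("b", "a", "a")))
#' numEdges(net)  # the three raw records collapse to the single edge {a,b}
#' @export
geneNetwork <- function(nodes = character(), edges = NULL, verbose = FALSE) {
    nodes <- unique(as.character(nodes))
    if (is.null(edges) || NROW(edges) == 0L) {
        em <- matrix(character(), ncol = 2L)
    } else {
        edges <- as.matrix(edges)
        if (ncol(edges) != 2L)
            stop("edges must have exactly two columns")
        mode(edges) <- "character"
        loop <- edges[, 1L] == edges[, 2L]
        if (any(loop) && verbose)
            message("dropped ", sum(loop), " self-loop(s)")
        edges <- edges[!loop, , drop = FALSE]
        em <- cbind(pmin(edges[, 1L], edges[, 2L]),
                    pmax(edges[, 1L], edges[, 2L]))
        dup <- duplicated(paste(em[, 1L], em[, 2L], sep = "\r"))
        if (any(dup) && verbose)
            message("collapsed ", sum(dup), " repeated edge record(s)")
        em <- em[!dup, , drop = FALSE]
        nodes <- unique(c(nodes, c(em)))
    }
    new("GeneNetwork", nodes = nodes, edges = em)
}

#' @describeIn geneNetwork gene identifiers of the network's nodes.
#' @param x,object a `GeneNetwork`.
#' @export
nodeIds <- function(x) x@nodes

#' @describeIn geneNetwork canonical two-column character edge matrix.
#' @export
edgeMatrix <- function(x) x@edges

#' @describeIn geneNetwork number of nodes.
#' @export
numNodes <- function(x) length(x@nodes)

#' @describeIn geneNetwork number of edges.
#' @export
numEdges <- function(x) nrow(x@edges)

#' @describeIn geneNetwork named integer vector of node degrees.
#' @export
degreeSequence <- function(x) {
    d <- setNames(integer(length(x@nodes)), x@nodes)
    if (nrow(x@edges)) {
        tab <- table(c(x@edges))
        d[names(tab)] <- as.integer(tab)
    }
    d
}

setMethod("show", "GeneNetwork", function(object) {
    cat("GeneNetwork with", numNodes(object), "nodes and",
        numEdges(object), "edges\n")
    if (numNodes(object)) {
        shown <- head(nodeIds(object), 6L)
        cat("  nodes:", paste(shown, collapse = ", "),
            if (numNodes(object) > 6L) "..." else "", "\n")
    }
})

# igraph view of a GeneNetwork (undirected, keeps isolated nodes)
.asIgraph <- function(net) {
    igraph::graph_from_data_frame(
        d = as.data.frame(edgeMatrix(net), stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = nodeIds(net),
                              stringsAsFactors = FALSE))
}

#' Subgraph induced by a set of genes
#'
#' Restricts a network to the given genes: the result contains the nodes in
#' the intersection of `genes` with the network's node set, and every edge of
#' the network with both endpoints in that intersection.  Genes absent from
#' the network are silently ignored.
#'
#' @param net a [GeneNetwork-class].
#' @param genes character vector of gene identifiers.
#' @return a [GeneNetwork-class] on `intersect(nodeIds(net), genes)`.
#' @examples
#' tri <- geneNetwork(edges = cbind(c("a", "a", "b"), c("b", "c", "c")))
#' inducedSubgraph(tri, c("a", "b"))  # one edge {a,b}
#' @export
inducedSubgraph <- function(net, genes) {
    keep <- intersect(nodeIds(net), as.character(genes))
    e <- edgeMatrix(net)
    if (nrow(e))
        e <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
    new("GeneNetwork", nodes = keep, edges = e)
}

#' Component-size sequence cs()
#'
#' The connectivity statistic: the sizes of the connected components of a
#' network, sorted in non-increasing order.  Isolated nodes contribute
#' size-1 entries; the empty network yields the empty sequence.
#'
#' @param net a [GeneNetwork-class].
#' @return integer vector, non-increasing, summing to `numNodes(net)`.
#' @examples
#' p <- geneNetwork(nodes = "d", edges = cbind(c("a", "b"), c("b", "c")))
#' componentSizeSeq(p)  # c(3, 1)
#' @export
componentSizeSeq <- function(net) {
    if (numNodes(net) == 0L) return(integer())
    if (numEdges(net) == 0L) return(rep.int(1L, numNodes(net)))
    comp <- igraph::components(.asIgraph(net))
    sort(as.integer(comp$csize), decreasing = TRUE)
}

#' Compare two component-size sequences
#'
#' Total order on component-size sequences: the shorter sequence is padded
#' with zeros to the length of the longer, and the order is decided at the
#' first index where the entries differ (the sequence holding the smaller
#' value is the smaller).  Sequences that agree entrywise after padding are
#' equal; two empty sequences are equal.
#'
#' @param a,b non-increasing integer vectors of positive component sizes.
#' @return one of `"less"`, `"equal"`, `"greater"` (ordering of `a`
#'   relative to `b`).
#' @examples
#' compareCS(c(2, 2), c(3, 1))  # "less"
#' compareCS(c(3, 1), 3)        # "greater": 3 pads to c(3, 0)
#' @export
compareCS <- function(a, b) {
    c("less", "equal", "greater")[.csOrder(a, b) + 2L]
}

# integer three-way comparison (-1, 0, 1) shared with the p-value loops
.csOrder <- function(a, b) {
    a <- as.integer(a)
    b <- as.integer(b)
    if (length(a) && (anyNA(a) || any(a < 1L) || is.unsorted(rev(a))))
        stop("'a' is not a valid component-size sequence")
    if (length(b) && (anyNA(b) || any(b < 1L) || is.unsorted(rev(b))))
        stop("'b' is not a valid component-size sequence")
    n <- max(length(a), length(b))
    if (n == 0L) return(0L)
    a <- c(a, integer(n - length(a)))
    b <- c(b, integer(n - length(b)))
    d <- which(a != b)
    if (!length(d)) return(0L)
    if (a[d[1L]] < b[d[1L]]) -1L else 1L
}
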