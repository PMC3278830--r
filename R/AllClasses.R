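#' GeneNetwork: a simple undirected graph over gene identifiers
#'
#' Gene identifiers are case-sensitive opaque strings.  The edge matrix is
#' stored in canonical form: two character columns, each row an unordered pair
#' written with the lexicographically smaller identifier first, no self-loops,
#' no duplicate rows, and both endpoints present in the node set.  Nodes may
#' be isolated.
#'
#' @slot nodes character vector of unique gene identifiers.
#' @slot edges two-column character matrix of canonical undirected edges.
#' @seealso [geneNetwork()] for construction with normalization.
#' @exportClass GeneNetwork
setClass("GeneNetwork",
    representation(nodes = "character", edges = "matrix"))

setValidity("GeneNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!is.character(e) || ncol(e) != 2L)
        return("edges must be a two-column character matrix")
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicated node identifiers")
    if (nrow(e)) {
        if (any(e[, 1L] == e[, 2L]))
            msg <- c(msg, "self-loops are not allowed")
        if (any(e[, 1L] > e[, 2L]))
            msg <- c(msg, "edges must be stored in canonical order")
        if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
            msg <- c(msg, "duplicate edges are not allowed")
        if (!all(c(e) %in% object@nodes))
            msg <- c(msg, "all edge endpoints must be nodes")
    }
    if (length(msg)) msg else TRUE
})

#' AnnotationSet: gene-to-function annotations with an optional ontology DAG
#'
#' Maps function (term) identifiers to the sets of genes they annotate.  The
#' optional DAG is a set of child-to-parent term pairs and must be acyclic;
#' it drives true-path-rule propagation (see [propagateTruePath()]).  Gene
#' sets are non-empty by construction (empty sets are dropped at load time,
#' with a message).
#'
#' @slot terms named list mapping term identifiers to character vectors of
#'   gene identifiers.
#' @slot dag two-column character matrix of (child, parent) term pairs;
#'   zero rows when no ontology is attached.
#' @seealso [annotationSet()], [propagateTruePath()], [filterFunctions()].
#' @exportClass AnnotationSet
setClass("AnnotationSet",
    representation(terms = "list", dag = "matrix"))

setValidity("AnnotationSet", function(object) {
    msg <- character()
    tm <- object@terms
    if (length(tm)) {
        if (is.null(names(tm)) || anyDuplicated(names(tm)) ||
            any(!nzchar(names(tm))))
            msg <- c(msg, "terms must be uniquely named")
        if (!all(vapply(tm, is.character, logical(1L))))
            msg <- c(msg, "each term must map to a character vector of genes")
        if (any(lengths(tm) == 0L))
            msg <- c(msg, "term gene sets must be non-empty")
    }
    d <- object@dag
    if (!is.character(d) || ncol(d) != 2L)
        return("dag must be a two-column character matrix")
    if (nrow(d)) {
        cyc <- .findDagCycle(d)
        if (!is.null(cyc))
            msg <- c(msg, paste0("dag contains a cycle: ",
                                 paste(cyc, collapse = " -> ")))
    }
    if (length(msg)) msg else TRUE
})

# Kahn's algorithm on child->parent edges; returns NULL when acyclic, else a
# closed walk through the cyclic part, e.g. c("a", "b", "a").
.findDagCycle <- function(dag) {
    terms <- unique(c(dag))
    idx <- setNames(seq_along(terms), terms)
    from <- idx[dag[, 1L]]
    to <- idx[dag[, 2L]]
    indeg <- tabulate(to, length(terms))
    queue <- which(indeg == 0L)
    nseen <- 0L
    while (length(queue)) {
        v <- queue[[1L]]
        queue <- queue[-1L]
        nseen <- nseen + 1L
        for (w in to[from == v]) {
            indeg[w] <- indeg[w] - 1L
            if (indeg[w] == 0L) queue <- c(queue, w)
        }
    }
    if (nseen == length(terms)) return(NULL)
    # every unprocessed node keeps an unprocessed predecessor, so walking
    # backwards through the residual part must close a cycle
    residual <- which(indeg > 0L)
    v <- residual[[1L]]
    path <- v
    repeat {
        prv <- from[to == v & from %in% residual][[1L]]
        if (prv %in% path) {
            cyc <- rev(c(path[which(path == prv):length(path)], prv))
            return(terms[cyc])
        }
        path <- c(path, prv)
        v <- prv
    }
}
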