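# Independent oracles and small builders shared across tests.  The oracle
# works directly on igraph and carries its own sequence comparison, so it
# shares no code with the package's Monte-Carlo engines.

# exact function-randomization p-value by enumerating every draw of u_f
# genes from the universal node set
exactFunctionPValue <- function(G, H, fGenes) {
    U <- nodeIds(G)
    uf <- sum(unique(as.character(fGenes)) %in% U)
    ig <- igraph::graph_from_data_frame(
        as.data.frame(edgeMatrix(H), stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = nodeIds(H), stringsAsFactors = FALSE))
    csOf <- function(genes) {
        keep <- intersect(nodeIds(H), genes)
        if (!length(keep)) return(integer())
        sub <- igraph::induced_subgraph(ig, keep)
        sort(as.integer(igraph::components(sub)$csize), decreasing = TRUE)
    }
    csGeq <- function(a, b) {
        n <- max(length(a), length(b))
        if (n == 0L) return(TRUE)
        a <- c(a, integer(n - length(a)))
        b <- c(b, integer(n - length(b)))
        d <- which(a != b)
        !length(d) || a[d[1L]] > b[d[1L]]
    }
    obs <- csOf(fGenes)
    draws <- utils::combn(U, uf, simplify = FALSE)
    mean(vapply(draws, function(X) csGeq(csOf(X), obs), logical(1L)))
}

# three-sigma binomial tolerance around an exact probability
binomTol <- function(p, n) 3 * sqrt(p * (1 - p) / n)

# random valid component-size sequence (possibly empty)
randomCS <- function(maxLen = 5L, maxSize = 6L) {
    len <- sample(0:maxLen, 1L)
    if (len == 0L) return(integer())
    sort(sample(seq_len(maxSize), len, replace = TRUE), decreasing = TRUE)
}

# complete graph on letters a, b, c, ...
letterClique <- function(n) {
    ids <- letters[seq_len(n)]
    e <- t(utils::combn(ids, 2L))
    geneNetwork(nodes = ids, edges = e)
}
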