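#' Hypergeometric upper-tail p-value (one-sided Fisher's exact test)
#'
#' Probability that a uniform draw of `uf` genes from a universe of `u`
#' genes contains at least `cf` of the `c` interesting genes — the
#' set-based enrichment baseline that the network-based test generalizes.
#' In whole-network mode (`u == c`) this is 1 for every term.
#'
#' @param u universe size.
#' @param c interesting-set size (`c <= u`).
#' @param uf number of universe genes annotated with the function
#'   (`uf <= u`).
#' @param cf number of interesting genes annotated with the function
#'   (`cf <= min(c, uf)`).
#' @return the tail probability.
#' @examples
#' fisherTailPValue(10, 5, 4, 3)  # 55/210
#' @export
fisherTailPValue <- function(u, c, uf, cf) {
    if (c > u || uf > u || cf > min(c, uf) || any(c(u, c, uf, cf) < 0))
        stop("invalid counts: need cf <= min(c, uf), uf <= u, c <= u")
    phyper(cf - 1, c, u - c, uf, lower.tail = FALSE)
}

# --- index plumbing between GeneNetwork and the C++ engines ----------------

# 0-based edge index matrix of `net` in the coordinate system of `universe`
.edgeIndex <- function(net, universe) {
    e <- edgeMatrix(net)
    if (!nrow(e)) return(matrix(integer(), ncol = 2L))
    cbind(match(e[, 1L], universe), match(e[, 2L], universe)) - 1L
}

#' Function-randomization p-value
#'
#' Empirical p-value for the connectivity of a function's subgraph under
#' uniform resampling of gene sets.  Sets `X` of size `u_f = |fGenes
#' intersect nodes(G)|` are drawn without replacement from the universal
#' node set; the p-value is the fraction of draws for which
#' `cs(H_X) >= cs(H_f)`, where `H_X` is the subgraph of the interesting
#' network `H` induced by `X` and `H_f` the one induced by `fGenes`.  With
#' all edges removed from `G` and `H` this converges to
#' [fisherTailPValue()].
#'
#' @param G universal [GeneNetwork-class].
#' @param H interesting [GeneNetwork-class]; `nodeIds(H)` must be a subset
#'   of `nodeIds(G)`.
#' @param fGenes genes annotated with the function (identifiers outside `G`
#'   are ignored for the draw size).
#' @param iterations number of random draws.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return list with elements `p`, `count`, `iterations`, and `csObserved`
#'   (the observed component-size sequence of `H_f`).
#' @export
functionRandomizationPValue <- function(G, H, fGenes, iterations = 10000L,
                                        seed = NULL) {
    stopifnot(iterations >= 1L)
    U <- nodeIds(G)
    if (!all(nodeIds(H) %in% U))
        stop("interesting network nodes must be a subset of the universal network")
    uf <- sum(unique(as.character(fGenes)) %in% U)
    if (uf == 0L)
        stop("no annotated gene is present in the universal network")
    Hf <- inducedSubgraph(H, fGenes)
    obs <- componentSizeSeq(Hf)
    hMember <- U %in% nodeIds(H)
    hEdges <- .edgeIndex(H, U)
    count <- .withSeed(seed,
        cpp_function_null_count(length(U), hEdges, hMember, uf,
                                as.integer(obs), as.integer(iterations)))
    list(p = count / iterations, count = count,
         iterations = as.integer(iterations), csObserved = obs)
}

#' Degree-preserving network randomization
#'
#' Rewires a network by `floor(k * numEdges)` double-edge-swap attempts.
#' Each attempt picks two distinct edges and one of the two possible
#' endpoint exchanges uniformly at random; attempts that would create a
#' self-loop or a duplicate edge are rejected (but still consumed), so the
#' result is simple and has exactly the degree sequence of the input.
#' Networks with fewer than two edges are returned unchanged.
#'
#' @param net a [GeneNetwork-class].
#' @param k swap-attempt multiplier (default 10).
#' @param seed optional integer seed.
#' @return a rewired [GeneNetwork-class] on the same node set.
#' @export
randomizeNetwork <- function(net, k = 10, seed = NULL) {
    stopifnot(k >= 0)
    if (numEdges(net) < 2L || floor(k * numEdges(net)) < 1)
        return(net)
    U <- nodeIds(net)
    e <- .withSeed(seed,
        cpp_randomize_edges(.edgeIndex(net, U), length(U), as.double(k)))
    geneNetwork(nodes = U, edges = cbind(U[e[, 1L] + 1L], U[e[, 2L] + 1L]))
}

#' Structure-randomization p-value
#'
#' Empirical p-value for the connectivity of a function's subgraph under
#' degree-preserving rewiring of the universal network.  At each iteration a
#' randomized network `G' = randomizeNetwork(G, k)` is generated and the
#' subgraph induced in `G'` by `intersect(C, fGenes)` is compared against
#' the observed `H_f`; the p-value is the fraction of iterations with
#' `cs(H'_f) >= cs(H_f)`.  The observed `H_f` is taken from the interesting
#' network `H` (which may lack some universal edges among `C`); by default
#' `H` is the subgraph of `G` induced by `C`.
#'
#' @param G universal [GeneNetwork-class].
#' @param C interesting gene collection (defaults to `nodeIds(H)` when `H`
#'   is given).
#' @param fGenes genes annotated with the function.
#' @param iterations number of randomized networks.
#' @param k swap-attempt multiplier passed to the rewiring.
#' @param seed optional integer seed.
#' @param H optional interesting [GeneNetwork-class] supplying the observed
#'   subgraph; when `NULL`, the subgraph of `G` induced by `C` is used.
#' @return list with elements `p`, `count`, `iterations`, `csObserved`.
#' @export
structureRandomizationPValue <- function(G, C = NULL, fGenes,
                                         iterations = 1000L, k = 10,
                                         seed = NULL, H = NULL) {
    stopifnot(iterations >= 1L, k >= 0)
    U <- nodeIds(G)
    if (is.null(H)) {
        if (is.null(C))
            stop("either C or H must be given")
        C <- intersect(U, as.character(C))
        H <- inducedSubgraph(G, C)
    } else {
        if (!all(nodeIds(H) %in% U))
            stop("interesting network nodes must be a subset of the universal network")
        C <- nodeIds(H)
    }
    obs <- componentSizeSeq(inducedSubgraph(H, fGenes))
    members <- match(intersect(intersect(C, as.character(fGenes)), U), U) - 1L
    counts <- .withSeed(seed,
        cpp_structure_null_counts(.edgeIndex(G, U), length(U), as.double(k),
                                  as.integer(iterations),
                                  list(as.integer(members)),
                                  list(as.integer(obs))))
    list(p = counts[[1L]] / iterations, count = counts[[1L]],
         iterations = as.integer(iterations), csObserved = obs)
}

#' Combine the two permutation p-values
#'
#' A function is called coherent only when both nulls agree, so the
#' combined p-value is the maximum of the two.
#'
#' @param pFunction,pStructure numeric vectors in `[0, 1]`.
#' @return elementwise maximum.
#' @export
combinePValues <- function(pFunction, pStructure) {
    stopifnot(all(pFunction >= 0 & pFunction <= 1),
              all(pStructure >= 0 & pStructure <= 1))
    pmax(pFunction, pStructure)
}

#' Merge improvement score
#'
#' Scores how much an added edge set improved a function's network
#' coherence: `s = log10(pWithout / pWith)`, where `pWithout` is the
#' enrichment p-value with the edge set removed and `pWith` the p-value
#' with all edges present.  Zero p-values are replaced by `floor`
#' (typically `1/iterations`, the resolution of the empirical null) before
#' taking the ratio; this is the only place flooring is applied.
#'
#' @param pWithout,pWith numeric vectors of p-values.
#' @param floor positive replacement for exact zeros.
#' @return `log10(pWithout / pWith)`; positive values mean the added edges
#'   improved coherence.
#' @examples
#' mergeScore(0.1329, 0.0003)  # 2.6464
#' @export
mergeScore <- function(pWithout, pWith, floor = 1e-5) {
    stopifnot(floor > 0)
    pWithout <- ifelse(pWithout <= 0, floor, pWithout)
    pWith <- ifelse(pWith <= 0, floor, pWith)
    log10(pWithout / pWith)
}

#' Network-based enrichment of every annotated function
#'
#' Runs the full analysis: for each term of a (pre-filtered) annotation
#' set, computes the observed component-size sequence of `H_f`, the
#' hypergeometric baseline, the function-randomization and
#' structure-randomization p-values, their combined maximum, and
#' Benjamini-Hochberg adjusted values (reported, never used for
#' filtering).
#'
#' Determinism: each term's function-randomization stream is seeded from
#' `(seed, term)`, so per-term p-values do not depend on term order; the
#' structure null draws one shared sequence of randomized networks for the
#' whole run, reused across terms.
#'
#' @param G universal [GeneNetwork-class].
#' @param H interesting [GeneNetwork-class]; must be a subgraph of `G`
#'   (nodes and edges).  Pass `G` itself for whole-network mode.
#' @param ann an [AnnotationSet-class], typically already passed through
#'   [filterFunctions()].
#' @param iterations Monte-Carlo iterations for both nulls.
#' @param k swap-attempt multiplier for the structure null.
#' @param seed integer run seed.
#' @return a `data.frame` with one row per term, columns `term`, `u_f`,
#'   `c_f`, `cs` (comma-joined component sizes), `fisher_p`, `p_function`,
#'   `p_structure`, `p_combined`, `bh_adjusted`, sorted by `p_combined`,
#'   then `u_f`, then `term`.  A combined p-value of exactly 0 means
#'   "smaller than 1/iterations".
#' @export
enrich <- function(G, H = G, ann, iterations = 1000L, k = 10, seed = 1L) {
    stopifnot(iterations >= 1L, k >= 0)
    U <- nodeIds(G)
    missNodes <- setdiff(nodeIds(H), U)
    if (length(missNodes))
        stop("interesting network nodes absent from the universal network: ",
             paste(head(missNodes, 5L), collapse = ", "))
    he <- edgeMatrix(H)
    if (nrow(he)) {
        gk <- paste(edgeMatrix(G)[, 1L], edgeMatrix(G)[, 2L], sep = "\r")
        hk <- paste(he[, 1L], he[, 2L], sep = "\r")
        bad <- which(!(hk %in% gk))
        if (length(bad))
            stop("interesting network edges absent from the universal network: ",
                 paste(paste(he[head(bad, 5L), 1L], he[head(bad, 5L), 2L],
                             sep = "--"), collapse = ", "))
    }
    terms <- termGenes(ann)
    if (!length(terms))
        return(.emptyEnrichment())
    Cnodes <- nodeIds(H)
    u <- length(U)
    cc <- length(Cnodes)
    ids <- names(terms)
    hMember <- U %in% Cnodes
    hEdges <- .edgeIndex(H, U)
    n_uf <- integer(length(terms))
    n_cf <- integer(length(terms))
    obs_list <- vector("list", length(terms))
    members <- vector("list", length(terms))
    p_fun <- numeric(length(terms))
    for (i in seq_along(terms)) {
        g <- unique(as.character(terms[[i]]))
        n_uf[i] <- sum(g %in% U)
        n_cf[i] <- sum(g %in% Cnodes)
        obs <- componentSizeSeq(inducedSubgraph(H, g))
        obs_list[[i]] <- as.integer(obs)
        members[[i]] <- as.integer(match(intersect(g, Cnodes), U) - 1L)
        if (n_uf[i] == 0L) {
            p_fun[i] <- 1
            next
        }
        count <- .withSeed(.substreamSeed(seed, ids[i]),
            cpp_function_null_count(u, hEdges, hMember, n_uf[i],
                                    obs_list[[i]], as.integer(iterations)))
        p_fun[i] <- count / iterations
    }
    sCounts <- .withSeed(.substreamSeed(seed, ".structure-pool"),
        cpp_structure_null_counts(.edgeIndex(G, U), u, as.double(k),
                                  as.integer(iterations), members, obs_list))
    p_str <- sCounts / iterations
    fisher <- vapply(seq_along(terms), function(i)
        fisherTailPValue(u, cc, n_uf[i], n_cf[i]), numeric(1L))
    p_comb <- combinePValues(p_fun, p_str)
    res <- data.frame(
        term = ids,
        u_f = n_uf,
        c_f = n_cf,
        cs = vapply(obs_list, paste, character(1L), collapse = ","),
        fisher_p = fisher,
        p_function = p_fun,
        p_structure = p_str,
        p_combined = p_comb,
        bh_adjusted = p.adjust(p_comb, method = "BH"),
        stringsAsFactors = FALSE)
    res <- res[order(res$p_combined, res$u_f, res$term), , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "iterations") <- as.integer(iterations)
    attr(res, "k") <- k
    attr(res, "seed") <- as.integer(seed)
    res
}

.emptyEnrichment <- function() {
    data.frame(term = character(), u_f = integer(), c_f = integer(),
               cs = character(), fisher_p = numeric(),
               p_function = numeric(), p_structure = numeric(),
               p_combined = numeric(), bh_adjusted = numeric(),
               stringsAsFactors = FALSE)
}
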