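test_that("hypergeometric tail matches exhaustive enumeration", {
    # all C(10,4) = 210 draws; 55 contain >= 3 of the 5 interesting genes
    expect_equal(fisherTailPValue(10, 5, 4, 3), 55 / 210)
    expect_equal(fisherTailPValue(10, 5, 4, 0), 1)
    expect_equal(fisherTailPValue(12, 12, 7, 7), 1)  # whole-network mode
    expect_error(fisherTailPValue(10, 11, 4, 3), "invalid counts")
    expect_error(fisherTailPValue(10, 5, 4, 5), "invalid counts")
})

test_that("function randomization reproduces the enumerable null", {
    G <- letterClique(6L)
    H <- inducedSubgraph(G, c("a", "b", "c", "d"))
    f <- c("a", "b")
    exact <- exactFunctionPValue(G, H, f)   # C(4,2)/C(6,2) = 0.4
    expect_equal(exact, 0.4)
    r <- functionRandomizationPValue(G, H, f, iterations = 10000L,
                                     seed = 99L)
    expect_equal(r$csObserved, 2L)
    expect_lt(abs(r$p - exact), binomTol(exact, 10000L))
})

test_that("an empty observed subgraph gives p = 1", {
    G <- letterClique(6L)
    H <- inducedSubgraph(G, c("a", "b"))
    r <- functionRandomizationPValue(G, H, c("e", "f"), iterations = 500L,
                                     seed = 1L)
    expect_equal(r$csObserved, integer())
    expect_equal(r$p, 1)
    expect_error(functionRandomizationPValue(G, H, "zz", 10L),
                 "no annotated gene")
})

test_that("with all edges removed the test collapses to Fisher's", {
    ids <- paste0("u", 1:10)
    G <- geneNetwork(nodes = ids)
    H <- geneNetwork(nodes = ids[1:5])
    f <- ids[c(1, 2, 3, 7)]     # u_f = 4, c_f = 3
    r <- functionRandomizationPValue(G, H, f, iterations = 50000L,
                                     seed = 5L)
    analytic <- fisherTailPValue(10, 5, 4, 3)
    expect_lt(abs(r$p - analytic), binomTol(analytic, 50000L))
})

test_that("degree-preserving rewiring keeps every swap-null invariant", {
    fams <- list(fixtureNetwork("erdos-renyi", 25L, 0.15, seed = 2L),
                 fixtureNetwork("preferential-attachment", 25L, 2L,
                                seed = 2L))
    for (net in fams) {
        expect_identical(randomizeNetwork(net, k = 0), net)
        for (s in 1:10) {
            rn <- randomizeNetwork(net, k = 10, seed = s)
            expect_identical(degreeSequence(rn), degreeSequence(net))
            expect_true(validObject(rn))   # simple, no self-loops
            expect_equal(numEdges(rn), numEdges(net))
        }
    }
})

test_that("a swap on two disjoint edges yields one of the two rewirings", {
    net <- geneNetwork(edges = rbind(c("a", "b"), c("c", "d")))
    seen <- character()
    for (s in 1:40) {
        rn <- randomizeNetwork(net, k = 5, seed = s)
        expect_identical(degreeSequence(rn), degreeSequence(net))
        key <- paste(sort(NetFEA:::.pairKey(edgeMatrix(rn))),
                     collapse = "|")
        seen <- c(seen, key)
    }
    allowed <- c("a\rb|c\rd", "a\rc|b\rd", "a\rd|b\rc")
    expect_true(all(seen %in% allowed))
    expect_gt(length(unique(seen)), 1L)   # swaps do happen
})

test_that("structure randomization honours its degenerate contracts", {
    # a single edge cannot be rewired, so the observed cs always recurs
    one <- geneNetwork(edges = cbind("a", "b"))
    r1 <- structureRandomizationPValue(one, C = c("a", "b"),
                                       fGenes = c("a", "b"),
                                       iterations = 200L, seed = 4L)
    expect_equal(r1$p, 1)
    # all-singleton observed subgraph is the order minimum
    net <- fixtureNetwork("erdos-renyi", 20L, 0.2, seed = 9L)
    frag <- NetFEA:::.withSeed(1L, NetFEA:::.plantFragmented(
        net, 4L, NetFEA:::.adjacencyList(net)))
    r2 <- structureRandomizationPValue(net, C = nodeIds(net),
                                       fGenes = frag,
                                       iterations = 300L, seed = 4L)
    expect_equal(r2$p, 1)
    # empty intersection with the interesting collection
    r3 <- structureRandomizationPValue(net, C = nodeIds(net)[1:5],
                                       fGenes = "nothere",
                                       iterations = 100L, seed = 4L)
    expect_equal(r3$p, 1)
})

test_that("combined p-values and merge scores follow their definitions", {
    expect_equal(combinePValues(0.01, 0.2), 0.2)
    expect_equal(combinePValues(0, 0), 0)
    expect_equal(combinePValues(0.37, 0.37), 0.37)
    expect_equal(mergeScore(0.5, 0.5), 0)
    expect_equal(mergeScore(0.1, 0, floor = 1e-4), 3)
    expect_equal(mergeScore(0, 0, floor = 1e-3), 0)
    expect_error(mergeScore(0.1, 0.1, floor = 0), "floor")
})

test_that("enrichment runs are deterministic and order-independent", {
    fx <- generateFixture("erdos-renyi", 30L, 0.12,
                          plantedTerms = list(
                              list(id = "conn", size = 5L,
                                   mode = "connected")),
                          nRandomTerms = 3L, seed = 21L)
    a <- enrich(fx$network, fx$network, fx$annotations,
                iterations = 200L, seed = 8L)
    b <- enrich(fx$network, fx$network, fx$annotations,
                iterations = 200L, seed = 8L)
    expect_identical(a, b)
    shuffled <- annotationSet(rev(termGenes(fx$annotations)))
    c_ <- enrich(fx$network, fx$network, shuffled,
                 iterations = 200L, seed = 8L)
    expect_equal(a[order(a$term), !(names(a) %in% "bh_adjusted")],
                 c_[order(c_$term), !(names(c_) %in% "bh_adjusted")],
                 ignore_attr = TRUE)
    # whole-network mode: the set-based baseline is uninformative
    expect_true(all(a$fisher_p == 1))
    # empirical p-values live on the 1/iterations grid
    expect_true(all(abs(a$p_function * 200 -
                        round(a$p_function * 200)) < 1e-9))
    expect_true(all(abs(a$p_structure * 200 -
                        round(a$p_structure * 200)) < 1e-9))
})

test_that("enrich refuses an interesting network outside the universe", {
    G <- letterClique(5L)
    Hbad <- geneNetwork(nodes = c("a", "zz"))
    ann <- annotationSet(list(f = c("a", "b")))
    expect_error(enrich(G, Hbad, ann, iterations = 10L), "zz")
    Hedge <- geneNetwork(edges = cbind("a", "b"))
    Gpath <- geneNetwork(nodes = letters[1:5],
                         edges = rbind(c("a", "c"), c("c", "b")))
    expect_error(enrich(Gpath, Hedge, ann, iterations = 10L), "a--b")
})

test_that("a spanning term outranks a fragmented term of equal size", {
    net <- geneNetwork(nodes = paste0("n", 1:12),
                       edges = rbind(c("n1", "n2"), c("n2", "n3"),
                                     c("n3", "n4")))
    ann <- annotationSet(list(span = paste0("n", 1:4),
                              scatter = paste0("n", c(5, 7, 9, 11))))
    res <- enrich(net, net, ann, iterations = 2000L, seed = 3L)
    expect_lte(res$p_combined[res$term == "span"],
               res$p_combined[res$term == "scatter"])
    expect_equal(res$p_combined[res$term == "scatter"], 1)
})
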