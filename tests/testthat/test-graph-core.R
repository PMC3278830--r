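test_that("construction normalizes to a simple undirected graph", {
    raw <- cbind(c("a", "b", "a", "c"), c("b", "a", "a", "a"))
    expect_message(net <- geneNetwork(edges = raw, verbose = TRUE),
                   "self-loop")
    expect_equal(numEdges(net), 2L)
    expect_setequal(nodeIds(net), c("a", "b", "c"))
    expect_equal(unname(edgeMatrix(net)[, 1L] <= edgeMatrix(net)[, 2L]),
                 c(TRUE, TRUE))
    expect_true(validObject(net))
})

test_that("induced subgraphs keep exactly the edges inside the gene set", {
    tri <- geneNetwork(edges = cbind(c("a", "a", "b"), c("b", "c", "c")))
    sub <- inducedSubgraph(tri, c("a", "b"))
    expect_setequal(nodeIds(sub), c("a", "b"))
    expect_equal(nrow(edgeMatrix(sub)), 1L)

    expect_equal(numNodes(inducedSubgraph(tri, character())), 0L)

    pd <- geneNetwork(nodes = "d", edges = cbind(c("a", "b"), c("b", "c")))
    sub2 <- inducedSubgraph(pd, c("a", "c", "d", "z"))
    expect_setequal(nodeIds(sub2), c("a", "c", "d"))
    expect_equal(numEdges(sub2), 0L)
})

test_that("component-size sequences are non-increasing and complete", {
    pd <- geneNetwork(nodes = "d", edges = cbind(c("a", "b"), c("b", "c")))
    expect_equal(componentSizeSeq(pd), c(3L, 1L))
    expect_equal(componentSizeSeq(geneNetwork()), integer())
    two <- geneNetwork(edges = cbind(c("a", "c"), c("b", "d")))
    expect_equal(componentSizeSeq(two), c(2L, 2L))
})

test_that("sequence comparison follows the zero-padding rule", {
    expect_equal(compareCS(c(3, 1), c(3, 1)), "equal")
    expect_equal(compareCS(c(2, 2), c(3, 1)), "less")
    expect_equal(compareCS(c(3, 1), 3), "greater")
    expect_equal(compareCS(c(1, 1, 1), 2), "less")
    expect_equal(compareCS(integer(), integer()), "equal")
    expect_error(compareCS(c(1, 3), c(2, 1)), "not a valid")
})

test_that("sequence comparison is a total order", {
    set.seed(42)
    flip <- function(o) c(less = "greater", equal = "equal",
                          greater = "less")[[o]]
    for (i in 1:200) {
        a <- randomCS(); b <- randomCS(); c_ <- randomCS()
        ab <- compareCS(a, b)
        expect_equal(compareCS(b, a), flip(ab))   # antisymmetry
        if (ab == "equal")
            expect_equal(compareCS(a, c_), compareCS(b, c_))
        # transitivity on the <= relation
        if (ab != "greater" && compareCS(b, c_) != "greater")
            expect_true(compareCS(a, c_) != "greater")
    }
})

test_that("the all-singletons partition is the connectivity minimum", {
    set.seed(7)
    for (i in 1:25) {
        n <- sample(2:15, 1L)
        net <- fixtureNetwork("erdos-renyi", n, runif(1, 0, 0.5), seed = i)
        cs <- componentSizeSeq(net)
        expect_equal(sum(cs), n)
        expect_true(compareCS(cs, rep(1L, n)) != "less")
    }
})

test_that("joining two components strictly increases the cs order", {
    set.seed(11)
    for (i in 1:20) {
        net <- fixtureNetwork("erdos-renyi", 12L, 0.12, seed = i + 100)
        comp <- igraph::components(NetFEA:::.asIgraph(net))
        if (comp$no < 2L) next
        ids <- nodeIds(net)
        a <- ids[comp$membership == 1L][1L]
        b <- ids[comp$membership == 2L][1L]
        before <- componentSizeSeq(net)
        after <- componentSizeSeq(
            geneNetwork(nodes = ids,
                        edges = rbind(edgeMatrix(net), c(a, b))))
        expect_equal(compareCS(after, before), "greater")
    }
})
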