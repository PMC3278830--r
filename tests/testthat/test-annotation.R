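test_that("true-path propagation annotates every ancestor", {
    ann <- annotationSet(list(f2 = "g1"), dag = cbind("f2", "f1"))
    out <- propagateTruePath(ann)
    expect_setequal(termGenes(out, "f1"), "g1")
    expect_setequal(termGenes(out, "f2"), "g1")

    noDag <- annotationSet(list(f1 = c("a", "b")))
    expect_identical(termGenes(propagateTruePath(noDag)), termGenes(noDag))

    chain <- annotationSet(list(f3 = "g"),
                           dag = rbind(c("f3", "f2"), c("f2", "f1")))
    out2 <- propagateTruePath(chain)
    expect_true(all(c("f1", "f2", "f3") %in% termNames(out2)))
    expect_true(all(vapply(termGenes(out2), function(g) "g" %in% g,
                           logical(1L))))
})

test_that("propagation is idempotent and monotone on a random DAG", {
    set.seed(3)
    for (rep in 1:5) {
        nt <- 8L
        ids <- paste0("t", seq_len(nt))
        # edges only from higher to lower index: acyclic by construction
        pairs <- t(utils::combn(ids, 2L))[, 2:1]
        dag <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
        terms <- lapply(setNames(ids, ids), function(i)
            paste0("g", sample(20L, sample(3L, 1L))))
        ann <- annotationSet(terms, dag = dag)
        once <- propagateTruePath(ann)
        twice <- propagateTruePath(once)
        expect_identical(lapply(termGenes(once), sort),
                         lapply(termGenes(twice), sort))
        for (t in termNames(ann))
            expect_true(all(termGenes(ann, t) %in% termGenes(once, t)))
        # child gene sets are contained in their parents' sets
        for (i in seq_len(nrow(dag)))
            expect_true(all(termGenes(once, dag[i, 1L]) %in%
                            termGenes(once, dag[i, 2L])))
    }
})

test_that("a cyclic ontology is rejected with an identified cycle", {
    expect_error(
        annotationSet(list(a = "g1"),
                      dag = rbind(c("a", "b"), c("b", "c"), c("c", "a"))),
        "cycle")
})

test_that("term filters are inclusive at both boundaries", {
    G <- geneNetwork(nodes = paste0("u", 1:20))
    H <- inducedSubgraph(G, paste0("u", 1:10))
    ann <- annotationSet(list(
        four = paste0("u", 1:4),                     # below min in universe
        five = paste0("u", 1:5),                     # exactly at min
        absent = paste0("x", 1:9),                   # none in universe
        big = paste0("u", 1:12)))                    # c_f = 10 <= 10
    out <- filterFunctions(ann, G, H, minUniversal = 5L,
                           maxInteresting = 10L)
    expect_setequal(termNames(out), c("five", "big"))
    tight <- filterFunctions(ann, G, H, minUniversal = 5L,
                             maxInteresting = 9L)
    expect_setequal(termNames(tight), "five")
    # re-filtering is a no-op
    expect_identical(termGenes(filterFunctions(out, G, H, 5L, 10L)),
                     termGenes(out))
})

test_that("annotation readers parse GMT, pair, and OBO formats", {
    gmt <- tempfile(fileext = ".gmt")
    writeLines(c("setA\tdesc\tg1\tg2\tg2", "setB\tna\tg3"), gmt)
    ann <- readGMT(gmt)
    expect_setequal(termGenes(ann, "setA"), c("g1", "g2"))
    expect_setequal(termGenes(ann, "setB"), "g3")

    pairs <- tempfile()
    writeLines(c("g1\tsetA", "g2 setA", "g1\tsetB"), pairs)
    ann2 <- readAnnotationPairs(pairs)
    expect_setequal(termGenes(ann2, "setA"), c("g1", "g2"))

    obo <- tempfile(fileext = ".obo")
    writeLines(c(
        "format-version: 1.2", "",
        "[Term]", "id: GO:0000002", "name: child",
        "is_a: GO:0000001 ! parent",
        "relationship: part_of GO:0000003 ! whole", "",
        "[Term]", "id: GO:0000009", "name: gone",
        "is_obsolete: true", "is_a: GO:0000001", "",
        "[Typedef]", "id: part_of"), obo)
    dag <- readOboDag(obo)
    expect_equal(nrow(dag), 1L)
    expect_equal(unname(dag[1L, ]), c("GO:0000002", "GO:0000001"))
    dag2 <- readOboDag(obo, includePartOf = TRUE)
    expect_equal(nrow(dag2), 2L)
    expect_true("GO:0000003" %in% dag2[, 2L])
})

test_that("GMT writing round-trips an annotation set", {
    ann <- annotationSet(list(a = c("g1", "g2"), b = "g9"))
    path <- tempfile(fileext = ".gmt")
    writeGMT(ann, path)
    back <- readGMT(path)
    expect_identical(lapply(termGenes(back), sort),
                     lapply(termGenes(ann), sort))
})
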