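#' Construct an annotation set
#'
#' @param terms named list mapping function (term) identifiers to character
#'   vectors of gene identifiers.  Duplicate genes within a term collapse
#'   silently; terms left with no genes are dropped with a message.
#' @param dag optional two-column character matrix or data frame of
#'   (child, parent) term pairs; must be acyclic (a cycle is reported in the
#'   error).  Terms appearing only in the DAG carry no genes until
#'   propagation assigns them some.
#' @param verbose report dropped empty terms.
#' @return an [AnnotationSet-class].
#' @examples
#' ann <- annotationSet(list(f1 = c("g1", "g2"), f2 = "g1"),
#'                      dag = cbind("f2", "f1"))
#' termGenes(ann, "f1")
#' @export
annotationSet <- function(terms = list(), dag = NULL, verbose = FALSE) {
    terms <- lapply(terms, function(g) unique(as.character(g)))
    empty <- lengths(terms) == 0L
    if (any(empty)) {
        if (verbose)
            message("dropped ", sum(empty), " term(s) with no genes")
        terms <- terms[!empty]
    }
    if (is.null(dag) || NROW(dag) == 0L) {
        dm <- matrix(character(), ncol = 2L)
    } else {
        dag <- as.matrix(dag)
        if (ncol(dag) != 2L)
            stop("dag must have exactly two columns (child, parent)")
        mode(dag) <- "character"
        dm <- dag[!duplicated(paste(dag[, 1L], dag[, 2L], sep = "\r")), ,
                  drop = FALSE]
    }
    new("AnnotationSet", terms = terms, dag = dm)
}

#' @describeIn annotationSet term identifiers.
#' @param x an `AnnotationSet`.
#' @export
termNames <- function(x) names(x@terms)

#' @describeIn annotationSet genes annotated to `term`, or the full named
#'   list when `term` is `NULL`.
#' @param term a single term identifier or `NULL`.
#' @export
termGenes <- function(x, term = NULL) {
    if (is.null(term)) return(x@terms)
    if (!term %in% names(x@terms))
        stop("unknown term: ", term)
    x@terms[[term]]
}

#' @describeIn annotationSet number of annotated terms.
#' @export
numTerms <- function(x) length(x@terms)

#' @describeIn annotationSet the (child, parent) DAG edge matrix.
#' @export
dagEdges <- function(x) x@dag

#' @describeIn annotationSet whether an ontology DAG is attached.
#' @export
hasDag <- function(x) nrow(x@dag) > 0L

setMethod("show", "AnnotationSet", function(object) {
    cat("AnnotationSet with", numTerms(object), "terms annotating",
        length(unique(unlist(object@terms, use.names = FALSE))),
        "genes\n")
    if (hasDag(object))
        cat("  ontology DAG:", nrow(object@dag), "child-parent pairs\n")
})

#' Apply the true-path rule
#'
#' Propagates annotations up the ontology: a gene annotated to a term
#' becomes annotated to every ancestor of that term in the DAG.  The
#' operation is idempotent and only ever grows gene sets.  Terms named only
#' in the DAG become annotated terms if propagation reaches them.
#'
#' @param ann an [AnnotationSet-class] with a DAG attached.
#' @return the propagated [AnnotationSet-class].
#' @export
propagateTruePath <- function(ann) {
    if (!hasDag(ann))
        return(ann)
    dag <- dagEdges(ann)
    terms <- ann@terms
    all_terms <- unique(c(names(terms), c(dag)))
    sets <- setNames(vector("list", length(all_terms)), all_terms)
    sets[names(terms)] <- terms
    # process children before parents so each pushed set is already complete
    ord <- .topoOrder(dag, all_terms)
    for (t in ord) {
        parents <- dag[dag[, 1L] == t, 2L]
        if (length(parents) && length(sets[[t]]))
            for (p in parents)
                sets[[p]] <- unique(c(sets[[p]], sets[[t]]))
    }
    sets <- sets[lengths(sets) > 0L]
    new("AnnotationSet", terms = sets, dag = dag)
}

# topological order of terms with all children preceding their parents;
# dag rows are (child, parent) and are known acyclic (class validity)
.topoOrder <- function(dag, terms) {
    idx <- setNames(seq_along(terms), terms)
    # remaining[p] = number of direct children of p not yet emitted
    remaining <- tabulate(idx[dag[, 2L]], length(terms))
    queue <- which(remaining == 0L)
    ord <- integer()
    while (length(queue)) {
        v <- queue[[1L]]
        queue <- queue[-1L]
        ord <- c(ord, v)
        vparents <- idx[dag[dag[, 1L] == terms[v], 2L]]
        for (p in vparents) {
            remaining[p] <- remaining[p] - 1L
            if (remaining[p] == 0L) queue <- c(queue, p)
        }
    }
    terms[ord]
}

#' Filter functions by annotation counts in the two networks
#'
#' Retains the terms annotating at least `minUniversal` genes present in the
#' universal network and at most `maxInteresting` genes present in the
#' interesting network (both boundaries inclusive).  Counts are taken
#' against the networks' node sets, because the permutation nulls draw from
#' those sets; annotations to genes outside them are kept in the set but do
#' not count.
#'
#' @param ann an [AnnotationSet-class].
#' @param universal,interesting [GeneNetwork-class] objects; in
#'   whole-network mode pass the same network twice.
#' @param minUniversal minimum count in the universal node set (default 5).
#' @param maxInteresting maximum count in the interesting node set
#'   (default 100).
#' @return the filtered [AnnotationSet-class]; re-filtering is a no-op.
#' @export
filterFunctions <- function(ann, universal, interesting = universal,
                            minUniversal = 5L, maxInteresting = 100L) {
    stopifnot(minUniversal >= 1L, maxInteresting >= 0L)
    U <- nodeIds(universal)
    C <- nodeIds(interesting)
    uf <- vapply(ann@terms, function(g) sum(g %in% U), integer(1L))
    cf <- vapply(ann@terms, function(g) sum(g %in% C), integer(1L))
    keep <- uf >= minUniversal & cf <= maxInteresting
    new("AnnotationSet", terms = ann@terms[keep], dag = ann@dag)
}

#' Read gene sets in GMT format
#'
#' Each tab-separated line holds a set name, a description (ignored), and
#' the member genes.
#'
#' @param path path to a GMT file.
#' @return an [AnnotationSet-class] without a DAG.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("GMT line ", short[1L], " has fewer than 3 fields")
    terms <- setNames(lapply(fields, function(f) f[-(1:2)]),
                      vapply(fields, `[[`, character(1L), 1L))
    annotationSet(terms)
}

#' Read two-column (gene, term) annotation pairs
#'
#' @param path path to a tab- or whitespace-separated file with one
#'   gene/term pair per line.
#' @return an [AnnotationSet-class] without a DAG.
#' @export
readAnnotationPairs <- function(path) {
    tab <- .readPairs(path, "annotation")
    annotationSet(split(tab[, 1L], tab[, 2L]))
}

#' Read a child-parent term DAG from a two-column file
#'
#' @param path path to a tab- or whitespace-separated (child, parent) file.
#' @return two-column character matrix suitable for [annotationSet()].
#' @export
readDagPairs <- function(path) {
    .readPairs(path, "DAG")
}

.readPairs <- function(path, what) {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    fields <- strsplit(trimws(lines[keep]), "[ \t]+")
    bad <- which(lengths(fields) < 2L)
    if (length(bad))
        stop(what, " line ", which(keep)[bad[1L]], " has fewer than 2 columns")
    cbind(vapply(fields, `[[`, character(1L), 1L),
          vapply(fields, `[[`, character(1L), 2L))
}

#' Extract a term DAG from an OBO ontology file
#'
#' Minimal reader for the OBO flat-file format: collects `is_a` edges (and,
#' optionally, `relationship: part_of` edges) from non-obsolete `[Term]`
#' stanzas.  Which relations the true-path rule should traverse is a
#' modelling choice; `is_a` alone is the default.
#'
#' @param path path to an OBO file.
#' @param includePartOf also treat `part_of` relationships as child-parent
#'   edges (default `FALSE`).
#' @return two-column character matrix of (child, parent) pairs.
#' @export
readOboDag <- function(path, includePartOf = FALSE) {
    lines <- readLines(path, warn = FALSE)
    children <- parents <- character()
    id <- NA_character_
    in_term <- FALSE
    obsolete <- FALSE
    pend_child <- pend_parent <- character()
    flush <- function() {
        if (in_term && !obsolete && !is.na(id) && length(pend_parent)) {
            children <<- c(children, rep(id, length(pend_parent)))
            parents <<- c(parents, pend_parent)
        }
    }
    for (ln in lines) {
        ln <- trimws(sub("!.*$", "", ln))
        if (ln == "[Term]") {
            flush()
            in_term <- TRUE
            obsolete <- FALSE
            id <- NA_character_
            pend_parent <- character()
        } else if (grepl("^\\[", ln)) {
            flush()
            in_term <- FALSE
        } else if (in_term) {
            if (startsWith(ln, "id:")) {
                id <- trimws(sub("^id:", "", ln))
            } else if (startsWith(ln, "is_a:")) {
                pend_parent <- c(pend_parent, trimws(sub("^is_a:", "", ln)))
            } else if (includePartOf &&
                       grepl("^relationship:\\s*part_of\\s", ln)) {
                pend_parent <- c(pend_parent,
                    trimws(sub("^relationship:\\s*part_of", "", ln)))
            } else if (grepl("^is_obsolete:\\s*true", ln)) {
                obsolete <- TRUE
            }
        }
    }
    flush()
    cbind(children, parents)
}
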