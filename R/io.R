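#' Read a network from an edge-list (TSV) or SIF file
#'
#' Tab/whitespace-separated edge lists have two columns (source, target)
#' or three (source, target, weight).  SIF lines are
#' `source interaction target [target ...]`; a single-token SIF line adds
#' an isolated node.  The result is normalized to a simple undirected
#' network: direction is ignored, repeated records collapse, self-loops
#' are dropped (counts reported via [message()]).
#'
#' @param path input file.
#' @param weightThreshold when given, the file must have a numeric third
#'   column and edges with weight strictly below the threshold are dropped.
#' @param format `"auto"` (by extension: `.sif` is SIF, anything else an
#'   edge list), `"tsv"`, or `"sif"`.
#' @return a [GeneNetwork-class].
#' @export
readNetwork <- function(path, weightThreshold = NULL,
                        format = c("auto", "tsv", "sif")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif"
                  else "tsv"
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    if (!any(keep)) {
        warning("empty network file: ", path)
        return(geneNetwork())
    }
    fields <- strsplit(trimws(lines[keep]), "[ \t]+")
    lineno <- which(keep)
    nodes <- character()
    if (format == "sif") {
        nf <- lengths(fields)
        if (any(nf == 2L))
            stop("SIF line ", lineno[which(nf == 2L)[1L]],
                 " has 2 tokens; expected 1 or >= 3")
        nodes <- vapply(fields[nf == 1L], `[[`, character(1L), 1L)
        ef <- fields[nf >= 3L]
        src <- tgt <- character()
        for (f in ef) {
            src <- c(src, rep(f[1L], length(f) - 2L))
            tgt <- c(tgt, f[-(1:2)])
        }
        em <- cbind(src, tgt)
    } else {
        nf <- lengths(fields)
        bad <- which(nf < 2L)
        if (length(bad))
            stop("line ", lineno[bad[1L]], " has fewer than 2 columns")
        em <- cbind(vapply(fields, `[[`, character(1L), 1L),
                    vapply(fields, `[[`, character(1L), 2L))
        if (!is.null(weightThreshold)) {
            noW <- which(nf < 3L)
            if (length(noW))
                stop("line ", lineno[noW[1L]],
                     " has no weight column but a threshold was given")
            w <- suppressWarnings(
                as.numeric(vapply(fields, `[[`, character(1L), 3L)))
            badW <- which(is.na(w))
            if (length(badW))
                stop("line ", lineno[badW[1L]], " has a non-numeric weight")
            low <- w < weightThreshold
            if (any(low))
                message("dropped ", sum(low), " edge(s) with weight below ",
                        weightThreshold)
            em <- em[!low, , drop = FALSE]
        }
    }
    geneNetwork(nodes = nodes, edges = em, verbose = TRUE)
}

#' Read a plain node list (one gene identifier per line)
#'
#' @param path input file.
#' @return character vector of unique identifiers.
#' @export
readNodeList <- function(path) {
    lines <- trimws(readLines(path, warn = FALSE))
    unique(lines[nzchar(lines)])
}

# fixed output formats: counts as integers, probabilities/scores via %.6g
.fmtNum <- function(x) sprintf("%.6g", x)

#' Write enrichment (or merge-score) results as TSV
#'
#' Numeric columns are written with the fixed `%.6g` format (6 significant
#' digits), counts as plain integers; [readEnrichmentResults()] reads the
#' file back so that all numeric fields compare equal to their formatted
#' values.
#'
#' @param res a results `data.frame` from [enrich()] or [runMergeCompare()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEnrichmentResults <- function(res, path) {
    out <- res
    for (cn in names(out))
        if (is.double(out[[cn]]))
            out[[cn]] <- .fmtNum(out[[cn]])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEnrichmentResults
#' @export
readEnrichmentResults <- function(path) {
    read.delim(path, stringsAsFactors = FALSE, colClasses = NA,
               check.names = FALSE)
}

#' Write a JSON run manifest next to an output file
#'
#' Records the run configuration (paths, iterations, k, thresholds, seed)
#' plus package and R versions, so a result file can always be traced back
#' to the run that produced it.
#'
#' @param config named list of configuration values.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(config, path) {
    config$package_version <-
        as.character(utils::packageVersion("NetFEA"))
    config$r_version <- as.character(getRversion())
    jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", digits = NA)
    invisible(path)
}

#' Write a network as a two-column TSV edge list
#'
#' Isolated nodes cannot be represented in a plain edge list and are
#' omitted with a warning; use SIF-style node lines or a node-list file to
#' carry them.
#'
#' @param net a [GeneNetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path) {
    iso <- setdiff(nodeIds(net), c(edgeMatrix(net)))
    if (length(iso))
        warning(length(iso), " isolated node(s) not representable in an ",
                "edge list were omitted")
    write.table(edgeMatrix(net), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write an annotation set in GMT format
#'
#' @param ann an [AnnotationSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(ann, path) {
    lines <- vapply(termNames(ann), function(t)
        paste(c(t, "na", termGenes(ann, t)), collapse = "\t"),
        character(1L))
    writeLines(lines, path)
    invisible(path)
}
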