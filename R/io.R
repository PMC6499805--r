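#' Read a gene x sample count matrix
#'
#' Reads TSV/CSV (genes in rows, header row of sample ids, first column gene
#' ids) or MatrixMarket triplet format with `<stem>_rows.txt` /
#' `<stem>_cols.txt` sidecar files, and joins a sample-to-group table.
#'
#' @param path count file.
#' @param group_table two-column TSV (`sample`, `group`) mapping every sample.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; default guessed from the file
#'   extension.
#' @return a [CountExperiment-class].
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(path, group_table,
                            format = c("auto", "tsv", "csv", "mtx")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto")
        format <- switch(tolower(tools::file_ext(path)),
                         csv = "csv", mtx = "mtx", "tsv")
    if (format == "mtx") {
        m <- as.matrix(Matrix::readMM(path))
        stem <- sub("\\.mtx$", "", path)
        rn <- readLines(paste0(stem, "_rows.txt"))
        cn <- readLines(paste0(stem, "_cols.txt"))
        dimnames(m) <- list(rn, cn)
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- utils::read.table(path, header = TRUE, sep = sep,
                                row.names = 1, check.names = FALSE,
                                stringsAsFactors = FALSE)
        m <- as.matrix(df)
        if (!is.numeric(m)) stop("non-numeric count entries in ", path)
    }
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene identifiers in ", path)
    bad <- which(m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf(
            "negative or non-integer count at gene '%s', sample '%s'",
            rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    gt <- utils::read.table(group_table, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% colnames(gt)))
        stop("group table needs 'sample' and 'group' columns")
    groups <- stats::setNames(gt$group, gt$sample)
    CountExperiment(m, groups)
}

#' Write a CountExperiment and its group table
#'
#' Inverse of [readCountMatrix()]; emits the counts in the requested format
#' plus a `sample`/`group` TSV.
#'
#' @param ce a [CountExperiment-class].
#' @param path destination count file.
#' @param group_table destination for the group table TSV.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @export
writeCountMatrix <- function(ce, path, group_table,
                             format = c("tsv", "csv", "mtx")) {
    format <- match.arg(format)
    m <- countsMatrix(ce)
    if (format == "mtx") {
        Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
        stem <- sub("\\.mtx$", "", path)
        writeLines(rownames(m), paste0(stem, "_rows.txt"))
        writeLines(colnames(m), paste0(stem, "_cols.txt"))
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                         stringsAsFactors = FALSE)
        utils::write.table(df, path, sep = sep, quote = FALSE,
                           row.names = FALSE)
    }
    g <- groupLabels(ce)
    utils::write.table(
        data.frame(sample = names(g), group = as.character(g)),
        group_table, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a STRING-style interaction edge list
#'
#' Rows are `protein1 protein2 combined_score`, whitespace- or
#' tab-delimited, optional header. Edges below `score_min` are dropped,
#' duplicate pairs in either orientation are collapsed keeping the maximum
#' score, and self-loops are removed.
#'
#' @param path edge-list file.
#' @param score_min combined-score floor (STRING scale 0-1000); 700 is the
#'   conventional "high confidence" cutoff.
#' @return an [InteractionNetwork-class].
#' @export
readInteractionNetwork <- function(path, score_min = 700) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) && grepl("^\\s*protein1", lines[1], ignore.case = TRUE))
        lines <- lines[-1]
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf != 3))
        stop("malformed row (expected 3 fields): line ", which(nf != 3)[1])
    a <- vapply(fields, `[`, "", 1L)
    b <- vapply(fields, `[`, "", 2L)
    s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (anyNA(s))
        stop("non-numeric combined_score: line ", which(is.na(s))[1])
    keep <- s >= score_min
    InteractionNetwork(data.frame(a, b, s, stringsAsFactors = FALSE)[keep, ,
                                                                     drop = FALSE])
}

#' Write / read a gene set as one-id-per-line text
#'
#' @param genes character vector of gene ids.
#' @param path destination / source file.
#' @export
writeGeneSet <- function(genes, path) {
    writeLines(unique(as.character(genes)), path)
    invisible(path)
}

#' @rdname writeGeneSet
#' @export
readGeneSet <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    unique(readLines(path))
}

#' Write a result table as TSV with header
#'
#' `DEResult` and other DataFrame-derived tables gain a leading `gene`
#' column from their rownames.
#'
#' @param x a data.frame or [S4Vectors::DataFrame].
#' @param path destination TSV.
#' @export
writeResultsTable <- function(x, path) {
    df <- as.data.frame(x)
    if (!is.null(rownames(df)) && !identical(rownames(df),
                                             as.character(seq_len(nrow(df)))))
        df <- cbind(gene = rownames(df), df)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write an interaction (sub)network as GraphML
#'
#' Node and edge attributes present on the graph (score, betweenness,
#' community, venn_region, ...) are carried into the GraphML.
#'
#' @param net an [InteractionNetwork-class] or [SubNetwork-class].
#' @param path destination `.graphml` file.
#' @export
writeGraphML <- function(net, path) {
    igraph::write_graph(interactionGraph(net), path, format = "graphml")
    invisible(path)
}
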