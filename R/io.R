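#' @include AllClasses.R
NULL

#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT format used by MSigDB: one set per line,
#' fields are set name, description, then member gene ids. Duplicate member
#' ids within a line are dropped, keeping the first occurrence; duplicate
#' set names across lines are an error.
#'
#' @param path path to a GMT file
#' @return a \linkS4class{GeneSetCollection}
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdemo\tA\tB\tC", f)
#' readGmt(f)
#' @export
readGmt <- function(path) {
    if (!file.exists(path))
        stop("GMT file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("malformed GMT line (fewer than 3 tab-separated fields) at line ",
             which(nf < 3L)[1L])
    nm <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(nm))
        stop("duplicate gene-set name(s) in GMT: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    desc <- vapply(fields, `[[`, "", 2L)
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- nm
    names(desc) <- nm
    GeneSetCollection(sets, desc, source = path)
}

#' Write a GeneSetCollection to a GMT file
#'
#' @param coll a \linkS4class{GeneSetCollection}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGmt <- function(coll, path) {
    lines <- vapply(names(coll@sets), function(nm) {
        paste(c(nm, coll@descriptions[[nm]], coll@sets[[nm]]),
              collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Read an expression matrix with labels from delimited text
#'
#' Reads a rectangular numeric table (TSV or CSV, chosen by file extension
#' or the \code{sep} argument) with ids in the first column and a header row
#' of ids, plus a separate two-column labels table (sample id, label).
#' Missing or non-numeric expression cells are a hard error; this package
#' does not impute.
#'
#' @param exprPath path to the expression table
#' @param labelsPath path to the labels table (columns: sample id, label);
#'   labels may be \code{control}/\code{diseased}, or -1/+1 with +1 meaning
#'   diseased
#' @param orientation \code{"genes_in_rows"} (default) or
#'   \code{"samples_in_rows"}; the latter is transposed on load so the
#'   returned dataset is always genes x samples
#' @param sep field separator; guessed from the file extension when NULL
#' @return an \linkS4class{ExpressionDataset}
#' @export
readExpression <- function(exprPath, labelsPath,
                           orientation = c("genes_in_rows", "samples_in_rows"),
                           sep = NULL) {
    orientation <- match.arg(orientation)
    m <- .readMatrix(exprPath, sep)
    if (orientation == "samples_in_rows")
        m <- t(m)
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample id(s) in expression table")
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene id(s) in expression table; collapse probes first")
    labels <- .readLabels(labelsPath, sep)
    miss <- setdiff(colnames(m), names(labels))
    if (length(miss))
        stop("sample(s) without a label: ", paste(miss, collapse = ", "))
    ExpressionDataset(m, labels[colnames(m)])
}

.guessSep <- function(path, sep) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.readMatrix <- function(path, sep = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- utils::read.table(path, sep = .guessSep(path, sep), header = TRUE,
                            row.names = 1L, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
    m <- as.matrix(df)
    if (!is.numeric(m) || anyNA(m))
        stop("expression table contains missing or non-numeric values")
    m
}

.readLabels <- function(path, sep = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- utils::read.table(path, sep = .guessSep(path, sep), header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "")
    if (ncol(df) < 2L)
        stop("labels table needs two columns: sample id, label")
    if (anyDuplicated(df[[1L]]))
        stop("duplicate sample id(s) in labels table")
    lab <- df[[2L]]
    if (is.numeric(lab)) lab <- ifelse(lab > 0, "diseased", "control")
    setNames(as.character(lab), as.character(df[[1L]]))
}

#' Collapse probe-level rows to gene level by largest fold change
#'
#' When several probes map to the same gene, keeps the single probe whose
#' absolute between-group difference of group means (the log-scale fold
#' change, since values are already log2) is largest; ties are broken by the
#' lexicographically smallest probe id. Probes without a gene mapping are
#' dropped.
#'
#' @param values probe x sample numeric matrix (log2 scale), probe ids as
#'   rownames
#' @param probeToGene named character vector mapping probe id -> gene id
#' @param labels per-sample labels (any encoding accepted by
#'   \code{\link{ExpressionDataset}}); the two groups define the fold change
#' @return an \linkS4class{ExpressionDataset} with one row per mapped gene
#' @export
collapseProbes <- function(values, probeToGene, labels) {
    values <- as.matrix(values)
    if (length(probeToGene) == 0L)
        stop("empty probe-to-gene mapping")
    lab <- .coerceLabels(labels)
    if (length(lab) != ncol(values))
        stop("one label per sample (column) is required")
    probes <- intersect(rownames(values), names(probeToGene))
    if (!length(probes))
        stop("no probe in the matrix is covered by the mapping")
    d <- lab == "diseased"
    fc <- abs(rowMeans(values[probes, d, drop = FALSE]) -
              rowMeans(values[probes, !d, drop = FALSE]))
    gene <- probeToGene[probes]
    ## per gene: largest |fold change|, ties -> smallest probe id
    ord <- order(gene, -fc, probes, method = "radix")
    keep <- probes[ord][!duplicated(gene[ord])]
    m <- values[keep, , drop = FALSE]
    rownames(m) <- probeToGene[keep]
    m <- m[order(rownames(m)), , drop = FALSE]
    ExpressionDataset(m, lab)
}

#' Restrict a gene-set collection to a dataset's gene universe
#'
#' Intersects every set with the genes measured in \code{ds} and drops sets
#' whose surviving membership falls below \code{minSize}. The input
#' collection is not modified. A minimum size of 2 is the default because a
#' one-gene set degenerates to a single squared gene statistic.
#'
#' @param coll a \linkS4class{GeneSetCollection}
#' @param ds an \linkS4class{ExpressionDataset} (or a character vector of
#'   gene ids)
#' @param minSize smallest allowed post-restriction set size (>= 1)
#' @return a restricted \linkS4class{GeneSetCollection}
#' @export
restrictCollection <- function(coll, ds, minSize = 2L) {
    if (minSize < 1L)
        stop("minSize must be >= 1")
    universe <- if (is.character(ds)) ds else geneIds(ds)
    sets <- lapply(coll@sets, function(g) g[g %in% universe])
    keep <- lengths(sets) >= minSize
    GeneSetCollection(sets[keep], coll@descriptions[keep],
                      source = coll@source)
}
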