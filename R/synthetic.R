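#' @include AllClasses.R
NULL

#' Simulate a two-class expression dataset with gene-set structure
#'
#' Draws a genes x samples matrix of correlated Gaussian log-expression:
#' each gene belonging to at least one set loads on that set's shared
#' standard-normal factor as \code{sqrt(rho) * factor +
#' sqrt(1 - rho) * noise} (unit marginal variance by construction), genes
#' outside every set are pure noise, and everything is scaled by
#' \code{sigma}. Marker genes then receive an additive mean shift
#' \code{delta} (log2 units) in the diseased samples only; the control
#' class has mean 0 everywhere. A gene in several sets loads on the factor
#' of the first set that contains it. Deterministic given \code{seed}.
#'
#' @param geneIds the gene universe (unique character ids)
#' @param coll a \linkS4class{GeneSetCollection} over (a subset of)
#'   \code{geneIds}; drives the correlation structure and is returned
#'   untouched for downstream scoring
#' @param markers named numeric vector: names are marker gene ids (must be
#'   in \code{geneIds}, but need not be in any set), values are the
#'   diseased-class mean shifts delta
#' @param nDiseased,nControl samples per class
#' @param rho within-set correlation, in [0, 1)
#' @param sigma marginal noise SD
#' @param seed integer seed
#' @return list with \code{ds} (an \linkS4class{ExpressionDataset}),
#'   \code{coll}, and \code{markers} (the ground truth)
#' @examples
#' coll <- GeneSetCollection(list(S1 = c("g1", "g2", "g3")))
#' sim <- simulateExpression(paste0("g", 1:10), coll,
#'                           markers = c(g1 = 2), nDiseased = 5,
#'                           nControl = 5, seed = 1)
#' @export
simulateExpression <- function(geneIds, coll, markers = numeric(0),
                               nDiseased = 30L, nControl = 30L,
                               rho = 0.2, sigma = 1, seed = 1L) {
    if (anyDuplicated(geneIds)) stop("gene ids must be unique")
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
    if (sigma <= 0) stop("sigma must be positive")
    if (length(markers)) {
        bad <- setdiff(names(markers), geneIds)
        if (length(bad))
            stop("marker(s) outside the gene universe: ",
                 paste(bad, collapse = ", "))
    }
    outside <- setdiff(unlist(geneSets(coll), use.names = FALSE), geneIds)
    if (length(outside))
        stop("collection gene(s) outside the universe: ",
             paste(outside, collapse = ", "))
    G <- length(geneIds)
    n <- nDiseased + nControl
    ## first set containing each gene (NA: none -> independent noise)
    firstSet <- rep(NA_integer_, G)
    names(firstSet) <- geneIds
    for (i in rev(seq_len(length(coll))))
        firstSet[coll@sets[[i]]] <- i

    set.seed(seed)
    eps <- matrix(stats::rnorm(G * n), G, n)
    vals <- eps
    if (length(coll) && rho > 0) {
        fac <- matrix(stats::rnorm(length(coll) * n), length(coll), n)
        inSet <- !is.na(firstSet)
        vals[inSet, ] <- sqrt(rho) * fac[firstSet[inSet], , drop = FALSE] +
            sqrt(1 - rho) * eps[inSet, , drop = FALSE]
    }
    vals <- sigma * vals
    sampleIds <- c(sprintf("d%03d", seq_len(nDiseased)),
                   sprintf("c%03d", seq_len(nControl)))
    dimnames(vals) <- list(geneIds, sampleIds)
    if (length(markers))
        vals[names(markers), seq_len(nDiseased)] <-
            vals[names(markers), seq_len(nDiseased), drop = FALSE] + markers
    labels <- rep(c("diseased", "control"), c(nDiseased, nControl))
    list(ds = ExpressionDataset(vals, labels), coll = coll,
         markers = markers)
}

#' Preset simulation scenarios probing marker/set overlap
#'
#' Named configurations that exercise the structural sensitivity of
#' pathway-guided selection to how widely the true markers are shared
#' across gene sets:
#' \describe{
#'   \item{markersInManySets}{5 markers (delta = 2) that belong to three
#'     gene sets simultaneously.}
#'   \item{markersInOneSet}{the same 5 markers, members of one set only.}
#'   \item{markersInNoSet}{5 shifted genes that belong to no set at all --
#'     pathway-guided selection can never recover them, whatever the
#'     effect size.}
#'   \item{pureNull}{no shift anywhere; labels carry no signal.}
#' }
#' All presets share a universe of 210 genes, twenty 10-gene sets covering
#' genes 1-200 (10 genes sit outside every set), 30 samples per class,
#' within-set correlation 0.2 and unit noise SD.
#'
#' @return named list of configuration lists, each accepted by
#'   \code{\link{simulateFromConfig}}
#' @export
overlapScenarios <- function() {
    geneIds <- sprintf("g%03d", 1:210)
    baseSets <- lapply(seq_len(20), function(k)
        geneIds[(10 * (k - 1) + 1):(10 * k)])
    names(baseSets) <- sprintf("set%02d", seq_len(20))
    inSetMarkers <- setNames(rep(2, 5), geneIds[1:5])
    manySets <- baseSets
    for (k in c("set02", "set03"))
        manySets[[k]] <- unique(c(manySets[[k]], names(inSetMarkers)))
    noSetMarkers <- setNames(rep(2, 5), geneIds[201:205])
    base <- list(geneIds = geneIds, nDiseased = 30L, nControl = 30L,
                 rho = 0.2, sigma = 1)
    cfg <- function(name, sets, markers)
        c(list(name = name, coll = GeneSetCollection(sets),
               markers = markers), base)
    list(
        markersInManySets = cfg("markersInManySets", manySets, inSetMarkers),
        markersInOneSet = cfg("markersInOneSet", baseSets, inSetMarkers),
        markersInNoSet = cfg("markersInNoSet", baseSets, noSetMarkers),
        pureNull = cfg("pureNull", baseSets, numeric(0)))
}

#' Run a simulation configuration
#'
#' @param config one element of \code{\link{overlapScenarios}} (or any list
#'   with the same fields)
#' @param seed integer seed
#' @return as \code{\link{simulateExpression}}
#' @export
simulateFromConfig <- function(config, seed = 1L) {
    simulateExpression(config$geneIds, config$coll,
                       markers = config$markers,
                       nDiseased = config$nDiseased,
                       nControl = config$nControl,
                       rho = config$rho, sigma = config$sigma, seed = seed)
}

#' Write a simulation to disk (expr.tsv, labels.tsv, sets.gmt, truth.json)
#'
#' @param sim result of \code{\link{simulateExpression}}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- exprValues(sim$ds)
    utils::write.table(data.frame(gene_id = rownames(m), m,
                                  check.names = FALSE),
                       file.path(dir, "expr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = sampleIds(sim$ds),
                                  label = as.character(sampleLabels(sim$ds))),
                       file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeGmt(sim$coll, file.path(dir, "sets.gmt"))
    jsonlite::write_json(list(markers = as.list(sim$markers)),
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(dir)
}
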