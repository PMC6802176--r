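#' @include AllClasses.R
NULL

#' @export
setGeneric("sizeClass", function(x) standardGeneric("sizeClass"))

#' @export
setGeneric("genomeGC", function(x) standardGeneric("genomeGC"))

#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @export
setGeneric("spacers", function(x) standardGeneric("spacers"))

#' @export
setGeneric("coverageMatrix", function(x) standardGeneric("coverageMatrix"))

#' @export
setGeneric("breadthMatrix", function(x) standardGeneric("breadthMatrix"))

#' @export
setGeneric("presenceCalls", function(x) standardGeneric("presenceCalls"))

#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))

#' Accessors
#'
#' Convenience accessors for the package's central classes.
#'
#' @param x an object of the documented class.
#' @name accessors
#' @aliases sizeClass genomeGC representatives clusters spacers
#'   coverageMatrix breadthMatrix presenceCalls zScores
NULL

#' @rdname accessors
#' @export
setMethod("sizeClass", "PhageGenomeSet", function(x)
    as.character(mcols(x)$size_class))

#' @rdname accessors
#' @export
setMethod("genomeGC", "PhageGenomeSet", function(x) mcols(x)$gc)

#' @rdname accessors
#' @export
setMethod("representatives", "DereplicationResult",
    function(x) x@representatives)

#' @rdname accessors
#' @export
setMethod("clusters", "DereplicationResult", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("spacers", "CrisprArray", function(x) x@spacers)

#' @rdname accessors
#' @export
setMethod("coverageMatrix", "AbundanceExperiment", function(x)
    SummarizedExperiment::assay(x, "cpg"))

#' @rdname accessors
#' @export
setMethod("breadthMatrix", "AbundanceExperiment", function(x)
    SummarizedExperiment::assay(x, "breadth"))

#' @rdname accessors
#' @export
setMethod("presenceCalls", "AbundanceExperiment", function(x)
    SummarizedExperiment::assay(x, "present"))

#' @rdname accessors
#' @export
setMethod("zScores", "AbundanceExperiment", function(x)
    SummarizedExperiment::assay(x, "zscore"))

setMethod("show", "PhageGenomeSet", function(object) {
    cat("PhageGenomeSet with", length(object), "genomes\n")
    if (length(object)) {
        len <- Biostrings::width(object)
        cat(sprintf("  length: %d-%d bp (median %.0f)\n",
                    min(len), max(len), stats::median(len)))
        tab <- table(factor(sizeClass(object),
                            c("miniphage", "regular", "megaphage")))
        cat(sprintf("  size classes: %d miniphage / %d regular / %d megaphage\n",
                    tab[["miniphage"]], tab[["regular"]], tab[["megaphage"]]))
    }
    invisible(object)
})

setMethod("show", "DereplicationResult", function(object) {
    cat("DereplicationResult:", length(unlist(object@clusters)),
        "genomes in", length(object@clusters), "clusters\n")
    sz <- lengths(object@clusters)
    if (length(sz))
        cat(sprintf("  cluster sizes: %s\n",
                    paste(sort(sz, decreasing = TRUE), collapse = ", ")))
    invisible(object)
})

setMethod("show", "CrisprArray", function(object) {
    cat(sprintf("CrisprArray on %s: %d repeats (%d bp consensus), %d spacers\n",
                object@hostId, length(object@repeats),
                nchar(object@repeatConsensus), length(object@spacers)))
    invisible(object)
})

setMethod("show", "MetagenomeSample", function(object) {
    cat(sprintf("MetagenomeSample %s: %d reads, %.3g bases\n",
                object@id, length(object@reads), object@totalBases))
    invisible(object)
})
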