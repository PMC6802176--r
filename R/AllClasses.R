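#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges reduce coverage width start end
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Set of candidate complete phage genomes
#'
#' Extends \linkS4class{DNAStringSet}. Each element is an origin-trimmed
#' circular phage genome; per-genome annotation lives in \code{mcols()}:
#' \code{raw_len} (assembled contig length before trimming),
#' \code{overlap_len} (terminal direct repeat removed), \code{gc}
#' (fraction G+C over unambiguous bases), \code{size_class}
#' (\code{"miniphage"} < 15 kb, \code{"megaphage"} > 200 kb, else
#' \code{"regular"}), \code{n_orfs}, and \code{source_sample}.
#'
#' @export
setClass("PhageGenomeSet", contains = "DNAStringSet")

setValidity("PhageGenomeSet", function(object) {
    mc <- mcols(object)
    need <- c("gc", "size_class")
    if (length(object) && (is.null(mc) || !all(need %in% colnames(mc))))
        return("mcols() must contain at least 'gc' and 'size_class'")
    if (length(object)) {
        len <- Biostrings::width(object)
        sc <- as.character(mc$size_class)
        bad <- (sc == "miniphage" & len >= 15000) |
               (sc == "megaphage" & len <= 200000) |
               (sc == "regular" & (len < 15000 | len > 200000))
        if (any(bad))
            return("size_class inconsistent with genome length thresholds")
    }
    TRUE
})

#' Single-linkage dereplication result
#'
#' Clusters of near-identical phage genomes (mutual aligned coverage >= 95%
#' from hits at > 95% nucleotide identity and e-value < 1e-3), merged by
#' single linkage. The longest member of each cluster is its representative
#' (ties broken by lexicographically smallest id).
#'
#' @slot clusters list of character vectors of member genome ids, one per
#'   cluster, sorted by representative id.
#' @slot representatives character vector, one id per cluster.
#' @slot comparisons data.frame of the pairwise comparisons that supported
#'   clustering (a_id, b_id, coverage_a, coverage_b, mean_identity).
#' @export
setClass("DereplicationResult",
    representation(clusters = "list",
                   representatives = "character",
                   comparisons = "data.frame"))

setValidity("DereplicationResult", function(object) {
    if (length(object@clusters) != length(object@representatives))
        return("one representative per cluster required")
    ok <- mapply(function(cl, rep) rep %in% cl,
                 object@clusters, object@representatives)
    if (length(ok) && !all(ok))
        return("each representative must belong to its cluster")
    memb <- unlist(object@clusters, use.names = FALSE)
    if (anyDuplicated(memb))
        return("clusters must partition the input genomes")
    TRUE
})

#' A CRISPR repeat/spacer array detected in a host genome
#'
#' @slot hostId id of the genome carrying the array.
#' @slot repeatConsensus consensus repeat sequence (majority base per column).
#' @slot repeats IRanges of the repeat copies on the host genome.
#' @slot spacers DNAStringSet of the spacers between consecutive repeats.
#' @slot spacerRanges IRanges of the spacers on the host genome.
#' @export
setClass("CrisprArray",
    representation(hostId = "character",
                   repeatConsensus = "character",
                   repeats = "IRanges",
                   spacers = "DNAStringSet",
                   spacerRanges = "IRanges"))

setValidity("CrisprArray", function(object) {
    nr <- length(object@repeats)
    if (nr < 3L) return("an array needs at least 3 repeat copies")
    if (length(object@spacers) != nr - 1L)
        return("number of spacers must equal number of repeats - 1")
    TRUE
})

#' Genome-by-sample abundance experiment
#'
#' Extends \linkS4class{SummarizedExperiment}. Assays: \code{cpg}
#' (coverage per gigabase of metagenome), \code{breadth} (fraction of
#' unmasked genome positions covered >= 1x), \code{present}
#' (breadth > 0.80, strict), and \code{zscore} (per-genome row Z-scores of
#' cpg across samples, population standard deviation; constant rows map
#' to zero). Sample metadata (date, depth, temperature) lives in
#' \code{colData()}.
#'
#' @export
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
    a <- SummarizedExperiment::assays(object)
    need <- c("cpg", "breadth", "present", "zscore")
    if (!all(need %in% names(a)))
        return(paste("assays must include", paste(need, collapse = ", ")))
    thr <- metadata(object)$presence_threshold
    if (is.null(thr)) thr <- 0.80
    if (!identical(unname(a$present), unname(a$breadth > thr)))
        return(sprintf(
            "present must equal breadth > %.2f (strict)", thr))
    TRUE
})

#' A sequenced metagenome sample
#'
#' Reads are held as a \linkS4class{DNAStringSet} (both mates, treated
#' independently downstream). \code{totalBases} is the summed read length
#' and is the denominator of coverage-per-gigabase normalisation.
#'
#' @slot id sample identifier.
#' @slot reads DNAStringSet of reads.
#' @slot totalBases numeric, total sequenced bases in the sample.
#' @slot sampleData list with optional typed fields \code{date},
#'   \code{depth_m}, \code{temperature_C}, \code{depth_label}.
#' @export
setClass("MetagenomeSample",
    representation(id = "character",
                   reads = "DNAStringSet",
                   totalBases = "numeric",
                   sampleData = "list"))

setValidity("MetagenomeSample", function(object) {
    if (length(object@reads) &&
        !isTRUE(all.equal(object@totalBases,
                          sum(Biostrings::width(object@reads)))))
        return("totalBases must equal the summed read lengths")
    TRUE
})
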