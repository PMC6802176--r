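#' @include seqcore-translated.R
NULL

#' Greedy incremental protein clustering
#'
#' Proteins are sorted by length (descending, ties by id) and processed
#' in order: each joins the first existing cluster whose representative
#' it matches at >= \code{identity_level} percent identity over >=
#' \code{min_coverage} of the shorter sequence (local alignment),
#' otherwise it founds a new cluster. Cluster representatives are
#' therefore always the longest members, and the procedure is
#' deterministic. Dataset labels (for cross-habitat novelty counting)
#' are taken from \code{mcols(proteins)$dataset} or "id|dataset" names.
#'
#' @param proteins an AAStringSet.
#' @param identity_level percent identity threshold (canonically 30 or
#'   60; any value accepted).
#' @param min_coverage minimum aligned fraction of the shorter sequence
#'   (default 0.8).
#' @return data.frame: cluster_id, representative, member, dataset,
#'   identity_to_rep.
#' @export
clusterProteins <- function(proteins, identity_level = 30,
                            min_coverage = 0.8) {
    if (!length(proteins)) return(data.frame(
        cluster_id = integer(), representative = character(),
        member = character(), dataset = character(),
        identity_to_rep = numeric()))
    ids <- names(proteins)
    if (is.null(ids)) ids <- sprintf("prot%04d", seq_along(proteins))
    ds <- mcols(proteins)$dataset
    if (is.null(ds)) {
        parts <- strsplit(ids, "|", fixed = TRUE)
        ds <- vapply(parts, function(p)
            if (length(p) >= 2L) p[2L] else NA_character_, "")
        ids <- vapply(parts, `[[`, "", 1L)
    }
    B <- .subst_matrix("BLOSUM45")
    aa <- gsub("[*]", "", as.character(proteins))
    len <- nchar(aa)
    o <- order(-len, ids)
    rep_idx <- integer()       # indices (into o-ordered set) of reps
    assign <- integer(length(o))
    ident <- numeric(length(o))
    for (pos in seq_along(o)) {
        i <- o[pos]
        placed <- FALSE
        for (ci in seq_along(rep_idx)) {
            r <- rep_idx[ci]
            pa <- Biostrings::pairwiseAlignment(
                AAString(aa[i]), AAString(aa[r]), type = "local",
                substitutionMatrix = B, gapOpening = 10,
                gapExtension = 1)
            alen <- Biostrings::nchar(pa)
            shorter <- min(len[i], len[r])
            if (alen < min_coverage * shorter) next
            pid <- Biostrings::nmatch(pa) / alen * 100
            if (pid >= identity_level) {
                assign[i] <- ci
                ident[i] <- pid
                placed <- TRUE
                break
            }
        }
        if (!placed) {
            rep_idx <- c(rep_idx, i)
            assign[i] <- length(rep_idx)
            ident[i] <- 100
        }
    }
    data.frame(cluster_id = assign, representative = ids[rep_idx[assign]],
               member = ids, dataset = ds, identity_to_rep = ident,
               stringsAsFactors = FALSE)[order(assign, ids), ]
}

#' Per-dataset unique protein cluster counts
#'
#' A cluster is unique to dataset D iff every member carries label D --
#' the novelty measure used when comparing phage protein space across
#' habitats.
#'
#' @param clusters data.frame from [clusterProteins()].
#' @param datasets labels to report (default: all observed).
#' @return named integer vector of unique-cluster counts.
#' @export
uniqueClusterCounts <- function(clusters, datasets = NULL) {
    if (is.null(datasets)) datasets <- sort(unique(clusters$dataset))
    per <- split(clusters$dataset, clusters$cluster_id)
    uniq <- vapply(per, function(d) {
        u <- unique(d)
        if (length(u) == 1L) u else NA_character_
    }, "")
    stats::setNames(vapply(datasets, function(d)
        sum(uniq == d, na.rm = TRUE), 0L), datasets)
}

#' Genome-level summary table and histograms
#'
#' @param genomes a PhageGenomeSet (or named DNAStringSet).
#' @return data.frame: id, length, gc, size_class.
#' @export
genomeSummary <- function(genomes) {
    if (!length(genomes))
        return(data.frame(id = character(), length = integer(),
                          gc = numeric(), size_class = character()))
    len <- Biostrings::width(genomes)
    gc <- if (!is.null(mcols(genomes)$gc)) mcols(genomes)$gc
          else gcContent(genomes)
    data.frame(id = names(genomes), length = len, gc = gc,
               size_class = classifySize(len), stringsAsFactors = FALSE)
}

#' Histogram export for length/GC distributions
#'
#' @param values numeric vector.
#' @param breaks number of bins or break vector (passed to hist).
#' @return data.frame: bin_start, bin_end, count.
#' @export
histogramTable <- function(values, breaks = 30) {
    h <- graphics::hist(values, breaks = breaks, plot = FALSE)
    data.frame(bin_start = utils::head(h$breaks, -1),
               bin_end = utils::tail(h$breaks, -1), count = h$counts)
}
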