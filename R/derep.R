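#' @include seqcore-align.R
NULL

# default hit filter for dereplication: e-value < 1e-3, identity > 95%
.derep_params <- function() {
    alignerParams("nucleotide", min_identity = 0,
                  min_alignment_length = 100L, max_expectation = 1e-3)
}

#' Pairwise genome comparison for dereplication
#'
#' Aligns two genomes and summarises the significant hits (e-value
#' < \code{max_expectation}, identity > \code{min_hit_identity}, both
#' strict) into per-genome aligned coverage and a length-weighted mean
#' identity. Overlapping hit intervals are merged before summing, so
#' coverage cannot exceed 1.
#'
#' @param a,b DNAString or character genome sequences.
#' @param a_id,b_id genome ids.
#' @param min_hit_identity per-hit percent identity floor (strict >;
#'   default 95).
#' @param max_expectation significance cutoff (strict <; default 1e-3).
#' @param params aligner parameters.
#' @param subject_profile optional precomputed seeding tables for
#'   \code{b}.
#' @return data.frame row: a_id, b_id, coverage_a, coverage_b,
#'   mean_identity.
#' @export
compareGenomePair <- function(a, b, a_id = "a", b_id = "b",
                              min_hit_identity = 95,
                              max_expectation = 1e-3,
                              params = .derep_params(),
                              subject_profile = NULL) {
    h <- nucAlign(a, b, params, a_id, b_id,
                  subject_profile = subject_profile)
    h <- h[h$pident > min_hit_identity & h$evalue < max_expectation, ,
           drop = FALSE]
    la <- nchar(.as_seq_char(a))
    lb <- nchar(.as_seq_char(b))
    if (!nrow(h))
        return(data.frame(a_id = a_id, b_id = b_id, coverage_a = 0,
                          coverage_b = 0, mean_identity = NA_real_,
                          stringsAsFactors = FALSE))
    cov_a <- sum(width(reduce(IRanges(h$qstart, h$qend)))) / la
    cov_b <- sum(width(reduce(IRanges(h$sstart, h$send)))) / lb
    data.frame(a_id = a_id, b_id = b_id,
               coverage_a = cov_a, coverage_b = cov_b,
               mean_identity = sum(h$pident * h$length) / sum(h$length),
               stringsAsFactors = FALSE)
}

# connected components over an edge list (single linkage)
.components <- function(ids, from, to) {
    comp <- seq_along(ids)
    names(comp) <- ids
    find <- function(i) {
        while (comp[i] != i) {
            comp[i] <<- comp[comp[i]]
            i <- comp[i]
        }
        i
    }
    for (k in seq_along(from)) {
        ri <- find(match(from[k], ids))
        rj <- find(match(to[k], ids))
        if (ri != rj) comp[ri] <- rj
    }
    roots <- vapply(seq_along(ids), find, 0L)
    split(ids, roots)
}

#' Single-linkage dereplication clustering
#'
#' Two genomes are linked when the aligned coverage of \emph{both} is
#' >= \code{min_coverage} (computed from hits at > 95\% identity and
#' e-value < 1e-3); linked pairs are merged into clusters by single
#' linkage (connected components). The longest member of each cluster is
#' its representative; equal lengths are broken by lexicographically
#' smallest id. Clusters are returned sorted by representative id, so
#' output is independent of input order.
#'
#' @param genomes a named DNAStringSet (or PhageGenomeSet).
#' @param min_coverage mutual-coverage threshold (default 0.95,
#'   inclusive).
#' @param min_hit_identity,max_expectation per-hit filters (see
#'   [compareGenomePair()]).
#' @param params aligner parameters.
#' @return a \linkS4class{DereplicationResult}.
#' @export
clusterGenomes <- function(genomes, min_coverage = 0.95,
                           min_hit_identity = 95,
                           max_expectation = 1e-3,
                           params = .derep_params()) {
    if (length(genomes) < 1L) stop("need at least one genome")
    ids <- names(genomes)
    if (is.null(ids)) stop("genomes must be named")
    n <- length(genomes)
    cmp <- list()
    from <- character(); to <- character()
    if (n > 1L) {
        chr <- as.character(genomes)
        prof <- lapply(chr, .nuc_subject_profile, params = params)
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            pc <- compareGenomePair(chr[i], chr[j], ids[i], ids[j],
                                    min_hit_identity, max_expectation,
                                    params, subject_profile = prof[[j]])
            cmp[[length(cmp) + 1L]] <- pc
            if (pc$coverage_a >= min_coverage &&
                pc$coverage_b >= min_coverage) {
                from <- c(from, ids[i]); to <- c(to, ids[j])
            }
        }
    }
    comps <- .components(ids, from, to)
    len <- stats::setNames(Biostrings::width(genomes), ids)
    reps <- vapply(comps, function(m) {
        m <- m[order(-len[m], m)]
        m[1L]
    }, character(1))
    o <- order(reps)
    new("DereplicationResult",
        clusters = lapply(unname(comps[o]), function(m) sort(m)),
        representatives = unname(reps[o]),
        comparisons = if (length(cmp)) do.call(rbind, cmp)
                      else data.frame())
}

#' Dereplicate a genome set
#'
#' Runs [clusterGenomes()] and returns one representative genome per
#' cluster together with the clustering and a cluster manifest mapping
#' each member to its representative (with coverage and identity to the
#' representative where computed).
#'
#' @inheritParams clusterGenomes
#' @return list with \code{representatives} (subset of \code{genomes}),
#'   \code{result} (DereplicationResult), and \code{manifest}
#'   (data.frame: cluster_id, representative, member, coverage_to_rep,
#'   identity_to_rep).
#' @export
dereplicate <- function(genomes, min_coverage = 0.95,
                        min_hit_identity = 95, max_expectation = 1e-3,
                        params = .derep_params()) {
    res <- clusterGenomes(genomes, min_coverage, min_hit_identity,
                          max_expectation, params)
    cmp <- res@comparisons
    man <- list()
    for (ci in seq_along(res@clusters)) {
        rep <- res@representatives[ci]
        for (m in res@clusters[[ci]]) {
            cov <- idn <- NA_real_
            if (m == rep) { cov <- 1; idn <- 100 }
            else if (nrow(cmp)) {
                r <- cmp[(cmp$a_id == rep & cmp$b_id == m) |
                         (cmp$a_id == m & cmp$b_id == rep), , drop = FALSE]
                if (nrow(r)) {
                    cov <- if (r$a_id[1L] == m) r$coverage_a[1L]
                           else r$coverage_b[1L]
                    idn <- r$mean_identity[1L]
                }
            }
            man[[length(man) + 1L]] <- data.frame(
                cluster_id = ci, representative = rep, member = m,
                coverage_to_rep = cov, identity_to_rep = idn,
                stringsAsFactors = FALSE)
        }
    }
    list(representatives = genomes[res@representatives],
         result = res,
         manifest = do.call(rbind, man))
}
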