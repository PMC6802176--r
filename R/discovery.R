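#' @include seqcore-orfs.R
NULL

#' Detect a circular genome signature on an assembled contig
#'
#' A contig assembled from a circular template carries a terminal direct
#' repeat: its first L bases reappear at its end. The contig is called
#' circular iff such a repeat of length >= \code{min_overlap_bp} exists,
#' allowing at most 1 mismatch per 100 bp of repeat. The trailing repeat
#' copy is trimmed off so every genome base is counted once.
#'
#' Candidate repeat lengths are anchored by exact occurrences of short
#' prefix words near the contig end (several anchor offsets are tried so
#' a single mismatch in the first word cannot hide a repeat), then
#' verified base-by-base over the full repeat length.
#'
#' @param contig DNAString or character.
#' @param min_overlap_bp minimum terminal repeat length (default 20).
#' @return list with \code{is_circular}, \code{overlap_len} (0 when not
#'   circular), and \code{trimmed} (a DNAString, only when circular).
#' @export
detectCircularity <- function(contig, min_overlap_bp = 20L) {
    chr <- .as_seq_char(contig)
    n <- nchar(chr)
    if (n <= min_overlap_bp)
        stop("contig must be longer than min_overlap_bp")
    w <- min(16L, min_overlap_bp)
    craw <- charToRaw(chr)
    best <- 0L
    for (off in c(0L, w, 2L * w)) {
        if (off + w > min(n %/% 2L, 10000L)) break
        anchor <- substr(chr, off + 1L, off + w)
        if (grepl("N", anchor, fixed = TRUE)) next
        hits <- gregexpr(anchor, chr, fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        for (p in hits) {
            p0 <- p - off          # putative start of the trailing copy
            if (p0 <= n %/% 2L) next
            L <- n - p0 + 1L
            if (L < min_overlap_bp || L <= best) next
            mm <- sum(craw[seq_len(L)] != craw[p0:n])
            if (mm <= floor(L / 100)) best <- L
        }
    }
    if (best == 0L)
        return(list(is_circular = FALSE, overlap_len = 0L))
    list(is_circular = TRUE, overlap_len = best,
         trimmed = DNAString(substr(chr, 1L, n - best)))
}

#' Size class of a phage genome
#'
#' Miniphage below 15 kb, megaphage above 200 kb (both strict), regular
#' in between.
#'
#' @param length_bp genome length(s) in bp (> 0).
#' @return character vector of "miniphage"/"regular"/"megaphage".
#' @export
classifySize <- function(length_bp) {
    stopifnot(all(length_bp > 0))
    ifelse(length_bp < 15000, "miniphage",
           ifelse(length_bp > 200000, "megaphage", "regular"))
}

#' Select complete (circular) phage genome candidates
#'
#' Screens assembled contigs for terminal direct repeats, trims the
#' trailing repeat copy, and retains circular contigs whose trimmed
#' length exceeds \code{min_length_bp} (strict, matching the "> 10 Kb"
#' rule). Each retained genome is annotated with GC content, ORF count,
#' and size class. Output order is stable: decreasing length, then id.
#'
#' @param contigs a named DNAStringSet of assembled contigs.
#' @param min_length_bp minimum trimmed genome length (default 10000,
#'   exclusive).
#' @param min_overlap_bp minimum terminal repeat length (default 20).
#' @param keep optional character vector of contig ids: when supplied,
#'   only these contigs are considered (hook for an external
#'   phage-confirmation filter).
#' @param min_orf_aa minimum ORF length passed to [findOrfs()].
#' @param source_sample sample label(s) recorded per genome.
#' @return a \linkS4class{PhageGenomeSet}.
#' @export
selectPhageCandidates <- function(contigs, min_length_bp = 10000L,
                                  min_overlap_bp = 20L, keep = NULL,
                                  min_orf_aa = 30L, source_sample = NA) {
    if (is.null(names(contigs)))
        names(contigs) <- sprintf("contig%04d", seq_along(contigs))
    if (!is.null(keep)) contigs <- contigs[names(contigs) %in% keep]
    src <- rep_len(source_sample, length(contigs))
    rows <- list()
    for (i in seq_along(contigs)) {
        cc <- detectCircularity(contigs[[i]], min_overlap_bp)
        if (!cc$is_circular) next
        g <- cc$trimmed
        if (length(g) <= min_length_bp) next
        orfs <- findOrfs(g, min_orf_aa, topology = "circular",
                         id = names(contigs)[i])
        rows[[length(rows) + 1L]] <- list(
            id = names(contigs)[i], seq = as.character(g),
            raw_len = nchar(as.character(contigs[[i]])),
            overlap_len = cc$overlap_len,
            gc = gcContent(as.character(g)),
            n_orfs = length(orfs), source_sample = src[i])
    }
    if (!length(rows)) {
        out <- new("PhageGenomeSet", DNAStringSet())
        return(out)
    }
    d <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
    d <- d[order(-nchar(d$seq), d$id), , drop = FALSE]
    ss <- DNAStringSet(d$seq)
    names(ss) <- d$id
    mcols(ss) <- DataFrame(raw_len = d$raw_len,
                           overlap_len = d$overlap_len, gc = d$gc,
                           size_class = classifySize(nchar(d$seq)),
                           n_orfs = d$n_orfs,
                           source_sample = d$source_sample)
    new("PhageGenomeSet", ss)
}

#' Write a phage candidate manifest
#'
#' TSV companion to the trimmed-genome FASTA: id, raw contig length,
#' trimmed length, terminal repeat length, GC, size class, ORF count.
#'
#' @param genomes a PhageGenomeSet.
#' @param path output TSV path.
#' @export
writeCandidateManifest <- function(genomes, path) {
    mc <- mcols(genomes)
    d <- data.frame(id = names(genomes), raw_len = mc$raw_len,
                    trimmed_len = Biostrings::width(genomes),
                    overlap_len = mc$overlap_len,
                    gc = round(mc$gc, 4), size_class = mc$size_class,
                    n_orfs = mc$n_orfs, stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
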