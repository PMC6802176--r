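#' @include seqcore-utils.R
NULL

# kmer -> position table for exact seeding; k-mers containing ambiguous
# bases are dropped.
.kmer_table <- function(chr, k) {
    n <- nchar(chr)
    if (n < k) return(data.table(kmer = character(), pos = integer()))
    pos <- seq_len(n - k + 1L)
    km <- substring(chr, pos, pos + k - 1L)
    if (grepl("N", chr, fixed = TRUE)) {
        keep <- !grepl("N", km, fixed = TRUE)
        km <- km[keep]
        pos <- pos[keep]
    }
    data.table(kmer = km, pos = pos)
}

# Precomputed seeding tables for a subject sequence (both strands);
# lets one-vs-many callers index each subject once.
.nuc_subject_profile <- function(subject, params) {
    schr <- .as_seq_char(subject)
    rc <- as.character(reverseComplement(DNAString(schr)))
    list(plus = list(chr = schr, tab = .kmer_table(schr,
                                                  params$seed_length)),
         minus = list(chr = rc, tab = .kmer_table(rc,
                                                  params$seed_length)))
}

# Maximal high-scoring ungapped segments along one diagonal.
# m: logical match vector; segments are split where a mismatch run alone
# would exceed the X-drop, then trimmed to start/end on matches. Only
# segments containing a seed position are evaluated (others cannot pass
# the seed-length filter anyway).
.diag_segments <- function(m, match, mismatch, xdrop, seed_len,
                           seed_pos = NULL) {
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    brk <- floor(xdrop / abs(mismatch)) + 1L
    breaking <- (!r$values) & (r$lengths >= brk)
    seg_id <- cumsum(c(0L, breaking[-length(breaking)])) + 1L
    seg_id[breaking] <- NA_integer_
    cand <- unique(seg_id[!is.na(seg_id)])
    if (!is.null(seed_pos)) {
        seed_run <- findInterval(seed_pos, starts)
        cand <- intersect(cand, unique(seg_id[seed_run]))
    }
    res <- list()
    for (sid in cand) {
        idx <- which(!is.na(seg_id) & seg_id == sid)
        tidx <- idx[r$values[idx]]
        if (!length(tidx)) next
        if (max(r$lengths[tidx]) < seed_len) next
        s0 <- starts[idx[1L]]; e0 <- ends[idx[length(idx)]]
        # maximal-scoring subsegment: random flanks score negatively
        # and are shed, as X-drop extension would
        x <- ifelse(m[s0:e0], match, mismatch)
        best <- .best_subarray(x)
        if (is.null(best)) next
        s <- s0 + best[1L] - 1L
        e <- s0 + best[2L] - 1L
        mseg <- m[s:e]
        rr <- rle(mseg)
        if (max(rr$lengths[rr$values]) < seed_len) next
        res[[length(res) + 1L]] <- c(s, e, sum(mseg))
    }
    if (!length(res)) return(NULL)
    do.call(rbind, res)
}

# One strand of seed-and-extend nucleotide alignment. Returns ungapped
# segments as a data.table with query/subject coordinates.
.nuc_align_strand <- function(qchr, schr, params, st = NULL,
                              qt = NULL) {
    k <- params$seed_length
    nq <- nchar(qchr); ns <- nchar(schr)
    if (is.null(qt)) qt <- .kmer_table(qchr, k)
    if (is.null(st)) st <- .kmer_table(schr, k)
    if (!nrow(qt) || !nrow(st)) return(NULL)
    seeds <- merge(qt, st, by = "kmer", allow.cartesian = TRUE,
                   suffixes = c("_q", "_s"))
    if (!nrow(seeds)) return(NULL)
    seeds$dg <- seeds$pos_s - seeds$pos_q
    bydiag <- split(seeds$pos_q, seeds$dg)
    diags <- as.integer(names(bydiag))
    qraw <- charToRaw(qchr)
    sraw <- charToRaw(schr)
    acgt <- charToRaw("ACGT")
    qok <- qraw %in% acgt
    sok <- sraw %in% acgt
    out <- vector("list", length(diags))
    for (i in seq_along(diags)) {
        dg <- diags[i]
        qlo <- max(1L, 1L - dg); qhi <- min(nq, ns - dg)
        if (qhi - qlo + 1L < k) next
        qi <- qlo:qhi; si <- qi + dg
        m <- (qraw[qi] == sraw[si]) & qok[qi] & sok[si]
        seg <- .diag_segments(m, params$match, params$mismatch,
                              params$xdrop, k,
                              seed_pos = bydiag[[i]] - qlo + 1L)
        if (is.null(seg)) next
        out[[i]] <- data.table(
            qstart = qlo + seg[, 1L] - 1L, qend = qlo + seg[, 2L] - 1L,
            sstart = qlo + seg[, 1L] - 1L + dg,
            send = qlo + seg[, 2L] - 1L + dg,
            matches = seg[, 3L], gapopen = 0L)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) return(NULL)
    data.table::rbindlist(out)
}

# Chain collinear segments on nearby diagonals into gapped hits.
.chain_segments <- function(seg, params) {
    if (nrow(seg) < 2L) return(seg)
    seg <- seg[order(seg$qstart, seg$sstart), ]
    merged <- TRUE
    while (merged && nrow(seg) > 1L) {
        merged <- FALSE
        for (i in seq_len(nrow(seg) - 1L)) {
            for (j in (i + 1L):nrow(seg)) {
                qgap <- seg$qstart[j] - seg$qend[i] - 1L
                sgap <- seg$sstart[j] - seg$send[i] - 1L
                dshift <- abs(qgap - sgap)
                if (qgap >= 0L && qgap <= 100L && sgap >= 0L &&
                    sgap <= 100L && dshift >= 1L && dshift <= params$band) {
                    seg$qend[i] <- seg$qend[j]
                    seg$send[i] <- seg$send[j]
                    seg$matches[i] <- seg$matches[i] + seg$matches[j]
                    seg$gapopen[i] <- seg$gapopen[i] + seg$gapopen[j] + 1L
                    seg <- seg[-j, ]
                    merged <- TRUE
                    break
                }
            }
            if (merged) break
        }
    }
    seg
}

#' Seed-and-extend local nucleotide alignment
#'
#' Aligns a query against both strands of a subject by exact k-mer
#' seeding followed by ungapped X-drop extension along each seeded
#' diagonal; collinear segments on nearby diagonals are chained into
#' gapped hits. All hits satisfying the parameter thresholds are
#' returned, sorted by score (descending); output is deterministic.
#' The query strand is always "+"; minus-strand hits carry
#' \code{strand == "-"} with subject coordinates ascending on the plus
#' strand of the subject.
#'
#' @param query,subject DNAString or character sequences.
#' @param params an [alignerParams()] object (nucleotide mode).
#' @param query_id,subject_id ids used in the hit table.
#' @param subject_profile optional precomputed subject seeding tables
#'   (internal; lets one-vs-many callers index each subject once).
#' @return a hits data.frame (see [writeHits()] for columns).
#' @export
nucAlign <- function(query, subject, params = alignerParams("nucleotide"),
                     query_id = "query", subject_id = "subject",
                     subject_profile = NULL) {
    stopifnot(params$mode == "nucleotide")
    qchr <- .as_seq_char(query)
    if (is.null(subject_profile))
        subject_profile <- .nuc_subject_profile(subject, params)
    schr <- subject_profile$plus$chr
    if (!nchar(qchr) || !nchar(schr)) stop("sequences must be non-empty")
    ns <- nchar(schr)
    qt <- .kmer_table(qchr, params$seed_length)
    res <- list()
    for (strand in c("+", "-")) {
        sp <- if (strand == "+") subject_profile$plus
              else subject_profile$minus
        stgt <- sp$chr
        seg <- .nuc_align_strand(qchr, stgt, params, st = sp$tab,
                                 qt = qt)
        if (is.null(seg) || !nrow(seg)) next
        seg <- .chain_segments(as.data.frame(seg), params)
        if (strand == "-") {
            s1 <- ns - seg$send + 1L
            s2 <- ns - seg$sstart + 1L
            seg$sstart <- s1
            seg$send <- s2
        }
        seg$strand <- strand
        res[[strand]] <- seg
    }
    if (!length(res)) return(.empty_hits())
    h <- do.call(rbind, res)
    len <- pmax(h$qend - h$qstart, h$send - h$sstart) + 1L
    mism <- len - h$matches - (len - (h$qend - h$qstart + 1L)) -
        (len - (h$send - h$sstart + 1L))
    mism <- pmax(mism, 0L)
    score <- h$matches * params$match + mism * params$mismatch -
        h$gapopen * params$gap_open -
        (len - (h$matches + mism)) * params$gap_extend
    pident <- h$matches / len * 100
    ev <- expectationValue(pmax(score, 0), nchar(qchr), ns, params)
    hits <- data.frame(qseqid = query_id, sseqid = subject_id,
                       pident = pident, length = as.integer(len),
                       mismatch = as.integer(mism), gapopen = h$gapopen,
                       qstart = h$qstart, qend = h$qend,
                       sstart = h$sstart, send = h$send,
                       evalue = ev, score = score, strand = h$strand,
                       mode = "nucleotide", stringsAsFactors = FALSE)
    hits <- hits[hits$length >= params$min_alignment_length &
                 hits$pident >= params$min_identity &
                 hits$evalue <= params$max_expectation, , drop = FALSE]
    hits <- hits[order(-hits$score, hits$qstart, hits$sstart), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    hits
}
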