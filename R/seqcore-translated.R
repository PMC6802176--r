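#' @include seqcore-align.R
NULL

# Substitution matrix with rows/cols for all residues we can emit,
# including 'X' and '*'. Falls back to -4 for pairs absent from the
# named matrix and +1 for stop-stop, the usual tabular-search
# convention. Cached per matrix name.
.subst_cache <- new.env(parent = emptyenv())
.subst_matrix <- function(name = "BLOSUM45") {
    if (!is.null(.subst_cache[[name]])) return(.subst_cache[[name]])
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    B <- e[[name]]
    want <- unique(c(rownames(B), "X", "*"))
    M <- matrix(-4, length(want), length(want),
                dimnames = list(want, want))
    M[rownames(B), colnames(B)] <- B
    if (!"*" %in% rownames(B)) M["*", "*"] <- 1
    M["X", ] <- pmin(M["X", ], 0)
    M[, "X"] <- pmin(M[, "X"], 0)
    .subst_cache[[name]] <- M
    M
}

# Translate the six frames of a nucleotide sequence (table 11).
# Returns a list of list(frame, aa) with aa a plain character string.
.six_frames <- function(chr) {
    gc11 <- Biostrings::getGeneticCode("11")
    translate_frames <- function(s, sign) {
        n <- nchar(s)
        lapply(1:3, function(f) {
            ncod <- (n - f + 1L) %/% 3L
            if (ncod < 1L) return(list(frame = sign * f, aa = ""))
            dna <- Biostrings::subseq(DNAString(s), f, f + 3L * ncod - 1L)
            aa <- as.character(Biostrings::translate(
                dna, genetic.code = gc11, if.fuzzy.codon = "X",
                no.init.codon = TRUE))
            list(frame = sign * f, aa = aa)
        })
    }
    rchr <- as.character(reverseComplement(DNAString(chr)))
    c(translate_frames(chr, 1L), translate_frames(rchr, -1L))
}

# aa string -> integer indices into the substitution matrix
.aa_index <- function(aa, B) {
    lut <- integer(128)
    lut[utf8ToInt(paste(rownames(B), collapse = ""))] <- seq_len(nrow(B))
    idx <- lut[utf8ToInt(aa)]
    idx[idx == 0L] <- match("X", rownames(B))
    idx
}

# map an aa interval [p1, p2] on frame f back to 1-based nt coordinates
.frame_to_nt <- function(p1, p2, f, n) {
    g <- abs(f)
    if (f > 0L) c(g + 3L * (p1 - 1L), g + 3L * p2 - 1L)
    else c(n - (g + 3L * p2 - 1L) + 1L, n - (g + 3L * (p1 - 1L)) + 1L)
}

# Best-scoring subsegment (Kadane via cumulative sums) of a score vector.
# Returns c(start, end, score) or NULL if all-negative.
.best_subarray <- function(sc) {
    cs <- cumsum(sc)
    base <- cummin(c(0, cs[-length(cs)]))
    gain <- cs - base
    j <- which.max(gain)
    if (gain[j] <= 0) return(NULL)
    i <- if (j == 1L) 1L else {
        w <- which(c(0, cs[-length(cs)]) == base[j])
        w[w <= j][1L]
    }
    c(i, j, gain[j])
}

# Precomputed six-frame translation profile: frames, substitution-matrix
# index vectors, and the seeding k-mer table. Lets all-vs-all callers
# translate each genome once.
.translated_profile <- function(seq, params) {
    chr <- .as_seq_char(seq)
    B <- .subst_matrix(params$matrix)
    frames <- .six_frames(chr)
    k <- params$seed_length
    kt <- data.table::rbindlist(lapply(frames, function(fr) {
        t <- .kmer_table_aa(fr$aa, k)
        if (nrow(t)) t$frame <- fr$frame
        t
    }), fill = TRUE)
    iv <- lapply(frames, function(fr) .aa_index(fr$aa, B))
    names(iv) <- vapply(frames, `[[`, 0L, "frame")
    list(chr = chr, n = nchar(chr), kmers = kt, index = iv)
}

#' Translated (six-frame) local alignment of two nucleotide sequences
#'
#' Compares all six reading frames of \code{a} against all six of
#' \code{b} at the protein level: exact amino-acid k-mer seeding,
#' per-diagonal scoring with the configured substitution matrix, and
#' X-drop segmentation. Hits are filtered at
#' \code{expectation <= params$max_expectation}. \code{length} and
#' \code{pident} are protein-level (aa); \code{qstart}/\code{qend} and
#' \code{sstart}/\code{send} are mapped back to nucleotide coordinates
#' on the input sequences. Extra columns \code{qframe}/\code{sframe}
#' record the frames.
#'
#' @param a,b DNAString or character sequences (>= 3 bp).
#' @param params an [alignerParams()] object in translated mode; the
#'   default applies significance e <= 1e-3 with BLOSUM45.
#' @param a_id,b_id sequence ids for the hit table.
#' @param profile_a,profile_b optional precomputed six-frame profiles
#'   (internal; lets all-vs-all callers translate each genome once).
#' @return a hits data.frame.
#' @export
translatedAlign <- function(a, b,
                            params = alignerParams("translated",
                                                   max_expectation = 1e-3),
                            a_id = "a", b_id = "b",
                            profile_a = NULL, profile_b = NULL) {
    stopifnot(params$mode == "translated")
    if (is.null(profile_a)) profile_a <- .translated_profile(a, params)
    if (is.null(profile_b)) profile_b <- .translated_profile(b, params)
    na <- profile_a$n; nb <- profile_b$n
    if (na < 3L || nb < 3L) stop("sequences must be >= 3 bp")
    B <- .subst_matrix(params$matrix)
    k <- params$seed_length
    ta <- profile_a$kmers; tb <- profile_b$kmers
    if (!nrow(ta) || !nrow(tb)) return(.empty_hits("translated"))
    seeds <- merge(ta, tb, by = "kmer", allow.cartesian = TRUE,
                   suffixes = c("_a", "_b"))
    if (!nrow(seeds)) return(.empty_hits("translated"))
    seeds$dg <- seeds$pos_b - seeds$pos_a
    av_all <- profile_a$index
    bv_all <- profile_b$index
    # two-hit heuristic: a diagonal is only extended when it carries two
    # seeds within `two_hit_window` residues (or >= 3 seeds anywhere);
    # isolated random seeds are dropped, as in standard translated search
    two_hit_window <- 40L
    data.table::setorder(seeds, frame_a, frame_b, dg, pos_a)
    gs <- seeds[, list(n = .N,
                       mind = if (.N > 1L) min(diff(pos_a)) else NA_integer_,
                       pmin = min(pos_a), pmax = max(pos_a)),
                by = c("frame_a", "frame_b", "dg")]
    gs <- gs[gs$n >= 3L | (!is.na(gs$mind) & gs$mind <= two_hit_window)]
    maa <- max(1L, na %/% 3L)
    mbb <- max(1L, nb %/% 3L)
    res <- list()
    for (gi in seq_len(nrow(gs))) {
        f1 <- gs$frame_a[gi]; f2 <- gs$frame_b[gi]; dg <- gs$dg[gi]
        av <- av_all[[as.character(f1)]]
        bv <- bv_all[[as.character(f2)]]
        la <- length(av); lb <- length(bv)
        qlo <- max(1L, 1L - dg); qhi <- min(la, lb - dg)
        if (qhi < qlo) next
        wlo <- max(qlo, gs$pmin[gi] - 100L)
        whi <- min(qhi, gs$pmax[gi] + k - 1L + 100L)
        qi <- wlo:whi
        sc <- B[cbind(av[qi], bv[qi + dg])]
        # split where a negative stretch alone exceeds the X-drop
        r <- rle(sc >= 0)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        cs <- cumsum(sc)
        runsum <- cs[ends] - c(0, cs[ends])[seq_along(ends)]
        breaking <- (!r$values) & (runsum <= -params$xdrop)
        seg_id <- cumsum(c(0L, breaking[-length(breaking)])) + 1L
        seg_id[breaking] <- NA_integer_
        for (sid in unique(seg_id[!is.na(seg_id)])) {
            idx <- which(!is.na(seg_id) & seg_id == sid)
            slo <- starts[idx[1L]]; shi <- ends[idx[length(idx)]]
            best <- .best_subarray(sc[slo:shi])
            if (is.null(best)) next
            p1 <- wlo + slo + best[1L] - 2L
            p2 <- wlo + slo + best[2L] - 2L
            len <- p2 - p1 + 1L
            if (len < params$min_alignment_length) next
            score <- best[3L]
            ev <- expectationValue(score, maa, mbb, params)
            if (ev > params$max_expectation) next
            matches <- sum(av[p1:p2] == bv[(p1:p2) + dg])
            qnt <- .frame_to_nt(p1, p2, f1, na)
            snt <- .frame_to_nt(p1 + dg, p2 + dg, f2, nb)
            res[[length(res) + 1L]] <- data.frame(
                qseqid = a_id, sseqid = b_id,
                pident = matches / len * 100, length = len,
                mismatch = len - matches, gapopen = 0L,
                qstart = qnt[1L], qend = qnt[2L],
                sstart = snt[1L], send = snt[2L],
                evalue = ev, score = score,
                strand = if (sign(f1) == sign(f2)) "+" else "-",
                mode = "translated", qframe = f1, sframe = f2,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(res)) return(.empty_hits("translated"))
    hits <- do.call(rbind, res)
    hits <- hits[order(-hits$score, hits$qstart, hits$sstart), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    hits
}

# aa k-mer table; seeds containing X or stop are not used
.kmer_table_aa <- function(aa, k) {
    n <- nchar(aa)
    if (n < k) return(data.table(kmer = character(), pos = integer()))
    pos <- seq_len(n - k + 1L)
    km <- substring(aa, pos, pos + k - 1L)
    keep <- !grepl("[X*]", km)
    data.table(kmer = km[keep], pos = pos[keep])
}

#' Summed translated comparison score between two genomes
#'
#' The scores of all significant translated hits between \code{a} and
#' \code{b} added together; the raw ingredient of the Dice-normalised
#' proteomic distance. Self-comparisons include all significant
#' self-hits (paralogous off-diagonal hits included).
#'
#' @inheritParams translatedAlign
#' @return a single numeric score (0 when there are no significant hits).
#' @export
summedScore <- function(a, b,
                        params = alignerParams("translated",
                                               max_expectation = 1e-3),
                        a_id = "a", b_id = "b",
                        profile_a = NULL, profile_b = NULL) {
    h <- translatedAlign(a, b, params, a_id, b_id, profile_a, profile_b)
    if (!nrow(h)) 0 else sum(h$score)
}
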