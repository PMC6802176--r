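#' @include seqcore-utils.R
NULL

.START_CODONS <- c("ATG", "GTG", "TTG")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

# ORFs in the three forward frames of one strand of `chr`.
# Returns data.frame(start, end, frame, aa) with coordinates on `chr`.
.scan_frames <- function(chr, min_length_aa, max_span = Inf) {
    n <- nchar(chr)
    gc11 <- Biostrings::getGeneticCode("11")
    out <- list()
    for (f in 1:3) {
        ncod <- (n - f + 1L) %/% 3L
        if (ncod < min_length_aa) next
        cs <- f + 3L * (seq_len(ncod) - 1L)
        codons <- substring(chr, cs, cs + 2L)
        is_stop <- codons %in% .STOP_CODONS
        is_start <- codons %in% .START_CODONS
        # ORF regions run from just after a stop (or frame start) to the
        # next stop (or frame end); the ORF begins at the first start
        # codon in the region.
        bound <- c(0L, which(is_stop), ncod + 1L)
        for (b in seq_len(length(bound) - 1L)) {
            lo <- bound[b] + 1L
            hi <- bound[b + 1L]        # stop codon index, or ncod+1
            if (lo > ncod || hi - lo < min_length_aa) next
            reg <- lo:min(hi - 1L, ncod)
            st <- reg[is_start[reg]][1L]
            if (is.na(st)) next
            has_stop <- hi <= ncod
            last_cod <- if (has_stop) hi else ncod
            aa_len <- if (has_stop) hi - st else ncod - st + 1L
            if (aa_len < min_length_aa) next
            e <- cs[last_cod] + 2L
            s <- cs[st]
            if (e - s + 1L > max_span) next
            aa_cod <- codons[st:(st + aa_len - 1L)]
            aas <- gc11[aa_cod]
            aas[is.na(aas)] <- "X"      # ambiguous codons
            aa <- paste(aas, collapse = "")
            substr(aa, 1L, 1L) <- "M"   # alternative starts translate as M
            out[[length(out) + 1L]] <-
                data.frame(start = s, end = e, frame = f, aa = aa,
                           stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(start = integer(), end = integer(),
                          frame = integer(), aa = character()))
    do.call(rbind, out)
}

#' Call open reading frames
#'
#' A simplified prokaryotic gene caller standing in for a dedicated gene
#' predictor: maximal ORFs in all six frames, translation table 11, start
#' codons ATG/GTG/TTG (all translated as M), ending at a stop codon or at
#' the sequence end. On circular sequences ORFs may span the origin
#' (reported with \code{end > length(seq)}, wrapping around).
#'
#' @param seq a DNAString or character sequence.
#' @param min_length_aa minimum protein length in residues (default 30).
#' @param topology "linear" or "circular".
#' @param id source sequence id recorded in the result.
#' @return an \linkS4class{AAStringSet}; \code{mcols()} has
#'   \code{source}, \code{start}, \code{end} (1-based inclusive on the
#'   source), and \code{frame} (1..3 forward, -1..-3 reverse).
#' @export
findOrfs <- function(seq, min_length_aa = 30L,
                     topology = c("linear", "circular"), id = "seq") {
    topology <- match.arg(topology)
    if (min_length_aa < 1L) stop("min_length_aa must be >= 1")
    chr <- .as_seq_char(seq)
    n <- nchar(chr)
    scan_one <- function(s, circ) {
        if (circ) {
            # scan the doubled sequence; keep ORFs starting in the first
            # copy and no longer than the genome
            d <- .scan_frames(paste0(s, s), min_length_aa, max_span = n)
            d[d$start <= n, , drop = FALSE]
        } else .scan_frames(s, min_length_aa)
    }
    circ <- topology == "circular"
    fwd <- scan_one(chr, circ)
    rchr <- as.character(reverseComplement(DNAString(chr)))
    rev <- scan_one(rchr, circ)
    if (nrow(rev)) {
        # map [s,e] on the reverse complement back to the forward strand;
        # origin-spanning reverse ORFs keep end > n (wrapped)
        if (circ) {
            s2 <- 2L * n - rev$end + 1L
            e2 <- 2L * n - rev$start + 1L
            wrap <- s2 > n
            s2[wrap] <- s2[wrap] - n
            e2[wrap] <- e2[wrap] - n
        } else {
            s2 <- n - rev$end + 1L
            e2 <- n - rev$start + 1L
        }
        rev$start <- s2
        rev$end <- e2
        rev$frame <- -rev$frame
    }
    d <- rbind(fwd, rev)
    if (!nrow(d)) {
        res <- AAStringSet()
        mcols(res) <- DataFrame(source = character(), start = integer(),
                                end = integer(), frame = integer())
        return(res)
    }
    d <- d[order(d$start, d$end, d$frame), , drop = FALSE]
    key <- paste(d$start %% n, d$end %% n, d$frame)
    d <- d[!duplicated(key), , drop = FALSE]
    res <- AAStringSet(d$aa)
    names(res) <- sprintf("%s_orf%03d", id, seq_len(nrow(d)))
    mcols(res) <- DataFrame(source = id, start = d$start, end = d$end,
                            frame = d$frame)
    res
}
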