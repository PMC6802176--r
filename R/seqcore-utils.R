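#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   reverseComplement readDNAStringSet writeXStringSet alphabetFrequency
#' @importFrom data.table data.table setkey :=
NULL

.as_seq_char <- function(x) {
    if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
    toupper(x)
}

#' Aligner parameter sets
#'
#' Bundles the thresholds and scoring scheme used by the seed-and-extend
#' aligners ([nucAlign()], [translatedAlign()]). Defaults follow the
#' high-identity regimes the pipeline operates in: exact k-mer seeding
#' (13 bp nucleotide, 4 aa translated), +1/-2 nucleotide scoring, BLOSUM45
#' for translated comparisons, X-drop ungapped extension with collinear
#' chaining.
#'
#' @param mode "nucleotide" or "translated".
#' @param seed_length exact-match seed length (>= 8 nt / >= 3 aa).
#' @param min_identity minimum percent identity a reported hit must reach.
#'   Strictness is caller-controlled: hits at exactly this identity are
#'   kept; use e.g. 95 + 1e-9 where a strict ">" is required.
#' @param min_alignment_length minimum hit length (bp, or aa in translated
#'   mode).
#' @param max_expectation maximum Karlin-Altschul expectation value.
#' @param match,mismatch nucleotide match/mismatch scores.
#' @param gap_open,gap_extend penalties (positive numbers) charged when
#'   chaining collinear segments across nearby diagonals.
#' @param matrix substitution matrix name for translated mode ("BLOSUM45",
#'   "BLOSUM62", ...), resolved from Biostrings.
#' @param xdrop extension is terminated where the running score drops more
#'   than this below its maximum (score units of the active scheme).
#' @param band maximum diagonal offset bridged when chaining segments into
#'   gapped hits.
#' @return a list of class "AlignerParams".
#' @export
alignerParams <- function(mode = c("nucleotide", "translated"),
                          seed_length = NULL,
                          min_identity = 0,
                          min_alignment_length = NULL,
                          max_expectation = 10,
                          match = 1, mismatch = -2,
                          gap_open = 5, gap_extend = 2,
                          matrix = "BLOSUM45",
                          xdrop = NULL,
                          band = 50) {
    mode <- match.arg(mode)
    if (is.null(seed_length))
        seed_length <- if (mode == "nucleotide") 13L else 4L
    min_seed <- if (mode == "nucleotide") 8L else 3L
    if (seed_length < min_seed)
        stop("seed_length must be >= ", min_seed, " for ", mode, " mode")
    if (min_identity < 0 || min_identity > 100)
        stop("min_identity must be in [0, 100]")
    if (is.null(min_alignment_length)) min_alignment_length <- seed_length
    if (is.null(xdrop)) xdrop <- if (mode == "nucleotide") 30 else 40
    structure(list(mode = mode, seed_length = as.integer(seed_length),
                   min_identity = min_identity,
                   min_alignment_length = as.integer(min_alignment_length),
                   max_expectation = max_expectation,
                   match = match, mismatch = mismatch,
                   gap_open = gap_open, gap_extend = gap_extend,
                   matrix = matrix, xdrop = xdrop, band = band),
              class = "AlignerParams")
}

# Karlin-Altschul constants per scoring scheme (ungapped values;
# +1/-2 for nucleotide, per-matrix for protein). Calibration exactness
# is not required here: every downstream use is a threshold comparison
# at a generous margin.
.ka_constants <- function(params) {
    if (params$mode == "nucleotide") return(c(K = 0.46, lambda = 1.28))
    switch(params$matrix,
           BLOSUM45 = c(K = 0.0924, lambda = 0.229),
           BLOSUM62 = c(K = 0.041, lambda = 0.267),
           c(K = 0.041, lambda = 0.267))
}

#' Karlin-Altschul expectation value
#'
#' E = K * m * n * exp(-lambda * S): the expected number of chance local
#' alignments of score >= S between a query of length m and a subject of
#' length n. Strictly decreasing in S and linear in the search space m*n.
#'
#' @param score raw alignment score (>= 0).
#' @param query_len,subject_len sequence lengths (> 0).
#' @param params an [alignerParams()] object selecting the K/lambda pair
#'   for the active scoring scheme; alternatively supply `K` and `lambda`
#'   directly.
#' @param K,lambda optional explicit constants (override `params`).
#' @return numeric expectation value (vectorised over `score`).
#' @export
expectationValue <- function(score, query_len, subject_len,
                             params = alignerParams(), K = NULL,
                             lambda = NULL) {
    if (any(query_len <= 0) || any(subject_len <= 0))
        stop("sequence lengths must be positive")
    if (any(score < 0)) stop("score must be >= 0")
    if (is.null(K) || is.null(lambda)) {
        kc <- .ka_constants(params)
        if (is.null(K)) K <- kc[["K"]]
        if (is.null(lambda)) lambda <- kc[["lambda"]]
    }
    K * as.numeric(query_len) * as.numeric(subject_len) *
        exp(-lambda * score)
}

#' GC content of a nucleotide sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); ambiguous bases (N) are excluded from
#' both numerator and denominator.
#'
#' @param seq a DNAString/DNAStringSet or character vector.
#' @return numeric fraction in [0, 1] (vectorised).
#' @export
gcContent <- function(seq) {
    if (is.character(seq)) seq <- DNAStringSet(toupper(seq))
    if (is(seq, "XString")) seq <- DNAStringSet(seq)
    af <- alphabetFrequency(seq, baseOnly = TRUE)
    acgt <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
    if (any(acgt == 0))
        stop("GC content undefined: sequence has no unambiguous bases")
    unname(rowSums(af[, c("G", "C"), drop = FALSE]) / acgt)
}

#' Read/write tabular alignment hits
#'
#' Hits travel as a 12-column table (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, score), the common tabular alignment-report
#' dialect. Coordinates are 1-based inclusive; minus-strand subject hits
#' have sstart > send.
#'
#' @param hits a hits data.frame as returned by [nucAlign()].
#' @param path output file.
#' @export
writeHits <- function(hits, path) {
    out <- hits
    minus <- out$strand == "-"
    tmp <- out$sstart[minus]
    out$sstart[minus] <- out$send[minus]
    out$send[minus] <- tmp
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
              "gapopen", "qstart", "qend", "sstart", "send", "evalue",
              "score")
    utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeHits
#' @export
readHits <- function(path) {
    h <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
        col.names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                      "gapopen", "qstart", "qend", "sstart", "send",
                      "evalue", "score"))
    h$strand <- ifelse(h$sstart > h$send, "-", "+")
    tmp <- pmin(h$sstart, h$send)
    h$send <- pmax(h$sstart, h$send)
    h$sstart <- tmp
    h
}

.empty_hits <- function(mode = "nucleotide") {
    data.frame(qseqid = character(), sseqid = character(),
               pident = numeric(), length = integer(),
               mismatch = integer(), gapopen = integer(),
               qstart = integer(), qend = integer(),
               sstart = integer(), send = integer(),
               evalue = numeric(), score = numeric(),
               strand = character(), mode = character(),
               stringsAsFactors = FALSE)
}
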