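#' @include seqcore-align.R
NULL

#' Mask rRNA (or other) intervals in a genome
#'
#' Replaces the bases in the given intervals with N. Length is
#' unchanged; downstream breadth and mean-depth computations exclude
#' masked (N) positions from their denominators. Overlapping intervals
#' are unioned first.
#'
#' @param genome DNAString or character.
#' @param intervals data.frame with \code{start}, \code{end} (1-based
#'   inclusive) or an IRanges; must lie within the genome.
#' @return a DNAString of the same length.
#' @export
maskRrna <- function(genome, intervals) {
    chr <- .as_seq_char(genome)
    ir <- if (is(intervals, "IRanges")) intervals
          else if (NROW(intervals) == 0L) IRanges()
          else IRanges(intervals$start, intervals$end)
    if (!length(ir)) return(DNAString(chr))
    n <- nchar(chr)
    if (min(start(ir)) < 1L || max(end(ir)) > n)
        stop("mask intervals must lie within the genome")
    ir <- reduce(ir)
    for (i in seq_along(ir)) {
        len <- width(ir)[i]
        substr(chr, start(ir)[i], end(ir)[i]) <-
            strrep("N", len)
    }
    DNAString(chr)
}

#' Construct a metagenome sample
#'
#' @param id sample id.
#' @param reads DNAStringSet of reads, or path(s) to FASTQ file(s)
#'   (read via Biostrings).
#' @param date,depth_m,temperature_C,depth_label optional typed sample
#'   metadata.
#' @return a \linkS4class{MetagenomeSample}.
#' @export
metagenomeSample <- function(id, reads, date = NA, depth_m = NA_real_,
                             temperature_C = NA_real_,
                             depth_label = NA_character_) {
    if (is.character(reads) && all(file.exists(reads)))
        reads <- do.call(c, lapply(reads, readDNAStringSet,
                                   format = "fastq"))
    if (is.character(reads)) reads <- DNAStringSet(reads)
    new("MetagenomeSample", id = id, reads = reads,
        totalBases = sum(Biostrings::width(reads)),
        sampleData = list(date = date, depth_m = depth_m,
                          temperature_C = temperature_C,
                          depth_label = depth_label))
}

#' Subsample reads from a sample
#'
#' Uniform random subsample without replacement, seeded and
#' deterministic. Used to cap read sets (the microbial-genome
#' recruitment path caps at 20 million reads; phage recruitment uses
#' full read sets).
#'
#' @param sample a MetagenomeSample.
#' @param max_reads maximum number of reads to keep (> 0).
#' @param seed integer seed.
#' @return a MetagenomeSample (unchanged if already small enough).
#' @export
subsampleReads <- function(sample, max_reads, seed = 1L) {
    stopifnot(max_reads > 0)
    n <- length(sample@reads)
    if (n <= max_reads) return(sample)
    set.seed(seed)
    keep <- sort(sample.int(n, max_reads))
    reads <- sample@reads[keep]
    new("MetagenomeSample", id = sample@id, reads = reads,
        totalBases = sum(Biostrings::width(reads)),
        sampleData = sample@sampleData)
}

# combined k-mer index over a genome set (with circular wrap extension)
.genome_index <- function(genomes, k, circular = TRUE) {
    idx <- list()
    for (i in seq_along(genomes)) {
        chr <- .as_seq_char(genomes[[i]])
        n <- nchar(chr)
        ext <- if (circular) paste0(chr, substr(chr, 1L, min(200L, n)))
               else chr
        t <- .kmer_table(ext, k)
        if (nrow(t)) {
            t$genome <- i
            idx[[length(idx) + 1L]] <- t
        }
    }
    tab <- data.table::rbindlist(idx)
    data.table::setkey(tab, kmer)
    tab
}

#' Fragment recruitment of a read set against genomes
#'
#' Aligns every read (both orientations) against a genome set by exact
#' k-mer seeding at several offsets along the read, verifies candidate
#' placements base-by-base (ungapped, appropriate for short
#' substitution-dominated reads), and counts a read for a genome iff
#' its best placement has identity > \code{min_identity} percent over
#' an alignment of >= \code{min_length} bp. Each mate is treated
#' independently. Reads whose best score ties across genomes are
#' assigned to the first genome encountered (with a warning) unless
#' \code{multi = "all"}.
#'
#' @param genomes named DNAStringSet (masked positions as N).
#' @param sample a MetagenomeSample.
#' @param min_identity percent identity cutoff (strict >; default 95).
#' @param min_length minimum alignment length in bp (default 50).
#' @param seed_k seed k-mer length (default 21).
#' @param circular treat genomes as circular (reads may span the
#'   origin; default TRUE).
#' @param multi "best" (default) or "all": handling of reads matching
#'   several genomes equally well.
#' @return list per genome: \code{depth} (integer vector, per unmasked
#'   reference position), \code{n_reads} mapped; plus \code{total}
#'   reads recruited overall.
#' @export
recruitReads <- function(genomes, sample, min_identity = 95,
                         min_length = 50L, seed_k = 21L,
                         circular = TRUE, multi = c("best", "all")) {
    multi <- match.arg(multi)
    stopifnot(length(genomes) > 0L)
    if (is.null(names(genomes)))
        names(genomes) <- sprintf("genome%03d", seq_along(genomes))
    gchr <- vapply(seq_along(genomes), function(i)
        .as_seq_char(genomes[[i]]), "")
    glen <- nchar(gchr)
    gext <- if (circular) paste0(gchr, substr(gchr, 1L,
                                              pmin(200L, glen)))
            else gchr
    idx <- .genome_index(genomes, seed_k, circular)
    reads <- as.character(sample@reads)
    nr <- length(reads)
    hits <- list()
    for (ori in 1:2) {
        rr <- if (ori == 1L) reads
              else as.character(reverseComplement(DNAStringSet(reads)))
        rlen <- nchar(rr)
        offs <- unique(pmax(1L, round(c(0, 0.33, 0.66, 1) *
                                      (max(rlen) - seed_k)) + 1L))
        cand <- list()
        for (o in offs) {
            ok <- rlen >= o + seed_k - 1L
            if (!any(ok)) next
            km <- substring(rr[ok], o, o + seed_k - 1L)
            dt <- data.table(kmer = km, read = which(ok), roff = o)
            m <- idx[dt, on = "kmer", nomatch = NULL,
                     allow.cartesian = TRUE]
            if (nrow(m)) cand[[length(cand) + 1L]] <-
                m[, list(read = m$read, genome = m$genome,
                         gstart = m$pos - m$roff + 1L)]
        }
        if (!length(cand)) next
        cand <- unique(data.table::rbindlist(cand))
        cand <- cand[cand$gstart >= 1L]
        cand$ori <- ori
        hits[[ori]] <- cand
    }
    if (!length(hits)) {
        return(c(lapply(seq_along(genomes), function(i)
            list(depth = integer(glen[i]), n_reads = 0L)) |>
                stats::setNames(names(genomes)), list(total = 0L)))
    }
    cand <- data.table::rbindlist(hits)
    # verify candidates: ungapped mismatch count at the seeded placement
    rall <- as.character(sample@reads)
    rcall <- as.character(reverseComplement(sample@reads))
    rlen <- nchar(rall)
    cand$rl <- rlen[cand$read]
    cand <- cand[cand$gstart + cand$rl - 1L <= nchar(gext)[cand$genome]]
    rstr <- ifelse(cand$ori == 1L, rall[cand$read], rcall[cand$read])
    gstr <- substring(gext[cand$genome], cand$gstart,
                      cand$gstart + cand$rl - 1L)
    mism <- .batch_mismatch(rstr, gstr, cand$rl)
    cand$pident <- (cand$rl - mism) / cand$rl * 100
    cand <- cand[cand$pident > min_identity & cand$rl >= min_length]
    res <- stats::setNames(lapply(seq_along(genomes), function(i)
        list(depth = integer(glen[i]), n_reads = 0L)), names(genomes))
    if (!nrow(cand)) return(c(res, list(total = 0L)))
    # best placement per read; tie across genomes -> first genome
    data.table::setorder(cand, read, -pident, genome, gstart)
    if (multi == "best") {
        best <- cand[!duplicated(cand$read)]
        bb <- merge(cand, best[, c("read", "pident", "genome")],
                    by = "read", suffixes = c("", ".best"))
        tied <- bb[bb$pident == bb$pident.best &
                   bb$genome != bb$genome.best]
        if (nrow(tied))
            warning(length(unique(tied$read)),
                    " read(s) matched multiple genomes equally well; ",
                    "assigned to first genome")
    } else {
        best <- cand[!duplicated(cand, by = c("read", "genome"))]
    }
    total <- length(unique(best$read))
    for (i in seq_along(genomes)) {
        b <- best[best$genome == i]
        if (!nrow(b)) next
        st <- b$gstart
        en <- st + b$rl - 1L
        if (circular) {
            st2 <- ((st - 1L) %% glen[i]) + 1L
            sh <- st2 - st
            st <- st2; en <- en + sh
            wrap <- en > glen[i]
            ir <- c(IRanges(st[!wrap], en[!wrap]),
                    IRanges(st[wrap], glen[i]),
                    IRanges(1L, en[wrap] - glen[i]))
        } else ir <- IRanges(pmin(st, glen[i]), pmin(en, glen[i]))
        cv <- as.integer(coverage(ir, width = glen[i]))
        res[[i]]$depth <- cv
        res[[i]]$n_reads <- nrow(b)
    }
    c(res, list(total = total))
}

# mismatch counts between equal-length string pairs, batched by length
.batch_mismatch <- function(a, b, len) {
    out <- integer(length(a))
    for (L in unique(len)) {
        w <- which(len == L)
        ar <- charToRaw(paste(a[w], collapse = ""))
        br <- charToRaw(paste(b[w], collapse = ""))
        ne <- ar != br
        out[w] <- as.integer(rowSums(matrix(ne, ncol = L, byrow = TRUE)))
    }
    out
}

#' Coverage per gigabase of metagenome
#'
#' Mean read depth over unmasked genome positions divided by the sample
#' size in gigabases -- the cross-sample-comparable abundance unit.
#'
#' @param depth integer depth vector over genome positions.
#' @param genome_len_unmasked number of unmasked positions (> 0).
#' @param sample_total_bases total sequenced bases in the sample (> 0).
#' @param masked optional logical vector marking masked positions to
#'   drop from \code{depth} before averaging.
#' @return numeric coverage per Gb.
#' @export
coveragePerGb <- function(depth, genome_len_unmasked,
                          sample_total_bases, masked = NULL) {
    stopifnot(sample_total_bases > 0, genome_len_unmasked > 0)
    if (!is.null(masked)) depth <- depth[!masked]
    (sum(depth) / genome_len_unmasked) / (sample_total_bases / 1e9)
}

#' Breadth-based presence call
#'
#' A genome is present in a sample only when more than 80 percent of
#' its (unmasked) positions are covered -- strictly greater, so a
#' breadth of exactly 0.80 is absent.
#'
#' @param breadth fraction of unmasked positions covered >= 1x.
#' @param threshold presence threshold (default 0.80, strict).
#' @return logical (vectorised).
#' @export
presenceCall <- function(breadth, threshold = 0.80) breadth > threshold

#' Row-wise Z-score normalisation
#'
#' Per genome across samples: (x - mean) / sd with the population
#' standard deviation; constant rows map to all zeros.
#'
#' @param m numeric matrix (genomes x samples).
#' @return matrix of the same shape.
#' @export
zscoreRows <- function(m) {
    z <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    for (i in seq_len(nrow(m))) {
        x <- m[i, ]
        mu <- mean(x)
        s <- sqrt(mean((x - mu)^2))
        if (s > 0) z[i, ] <- (x - mu) / s
    }
    z
}

#' Cluster abundance profiles
#'
#' Distance 1 - Spearman rank correlation (average ranks for ties),
#' average-linkage agglomeration. Rows are ordered by id first so the
#' result is deterministic.
#'
#' @param m numeric matrix (>= 2 rows) with rownames.
#' @return an \code{hclust} object; leaf order in \code{$order}.
#' @export
clusterProfiles <- function(m) {
    if (nrow(m) < 2L) stop("need at least two profiles")
    if (!is.null(rownames(m))) m <- m[order(rownames(m)), , drop = FALSE]
    d <- stats::as.dist(1 - stats::cor(t(m), method = "spearman"))
    stats::hclust(d, method = "average")
}

#' Build an abundance experiment across a time series
#'
#' Recruits every sample's reads against the genome set and assembles
#' the genome x sample matrices: coverage per gigabase, breadth,
#' presence (breadth > 0.80 strict), and row Z-scores of coverage.
#'
#' @param genomes named DNAStringSet (apply [maskRrna()] beforehand
#'   where needed).
#' @param samples list of MetagenomeSample objects.
#' @param min_identity,min_length recruitment cutoffs (defaults > 95
#'   percent, >= 50 bp).
#' @param max_reads optional read cap applied per sample via
#'   [subsampleReads()] (the microbial-genome path caps at 2e7; phage
#'   profiling uses the full read sets, the default).
#' @param seed seed for subsampling.
#' @param presence_threshold breadth threshold (default 0.80).
#' @param circular treat genomes as circular.
#' @return an \linkS4class{AbundanceExperiment}.
#' @export
abundanceExperiment <- function(genomes, samples, min_identity = 95,
                                min_length = 50L, max_reads = NULL,
                                seed = 1L, presence_threshold = 0.80,
                                circular = TRUE) {
    gids <- names(genomes)
    sids <- vapply(samples, function(s) s@id, "")
    gchr <- vapply(seq_along(genomes), function(i)
        .as_seq_char(genomes[[i]]), "")
    unmasked <- lapply(gchr, function(g)
        strsplit(g, "")[[1L]] != "N")
    nun <- vapply(unmasked, sum, 0L)
    cpg <- br <- matrix(0, length(genomes), length(samples),
                        dimnames = list(gids, sids))
    for (si in seq_along(samples)) {
        smp <- samples[[si]]
        if (!is.null(max_reads))
            smp <- subsampleReads(smp, max_reads, seed + si)
        rec <- recruitReads(genomes, smp, min_identity, min_length,
                            circular = circular)
        for (gi in seq_along(genomes)) {
            dep <- rec[[gi]]$depth[unmasked[[gi]]]
            cpg[gi, si] <- coveragePerGb(dep, nun[gi], smp@totalBases)
            br[gi, si] <- mean(dep > 0L)
        }
    }
    present <- br > presence_threshold
    cd <- DataFrame(row.names = sids)
    for (f in c("date", "depth_m", "temperature_C", "depth_label"))
        cd[[f]] <- unlist(lapply(samples, function(s) {
            v <- s@sampleData[[f]]
            if (is.null(v) || !length(v)) NA else v
        }))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(cpg = cpg, breadth = br, present = present,
                      zscore = zscoreRows(cpg)),
        colData = cd,
        metadata = list(presence_threshold = presence_threshold))
    new("AbundanceExperiment", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write abundance tables
#'
#' Long-format TSV (genome, sample, coverage_per_gb, breadth, present)
#' plus a Z-score matrix TSV and the profile dendrogram in Newick.
#'
#' @param x an AbundanceExperiment.
#' @param prefix output path prefix.
#' @export
writeAbundance <- function(x, prefix) {
    cpg <- coverageMatrix(x)
    long <- data.frame(
        genome = rep(rownames(cpg), ncol(cpg)),
        sample = rep(colnames(cpg), each = nrow(cpg)),
        coverage_per_gb = as.vector(cpg),
        breadth = as.vector(breadthMatrix(x)),
        present = as.vector(presenceCalls(x)))
    utils::write.table(long, paste0(prefix, "_abundance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(zScores(x), paste0(prefix, "_zscore.tsv"),
                       sep = "\t", quote = FALSE)
    if (nrow(cpg) >= 2L && ncol(cpg) >= 2L) {
        hc <- clusterProfiles(cpg)
        ape::write.tree(ape::as.phylo(hc),
                        paste0(prefix, "_profiles.nwk"))
    }
    invisible(prefix)
}
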