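#' @include seqcore-align.R
NULL

.evidence_row <- function(phage_id, host_id, channel, resolution,
                          detail = NA_character_, qstart = NA, qend = NA,
                          sstart = NA, send = NA, pident = NA,
                          evalue = NA) {
    data.frame(phage_id = phage_id, host_id = host_id, channel = channel,
               taxon_resolution = resolution, detail = detail,
               qstart = qstart, qend = qend, sstart = sstart,
               send = send, pident = pident, evalue = evalue,
               stringsAsFactors = FALSE)
}

.empty_evidence <- function() {
    data.frame(phage_id = character(), host_id = character(),
               channel = character(), taxon_resolution = character(),
               detail = character(), qstart = numeric(),
               qend = numeric(), sstart = numeric(), send = numeric(),
               pident = numeric(), evalue = numeric(),
               stringsAsFactors = FALSE)
}

#' Host evidence from phage-borne marker genes
#'
#' Aligns each phage ORF against a set of taxon-labelled marker proteins
#' (e.g. WhiB-family transcription factors restricted to
#' Actinobacteria). Evidence is emitted when an ORF matches a marker at
#' >= \code{min_identity} percent identity over >= \code{min_marker_cov}
#' of the marker length with expectation <= \code{max_expectation}.
#' Marker evidence resolves hosts at phylum level only. A phage carrying
#' several marker copies yields several evidence records.
#'
#' @param phage DNAString/character phage genome.
#' @param phage_id phage id.
#' @param markers AAStringSet of marker proteins; taxon labels taken
#'   from \code{mcols(markers)$taxon} or from "id|taxon" names.
#' @param min_identity percent identity threshold (default 30).
#' @param min_marker_cov fraction of marker length that must align
#'   (default 0.7).
#' @param max_expectation e-value cutoff (default 1e-5).
#' @param min_orf_aa ORF calling threshold.
#' @return evidence data.frame (one row per ORF-marker match).
#' @export
detectMarkerGenes <- function(phage, phage_id = "phage", markers,
                              min_identity = 30, min_marker_cov = 0.7,
                              max_expectation = 1e-5, min_orf_aa = 30L) {
    if (!length(markers)) stop("marker set must be non-empty")
    taxa <- mcols(markers)$taxon
    if (is.null(taxa)) {
        parts <- strsplit(names(markers), "|", fixed = TRUE)
        taxa <- vapply(parts, function(p) p[min(2L, length(p))], "")
    }
    orfs <- findOrfs(phage, min_orf_aa, topology = "circular",
                     id = phage_id)
    if (!length(orfs)) return(.empty_evidence())
    B <- .subst_matrix("BLOSUM45")
    oset <- AAStringSet(gsub("[*]", "", as.character(orfs)))
    olen <- Biostrings::width(oset)
    out <- list()
    for (mi in seq_along(markers)) {
        mseq <- AAString(gsub("[*]", "", as.character(markers[[mi]])))
        mlen <- length(mseq)
        pa <- Biostrings::pairwiseAlignment(
            oset, mseq, type = "local", substitutionMatrix = B,
            gapOpening = 14, gapExtension = 2)
        alen <- Biostrings::nchar(pa)
        pid <- Biostrings::nmatch(pa) / alen * 100
        # gapped Karlin-Altschul constants for BLOSUM45 (14/2)
        ev <- expectationValue(pmax(Biostrings::score(pa), 0),
                               olen, mlen, K = 0.032, lambda = 0.195)
        keep <- which(alen >= min_marker_cov * mlen &
                      pid >= min_identity & ev <= max_expectation)
        for (oi in keep)
            out[[length(out) + 1L]] <- .evidence_row(
                phage_id, taxa[mi], "marker_gene", "phylum",
                detail = sub("\\|.*", "", names(markers)[mi]),
                qstart = mcols(orfs)$start[oi],
                qend = mcols(orfs)$end[oi], pident = pid[oi],
                evalue = ev[oi])
    }
    if (!length(out)) return(.empty_evidence())
    do.call(rbind, out)
}

#' Detect CRISPR repeat/spacer arrays
#'
#' CRT-style detector: at least \code{min_repeats} near-identical direct
#' repeats (length within \code{repeat_bounds}, each copy at most 1
#' mismatch to the column-majority consensus) separated by spacers of
#' length within \code{spacer_bounds}. Candidate arrays are anchored by
#' exact repeat words recurring at array-like spacing, then extended to
#' the full repeat length.
#'
#' @param host DNAString/character host genome.
#' @param host_id id recorded on the arrays.
#' @param repeat_bounds repeat length bounds (default c(23, 47)).
#' @param spacer_bounds spacer length bounds (default c(26, 50)).
#' @param min_repeats minimum repeat copies (default 3).
#' @return list of \linkS4class{CrisprArray} objects.
#' @export
detectCrisprArrays <- function(host, host_id = "host",
                               repeat_bounds = c(23L, 47L),
                               spacer_bounds = c(26L, 50L),
                               min_repeats = 3L) {
    chr <- .as_seq_char(host)
    n <- nchar(chr)
    w <- repeat_bounds[1L]
    if (n < min_repeats * w) return(list())
    kt <- .kmer_table(chr, w)
    dup <- kt[, .N, by = "kmer"][N >= min_repeats]
    if (!nrow(dup)) return(list())
    cand <- kt[kt$kmer %in% dup$kmer]
    gap_min <- w + spacer_bounds[1L]
    gap_max <- repeat_bounds[2L] + spacer_bounds[2L]
    used <- integer()
    arrays <- list()
    for (km in unique(cand$kmer)) {
        pos <- sort(cand[cand$kmer == km]$pos)
        if (any(pos %in% used)) next
        # chain positions with array-like spacing
        runs <- split(pos, cumsum(c(TRUE, diff(pos) < gap_min |
                                            diff(pos) > gap_max)))
        for (pp in runs) {
            if (length(pp) < min_repeats || any(pp %in% used)) next
            arr <- .refine_array(chr, pp, w, repeat_bounds,
                                 spacer_bounds, min_repeats)
            if (is.null(arr)) next
            used <- c(used, unlist(lapply(seq_along(arr@repeats),
                function(i) start(arr@repeats)[i]:end(arr@repeats)[i])))
            arr@hostId <- host_id
            arrays[[length(arrays) + 1L]] <- arr
        }
    }
    arrays
}

# Extend anchor positions (starts of an exact w-mer) to the maximal
# repeat, check repeat/spacer constraints, and extract spacers.
.refine_array <- function(chr, pos, w, repeat_bounds, spacer_bounds,
                          min_repeats) {
    n <- nchar(chr)
    craw <- charToRaw(chr)
    max_r <- repeat_bounds[2L]
    # extend right while all copies agree with the majority base
    ext_r <- 0L
    while (w + ext_r < max_r) {
        p <- pos + w + ext_r
        if (any(p > n)) break
        b <- craw[p]
        if (length(unique(b)) > 1L) break
        ext_r <- ext_r + 1L
    }
    ext_l <- 0L
    while (w + ext_r + ext_l < max_r) {
        p <- pos - ext_l - 1L
        if (any(p < 1L)) break
        b <- craw[p]
        if (length(unique(b)) > 1L) break
        ext_l <- ext_l + 1L
    }
    rs <- pos - ext_l
    rlen <- w + ext_l + ext_r
    if (rlen < repeat_bounds[1L] || rlen > repeat_bounds[2L])
        return(NULL)
    gaps <- diff(rs) - rlen
    ok <- gaps >= spacer_bounds[1L] & gaps <= spacer_bounds[2L]
    if (sum(ok) + 1L < min_repeats) return(NULL)
    if (!all(ok)) {
        # keep the longest run of valid spacings
        r <- rle(ok)
        ends <- cumsum(r$lengths)
        best <- which.max(ifelse(r$values, r$lengths, 0L))
        i2 <- ends[best]; i1 <- i2 - r$lengths[best] + 1L
        rs <- rs[i1:(i2 + 1L)]
        if (length(rs) < min_repeats) return(NULL)
    }
    copies <- substring(chr, rs, rs + rlen - 1L)
    cons <- .majority_consensus(copies)
    mm <- vapply(copies, function(x)
        sum(charToRaw(x) != charToRaw(cons)), 0L)
    if (any(mm > 1L)) return(NULL)
    sp_start <- rs[-length(rs)] + rlen
    sp_end <- rs[-1L] - 1L
    new("CrisprArray", hostId = "host", repeatConsensus = cons,
        repeats = IRanges(rs, rs + rlen - 1L),
        spacers = DNAStringSet(substring(chr, sp_start, sp_end)),
        spacerRanges = IRanges(sp_start, sp_end))
}

.majority_consensus <- function(copies) {
    m <- do.call(rbind, lapply(copies, function(x)
        strsplit(x, "")[[1L]]))
    paste(apply(m, 2L, function(col)
        names(sort(table(col), decreasing = TRUE))[1L]), collapse = "")
}

#' Match CRISPR spacers against phage genomes
#'
#' Each spacer is aligned to each phage genome; evidence requires
#' alignment length >= 30 bp, identity >= 97 percent, spacer (query)
#' coverage >= 97 percent, and expectation <= 1e-5 -- the stringent
#' spacer-matching cutoffs. Spacer evidence resolves hosts at strain
#' level.
#'
#' @param arrays list of CrisprArray objects.
#' @param phages named DNAStringSet of phage genomes.
#' @param min_length,min_identity,min_query_cov,max_expectation channel
#'   cutoffs (defaults 30 bp, 97, 0.97, 1e-5).
#' @return evidence data.frame.
#' @export
matchSpacers <- function(arrays, phages, min_length = 30L,
                         min_identity = 97, min_query_cov = 0.97,
                         max_expectation = 1e-5) {
    out <- list()
    params <- alignerParams("nucleotide", min_alignment_length = 20L)
    prof <- lapply(seq_along(phages), function(i)
        .nuc_subject_profile(phages[[i]], params))
    for (arr in arrays) {
        sp <- arr@spacers
        for (si in seq_along(sp)) {
            spc <- as.character(sp[[si]])
            for (pi in seq_along(phages)) {
                h <- nucAlign(spc, NULL, params,
                              "spacer", names(phages)[pi],
                              subject_profile = prof[[pi]])
                h <- h[h$length >= min_length &
                       h$pident >= min_identity &
                       (h$qend - h$qstart + 1L) >=
                           min_query_cov * nchar(spc) &
                       h$evalue <= max_expectation, , drop = FALSE]
                if (!nrow(h)) next
                h <- h[1L, ]
                out[[length(out) + 1L]] <- .evidence_row(
                    names(phages)[pi], arr@hostId, "crispr_spacer",
                    "strain", detail = sprintf("spacer%02d", si),
                    qstart = h$sstart, qend = h$send,
                    sstart = h$qstart, send = h$qend,
                    pident = h$pident, evalue = h$evalue)
            }
        }
    }
    if (!length(out)) return(.empty_evidence())
    do.call(rbind, out)
}

#' tRNA / attB integration-site evidence
#'
#' Temperate phages integrate at host attachment (attB) sites, usually
#' within a tRNA locus, leaving shared sequence there. The phage is
#' aligned to the host and hits are restricted to those overlapping an
#' annotated tRNA locus by >= \code{min_locus_overlap} bp; hits must
#' also satisfy length >= 30 bp, identity >= 97 percent, expectation
#' <= 1e-5.
#'
#' @param phage,host DNAString/character genomes.
#' @param phage_id,host_id ids.
#' @param trna_loci data.frame with \code{start}, \code{end} (1-based,
#'   on the host) or an IRanges.
#' @param min_locus_overlap minimum hit/locus overlap in bp (default 20).
#' @param min_length,min_identity,max_expectation channel cutoffs.
#' @param hits optional precomputed phage-vs-host hit table (shared
#'   with the shared-sequence channel).
#' @return evidence data.frame.
#' @export
matchTrnaAttB <- function(phage, host, phage_id = "phage",
                          host_id = "host", trna_loci,
                          min_locus_overlap = 20L, min_length = 30L,
                          min_identity = 97, max_expectation = 1e-5,
                          hits = NULL) {
    loci <- if (is(trna_loci, "IRanges")) trna_loci
            else IRanges(trna_loci$start, trna_loci$end)
    if (!length(loci)) return(.empty_evidence())
    params <- alignerParams("nucleotide", min_alignment_length = 20L)
    h <- if (is.null(hits)) nucAlign(phage, host, params, phage_id,
                                     host_id) else hits
    h <- h[h$length >= min_length & h$pident >= min_identity &
           h$evalue <= max_expectation, , drop = FALSE]
    if (!nrow(h)) return(.empty_evidence())
    hr <- IRanges(h$sstart, h$send)
    ov <- IRanges::findOverlaps(hr, loci, minoverlap = min_locus_overlap)
    if (!length(ov)) return(.empty_evidence())
    keep <- unique(S4Vectors::queryHits(ov))
    h <- h[keep, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(h)), function(i) .evidence_row(
        phage_id, host_id, "trna_attb", "strain",
        detail = "attB", qstart = h$qstart[i], qend = h$qend[i],
        sstart = h$sstart[i], send = h$send[i], pident = h$pident[i],
        evalue = h$evalue[i])))
}

#' Shared nucleotide sequence evidence
#'
#' Direct phage-vs-host genome comparison; any hit with alignment
#' length >= 30 bp, identity >= 97 percent, and expectation <= 1e-5
#' (e.g. a prophage-like region) links the pair at strain resolution.
#'
#' @inheritParams matchTrnaAttB
#' @return evidence data.frame.
#' @export
sharedSequenceEvidence <- function(phage, host, phage_id = "phage",
                                   host_id = "host", min_length = 30L,
                                   min_identity = 97,
                                   max_expectation = 1e-5, hits = NULL) {
    params <- alignerParams("nucleotide", min_alignment_length = 20L)
    h <- if (is.null(hits)) nucAlign(phage, host, params, phage_id,
                                     host_id) else hits
    h <- h[h$length >= min_length & h$pident >= min_identity &
           h$evalue <= max_expectation, , drop = FALSE]
    if (!nrow(h)) return(.empty_evidence())
    do.call(rbind, lapply(seq_len(nrow(h)), function(i) .evidence_row(
        phage_id, host_id, "shared_sequence", "strain",
        detail = "shared", qstart = h$qstart[i], qend = h$qend[i],
        sstart = h$sstart[i], send = h$send[i], pident = h$pident[i],
        evalue = h$evalue[i])))
}

#' Integrate evidence channels into one host call per phage
#'
#' Channel precedence: crispr_spacer > trna_attb > shared_sequence >
#' marker_gene. Within the highest-precedence non-empty channel the host
#' with the most evidence records wins; a tie yields status
#' "ambiguous"; no evidence yields "unassigned". The call is a pure
#' function of the evidence multiset (input order is irrelevant).
#'
#' @param evidence evidence data.frame for one phage (rows from any
#'   channel functions).
#' @param phage_id id used when \code{evidence} is empty.
#' @return one-row data.frame: phage_id, host_id, winning_channel,
#'   n_evidence, status.
#' @export
assignHost <- function(evidence, phage_id = NA_character_) {
    prec <- c("crispr_spacer", "trna_attb", "shared_sequence",
              "marker_gene")
    if (is.null(evidence) || !nrow(evidence))
        return(data.frame(phage_id = phage_id, host_id = NA_character_,
                          winning_channel = NA_character_,
                          n_evidence = 0L, status = "unassigned",
                          stringsAsFactors = FALSE))
    pid <- unique(evidence$phage_id)
    if (length(pid) != 1L)
        stop("assignHost expects evidence for a single phage")
    for (ch in prec) {
        e <- evidence[evidence$channel == ch, , drop = FALSE]
        if (!nrow(e)) next
        tab <- sort(table(e$host_id), decreasing = TRUE)
        if (length(tab) > 1L && tab[1L] == tab[2L])
            return(data.frame(phage_id = pid, host_id = NA_character_,
                              winning_channel = ch,
                              n_evidence = nrow(e),
                              status = "ambiguous",
                              stringsAsFactors = FALSE))
        res <- if (ch == "marker_gene") "phylum" else "strain"
        return(data.frame(phage_id = pid, host_id = names(tab)[1L],
                          winning_channel = ch,
                          n_evidence = as.integer(tab[1L]),
                          status = "assigned",
                          stringsAsFactors = FALSE))
    }
}

#' Run all host-prediction channels over a community
#'
#' Convenience wrapper: detects CRISPR arrays on every host, runs the
#' four evidence channels for every phage, and integrates per-phage
#' calls.
#'
#' @param phages named DNAStringSet of phage genomes.
#' @param hosts named DNAStringSet of host genomes.
#' @param trna_loci data.frame with host_id, start, end columns (or
#'   NULL).
#' @param markers AAStringSet of taxon-labelled marker proteins (or
#'   NULL).
#' @return list with \code{evidence} (all channels) and \code{calls}
#'   (one row per phage).
#' @export
predictHosts <- function(phages, hosts, trna_loci = NULL,
                         markers = NULL) {
    evid <- list()
    arrays <- list()
    host_prof <- lapply(seq_along(hosts), function(i)
        .nuc_subject_profile(hosts[[i]],
                             alignerParams("nucleotide")))
    for (hi in seq_along(hosts))
        arrays <- c(arrays, detectCrisprArrays(hosts[[hi]],
                                               names(hosts)[hi]))
    ev <- matchSpacers(arrays, phages)
    if (nrow(ev)) evid[[length(evid) + 1L]] <- ev
    for (pi in seq_along(phages)) {
        pid <- names(phages)[pi]
        pchr <- as.character(phages[[pi]])
        if (!is.null(markers) && length(markers)) {
            ev <- detectMarkerGenes(pchr, pid, markers)
            if (nrow(ev)) evid[[length(evid) + 1L]] <- ev
        }
        for (hi in seq_along(hosts)) {
            hid <- names(hosts)[hi]
            hchr <- as.character(hosts[[hi]])
            # one phage-vs-host alignment shared by both channels
            hh <- nucAlign(pchr, NULL,
                           alignerParams("nucleotide",
                                         min_alignment_length = 20L),
                           pid, hid,
                           subject_profile = host_prof[[hi]])
            if (!is.null(trna_loci)) {
                tl <- trna_loci[trna_loci$host_id == hid, , drop = FALSE]
                if (nrow(tl)) {
                    ev <- matchTrnaAttB(pchr, hchr, pid, hid, tl,
                                        hits = hh)
                    if (nrow(ev)) evid[[length(evid) + 1L]] <- ev
                }
            }
            ev <- sharedSequenceEvidence(pchr, hchr, pid, hid,
                                         hits = hh)
            if (nrow(ev)) evid[[length(evid) + 1L]] <- ev
        }
    }
    evidence <- if (length(evid)) do.call(rbind, evid)
                else .empty_evidence()
    calls <- do.call(rbind, lapply(names(phages), function(pid)
        assignHost(evidence[evidence$phage_id == pid, , drop = FALSE],
                   pid)))
    list(evidence = evidence, calls = calls, arrays = arrays)
}
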