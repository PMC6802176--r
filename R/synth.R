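#' @include discovery.R
NULL

.DNA <- c("A", "C", "G", "T")

# random nucleotide string at a target GC fraction
.rand_seq <- function(n, gc = 0.5) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(.DNA, n, replace = TRUE, prob = p), collapse = "")
}

# Codons of translation table 11 indexed by amino acid, with stop codons
# removed; used to emit coding sequence free of internal stops.
.codons_by_aa <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        gc11 <- Biostrings::getGeneticCode("11")
        cod <- names(gc11)[gc11 != "*"]
        cache <<- split(cod, gc11[gc11 != "*"])
        cache
    }
})

# random protein-coding gene (start codon, no internal stops, stop)
.rand_gene <- function(aa_len, gc = 0.5) {
    cba <- .codons_by_aa()
    aas <- sample(names(cba), aa_len - 1L, replace = TRUE)
    pick <- vapply(aas, function(a) {
        cands <- cba[[a]]
        gcw <- (nchar(gsub("[AT]", "", cands)) + 0.5) * gc +
               (1 - gc) * 0.5
        sample(cands, 1L, prob = gcw)[1L]
    }, "")
    paste0("ATG", paste(pick, collapse = ""),
           sample(c("TAA", "TAG", "TGA"), 1L))
}

# reverse-translate a protein into a stop-free CDS
.reverse_translate <- function(aa, gc = 0.5) {
    cba <- .codons_by_aa()
    aa <- gsub("[*]", "", aa)
    res <- vapply(strsplit(aa, "")[[1L]], function(a) {
        cands <- cba[[a]]
        if (is.null(cands)) cands <- cba[["A"]]
        sample(cands, 1L)[1L]
    }, "")
    paste0(paste(res, collapse = ""), "TAA")
}

# gene-dense genome of approximately `len` bp at GC fraction `gc`;
# optional extra CDS sequences (e.g. marker genes) are embedded among
# the random genes. Returns the sequence string.
.build_genome <- function(len, gc, extra_cds = character()) {
    parts <- character()
    total <- 0L
    extra <- sample(extra_cds)
    while (total < len) {
        if (length(extra)) {
            cds <- extra[1L]
            extra <- extra[-1L]
        } else cds <- .rand_gene(sample(80:400, 1L), gc)
        ig <- .rand_seq(sample(20:120, 1L), gc)
        parts <- c(parts, cds, ig)
        total <- total + nchar(cds) + nchar(ig)
    }
    s <- paste(parts, collapse = "")
    substr(s, 1L, len)
}

.mutate <- function(chr, rate) {
    n <- nchar(chr)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(chr)
    pos <- sample.int(n, k)
    v <- strsplit(chr, "")[[1L]]
    v[pos] <- vapply(v[pos], function(b)
        sample(setdiff(.DNA, b), 1L), "")
    paste(v, collapse = "")
}

#' Specification of a synthetic phage/host community
#'
#' Defaults emulate the freshwater study conditions: a bimodal
#' log-normal genome length mixture with modes near 15 kb and 40 kb
#' truncated to [13,500, 446,000] bp, habitat-like GC (normal around
#' 0.45, sd 0.05), replicate groups of nearly identical genomes
#' (1 percent substitutions per copy) emulating repeated capture of
#' persistent phages, and planted host-evidence links (CRISPR spacer,
#' tRNA/attB, shared prophage-like sequence, marker gene) on
#' replicate-group founders or singletons.
#'
#' @param n_phages number of distinct phage genomes including replicate
#'   copies (default 20).
#' @param replicate_groups integer vector of replicate group sizes
#'   (default c(3, 3, 2, 2); remaining phages are singletons).
#' @param mutation_rate substitution rate per replicate copy (default
#'   0.01; must be <= 0.05).
#' @param length_modes,length_sdlog,length_weights log-normal mixture
#'   parameters for genome length.
#' @param length_range truncation bounds in bp.
#' @param gc_mean,gc_sd per-genome GC draw.
#' @param n_hosts number of host genomes (default 5).
#' @param host_length host genome length in bp (default 2e5).
#' @param links data.frame (phage index, host index, channel) or NULL
#'   for the default plan: spacer links to hosts 1-2, attB to host 3,
#'   shared to host 4, markers (one single, one double copy) for host
#'   5's phylum.
#' @param terminal_repeat_range contig terminal repeat lengths.
#' @return list of class "CommunitySpec".
#' @export
communitySpec <- function(n_phages = 20L,
                          replicate_groups = c(3L, 3L, 2L, 2L),
                          mutation_rate = 0.01,
                          length_modes = c(15000, 40000),
                          length_sdlog = c(0.06, 0.35),
                          length_weights = c(0.45, 0.55),
                          length_range = c(13500, 446000),
                          gc_mean = 0.45, gc_sd = 0.05,
                          n_hosts = 5L, host_length = 200000L,
                          links = NULL,
                          terminal_repeat_range = c(80L, 150L)) {
    if (mutation_rate < 0 || mutation_rate > 0.05)
        stop("mutation_rate must be in [0, 0.05]")
    if (sum(replicate_groups) > n_phages)
        stop("replicate groups exceed n_phages")
    structure(list(n_phages = as.integer(n_phages),
                   replicate_groups = as.integer(replicate_groups),
                   mutation_rate = mutation_rate,
                   length_modes = length_modes,
                   length_sdlog = length_sdlog,
                   length_weights = length_weights,
                   length_range = length_range,
                   gc_mean = gc_mean, gc_sd = gc_sd,
                   n_hosts = as.integer(n_hosts),
                   host_length = as.integer(host_length),
                   links = links,
                   terminal_repeat_range = terminal_repeat_range),
              class = "CommunitySpec")
}

.draw_lengths <- function(n, spec) {
    comp <- sample.int(length(spec$length_modes), n, replace = TRUE,
                       prob = spec$length_weights)
    len <- round(stats::rlnorm(n, log(spec$length_modes[comp]),
                               spec$length_sdlog[comp]))
    pmin(pmax(len, spec$length_range[1L]), spec$length_range[2L])
}

#' Generate a synthetic phage/host community
#'
#' Deterministic given the seed. Produces circular phage genomes (and
#' contig versions carrying planted terminal direct repeats), host
#' genomes carrying planted CRISPR arrays (with spacers copied verbatim
#' from linked phages), annotated tRNA loci with attB copies shared
#' into linked phages, prophage-like shared regions, and marker genes;
#' plus a taxon-labelled marker protein reference set and a
#' ground-truth ledger that fully determines the expected pipeline
#' outputs.
#'
#' @param spec a [communitySpec()].
#' @param seed integer seed.
#' @param out_dir optional directory: writes phages.fasta,
#'   contigs.fasta, hosts.fasta, markers.fasta, trna_loci.bed and
#'   ledger.json.
#' @return list with \code{phages}, \code{contigs}, \code{hosts}
#'   (DNAStringSets), \code{trna_loci} (data.frame), \code{markers}
#'   (AAStringSet with taxon mcols), \code{host_taxa}, and
#'   \code{ledger}.
#' @export
generateCommunity <- function(spec = communitySpec(), seed = 1L,
                              out_dir = NULL) {
    set.seed(seed)
    np <- spec$n_phages
    groups <- spec$replicate_groups
    n_founders <- np - sum(groups) + length(groups)
    # assign group membership: first length(groups) founders get copies
    group_of <- integer(np)
    founder_of <- integer(np)
    idx <- 1L
    for (g in seq_along(groups)) {
        group_of[idx:(idx + groups[g] - 1L)] <- g
        founder_of[idx:(idx + groups[g] - 1L)] <- idx
        idx <- idx + groups[g]
    }
    if (idx <= np) {
        group_of[idx:np] <- seq(length(groups) + 1L,
                                length.out = np - idx + 1L)
        founder_of[idx:np] <- idx:np
    }
    founders <- which(founder_of == seq_len(np))
    lens <- numeric(np)
    gcs <- numeric(np)
    lens[founders] <- .draw_lengths(length(founders), spec)
    gcs[founders] <- pmin(pmax(stats::rnorm(length(founders),
                                            spec$gc_mean, spec$gc_sd),
                               0.30), 0.65)
    # ids: copies share the founder stem so the founder sorts first
    ids <- character(np)
    for (i in seq_len(np)) {
        if (founder_of[i] == i) ids[i] <- sprintf("uvig%03d", i)
        else ids[i] <- sprintf("uvig%03d_r%d", founder_of[i],
                               i - founder_of[i])
    }
    # marker proteins: one WhiB-like family per host phylum
    taxa <- sprintf("phylum%02d", seq_len(spec$n_hosts))
    markers <- vapply(seq_len(spec$n_hosts), function(i)
        paste(sample(setdiff(names(.codons_by_aa()), "M"), 120,
                     replace = TRUE), collapse = ""), "")
    markers <- paste0("M", substr(markers, 2L, 120L))
    # default link plan on founders (distinct phages per channel)
    links <- spec$links
    if (is.null(links)) {
        f <- founders
        links <- data.frame(
            phage = f[c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 7L)],
            host = c(1L, 2L, 3L, 4L, 5L, 5L, 5L, 5L),
            channel = c("spacer", "spacer", "attb", "shared",
                        "marker", "marker", "marker", "marker"),
            stringsAsFactors = FALSE)
        # phage f[7] carries two marker copies; f[5], f[6] one each
    }
    marker_count <- table(factor(links$phage[links$channel == "marker"],
                                 levels = seq_len(np)))
    marker_host <- integer(np)
    mrows <- links[links$channel == "marker", , drop = FALSE]
    marker_host[mrows$phage] <- mrows$host
    # build founder genomes (embedding marker CDS copies where planted)
    seqs <- character(np)
    for (i in founders) {
        extra <- character()
        if (marker_count[i] > 0L)
            extra <- rep(.reverse_translate(markers[marker_host[i]],
                                            gcs[i]),
                         marker_count[i])
        seqs[i] <- .build_genome(lens[i], gcs[i], extra)
    }
    for (i in which(founder_of != seq_len(np))) {
        seqs[i] <- .mutate(seqs[founder_of[i]], spec$mutation_rate)
        lens[i] <- nchar(seqs[i])
        gcs[i] <- gcContent(seqs[i])
    }
    # rotate each genome's origin before planting link evidence, so the
    # ledger coordinates refer to the emitted linearisation
    for (i in seq_len(np)) {
        rot <- sample.int(nchar(seqs[i]), 1L)
        seqs[i] <- paste0(substr(seqs[i], rot, nchar(seqs[i])),
                          substr(seqs[i], 1L, rot - 1L))
    }
    # hosts with tRNA loci
    hosts <- character(spec$n_hosts)
    host_ids <- sprintf("host%02d", seq_len(spec$n_hosts))
    trna <- list()
    ledger_links <- list()
    for (h in seq_len(spec$n_hosts)) {
        hg <- .rand_seq(spec$host_length, spec$gc_mean)
        n_trna <- 5L
        tpos <- sort(sample.int(spec$host_length - 200L, n_trna))
        for (t in seq_len(n_trna)) {
            trna[[length(trna) + 1L]] <- data.frame(
                host_id = host_ids[h], start = tpos[t],
                end = tpos[t] + 74L, stringsAsFactors = FALSE)
        }
        hosts[h] <- hg
    }
    trna <- do.call(rbind, trna)
    # plant link evidence
    for (r in seq_len(nrow(links))) {
        p <- links$phage[r]; h <- links$host[r]
        ch <- links$channel[r]
        plen <- nchar(seqs[p])
        if (ch == "spacer") {
            sp_from <- sample.int(plen - 40L, 1L)
            sp_len <- sample(31:35, 1L)
            spacer <- substr(seqs[p], sp_from, sp_from + sp_len - 1L)
            arr <- .plant_array(hosts[h], spacer, spec)
            hosts[h] <- arr$seq
            ledger_links[[length(ledger_links) + 1L]] <- list(
                phage = ids[p], host = host_ids[h],
                channel = "crispr_spacer",
                phage_start = sp_from,
                phage_end = sp_from + sp_len - 1L,
                host_start = arr$spacer_start)
        } else if (ch == "attb") {
            tl <- trna[trna$host_id == host_ids[h], ][1L, ]
            att <- substr(hosts[h], tl$end - 44L, tl$end)
            at_pos <- sample.int(plen - 60L, 1L)
            substr(seqs[p], at_pos, at_pos + 44L) <- att
            ledger_links[[length(ledger_links) + 1L]] <- list(
                phage = ids[p], host = host_ids[h],
                channel = "trna_attb", phage_start = at_pos,
                phage_end = at_pos + 44L, host_start = tl$end - 44L)
        } else if (ch == "shared") {
            reg_len <- 5000L
            p_from <- sample.int(plen - reg_len, 1L)
            h_at <- sample.int(spec$host_length - reg_len - 1000L, 1L) +
                500L
            substr(hosts[h], h_at, h_at + reg_len - 1L) <-
                substr(seqs[p], p_from, p_from + reg_len - 1L)
            ledger_links[[length(ledger_links) + 1L]] <- list(
                phage = ids[p], host = host_ids[h],
                channel = "shared_sequence", phage_start = p_from,
                phage_end = p_from + reg_len - 1L, host_start = h_at)
        } else if (ch == "marker") {
            ledger_links[[length(ledger_links) + 1L]] <- list(
                phage = ids[p], host = taxa[h],
                channel = "marker_gene")
        }
    }
    # contigs: genomes with planted terminal direct repeats
    contigs <- character(np)
    trep <- sample(spec$terminal_repeat_range[1L]:
                   spec$terminal_repeat_range[2L], np, replace = TRUE)
    for (i in seq_len(np))
        contigs[i] <- paste0(seqs[i], substr(seqs[i], 1L, trep[i]))
    phages <- DNAStringSet(seqs)
    names(phages) <- ids
    contig_set <- DNAStringSet(contigs)
    names(contig_set) <- ids
    host_set <- DNAStringSet(hosts)
    names(host_set) <- host_ids
    marker_set <- AAStringSet(markers)
    names(marker_set) <- sprintf("whiB_like_%02d|%s",
                                 seq_len(spec$n_hosts), taxa)
    mcols(marker_set) <- DataFrame(taxon = taxa)
    ledger <- list(
        seed = seed,
        genomes = data.frame(id = ids, length = nchar(seqs), gc = gcs,
                             group = group_of, founder = ids[founder_of],
                             terminal_repeat = trep,
                             stringsAsFactors = FALSE),
        links = ledger_links,
        host_taxa = stats::setNames(taxa, host_ids),
        n_groups = max(group_of))
    out <- list(phages = phages, contigs = contig_set,
                hosts = host_set, trna_loci = trna,
                markers = marker_set,
                host_taxa = ledger$host_taxa, ledger = ledger)
    if (!is.null(out_dir)) writeCommunity(out, out_dir)
    out
}

# insert a CRISPR array (5 identical 30 bp repeats, 4 spacers, one of
# them the planted phage-derived spacer) at a random host position
.plant_array <- function(host, spacer, spec) {
    rep_seq <- .rand_seq(30L, 0.5)
    others <- replicate(3L, .rand_seq(nchar(spacer), 0.5))
    spcs <- sample(c(spacer, others))
    arr <- paste0(rep_seq,
                  paste(paste0(spcs, rep_seq), collapse = ""))
    at <- sample.int(nchar(host) - nchar(arr) - 1000L, 1L) + 500L
    seq <- paste0(substr(host, 1L, at - 1L), arr,
                  substr(host, at, nchar(host)))
    sp_i <- which(spcs == spacer)[1L]
    sp_start <- at + 30L + (sp_i - 1L) * (nchar(spacer) + 30L)
    list(seq = seq, array_start = at, spacer_start = sp_start)
}

#' Write a synthetic community to disk
#'
#' @param community result of [generateCommunity()].
#' @param out_dir output directory (created if missing).
#' @export
writeCommunity <- function(community, out_dir) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeXStringSet(community$phages,
                    file.path(out_dir, "phages.fasta"), width = 60)
    writeXStringSet(community$contigs,
                    file.path(out_dir, "contigs.fasta"), width = 60)
    writeXStringSet(community$hosts,
                    file.path(out_dir, "hosts.fasta"), width = 60)
    writeXStringSet(community$markers,
                    file.path(out_dir, "markers.fasta"), width = 60)
    bed <- data.frame(chrom = community$trna_loci$host_id,
                      start = community$trna_loci$start - 1L,
                      end = community$trna_loci$end,
                      name = sprintf("tRNA%03d",
                                     seq_len(nrow(community$trna_loci))),
                      score = 0L, strand = "+")
    utils::write.table(bed, file.path(out_dir, "trna_loci.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(community$ledger,
                         file.path(out_dir, "ledger.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(out_dir)
}

#' Specification of a metagenome time series
#'
#' Emulates a stratified-lake sampling design: epilimnion and
#' hypolimnion samples across the season, with mixis (full-column
#' mixing) at the series ends. Each phage is assigned an abundance
#' regime: \code{boom_bust} (a short-lived epilimnion peak followed by
#' near disappearance), \code{persistent} (sustained hypolimnion
#' presence), or \code{mixis_shared} (appearing in the mixed-column
#' samples of both layers).
#'
#' @param samples data.frame with id, date, depth_label ("epi"/"hypo"),
#'   depth_m, temperature_C, mixis (logical). Default: 10 samples, 5
#'   per layer, first and last dates mixic.
#' @param read_length read length in bp (default 151; pairs are 2 x
#'   151).
#' @param error_rate per-base substitution error rate (default 0.005).
#' @param peak_depth,persist_depth,mixis_depth,background_depth mean
#'   per-genome fold coverages defining the regimes.
#' @return list of class "TimeSeriesSpec".
#' @export
timeSeriesSpec <- function(samples = NULL, read_length = 151L,
                           error_rate = 0.005, peak_depth = 15,
                           persist_depth = 8, mixis_depth = 10,
                           background_depth = 0.05) {
    if (is.null(samples)) {
        dates <- c("2015-04-15", "2015-06-10", "2015-07-15",
                   "2015-08-20", "2015-11-25")
        samples <- data.frame(
            id = c(paste0("RE", 1:5), paste0("RH", 1:5)),
            date = rep(dates, 2L),
            depth_label = rep(c("epi", "hypo"), each = 5L),
            depth_m = rep(c(0.5, 30), each = 5L),
            temperature_C = c(10, 18, 22, 24, 6, 5, 5, 6, 6, 5),
            mixis = rep(c(TRUE, FALSE, FALSE, FALSE, TRUE), 2L),
            stringsAsFactors = FALSE)
    }
    structure(list(samples = samples,
                   read_length = as.integer(read_length),
                   error_rate = error_rate, peak_depth = peak_depth,
                   persist_depth = persist_depth,
                   mixis_depth = mixis_depth,
                   background_depth = background_depth),
              class = "TimeSeriesSpec")
}

# depth matrix (genome x sample) realising the regimes
.regime_depths <- function(regimes, tspec) {
    smp <- tspec$samples
    ns <- nrow(smp)
    D <- matrix(0, length(regimes), ns,
                dimnames = list(names(regimes), smp$id))
    epi <- which(smp$depth_label == "epi" & !smp$mixis)
    hypo <- which(smp$depth_label == "hypo" & !smp$mixis)
    mix <- which(smp$mixis)
    resample <- function(x, n) x[sample.int(length(x), n)]
    for (i in seq_along(regimes)) {
        D[i, ] <- tspec$background_depth
        if (regimes[i] == "boom_bust") {
            pk <- resample(epi, min(length(epi), sample.int(2L, 1L)))
            D[i, pk] <- tspec$peak_depth
        } else if (regimes[i] == "persistent") {
            hypo_all <- which(smp$depth_label == "hypo")
            n_on <- min(length(hypo_all),
                        max(ceiling(length(hypo_all) * 0.6),
                            length(hypo_all) - 2L))
            on <- resample(hypo_all, n_on)
            D[i, on] <- tspec$persist_depth *
                stats::runif(length(on), 0.7, 1.3)
        } else if (regimes[i] == "mixis_shared") {
            D[i, mix] <- tspec$mixis_depth
        }
    }
    D
}

#' Simulate time-series read sets from a community
#'
#' Draws paired reads uniformly from circular genomes (origin-spanning
#' allowed) at per-sample depths realising each genome's abundance
#' regime, applies substitution errors, and records per-sample totals
#' in the ground-truth ledger.
#'
#' @param community a [generateCommunity()] result.
#' @param tspec a [timeSeriesSpec()].
#' @param seed integer seed.
#' @param regimes optional named character vector (genome id ->
#'   regime); default: founders of replicate groups are persistent
#'   (hypolimnion), phages with planted links mixis_shared or
#'   boom_bust, the rest boom_bust.
#' @param out_dir optional directory for FASTQ and metadata TSV output.
#' @return list with \code{samples} (list of MetagenomeSample),
#'   \code{depths} (planted genome x sample depth matrix),
#'   \code{regimes}, and \code{metadata}.
#' @export
generateReads <- function(community, tspec = timeSeriesSpec(),
                          seed = 1L, regimes = NULL, out_dir = NULL) {
    set.seed(seed + 1000L)
    ids <- names(community$phages)
    if (is.null(regimes)) {
        led <- community$ledger$genomes
        regimes <- stats::setNames(rep("boom_bust", length(ids)), ids)
        grp_sizes <- table(led$group)
        in_group <- led$group %in% names(grp_sizes)[grp_sizes > 1L]
        regimes[in_group] <- "persistent"
        linked <- unique(vapply(community$ledger$links, function(l)
            l$phage, ""))
        cand <- intersect(linked, ids[!in_group])
        if (length(cand))
            regimes[utils::head(cand, 2L)] <- "mixis_shared"
    }
    D <- .regime_depths(regimes, tspec)
    rl <- tspec$read_length
    glen <- Biostrings::width(community$phages)
    gchr <- as.character(community$phages)
    gext <- paste0(gchr, substr(gchr, 1L, rl + 600L))
    samples <- list()
    for (si in seq_len(nrow(tspec$samples))) {
        rs <- list()
        for (gi in seq_along(ids)) {
            d <- D[gi, si]
            n_pairs <- round(d * glen[gi] / (2 * rl))
            if (n_pairs < 1L) next
            starts <- sample.int(glen[gi], n_pairs, replace = TRUE)
            insert <- pmax(2L * rl,
                           round(stats::rnorm(n_pairs, 350, 50)))
            r1 <- substring(gext[gi], starts, starts + rl - 1L)
            m2s <- starts + insert - rl
            r2 <- substring(gext[gi], m2s, m2s + rl - 1L)
            r2 <- as.character(reverseComplement(DNAStringSet(r2)))
            rs[[length(rs) + 1L]] <- c(r1, r2)
        }
        reads <- unlist(rs)
        if (is.null(reads)) reads <- character()
        if (length(reads) && tspec$error_rate > 0)
            reads <- .add_errors(reads, tspec$error_rate)
        if (length(reads)) {
            reads <- sample(reads)
            names(reads) <- sprintf("%s_read%06d",
                                    tspec$samples$id[si],
                                    seq_along(reads))
        }
        md <- tspec$samples[si, ]
        samples[[si]] <- metagenomeSample(
            md$id, DNAStringSet(reads), date = md$date,
            depth_m = md$depth_m, temperature_C = md$temperature_C,
            depth_label = md$depth_label)
    }
    md <- tspec$samples
    md$total_bases <- vapply(samples, function(s) s@totalBases, 0)
    md$n_reads <- vapply(samples, function(s)
        length(s@reads), 0L)
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        for (s in samples) {
            q <- Biostrings::BStringSet(strrep("I",
                Biostrings::width(s@reads)))
            Biostrings::writeXStringSet(
                s@reads, file.path(out_dir, paste0(s@id, ".fastq")),
                format = "fastq", qualities = q)
        }
        utils::write.table(md, file.path(out_dir, "samples.tsv"),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    list(samples = samples, depths = D, regimes = regimes,
         metadata = md)
}

# iid substitution errors over a read vector
.add_errors <- function(reads, rate) {
    n <- nchar(reads)
    tot <- sum(n)
    v <- strsplit(paste(reads, collapse = ""), "")[[1L]]
    k <- stats::rbinom(1L, tot, rate)
    if (k > 0L) {
        pos <- sample.int(tot, k)
        v[pos] <- vapply(v[pos], function(b)
            sample(setdiff(.DNA, b), 1L), "")
    }
    s <- paste(v, collapse = "")
    ends <- cumsum(n)
    substring(s, ends - n + 1L, ends)
}
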