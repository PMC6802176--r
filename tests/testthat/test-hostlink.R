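test_that("planted marker proteins are detected at phylum resolution", {
    set.seed(501)
    marker_aa <- paste0("M", paste(sample(setdiff(
        strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "M"), 119,
        replace = TRUE), collapse = ""))
    markers <- Biostrings::AAStringSet(c("whiB_like|Actinobacteria" =
                                             marker_aa))
    cds <- limnophage:::.reverse_translate(marker_aa)
    phage <- paste0(coding_genome(4000), cds, coding_genome(4000))
    ev <- detectMarkerGenes(phage, "p1", markers)
    expect_gte(nrow(ev), 1)
    expect_equal(unique(ev$host_id), "Actinobacteria")
    expect_equal(unique(ev$taxon_resolution), "phylum")
    # two planted copies -> two evidence records
    phage2 <- paste0(coding_genome(3000), cds, rand_seq(500), cds,
                     coding_genome(3000))
    ev2 <- detectMarkerGenes(phage2, "p2", markers)
    expect_gte(nrow(ev2), 2)
    # random ORFs yield no marker evidence
    set.seed(502)
    fp <- 0
    for (i in 1:10) {
        evr <- detectMarkerGenes(coding_genome(6000), "px", markers)
        if (nrow(evr)) fp <- fp + 1
    }
    expect_equal(fp, 0)
})

test_that("planted CRISPR arrays are recovered with exact spacers", {
    set.seed(503)
    rep30 <- rand_seq(30)
    spc <- replicate(4, rand_seq(32))
    arr <- paste0(rep30, paste(paste0(spc, rep30), collapse = ""))
    host <- paste0(rand_seq(40000), arr, rand_seq(40000))
    arrays <- detectCrisprArrays(host, "h1")
    expect_length(arrays, 1)
    a <- arrays[[1]]
    expect_equal(length(a@repeats), 5L)
    expect_equal(a@repeatConsensus, rep30)
    expect_equal(unname(as.character(spacers(a))), spc)
    # two repeat copies only: below the minimum of three
    arr2 <- paste0(rep30, spc[1], rep30)
    host2 <- paste0(rand_seq(20000), arr2, rand_seq(20000))
    expect_length(detectCrisprArrays(host2, "h2"), 0)
})

test_that("random hosts yield no CRISPR arrays", {
    set.seed(504)
    fp <- 0
    for (i in 1:5)
        fp <- fp + length(detectCrisprArrays(rand_seq(2e5), "h"))
    expect_equal(fp, 0)
})

test_that("spacer matching enforces the stringent printed cutoffs", {
    set.seed(505)
    phage <- rand_seq(20000)
    mkarr <- function(spacer) {
        rep30 <- rand_seq(30)
        others <- replicate(3, rand_seq(nchar(spacer)))
        seqs <- c(spacer, others)
        arr_seq <- paste0(rep30, paste(paste0(seqs, rep30),
                                       collapse = ""))
        host <- paste0(rand_seq(5000), arr_seq, rand_seq(5000))
        detectCrisprArrays(host, "hostX")
    }
    phages <- Biostrings::DNAStringSet(c(pA = phage))
    # 32 bp verbatim spacer -> link
    sp32 <- substr(phage, 1001, 1032)
    ev <- matchSpacers(mkarr(sp32), phages)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$phage_id, "pA")
    expect_equal(ev$taxon_resolution, "strain")
    # 29 bp exact match -> rejected (length < 30)
    ev29 <- matchSpacers(mkarr(substr(phage, 2001, 2029)), phages)
    expect_equal(nrow(ev29), 0)
    # 32 bp at ~94% identity (2 mismatches) -> rejected (< 97%)
    sp_mut <- sp32
    substr(sp_mut, 5, 5) <- setdiff(DNA, substr(sp_mut, 5, 5))[1]
    substr(sp_mut, 20, 20) <- setdiff(DNA, substr(sp_mut, 20, 20))[1]
    ev_mut <- matchSpacers(mkarr(sp_mut), phages)
    expect_equal(nrow(ev_mut), 0)
})

test_that("attB evidence requires overlap with an annotated tRNA locus", {
    set.seed(506)
    host <- rand_seq(50000)
    loci <- data.frame(start = 30001, end = 30075)
    att <- substr(host, 30031, 30075)          # 45 bp of tRNA 3' end
    phage_in <- paste0(rand_seq(8000), att, rand_seq(8000))
    ev <- matchTrnaAttB(phage_in, host, "p", "h", loci)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$channel, "trna_attb")
    # same 45 bp match outside any locus: no attB evidence, but the
    # shared-sequence channel still fires
    att_out <- substr(host, 10000, 10044)
    phage_out <- paste0(rand_seq(8000), att_out, rand_seq(8000))
    expect_equal(nrow(matchTrnaAttB(phage_out, host, "p", "h", loci)), 0)
    expect_gte(nrow(sharedSequenceEvidence(phage_out, host, "p", "h")),
               1)
})

test_that("shared-sequence evidence follows the per-hit cutoffs", {
    set.seed(507)
    phage <- rand_seq(30000)
    host <- paste0(rand_seq(20000), substr(phage, 5001, 10000),
                   rand_seq(20000))
    ev <- sharedSequenceEvidence(phage, host, "p", "h")
    expect_gte(nrow(ev), 1)
    expect_true(all(ev$pident >= 97 & ev$evalue <= 1e-5))
    # 25 bp match at high identity -> rejected (< 30 bp)
    host25 <- paste0(rand_seq(20000), substr(phage, 101, 125),
                     rand_seq(20000))
    expect_equal(nrow(sharedSequenceEvidence(phage, host25, "p", "h")),
                 0)
    # unrelated pair -> no evidence
    fp <- 0
    for (i in 1:5)
        fp <- fp + nrow(sharedSequenceEvidence(rand_seq(20000),
                                               rand_seq(20000)))
    expect_equal(fp, 0)
})

test_that("host assignment respects precedence, ties, and emptiness", {
    ev <- function(ch, host, n = 1)
        do.call(rbind, replicate(n, limnophage:::.evidence_row(
            "p1", host, ch,
            if (ch == "marker_gene") "phylum" else "strain"),
            simplify = FALSE))
    # spacer beats marker
    e <- rbind(ev("crispr_spacer", "H1"), ev("marker_gene", "PhyX"))
    call <- assignHost(e)
    expect_equal(call$host_id, "H1")
    expect_equal(call$winning_channel, "crispr_spacer")
    # marker-only: phylum-level assignment
    call2 <- assignHost(ev("marker_gene", "PhyX", 2))
    expect_equal(call2$host_id, "PhyX")
    expect_equal(call2$status, "assigned")
    # tie within the winning channel -> ambiguous
    call3 <- assignHost(rbind(ev("crispr_spacer", "H1"),
                              ev("crispr_spacer", "H2")))
    expect_equal(call3$status, "ambiguous")
    # empty -> unassigned
    call4 <- assignHost(limnophage:::.empty_evidence(), "p9")
    expect_equal(call4$status, "unassigned")
    # pure function of the evidence multiset: order-invariant
    e5 <- rbind(ev("shared_sequence", "H1"), ev("trna_attb", "H2"),
                ev("shared_sequence", "H1"))
    expect_equal(assignHost(e5), assignHost(e5[c(3, 1, 2), ]))
})
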