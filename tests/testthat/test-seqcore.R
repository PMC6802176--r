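test_that("GC content matches direct base counting and handles N", {
    expect_equal(gcContent("ATGC"), 0.5)
    expect_equal(gcContent("GGCC"), 1.0)
    set.seed(101)
    s <- rand_seq(10000, gc = 0.42)
    v <- strsplit(s, "")[[1]]
    expect_equal(gcContent(s),
                 sum(v %in% c("G", "C")) / length(v))
    # N excluded from numerator and denominator
    expect_equal(gcContent("GGNNAA"), 0.5)
    expect_error(gcContent("NNNN"), "undefined")
})

test_that("expectation value follows the Karlin-Altschul form", {
    p <- alignerParams("nucleotide")
    # linear in the search space
    expect_equal(expectationValue(50, 100, 2000, p),
                 2 * expectationValue(50, 100, 1000, p))
    # strictly decreasing in score
    expect_lt(expectationValue(60, 1000, 1000, p),
              expectationValue(50, 1000, 1000, p))
    # direct arithmetic with explicit constants
    expect_equal(expectationValue(100, 1000, 1000, K = 0.041,
                                  lambda = 0.267),
                 0.041 * 1000 * 1000 * exp(-0.267 * 100))
    expect_error(expectationValue(10, 0, 100, p), "positive")
    expect_error(expectationValue(-1, 10, 10, p), "score")
})

test_that("ORF calling recovers a planted ORF with exact coordinates", {
    set.seed(102)
    gene <- rand_gene(300)             # 300 aa + start/stop = 906 bp
    flank1 <- rand_seq(500)
    s <- paste0(flank1, "TAA", gene, "TAA", rand_seq(500))
    orfs <- findOrfs(s, min_length_aa = 250)
    mc <- as.data.frame(S4Vectors::mcols(orfs))
    idx <- which(mc$start == nchar(flank1) + 4 &
                 mc$end == nchar(flank1) + 3 + nchar(gene))
    expect_length(idx, 1L)
    expect_equal(mc$frame[idx], (nchar(flank1) + 3) %% 3 + 1)
    expect_equal(Biostrings::width(orfs)[idx], 301)
})

test_that("sequences without start codons yield no ORFs", {
    # poly-C has no ATG/GTG/TTG on either strand
    expect_length(findOrfs(strrep("C", 3000), 10), 0L)
})

test_that("ORF sets are strand-symmetric", {
    set.seed(103)
    s <- coding_genome(4000)
    a <- findOrfs(s, 50)
    b <- findOrfs(revcomp(s), 50)
    expect_setequal(unname(as.character(a)), unname(as.character(b)))
    # intervals mirror: start' = n - end + 1
    n <- nchar(s)
    ma <- as.data.frame(S4Vectors::mcols(a))
    mb <- as.data.frame(S4Vectors::mcols(b))
    ka <- sort(paste(ma$start, ma$end))
    kb <- sort(paste(n - mb$end + 1, n - mb$start + 1))
    expect_identical(ka, kb)
})

test_that("self-alignment yields one full-length perfect hit", {
    set.seed(104)
    s <- rand_seq(1000)
    h <- nucAlign(s, s)
    top <- h[1, ]
    expect_equal(top$pident, 100)
    expect_equal(top$length, 1000L)
    expect_equal(top$strand, "+")
    expect_equal(c(top$qstart, top$qend, top$sstart, top$send),
                 c(1L, 1000L, 1L, 1000L))
})

test_that("reverse-complement subject aligns full length on minus strand", {
    set.seed(105)
    s <- rand_seq(1000)
    h <- nucAlign(s, revcomp(s))
    expect_equal(h$strand[1], "-")
    expect_equal(h$pident[1], 100)
    expect_equal(h$length[1], 1000L)
})

test_that("sequences sharing no seed k-mer produce no hits", {
    set.seed(106)
    k <- 13
    repeat {
        a <- rand_seq(1000); b <- rand_seq(1000)
        ka <- substring(a, 1:(1000 - k + 1), k:1000)
        kb <- substring(b, 1:(1000 - k + 1), k:1000)
        kb_rc <- substring(revcomp(b), 1:(1000 - k + 1), k:1000)
        if (!length(intersect(ka, c(kb, kb_rc)))) break
    }
    expect_equal(nrow(nucAlign(a, b)), 0L)
})

test_that("reported hits satisfy the parameter thresholds post hoc", {
    set.seed(107)
    a <- coding_genome(3000)
    b <- paste0(rand_seq(400), substr(a, 1001, 2200), rand_seq(400))
    p <- alignerParams("nucleotide", min_identity = 90,
                       min_alignment_length = 100,
                       max_expectation = 1e-3)
    h <- nucAlign(a, b, p)
    expect_gt(nrow(h), 0)
    expect_true(all(h$pident >= 90))
    expect_true(all(h$length >= 100))
    expect_true(all(h$evalue <= 1e-3))
    # alignment symmetric up to interval swap
    h2 <- nucAlign(b, a, p)
    expect_equal(nrow(h), nrow(h2))
    expect_setequal(paste(h$qstart, h$qend, h$sstart, h$send),
                    paste(h2$sstart, h2$send, h2$qstart, h2$qend))
})

test_that("translated self-alignment is consistent with summed scores", {
    set.seed(108)
    g <- coding_genome(2000)
    h <- translatedAlign(g, g)
    expect_gt(nrow(h), 0)
    expect_equal(sum(h$score), summedScore(g, g))
    # six perfect frame self-hits dominate
    self6 <- h[h$qframe == h$sframe & h$pident == 100, ]
    expect_gte(nrow(self6), 6)
})

test_that("a frame shift still reveals the shared protein", {
    set.seed(109)
    g <- paste0(rand_seq(90), rand_gene(200), rand_seq(90))
    shifted <- substr(g, 2, nchar(g))
    h <- translatedAlign(g, shifted)
    expect_gt(nrow(h), 0)
    best <- h[1, ]
    expect_gte(best$length, 180)
    expect_equal(best$pident, 100)
    expect_gt(best$qframe, 0)
    expect_gt(best$sframe, 0)
    expect_true(best$qframe != best$sframe)   # found in the shifted frame
})

test_that("random non-coding sequences rarely reach translated significance", {
    set.seed(110)
    fails <- 0
    for (i in 1:20) {
        a <- rand_seq(5000); b <- rand_seq(5000)
        h <- translatedAlign(a, b)
        if (nrow(h) > 0) fails <- fails + 1
    }
    expect_lte(fails, 1)   # >= 95% of trials hit-free
})

test_that("hit tables round-trip through the 12-column format", {
    set.seed(111)
    a <- rand_seq(800)
    h <- nucAlign(a, revcomp(a))
    tf <- tempfile(fileext = ".tsv")
    writeHits(h, tf)
    h2 <- readHits(tf)
    expect_equal(h2$strand, h$strand)
    expect_equal(h2$sstart, h$sstart)
    expect_equal(h2$send, h$send)
    expect_equal(h2$pident, h$pident, tolerance = 1e-6)
    unlink(tf)
})

test_that("aligner parameter validation rejects bad settings", {
    expect_error(alignerParams("nucleotide", seed_length = 5), ">= 8")
    expect_error(alignerParams("translated", seed_length = 2), ">= 3")
    expect_error(alignerParams("nucleotide", min_identity = 120),
                 "min_identity")
})
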