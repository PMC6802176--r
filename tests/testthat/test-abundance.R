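test_that("rRNA masking replaces intervals with N and preserves length", {
    set.seed(601)
    g <- rand_seq(10000)
    m <- maskRrna(g, data.frame(start = 1, end = 1500))
    expect_equal(length(m), 10000L)
    expect_equal(Biostrings::countPattern("N", m), 1500L)
    expect_equal(as.character(Biostrings::subseq(m, 1501, 10000)),
                 substr(g, 1501, 10000))
    # empty interval list is the identity
    expect_equal(as.character(maskRrna(g, data.frame())), g)
    # overlapping intervals are unioned
    m2 <- maskRrna(g, data.frame(start = c(1, 50), end = c(100, 150)))
    expect_equal(Biostrings::countPattern("N", m2), 150L)
    expect_error(maskRrna(g, data.frame(start = 9999, end = 10001)),
                 "within")
})

test_that("read subsampling is capped, seeded, and deterministic", {
    set.seed(602)
    reads <- Biostrings::DNAStringSet(replicate(1000, rand_seq(151)))
    names(reads) <- sprintf("r%04d", 1:1000)
    s <- metagenomeSample("s1", reads)
    expect_identical(subsampleReads(s, 2000, 1)@reads, reads)
    a <- subsampleReads(s, 100, seed = 9)
    b <- subsampleReads(s, 100, seed = 9)
    expect_equal(length(a@reads), 100L)
    expect_identical(names(a@reads), names(b@reads))
    expect_equal(a@totalBases, 100 * 151)
})

test_that("coverage per gigabase matches direct arithmetic", {
    # 1000 reads x 150 bp on a 10 kb genome in a 1 Gb sample:
    # mean depth 15 -> 15 per Gb
    depth <- rep(15L, 10000)
    expect_equal(coveragePerGb(depth, 10000, 1e9), 15)
    expect_equal(coveragePerGb(rep(0L, 10000), 10000, 1e9), 0)
    # doubling the sample halves the value
    expect_equal(coveragePerGb(depth, 10000, 2e9), 7.5)
})

test_that("presence calls use a strict 80% breadth rule", {
    expect_false(presenceCall(0.79))
    expect_false(presenceCall(0.80))
    expect_true(presenceCall(0.90))
})

test_that("row Z-scores use the population sd and zero constant rows", {
    z <- zscoreRows(matrix(c(1, 2, 3), 1))
    expect_equal(as.vector(z), c(-1, 0, 1) * sqrt(3 / 2),
                 tolerance = 1e-12)
    expect_equal(as.vector(zscoreRows(matrix(5, 1, 4))), rep(0, 4))
    set.seed(603)
    m <- matrix(rnorm(50), 5)
    z <- zscoreRows(m)
    expect_true(all(abs(rowMeans(z)) < 1e-9))
    sds <- apply(z, 1, function(r) sqrt(mean((r - mean(r))^2)))
    expect_true(all(abs(sds - 1) < 1e-9))
})

test_that("profile clustering matches a brute-force average-linkage oracle", {
    set.seed(604)
    # identical profiles join at height 0; anti-correlated at 2
    m <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
               c = c(5, 4, 3, 2, 1))
    hc <- clusterProfiles(m)
    expect_equal(hc$height[1], 0, tolerance = 1e-12)   # rho = 1
    expect_equal(max(hc$height), 2, tolerance = 1e-12) # rho = -1
    # two planted correlation blocks among 10 profiles
    base1 <- seq(1, 5, length.out = 8)
    base2 <- rev(base1)
    prof <- rbind(
        t(sapply(1:5, function(i) base1 + rnorm(8, 0, 0.1))),
        t(sapply(1:5, function(i) base2 + rnorm(8, 0, 0.1))))
    rownames(prof) <- sprintf("g%02d", 1:10)
    hc <- clusterProfiles(prof)
    top <- stats::cutree(hc, 2)
    expect_equal(length(unique(top[1:5])), 1L)
    expect_equal(length(unique(top[6:10])), 1L)
    expect_true(top[1] != top[10])
    # O(n^3) oracle for average-linkage merge heights on 1 - rho
    d <- 1 - stats::cor(t(prof), method = "spearman")
    oracle_heights <- local({
        groups <- as.list(rownames(prof))
        hts <- numeric()
        while (length(groups) > 1) {
            best <- c(Inf, 0, 0)
            for (i in seq_along(groups)) for (j in seq_along(groups)) {
                if (i >= j) next
                dd <- mean(d[groups[[i]], groups[[j]]])
                if (dd < best[1]) best <- c(dd, i, j)
            }
            hts <- c(hts, best[1])
            groups[[best[2]]] <- c(groups[[best[2]]],
                                   groups[[best[3]]])
            groups <- groups[-best[3]]
        }
        hts
    })
    expect_equal(sort(hc$height), sort(oracle_heights),
                 tolerance = 1e-12)
})

test_that("recruitment recovers error-free reads and rejects junk", {
    set.seed(605)
    g <- rand_seq(15000)
    gext <- paste0(g, substr(g, 1, 200))
    starts <- sample.int(15000, 400, replace = TRUE)
    reads <- substring(gext, starts, starts + 150)
    # half the reads on the minus strand
    flip <- seq(1, 400, 2)
    reads[flip] <- vapply(reads[flip], revcomp, "")
    smp <- metagenomeSample("s", Biostrings::DNAStringSet(reads))
    genomes <- Biostrings::DNAStringSet(c(gen = g,
                                          other = rand_seq(12000)))
    rec <- recruitReads(genomes, smp)
    expect_equal(rec$gen$n_reads, 400L)
    expect_equal(rec$other$n_reads, 0L)
    expect_equal(sum(rec$gen$depth), 400L * 151L)
    # reads from an unrelated genome recruit nowhere
    junk <- Biostrings::DNAStringSet(replicate(100, rand_seq(151)))
    rec2 <- recruitReads(genomes, metagenomeSample("s2", junk))
    expect_equal(rec2$total, 0L)
    # 40 bp fragments: below the 50 bp alignment-length floor
    short <- Biostrings::DNAStringSet(
        substring(g, seq(1, 4000, 100), seq(40, 4039, 100)))
    rec3 <- recruitReads(genomes, metagenomeSample("s3", short))
    expect_equal(rec3$total, 0L)
})

test_that("abundance experiments assemble consistent matrices", {
    set.seed(606)
    g1 <- rand_seq(12000); g2 <- rand_seq(12000)
    mk_reads <- function(g, n) {
        gext <- paste0(g, substr(g, 1, 200))
        st <- sample.int(nchar(g), n, replace = TRUE)
        Biostrings::DNAStringSet(substring(gext, st, st + 150))
    }
    s1 <- metagenomeSample("s1", mk_reads(g1, 800), date = "2015-06-01",
                           temperature_C = 20, depth_label = "epi")
    s2 <- metagenomeSample("s2", c(mk_reads(g1, 100), mk_reads(g2, 900)),
                           date = "2015-07-01", temperature_C = 22,
                           depth_label = "epi")
    ab <- abundanceExperiment(
        Biostrings::DNAStringSet(c(g1 = g1, g2 = g2)), list(s1, s2))
    expect_s4_class(ab, "AbundanceExperiment")
    expect_equal(dim(ab), c(2L, 2L))
    expect_identical(presenceCalls(ab), breadthMatrix(ab) > 0.8)
    expect_false(presenceCalls(ab)["g2", "s1"])
    expect_true(presenceCalls(ab)["g1", "s1"])
    expect_true(presenceCalls(ab)["g2", "s2"])
    # coverage/Gb invariance under duplication of the sample
    dup <- metagenomeSample("dup", c(s1@reads, s1@reads))
    ab2 <- abundanceExperiment(Biostrings::DNAStringSet(c(g1 = g1)),
                               list(s1, dup))
    cpg <- coverageMatrix(ab2)
    expect_equal(cpg["g1", "s1"], cpg["g1", "dup"], tolerance = 1e-9)
    expect_equal(SummarizedExperiment::colData(ab)$temperature_C,
                 c(20, 22))
})

test_that("masked positions are excluded from depth and breadth", {
    set.seed(607)
    g <- rand_seq(10000)
    masked <- maskRrna(g, data.frame(start = 1, end = 2000))
    unmasked_region <- substr(g, 2001, 10000)
    st <- sample.int(7850, 600, replace = TRUE)
    reads <- Biostrings::DNAStringSet(
        substring(unmasked_region, st, pmin(st + 150, 8000)))
    reads <- reads[Biostrings::width(reads) >= 51]
    smp <- metagenomeSample("s", reads)
    ab <- abundanceExperiment(Biostrings::DNAStringSet(c(g = masked)),
                              list(smp), circular = FALSE)
    expect_true(breadthMatrix(ab)["g", "s"] > 0.95)
})
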