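test_that("community generation is byte-identical under a fixed seed", {
    spec <- communitySpec(n_phages = 6, replicate_groups = c(2L),
                          length_modes = c(14000, 16000),
                          host_length = 60000L, n_hosts = 2L,
                          links = data.frame(phage = 3L, host = 1L,
                                             channel = "spacer"))
    d1 <- tempfile(); d2 <- tempfile()
    c1 <- generateCommunity(spec, seed = 7, out_dir = d1)
    c2 <- generateCommunity(spec, seed = 7, out_dir = d2)
    for (f in c("phages.fasta", "contigs.fasta", "hosts.fasta"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    c3 <- generateCommunity(spec, seed = 8)
    expect_false(identical(as.character(c1$phages),
                           as.character(c3$phages)))
    unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted spacers occur verbatim in their phage", {
    spec <- communitySpec(n_phages = 5, replicate_groups = integer(),
                          length_modes = c(14000, 15000),
                          host_length = 50000L, n_hosts = 2L,
                          links = data.frame(phage = c(1L, 2L),
                                             host = c(1L, 2L),
                                             channel = "spacer"))
    comm <- generateCommunity(spec, seed = 21)
    for (l in comm$ledger$links) {
        sp <- substr(as.character(comm$phages[[l$phage]]),
                     l$phage_start, l$phage_end)
        expect_gte(nchar(sp), 31)
        expect_true(grepl(sp, as.character(comm$hosts[[l$host]]),
                          fixed = TRUE))
    }
})

test_that("replicate copies sit at the planted mutation distance", {
    spec <- communitySpec(n_phages = 4, replicate_groups = c(2L),
                          mutation_rate = 0.02,
                          length_modes = c(14000, 15000),
                          host_length = 50000L, n_hosts = 1L,
                          links = data.frame(phage = 3L, host = 1L,
                                             channel = "shared"))
    comm <- generateCommunity(spec, seed = 31)
    led <- comm$ledger$genomes
    copy <- led$id[led$group == 1 & led$id != led$founder][1]
    founder <- led$founder[led$id == copy]
    pc <- compareGenomePair(as.character(comm$phages[[founder]]),
                            as.character(comm$phages[[copy]]))
    expect_gt(pc$coverage_a, 0.98)
    expect_equal(pc$mean_identity, 98, tolerance = 0.3)
})

test_that("contigs carry detectable terminal repeats for every phage", {
    spec <- communitySpec(n_phages = 5, replicate_groups = integer(),
                          length_modes = c(14000, 15000),
                          host_length = 50000L, n_hosts = 1L,
                          links = data.frame(phage = 1L, host = 1L,
                                             channel = "marker"))
    comm <- generateCommunity(spec, seed = 41)
    led <- comm$ledger$genomes
    for (i in seq_along(comm$contigs)) {
        cc <- detectCircularity(comm$contigs[[i]], 20)
        expect_true(cc$is_circular)
        expect_equal(cc$overlap_len, led$terminal_repeat[i])
        expect_equal(as.character(cc$trimmed),
                     as.character(comm$phages[[i]]))
    }
})

test_that("error-free reads recruit fully at the planted depth", {
    set.seed(801)
    g <- coding_genome(12000)
    comm <- list(phages = Biostrings::DNAStringSet(c(pg = g)),
                 ledger = list(genomes = data.frame(
                     id = "pg", group = 1L, stringsAsFactors = FALSE),
                     links = list()))
    tspec <- timeSeriesSpec(
        samples = data.frame(id = "s1", date = "2015-06-01",
                             depth_label = "epi", depth_m = 0.5,
                             temperature_C = 20, mixis = FALSE),
        error_rate = 0)
    rd <- generateReads(comm, tspec, seed = 5,
                        regimes = c(pg = "boom_bust"))
    # boom_bust peaks in its single epi sample... the sample is mixis-free
    expect_equal(unname(rd$depths["pg", "s1"]), 15)
    smp <- rd$samples[[1]]
    rec <- recruitReads(comm$phages, smp)
    expect_equal(rec$pg$n_reads, length(smp@reads))
    depth <- mean(rec$pg$depth)
    expect_equal(depth, 15, tolerance = 0.1)   # binomial expectation
})

test_that("substitution errors keep reads recruitable above 95% identity", {
    set.seed(802)
    g <- coding_genome(12000)
    comm <- list(phages = Biostrings::DNAStringSet(c(pg = g)),
                 ledger = list(genomes = data.frame(
                     id = "pg", group = 1L, stringsAsFactors = FALSE),
                     links = list()))
    tspec <- timeSeriesSpec(
        samples = data.frame(id = "s1", date = "2015-06-01",
                             depth_label = "epi", depth_m = 0.5,
                             temperature_C = 20, mixis = FALSE),
        error_rate = 0.005)
    rd <- generateReads(comm, tspec, seed = 6,
                        regimes = c(pg = "boom_bust"))
    smp <- rd$samples[[1]]
    rec <- recruitReads(comm$phages, smp)
    expect_gt(rec$pg$n_reads / length(smp@reads), 0.98)
})

test_that("regime depth profiles respect the layer constraints", {
    set.seed(803)
    tspec <- timeSeriesSpec()
    regimes <- c(a = "boom_bust", b = "persistent", c = "mixis_shared")
    D <- limnophage:::.regime_depths(regimes, tspec)
    smp <- tspec$samples
    # boom-bust: high depth in at most 2 epi samples, background elsewhere
    peaks_a <- which(D["a", ] > 1)
    expect_lte(length(peaks_a), 2)
    expect_true(all(smp$depth_label[peaks_a] == "epi"))
    # persistent: above presence-supporting depth in >= half the
    # hypolimnion samples
    hypo <- which(smp$depth_label == "hypo")
    expect_gte(sum(D["b", hypo] >= 5), length(hypo) / 2)
    # mixis phages appear in mixis samples of both layers
    mix <- which(smp$mixis)
    expect_true(all(D["c", mix] > 1))
    expect_setequal(unique(smp$depth_label[mix]), c("epi", "hypo"))
})

test_that("generator outputs round-trip through their format readers", {
    spec <- communitySpec(n_phages = 4, replicate_groups = integer(),
                          length_modes = c(14000, 15000),
                          host_length = 40000L, n_hosts = 1L,
                          links = data.frame(phage = 1L, host = 1L,
                                             channel = "attb"))
    d <- tempfile()
    comm <- generateCommunity(spec, seed = 51, out_dir = d)
    ph <- Biostrings::readDNAStringSet(file.path(d, "phages.fasta"))
    expect_equal(as.character(ph), as.character(comm$phages))
    bed <- rtracklayer::import(file.path(d, "trna_loci.bed"))
    expect_equal(length(bed), nrow(comm$trna_loci))
    expect_equal(GenomicRanges::start(bed), comm$trna_loci$start)
    led <- jsonlite::read_json(file.path(d, "ledger.json"))
    expect_equal(led$seed, 51)
    # FASTQ round-trip
    tspec <- timeSeriesSpec(samples = data.frame(
        id = "s1", date = "2015-06-01", depth_label = "epi",
        depth_m = 0.5, temperature_C = 20, mixis = FALSE))
    rd <- generateReads(comm, tspec, seed = 52,
                        regimes = stats::setNames(
                            rep("boom_bust", 4), names(comm$phages)),
                        out_dir = d)
    fq <- Biostrings::readDNAStringSet(file.path(d, "s1.fastq"),
                                       format = "fastq")
    expect_equal(length(fq), length(rd$samples[[1]]@reads))
    unlink(d, recursive = TRUE)
})

test_that("infeasible specifications are rejected", {
    expect_error(communitySpec(mutation_rate = 0.2), "mutation_rate")
    expect_error(communitySpec(n_phages = 3,
                               replicate_groups = c(3L, 3L)),
                 "exceed")
})
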