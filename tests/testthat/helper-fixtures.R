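# Shared fixture builders: random sequences, coding genomes, additive
# distance matrices. All deterministic under the caller's seed.

DNA <- c("A", "C", "G", "T")

rand_seq <- function(n, gc = 0.5) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(DNA, n, replace = TRUE, prob = p), collapse = "")
}

.codons <- local({
    gc11 <- Biostrings::getGeneticCode("11")
    names(gc11)[gc11 != "*"]
})

rand_gene <- function(n_aa) {
    paste0("ATG", paste(sample(.codons, n_aa, replace = TRUE),
                        collapse = ""), "TAA")
}

# gene-dense coding genome of ~len bp
coding_genome <- function(len, gene_aa = 80:300) {
    parts <- character(); tot <- 0L
    while (tot < len) {
        g <- rand_gene(sample(gene_aa, 1L))
        ig <- rand_seq(sample(20:80, 1L))
        parts <- c(parts, g, ig)
        tot <- tot + nchar(g) + nchar(ig)
    }
    substr(paste(parts, collapse = ""), 1L, len)
}

# substitute a fraction of positions (never to the original base)
mutate_seq <- function(chr, rate) {
    n <- nchar(chr)
    k <- round(n * rate)
    if (k == 0L) return(chr)
    pos <- sample.int(n, k)
    v <- strsplit(chr, "")[[1L]]
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(DNA, b), 1L), "")
    paste(v, collapse = "")
}

revcomp <- function(chr)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(chr)))

# random unrooted binary tree over n taxa with positive branch lengths,
# and its additive patristic distance matrix
random_additive_matrix <- function(n, min_edge = 0.05, max_edge = 0.3) {
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) runif(k, min_edge, max_edge))
    tr$tip.label <- sprintf("t%02d", seq_len(n))
    D <- ape::cophenetic.phylo(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    list(tree = tr, D = D)
}

# canonical set of non-trivial bipartitions of an unrooted tree, each
# encoded as the sorted side not containing the first tip (alphabetical)
tree_bipartitions <- function(tree) {
    tree <- ape::unroot(tree)
    tips <- sort(tree$tip.label)
    pp <- ape::prop.part(tree)
    labs <- attr(pp, "labels")
    out <- character()
    for (cl in pp) {
        side <- labs[cl]
        if (length(side) <= 1L || length(side) >= length(tips) - 1L)
            next
        if (tips[1L] %in% side) side <- setdiff(tips, side)
        if (length(side) <= 1L || length(side) >= length(tips) - 1L)
            next
        out <- c(out, paste(sort(side), collapse = ","))
    }
    sort(unique(out))
}

same_topology <- function(t1, t2)
    identical(tree_bipartitions(t1), tree_bipartitions(t2))
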