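#' @include seqcore-translated.R
NULL

#' Dice distance from summed comparison scores
#'
#' Similarity = 2 * S(A,B) / (S(A,A) + S(B,B)) over summed translated
#' comparison scores; distance = 1 - similarity, clamped to [0, 1].
#'
#' @param score_ab summed score of all significant hits between A and B.
#' @param score_aa,score_bb self-comparison scores (must be > 0).
#' @return numeric distance in [0, 1].
#' @export
diceDistance <- function(score_ab, score_aa, score_bb) {
    if (any(score_aa <= 0) || any(score_bb <= 0))
        stop("distance undefined: zero self-comparison score")
    d <- 1 - 2 * score_ab / (score_aa + score_bb)
    pmin(pmax(d, 0), 1)
}

#' Proteomic distance matrix
#'
#' All-vs-all translated comparison of a genome set: for each unordered
#' pair the scores of all significant hits (e <= max_expectation) are
#' summed, normalised by the two self-comparison scores (Dice
#' coefficient), and subtracted from 1. Symmetric by construction with a
#' zero diagonal.
#'
#' @param genomes named DNAStringSet (every genome must have coding
#'   content: a zero self-score is an error).
#' @param params translated-mode [alignerParams()].
#' @return a symmetric numeric matrix with genome ids as dimnames.
#' @export
proteomicDistance <- function(genomes,
                              params = alignerParams("translated",
                                                     max_expectation = 1e-3)) {
    ids <- names(genomes)
    if (is.null(ids)) stop("genomes must be named")
    n <- length(genomes)
    chr <- as.character(genomes)
    prof <- lapply(chr, .translated_profile, params = params)
    self <- vapply(seq_len(n), function(i)
        summedScore(chr[i], chr[i], params, ids[i], ids[i],
                    prof[[i]], prof[[i]]), numeric(1))
    if (any(self <= 0))
        stop("zero self-comparison score for: ",
             paste(ids[self <= 0], collapse = ", "))
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        sab <- summedScore(chr[i], chr[j], params, ids[i], ids[j],
                           prof[[i]], prof[[j]])
        sab <- min(sab, (self[i] + self[j]) / 2)
        D[i, j] <- D[j, i] <- diceDistance(sab, self[i], self[j])
    }
    D
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param D symmetric matrix with dimnames.
#' @param path output file.
#' @export
writePhylip <- function(D, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(D)), con)
    for (i in seq_len(nrow(D)))
        writeLines(paste(formatC(rownames(D)[i], width = -10),
                         paste(sprintf("%.6f", D[i, ]), collapse = " ")),
                   con)
    invisible(path)
}

#' Neighbor-joining with seeded tie handling
#'
#' Canonical neighbor-joining on a symmetric distance matrix. With
#' \code{seed = NULL} the algorithm is deterministic: among pairs whose
#' Q-criterion is within \code{epsilon} of the minimum, the first in
#' row-major order is joined. With a seed, the join is drawn uniformly
#' from that near-minimal set and the leaf order is randomly permuted
#' first -- repeated seeds generate alternative, equally valid
#' topologies for consensus support. Negative branch lengths are clamped
#' to zero.
#'
#' @param D symmetric numeric matrix (n >= 2) with dimnames.
#' @param seed integer or NULL.
#' @param epsilon Q-criterion tie tolerance (default 1e-9 * max(D)).
#' @return an \code{ape::phylo} tree (unrooted for n >= 3).
#' @export
neighborJoining <- function(D, seed = NULL, epsilon = NULL) {
    if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
        stop("distance matrix must be symmetric")
    n <- nrow(D)
    if (n < 2L) stop("need at least two taxa")
    ids <- rownames(D)
    if (is.null(epsilon)) epsilon <- 1e-9 * max(D, 1e-12)
    if (!is.null(seed)) {
        set.seed(seed)
        o <- sample(n)
        D <- D[o, o, drop = FALSE]
        ids <- ids[o]
    }
    if (n == 2L) {
        nw <- sprintf("(%s:%.10g,%s:%.10g);", ids[1L], D[1, 2] / 2,
                      ids[2L], D[1, 2] / 2)
        return(ape::read.tree(text = nw))
    }
    lab <- ids          # current subtree newick fragments
    act <- seq_len(n)   # active indices into D
    M <- D
    while (length(act) > 2L) {
        m <- length(act)
        dm <- M[act, act, drop = FALSE]
        r <- rowSums(dm)
        Q <- (m - 2) * dm - outer(r, r, "+")
        diag(Q) <- Inf
        qmin <- min(Q)
        cand <- which(Q <= qmin + epsilon, arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        pick <- if (is.null(seed) || nrow(cand) == 1L) 1L
                else sample(nrow(cand), 1L)
        i <- cand[pick, 1L]; j <- cand[pick, 2L]
        di <- 0.5 * dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
        dj <- dm[i, j] - di
        di <- max(di, 0); dj <- max(dj, 0)
        ai <- act[i]; aj <- act[j]
        new_lab <- sprintf("(%s:%.10g,%s:%.10g)", lab[ai], di,
                           lab[aj], dj)
        # distances from the new node to the remaining taxa
        rest <- act[-c(i, j)]
        dnew <- 0.5 * (M[ai, rest] + M[aj, rest] - M[ai, aj])
        M[ai, rest] <- M[rest, ai] <- pmax(dnew, 0)
        lab[ai] <- new_lab
        act <- c(ai, rest)
    }
    a1 <- act[1L]; a2 <- act[2L]
    d12 <- max(M[a1, a2], 0)
    nw <- sprintf("(%s:%.10g,%s:%.10g);", lab[a1], d12 / 2, lab[a2],
                  d12 / 2)
    tr <- ape::read.tree(text = nw)
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
}

#' Generate alternative NJ topologies
#'
#' Runs [neighborJoining()] under a series of derived seeds, emulating
#' relaxed-NJ style exploration of equally valid topologies.
#'
#' @param D distance matrix.
#' @param n_trees number of topologies (default 100).
#' @param seed base seed; tree t uses seed + t.
#' @param epsilon tie tolerance passed through.
#' @return a \code{multiPhylo} list of trees.
#' @export
alternativeTopologies <- function(D, n_trees = 100L, seed = 1L,
                                  epsilon = NULL) {
    trees <- lapply(seq_len(n_trees), function(t)
        neighborJoining(D, seed = seed + t, epsilon = epsilon))
    class(trees) <- "multiPhylo"
    trees
}

# canonical bipartition key: the side not containing the reference leaf,
# as a sorted comma-joined string
.bipartitions <- function(tree, ref) {
    tree <- ape::unroot(tree)
    n <- length(tree$tip.label)
    pp <- ape::prop.part(tree)
    labs <- attr(pp, "labels")
    keys <- character()
    for (cl in pp) {
        if (length(cl) <= 1L || length(cl) >= n - 1L) next
        side <- labs[cl]
        if (ref %in% side) side <- setdiff(labs, side)
        if (length(side) <= 1L || length(side) >= n - 1L) next
        keys <- c(keys, paste(sort(side), collapse = ","))
    }
    unique(keys)
}

#' Majority-rule consensus tree with support values
#'
#' Counts bipartitions across the input trees and keeps those present in
#' strictly more than half of them (majority bipartitions are pairwise
#' compatible, so they always form a tree). Support on each retained
#' internal node is the fraction of input trees containing its
#' bipartition, stored as node labels. Conflicting fully resolved inputs
#' collapse towards a star tree.
#'
#' @param trees a list / multiPhylo of trees over one shared leaf set.
#' @return an \code{ape::phylo} with node labels giving support in
#'   (0.5, 1].
#' @export
majorityConsensus <- function(trees) {
    if (!length(trees)) stop("need at least one tree")
    tips <- sort(trees[[1L]]$tip.label)
    for (t in trees)
        if (!identical(sort(t$tip.label), tips))
            stop("all trees must share one leaf set")
    ref <- tips[1L]
    T <- length(trees)
    counts <- table(unlist(lapply(trees, .bipartitions, ref = ref)))
    keep <- counts[counts / T > 0.5]
    clusters <- strsplit(names(keep), ",", fixed = TRUE)
    support <- as.numeric(keep) / T
    o <- order(-lengths(clusters))
    clusters <- clusters[o]
    support <- support[o]
    # laminar family: nest clusters, then emit newick with support labels
    build <- function(leaves, cl_idx) {
        inner <- character()
        used <- character()
        ci <- cl_idx
        while (length(ci)) {
            i <- ci[1L]
            ci <- ci[-1L]
            cl <- clusters[[i]]
            if (!all(cl %in% leaves) || any(cl %in% used)) next
            sub <- ci[vapply(ci, function(j)
                all(clusters[[j]] %in% cl), logical(1))]
            inner <- c(inner, paste0(build(cl, sub),
                                     sprintf("%.6g", support[i])))
            used <- c(used, cl)
            ci <- setdiff(ci, sub)
        }
        free <- setdiff(leaves, used)
        paste0("(", paste(c(free, inner), collapse = ","), ")")
    }
    nw <- paste0(build(tips, seq_along(clusters)), ";")
    ape::read.tree(text = nw)
}

#' Build a proteomic tree
#'
#' Distance matrix via [proteomicDistance()] (or a precomputed matrix),
#' alternative NJ topologies, and a majority-rule consensus with
#' per-bipartition support.
#'
#' @param genomes named DNAStringSet, or NULL when \code{D} is given.
#' @param D optional precomputed distance matrix.
#' @param n_trees number of alternative topologies (default 100).
#' @param seed base seed for topology generation.
#' @param params translated aligner parameters.
#' @return list with \code{distance}, \code{trees}, \code{consensus}.
#' @export
proteomicTree <- function(genomes = NULL, D = NULL, n_trees = 100L,
                          seed = 1L,
                          params = alignerParams("translated",
                                                 max_expectation = 1e-3)) {
    if (is.null(D)) D <- proteomicDistance(genomes, params)
    trees <- alternativeTopologies(D, n_trees, seed)
    list(distance = D, trees = trees,
         consensus = majorityConsensus(trees))
}
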