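#' @include synth.R
NULL

#' Pipeline configuration with the study's printed thresholds
#'
#' Every default equals the published cutoff it implements:
#' candidate length > 10,000 bp; dereplication coverage >= 95 percent
#' with per-hit identity > 95 percent at e < 1e-3; spacer matching
#' >= 30 bp / >= 97 percent identity / >= 97 percent query coverage /
#' e <= 1e-5; recruitment > 95 percent identity over >= 50 bp;
#' presence at breadth > 0.80; protein clustering at 30 and 60 percent
#' identity; translated-comparison significance e <= 1e-3; microbial
#' read cap 2e7.
#'
#' @param ... named overrides of any default (nested lists merged one
#'   level deep).
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        candidate = list(min_length_bp = 10000, min_overlap_bp = 20),
        derep = list(min_coverage = 0.95, min_hit_identity = 95,
                     max_expectation = 1e-3),
        tree = list(max_expectation = 1e-3, matrix = "BLOSUM45",
                    n_topologies = 100),
        spacer = list(min_length = 30, min_identity = 97,
                      min_query_coverage = 0.97,
                      max_expectation = 1e-5),
        host_direct = list(min_length = 30, min_identity = 97,
                           max_expectation = 1e-5),
        marker = list(min_identity = 30, min_marker_coverage = 0.7,
                      max_expectation = 1e-5),
        recruitment = list(min_identity = 95, min_length = 50,
                           max_microbial_reads = 2e7),
        presence = list(threshold = 0.80),
        protein_clustering = list(identity_levels = c(30, 60),
                                  min_coverage = 0.8),
        seed = 1,
        verbosity = 1)
    dots <- list(...)
    for (nm in names(dots)) {
        if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
            cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
        else cfg[[nm]] <- dots[[nm]]
    }
    structure(cfg, class = "PipelineConfig")
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip through YAML serialisation; unknown keys
#' are rejected with the list of valid keys.
#'
#' @param path YAML file path.
#' @param config a [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    valid <- names(pipelineConfig())
    bad <- setdiff(names(raw), valid)
    if (length(bad))
        stop("invalid config key(s): ", paste(bad, collapse = ", "),
             "; valid keys: ", paste(valid, collapse = ", "))
    do.call(pipelineConfig, raw)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

.log_msg <- function(cfg, ...) {
    if (isTRUE(cfg$verbosity >= 1))
        message(format(Sys.time(), "%H:%M:%S "), ...)
}

.repro_block <- function(cfg, out_dir, stage) {
    tmp <- tempfile()
    yaml::write_yaml(unclass(cfg), tmp)
    block <- list(stage = stage,
                  package_version =
                      as.character(utils::packageVersion("limnophage")),
                  seed = cfg$seed,
                  config_md5 = unname(tools::md5sum(tmp)))
    unlink(tmp)
    jsonlite::write_json(block,
                         file.path(out_dir,
                                   paste0(stage, "_manifest.json")),
                         auto_unbox = TRUE)
    block
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: \code{simulate} (synthetic community + reads),
#' \code{discover} (circular candidates), \code{dereplicate},
#' \code{tree} (proteomic tree of representatives), \code{host}
#' (host prediction), \code{abundance} (fragment recruitment time
#' series), \code{catalog} (protein clustering + genome summaries), or
#' \code{all}. Each stage writes its outputs and a manifest with a
#' reproducibility block (package version, seed, config hash) to
#' \code{out_dir} and returns its results invisibly. Inputs not given
#' are taken from the results of earlier stages passed via
#' \code{inputs}.
#'
#' @param name stage name.
#' @param config a [pipelineConfig()].
#' @param inputs named list of stage inputs (\code{contigs},
#'   \code{community}, \code{reads}, \code{genomes}, ... depending on
#'   stage).
#' @param out_dir output directory (default a temporary directory).
#' @return list of stage results (invisible).
#' @export
runStage <- function(name = c("all", "simulate", "discover",
                              "dereplicate", "tree", "host",
                              "abundance", "catalog"),
                     config = pipelineConfig(), inputs = list(),
                     out_dir = tempfile("limnophage_")) {
    name <- match.arg(name)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    res <- inputs
    run <- function(stage) name == "all" || name == stage
    if (run("simulate") &&
        (name == "simulate" || is.null(res$community))) {
        .log_msg(config, "simulating community (seed ", config$seed, ")")
        res$community <- generateCommunity(communitySpec(),
                                           seed = config$seed,
                                           out_dir = out_dir)
        res$reads <- generateReads(res$community, timeSeriesSpec(),
                                   seed = config$seed)
        .repro_block(config, out_dir, "simulate")
    }
    if (run("discover")) {
        contigs <- res$contigs %||% res$community$contigs
        if (is.null(contigs)) stop("missing input: contigs ",
                                   "(FASTA of assembled contigs)")
        .log_msg(config, "selecting circular phage candidates")
        res$candidates <- selectPhageCandidates(
            contigs, min_length_bp = config$candidate$min_length_bp,
            min_overlap_bp = config$candidate$min_overlap_bp)
        writeXStringSet(res$candidates,
                        file.path(out_dir, "candidates.fasta"),
                        width = 60)
        writeCandidateManifest(res$candidates,
                               file.path(out_dir, "candidates.tsv"))
        .repro_block(config, out_dir, "discover")
    }
    if (run("dereplicate")) {
        gen <- res$candidates %||% res$genomes
        if (is.null(gen)) stop("missing input: genomes")
        .log_msg(config, "dereplicating ", length(gen), " genomes")
        res$derep <- dereplicate(
            gen, min_coverage = config$derep$min_coverage,
            min_hit_identity = config$derep$min_hit_identity,
            max_expectation = config$derep$max_expectation)
        writeXStringSet(res$derep$representatives,
                        file.path(out_dir, "representatives.fasta"),
                        width = 60)
        utils::write.table(res$derep$manifest,
                           file.path(out_dir, "clusters.tsv"),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE)
        .repro_block(config, out_dir, "dereplicate")
    }
    if (run("tree")) {
        reps <- if (!is.null(res$derep)) res$derep$representatives
                else res$genomes
        if (is.null(reps)) stop("missing input: genomes")
        .log_msg(config, "building proteomic tree over ", length(reps),
                 " representatives")
        res$tree <- proteomicTree(
            reps,
            n_trees = config$tree$n_topologies, seed = config$seed,
            params = alignerParams("translated",
                max_expectation = config$tree$max_expectation,
                matrix = config$tree$matrix))
        writePhylip(res$tree$distance,
                    file.path(out_dir, "proteomic_distance.phylip"))
        ape::write.tree(res$tree$consensus,
                        file.path(out_dir, "consensus.nwk"))
        .repro_block(config, out_dir, "tree")
    }
    if (run("host")) {
        phages <- if (!is.null(res$derep)) res$derep$representatives
                  else res$genomes
        hosts <- res$hosts %||% res$community$hosts
        if (is.null(phages) || is.null(hosts))
            stop("missing input: phage and host genomes")
        .log_msg(config, "predicting hosts")
        res$hostcalls <- predictHosts(
            phages, hosts,
            trna_loci = res$trna_loci %||% res$community$trna_loci,
            markers = res$markers %||% res$community$markers)
        utils::write.table(res$hostcalls$evidence,
                           file.path(out_dir, "host_evidence.tsv"),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(res$hostcalls$calls,
                           file.path(out_dir, "host_calls.tsv"),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE)
        .repro_block(config, out_dir, "host")
    }
    if (run("abundance")) {
        gen <- if (!is.null(res$candidates)) res$candidates
               else res$genomes
        samples <- res$samples %||% res$reads$samples
        if (is.null(gen) || is.null(samples))
            stop("missing input: genomes and samples")
        .log_msg(config, "recruiting reads across ", length(samples),
                 " samples")
        res$abundance <- abundanceExperiment(
            gen, samples,
            min_identity = config$recruitment$min_identity,
            min_length = config$recruitment$min_length,
            presence_threshold = config$presence$threshold)
        writeAbundance(res$abundance, file.path(out_dir, "phage"))
        .repro_block(config, out_dir, "abundance")
    }
    if (run("catalog")) {
        gen <- if (!is.null(res$candidates)) res$candidates
               else res$genomes
        if (!is.null(gen)) {
            .log_msg(config, "writing catalog summaries")
            utils::write.table(genomeSummary(gen),
                               file.path(out_dir, "genome_summary.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
            .repro_block(config, out_dir, "catalog")
        }
    }
    invisible(res)
}
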