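#' Default pipeline configuration
#'
#' All thresholds and seeds of the full analysis, overridable by name.
#' Defaults: expression filter FPKM >= 1 in > 80\% of samples; miRNA
#' activity window (0.01, 100); >= 6 binding-site families per gene;
#' overlap B-H q < 0.05; 2000 label permutations; direct calls at CES > 0.6
#' and B-H q < 0.01; enrichment gate of 5; ForwardStop alpha 0.01; 1000
#' solver permutations; 100 enrichment trials.
#'
#' @param ... named overrides of any default.
#' @return Named list of configuration values.
#' @export
defaultConfig <- function(...) {
    cfg <- list(min_abundance = 1, min_fraction = 0.8,
                mirna_lo = 0.01, mirna_hi = 100,
                min_sites = 6, overlap_q = 0.05,
                n_perm = 2000, ces_cutoff = 0.6, q_cutoff = 0.01,
                min_Q_overlap = 5, alpha_forwardstop = 0.01,
                mediator_n_perm = 1000, enrichment_trials = 100,
                direction = "both", method = "pearson",
                master_seed = 1)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("unknown configuration field(s): ",
             paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    cfg
}

#' Run the full analysis pipeline
#'
#' Executes network construction, the direct screen, the indirect screen,
#' and (for every called indirect pair) mediator minimisation, writing each
#' stage's outputs and a MANIFEST to \code{out_dir}. The configuration is
#' serialised verbatim alongside the results for provenance. Per-stage
#' random streams derive from \code{master_seed} by stable hashing of the
#' stage name, so results are reproducible and independent of stage order.
#'
#' @param expr,mirna_expr \linkS4class{CeExpressionSet} inputs.
#' @param targets \linkS4class{MirnaTargetMap}.
#' @param pathways \linkS4class{PathwayCollection}.
#' @param out_dir output directory.
#' @param config list from \code{\link{defaultConfig}}.
#' @param reference optional reference gene list for mediator enrichment.
#' @param stages character subset of
#'   \code{c("network","direct","indirect","mediators")}.
#' @return Invisibly, a list with the network, the direct and indirect call
#'   tables, the mediator results, and the output file paths.
#' @export
runPipeline <- function(expr, mirna_expr, targets, pathways, out_dir,
                        config = defaultConfig(), reference = NULL,
                        stages = c("network", "direct", "indirect",
                                   "mediators")) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- file.path(out_dir, "MANIFEST")
    writeLines(c("status: running",
                 paste0("version: ",
                        as.character(utils::packageVersion("cePathways")))),
               manifest)
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    res <- list(files = character(0))
    t0 <- proc.time()[["elapsed"]]
    log_stage <- function(name, t_start)
        message(sprintf("[%s] done in %.1fs", name,
                        proc.time()[["elapsed"]] - t_start))
    ok <- TRUE
    tryCatch({
        if ("network" %in% stages) {
            t <- proc.time()[["elapsed"]]
            net <- buildCernaNetwork(
                expr, mirna_expr, targets,
                min_abundance = config$min_abundance,
                min_fraction = config$min_fraction,
                mirna_lo = config$mirna_lo, mirna_hi = config$mirna_hi,
                min_sites = config$min_sites, q_cutoff = config$overlap_q,
                method = config$method)
            f <- file.path(out_dir, "network_edges.tsv")
            writeNetworkEdges(net, f)
            jsonlite::write_json(filterReport(net),
                                 file.path(out_dir, "filter_report.json"),
                                 auto_unbox = TRUE, digits = NA)
            res$network <- net
            res$files <- c(res$files, f)
            log_stage("network", t)
        }
        if ("direct" %in% stages) {
            t <- proc.time()[["elapsed"]]
            direct <- screenDirectPairs(
                res$network, pathways, direction = config$direction,
                n_perm = config$n_perm,
                seed = stableSeed(config$master_seed, "direct"),
                ces_cutoff = config$ces_cutoff,
                q_cutoff = config$q_cutoff,
                min_Q_overlap = config$min_Q_overlap)
            f <- file.path(out_dir, "direct_calls.tsv")
            writeResultsTable(direct, f)
            res$direct <- direct
            res$files <- c(res$files, f)
            log_stage("direct", t)
        }
        if ("indirect" %in% stages) {
            t <- proc.time()[["elapsed"]]
            indirect <- screenIndirectPairs(
                res$network, expr, pathways,
                direction = config$direction, n_perm = config$n_perm,
                seed = stableSeed(config$master_seed, "indirect"),
                alpha = config$alpha_forwardstop,
                min_Q_overlap = config$min_Q_overlap,
                method = config$method)
            f <- file.path(out_dir, "indirect_calls.tsv")
            writeResultsTable(indirect, f)
            res$indirect <- indirect
            res$files <- c(res$files, f)
            log_stage("indirect", t)
        }
        if ("mediators" %in% stages && !is.null(res$indirect)) {
            t <- proc.time()[["elapsed"]]
            rankings <- attr(res$indirect, "rankings")
            done <- character(0)
            med <- list()
            for (i in seq_len(nrow(res$indirect))) {
                p <- res$indirect$pathway_P[i]
                q <- res$indirect$pathway_Q[i]
                key <- paste(sort(c(p, q)), collapse = "|")
                if (key %in% done) next
                done <- c(done, key)
                inst <- tryCatch(
                    buildCoverInstance(rankings[[p]], rankings[[q]],
                                       geneSets(pathways, p),
                                       geneSets(pathways, q)),
                    error = function(e) NULL)
                if (is.null(inst)) next
                med[[key]] <- aggregateMinimalMediators(
                    inst, n_perm = config$mediator_n_perm,
                    seed = stableSeed(config$master_seed, "mediators", key))
            }
            rows <- lapply(names(med), function(k) data.frame(
                pathway_pair = k,
                optimum_size = optimumSize(med[[k]]),
                n_solutions = length(coverSolutions(med[[k]])),
                union_minimal = paste(unionMinimal(med[[k]]),
                                      collapse = ","),
                stringsAsFactors = FALSE))
            f <- file.path(out_dir, "mediators.tsv")
            write.table(do.call(rbind, c(rows, list(
                data.frame(pathway_pair = character(0),
                           optimum_size = integer(0),
                           n_solutions = integer(0),
                           union_minimal = character(0))))),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
            res$mediators <- med
            res$files <- c(res$files, f)
            if (!is.null(reference) && length(med)) {
                background <- setdiff(networkNodes(res$network),
                                      unlist(geneSets(pathways)))
                enr <- lapply(names(med), function(k) {
                    u <- unionMinimal(med[[k]])
                    if (!all(u %in% background)) return(NULL)
                    mediatorEnrichment(
                        u, reference, background,
                        n_trials = config$enrichment_trials,
                        seed = stableSeed(config$master_seed, "enrich", k))
                })
                names(enr) <- names(med)
                res$enrichment <- enr
            }
            log_stage("mediators", t)
        }
        ok <- TRUE
    }, error = function(e) {
        ok <<- FALSE
        writeLines(c("status: FAILED", paste0("error: ",
                                              conditionMessage(e))),
                   manifest)
        stop(e)
    })
    writeLines(c("status: complete",
                 paste0("version: ",
                        as.character(utils::packageVersion("cePathways"))),
                 paste0("elapsed_s: ",
                        sprintf("%.1f", proc.time()[["elapsed"]] - t0)),
                 paste0("files: ", paste(basename(res$files),
                                         collapse = ", "))),
               manifest)
    invisible(res)
}
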