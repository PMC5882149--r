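#' Specification of a synthetic ceRNA study
#'
#' Validates and completes the parameters of the synthetic-data generator.
#' Defaults describe the study conditions used throughout the package's
#' tests: 200 genes, 20 disjoint pathways of 10 genes, 150 miRNA families
#' (120 inside the moderate-expression window, 30 decoys outside it), 50
#' matched samples per condition, log-normal abundance with unit log-scale
#' noise.
#'
#' @param n_genes total number of genes.
#' @param n_mirna_families total miRNA families; 80\% are generated inside
#'   the active-expression window, the rest outside it.
#' @param n_samples_per_group matched samples per condition.
#' @param n_pathways,pathway_size disjoint pathways carved from the gene
#'   pool (\code{n_pathways * pathway_size <= n_genes} required).
#' @param planted_pairs list of \code{list(P=, Q=, direction=, effect=)}
#'   with pathway indices, direction \code{"loss"} or \code{"gain"}, and
#'   effect in (0, 1]: the within-group correlation of the planted latent
#'   factor.
#' @param planted_chains list of \code{list(P=, mediator_count=, Q=,
#'   direction=, effect=)}: indirect structure routed through dedicated
#'   mediator genes outside all pathways.
#' @param noise_sd log-scale noise standard deviation.
#' @param seed mandatory integer seed.
#' @return Validated spec (classed list).
#' @export
syntheticSpec <- function(n_genes = 200, n_mirna_families = 150,
                          n_samples_per_group = 50, n_pathways = 20,
                          pathway_size = 10, planted_pairs = list(),
                          planted_chains = list(), noise_sd = 1,
                          seed) {
    stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1L)
    if (n_pathways * pathway_size > n_genes)
        stop("pathway_size * n_pathways exceeds n_genes")
    chk <- function(x, what) {
        stopifnot(x$effect > 0, x$effect <= 1,
                  x$direction %in% c("loss", "gain"))
        if (x$P < 1 || x$P > n_pathways || x$Q < 1 || x$Q > n_pathways ||
            x$P == x$Q)
            stop("invalid pathway index in ", what)
    }
    lapply(planted_pairs, chk, what = "planted_pairs")
    lapply(planted_chains, chk, what = "planted_chains")
    structure(list(n_genes = n_genes, n_mirna_families = n_mirna_families,
                   n_samples_per_group = n_samples_per_group,
                   n_pathways = n_pathways, pathway_size = pathway_size,
                   planted_pairs = planted_pairs,
                   planted_chains = planted_chains,
                   noise_sd = noise_sd, seed = as.integer(seed)),
              class = "syntheticSpec")
}

#' Generate a synthetic two-condition ceRNA study
#'
#' Produces an mRNA expression set, a family-level miRNA expression set, a
#' gene-to-family target map and a pathway collection, with optional
#' planted direct and indirect ceRNA structure, plus a ground-truth record.
#'
#' Baseline abundance is log-normal with uniform background target sets,
#' so the hypergeometric overlap test is exactly calibrated on background
#' gene pairs. Half of the non-planted genes are organised into background
#' co-targeting modules (cliques of 4 genes sharing a 10-family block, with
#' independent expression), providing a sparse background network whose
#' delta_rho is pure noise.
#'
#' A planted direct pair (P, Q) loads all genes of both pathways on a
#' shared standard-normal latent factor in the co-expressed condition only
#' (the reference group for a loss, the second group for a gain), with
#' loading \code{noise_sd * sqrt(effect/(1-effect))} so their within-group
#' log-abundance correlation equals \code{effect} (Pearson correlation on
#' the abundance scale is somewhat attenuated, as for any log-normal). Co-targeting is asymmetric:
#' Q's genes and 15 independent decoy genes carry a full 20-family block
#' while each P gene carries a random half of it, so every (P, Q) and
#' (P, decoy) overlap is significant but P's genes share no edge among
#' themselves -- P's neighbourhood then ranks Q's genes (strong, signed
#' score) against decoys (noise), as in a real sponge neighbourhood.
#'
#' A planted chain loads P's genes, dedicated mediator genes and Q's genes
#' on one factor, with P-side and Q-side family blocks that never cross:
#' P genes and mediators share one block, mediators and Q genes the other,
#' plus per-side decoys. Direct (P gene, Q gene) edges therefore cannot
#' form and the relationship is recoverable only through the mediators,
#' with sign-consistent co-expression changes along every chain.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with elements \code{mrna}, \code{mirna}
#'   (\linkS4class{CeExpressionSet}), \code{targets}
#'   (\linkS4class{MirnaTargetMap}), \code{pathways}
#'   (\linkS4class{PathwayCollection}), \code{ground_truth}, \code{spec}.
#' @export
simulateCernaStudy <- function(spec) {
    stopifnot(inherits(spec, "syntheticSpec"))
    withSeed(spec$seed, {
        n_g <- spec$n_genes
        n_s <- spec$n_samples_per_group
        genes <- sprintf("G%04d", seq_len(n_g))
        samples <- c(sprintf("N%03d", seq_len(n_s)),
                     sprintf("T%03d", seq_len(n_s)))
        condition <- rep(c("normal", "tumor"), each = n_s)
        pair_id <- rep(sprintf("s%03d", seq_len(n_s)), 2L)

        pw_names <- sprintf("PW%02d", seq_len(spec$n_pathways))
        pw_sets <- split(genes[seq_len(spec$n_pathways * spec$pathway_size)],
                         rep(seq_len(spec$n_pathways),
                             each = spec$pathway_size))
        names(pw_sets) <- pw_names
        free_pool <- genes[-seq_len(spec$n_pathways * spec$pathway_size)]

        fams <- sprintf("Fam%03d", seq_len(spec$n_mirna_families))
        n_active <- ceiling(0.8 * spec$n_mirna_families)
        active <- fams[seq_len(n_active)]
        decoys <- fams[-seq_len(n_active)]
        # reserve exactly as many active families as the planted blocks
        # need (20 per direct pair, 2 x 10 per chain); the rest form the
        # background co-targeting pool
        n_res <- 20L * length(spec$planted_pairs) +
                 20L * length(spec$planted_chains)
        if (n_res >= n_active)
            stop("too many planted structures for the family universe")
        reserved <- if (n_res) active[(n_active - n_res + 1L):n_active]
                    else character(0)
        background_fams <- c(active[seq_len(n_active - n_res)], decoys)

        # baseline log-normal abundance
        mu <- runif(n_g, log(20), log(100))
        logx <- matrix(rnorm(n_g * 2L * n_s, sd = spec$noise_sd),
                       nrow = n_g,
                       dimnames = list(genes, samples)) + mu
        is_ref <- condition == "normal"

        # background family sets: uniform sampling, so the hypergeometric
        # overlap test is exactly calibrated on background pairs
        draw_tail <- function(k)
            sample(background_fams, min(k, length(background_fams)))
        fam_sets <- lapply(seq_len(n_g), function(i)
            draw_tail(10L + rpois(1L, 8L)))
        names(fam_sets) <- genes

        load_factor <- function(rows, cols, effect) {
            a <- spec$noise_sd * sqrt(effect / (1 - effect + 1e-12))
            f <- rnorm(sum(cols))
            logx[rows, cols] <<- logx[rows, cols] +
                a * matrix(f, nrow = length(rows), ncol = sum(cols),
                           byrow = TRUE)
        }
        next_block <- local({
            i <- 0L
            function(size = 10L) {
                if (i + size > length(reserved))
                    stop("not enough reserved families for planted blocks")
                b <- reserved[i + seq_len(size)]
                i <<- i + size
                b
            }
        })

        take_free <- function(k, what) {
            if (length(free_pool) < k)
                stop("not enough free genes for ", what)
            g <- free_pool[seq_len(k)]
            free_pool <<- free_pool[-seq_len(k)]
            g
        }
        n_decoy <- 15L

        gt_pairs <- list()
        for (pp in spec$planted_pairs) {
            pg <- pw_sets[[pp$P]]; qg <- pw_sets[[pp$Q]]
            block <- next_block(20L)
            # asymmetric co-targeting: every Q gene carries the full block
            # (sponge-like), every P gene a random half of it, so each
            # (P, Q) pair shares >= 10 families (a significant overlap)
            # while two P genes share only ~5 (not significant) -- P's
            # neighbourhood then contains Q's genes but not P's own
            for (g in pg)
                fam_sets[[g]] <- c(sample(block, 10L), draw_tail(8L))
            for (g in qg)
                fam_sets[[g]] <- c(block, draw_tail(4L))
            # decoy neighbours: share the block (hence edges to the planted
            # genes) but have independent expression, so the pathway
            # rankings contain realistic low-score misses
            decoy_g <- take_free(n_decoy, "planted-pair decoys")
            for (g in decoy_g) fam_sets[[g]] <- c(block, draw_tail(4L))
            cols <- if (pp$direction == "loss") is_ref else !is_ref
            load_factor(c(pg, qg), cols, pp$effect)
            gt_pairs[[length(gt_pairs) + 1L]] <- list(
                P = pw_names[pp$P], Q = pw_names[pp$Q],
                direction = pp$direction, effect = pp$effect,
                shared_families = block, decoys = decoy_g)
        }

        gt_chains <- list()
        for (ch in spec$planted_chains) {
            pg <- pw_sets[[ch$P]]; qg <- pw_sets[[ch$Q]]
            meds <- take_free(ch$mediator_count, "chain mediators")
            block_P <- next_block(); block_Q <- next_block()
            # the dedicated blocks never cross sides, so a (P gene, Q gene)
            # pair cannot reach a significant direct overlap; decoys per
            # side supply independent-expression misses for the rankings
            for (g in pg) fam_sets[[g]] <- c(block_P, draw_tail(8L))
            for (g in qg) fam_sets[[g]] <- c(block_Q, draw_tail(8L))
            for (g in meds) fam_sets[[g]] <-
                c(block_P, block_Q, draw_tail(8L))
            decoys_P <- take_free(n_decoy, "chain decoys")
            decoys_Q <- take_free(n_decoy, "chain decoys")
            for (g in decoys_P) fam_sets[[g]] <- c(block_P, draw_tail(8L))
            for (g in decoys_Q) fam_sets[[g]] <- c(block_Q, draw_tail(8L))
            cols <- if (ch$direction == "loss") is_ref else !is_ref
            load_factor(c(pg, meds, qg), cols, ch$effect)
            gt_chains[[length(gt_chains) + 1L]] <- list(
                P = pw_names[ch$P], Q = pw_names[ch$Q],
                direction = ch$direction, effect = ch$effect,
                mediators = meds, P_genes = pg, Q_genes = qg,
                decoys = c(decoys_P, decoys_Q))
        }

        # background co-targeting modules: small cliques of genes sharing
        # a family block (as sponge-like target hubs do in real site
        # databases) but with independent expression, so the network has a
        # realistic sparse background of edges whose delta_rho is pure
        # noise; planted genes are left untouched
        planted_genes <- unique(c(
            unlist(lapply(gt_pairs, function(g)
                c(pw_sets[[g$P]], pw_sets[[g$Q]], g$decoys))),
            unlist(lapply(gt_chains, function(g)
                c(g$P_genes, g$Q_genes, g$mediators, g$decoys)))))
        module_pool <- sample(setdiff(genes, planted_genes))
        n_modules <- length(module_pool) %/% 8L
        gt_modules <- list()
        for (mi in seq_len(n_modules)) {
            members <- module_pool[(mi - 1L) * 4L + seq_len(4L)]
            mblock <- sample(background_fams, 10L)
            for (g in members)
                fam_sets[[g]] <- c(mblock, draw_tail(8L))
            gt_modules[[mi]] <- list(members = members)
        }

        mrna <- CeExpressionSet(exp(logx), condition = condition,
                                reference = "normal", pair_id = pair_id)

        # family-level miRNA abundance: active families inside the moderate
        # window, decoys outside it (too low / too high alternately)
        mir <- matrix(0, nrow = length(fams), ncol = length(samples),
                      dimnames = list(fams, samples))
        mir[active, ] <- exp(matrix(
            rnorm(length(active) * length(samples), log(10), 0.5),
            nrow = length(active)))
        if (length(decoys)) {
            lo <- seq_along(decoys) %% 2L == 0L
            mir[decoys[lo], ] <- 0.001
            mir[decoys[!lo], ] <- 500
        }
        mirna <- CeExpressionSet(mir, condition = condition,
                                 reference = "normal", pair_id = pair_id)

        targets <- MirnaTargetMap(fam_sets, universe = fams)
        pathways <- PathwayCollection(pw_sets, source = "synthetic")
        list(mrna = mrna, mirna = mirna, targets = targets,
             pathways = pathways,
             ground_truth = list(pairs = gt_pairs, chains = gt_chains,
                                 modules = gt_modules),
             spec = spec)
    })
}

#' @describeIn simulateCernaStudy same generator with all planted structure
#'   removed (pure null study).
#' @export
simulateNullStudy <- function(spec) {
    spec$planted_pairs <- list()
    spec$planted_chains <- list()
    simulateCernaStudy(spec)
}

#' Write a synthetic study to disk
#'
#' Serialises every generator output in the formats the readers consume:
#' \code{expr.tsv}, \code{mirna.tsv} (matrices), \code{conditions.tsv}
#' (sample map with pairing), \code{targets.tsv} (gene/family/score rows),
#' \code{pathways.gmt}, and \code{ground_truth.json}.
#'
#' @param study output of \code{\link{simulateCernaStudy}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeStudyFiles <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(expr = file.path(dir, "expr.tsv"),
               mirna = file.path(dir, "mirna.tsv"),
               conditions = file.path(dir, "conditions.tsv"),
               targets = file.path(dir, "targets.tsv"),
               gmt = file.path(dir, "pathways.gmt"),
               truth = file.path(dir, "ground_truth.json"))
    write_mat <- function(x, path) {
        m <- exprValues(x)
        tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                          stringsAsFactors = FALSE)
        write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_mat(study$mrna, paths["expr"])
    write_mat(study$mirna, paths["mirna"])
    cd <- SummarizedExperiment::colData(study$mrna)
    cond <- data.frame(sample_id = rownames(cd),
                       group = as.character(cd$condition),
                       stringsAsFactors = FALSE)
    if (isPaired(study$mrna)) cond$pair_id <- cd$pair_id
    write.table(cond, paths["conditions"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    fam <- targetFamilies(study$targets)
    tt <- data.frame(gene_id = rep(names(fam), lengths(fam)),
                     mirna_family_id = unlist(fam, use.names = FALSE),
                     score = 1, stringsAsFactors = FALSE)
    write.table(tt, paths["targets"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    sets <- geneSets(study$pathways)
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
    writeLines(lines, paths["gmt"])
    jsonlite::write_json(study$ground_truth, paths["truth"],
                         auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
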