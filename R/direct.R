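#' Rank a pathway's network neighbours by summed co-expression change
#'
#' For every gene y adjacent in the network to at least one member of
#' pathway P, theta_P(y) is the sum of delta_rho over the edges (x, y) with
#' x in P. Negative theta marks ceRNA relationship loss towards P, positive
#' theta gain. Genes with theta exactly 0 are excluded. A pathway gene may
#' itself appear in the ranking when it neighbours other members of P.
#'
#' @param net a \linkS4class{ChangeNetwork}.
#' @param P character vector of pathway gene ids (non-empty).
#' @param pathway_name label stored on the ranking.
#' @return A \linkS4class{ThetaRanking}; empty (zero rows) when P is
#'   disjoint from the network.
#' @export
computeTheta <- function(net, P, pathway_name = "P") {
    stopifnot(length(P) > 0)
    e <- networkEdges(net)
    inPx <- e$gene_x %in% P
    inPy <- e$gene_y %in% P
    # each edge contributes to the neighbour on the other side; an edge
    # inside P contributes to both endpoints
    y <- c(e$gene_y[inPx], e$gene_x[inPy])
    d <- c(e$delta_rho[inPx], e$delta_rho[inPy])
    if (!length(y)) {
        ent <- data.frame(gene = character(0), score = numeric(0))
    } else {
        s <- vapply(split(d, y), sum, 0.0)
        s <- s[s != 0]
        ent <- data.frame(gene = names(s), score = unname(s),
                          stringsAsFactors = FALSE)
        ent <- ent[order(ent$gene), , drop = FALSE]
        rownames(ent) <- NULL
    }
    new("ThetaRanking", pathway = pathway_name, entries = ent,
        statistic = "theta")
}

#' Weighted running-sum enrichment score
#'
#' Walks a single sign partition of a ranking: at a gene belonging to Q the
#' sum increases by |score|/N_R (N_R = total |score| over hits); at any
#' other gene it decreases by 1/(N - N_H). The score is the maximum absolute
#' deviation of the running sum from zero, in [0, 1]; 0 when there is no
#' hit, 1 exactly when all hits precede all misses.
#'
#' @param weights non-negative weights (|theta| or |kappa|) in ranked order.
#' @param hit logical, same length: membership of the ranked gene in Q.
#' @return The enrichment score, a single non-negative number.
#' @export
cesScore <- function(weights, hit) {
    n <- length(weights)
    stopifnot(length(hit) == n)
    nh <- sum(hit)
    if (nh == 0L || n == 0L) return(0)
    nr <- sum(weights[hit])
    if (nr == 0) return(0)
    incr <- if (nh == n) weights / nr
            else ifelse(hit, weights / nr, -1 / (n - nh))
    max(abs(cumsum(incr)))
}

#' @describeIn cesScore evaluate the score for one direction of a ranking
#'   against gene set Q.
#' @param ranking a \linkS4class{ThetaRanking} (or KappaRanking).
#' @param Q character vector of gene ids.
#' @param direction \code{"loss"} (negative scores, ascending) or
#'   \code{"gain"} (positive scores, descending).
#' @export
computeCes <- function(ranking, Q, direction = c("loss", "gain")) {
    direction <- match.arg(direction)
    sub <- if (direction == "loss") lossRanking(ranking)
           else gainRanking(ranking)
    cesScore(abs(sub$score), sub$gene %in% Q)
}

# Null distribution of the enrichment score under gene-label permutation:
# the weight sequence stays fixed and `nh` hit labels land uniformly at
# random, so the null depends only on (weights, nh).
.nullCes <- function(weights, nh, n_perm, seed) {
    n <- length(weights)
    withSeed(seed, vapply(seq_len(n_perm), function(i) {
        pos <- sample.int(n, nh)
        hit <- logical(n)
        hit[pos] <- TRUE
        cesScore(weights, hit)
    }, 0.0))
}

#' Gene-label permutation p-value for an enrichment score
#'
#' Permutes which ranked positions carry Q membership while keeping the
#' weight sequence fixed, and reports the fraction of permutations whose
#' score is greater than or equal to the observed one (so p = 0 is
#' attainable). With no Q gene in the sublist the test is undefined and a
#' sentinel \code{NA} p-value is returned.
#'
#' @inheritParams computeCes
#' @param n_perm number of label permutations (default 2000).
#' @param seed integer seed for the permutation stream.
#' @return list with \code{ces_obs}, \code{p}, and \code{n_hits}.
#' @export
permutationPvalue <- function(ranking, Q, direction = c("loss", "gain"),
                              n_perm = 2000, seed = 1) {
    direction <- match.arg(direction)
    stopifnot(n_perm >= 1)
    sub <- if (direction == "loss") lossRanking(ranking)
           else gainRanking(ranking)
    w <- abs(sub$score)
    hit <- sub$gene %in% Q
    nh <- sum(hit)
    if (nh == 0L)
        return(list(ces_obs = 0, p = NA_real_, n_hits = 0L))
    obs <- cesScore(w, hit)
    null <- .nullCes(w, nh, n_perm, seed)
    list(ces_obs = obs, p = mean(null >= obs), n_hits = nh)
}

#' Enumerate all unordered pathway pairs
#'
#' @param pathways a \linkS4class{PathwayCollection} (>= 2 pathways).
#' @return Two-column character matrix, one row per unordered pair.
#' @export
enumeratePathwayPairs <- function(pathways) {
    nm <- pathwayNames(pathways)
    n <- length(nm)
    stopifnot(n >= 2L)
    ij <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    cbind(P = nm[ij[, 1L]], Q = nm[ij[, 2L]])
}

# shared screening core for the direct (theta) and indirect (kappa)
# analyses: scores every ordered orientation (P ranking vs Q set) in the
# requested directions, with a permutation-null cache keyed by
# (pathway, direction, hit count).
.screenCore <- function(rankings, pathways, directions, n_perm, seed,
                        min_Q_overlap) {
    nm <- pathwayNames(pathways)
    sets <- geneSets(pathways)
    sublists <- list()
    for (p in nm) {
        sublists[[p]] <- list(loss = lossRanking(rankings[[p]]),
                              gain = gainRanking(rankings[[p]]))
    }
    cache <- new.env(parent = emptyenv())
    rows <- vector("list", 0L)
    for (p in nm) {
        rank_genes <- rankings[[p]]@entries$gene
        if (!length(rank_genes)) next
        for (q in nm) {
            if (q == p) next
            Q <- sets[[q]]
            if (sum(Q %in% rank_genes) < min_Q_overlap) next  # not enriched
            for (dir in directions) {
                sub <- sublists[[p]][[dir]]
                w <- abs(sub$score)
                hit <- sub$gene %in% Q
                nh <- sum(hit)
                if (nh == 0L) next
                obs <- cesScore(w, hit)
                key <- paste(p, dir, nh, sep = "\r")
                null <- cache[[key]]
                if (is.null(null)) {
                    null <- .nullCes(w, nh, n_perm,
                                     stableSeed(seed, p, dir, nh))
                    cache[[key]] <- null
                }
                rows[[length(rows) + 1L]] <- data.frame(
                    pathway_P = p, pathway_Q = q, direction = dir,
                    ces = obs, p_perm = mean(null >= obs),
                    n_Q_in_ranking = nh, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows))
        return(data.frame(pathway_P = character(0), pathway_Q = character(0),
                          direction = character(0), ces = numeric(0),
                          p_perm = numeric(0), n_Q_in_ranking = integer(0)))
    do.call(rbind, rows)
}

#' Screen all pathway pairs for direct ceRNA crosstalk change
#'
#' Evaluates every unordered pathway pair in both orientations (P's ranking
#' walked with Q's membership, and vice versa) and both requested
#' directions. Pairs where fewer than \code{min_Q_overlap} genes of Q appear
#' in P's ranking are skipped as not enriched. Benjamini-Hochberg correction
#' is applied across all computed p-values within each direction, and calls
#' passing both the CES and the q cutoffs are returned, ordered by q, then
#' CES descending, then names.
#'
#' @param net a \linkS4class{ChangeNetwork}.
#' @param pathways a \linkS4class{PathwayCollection} (>= 2 pathways).
#' @param direction \code{"both"} (default), \code{"loss"} or \code{"gain"}.
#' @param n_perm label permutations per test (default 2000).
#' @param seed master seed; per-test streams are derived deterministically.
#' @param ces_cutoff minimum enrichment score for a call (default 0.6).
#' @param q_cutoff B-H significance cutoff (default 0.01).
#' @param min_Q_overlap enrichment gate on Q genes in P's ranking
#'   (default 5).
#' @return data.frame of calls (columns \code{pathway_P}, \code{pathway_Q},
#'   \code{direction}, \code{ces}, \code{p_perm}, \code{q_value},
#'   \code{n_Q_in_ranking}). Attributes: \code{all_tests} (every scored
#'   orientation with its q-value) and \code{n_pairs_enumerated}.
#' @export
screenDirectPairs <- function(net, pathways, direction = c("both", "loss",
                                                           "gain"),
                              n_perm = 2000, seed = 1, ces_cutoff = 0.6,
                              q_cutoff = 0.01, min_Q_overlap = 5) {
    direction <- match.arg(direction)
    directions <- if (direction == "both") c("loss", "gain") else direction
    nm <- pathwayNames(pathways)
    stopifnot(length(nm) >= 2L)
    rankings <- lapply(setNames(nm, nm), function(p)
        computeTheta(net, geneSets(pathways, p), pathway_name = p))
    tests <- .screenCore(rankings, pathways, directions, n_perm, seed,
                         min_Q_overlap)
    tests$q_value <- rep(NA_real_, nrow(tests))
    for (dir in directions) {
        idx <- tests$direction == dir
        tests$q_value[idx] <- p.adjust(tests$p_perm[idx], method = "BH")
    }
    calls <- tests[!is.na(tests$q_value) & tests$q_value < q_cutoff &
                   tests$ces > ces_cutoff, , drop = FALSE]
    calls <- calls[order(calls$q_value, -calls$ces, calls$pathway_P,
                         calls$pathway_Q), , drop = FALSE]
    rownames(calls) <- NULL
    attr(calls, "all_tests") <- tests
    attr(calls, "n_pairs_enumerated") <-
        length(nm) * (length(nm) - 1) / 2
    calls
}
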