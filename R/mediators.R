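#' Build a set-cover instance from mediator provenance
#'
#' For a called indirect pathway pair (P, Q): every qualifying chain
#' x -- y -- z contributes its pathway-side endpoints (x and z, members of
#' P or Q) to the universe, and its mediator y to the candidate sets, y
#' covering the endpoints of the chains it mediates. Mediators inside
#' P or Q are excluded; universe genes left uncovered after that exclusion
#' are pruned and reported in the \code{dropped} slot.
#'
#' @param kappa_P \linkS4class{KappaRanking} of P (partners z restricted to
#'   Q internally).
#' @param kappa_Q optional \linkS4class{KappaRanking} of Q, for the reverse
#'   orientation; \code{NULL} uses only P's chains.
#' @param P,Q pathway gene sets.
#' @return A \linkS4class{CoverInstance}.
#' @export
buildCoverInstance <- function(kappa_P, kappa_Q = NULL, P, Q) {
    harvest <- function(kr, from, to) {
        prov <- mediatorProvenance(kr)
        prov <- prov[names(prov) %in% to]
        out <- list()
        for (z in names(prov)) {
            for (x in names(prov[[z]])) {
                if (!x %in% from) next
                for (y in prov[[z]][[x]])
                    out[[y]] <- unique(c(out[[y]], x, z))
            }
        }
        out
    }
    sets <- harvest(kappa_P, P, Q)
    if (!is.null(kappa_Q)) {
        rev <- harvest(kappa_Q, Q, P)
        for (y in names(rev))
            sets[[y]] <- unique(c(sets[[y]], rev[[y]]))
    }
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
    if (!length(universe))
        stop("no mediated relationships between the pathway pair")
    pq <- union(P, Q)
    sets <- sets[!names(sets) %in% pq]
    covered <- sort(unique(unlist(sets, use.names = FALSE)))
    dropped <- setdiff(universe, covered)
    if (length(dropped))
        message(length(dropped), " pathway gene(s) uncoverable after ",
                "excluding in-pathway mediators; pruned from the universe")
    universe <- intersect(universe, covered)
    if (!length(universe))
        stop("no mediated relationships between the pathway pair")
    sets <- lapply(sets, function(s) sort(intersect(s, universe)))
    sets <- sets[order(names(sets))]
    new("CoverInstance", universe = universe, cover_sets = sets,
        dropped = dropped)
}

# ---- exact minimum set cover ------------------------------------------------

# Depth-first branch and bound over candidate sets, branching on the
# uncovered element with the fewest remaining covering sets and pruning
# with the bound |current| + ceiling(uncovered / max set size). `prec`
# gives the branching precedence of the sets; permuting it steers which of
# several co-optimal covers is found first.
.bnbCover <- function(sets_idx, n_elem, prec) {
    n_sets <- length(sets_idx)
    covers_of <- vector("list", n_elem)
    for (s in seq_len(n_sets))
        for (el in sets_idx[[s]])
            covers_of[[el]] <- c(covers_of[[el]], s)
    # greedy initial incumbent for the bound; ties follow the permuted
    # precedence so co-optimal covers vary across solver runs
    greedy <- integer(0)
    unc <- rep(TRUE, n_elem)
    while (any(unc)) {
        gains <- vapply(sets_idx, function(s) sum(unc[s]), 0L)
        cand <- which(gains == max(gains))
        pick <- cand[which.min(prec[cand])]
        greedy <- c(greedy, pick)
        unc[sets_idx[[pick]]] <- FALSE
    }
    best <- new.env(parent = emptyenv())
    best$size <- length(greedy)
    best$sol <- sort(greedy)
    max_size <- max(lengths(sets_idx))
    recurse <- function(uncov, chosen) {
        n_unc <- sum(uncov)
        if (n_unc == 0L) {
            if (length(chosen) < best$size) {
                best$size <- length(chosen)
                best$sol <- sort(chosen)
            }
            return(invisible(NULL))
        }
        if (length(chosen) + ceiling(n_unc / max_size) >= best$size)
            return(invisible(NULL))
        # branch element: uncovered element with fewest covering sets
        cand <- which(uncov)
        n_opts <- vapply(covers_of[cand], length, 0L)
        el <- cand[which.min(n_opts)]
        branch <- covers_of[[el]]
        branch <- branch[order(prec[branch])]
        for (s in branch) {
            u2 <- uncov
            u2[sets_idx[[s]]] <- FALSE
            recurse(u2, c(chosen, s))
        }
        invisible(NULL)
    }
    recurse(rep(TRUE, n_elem), integer(0))
    best$sol
}

#' Exact minimum mediator cover
#'
#' Finds a provably minimum-cardinality set of mediators covering every
#' pathway gene of the instance, by exact branch and bound on the
#' equivalent minimum-set-cover integer program (binary variable per
#' mediator, one covering constraint per pathway gene). When several
#' optimal covers exist, the one returned depends on the branching order,
#' which \code{seed} (or an explicit \code{order}) permutes -- mirroring
#' solver behaviour under input permutation.
#'
#' @param instance a \linkS4class{CoverInstance}.
#' @param seed optional integer; permutes the branching precedence.
#' @param order optional explicit precedence (permutation of mediator
#'   indices); overrides \code{seed}.
#' @return Character vector of mediator gene ids (a minimum cover, sorted).
#' @export
solveMinCover <- function(instance, seed = NULL, order = NULL) {
    meds <- names(instance@cover_sets)
    n <- length(meds)
    elem <- instance@universe
    sets_idx <- lapply(instance@cover_sets, match, table = elem)
    prec <- seq_len(n)
    if (!is.null(order)) {
        stopifnot(length(order) == n)
        prec[order] <- seq_len(n)
    } else if (!is.null(seed)) {
        perm <- withSeed(as.integer(seed), sample.int(n))
        prec[perm] <- seq_len(n)
    }
    sol <- .bnbCover(sets_idx, length(elem), prec)
    covered <- unique(unlist(sets_idx[sol]))
    if (length(covered) != length(elem))
        stop("internal error: solver returned a non-covering solution")
    sort(meds[sol])
}

#' Enumerate every minimum cover (small instances)
#'
#' Exhaustive search by increasing cardinality; intended as a bound on what
#' solution aggregation can discover, and as an independent check of the
#' branch-and-bound optimum. Cost grows combinatorially -- use only when
#' the number of mediators is small (<= ~25).
#'
#' @param instance a \linkS4class{CoverInstance}.
#' @return List of character vectors: all distinct minimum covers.
#' @export
enumerateMinCovers <- function(instance) {
    meds <- names(instance@cover_sets)
    elem <- instance@universe
    sets_idx <- lapply(instance@cover_sets, match, table = elem)
    n <- length(meds)
    for (k in seq_len(n)) {
        combos <- combn(n, k)
        found <- list()
        for (ci in seq_len(ncol(combos))) {
            sel <- combos[, ci]
            if (length(unique(unlist(sets_idx[sel]))) == length(elem))
                found[[length(found) + 1L]] <- sort(meds[sel])
        }
        if (length(found)) return(found)
    }
    list()
}

#' Aggregate minimum covers across solver-input permutations
#'
#' Re-solves the instance \code{n_perm} times with the mediator precedence
#' randomly permuted, collecting the distinct minimum covers encountered.
#' Every trial is asserted to return the common optimum size. The union of
#' all discovered covers is the minimally-mediating gene set; candidate
#' mediators in no discovered cover are reported separately.
#'
#' @param instance a \linkS4class{CoverInstance}.
#' @param n_perm number of permutation trials (default 1000).
#' @param seed master seed for the permutation stream.
#' @return A \linkS4class{MinimalMediatorResult}.
#' @export
aggregateMinimalMediators <- function(instance, n_perm = 1000, seed = 1) {
    stopifnot(n_perm >= 1)
    seen <- new.env(parent = emptyenv())
    solutions <- list()
    opt <- NA_integer_
    for (t in seq_len(n_perm)) {
        sol <- solveMinCover(instance, seed = stableSeed(seed, "cover", t))
        if (is.na(opt)) {
            opt <- length(sol)
        } else if (length(sol) != opt) {
            stop("internal consistency error: trial ", t, " returned a ",
                 "cover of size ", length(sol), " != optimum ", opt)
        }
        key <- paste(sol, collapse = "\r")
        if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            solutions[[length(solutions) + 1L]] <- sol
        }
    }
    un <- sort(unique(unlist(solutions)))
    new("MinimalMediatorResult",
        optimum_size = as.integer(opt), solutions = solutions,
        union_minimal = un,
        other_mediators = setdiff(names(instance@cover_sets), un))
}

#' Enrichment of a mediator set in a reference gene list
#'
#' Compares the fraction of mediators found in \code{reference} with the
#' fractions obtained for \code{n_trials} random draws of the same number
#' of genes from \code{background} (without replacement). The empirical p
#' is the fraction of trials reaching at least the observed fraction.
#'
#' @param mediator_set gene ids under test.
#' @param reference reference gene list (e.g. tumour suppressors).
#' @param background gene pool to draw from; must contain
#'   \code{mediator_set}.
#' @param n_trials number of random draws (default 100).
#' @param seed integer seed.
#' @return list with \code{observed_fraction}, \code{null_mean},
#'   \code{null_sd}, \code{empirical_p}, \code{null_fractions}.
#' @export
mediatorEnrichment <- function(mediator_set, reference, background,
                               n_trials = 100, seed = 1) {
    mediator_set <- unique(mediator_set)
    background <- unique(background)
    if (!all(mediator_set %in% background))
        stop("background must contain every mediator gene")
    if (length(background) < length(mediator_set))
        stop("background smaller than the mediator set")
    k <- length(mediator_set)
    observed <- sum(mediator_set %in% reference) / k
    null <- withSeed(as.integer(seed),
        vapply(seq_len(n_trials), function(i)
            sum(sample(background, k) %in% reference) / k, 0.0))
    list(observed_fraction = observed,
         null_mean = mean(null), null_sd = sd(null),
         empirical_p = mean(null >= observed),
         null_fractions = null)
}
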