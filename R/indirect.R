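#' Rank a pathway's two-hop partners by mediated co-expression change
#'
#' A candidate indirect partner z is any gene two hops from pathway P in the
#' network, outside P, whose direct pair (x, z) is NOT itself an edge (those
#' pairs carry direct, not mediated, evidence). A pathway gene x contributes
#' delta_rho(x, z) -- computed from expression per condition group, since
#' (x, z) need not be an edge -- exactly once when at least one mediator y
#' satisfies (x,y) and (y,z) in E with sign(delta_rho(x,y)) =
#' sign(delta_rho(y,z)) = sign(delta_rho(x,z)), all non-zero. kappa_P(z) is
#' the sum over contributing x; mediator provenance is recorded per (z, x).
#'
#' @param net a \linkS4class{ChangeNetwork}.
#' @param expr the \linkS4class{CeExpressionSet} the network was built from
#'   (same gene space).
#' @param P pathway gene ids.
#' @param pathway_name label stored on the ranking.
#' @param method correlation kind, as in the network build.
#' @return A \linkS4class{KappaRanking}.
#' @export
computeKappa <- function(net, expr, P, pathway_name = "P",
                         method = "pearson") {
    adj <- .adjacency(net)
    Pn <- intersect(P, networkNodes(net))
    empty <- new("KappaRanking", pathway = pathway_name,
                 entries = data.frame(gene = character(0),
                                      score = numeric(0)),
                 statistic = "kappa", mediators = list())
    if (!length(Pn)) return(empty)
    e <- networkEdges(net)
    ekeys <- .edge_key(e$gene_x, e$gene_y)
    in_E <- function(a, b) .edge_key(a, b) %in% ekeys

    # enumerate candidate chains x (in P) -- y -- z
    xs <- character(0); ys <- character(0); zs <- character(0)
    dxy <- numeric(0); dyz <- numeric(0)
    for (x in Pn) {
        ax <- adj[[x]]
        if (is.null(ax)) next
        for (i in seq_len(nrow(ax))) {
            y <- ax$other[i]
            az <- adj[[y]]
            keep <- !(az$other %in% P) & az$other != x
            if (!any(keep)) next
            z <- az$other[keep]
            xs <- c(xs, rep(x, length(z)))
            ys <- c(ys, rep(y, length(z)))
            zs <- c(zs, z)
            dxy <- c(dxy, rep(ax$delta_rho[i], length(z)))
            dyz <- c(dyz, az$delta_rho[keep])
        }
    }
    if (!length(xs)) return(empty)
    direct <- in_E(xs, zs)
    xs <- xs[!direct]; ys <- ys[!direct]; zs <- zs[!direct]
    dxy <- dxy[!direct]; dyz <- dyz[!direct]
    if (!length(xs)) return(empty)

    # delta_rho(x, z) from expression, per group, for the needed pairs
    ux <- unique(xs); uz <- unique(zs)
    m <- exprValues(expr)
    skipped_z <- character(0)
    dr <- lapply(1:2, function(g) {
        mg <- groupValues(expr, g)
        a <- t(mg[ux, , drop = FALSE])
        b <- t(mg[uz, , drop = FALSE])
        suppressWarnings(cor(a, b, method = method))
    })
    vars_ok <- function(mat, genes) {
        v <- apply(mat[genes, , drop = FALSE], 1L, sd)
        genes[v > 0]
    }
    g1 <- groupValues(expr, 1L); g2 <- groupValues(expr, 2L)
    okz <- intersect(vars_ok(g1, uz), vars_ok(g2, uz))
    skipped_z <- setdiff(uz, okz)
    if (length(skipped_z))
        message(length(skipped_z),
                " indirect partner(s) skipped: zero variance in a group")
    dxz <- dr[[2L]][cbind(match(xs, ux), match(zs, uz))] -
           dr[[1L]][cbind(match(xs, ux), match(zs, uz))]

    qual <- zs %in% okz & !is.na(dxz) &
        dxy != 0 & dyz != 0 & dxz != 0 &
        sign(dxy) == sign(dyz) & sign(dyz) == sign(dxz)
    if (!any(qual)) return(empty)
    xs <- xs[qual]; ys <- ys[qual]; zs <- zs[qual]; dxz <- dxz[qual]

    # one contribution per (x, z) regardless of mediator multiplicity
    pair_id <- paste(xs, zs, sep = "\r")
    first <- !duplicated(pair_id)
    kappa <- vapply(split(dxz[first], zs[first]), sum, 0.0)
    kappa <- kappa[kappa != 0]
    if (!length(kappa)) return(empty)

    meds <- lapply(split(seq_along(zs), zs)[names(kappa)], function(idx) {
        lapply(split(idx, xs[idx]), function(j) sort(unique(ys[j])))
    })
    ent <- data.frame(gene = names(kappa), score = unname(kappa),
                      stringsAsFactors = FALSE)
    ent <- ent[order(ent$gene), , drop = FALSE]
    rownames(ent) <- NULL
    new("KappaRanking", pathway = pathway_name, entries = ent,
        statistic = "kappa", mediators = meds[ent$gene])
}

#' ForwardStop rule for ordered hypotheses
#'
#' Given p-values already sorted ascending, returns the largest k such that
#' the running mean of -log(1 - p_i) over the first k values stays at or
#' below \code{alpha} (p clamped below 1 before the log). The k smallest
#' p-values are then rejected; k = 0 when no prefix qualifies. Input that is
#' not sorted is an error, never silently sorted.
#'
#' @param p_values numeric vector sorted ascending, values in [0, 1].
#' @param alpha target FDR level in (0, 1).
#' @return Integer k_hat, the number of rejected hypotheses.
#' @export
forwardStop <- function(p_values, alpha) {
    stopifnot(alpha > 0, alpha < 1)
    if (!length(p_values)) return(0L)
    if (is.unsorted(p_values))
        stop("p-values must be sorted ascending before ForwardStop")
    if (any(p_values < 0 | p_values > 1))
        stop("p-values must lie in [0, 1]")
    pc <- pmin(p_values, 1 - 1e-15)
    crit <- cumsum(-log1p(-pc)) / seq_along(pc)
    k <- which(crit <= alpha)
    if (!length(k)) 0L else max(k)
}

#' Screen all pathway pairs for indirect (mediated) crosstalk change
#'
#' Identical machinery to \code{\link{screenDirectPairs}} but with the
#' two-hop kappa ranking in place of theta, and ForwardStop (over the
#' pooled, sorted permutation p-values within each direction) in place of
#' Benjamini-Hochberg. No CES cutoff is applied. Mediator provenance for
#' every called pair is attached for the set-cover stage.
#'
#' @inheritParams screenDirectPairs
#' @param expr the expression set the network was built from.
#' @param alpha ForwardStop level (default 0.01).
#' @param method correlation kind for on-demand delta_rho.
#' @return data.frame of rejected calls (q_value is \code{NA}; ForwardStop
#'   has no per-test adjusted value), ordered by p then names. Attributes:
#'   \code{all_tests}, \code{k_hat} (named by direction),
#'   \code{rankings} (the per-pathway \linkS4class{KappaRanking} objects).
#' @export
screenIndirectPairs <- function(net, expr, pathways,
                                direction = c("both", "loss", "gain"),
                                n_perm = 2000, seed = 1, alpha = 0.01,
                                min_Q_overlap = 5, method = "pearson") {
    direction <- match.arg(direction)
    directions <- if (direction == "both") c("loss", "gain") else direction
    nm <- pathwayNames(pathways)
    stopifnot(length(nm) >= 2L)
    rankings <- lapply(setNames(nm, nm), function(p)
        computeKappa(net, expr, geneSets(pathways, p), pathway_name = p,
                     method = method))
    tests <- .screenCore(rankings, pathways, directions, n_perm, seed,
                         min_Q_overlap)
    tests$q_value <- rep(NA_real_, nrow(tests))
    tests$rejected <- rep(FALSE, nrow(tests))
    k_hat <- setNames(integer(length(directions)), directions)
    for (dir in directions) {
        idx <- which(tests$direction == dir)
        if (!length(idx)) next
        ord <- idx[order(tests$p_perm[idx], tests$pathway_P[idx],
                         tests$pathway_Q[idx])]
        k <- forwardStop(tests$p_perm[ord], alpha)
        k_hat[dir] <- k
        if (k > 0L) tests$rejected[ord[seq_len(k)]] <- TRUE
    }
    calls <- tests[tests$rejected, , drop = FALSE]
    calls$rejected <- NULL
    calls <- calls[order(calls$p_perm, -calls$ces, calls$pathway_P,
                         calls$pathway_Q), , drop = FALSE]
    rownames(calls) <- NULL
    attr(calls, "all_tests") <- tests
    attr(calls, "k_hat") <- k_hat
    attr(calls, "rankings") <- rankings
    calls
}
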