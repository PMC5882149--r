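#' Select expressed genes
#'
#' Keeps genes with abundance at or above \code{min_abundance} in strictly
#' more than \code{min_fraction} of all samples, both condition groups
#' pooled (defaults: FPKM >= 1 in > 80\% of samples).
#'
#' @param expr a \linkS4class{CeExpressionSet}.
#' @param min_abundance abundance threshold (inclusive).
#' @param min_fraction required fraction of samples (strict inequality).
#' @return Character vector of retained gene ids.
#' @export
filterExpressedGenes <- function(expr, min_abundance = 1, min_fraction = 0.8) {
    stopifnot(min_fraction > 0, min_fraction <= 1)
    m <- exprValues(expr)
    frac <- rowMeans(m >= min_abundance)
    keep <- rownames(m)[frac > min_fraction]
    if (!length(keep))
        warning("no gene passes the expression filter")
    keep
}

#' Select actively expressed miRNA families
#'
#' A family is active when its mean abundance across all samples lies
#' strictly between \code{lo} and \code{hi} (defaults 0.01 and 100, the
#' moderate-expression window in which ceRNA competition is effective).
#'
#' @param mirna_expr \linkS4class{CeExpressionSet} of family-level miRNA
#'   abundance.
#' @param lo,hi window bounds (both strict).
#' @return Character vector of active family ids.
#' @export
filterActiveMirnas <- function(mirna_expr, lo = 0.01, hi = 100) {
    stopifnot(lo < hi)
    m <- exprValues(mirna_expr)
    mu <- rowMeans(m)
    rownames(m)[mu > lo & mu < hi]
}

#' Hypergeometric binding-site overlap test
#'
#' For every unordered pair of genes (after removing genes with fewer than
#' \code{min_sites} families within the active universe), tests whether the
#' number of shared miRNA families k is larger than expected when drawing
#' |F(y)| families from the universe containing |F(x)| successes:
#' p = P(X >= k), upper-tail hypergeometric. Benjamini-Hochberg correction
#' is applied across all tested pairs and pairs with q < \code{q_cutoff}
#' are returned.
#'
#' @param targets a \linkS4class{MirnaTargetMap}, already restricted to the
#'   active family universe (see \code{\link{restrictUniverse}}).
#' @param genes candidate gene ids (e.g. expressed genes).
#' @param min_sites minimum family count per gene (default 6).
#' @param q_cutoff B-H significance cutoff (default 0.05).
#' @return data.frame with columns \code{gene_x}, \code{gene_y} (gene_x <
#'   gene_y), \code{overlap_k}, \code{overlap_p}, \code{overlap_q}, one row
#'   per significant pair; attributes \code{n_genes_tested} and
#'   \code{n_pairs_tested} record the multiplicity.
#' @export
testBindingOverlap <- function(targets, genes, min_sites = 6, q_cutoff = 0.05) {
    fam <- targetFamilies(targets)
    fam <- fam[intersect(genes, names(fam))]
    N <- length(familyUniverse(targets))
    too_big <- lengths(fam) > N
    if (any(too_big))
        stop("gene family set larger than the universe: ",
             names(fam)[too_big][1L])
    fam <- fam[lengths(fam) >= min_sites]
    g <- sort(names(fam))
    empty <- data.frame(gene_x = character(0), gene_y = character(0),
                        overlap_k = integer(0), overlap_p = numeric(0),
                        overlap_q = numeric(0))
    if (length(g) < 2L) {
        attr(empty, "n_genes_tested") <- length(g)
        attr(empty, "n_pairs_tested") <- 0L
        return(empty)
    }
    # indicator matrix genes x families -> pairwise overlap via crossprod
    uni <- familyUniverse(targets)
    ind <- matrix(0L, nrow = length(g), ncol = N,
                  dimnames = list(g, uni))
    for (i in seq_along(g)) ind[i, fam[[g[i]]]] <- 1L
    K <- tcrossprod(ind)                      # shared family counts
    sizes <- rowSums(ind)
    ij <- which(upper.tri(K), arr.ind = TRUE)
    k <- K[ij]
    m1 <- sizes[ij[, 1L]]
    m2 <- sizes[ij[, 2L]]
    # P(X >= k) drawing m2 from N with m1 successes (symmetric in m1, m2)
    p <- phyper(k - 1, m1, N - m1, m2, lower.tail = FALSE)
    q <- p.adjust(p, method = "BH")
    keep <- q < q_cutoff
    res <- data.frame(gene_x = g[ij[keep, 1L]], gene_y = g[ij[keep, 2L]],
                      overlap_k = as.integer(k[keep]),
                      overlap_p = p[keep], overlap_q = q[keep],
                      stringsAsFactors = FALSE)
    swap <- res$gene_x > res$gene_y
    if (any(swap)) {
        tmp <- res$gene_x[swap]
        res$gene_x[swap] <- res$gene_y[swap]
        res$gene_y[swap] <- tmp
    }
    res <- res[order(res$gene_x, res$gene_y), , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "n_genes_tested") <- length(g)
    attr(res, "n_pairs_tested") <- length(p)
    res
}

.group_cor <- function(expr, genes, method = "pearson") {
    # per-group correlation matrices restricted to `genes`; genes with zero
    # variance in a group are flagged, their correlations set to NA
    lapply(1:2, function(gidx) {
        m <- t(groupValues(expr, gidx)[genes, , drop = FALSE])
        if (nrow(m) < 3L)
            stop("need >= 3 samples per group to compute correlations")
        sds <- apply(m, 2L, sd)
        r <- suppressWarnings(cor(m, method = method))
        r[sds == 0, ] <- NA_real_
        r[, sds == 0] <- NA_real_
        r
    })
}

#' Assemble the ceRNA relationship change network
#'
#' Annotates each significant binding-overlap pair with its within-group
#' Pearson correlations (reference group first: \code{rho_normal}) and the
#' change \code{delta_rho = rho_tumor - rho_normal}. Pairs touching a gene
#' with zero variance in either group are dropped (undefined correlation
#' must not masquerade as absent co-expression); the dropped count is kept
#' in the filter report.
#'
#' @param expr \linkS4class{CeExpressionSet} restricted (or restrictable) to
#'   the filtered genes; at least 3 samples per group.
#' @param significant_pairs data.frame from \code{\link{testBindingOverlap}}.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param q_cutoff cutoff recorded on the network object.
#' @return A \linkS4class{ChangeNetwork}.
#' @export
buildChangeNetwork <- function(expr, significant_pairs, method = "pearson",
                               q_cutoff = 0.05) {
    e <- significant_pairs
    genes <- sort(unique(c(e$gene_x, e$gene_y)))
    missing <- setdiff(genes, rownames(expr))
    if (length(missing))
        stop("pair genes absent from expression data: ",
             paste(head(missing, 3L), collapse = ", "))
    n_dropped <- 0L
    if (nrow(e)) {
        cors <- .group_cor(expr, genes, method)
        i <- match(e$gene_x, genes)
        j <- match(e$gene_y, genes)
        rho_n <- cors[[1L]][cbind(i, j)]
        rho_t <- cors[[2L]][cbind(i, j)]
        ok <- !is.na(rho_n) & !is.na(rho_t)
        n_dropped <- sum(!ok)
        if (n_dropped)
            message(n_dropped,
                    " edge(s) dropped: zero-variance gene in one group")
        e <- data.frame(gene_x = e$gene_x[ok], gene_y = e$gene_y[ok],
                        rho_normal = rho_n[ok], rho_tumor = rho_t[ok],
                        delta_rho = rho_t[ok] - rho_n[ok],
                        overlap_k = e$overlap_k[ok],
                        overlap_p = e$overlap_p[ok],
                        overlap_q = e$overlap_q[ok],
                        stringsAsFactors = FALSE)
    } else {
        e <- data.frame(gene_x = character(0), gene_y = character(0),
                        rho_normal = numeric(0), rho_tumor = numeric(0),
                        delta_rho = numeric(0), overlap_k = integer(0),
                        overlap_p = numeric(0), overlap_q = numeric(0))
    }
    rownames(e) <- NULL
    new("ChangeNetwork",
        nodes = sort(unique(c(e$gene_x, e$gene_y))),
        edges = e, q_cutoff = q_cutoff,
        report = list(n_edges = nrow(e), n_edges_dropped_zero_var = n_dropped))
}

#' Full network-construction chain
#'
#' Convenience wrapper running the expression filter, the active-miRNA
#' filter, the binding-overlap test and the network assembly, recording the
#' gene/family counts at every stage in the network's filter report.
#'
#' @param expr mRNA \linkS4class{CeExpressionSet}.
#' @param mirna_expr family-level miRNA \linkS4class{CeExpressionSet}.
#' @param targets \linkS4class{MirnaTargetMap}.
#' @param min_abundance,min_fraction see \code{\link{filterExpressedGenes}}.
#' @param mirna_lo,mirna_hi see \code{\link{filterActiveMirnas}}.
#' @param min_sites,q_cutoff see \code{\link{testBindingOverlap}}.
#' @param method correlation kind for \code{\link{buildChangeNetwork}}.
#' @return A \linkS4class{ChangeNetwork} with a complete filter report.
#' @export
buildCernaNetwork <- function(expr, mirna_expr, targets,
                              min_abundance = 1, min_fraction = 0.8,
                              mirna_lo = 0.01, mirna_hi = 100,
                              min_sites = 6, q_cutoff = 0.05,
                              method = "pearson") {
    expressed <- filterExpressedGenes(expr, min_abundance, min_fraction)
    active <- filterActiveMirnas(mirna_expr, mirna_lo, mirna_hi)
    tmap <- restrictUniverse(targets, active)
    pairs <- testBindingOverlap(tmap, expressed, min_sites, q_cutoff)
    net <- buildChangeNetwork(
        expr[intersect(rownames(expr), expressed), ], pairs,
        method = method, q_cutoff = q_cutoff)
    net@report <- c(list(
        n_genes_in = nrow(expr),
        n_genes_expressed = length(expressed),
        n_genes_with_min_sites = attr(pairs, "n_genes_tested"),
        n_mirna_families_active = length(active),
        n_pairs_tested = attr(pairs, "n_pairs_tested")), net@report)
    net
}

# adjacency list of a ChangeNetwork: gene -> data.frame(other, delta_rho)
.adjacency <- function(net) {
    e <- networkEdges(net)
    both <- data.frame(gene = c(e$gene_x, e$gene_y),
                       other = c(e$gene_y, e$gene_x),
                       delta_rho = c(e$delta_rho, e$delta_rho),
                       stringsAsFactors = FALSE)
    split(both[c("other", "delta_rho")], both$gene)
}

# fast undirected edge lookup key
.edge_key <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "\r")
}
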