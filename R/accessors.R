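#' Construct a CeExpressionSet
#'
#' @param values numeric matrix, genes x samples, non-negative, no NA.
#' @param condition factor or character of length \code{ncol(values)}; two
#'   groups. If character, levels are ordered with \code{reference} first.
#' @param reference optional reference level; defaults to \code{"normal"}
#'   when present, else the alphabetically first group.
#' @param pair_id optional per-sample pairing labels (matched designs).
#' @return A \linkS4class{CeExpressionSet}.
#' @export
CeExpressionSet <- function(values, condition, reference = NULL,
                            pair_id = NULL) {
    values <- as.matrix(values)
    if (!is.factor(condition)) {
        condition <- as.character(condition)
        groups <- sort(unique(condition))
        if (is.null(reference))
            reference <- if ("normal" %in% groups) "normal" else groups[1L]
        condition <- factor(condition,
                            levels = c(reference, setdiff(groups, reference)))
    } else if (!is.null(reference)) {
        condition <- stats::relevel(condition, ref = reference)
    }
    cd <- S4Vectors::DataFrame(condition = condition,
                               row.names = colnames(values))
    paired <- !is.null(pair_id)
    if (paired) cd$pair_id <- as.character(pair_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = values), colData = cd)
    new("CeExpressionSet", se, paired = paired)
}

#' @describeIn CeExpressionSet abundance matrix accessor.
#' @param x a \code{CeExpressionSet}.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @describeIn CeExpressionSet per-sample condition factor; the first level
#'   is the reference group.
#' @export
conditionOf <- function(x) SummarizedExperiment::colData(x)$condition

#' @describeIn CeExpressionSet abundance submatrix of one condition group
#'   (by level name or index 1/2).
#' @param group condition level name, or 1 (reference) / 2.
#' @export
groupValues <- function(x, group) {
    cond <- conditionOf(x)
    if (is.numeric(group)) group <- levels(cond)[group]
    exprValues(x)[, cond == group, drop = FALSE]
}

#' @describeIn CeExpressionSet whether a sample pairing was declared.
#' @export
isPaired <- function(x) x@paired

setMethod("show", "CeExpressionSet", function(object) {
    cond <- conditionOf(object)
    cat("CeExpressionSet:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  groups:", paste(sprintf("%s (n=%d)", levels(cond), table(cond)),
                           collapse = ", "),
        if (isPaired(object)) "[paired]\n" else "\n")
})

#' Construct a MirnaTargetMap
#'
#' @param families named list of character vectors: gene id -> miRNA family
#'   ids (deduplicated internally).
#' @param universe family universe; defaults to the union of all sets.
#' @return A \linkS4class{MirnaTargetMap}.
#' @export
MirnaTargetMap <- function(families, universe = NULL) {
    families <- lapply(families, function(f) sort(unique(as.character(f))))
    if (is.null(universe))
        universe <- sort(unique(unlist(families, use.names = FALSE)))
    new("MirnaTargetMap", families = families,
        universe = sort(unique(as.character(universe))))
}

#' @describeIn MirnaTargetMap family sets of one gene or all genes.
#' @param x a \code{MirnaTargetMap}.
#' @param gene optional gene id.
#' @export
targetFamilies <- function(x, gene = NULL) {
    if (is.null(gene)) x@families
    else x@families[[gene]]
}

#' @describeIn MirnaTargetMap the family universe.
#' @export
familyUniverse <- function(x) x@universe

#' Restrict a target map to a family universe
#'
#' Intersects every gene's family set with \code{keep} and shrinks the
#' universe accordingly; used to restrict the map to actively expressed
#' miRNA families before overlap testing.
#'
#' @param x a \code{MirnaTargetMap}.
#' @param keep character vector of family ids to retain.
#' @return A \code{MirnaTargetMap} over the restricted universe.
#' @export
restrictUniverse <- function(x, keep) {
    keep <- intersect(x@universe, keep)
    fam <- lapply(x@families, intersect, y = keep)
    MirnaTargetMap(fam[lengths(fam) > 0L], universe = keep)
}

setMethod("show", "MirnaTargetMap", function(object) {
    cat("MirnaTargetMap:", length(object@families), "genes,",
        length(object@universe), "miRNA families\n")
})

#' Construct a PathwayCollection
#'
#' @param sets named list of character vectors (gene ids per pathway).
#' @param descriptions optional character vector, one per pathway.
#' @param source free-text provenance.
#' @return A \linkS4class{PathwayCollection}.
#' @export
PathwayCollection <- function(sets, descriptions = NULL, source = "") {
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (is.null(descriptions)) descriptions <- rep("", length(sets))
    new("PathwayCollection", sets = sets,
        descriptions = as.character(descriptions), source = source)
}

#' @describeIn PathwayCollection pathway names, in file order.
#' @param x a \code{PathwayCollection}.
#' @export
pathwayNames <- function(x) names(x@sets)

#' @describeIn PathwayCollection gene sets (all, or one by name).
#' @param name optional pathway name.
#' @export
geneSets <- function(x, name = NULL) {
    if (is.null(name)) x@sets else x@sets[[name]]
}

setMethod("length", "PathwayCollection", function(x) length(x@sets))

setMethod("show", "PathwayCollection", function(object) {
    cat("PathwayCollection:", length(object@sets), "pathways",
        sprintf("(median size %d)",
                as.integer(stats::median(lengths(object@sets)))), "\n")
})

#' @rdname ChangeNetwork-class
#' @param x a \code{ChangeNetwork}.
#' @export
networkEdges <- function(x) x@edges

#' @rdname ChangeNetwork-class
#' @export
networkNodes <- function(x) x@nodes

#' Counts along the gene/family filter chain (number of input genes,
#' expressed genes, genes with enough binding sites, active families,
#' tested pairs, edges).
#' @rdname ChangeNetwork-class
#' @export
filterReport <- function(x) x@report

setMethod("show", "ChangeNetwork", function(object) {
    cat("ChangeNetwork:", length(object@nodes), "genes,",
        nrow(object@edges), "edges (overlap q <", object@q_cutoff, ")\n")
    if (nrow(object@edges))
        cat(sprintf("  delta_rho: %.1f%% loss (<0), mean %+.3f\n",
                    100 * mean(object@edges$delta_rho < 0),
                    mean(object@edges$delta_rho)))
})

#' Sign partitions of a ranking: entries with negative score ranked
#' ascending (strongest loss first) or positive score ranked descending
#' (strongest gain first); ties broken by gene id.
#' @rdname ThetaRanking-class
#' @param x a ranking.
#' @export
lossRanking <- function(x) {
    e <- x@entries[x@entries$score < 0, , drop = FALSE]
    e[order(e$score, e$gene), , drop = FALSE]
}

#' @rdname ThetaRanking-class
#' @export
gainRanking <- function(x) {
    e <- x@entries[x@entries$score > 0, , drop = FALSE]
    e[order(-e$score, e$gene), , drop = FALSE]
}

setMethod("show", "ThetaRanking", function(object) {
    cat(sprintf("%s ranking for pathway '%s': %d genes (%d loss / %d gain)\n",
                object@statistic, object@pathway, nrow(object@entries),
                sum(object@entries$score < 0), sum(object@entries$score > 0)))
})

#' Mediator provenance: for each indirect partner z (optionally one), a
#' list mapping each qualifying pathway gene x to its mediating genes y.
#' @rdname KappaRanking-class
#' @param x a \code{KappaRanking}.
#' @param z optional partner gene id.
#' @export
mediatorProvenance <- function(x, z = NULL) {
    if (is.null(z)) x@mediators else x@mediators[[z]]
}

setMethod("show", "CoverInstance", function(object) {
    cat("CoverInstance:", length(object@universe), "pathway genes,",
        length(object@cover_sets), "candidate mediators")
    if (length(object@dropped))
        cat(" (", length(object@dropped), "uncoverable genes dropped)")
    cat("\n")
})

setMethod("show", "MinimalMediatorResult", function(object) {
    cat("MinimalMediatorResult: optimum size", object@optimum_size, "-",
        length(object@solutions), "distinct solutions,",
        length(object@union_minimal), "genes in the union\n")
})

#' Accessors for the optimum cover size, the discovered solutions, their
#' union, and the remaining mediators.
#' @rdname MinimalMediatorResult-class
#' @param x a \code{MinimalMediatorResult}.
#' @export
optimumSize <- function(x) x@optimum_size

#' @rdname MinimalMediatorResult-class
#' @export
coverSolutions <- function(x) x@solutions

#' @rdname MinimalMediatorResult-class
#' @export
unionMinimal <- function(x) x@union_minimal

#' @rdname MinimalMediatorResult-class
#' @export
otherMediators <- function(x) x@other_mediators
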