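#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor sd phyper p.adjust setNames rnorm runif rpois
#' @importFrom stats median relevel
#' @importFrom utils combn read.delim write.table head
NULL

#' Two-condition expression container
#'
#' Extends \linkS4class{SummarizedExperiment} with the constraints the ceRNA
#' analysis relies on: a dense, non-negative, NA-free abundance matrix
#' (FPKM-like units) and a two-level \code{condition} factor in
#' \code{colData}. The first factor level is the reference condition
#' (typically \code{"normal"}); correlation changes are always reported as
#' second level minus first level. An optional \code{pair_id} column records
#' matched samples; pairing is carried as metadata only and does not alter
#' the per-group correlation computations.
#'
#' @slot paired logical; \code{TRUE} when a bijective sample pairing between
#'   the two groups was declared.
#' @export
setClass("CeExpressionSet",
    contains = "SummarizedExperiment",
    slots = c(paired = "logical"),
    prototype = prototype(paired = FALSE))

setValidity("CeExpressionSet", function(object) {
    msg <- character()
    a <- SummarizedExperiment::assay(object)
    if (anyNA(a))
        msg <- c(msg, "abundance matrix contains missing values")
    if (any(a < 0, na.rm = TRUE))
        msg <- c(msg, "abundance matrix contains negative values")
    if (anyDuplicated(rownames(a)))
        msg <- c(msg, "duplicated gene identifiers")
    cd <- SummarizedExperiment::colData(object)
    if (!"condition" %in% colnames(cd)) {
        msg <- c(msg, "colData lacks a 'condition' column")
    } else {
        cond <- cd$condition
        if (!is.factor(cond) || nlevels(cond) != 2L)
            msg <- c(msg, "'condition' must be a factor with exactly 2 levels")
        else if (any(table(cond) == 0L))
            msg <- c(msg, "both condition groups must be non-empty")
    }
    if (isTRUE(object@paired)) {
        if (!"pair_id" %in% colnames(cd)) {
            msg <- c(msg, "paired = TRUE but colData lacks 'pair_id'")
        } else {
            cond <- cd$condition
            p1 <- sort(as.character(cd$pair_id[cond == levels(cond)[1L]]))
            p2 <- sort(as.character(cd$pair_id[cond == levels(cond)[2L]]))
            if (length(p1) != length(p2) || anyDuplicated(p1) ||
                anyDuplicated(p2) || !identical(p1, p2))
                msg <- c(msg, "pairing map is not a bijection between groups")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Gene to miRNA-family target map
#'
#' Maps each gene to the set of miRNA families (TargetScan-style family
#' identifiers) with a binding site on it, together with the family universe
#' the hypergeometric overlap test draws from. Sets are family-level and
#' deduplicated.
#'
#' @slot families named list; per-gene character vectors of family ids.
#' @slot universe character; every family id under consideration.
#' @export
setClass("MirnaTargetMap",
    slots = c(families = "list", universe = "character"))

setValidity("MirnaTargetMap", function(object) {
    msg <- character()
    if (is.null(names(object@families)) || anyDuplicated(names(object@families)))
        msg <- c(msg, "family list must be uniquely named by gene id")
    if (any(vapply(object@families, anyDuplicated, 1L) > 0L))
        msg <- c(msg, "family sets must be deduplicated")
    if (anyDuplicated(object@universe))
        msg <- c(msg, "universe contains duplicates")
    stray <- setdiff(unique(unlist(object@families, use.names = FALSE)),
                     object@universe)
    if (length(stray))
        msg <- c(msg, paste0("families outside the universe: ",
                             paste(head(stray, 3L), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Named collection of gene sets
#'
#' An ordered map from pathway name to gene set, as read from an mSigDB-style
#' GMT file. Names are unique and every set is non-empty.
#'
#' @slot sets named list of character vectors (gene ids).
#' @slot descriptions character; one description per set (retained, unused).
#' @slot source free-text provenance of the collection.
#' @export
setClass("PathwayCollection",
    slots = c(sets = "list", descriptions = "character", source = "character"))

setValidity("PathwayCollection", function(object) {
    msg <- character()
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        msg <- c(msg, "pathway names must be unique and non-empty")
    if (any(lengths(object@sets) == 0L))
        msg <- c(msg, "every pathway must contain at least one gene")
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "one description per pathway required")
    if (length(msg)) msg else TRUE
})

#' ceRNA relationship change network
#'
#' Undirected graph over genes whose edges are pairs with significant miRNA
#' binding-site overlap, annotated with the per-condition Pearson
#' co-expression (\code{rho_normal}, \code{rho_tumor}), its change
#' \code{delta_rho = rho_tumor - rho_normal}, and the overlap test results.
#' \code{gene_x < gene_y} lexicographically on every row, no self loops.
#'
#' @slot nodes character; genes incident to at least one edge.
#' @slot edges data.frame with columns \code{gene_x}, \code{gene_y},
#'   \code{rho_normal}, \code{rho_tumor}, \code{delta_rho}, \code{overlap_k},
#'   \code{overlap_p}, \code{overlap_q}.
#' @slot q_cutoff numeric; the overlap significance cutoff every edge passed.
#' @slot report list; gene/family counts along the filter chain
#'   (see \code{\link{filterReport}}).
#' @export
setClass("ChangeNetwork",
    slots = c(nodes = "character", edges = "data.frame",
              q_cutoff = "numeric", report = "list"))

.edge_cols <- c("gene_x", "gene_y", "rho_normal", "rho_tumor", "delta_rho",
                "overlap_k", "overlap_p", "overlap_q")

setValidity("ChangeNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(.edge_cols %in% colnames(e)))
        msg <- c(msg, paste0("edges must have columns: ",
                             paste(.edge_cols, collapse = ", ")))
    else if (nrow(e)) {
        if (any(e$gene_x == e$gene_y))
            msg <- c(msg, "self loops are not allowed")
        if (any(e$gene_x > e$gene_y))
            msg <- c(msg, "edges must be stored with gene_x < gene_y")
        if (any(abs(e$delta_rho - (e$rho_tumor - e$rho_normal)) > 1e-12))
            msg <- c(msg, "delta_rho must equal rho_tumor - rho_normal")
        if (length(object@q_cutoff) == 1L && any(e$overlap_q >= object@q_cutoff))
            msg <- c(msg, "every edge must pass the overlap q cutoff")
        if (!all(c(e$gene_x, e$gene_y) %in% object@nodes))
            msg <- c(msg, "edge endpoints missing from node set")
    }
    if (length(msg)) msg else TRUE
})

#' Ranked neighbourhood of a pathway
#'
#' Genes adjacent in the change network to at least one member of pathway P,
#' scored by the summed co-expression change theta_P (direct analysis).
#' Genes with score exactly 0 are excluded. The loss sublist ranks negative
#' scores ascending (strongest loss first); the gain sublist ranks positive
#' scores descending.
#'
#' @slot pathway name of P.
#' @slot entries data.frame with columns \code{gene}, \code{score}.
#' @slot statistic \code{"theta"} or \code{"kappa"}.
#' @export
setClass("ThetaRanking",
    slots = c(pathway = "character", entries = "data.frame",
              statistic = "character"),
    prototype = prototype(statistic = "theta"))

setValidity("ThetaRanking", function(object) {
    msg <- character()
    e <- object@entries
    if (!all(c("gene", "score") %in% colnames(e)))
        msg <- c(msg, "entries must have columns gene, score")
    else {
        if (anyDuplicated(e$gene)) msg <- c(msg, "duplicate genes in ranking")
        if (any(e$score == 0)) msg <- c(msg, "zero scores must be excluded")
    }
    if (length(msg)) msg else TRUE
})

#' Two-hop (indirect) ranking with mediator provenance
#'
#' As \linkS4class{ThetaRanking} but scored by kappa_P: the summed
#' co-expression change of indirect partners z reachable from P through a
#' mediating gene y with sign-consistent changes along (x,y), (y,z) and
#' (x,z). \code{mediators} records, per partner z, which pathway genes x
#' qualified and through which mediators y.
#'
#' @slot mediators named list: z -> named list: x -> character vector of y.
#' @export
setClass("KappaRanking", contains = "ThetaRanking",
    slots = c(mediators = "list"),
    prototype = prototype(statistic = "kappa"))

#' Set-cover instance for mediator minimisation
#'
#' For a dysregulated indirect pathway pair (P,Q): the universe is the set of
#' pathway genes participating in at least one qualifying mediated chain, and
#' each candidate mediator covers the pathway-side endpoints of the chains it
#' mediates. Mediators never belong to P or Q.
#'
#' @slot universe character; coverable pathway genes.
#' @slot cover_sets named list; mediator -> subset of universe.
#' @slot dropped character; universe genes excluded because no mediator
#'   covers them.
#' @export
setClass("CoverInstance",
    slots = c(universe = "character", cover_sets = "list",
              dropped = "character"))

setValidity("CoverInstance", function(object) {
    msg <- character()
    if (!length(object@universe))
        msg <- c(msg, "empty universe")
    if (is.null(names(object@cover_sets)) || anyDuplicated(names(object@cover_sets)))
        msg <- c(msg, "cover sets must be uniquely named by mediator")
    covered <- unique(unlist(object@cover_sets, use.names = FALSE))
    if (!all(object@universe %in% covered))
        msg <- c(msg, "every universe gene must be covered by some mediator")
    if (any(!unlist(object@cover_sets, use.names = FALSE) %in% object@universe))
        msg <- c(msg, "cover sets may only contain universe genes")
    if (length(msg)) msg else TRUE
})

#' Aggregated minimum-cover solutions
#'
#' @slot optimum_size integer; provably minimum number of mediators.
#' @slot solutions list of character vectors, each a distinct minimum cover.
#' @slot union_minimal character; union over all discovered minimum covers.
#' @slot other_mediators character; candidate mediators in no discovered
#'   minimum cover.
#' @export
setClass("MinimalMediatorResult",
    slots = c(optimum_size = "integer", solutions = "list",
              union_minimal = "character", other_mediators = "character"))
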