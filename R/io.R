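#' Read an expression matrix with its condition map
#'
#' The expression table is TSV with a header row of sample ids and gene ids
#' in the first column. The condition map is TSV with columns
#' \code{sample_id}, \code{group} and optionally \code{pair_id}; it must
#' cover exactly the samples present in the matrix and define two non-empty
#' groups. Missing values are an error, never imputed; duplicated gene ids
#' are rejected by name.
#'
#' @param path expression TSV.
#' @param condition_map_path condition map TSV.
#' @param reference reference group passed to \code{\link{CeExpressionSet}}.
#' @return A \linkS4class{CeExpressionSet}.
#' @export
readExpressionTable <- function(path, condition_map_path, reference = NULL) {
    tab <- tryCatch(
        read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE),
        error = function(e) stop("failed to parse '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    if (ncol(tab) < 2L)
        stop("expression table needs a gene column plus >=1 sample column")
    genes <- as.character(tab[[1L]])
    dup <- unique(genes[duplicated(genes)])
    if (length(dup))
        stop("duplicated gene id(s): ", paste(head(dup, 5L), collapse = ", "))
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    if (anyNA(m))
        stop("missing or non-numeric abundance values in '", path, "'")
    if (any(m < 0))
        stop("negative abundance values in '", path, "'")

    cm <- read.delim(condition_map_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("sample_id", "group")
    if (!all(need %in% colnames(cm)))
        stop("condition map must have columns sample_id and group")
    unknown <- setdiff(cm$sample_id, colnames(m))
    if (length(unknown))
        stop("condition map lists sample(s) absent from the matrix: ",
             paste(head(unknown, 5L), collapse = ", "))
    missing <- setdiff(colnames(m), cm$sample_id)
    if (length(missing))
        stop("sample(s) without a condition: ",
             paste(head(missing, 5L), collapse = ", "))
    cm <- cm[match(colnames(m), cm$sample_id), , drop = FALSE]
    pair_id <- if ("pair_id" %in% colnames(cm)) cm$pair_id else NULL
    CeExpressionSet(m, condition = cm$group, reference = reference,
                    pair_id = pair_id)
}

#' Read a GMT gene-set file
#'
#' Each line is \code{name<TAB>description<TAB>gene1<TAB>gene2...}; lines
#' with fewer than three fields and duplicate pathway names are errors.
#' File order is preserved.
#'
#' @param path GMT file.
#' @return A \linkS4class{PathwayCollection}.
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty GMT file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("GMT line ", short[1L], " has fewer than 3 fields (no genes)")
    nm <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(nm))
        stop("duplicate pathway name: ", nm[duplicated(nm)][1L])
    sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
    names(sets) <- nm
    PathwayCollection(sets,
                      descriptions = vapply(fields, `[[`, "", 2L),
                      source = path)
}

#' Read a gene / miRNA-family binding-site table
#'
#' TSV with columns \code{gene_id}, \code{mirna_family_id} and optionally
#' \code{score} (a Pct-like site-confidence score). When \code{min_score}
#' is non-NULL, rows with \code{score <= min_score} are dropped; the default
#' 0 keeps only preferentially conserved sites (Pct > 0). The family
#' universe is every family seen in the file before any gene-level
#' filtering.
#'
#' @param path target table TSV.
#' @param min_score drop rows with score at or below this; \code{NULL}
#'   keeps all rows.
#' @return A \linkS4class{MirnaTargetMap}.
#' @export
readMirnaTargetTable <- function(path, min_score = 0) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("gene_id", "mirna_family_id")
    if (!all(need %in% colnames(tab)))
        stop("target table must have columns gene_id and mirna_family_id")
    universe <- sort(unique(as.character(tab$mirna_family_id)))
    if (!is.null(min_score)) {
        if (!"score" %in% colnames(tab))
            stop("min_score given but table has no 'score' column")
        tab <- tab[tab$score > min_score, , drop = FALSE]
    }
    if (!nrow(tab))
        stop("no target rows remain after score filtering")
    fam <- split(as.character(tab$mirna_family_id),
                 as.character(tab$gene_id))
    MirnaTargetMap(fam, universe = universe)
}

.results_cols <- c("pathway_P", "pathway_Q", "direction", "CES", "p_perm",
                   "q_value", "n_contributing_genes")

#' Write pathway-pair calls to TSV
#'
#' Writes the standard results table (columns \code{pathway_P},
#' \code{pathway_Q}, \code{direction}, \code{CES}, \code{p_perm},
#' \code{q_value}, \code{n_contributing_genes}) with numeric fields at six
#' decimals, ordered by q-value, then CES descending, then pathway names.
#' An empty call set writes a header-only file.
#'
#' @param calls data.frame of calls as returned by the screen functions.
#' @param path output TSV.
#' @return Invisibly, the ordered table as written.
#' @export
writeResultsTable <- function(calls, path) {
    if (is.null(calls) || !nrow(calls)) {
        out <- as.data.frame(setNames(rep(list(character(0)),
                                          length(.results_cols)),
                                      .results_cols))
    } else {
        out <- data.frame(
            pathway_P = calls$pathway_P,
            pathway_Q = calls$pathway_Q,
            direction = calls$direction,
            CES = round(calls$ces, 6L),
            p_perm = round(calls$p_perm, 6L),
            q_value = round(calls$q_value, 6L),
            n_contributing_genes = calls$n_Q_in_ranking,
            stringsAsFactors = FALSE)
        out <- out[order(out$q_value, -out$CES, out$pathway_P, out$pathway_Q,
                         na.last = FALSE), , drop = FALSE]
        rownames(out) <- NULL
    }
    tryCatch(
        write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
        error = function(e) stop("cannot write results to '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    invisible(out)
}

#' Read back a results table written by \code{writeResultsTable}
#'
#' @param path results TSV.
#' @return data.frame with the standard result columns.
#' @export
readResultsTable <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (!all(.results_cols %in% colnames(tab)))
        stop("not a results table: ", path)
    tab
}

#' Write / read a change-network edge list
#'
#' TSV serialisation of \code{\link{networkEdges}} with the lexicographically
#' smaller gene first on each row.
#'
#' @param net a \linkS4class{ChangeNetwork}.
#' @param path edge-list TSV.
#' @return \code{writeNetworkEdges} returns the path invisibly;
#'   \code{readNetworkEdges} a \code{ChangeNetwork}.
#' @export
writeNetworkEdges <- function(net, path) {
    e <- networkEdges(net)
    e <- e[order(e$gene_x, e$gene_y), , drop = FALSE]
    write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeNetworkEdges
#' @param q_cutoff overlap significance cutoff the edges were filtered at.
#' @export
readNetworkEdges <- function(path, q_cutoff = 0.05) {
    e <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    if (!all(.edge_cols %in% colnames(e)))
        stop("not an edge list: ", path)
    new("ChangeNetwork",
        nodes = sort(unique(c(e$gene_x, e$gene_y))),
        edges = e[, .edge_cols, drop = FALSE],
        q_cutoff = q_cutoff, report = list())
}
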