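# Shared fixture builders. Everything is generated in code; no data files.

# small two-group expression set with log-normal abundance
make_expr <- function(n_genes = 12, n_per_group = 10, seed = 1,
                      gene_ids = sprintf("g%02d", seq_len(n_genes))) {
    set.seed(seed)
    m <- matrix(exp(rnorm(n_genes * 2 * n_per_group, log(20), 1)),
                nrow = n_genes,
                dimnames = list(gene_ids,
                                c(sprintf("N%02d", seq_len(n_per_group)),
                                  sprintf("T%02d", seq_len(n_per_group)))))
    CeExpressionSet(m, condition = rep(c("normal", "tumor"),
                                       each = n_per_group))
}

# ChangeNetwork over `expr` with the given gene pairs as edges; the
# correlation annotation is computed by buildChangeNetwork itself, so use
# this only to construct inputs for downstream operations
make_network <- function(expr, pairs) {
    sig <- data.frame(gene_x = pmin(pairs[, 1], pairs[, 2]),
                      gene_y = pmax(pairs[, 1], pairs[, 2]),
                      overlap_k = 6L, overlap_p = 1e-8, overlap_q = 1e-6,
                      stringsAsFactors = FALSE)
    sig <- sig[!duplicated(paste(sig$gene_x, sig$gene_y)), , drop = FALSE]
    buildChangeNetwork(expr, sig)
}

# bare ranking object from parallel gene / score vectors
make_ranking <- function(genes, scores, pathway = "P") {
    new("ThetaRanking", pathway = pathway,
        entries = data.frame(gene = genes, score = scores,
                             stringsAsFactors = FALSE),
        statistic = "theta")
}

# independent Pearson correlation (textbook formula), used as the oracle
# against the cor()-based implementation
pearson_oracle <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# independent upper-tail hypergeometric probability by direct summation of
# the pmf: P(X >= k) drawing n from N with K successes
hyper_tail_oracle <- function(k, K, n, N) {
    j <- seq(from = k, to = min(K, n))
    if (!length(j) || k > min(K, n)) return(if (k <= 0) 1 else 0)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# independent running-sum evaluation at every prefix (explicit loop)
ces_oracle <- function(w, hit) {
    n <- length(w)
    nh <- sum(hit)
    if (nh == 0L) return(0)
    nr <- sum(w[hit])
    if (nr == 0) return(0)
    run <- 0; best <- 0
    for (i in seq_len(n)) {
        run <- run + (if (hit[i]) w[i] / nr else -1 / (n - nh))
        if (abs(run) > best) best <- abs(run)
    }
    best
}

# exhaustive minimum set cover by increasing cardinality (independent of
# the package's branch-and-bound and of its own enumerator)
min_cover_oracle <- function(sets, universe) {
    idx <- lapply(sets, match, table = universe)
    n <- length(sets)
    for (k in seq_len(n)) {
        combos <- utils::combn(n, k)
        for (ci in seq_len(ncol(combos))) {
            sel <- combos[, ci]
            if (length(unique(unlist(idx[sel]))) == length(universe))
                return(k)
        }
    }
    Inf
}

# random set-cover instance with every universe element covered
random_cover_instance <- function(n_elem, n_sets, seed) {
    set.seed(seed)
    elem <- sprintf("p%02d", seq_len(n_elem))
    repeat {
        sets <- lapply(seq_len(n_sets), function(i) {
            s <- elem[runif(n_elem) < 0.25]
            if (!length(s)) s <- sample(elem, 1L)
            s
        })
        names(sets) <- sprintf("m%02d", seq_len(n_sets))
        if (all(elem %in% unique(unlist(sets)))) break
        seed <- seed + 10000L
        set.seed(seed)
    }
    new("CoverInstance", universe = elem, cover_sets = sets,
        dropped = character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
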