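mk_kappa <- function(pathway, meds) {
    genes <- names(meds)
    new("KappaRanking", pathway = pathway,
        entries = data.frame(gene = genes,
                             score = -seq_along(genes),
                             stringsAsFactors = FALSE),
        statistic = "kappa", mediators = meds)
}

test_that("cover instances collect chain endpoints per mediator", {
    # single chain x -- y -- z with x in P, z in Q
    kP <- mk_kappa("P", list(z = list(x = "y")))
    inst <- buildCoverInstance(kP, NULL, P = c("x", "x2"), Q = c("z", "z2"))
    expect_setequal(inst@universe, c("x", "z"))
    expect_identical(inst@cover_sets, list(y = c("x", "z")))

    # two chains sharing a mediator cover all four endpoints
    kP2 <- mk_kappa("P", list(z = list(x = "y"), z2 = list(x2 = "y")))
    inst2 <- buildCoverInstance(kP2, NULL, P = c("x", "x2"),
                                Q = c("z", "z2"))
    expect_setequal(inst2@cover_sets$y, c("x", "z", "x2", "z2"))

    # both orientations merge their provenance
    kQ <- mk_kappa("Q", list(x2 = list(z2 = "y2")))
    inst3 <- buildCoverInstance(kP, kQ, P = c("x", "x2"), Q = c("z", "z2"))
    expect_setequal(names(inst3@cover_sets), c("y", "y2"))
    expect_setequal(inst3@universe, c("x", "z", "x2", "z2"))

    # mediators inside P or Q are excluded; uncovered genes are pruned
    kP3 <- mk_kappa("P", list(z = list(x = "x2"), z2 = list(x = "y")))
    expect_message(
        inst4 <- buildCoverInstance(kP3, NULL, P = c("x", "x2"),
                                    Q = c("z", "z2")),
        "uncoverable")
    expect_setequal(inst4@universe, c("x", "z2"))
    expect_identical(inst4@dropped, "z")

    kEmpty <- mk_kappa("P", list(other = list(x = "y")))
    expect_error(buildCoverInstance(kEmpty, NULL, P = "x", Q = "z"),
                 "no mediated")
})

test_that("the exact solver finds provably minimum covers", {
    inst <- new("CoverInstance", universe = c("1", "2", "3", "4"),
                cover_sets = list(m1 = c("1", "2"), m2 = c("3", "4"),
                                  m3 = c("1", "2", "3")),
                dropped = character(0))
    sol <- solveMinCover(inst)
    expect_identical(length(sol), 2L)
    expect_true("m2" %in% sol)

    one <- new("CoverInstance", universe = c("1", "2"),
               cover_sets = list(big = c("1", "2"), small = "1"),
               dropped = character(0))
    expect_identical(solveMinCover(one), "big")

    # degenerate tie: one gene, five equivalent mediators -> size 1
    tie <- new("CoverInstance", universe = "1",
               cover_sets = setNames(replicate(5, "1", simplify = FALSE),
                                     paste0("m", 1:5)),
               dropped = character(0))
    picks <- unique(vapply(1:20, function(s)
        solveMinCover(tie, seed = s), ""))
    expect_true(all(lengths(strsplit(picks, " ")) == 1))
    expect_gt(length(picks), 1)  # the tie really is order-dependent
})

test_that("solver cardinality equals exhaustive search on random instances", {
    for (s in 1:50) {
        inst <- random_cover_instance(n_elem = sample(5:10, 1),
                                      n_sets = sample(6:20, 1),
                                      seed = 7000 + s)
        sol <- solveMinCover(inst, seed = s)
        expect_identical(length(sol),
                         min_cover_oracle(inst@cover_sets, inst@universe))
        covered <- unique(unlist(inst@cover_sets[sol]))
        expect_true(all(inst@universe %in% covered))
    }
})

test_that("solution aggregation discovers all co-optimal covers", {
    inst <- new("CoverInstance", universe = c("1", "2", "3", "4"),
                cover_sets = list(m1 = c("1", "2"), m2 = c("3", "4"),
                                  m3 = c("1", "2"), m4 = c("1", "3")),
                dropped = character(0))
    res <- aggregateMinimalMediators(inst, n_perm = 60, seed = 1)
    expect_identical(optimumSize(res), 2L)
    # enumeration bounds the union: {m1,m2} and {m3,m2} are the optima
    enum <- enumerateMinCovers(inst)
    expect_setequal(unionMinimal(res),
                    sort(unique(unlist(enum))))
    expect_setequal(unionMinimal(res), c("m1", "m2", "m3"))
    expect_identical(otherMediators(res), "m4")
    expect_true(all(lengths(coverSolutions(res)) == 2L))

    # unique optimum: the union equals it for any permutation count
    uni <- new("CoverInstance", universe = c("1", "2"),
               cover_sets = list(a = c("1", "2"), b = "1"),
               dropped = character(0))
    expect_identical(unionMinimal(aggregateMinimalMediators(uni, 25, 3)),
                     "a")
    one_perm <- aggregateMinimalMediators(inst, n_perm = 1, seed = 2)
    expect_identical(length(coverSolutions(one_perm)), 1L)
    expect_identical(unionMinimal(one_perm), coverSolutions(one_perm)[[1]])
})

test_that("aggregated unions grow monotonically and stay bounded", {
    inst <- random_cover_instance(8, 14, seed = 99)
    full <- sort(unique(unlist(enumerateMinCovers(inst))))
    prev <- character(0)
    for (np in c(1, 5, 25, 80)) {
        u <- unionMinimal(aggregateMinimalMediators(inst, np, seed = 5))
        expect_true(all(prev %in% u))
        expect_true(all(u %in% full))
        prev <- u
    }
})

test_that("mediator enrichment compares against random draws", {
    bg <- sprintf("b%03d", 1:200)
    ref <- bg[1:40]
    res <- mediatorEnrichment(bg[1:10], reference = bg, background = bg,
                              n_trials = 50, seed = 1)
    expect_equal(res$observed_fraction, 1)
    expect_equal(res$null_mean, 1)
    expect_equal(res$empirical_p, 1)

    res0 <- mediatorEnrichment(bg[101:120], reference = ref,
                               background = bg[41:200],
                               n_trials = 100, seed = 2)
    expect_equal(res0$observed_fraction, 0)
    expect_gt(res0$empirical_p, 0.9)

    expect_error(mediatorEnrichment(bg[1:10], ref, background = bg[1:5]),
                 "background")

    # planted enrichment: mediators drawn 3x over-weighted from the
    # reference are flagged in most replicates
    set.seed(33)
    bg2 <- sprintf("c%03d", 1:500); ref2 <- bg2[1:100]
    hits <- 0L
    for (r in 1:50) {
        w <- ifelse(bg2 %in% ref2, 3, 1)
        med <- sample(bg2, 50, prob = w)
        p <- mediatorEnrichment(med, ref2, bg2, n_trials = 100,
                                seed = r)$empirical_p
        hits <- hits + (p <= 0.05)
    }
    expect_gte(hits, 45L)
})

test_that("end-to-end mediators recover a planted chain's true mediators", {
    spec <- syntheticSpec(
        n_genes = 240,
        planted_chains = list(list(P = 1, mediator_count = 4, Q = 2,
                                   direction = "loss", effect = 0.8)),
        seed = 1618)
    st <- simulateCernaStudy(spec)
    net <- suppressMessages(buildCernaNetwork(st$mrna, st$mirna, st$targets))
    calls <- screenIndirectPairs(net, st$mrna, st$pathways, n_perm = 300,
                                 seed = 6)
    expect_gt(nrow(calls), 0)
    rk <- attr(calls, "rankings")
    inst <- buildCoverInstance(rk[["PW01"]], rk[["PW02"]],
                               geneSets(st$pathways, "PW01"),
                               geneSets(st$pathways, "PW02"))
    truth <- st$ground_truth$chains[[1]]$mediators
    expect_true(all(solveMinCover(inst, seed = 1) %in%
                    names(inst@cover_sets)))
    # every planted mediator is a candidate; the minimal set is drawn
    # from genuinely covering genes
    expect_true(all(truth %in% names(inst@cover_sets)))
    res <- aggregateMinimalMediators(inst, n_perm = 30, seed = 2)
    expect_true(all(unionMinimal(res) %in% names(inst@cover_sets)))
    expect_lte(optimumSize(res), length(truth))
})
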