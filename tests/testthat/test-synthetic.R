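test_that("generation is deterministic under a fixed seed", {
    sp <- syntheticSpec(seed = 12,
                        planted_pairs = list(list(P = 1, Q = 2,
                                                  direction = "loss",
                                                  effect = 0.5)),
                        n_genes = 230)
    a <- simulateCernaStudy(sp)
    b <- simulateCernaStudy(sp)
    expect_identical(exprValues(a$mrna), exprValues(b$mrna))
    expect_identical(exprValues(a$mirna), exprValues(b$mirna))
    expect_identical(targetFamilies(a$targets), targetFamilies(b$targets))
    expect_identical(geneSets(a$pathways), geneSets(b$pathways))
    expect_identical(a$ground_truth, b$ground_truth)
})

test_that("spec validation rejects impossible layouts", {
    expect_error(syntheticSpec(n_genes = 50, n_pathways = 20,
                               pathway_size = 10, seed = 1),
                 "exceeds n_genes")
    expect_error(syntheticSpec(seed = 1, planted_pairs = list(
        list(P = 1, Q = 1, direction = "loss", effect = 0.5))),
        "invalid pathway index")
    expect_error(syntheticSpec(seed = 1, planted_pairs = list(
        list(P = 1, Q = 2, direction = "loss", effect = 1.5))))
    expect_error(simulateCernaStudy(syntheticSpec(
        n_genes = 205, seed = 1, planted_chains = list(
            list(P = 1, mediator_count = 4, Q = 2, direction = "loss",
                 effect = 0.5)))),
        "not enough free genes")
    st <- simulateCernaStudy(syntheticSpec(n_genes = 205, seed = 1))
    expect_length(st$ground_truth$pairs, 0)
})

test_that("null studies have empty ground truth and centred delta_rho", {
    st <- simulateNullStudy(syntheticSpec(
        seed = 5, planted_pairs = list(list(P = 1, Q = 2,
                                            direction = "loss",
                                            effect = 0.9))))
    expect_length(st$ground_truth$pairs, 0)
    expect_length(st$ground_truth$chains, 0)
    net <- suppressMessages(buildCernaNetwork(st$mrna, st$mirna,
                                              st$targets))
    e <- networkEdges(net)
    expect_gt(nrow(e), 10)  # background modules provide edges
    expect_lt(abs(mean(e$delta_rho)), 0.1)
})

test_that("planted direct pairs show the prescribed co-expression change", {
    st <- simulateCernaStudy(syntheticSpec(
        n_genes = 230,
        planted_pairs = list(list(P = 1, Q = 2, direction = "loss",
                                  effect = 0.8)),
        seed = 31))
    P <- geneSets(st$pathways, "PW01"); Q <- geneSets(st$pathways, "PW02")
    gn <- groupValues(st$mrna, "normal"); gt <- groupValues(st$mrna, "tumor")
    d <- c(outer(P, Q, Vectorize(function(x, y)
        pearson_oracle(gt[x, ], gt[y, ]) - pearson_oracle(gn[x, ], gn[y, ]))))
    expect_lt(mean(d), -0.3)

    # gain direction flips the sign
    stg <- simulateCernaStudy(syntheticSpec(
        n_genes = 230,
        planted_pairs = list(list(P = 3, Q = 4, direction = "gain",
                                  effect = 0.8)),
        seed = 32))
    P <- geneSets(stg$pathways, "PW03"); Q <- geneSets(stg$pathways, "PW04")
    gn <- groupValues(stg$mrna, "normal")
    gt <- groupValues(stg$mrna, "tumor")
    dg <- c(outer(P, Q, Vectorize(function(x, y)
        pearson_oracle(gt[x, ], gt[y, ]) - pearson_oracle(gn[x, ], gn[y, ]))))
    expect_gt(mean(dg), 0.3)
})

test_that("recovered effect grows monotonically with the planted effect", {
    est <- vapply(c(0.2, 0.5, 0.8), function(eff) {
        st <- simulateCernaStudy(syntheticSpec(
            n_genes = 230,
            planted_pairs = list(list(P = 1, Q = 2, direction = "loss",
                                      effect = eff)),
            seed = 64))
        P <- geneSets(st$pathways, "PW01")
        Q <- geneSets(st$pathways, "PW02")
        gn <- groupValues(st$mrna, "normal")
        gt <- groupValues(st$mrna, "tumor")
        -mean(c(outer(P, Q, Vectorize(function(x, y)
            pearson_oracle(gt[x, ], gt[y, ]) -
            pearson_oracle(gn[x, ], gn[y, ])))))
    }, 0.0)
    # monotone in the planted effect; Pearson on the abundance scale is
    # attenuated relative to the log-scale loading (log-normal tails)
    expect_true(all(diff(est) > 0))
    expect_gt(est[3], 0.45)
})

test_that("without planted structure delta_rho vanishes at large n", {
    st <- simulateNullStudy(syntheticSpec(n_genes = 60, n_pathways = 6,
                                          pathway_size = 10,
                                          n_samples_per_group = 200,
                                          seed = 202))
    gn <- groupValues(st$mrna, "normal"); gt <- groupValues(st$mrna, "tumor")
    set.seed(1)
    ij <- t(combn(rownames(st$mrna), 2))[sample(1770, 150), ]
    d <- apply(ij, 1, function(p)
        pearson_oracle(gt[p[1], ], gt[p[2], ]) -
        pearson_oracle(gn[p[1], ], gn[p[2], ]))
    expect_lt(mean(abs(d)), 0.1)
})

test_that("planted chains are recoverable exactly at the ground truth", {
    st <- simulateCernaStudy(syntheticSpec(
        n_genes = 240,
        planted_chains = list(list(P = 1, mediator_count = 4, Q = 2,
                                   direction = "loss", effect = 0.8)),
        seed = 12345))
    truth <- st$ground_truth$chains[[1]]
    net <- suppressMessages(buildCernaNetwork(st$mrna, st$mirna,
                                              st$targets))
    kr <- computeKappa(net, st$mrna, geneSets(st$pathways, "PW01"), "PW01")
    # every planted Q gene appears as an indirect loss partner
    expect_true(all(truth$Q_genes %in% kr@entries$gene))
    expect_true(all(kr@entries$score[kr@entries$gene %in% truth$Q_genes] < 0))
    # recorded mediators for those partners are the planted ones
    for (z in truth$Q_genes) {
        meds <- unique(unlist(mediatorProvenance(kr, z)))
        expect_true(all(meds %in% truth$mediators))
    }
})

test_that("miRNA abundances place active families inside the window", {
    st <- simulateNullStudy(syntheticSpec(seed = 8))
    mu <- rowMeans(exprValues(st$mirna))
    active <- filterActiveMirnas(st$mirna)
    expect_identical(length(active), 120L)
    expect_true(all(mu[active] > 0.01 & mu[active] < 100))
    expect_true(all(mu[setdiff(names(mu), active)] <= 0.01 |
                    mu[setdiff(names(mu), active)] >= 100))
})

test_that("target map density matches the set-size parameter", {
    st <- simulateNullStudy(syntheticSpec(seed = 15))
    sizes <- lengths(targetFamilies(st$targets))
    expect_identical(length(sizes), 200L)
    expect_equal(mean(sizes), 18, tolerance = 0.05 * 18)  # 10 + Pois(8)
    expect_true(all(unlist(targetFamilies(st$targets)) %in%
                    familyUniverse(st$targets)))
})

test_that("written study files load back through the standard readers", {
    st <- simulateCernaStudy(syntheticSpec(
        n_genes = 230,
        planted_pairs = list(list(P = 1, Q = 2, direction = "loss",
                                  effect = 0.8)),
        seed = 55))
    d <- withr::local_tempdir()
    paths <- writeStudyFiles(st, d)
    expect_true(all(file.exists(paths)))

    expr <- readExpressionTable(paths["expr"], paths["conditions"])
    expect_equal(exprValues(expr), exprValues(st$mrna), tolerance = 1e-9)
    expect_true(isPaired(expr))
    mir <- readExpressionTable(paths["mirna"], paths["conditions"])
    expect_identical(dim(mir), dim(st$mirna))
    tm <- readMirnaTargetTable(paths["targets"])
    expect_identical(lapply(targetFamilies(tm),  sort),
                     lapply(targetFamilies(st$targets), sort))
    pc <- readGmt(paths["gmt"])
    expect_identical(geneSets(pc), geneSets(st$pathways))
    truth <- jsonlite::read_json(paths["truth"])
    expect_identical(length(truth$pairs), 1L)
})
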