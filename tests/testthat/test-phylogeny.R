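test_that("p-distances count mismatches over shared calls", {
    calls <- matrix(c(0L, 0L, 1L, 1L,
                      0L, 1L, 1L, 0L,
                      0L, 0L, 1L, 1L), 4, 3)
    colnames(calls) <- c("s1", "s2", "s3")
    dm <- snpDistance(makeGeno(calls))
    expect_equal(dm["s1", "s3"], 0)
    expect_equal(dm["s1", "s2"], 0.5)
    expect_equal(dm, t(dm))
    expect_equal(unname(diag(dm)), rep(0, 3))

    withNA <- matrix(c(0L, NA, 1L, 0L, 1L, 1L), 3, 2)
    colnames(withNA) <- c("x", "y")
    expect_equal(snpDistance(makeGeno(withNA))["x", "y"], 0)

    allNA <- matrix(c(NA, NA, 0L, 1L), 2, 2)
    colnames(allNA) <- c("bad", "ok")
    expect_error(snpDistance(makeGeno(allNA)), "bad")
})

test_that("NJ exactly recovers additive trees", {
    skip_if_not_installed("phangorn")
    set.seed(10)
    for (ntaxa in c(4, 6, 8)) {
        tr <- ape::rtree(ntaxa)
        dm <- ape::cophenetic.phylo(tr)
        rec <- njTree(dm)
        expect_equal(phangorn::RF.dist(ape::unroot(tr), rec), 0)
        expect_equal(ape::cophenetic.phylo(rec)[rownames(dm), rownames(dm)],
                     dm, tolerance = 1e-8)
    }
})

test_that("3-taxon NJ lengths follow the closed-form 3-point formulas", {
    dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
                 dimnames = list(letters[1:3], letters[1:3]))
    tree <- njTree(dm)
    len <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                    tree$tip.label)
    expect_equal(len[["a"]], (3 + 4 - 5) / 2)
    expect_equal(len[["b"]], (3 + 5 - 4) / 2)
    expect_equal(len[["c"]], (4 + 5 - 3) / 2)
})

test_that("taxon order does not change the NJ topology", {
    skip_if_not_installed("phangorn")
    set.seed(11)
    tr <- ape::rtree(7)
    dm <- ape::cophenetic.phylo(tr)
    perm <- sample(rownames(dm))
    t1 <- njTree(dm)
    t2 <- njTree(dm[perm, perm])
    expect_equal(phangorn::RF.dist(t1, t2), 0)
})

test_that("Fitch scoring matches brute-force enumeration", {
    # hand case: ((A,B),(C,D)) with a clean split costs one change
    tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
    calls <- matrix(c(0L, 0L, 1L, 1L,      # split marker
                      1L, 1L, 1L, 1L),     # invariant marker
                    2, 4, byrow = TRUE)
    colnames(calls) <- c("A", "B", "C", "D")
    expect_equal(fitchScore(tree, makeGeno(calls)), 1L)

    set.seed(12)
    for (rep in 1:5) {
        ntaxa <- sample(4:6, 1)
        tr <- ape::rtree(ntaxa)
        g <- matrix(sample(c(0L, 1L, NA), 8 * ntaxa, replace = TRUE,
                           prob = c(0.45, 0.45, 0.1)), 8, ntaxa)
        colnames(g) <- tr$tip.label
        expected <- sum(vapply(seq_len(nrow(g)), function(i)
            bruteFitch(tr, g[i, ]), 0))
        expect_equal(fitchScore(tr, makeGeno(g)), expected)
    }
})

test_that("Fitch agrees with brute force on all 15 five-leaf topologies", {
    skip_if_not_installed("phangorn")
    set.seed(13)
    g <- matrix(sample(c(0L, 1L), 50, replace = TRUE), 10, 5)
    colnames(g) <- paste0("t", 1:5)
    geno <- makeGeno(g)
    topos <- phangorn::allTrees(5, tip.label = paste0("t", 1:5))
    for (i in seq_along(topos)) {
        tr <- topos[[i]]
        tr$edge.length <- rep(1, nrow(tr$edge))
        expected <- sum(vapply(seq_len(nrow(g)), function(i)
            bruteFitch(tr, g[i, ]), 0))
        expect_equal(fitchScore(tr, geno), expected)
    }
})

test_that("missing leaves are reported by name", {
    tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")
    calls <- matrix(0L, 2, 4,
                    dimnames = list(NULL, c("A", "B", "C", "D")))
    expect_error(fitchScore(tree, makeGeno(calls)), "E")
})

test_that("clade cutting honours tree structure", {
    tree <- ape::read.tree(text = "((A:1,B:1):5,(C:1,D:1):5);")
    one <- cutClades(tree, 1)
    expect_equal(unname(one), rep(1L, 4))
    # caterpillar with one long internal edge splits at that edge
    cat4 <- ape::read.tree(
        text = "(A:1,(B:1,(C:1,(D:1,E:1):0.1):10):0.1);")
    two <- cutClades(cat4, 2)
    expect_equal(length(unique(two)), 2)
    expect_equal(unname(two[c("C", "D", "E")]), rep(two[["C"]], 3))
    expect_equal(unname(two[c("A", "B")]), rep(two[["A"]], 2))
    expect_error(cutClades(cat4, 10), "")
})

test_that("planted clades are recovered from simulated SNPs", {
    cfg <- simConfig(n_accessions = 30, n_clades = 2, n_markers = 300,
                     seed = 14)
    sim <- simulateGenotypes(cfg)
    clades <- cutClades(njTree(snpDistance(sim$geno)), 2)
    expect_equal(ari(clades, sim$truth$clade[names(clades)]), 1)
})

test_that("clade enrichment reproduces fold and hypergeometric p", {
    enr <- cladeEnrichment(7, 14, 19, 185)
    expect_equal(round(enr$fold, 2), 4.87)
    # clade composition equal to population composition -> fold 1
    expect_equal(cladeEnrichment(2, 20, 10, 100)$fold, 1)
    # upper-tail p equals explicit pmf summation
    pmfSum <- sum(dhyper(3:5, 6, 14, 5))
    expect_equal(cladeEnrichment(3, 5, 6, 20)$p, pmfSum,
                 tolerance = 1e-12)
    expect_true(is.na(cladeEnrichment(0, 5, 0, 20)$fold))
})
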