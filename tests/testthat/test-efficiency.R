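test_that("BEI combines the two ratios multiplicatively", {
    expect_equal(beiShoot(1, 1), 1)
    expect_equal(beiShoot(0.5, 0.5), 0.25)
    expect_true(is.na(beiShoot(NA_real_, 0.5)))
    expect_equal(beiRoot(1, 1), 1)
    expect_equal(beiRoot(0.7, 1.684), 1.179, tolerance = 1e-3)
    # alternative forms behind the config switch
    expect_equal(beiShoot(0.4, 0.9, "geometric"), sqrt(0.36))
    expect_equal(beiShoot(0.4, 0.9, "arithmetic"), 0.65)
})

test_that("BEI is strictly monotone in each ratio", {
    set.seed(3)
    for (i in 1:10) {
        a <- runif(1, 0.05, 1.5); b <- runif(1, 0.05, 1.5)
        eps <- runif(1, 0.01, 0.2)
        expect_gt(beiShoot(a + eps, b), beiShoot(a, b))
        expect_gt(beiShoot(a, b + eps), beiShoot(a, b))
    }
})

test_that("the printed root index is consistent with the product form", {
    # a 76.9% PRL reduction with the printed index implies a lateral
    # ratio inside [0, 1]
    implied_tlrl <- 0.054 / (1 - 0.769)
    expect_gt(implied_tlrl, 0)
    expect_lt(implied_tlrl, 1)
})

test_that("percentile classification yields exact class counts", {
    set.seed(7)
    n <- 185
    sc <- EfficiencyScores(data.frame(
        accession = sprintf("a%03d", 1:n),
        bei_shoot = sort(rexp(n, 4)), bei_root = runif(n)))
    out <- scoreTable(classifyAccessions(sc, cfg = pipelineConfig()))
    expect_equal(sum(out$class == "B-efficient"), 19)
    expect_equal(sum(out$class == "highly-B-deficiency-sensitive"), 19)
    expect_equal(sum(table(out$class)), n)
    # the intermediate rule applies only outside the efficient set
    inter <- out$class == "B-intermediate-efficient"
    expect_true(all(out$bei_shoot[inter] > 0.400))
    eff_min <- min(out$bei_shoot[out$class == "B-efficient"])
    expect_true(all(out$bei_shoot[inter] <= eff_min))
})

test_that("ties in BEI break by accession id and still partition", {
    sc <- EfficiencyScores(data.frame(
        accession = sprintf("a%02d", 1:20), bei_shoot = rep(0.3, 20)))
    out <- scoreTable(classifyAccessions(sc, cfg = pipelineConfig()))
    expect_equal(sum(out$class == "B-efficient"), 2)
    expect_identical(out$accession[out$class == "B-efficient"],
                     c("a01", "a02"))
    expect_identical(out$accession[out$class ==
                                   "highly-B-deficiency-sensitive"],
                     c("a19", "a20"))
    expect_error(classifyAccessions(
        EfficiencyScores(data.frame(accession = "x", bei_shoot = 1)),
        cfg = pipelineConfig()), "percentile")
})

test_that("combined flags mark the intersection of both top deciles", {
    set.seed(9)
    n <- 50
    shoot <- runif(n); root <- runif(n)
    # plant 5 accessions that are top-decile (top 5) in both indices
    both <- 1:5
    shoot[both] <- 2 + runif(5); root[both] <- 2 + runif(5)
    sc <- EfficiencyScores(data.frame(
        accession = sprintf("a%02d", 1:n), bei_shoot = shoot,
        bei_root = root))
    out <- scoreTable(classifyAccessions(sc, cfg = pipelineConfig()))
    expect_equal(sum(out$combined_tolerant), 5)
    expect_identical(which(out$combined_tolerant), both)
    # combined flags are subsets of the single-index extreme sets
    expect_true(all(out$class[out$combined_tolerant] == "B-efficient"))
    expect_true(all(out$class[out$combined_sensitive] ==
                    "highly-B-deficiency-sensitive"))
})

test_that("highly-tolerant flags need maintained FW and DW", {
    sc <- EfficiencyScores(data.frame(
        accession = sprintf("a%02d", 1:10),
        bei_shoot = seq(1, 0.1, length.out = 10)))
    ratios <- data.frame(
        accession = rep(sprintf("a%02d", 1:10), 2),
        feature = rep(c("FW", "DW"), each = 10),
        ratio = c(0.9, rep(0.5, 9), 0.85, rep(0.5, 9)))
    out <- scoreTable(classifyAccessions(sc, ratios, pipelineConfig()))
    expect_identical(which(out$highly_tolerant), 1L)
})

test_that("normality check flags skew and validates input", {
    exact <- qnorm(ppoints(50))
    expect_gt(normalityCheck(exact)$p, 0.5)
    set.seed(12)
    skewed <- rexp(185)
    res <- normalityCheck(skewed)
    expect_lt(res$p, 0.001)
    expect_gt(res$skewness, 0)
    expect_error(normalityCheck(rep(1, 10)), "variance")
    expect_error(normalityCheck(c(1, 2)), "3 <= n")
})

test_that("shoot content is concentration times dry weight", {
    expect_equal(shootContent(15.53, 2.35), 36.4955, tolerance = 1e-6)
    expect_equal(shootContent(10, 0), 0)
    expect_equal(shootContent(8.13, 12.29), 99.9177, tolerance = 1e-6)
    expect_error(shootContent(-1, 5), "non-negative")
})

test_that("group contrasts report fold and Welch p", {
    same <- groupContrast(c(1, 2, 1, 2), c("A", "A", "B", "B"))
    expect_equal(same$fold, 1)
    expect_equal(same$p, 1)
    gc <- groupContrast(c(4, 6, 1, 1), c("A", "A", "B", "B"))
    expect_equal(gc$fold, 5)
    flipped <- groupContrast(c(4, 6, 1, 1),
                             factor(c("A", "A", "B", "B"),
                                    levels = c("B", "A")))
    expect_equal(flipped$fold, 1 / gc$fold)
    expect_equal(flipped$p, gc$p)
    expect_error(groupContrast(c(1, 2, 3), c("A", "A", "B")), ">= 2")
})
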