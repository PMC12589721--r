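test_that("MAF filtering keeps the boundary and drops monomorphics", {
    calls <- rbind(c(rep(0L, 19), 1L),       # MAF 0.05, boundary
                   rep(0L, 20),              # monomorphic
                   c(rep(0L, 10), rep(1L, 10)))
    colnames(calls) <- sprintf("a%02d", 1:20)
    geno <- makeGeno(calls)
    kept <- mafFilter(geno, 0.05)
    expect_equal(nrow(genoCalls(kept)), 2)
    expect_true(markerMap(geno)$marker[1] %in% markerMap(kept)$marker)
    zero <- mafFilter(geno, 0)
    expect_equal(nrow(genoCalls(zero)), 2)   # only monomorphic removed
})

test_that("the scan matches the closed-form regression oracle", {
    set.seed(15)
    n <- 30
    calls <- matrix(sample(c(0L, 1L, NA), n * 8, replace = TRUE,
                           prob = c(0.5, 0.4, 0.1)), 8, n)
    colnames(calls) <- sprintf("a%02d", 1:n)
    geno <- makeGeno(calls)
    y <- setNames(rnorm(n) + 0.5 * ifelse(is.na(calls[3, ]), 0,
                                          calls[3, ]), colnames(calls))
    res <- markerScan(y, geno, trait = "y")
    for (i in seq_len(nrow(res))) {
        g <- calls[match(res$marker[i], markerMap(geno)$marker), ]
        fit <- summary(lm(y ~ g))$coefficients
        expect_equal(res$beta[i], fit["g", "Estimate"],
                     tolerance = 1e-10)
        expect_equal(res$se[i], fit["g", "Std. Error"],
                     tolerance = 1e-10)
        expect_equal(res$p[i], fit["g", "Pr(>|t|)"], tolerance = 1e-10)
    }
})

test_that("a perfect association is detected with the exact slope", {
    calls <- matrix(rep(c(0L, 1L), 6), 1, 12)
    colnames(calls) <- sprintf("a%02d", 1:12)
    y <- setNames(2 * calls[1, ], colnames(calls))
    res <- markerScan(y, makeGeno(calls), trait = "y")
    expect_equal(res$beta, 2)
    expect_lt(res$p, 1e-8)
})

test_that("invariant markers are omitted with a warning", {
    calls <- rbind(rep(0L, 12), rep(c(0L, 1L), 6))
    colnames(calls) <- sprintf("a%02d", 1:12)
    y <- setNames(rnorm(12), colnames(calls))
    expect_warning(res <- markerScan(y, makeGeno(calls), trait = "y"),
                   "omitted")
    expect_equal(nrow(res), 1)
})

test_that("Bonferroni thresholds scale with the marker count", {
    b <- bonferroniThreshold(1000)
    expect_equal(b$p_threshold, 5e-5)
    expect_equal(b$neglog10, 4.301, tolerance = 1e-3)
    expect_equal(bonferroniThreshold(1)$p_threshold, 0.05)
    expect_equal(bonferroniThreshold(2000)$p_threshold,
                 bonferroniThreshold(1000)$p_threshold / 2)
    expect_error(bonferroniThreshold(0), ">= 1")
})

test_that("QTL windows pad, clip and clump correctly", {
    assoc <- data.frame(
        marker = c("M4_15415403", "M4_16107011", "M4_15700000",
                   "M1_00001000", "M1_05000000"),
        chrom = c("4", "4", "4", "1", "1"),
        pos = c(15415403L, 16107011L, 15700000L, 1000L, 5000000L),
        trait = "bei", beta = 1, se = 0.1,
        p = c(1e-5, 1e-6, 1e-4, 1e-5, 1e-7),
        neglog10p = c(5, 6, 4, 5, 7), n = 185L)
    w <- qtlWindows(assoc, min_neglogp = 4, padding_bp = 3365,
                    clump_gap_bp = 1e6)
    df <- as.data.frame(w)
    chr4 <- df[df$seqnames == "4", ]
    expect_equal(chr4$start, 15412038)
    expect_equal(chr4$end, 16110376)
    expect_equal(chr4$lead_marker, "M4_16107011")
    # far-apart qualifying markers clump separately
    chr1 <- df[df$seqnames == "1", ]
    expect_equal(nrow(chr1), 2)
    expect_equal(chr1$start[1], 1)               # clipped at position 1
    expect_equal(chr1$end[1], 1000 + 3365)
    # single qualifying marker spans +/- padding
    single <- qtlWindows(assoc[5, ], padding_bp = 3365)
    expect_equal(as.data.frame(single)$start, 5000000 - 3365)
    expect_equal(as.data.frame(single)$end, 5000000 + 3365)
    # member positions lie inside the unpadded core (unless clipped)
    for (i in seq_len(nrow(df))) {
        memb <- strsplit(df$members[i], ",")[[1]]
        pos <- assoc$pos[match(memb, assoc$marker)]
        if (df$start[i] > 1)
            expect_true(all(pos >= df$start[i] + 3365 - 1e-9))
        expect_true(all(pos <= df$end[i] - 3365 + 1e-9))
    }
    # windows on one chromosome never overlap after clumping
    expect_true(all(chr1$start[-1] > chr1$end[-nrow(chr1)]))
    expect_equal(length(qtlWindows(assoc[assoc$neglog10p < 4, ])), 0)
})

test_that("efficiency alleles go to the higher-mean group", {
    calls <- rbind(c(rep(0L, 6), rep(1L, 6)),
                   rep(c(0L, 1L), 6))
    colnames(calls) <- sprintf("a%02d", 1:12)
    geno <- makeGeno(calls)
    bei <- setNames(c(rep(0.192, 6), rep(0.276, 6)), colnames(calls))
    led <- efficiencyAlleles(markerMap(geno)$marker[1], geno, bei)
    expect_equal(led$efficiency_allele, 1L)
    expect_equal(led$mean_bei_eff, 0.276)
    expect_equal(led$mean_bei_other, 0.192)
    expect_equal(led$prevalence_pct, 50)
    expect_false(led$tie)
    expect_true(led$mean_bei_eff >= led$mean_bei_other)

    tied <- setNames(rep(c(0.1, 0.1), 6), colnames(calls))
    led2 <- efficiencyAlleles(markerMap(geno)$marker[2], geno, tied)
    expect_true(led2$tie)
    expect_equal(led2$efficiency_allele, 0L)
})

test_that("per-accession efficiency-allele counts match a hand tally", {
    calls <- rbind(c(1L, 0L, 1L, NA, 0L),
                   c(1L, 1L, 0L, 0L, 0L),
                   c(0L, 1L, 1L, 1L, 0L))
    colnames(calls) <- paste0("a", 1:5)
    geno <- makeGeno(calls)
    ledger <- data.frame(marker = markerMap(geno)$marker,
                         efficiency_allele = c(1L, 0L, 1L))
    counts <- countEfficiencyAlleles(ledger, geno)
    expect_identical(unname(counts), c(1L, 1L, 3L, 2L, 1L))
    empty <- countEfficiencyAlleles(ledger[0, ], geno)
    expect_identical(unname(empty), rep(0L, 5))
})

test_that("allelic ANOVA matches t-squared and hand values", {
    y <- c(1, 2, 3, 7, 8, 9)
    g <- rep(c(0, 1), each = 3)
    res <- allelicAnova(y, g)
    expect_equal(res$F, 54)
    expect_lt(res$p, 0.01)
    expect_equal(res$stars, "*")   # p = 0.0018, between 0.001 and 0.05
    tt <- t.test(y[g == 0], y[g == 1], var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    flat <- allelicAnova(c(1, 2, 1, 2), c(0, 0, 1, 1))
    expect_equal(flat$F, 0)
    expect_equal(flat$p, 1)
    expect_error(allelicAnova(c(1, 2, 3), c(0, 0, 1)), ">= 2")
})

test_that("haplotype contrasts report percent difference vs reference", {
    hap <- data.frame(gene = "BORX",
                      haplotype = rep(c("a", "j"), c(5, 4)),
                      accession = paste0("a", 1:9))
    sc <- EfficiencyScores(data.frame(
        accession = paste0("a", 1:9),
        bei_shoot = c(rep(0.200, 5), rep(0.462, 4)),
        bei_root = c(rep(0.2, 5), rep(0.43, 4))))
    hc <- haplotypeContrast(hap, sc)
    expect_equal(hc$pct_diff_shoot[hc$haplotype == "a"], 0)
    expect_equal(hc$pct_diff_shoot[hc$haplotype == "j"], 131)
    expect_false(any(hc$low_confidence))
    # antisymmetry: swapping the means flips the sign
    sc2 <- EfficiencyScores(data.frame(
        accession = paste0("a", 1:9),
        bei_shoot = c(rep(0.462, 5), rep(0.200, 4))))
    hc2 <- haplotypeContrast(hap, sc2)
    expect_lt(hc2$pct_diff_shoot[hc2$haplotype == "j"], 0)
    # small groups are flagged
    hap3 <- data.frame(gene = "G", haplotype = c("a", "a", "a", "b"),
                       accession = paste0("a", 1:4))
    hc3 <- haplotypeContrast(hap3, sc)
    expect_true(hc3$low_confidence[hc3$haplotype == "b"])
})
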