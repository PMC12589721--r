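#' Filter markers by minor allele frequency
#'
#' Retains markers with MAF at or above the cutoff, computed over
#' non-missing calls; monomorphic markers are always removed.
#'
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param cutoff MAF cutoff in [0, 0.5] (default 0.05).
#' @return Filtered \linkS4class{GenotypeMatrix}.
#' @export
mafFilter <- function(geno, cutoff = 0.05) {
    stopifnot(cutoff >= 0, cutoff <= 0.5)
    maf <- markerMAF(geno)
    keep <- !is.na(maf) & maf > 0 & maf >= cutoff
    GenotypeMatrix(genoCalls(geno)[keep, , drop = FALSE],
                   markerMap(geno)[keep, , drop = FALSE])
}

#' Single-marker association scan
#'
#' Per marker, ordinary least squares of the trait on the 0/1 allele code
#' with an intercept, with a two-sided t-test on the slope. Accessions
#' missing the trait or the marker call are dropped marker-wise. This is
#' a deliberately simple single-locus scan without kinship or structure
#' correction; multi-locus mixed-model methods (e.g. FarmCPU) are not
#' re-implemented here, and downstream window/ledger rules are
#' scan-agnostic.
#'
#' @param y named numeric vector of per-accession trait values.
#' @param geno A \linkS4class{GenotypeMatrix}; columns matched to
#'   `names(y)`.
#' @param trait trait name recorded in the result.
#' @param min_n minimum accessions with both trait and call (default 10).
#' @return data.frame with `marker`, `chrom`, `pos`, `trait`, `beta`,
#'   `se`, `p`, `neglog10p`, `n`. Markers with zero genotype variance
#'   after NA removal are omitted with a warning.
#' @export
markerScan <- function(y, geno, trait = "trait", min_n = 10L) {
    g <- genoCalls(geno)
    common <- intersect(colnames(g), names(y))
    if (length(common) < min_n)
        stop("fewer than ", min_n, " accessions with trait and genotypes")
    g <- g[, common, drop = FALSE]
    yv <- y[common]
    G <- t(g)                                  # accessions x markers
    M <- (!is.na(G) & !is.na(yv)) * 1
    Gz <- G; Gz[is.na(Gz)] <- 0L
    yz <- ifelse(is.na(yv), 0, yv)
    n <- colSums(M)
    Sx <- colSums(Gz * M)
    Sy <- colSums(yz * M)
    Sxx <- colSums(Gz * Gz * M)
    Sxy <- colSums(Gz * yz * M)
    Syy <- colSums(yz * yz * M)
    vx <- Sxx - Sx^2 / n
    beta <- (Sxy - Sx * Sy / n) / vx
    sse <- pmax(Syy - Sy^2 / n - beta^2 * vx, 0)
    df <- n - 2
    se <- sqrt(sse / df / vx)
    tstat <- beta / se
    p <- 2 * pt(-abs(tstat), df)
    ok <- n >= min_n & vx > 0
    if (any(!ok))
        warning(sum(!ok), " marker(s) omitted (zero genotype variance or ",
                "too few complete accessions)", call. = FALSE)
    map <- markerMap(geno)
    out <- data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
                      trait = trait, beta = beta, se = se, p = p,
                      neglog10p = -log10(p), n = as.integer(n),
                      stringsAsFactors = FALSE)
    out[ok, , drop = FALSE]
}

#' Bonferroni significance threshold
#'
#' @param m number of tested markers.
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `p_threshold` = alpha/m and `neglog10` =
#'   log10(m/alpha), the Manhattan-plot line.
#' @export
bonferroniThreshold <- function(m, alpha = 0.05) {
    if (m < 1) stop("m must be >= 1")
    list(p_threshold = alpha / m, neglog10 = log10(m / alpha))
}

#' Define QTL windows from an association scan
#'
#' Per chromosome, markers reaching `min_neglogp` are grouped into clumps
#' in which consecutive qualifying markers are at most `clump_gap_bp`
#' apart; each clump becomes a window spanning its outermost qualifying
#' markers padded by `padding_bp` on each side (half the LD decay
#' distance), clipped at position 1. The lead marker is the clump maximum
#' of -log10 p, ties broken by smaller position.
#'
#' @param assoc scan results from \code{\link{markerScan}}.
#' @param min_neglogp -log10 p needed to qualify (default 4.0).
#' @param padding_bp window padding in bp (default 3365).
#' @param clump_gap_bp maximum within-clump gap in bp (default 1e6).
#' @return A `GRanges` (possibly empty) with metadata columns
#'   `n_markers`, `lead_marker`, `lead_neglog10p`, `members`
#'   (comma-separated marker ids).
#' @export
qtlWindows <- function(assoc, min_neglogp = 4.0, padding_bp = 3365,
                       clump_gap_bp = 1e6) {
    sel <- assoc[!is.na(assoc$neglog10p) &
                 assoc$neglog10p >= min_neglogp, , drop = FALSE]
    empty <- GenomicRanges::GRanges(
        seqnames = character(0),
        ranges = IRanges::IRanges(start = integer(0), end = integer(0)),
        n_markers = integer(0), lead_marker = character(0),
        lead_neglog10p = numeric(0), members = character(0))
    if (!nrow(sel)) return(empty)
    rows <- list()
    for (chr in unique(sel$chrom)) {
        sc <- sel[sel$chrom == chr, , drop = FALSE]
        sc <- sc[order(sc$pos), , drop = FALSE]
        clump <- cumsum(c(1, diff(sc$pos) > clump_gap_bp))
        for (cl in unique(clump)) {
            cc <- sc[clump == cl, , drop = FALSE]
            lead <- cc[order(-cc$neglog10p, cc$pos)[1], ]
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = chr,
                start = max(1, min(cc$pos) - padding_bp),
                end = max(cc$pos) + padding_bp,
                n_markers = nrow(cc),
                lead_marker = lead$marker,
                lead_neglog10p = lead$neglog10p,
                members = paste(cc$marker, collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    df <- do.call(rbind, rows)
    GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start, end = df$end),
        n_markers = df$n_markers, lead_marker = df$lead_marker,
        lead_neglog10p = df$lead_neglog10p, members = df$members)
}

#' Designate efficiency alleles at significant markers
#'
#' At each marker, accessions are grouped by allele and the allele whose
#' carriers have the higher mean BEI_shoot is designated the efficiency
#' allele; a tie designates the reference (0) allele and sets the tie
#' flag. Prevalence is the percentage of non-missing accessions carrying
#' the efficiency allele.
#'
#' @param markers marker ids to report.
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param scores named numeric vector of BEI_shoot per accession.
#' @param trait label(s) recorded in the `associated_trait` column.
#' @return data.frame ledger: `marker`, `associated_trait`,
#'   `efficiency_allele` (0/1 code), `prevalence_pct`, `mean_bei_eff`,
#'   `sd_bei_eff`, `mean_bei_other`, `sd_bei_other`, `tie`.
#' @export
efficiencyAlleles <- function(markers, geno, scores, trait = "bei_shoot") {
    g <- genoCalls(geno)
    common <- intersect(colnames(g), names(scores))
    g <- g[, common, drop = FALSE]
    s <- scores[common]
    trait <- rep_len(trait, length(markers))
    rows <- lapply(seq_along(markers), function(i) {
        mk <- markers[i]
        if (!mk %in% rownames(g)) stop("unknown marker: ", mk)
        a <- g[mk, ]
        ok <- !is.na(a) & !is.na(s)
        if (length(unique(a[ok])) < 2)
            stop("both alleles must be present at ", mk)
        m0 <- mean(s[ok & a == 0L]); m1 <- mean(s[ok & a == 1L])
        s0 <- sd(s[ok & a == 0L]); s1 <- sd(s[ok & a == 1L])
        tie <- m0 == m1
        eff <- if (m1 > m0) 1L else 0L
        data.frame(marker = mk, associated_trait = trait[i],
                   efficiency_allele = eff,
                   prevalence_pct = 100 * mean(a[ok] == eff),
                   mean_bei_eff = if (eff == 1L) m1 else m0,
                   sd_bei_eff = if (eff == 1L) s1 else s0,
                   mean_bei_other = if (eff == 1L) m0 else m1,
                   sd_bei_other = if (eff == 1L) s0 else s1,
                   tie = tie, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Count efficiency alleles per accession
#'
#' Number of ledger markers at which each accession carries the
#' designated efficiency allele; missing genotypes do not count.
#'
#' @param ledger output of \code{\link{efficiencyAlleles}} (may have zero
#'   rows).
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @return Named integer vector per accession.
#' @export
countEfficiencyAlleles <- function(ledger, geno) {
    g <- genoCalls(geno)
    counts <- setNames(integer(ncol(g)), colnames(g))
    for (i in seq_len(nrow(ledger))) {
        a <- g[ledger$marker[i], ]
        hit <- !is.na(a) & a == ledger$efficiency_allele[i]
        counts[hit] <- counts[hit] + 1L
    }
    counts
}

#' One-way ANOVA of a trait by allele
#'
#' @param values numeric trait values.
#' @param alleles allele codes parallel to `values`; each group must have
#'   at least two members after NA removal.
#' @return list with `F`, `p` and `stars` (significance at 0.05, 0.001
#'   and 0.0001).
#' @export
allelicAnova <- function(values, alleles) {
    ok <- !is.na(values) & !is.na(alleles)
    v <- values[ok]
    gr <- factor(alleles[ok])
    if (nlevels(gr) < 2) stop("need >= 2 allele groups")
    if (any(table(gr) < 2)) stop("each allele group needs >= 2 members")
    fit <- anova(lm(v ~ gr))
    f <- fit$`F value`[1]
    p <- fit$`Pr(>F)`[1]
    stars <- if (is.na(p)) "" else if (p < 1e-4) "****" else
        if (p < 1e-3) "***" else if (p < 0.05) "*" else ""
    list(F = f, p = p, stars = stars)
}

#' Protein-haplotype contrasts of BEI scores
#'
#' Per gene and haplotype: mean BEI_shoot and BEI_root of the member
#' accessions and the percentage difference of the BEI_shoot mean versus
#' the reference haplotype (`100 * (mean_h - mean_ref) / mean_ref`).
#' Groups with fewer than three members are flagged low-confidence.
#'
#' @param haplotypes data.frame with columns `gene`, `haplotype`,
#'   `accession`.
#' @param scores An \linkS4class{EfficiencyScores} (or its table).
#' @param reference optional named character vector gene -> reference
#'   haplotype label; defaults to the lexicographically smallest label
#'   per gene.
#' @return data.frame `gene`, `haplotype`, `n`, `mean_bei_shoot`,
#'   `mean_bei_root`, `pct_diff_shoot`, `pct_diff_root`,
#'   `low_confidence`.
#' @export
haplotypeContrast <- function(haplotypes, scores, reference = NULL) {
    if (is(scores, "EfficiencyScores")) scores <- scoreTable(scores)
    need <- c("gene", "haplotype", "accession")
    miss <- setdiff(need, names(haplotypes))
    if (length(miss))
        stop("haplotype table lacks column(s): ",
             paste(miss, collapse = ", "))
    rows <- list()
    for (gene in unique(haplotypes$gene)) {
        hg <- haplotypes[haplotypes$gene == gene, ]
        ref <- if (!is.null(reference) && gene %in% names(reference))
            reference[[gene]] else min(hg$haplotype)
        if (!ref %in% hg$haplotype)
            stop("reference haplotype ", ref, " absent for gene ", gene)
        stat <- function(h) {
            acc <- hg$accession[hg$haplotype == h]
            i <- match(acc, scores$accession)
            list(n = sum(!is.na(i)),
                 shoot = mean(scores$bei_shoot[i], na.rm = TRUE),
                 root = mean(scores$bei_root[i], na.rm = TRUE))
        }
        rs <- stat(ref)
        pct <- function(m, mref)
            if (is.na(mref) || mref == 0) NA_real_ else 100 * (m - mref) / mref
        for (h in sort(unique(hg$haplotype))) {
            st <- stat(h)
            rows[[length(rows) + 1L]] <- data.frame(
                gene = gene, haplotype = h, n = st$n,
                mean_bei_shoot = st$shoot, mean_bei_root = st$root,
                pct_diff_shoot = pct(st$shoot, rs$shoot),
                pct_diff_root = pct(st$root, rs$root),
                low_confidence = st$n < 3, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}
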