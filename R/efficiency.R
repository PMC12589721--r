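combineRatios <- function(a, b, form) {
    switch(form,
           product = a * b,
           geometric = sqrt(a * b),
           arithmetic = (a + b) / 2)
}

#' Shoot boron-efficiency index
#'
#' Composite of the deficiency:sufficiency ratios of shoot fresh weight at
#' harvest and projected leaf area on the last imaging day. The default
#' form is the product of the two ratios, so an accession that fully
#' maintains both traits scores 1 and an accession that gains under
#' deficiency can exceed 1.
#'
#' @param fw_ratio deficient/sufficient shoot FW ratio.
#' @param pla16_ratio deficient/sufficient PLA ratio at day 16.
#' @param form `"product"` (default), `"geometric"` or `"arithmetic"`.
#' @return BEI_shoot (dimensionless, >= 0; `NA` when a ratio is `NA`).
#' @export
beiShoot <- function(fw_ratio, pla16_ratio, form = "product") {
    stopifnot(all(fw_ratio >= 0, na.rm = TRUE),
              all(pla16_ratio >= 0, na.rm = TRUE))
    combineRatios(fw_ratio, pla16_ratio, form)
}

#' Root boron-efficiency index
#'
#' Same composite form as \code{\link{beiShoot}}, applied to the primary
#' root length and total lateral root length ratios.
#'
#' @param prl_ratio deficient/sufficient primary root length ratio.
#' @param tlrl_ratio deficient/sufficient total lateral root length ratio.
#' @param form `"product"` (default), `"geometric"` or `"arithmetic"`.
#' @return BEI_root (dimensionless, >= 0; `NA` when a ratio is `NA`).
#' @export
beiRoot <- function(prl_ratio, tlrl_ratio, form = "product") {
    stopifnot(all(prl_ratio >= 0, na.rm = TRUE),
              all(tlrl_ratio >= 0, na.rm = TRUE))
    combineRatios(prl_ratio, tlrl_ratio, form)
}

#' Classify accessions by BEI_shoot percentile rank
#'
#' Rank-based classification: accessions are ranked by BEI_shoot
#' descending (ties broken by accession id); the top `ceil(f*N)` become
#' B-efficient and the bottom `ceil(f*N)` highly-B-deficiency-sensitive.
#' Among the remainder, BEI_shoot above the intermediate threshold gives
#' B-intermediate-efficient, the rest B-inefficient. The highly-tolerant
#' flag marks B-efficient accessions that additionally maintained both the
#' FW and DW ratio above the maintenance threshold; the combined flags
#' mark accessions in the top (bottom) `ceil(f*N)` of both BEI_shoot and
#' BEI_root.
#'
#' @param es An \linkS4class{EfficiencyScores} with `bei_shoot` (and
#'   optionally `bei_root`) filled in.
#' @param ratios response-feature table from \code{\link{traitRatios}} /
#'   \code{\link{responseFeatures}} (used for the FW/DW maintenance flag);
#'   may be `NULL`.
#' @param cfg a \code{\link{pipelineConfig}} (percentile fraction,
#'   intermediate threshold, maintenance threshold).
#' @return The completed \linkS4class{EfficiencyScores}.
#' @export
classifyAccessions <- function(es, ratios = NULL, cfg = pipelineConfig()) {
    sc <- scoreTable(es)
    n <- nrow(sc)
    f <- cfg$percentile
    if (n < 1 / f)
        stop(sprintf("percentile fraction %g undefined for %d accessions",
                     f, n))
    if (anyNA(sc$bei_shoot))
        stop("bei_shoot must be present for all accessions")
    ntail <- ceiling(f * n)
    o <- order(-sc$bei_shoot, sc$accession)
    cls <- rep("B-inefficient", n)
    top <- o[seq_len(ntail)]
    bottom <- o[seq.int(n - ntail + 1L, n)]
    cls[top] <- "B-efficient"
    cls[bottom] <- "highly-B-deficiency-sensitive"
    mid <- setdiff(seq_len(n), c(top, bottom))
    cls[mid][sc$bei_shoot[mid] > cfg$intermediate] <-
        "B-intermediate-efficient"
    sc$class <- cls

    sc$highly_tolerant <- FALSE
    if (!is.null(ratios)) {
        fw <- ratios$ratio[match(paste(sc$accession, "FW"),
                                 paste(ratios$accession, ratios$feature))]
        dw <- ratios$ratio[match(paste(sc$accession, "DW"),
                                 paste(ratios$accession, ratios$feature))]
        sc$highly_tolerant <- cls == "B-efficient" &
            !is.na(fw) & fw > cfg$maintenance &
            !is.na(dw) & dw > cfg$maintenance
    }
    sc$combined_tolerant <- sc$combined_sensitive <- FALSE
    if (!all(is.na(sc$bei_root))) {
        or_ <- order(-sc$bei_root, sc$accession)
        rtop <- or_[seq_len(ntail)]
        rbottom <- or_[seq.int(n - ntail + 1L, n)]
        sc$combined_tolerant[intersect(top, rtop)] <- TRUE
        sc$combined_sensitive[intersect(bottom, rbottom)] <- TRUE
    }
    EfficiencyScores(sc)
}

#' Compute BEI indices and classification from a feature table
#'
#' Convenience wrapper: extracts the FW, day-16 PLA, PRL and TLRL ratios
#' per accession, forms BEI_shoot and BEI_root and classifies the panel.
#'
#' @param features response-feature table (\code{\link{responseFeatures}}).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return An \linkS4class{EfficiencyScores}.
#' @export
efficiencyScores <- function(features, cfg = pipelineConfig()) {
    accs <- sort(unique(features$accession))
    get <- function(feat) features$ratio[match(paste(accs, feat),
        paste(features$accession, features$feature))]
    sc <- data.frame(accession = accs,
                     bei_shoot = beiShoot(get("FW"), get("PLA_d16"),
                                          cfg$bei_form),
                     bei_root = beiRoot(get("PRL"), get("TLRL"),
                                        cfg$bei_form),
                     stringsAsFactors = FALSE)
    classifyAccessions(EfficiencyScores(sc), features, cfg)
}

#' Shapiro-Wilk normality check with sample skewness
#'
#' @param values numeric score vector, 3 <= n <= 5000 after NA removal.
#' @return list with `W`, `p` and `skewness` (g1, bias-uncorrected).
#' @export
normalityCheck <- function(values) {
    values <- values[!is.na(values)]
    n <- length(values)
    if (n < 3 || n > 5000)
        stop("Shapiro-Wilk requires 3 <= n <= 5000")
    if (sd(values) == 0) stop("zero variance")
    sw <- shapiro.test(values)
    m <- mean(values)
    g1 <- mean((values - m)^3) / (mean((values - m)^2)^1.5)
    list(W = unname(sw$statistic), p = sw$p.value, skewness = g1)
}

#' Shoot element content from concentration and dry weight
#'
#' `content = concentration x DW`; a concentration in mg per kg DW is
#' numerically an amount in ng per mg DW, so the product of mg kg^-1 and
#' mg is in ng.
#'
#' @param concentration element concentration, mg kg^-1 DW.
#' @param dw shoot dry weight, mg.
#' @return Content in ng.
#' @export
shootContent <- function(concentration, dw) {
    if (any(concentration < 0, na.rm = TRUE) || any(dw < 0, na.rm = TRUE))
        stop("concentration and dry weight must be non-negative")
    concentration * dw
}

#' Two-group fold difference with Welch t-test
#'
#' @param values numeric per-accession metric.
#' @param groups factor/character of two group labels parallel to
#'   `values`; the fold is mean(first level) / mean(second level).
#' @return list with `fold`, `p` (two-sided Welch), `levels`.
#' @export
groupContrast <- function(values, groups) {
    groups <- as.factor(groups)
    if (nlevels(groups) != 2) stop("exactly two groups required")
    a <- values[groups == levels(groups)[1]]
    b <- values[groups == levels(groups)[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2)
        stop("need >= 2 accessions per group")
    fold <- if (mean(b) == 0) NA_real_ else mean(a) / mean(b)
    p <- if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) 1
         else t.test(a, b, var.equal = FALSE)$p.value
    list(fold = fold, p = p, levels = levels(groups))
}
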