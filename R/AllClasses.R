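#' @import methods
#' @importFrom stats aggregate anova as.dist coef complete.cases cor cor.test ks.test
#'   lm median na.omit p.adjust phyper plogis pnorm pt quantile rbinom rlnorm
#'   rnorm runif sd setNames shapiro.test t.test var
#' @importFrom utils read.delim write.table
NULL

TREATMENTS <- c("deficient", "sufficient")

## long replicated trait table: one row per
## (accession, treatment, day-or-endpoint, replicate, trait) measurement

#' TraitMatrix: replicated accession x treatment trait measurements
#'
#' Long-format container of replicated trait measurements across two boron
#' treatments. Daily imaging traits (e.g. projected leaf area, PLA) carry an
#' integer day; endpoint traits (FW/DW at harvest, root system traits) carry
#' `NA` in the day column. Values are non-negative in trait units (PLA mm^2,
#' FW/DW mg, root lengths cm, counts dimensionless).
#'
#' @slot records data.frame with columns `accession`, `treatment`
#'   (`"deficient"` or `"sufficient"`), `day` (integer or `NA`),
#'   `replicate`, `trait`, `value`.
#' @export
setClass("TraitMatrix", slots = c(records = "data.frame"))

setValidity("TraitMatrix", function(object) {
    rec <- object@records
    need <- c("accession", "treatment", "day", "replicate", "trait", "value")
    miss <- setdiff(need, names(rec))
    if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
    if (!all(rec$treatment %in% TREATMENTS))
        return(sprintf("unknown treatment value(s): %s",
                       paste(unique(setdiff(rec$treatment, TREATMENTS)),
                             collapse = ", ")))
    if (!is.numeric(rec$value))
        return("'value' must be numeric")
    if (any(rec$value < 0, na.rm = TRUE))
        return("trait values must be non-negative")
    key <- paste(rec$accession, rec$treatment, rec$day, rec$replicate,
                 rec$trait, sep = "\r")
    if (anyDuplicated(key))
        return("duplicate (accession, treatment, day, replicate, trait) records")
    TRUE
})

#' Construct a TraitMatrix
#'
#' @param records data.frame of replicated measurements (see
#'   \linkS4class{TraitMatrix}).
#' @return A \linkS4class{TraitMatrix}.
#' @export
TraitMatrix <- function(records) {
    records$accession <- as.character(records$accession)
    records$treatment <- as.character(records$treatment)
    records$trait <- as.character(records$trait)
    records$day <- as.integer(records$day)
    records$value <- as.numeric(records$value)
    new("TraitMatrix", records = as.data.frame(records,
                                               stringsAsFactors = FALSE))
}

#' @describeIn TraitMatrix access the long record table
#' @param tm A `TraitMatrix`.
#' @export
traitRecords <- function(tm) tm@records

setMethod("show", "TraitMatrix", function(object) {
    rec <- object@records
    cat("TraitMatrix:", nrow(rec), "records,",
        length(unique(rec$accession)), "accessions,",
        length(unique(rec$trait)), "traits\n")
})

## biallelic genotype matrix, markers x accessions, VCF orientation

#' GenotypeMatrix: biallelic accession genotypes with a marker map
#'
#' Markers are rows (sorted by chromosome then 1-based position), accessions
#' are columns; calls are 0 (reference), 1 (alternative) or `NA`. The panel
#' is assumed to consist of homozygous inbred lines, so a single haploid
#' code per accession suffices.
#'
#' @slot calls integer matrix (markers x accessions) of 0/1/NA calls, with
#'   marker ids as row names and accession ids as column names.
#' @slot map data.frame with columns `marker`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, parallel to the rows of `calls`.
#' @export
setClass("GenotypeMatrix", slots = c(calls = "matrix", map = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
    g <- object@calls
    map <- object@map
    need <- c("marker", "chrom", "pos", "ref", "alt")
    miss <- setdiff(need, names(map))
    if (length(miss))
        return(paste("map lacks column(s):", paste(miss, collapse = ", ")))
    if (nrow(map) != nrow(g))
        return("map rows must parallel call matrix rows")
    if (!all(g %in% c(0L, 1L, NA_integer_)))
        return("calls must be 0, 1 or NA")
    if (any(map$pos < 1))
        return("positions must be 1-based (>= 1)")
    key <- paste(map$chrom, map$pos)
    if (anyDuplicated(key))
        return("duplicate (chrom, pos) markers")
    o <- order(map$chrom, map$pos)
    if (!identical(o, seq_len(nrow(map))))
        return("markers must be sorted by (chrom, pos)")
    TRUE
})

#' Construct a GenotypeMatrix
#'
#' Rows are reordered so markers are sorted by (chromosome, position).
#'
#' @param calls integer matrix, markers x accessions, values 0/1/NA.
#' @param map data.frame with `marker`, `chrom`, `pos`, `ref`, `alt`.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(calls, map) {
    mode(calls) <- "integer"
    map$marker <- as.character(map$marker)
    map$chrom <- as.character(map$chrom)
    map$pos <- as.integer(map$pos)
    o <- order(map$chrom, map$pos)
    map <- map[o, , drop = FALSE]
    calls <- calls[o, , drop = FALSE]
    rownames(map) <- NULL
    rownames(calls) <- map$marker
    new("GenotypeMatrix", calls = calls, map = map)
}

#' @describeIn GenotypeMatrix the markers x accessions call matrix
#' @param geno A `GenotypeMatrix`.
#' @export
genoCalls <- function(geno) geno@calls

#' @describeIn GenotypeMatrix the marker map (marker, chrom, pos, ref, alt)
#' @export
markerMap <- function(geno) geno@map

#' @describeIn GenotypeMatrix accession ids (column names)
#' @export
accessionNames <- function(geno) colnames(geno@calls)

#' Per-marker minor allele frequency
#'
#' Computed over non-missing calls; `NaN` for markers with no calls.
#'
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @return Named numeric vector of MAF in [0, 0.5].
#' @export
markerMAF <- function(geno) {
    f <- rowMeans(geno@calls, na.rm = TRUE)
    setNames(pmin(f, 1 - f), geno@map$marker)
}

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix:", nrow(object@calls), "markers x",
        ncol(object@calls), "accessions on",
        length(unique(object@map$chrom)), "chromosome(s)\n")
})

#' EfficiencyScores: per-accession B-efficiency indices and classes
#'
#' Holds the composite shoot and root boron-efficiency indices together with
#' the four-way shoot classification and tolerance flags.
#'
#' @slot scores data.frame with columns `accession`, `bei_shoot`,
#'   `bei_root`, `class`, `highly_tolerant`, `combined_tolerant`,
#'   `combined_sensitive`.
#' @export
setClass("EfficiencyScores", slots = c(scores = "data.frame"))

EFFICIENCY_CLASSES <- c("B-efficient", "B-intermediate-efficient",
                        "B-inefficient", "highly-B-deficiency-sensitive")

setValidity("EfficiencyScores", function(object) {
    sc <- object@scores
    need <- c("accession", "bei_shoot", "bei_root", "class",
              "highly_tolerant", "combined_tolerant", "combined_sensitive")
    miss <- setdiff(need, names(sc))
    if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
    if (anyDuplicated(sc$accession))
        return("duplicate accession ids")
    if (!all(is.na(sc$class) | sc$class %in% EFFICIENCY_CLASSES))
        return("invalid class label")
    TRUE
})

#' Construct EfficiencyScores
#'
#' @param scores data.frame (see \linkS4class{EfficiencyScores}); missing
#'   flag columns are initialised to `FALSE`, missing class to `NA`.
#' @return An \linkS4class{EfficiencyScores} object.
#' @export
EfficiencyScores <- function(scores) {
    if (is.null(scores$bei_root)) scores$bei_root <- NA_real_
    if (is.null(scores$class)) scores$class <- NA_character_
    for (fl in c("highly_tolerant", "combined_tolerant", "combined_sensitive"))
        if (is.null(scores[[fl]])) scores[[fl]] <- FALSE
    scores$accession <- as.character(scores$accession)
    new("EfficiencyScores", scores = as.data.frame(scores,
                                                   stringsAsFactors = FALSE))
}

#' @describeIn EfficiencyScores access the score table
#' @param es An `EfficiencyScores` object.
#' @export
scoreTable <- function(es) es@scores

setMethod("show", "EfficiencyScores", function(object) {
    sc <- object@scores
    cat("EfficiencyScores:", nrow(sc), "accessions\n")
    if (!all(is.na(sc$class))) {
        tab <- table(factor(sc$class, levels = EFFICIENCY_CLASSES))
        for (cl in names(tab)) cat(" ", cl, ":", tab[[cl]], "\n")
    }
})
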