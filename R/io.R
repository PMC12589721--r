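## TSV writer that preserves doubles to full precision (%.17g survives a
## read/parse round trip exactly)
writeTsv <- function(df, path) {
    out <- df
    for (j in seq_along(out)) {
        if (is.double(out[[j]])) {
            v <- sprintf("%.17g", out[[j]])
            v[is.na(out[[j]])] <- "NA"
            out[[j]] <- v
        }
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    invisible(path)
}

parseNumeric <- function(x, what, path) {
    x[x %in% c(".", "NA", "")] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
        stop(sprintf("non-numeric '%s' value in %s at data row %d: '%s'",
                     what, path, bad[1], x[bad[1]]), call. = FALSE)
    v
}

#' Read a replicated trait table
#'
#' Reads a tab-separated table with columns `accession`, `treatment`,
#' `day`, `replicate`, `trait`, `value`. Treatments must be `deficient` /
#' `sufficient` or one of the aliases in `treatment_map`; `day` may be `NA`
#' (or `.`) for endpoint traits; values may be `NA`.
#'
#' @param path path to a TSV file.
#' @param treatment_map named character vector mapping accepted aliases to
#'   canonical treatment names.
#' @return A \linkS4class{TraitMatrix}.
#' @export
readTraitTable <- function(path,
                           treatment_map = c(minus_b = "deficient",
                                             plus_b = "sufficient")) {
    tab <- read.delim(path, colClasses = "character",
                      check.names = FALSE, na.strings = NULL)
    need <- c("accession", "treatment", "day", "replicate", "trait", "value")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop(sprintf("trait table %s lacks required column(s): %s", path,
                     paste(miss, collapse = ", ")), call. = FALSE)
    trt <- tab$treatment
    alias <- trt %in% names(treatment_map)
    trt[alias] <- treatment_map[trt[alias]]
    bad <- setdiff(unique(trt), TREATMENTS)
    if (length(bad))
        stop(sprintf("trait table %s: unknown treatment value(s): %s", path,
                     paste(bad, collapse = ", ")), call. = FALSE)
    TraitMatrix(data.frame(
        accession = tab$accession,
        treatment = trt,
        day = as.integer(parseNumeric(tab$day, "day", path)),
        replicate = tab$replicate,
        trait = tab$trait,
        value = parseNumeric(tab$value, "value", path),
        stringsAsFactors = FALSE))
}

#' Write a TraitMatrix to TSV
#'
#' Values are written at full double precision so that a read round trip
#' reproduces them exactly.
#'
#' @param tm A \linkS4class{TraitMatrix}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTraitTable <- function(tm, path) writeTsv(traitRecords(tm), path)

genoFromGT <- function(gt) {
    g <- rep(NA_integer_, length(gt))
    g[gt %in% c("0/0", "0|0", "0")] <- 0L
    g[gt %in% c("1/1", "1|1", "1")] <- 1L
    het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
    if (any(het))
        warning(sprintf(
            "%d heterozygous call(s) set to NA (inbred panel assumed)",
            sum(het)), call. = FALSE)
    g
}

defaultMarkerIds <- function(chrom, pos) sprintf("M%s_%08d", chrom, pos)

#' Read a biallelic genotype matrix
#'
#' Two dialects are supported: a minimal VCF v4.x subset (GT field,
#' biallelic sites; multi-allelic records are skipped with a warning and
#' heterozygous calls become `NA` because the panel consists of inbred
#' lines) and a TSV dialect with columns `marker` (optional), `chrom`,
#' `pos`, `ref`, `alt` followed by one 0/1/NA column per accession.
#'
#' @param path input file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return A \linkS4class{GenotypeMatrix} with markers sorted by
#'   (chromosome, position), positions 1-based.
#' @export
readGenotypes <- function(path, dialect = c("tsv", "vcf")) {
    dialect <- match.arg(dialect)
    if (dialect == "vcf") {
        vcf <- vcfR::read.vcfR(path, verbose = FALSE)
        fix <- vcfR::getFIX(vcf)
        fix <- matrix(fix, ncol = length(colnames(fix)),
                      dimnames = list(NULL, colnames(fix)))
        multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
        if (any(multi))
            warning(sprintf("%d multi-allelic record(s) skipped", sum(multi)),
                    call. = FALSE)
        gt <- vcfR::extract.gt(vcf, element = "GT")
        keep <- which(!multi)
        calls <- matrix(NA_integer_, length(keep), ncol(gt),
                        dimnames = list(NULL, colnames(gt)))
        for (i in seq_along(keep))
            calls[i, ] <- genoFromGT(gt[keep[i], ])
        id <- fix[keep, "ID"]
        noid <- is.na(id) | id == "."
        id[noid] <- defaultMarkerIds(fix[keep, "CHROM"][noid],
                                     as.integer(fix[keep, "POS"])[noid])
        map <- data.frame(marker = id,
                          chrom = fix[keep, "CHROM"],
                          pos = as.integer(fix[keep, "POS"]),
                          ref = fix[keep, "REF"],
                          alt = fix[keep, "ALT"],
                          stringsAsFactors = FALSE)
    } else {
        tab <- read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
        need <- c("chrom", "pos", "ref", "alt")
        miss <- setdiff(need, names(tab))
        if (length(miss))
            stop(sprintf("genotype TSV %s lacks column(s): %s", path,
                         paste(miss, collapse = ", ")), call. = FALSE)
        fixed <- intersect(c("marker", need), names(tab))
        samp <- setdiff(names(tab), fixed)
        if (!length(samp))
            stop("genotype TSV has no accession columns", call. = FALSE)
        calls <- sapply(tab[samp],
                        function(x) as.integer(parseNumeric(x, "genotype",
                                                            path)))
        calls <- matrix(calls, ncol = length(samp),
                        dimnames = list(NULL, samp))
        id <- if ("marker" %in% fixed) tab$marker else
            defaultMarkerIds(tab$chrom, as.integer(tab$pos))
        map <- data.frame(marker = id, chrom = tab$chrom,
                          pos = as.integer(tab$pos),
                          ref = tab$ref, alt = tab$alt,
                          stringsAsFactors = FALSE)
    }
    key <- paste(map$chrom, map$pos)
    if (anyDuplicated(key))
        stop(sprintf("duplicate (chrom, pos) marker(s) in %s: %s", path,
                     key[duplicated(key)][1]), call. = FALSE)
    GenotypeMatrix(calls, map)
}

#' Write a GenotypeMatrix
#'
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @param dialect `"tsv"` or `"vcf"` (minimal VCF v4.2, GT-only FORMAT).
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(geno, path, dialect = c("tsv", "vcf")) {
    dialect <- match.arg(dialect)
    map <- markerMap(geno)
    calls <- genoCalls(geno)
    if (dialect == "tsv") {
        df <- cbind(map, as.data.frame(calls, check.names = FALSE))
        rownames(df) <- NULL
        return(writeTsv(df, path))
    }
    gtChr <- matrix("./.", nrow(calls), ncol(calls))
    gtChr[which(calls == 0L)] <- "0/0"
    gtChr[which(calls == 1L)] <- "1/1"
    body <- cbind(map$chrom, map$pos, map$marker, map$ref, map$alt,
                  ".", "PASS", ".", "GT", gtChr)
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(calls)), collapse = "\t"),
               apply(body, 1, paste, collapse = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Pipeline configuration
#'
#' Bundles file paths and the fixed analysis constants: the percentile
#' fraction used for the efficient / highly-sensitive classes, the
#' intermediate BEI threshold, the trait-maintenance threshold for the
#' highly-tolerant flag, the number of k-means clusters and tree clades,
#' the MAF cutoff, the -log10 p needed for QTL windows, the LD half-decay
#' padding and the clump gap.
#'
#' @param trait_table,genotypes,ionome,haplotypes,out_dir file paths
#'   (any of the inputs may be `NULL` when the corresponding stage is not
#'   run).
#' @param genotype_dialect `"tsv"` or `"vcf"`.
#' @param percentile fraction of the panel classed efficient (and, at the
#'   other tail, highly sensitive); default 0.10.
#' @param intermediate BEI_shoot threshold for the intermediate class
#'   (default 0.400).
#' @param maintenance FW/DW ratio needed for the highly-tolerant flag
#'   (default 0.80).
#' @param k number of k-means clusters (default 12).
#' @param n_clades number of tree clades (default 11).
#' @param maf minor-allele-frequency cutoff (default 0.05).
#' @param min_neglogp -log10 p at which markers seed QTL windows
#'   (default 4.0).
#' @param padding_bp QTL window padding, half the LD decay distance
#'   (default 3365 bp).
#' @param clump_gap_bp maximum gap between qualifying markers within one
#'   window (default 1e6 bp).
#' @param bei_form how the two trait ratios combine into a BEI:
#'   `"product"` (default), `"geometric"` or `"arithmetic"`.
#' @param min_reps minimum replicates per side for a trait ratio.
#' @param seed random seed used for clustering restarts and any
#'   simulation the pipeline performs.
#' @return A validated configuration list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(trait_table = NULL, genotypes = NULL,
                           genotype_dialect = "tsv", ionome = NULL,
                           haplotypes = NULL, out_dir = ".",
                           percentile = 0.10, intermediate = 0.400,
                           maintenance = 0.80, k = 12L, n_clades = 11L,
                           maf = 0.05, min_neglogp = 4.0,
                           padding_bp = 3365, clump_gap_bp = 1e6,
                           bei_form = c("product", "geometric", "arithmetic"),
                           min_reps = 3L, seed = 1L) {
    stopifnot(percentile > 0, percentile < 1,
              maintenance > 0, maintenance < 1,
              padding_bp > 0, clump_gap_bp > 0,
              k >= 1, n_clades >= 1, maf >= 0, maf <= 0.5,
              min_neglogp > 0, min_reps >= 1)
    cfg <- list(trait_table = trait_table, genotypes = genotypes,
                genotype_dialect = genotype_dialect, ionome = ionome,
                haplotypes = haplotypes, out_dir = out_dir,
                percentile = percentile, intermediate = intermediate,
                maintenance = maintenance, k = as.integer(k),
                n_clades = as.integer(n_clades), maf = maf,
                min_neglogp = min_neglogp, padding_bp = padding_bp,
                clump_gap_bp = clump_gap_bp,
                bei_form = match.arg(bei_form),
                min_reps = as.integer(min_reps), seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Write pipeline products to an output directory
#'
#' Tabular products become TSV, trees become newick; the run log echoes the
#' configuration and seed. Unknown product types raise an error.
#'
#' @param results named list of pipeline products (`data.frame`,
#'   \linkS4class{EfficiencyScores}, `GRanges`, `phylo`).
#' @param out_dir output directory (created if absent).
#' @param config optional `PipelineConfig` echoed into `run.log`.
#' @return Character vector of written file paths, invisibly.
#' @export
writeOutputs <- function(results, out_dir, config = NULL) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", out_dir, call. = FALSE)
    written <- character(0)
    for (nm in names(results)) {
        x <- results[[nm]]
        if (inherits(x, "phylo")) {
            f <- file.path(out_dir, paste0(nm, ".nwk"))
            ape::write.tree(x, f)
        } else {
            f <- file.path(out_dir, paste0(nm, ".tsv"))
            if (is(x, "EfficiencyScores")) x <- scoreTable(x)
            if (is(x, "GRanges")) {
                x <- as.data.frame(x)
                names(x)[names(x) == "seqnames"] <- "chrom"
            }
            if (!is.data.frame(x))
                stop("cannot serialise product '", nm, "' of class ",
                     class(x)[1], call. = FALSE)
            writeTsv(x, f)
        }
        written <- c(written, f)
    }
    log <- c(paste("boreff run", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             paste("products:", paste(names(results), collapse = ", ")))
    if (!is.null(config)) {
        scal <- vapply(config, function(v)
            if (is.null(v)) "NULL" else paste(v, collapse = ","), "")
        log <- c(log, paste0("config ", names(scal), " = ", scal))
    }
    logf <- file.path(out_dir, "run.log")
    writeLines(log, logf)
    invisible(c(written, logf))
}

#' Run the full boron-efficiency pipeline
#'
#' Executes the stages traits -> efficiency -> profiling -> phylogeny ->
#' gwas in order, reading inputs from the paths in `config` and writing
#' the declared outputs (`trait_ratios.tsv`, `scores.tsv`, `clusters.tsv`,
#' `tree.nwk`, `clades.tsv`, `associations.tsv`, `qtl_windows.tsv`, plus
#' auxiliary tables and `run.log`) to `config$out_dir`. A stage failure
#' aborts with an error naming the stage.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param stages subset of stages to run; phylogeny and gwas require a
#'   genotype path.
#' @return Invisibly, the named list of in-memory products.
#' @export
runPipeline <- function(config,
                        stages = c("traits", "efficiency", "profiling",
                                   "phylogeny", "gwas")) {
    stopifnot(inherits(config, "PipelineConfig"))
    stages <- match.arg(stages, several.ok = TRUE)
    if (any(c("phylogeny", "gwas") %in% stages) && is.null(config$genotypes))
        stop("configuration error: genotype path required for stage(s) ",
             paste(intersect(c("phylogeny", "gwas"), stages), collapse = ", "),
             call. = FALSE)
    if (is.null(config$trait_table))
        stop("configuration error: trait table path required", call. = FALSE)
    set.seed(config$seed)
    run <- function(stage, expr) tryCatch(expr, error = function(e)
        stop(sprintf("stage %s: %s", stage, conditionMessage(e)),
             call. = FALSE))
    out <- list()

    tm <- run("traits", readTraitTable(config$trait_table))
    feats <- run("traits", responseFeatures(tm, min_reps = config$min_reps))
    out$trait_ratios <- feats

    if (any(c("efficiency", "profiling", "gwas") %in% stages)) {
        es <- run("efficiency", efficiencyScores(feats, config))
        out$scores <- es
        if (!is.null(config$ionome)) {
            ion <- read.delim(config$ionome)
            rm_ <- replicateMeans(tm)
            dw <- rm_[rm_$trait == "DW", ]
            i <- match(paste(ion$accession, ion$treatment),
                       paste(dw$accession, dw$treatment))
            ion$dw_mg <- dw$mean[i]
            ion$content_ng <- shootContent(ion$concentration, ion$dw_mg)
            out$ionome_contents <- ion
            sc <- scoreTable(es)
            cls <- sc$class[match(ion$accession, sc$accession)]
            sel <- ion$treatment == "deficient" & !is.na(ion$content_ng) &
                cls %in% c("B-efficient", "B-inefficient")
            if (sum(sel) >= 4) {
                gc <- run("efficiency", groupContrast(
                    ion$content_ng[sel],
                    factor(cls[sel], levels = c("B-efficient",
                                                "B-inefficient"))))
                out$ionome_contrast <- data.frame(
                    element = unique(ion$element)[1],
                    treatment = "deficient",
                    fold_efficient_vs_inefficient = gc$fold,
                    welch_p = gc$p)
            }
        }
    }
    if ("profiling" %in% stages) {
        pm <- run("profiling", centerScale(feats))
        cp <- run("profiling",
                  kmeansProfile(pm, k = min(config$k, nrow(pm)),
                                seed = config$seed))
        out$clusters <- data.frame(accession = rownames(pm),
                                   cluster = cp$cluster)
        out$cluster_means <- run("profiling", clusterSummary(cp, pm))
    }
    geno <- NULL
    if (!is.null(config$genotypes) &&
        any(c("phylogeny", "gwas") %in% stages))
        geno <- run("io", readGenotypes(config$genotypes,
                                        config$genotype_dialect))
    if ("phylogeny" %in% stages) {
        dm <- run("phylogeny", snpDistance(geno))
        tree <- run("phylogeny", njTree(dm))
        clades <- run("phylogeny", cutClades(tree, config$n_clades))
        out$tree <- tree
        out$clades <- data.frame(accession = names(clades), clade = clades)
        if (!is.null(out$scores)) {
            sc <- scoreTable(out$scores)
            eff <- sc$accession[sc$class == "B-efficient"]
            enr <- do.call(rbind, lapply(sort(unique(clades)), function(cl) {
                memb <- names(clades)[clades == cl]
                e <- cladeEnrichment(sum(memb %in% eff), length(memb),
                                     length(eff), length(clades))
                data.frame(clade = cl, k_in = sum(memb %in% eff),
                           n_clade = length(memb), K_class = length(eff),
                           N = length(clades), fold = e$fold, p = e$p)
            }))
            out$clade_enrichment <- enr
        }
    }
    if ("gwas" %in% stages) {
        geno <- run("gwas", mafFilter(geno, config$maf))
        sc <- scoreTable(out$scores)
        y <- setNames(sc$bei_shoot, sc$accession)
        assoc <- run("gwas", markerScan(y, geno, trait = "bei_shoot"))
        out$associations <- assoc
        out$qtl_windows <- run("gwas",
            qtlWindows(assoc, min_neglogp = config$min_neglogp,
                       padding_bp = config$padding_bp,
                       clump_gap_bp = config$clump_gap_bp))
        bonf <- bonferroniThreshold(nrow(assoc))
        sig <- assoc$marker[assoc$p < bonf$p_threshold]
        if (length(sig)) {
            ledger <- run("gwas", efficiencyAlleles(sig, geno, y,
                                                    trait = "bei_shoot"))
            out$allele_ledger <- ledger
            out$allele_counts <- data.frame(
                accession = accessionNames(geno),
                n_efficiency_alleles = countEfficiencyAlleles(ledger, geno))
        }
        if (!is.null(config$haplotypes)) {
            hap <- read.delim(config$haplotypes, colClasses = "character")
            out$haplotypes <- run("gwas", haplotypeContrast(hap, out$scores))
        }
    }
    writeOutputs(out, config$out_dir, config)
    invisible(out)
}
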