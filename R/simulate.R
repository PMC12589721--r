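#' Simulation configuration
#'
#' Defaults emulate the study conditions of the screened panel: 185
#' accessions in 11 clades, 5000 biallelic markers on 5 chromosomes of
#' 30 Mb, 6 replicates per treatment, daily shoot imaging on days 9-16
#' with endpoint FW/DW at day 20 and root traits at day 15, a replicate
#' coefficient of variation of 0.25, and one planted pleiotropic QTL
#' acting on the latent deficiency tolerance that drives both shoot and
#' root ratios.
#'
#' @param n_accessions panel size (default 185).
#' @param n_clades number of planted clades (default 11).
#' @param n_markers number of biallelic markers (default 5000).
#' @param n_chrom,chrom_length_bp genome layout (5 x 30 Mb).
#' @param replicates replicates per treatment (default 6).
#' @param days daily imaging days (default 9:16).
#' @param cv replicate coefficient of variation (default 0.25).
#' @param qtl_beta effect sizes (latent scale) of planted QTLs; an empty
#'   vector plants none (null panel).
#' @param qtl_maf_range MAF band from which causal markers are drawn
#'   (default `c(0.05, 0.15)`, matching the rare efficiency alleles the
#'   association stage is expected to recover).
#' @param qtl_marker optional explicit causal marker ids (overrides the
#'   MAF-band draw).
#' @param clade_sd SD of clade-level latent tolerance effects.
#' @param eps_sd SD of accession-level latent noise.
#' @param mu latent tolerance intercept.
#' @param n_forced_lateral number of accessions forced to increase total
#'   lateral root length under deficiency; the default scales the panel's
#'   15-of-185 proportion to `n_accessions`.
#' @param seed integer seed.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(n_accessions = 185L, n_clades = 11L,
                      n_markers = 5000L, n_chrom = 5L,
                      chrom_length_bp = 30e6, replicates = 6L,
                      days = 9:16, cv = 0.25, qtl_beta = 2.0,
                      qtl_maf_range = c(0.05, 0.15), qtl_marker = NULL,
                      clade_sd = 0.5, eps_sd = 0.5, mu = -0.9,
                      n_forced_lateral = NULL, seed = 1L) {
    if (is.null(n_forced_lateral))
        n_forced_lateral <- round(n_accessions * 15 / 185)
    stopifnot(n_clades <= n_accessions, cv > 0,
              all(is.finite(qtl_beta)), n_markers >= length(qtl_beta),
              n_forced_lateral <= n_accessions)
    cfg <- list(n_accessions = as.integer(n_accessions),
                n_clades = as.integer(n_clades),
                n_markers = as.integer(n_markers),
                n_chrom = as.integer(n_chrom),
                chrom_length_bp = chrom_length_bp,
                replicates = as.integer(replicates), days = as.integer(days),
                cv = cv, qtl_beta = qtl_beta,
                qtl_maf_range = qtl_maf_range, qtl_marker = qtl_marker,
                clade_sd = clade_sd,
                eps_sd = eps_sd, mu = mu,
                n_forced_lateral = as.integer(n_forced_lateral),
                seed = as.integer(seed))
    class(cfg) <- "SimConfig"
    cfg
}

## random binary newick over a label set (no branch length on the
## returned node itself); child branch lengths ~ U(0.1, 1) * scale
randomSubtreeNewick <- function(labels, scale) {
    bl <- function() runif(1, 0.1, 1) * scale
    if (length(labels) == 1)
        return(labels)
    k <- if (length(labels) == 2) 1 else
        sample.int(length(labels) - 1L, 1)
    idx <- sample(seq_along(labels))
    left <- labels[idx[seq_len(k)]]
    right <- labels[idx[-seq_len(k)]]
    sprintf("(%s:%.6f,%s:%.6f)", randomSubtreeNewick(left, scale), bl(),
            randomSubtreeNewick(right, scale), bl())
}

## tips below the child node of each edge (list parallel to edge rows)
edgeDescendants <- function(tree) {
    ntip <- length(tree$tip.label)
    tr <- ape::reorder.phylo(tree, "postorder")
    desc <- vector("list", ntip + tr$Nnode)
    for (i in seq_len(ntip)) desc[[i]] <- i
    for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
        desc[[p]] <- c(desc[[p]], desc[[ch]])
    }
    lapply(seq_len(nrow(tree$edge)), function(e) desc[[tree$edge[e, 2]]])
}

#' Simulate clade-structured genotypes
#'
#' Builds a random bifurcating tree whose backbone separates `n_clades`
#' subtrees (long internal backbone branches, short within-clade
#' branches), then drops each marker once on a uniformly chosen branch
#' (infinite-sites): tips below the branch carry the alternative allele.
#' Every marker is polymorphic by construction. Markers receive unique
#' sorted positions over the configured chromosomes, and planted causal
#' markers are drawn from the configured minor-allele-frequency band
#' (or taken from `qtl_marker` when given).
#'
#' @param cfg a \code{\link{simConfig}}; its `seed` is used.
#' @return list with `geno` (\linkS4class{GenotypeMatrix}) and `truth`
#'   (list: `clade` named integer vector, `tree` phylo, `causal`
#'   data.frame of marker ids and latent effects).
#' @export
simulateGenotypes <- function(cfg = simConfig()) {
    set.seed(cfg$seed)
    n <- cfg$n_accessions
    accs <- sprintf("acc%03d", seq_len(n))
    sizes <- rep(n %/% cfg$n_clades, cfg$n_clades)
    extra <- n - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    cladeOf <- rep(seq_len(cfg$n_clades), sizes)
    members <- split(accs, cladeOf)
    subNwk <- vapply(members, function(lab)
        randomSubtreeNewick(lab, scale = 0.4), "")
    ## backbone over clade subtrees with long branches
    nwk <- if (cfg$n_clades == 1) paste0(subNwk[[1]], ";") else {
        grouped <- unname(subNwk)
        while (length(grouped) > 1) {
            i <- sample.int(length(grouped), 2)
            joined <- sprintf("(%s:%.6f,%s:%.6f)", grouped[i[1]],
                              runif(1, 2, 4), grouped[i[2]],
                              runif(1, 2, 4))
            grouped <- c(grouped[-i], joined)
        }
        paste0(grouped, ";")
    }
    tree <- ape::read.tree(text = nwk)
    desc <- edgeDescendants(tree)
    properEdges <- which(lengths(desc) < length(tree$tip.label))
    calls <- matrix(0L, cfg$n_markers, n)
    colnames(calls) <- tree$tip.label
    ## classic infinite-sites: mutation probability proportional to branch
    ## length, so backbone branches separating clades accumulate most
    ## mutations and every marker is polymorphic by construction
    hit <- sample(properEdges, cfg$n_markers, replace = TRUE,
                  prob = tree$edge.length[properEdges])
    for (m in seq_len(cfg$n_markers))
        calls[m, desc[[hit[m]]]] <- 1L
    calls <- calls[, accs, drop = FALSE]
    ## unique sorted positions
    repeat {
        chrom <- sample.int(cfg$n_chrom, cfg$n_markers, replace = TRUE)
        pos <- sample.int(cfg$chrom_length_bp, cfg$n_markers,
                          replace = TRUE)
        if (!anyDuplicated(paste(chrom, pos))) break
    }
    map <- data.frame(marker = defaultMarkerIds(chrom, pos),
                      chrom = as.character(chrom), pos = pos,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
    geno <- GenotypeMatrix(calls, map)
    causal <- data.frame(marker = character(0), beta = numeric(0))
    if (length(cfg$qtl_beta)) {
        if (!is.null(cfg$qtl_marker)) {
            stopifnot(length(cfg$qtl_marker) == length(cfg$qtl_beta),
                      all(cfg$qtl_marker %in% map$marker))
            mk <- cfg$qtl_marker
        } else {
            maf <- markerMAF(geno)
            pool <- names(maf)[maf >= cfg$qtl_maf_range[1] &
                               maf <= cfg$qtl_maf_range[2]]
            if (length(pool) < length(cfg$qtl_beta))
                pool <- names(sort(maf, decreasing = TRUE))[
                    seq_along(cfg$qtl_beta)]
            mk <- sample(pool, length(cfg$qtl_beta))
        }
        causal <- data.frame(marker = mk, beta = cfg$qtl_beta,
                             stringsAsFactors = FALSE)
    }
    truth <- list(clade = setNames(cladeOf, accs), tree = tree,
                  causal = causal)
    list(geno = geno, truth = truth)
}

## mean-preserving multiplicative lognormal replicate noise at given CV
replNoise <- function(n, cv) {
    sdlog <- sqrt(log1p(cv^2))
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate phenotypes and ionome from genotypes
#'
#' Each accession receives a latent deficiency-tolerance multiplier
#' `m = 1.3 * logistic(mu + sum(beta * x) + clade + eps)`. Sufficient
#' growth is exponential, `PLA(t) = A * exp(r (t - 9))`; under deficiency
#' the growth rate is multiplied by a factor that phases in linearly over
#' days 13-14 and settles at `m`, so treatments diverge only after day
#' 12. Endpoint FW at day 20 is proportional to day-16 PLA with
#' multiplicative lognormal noise sized so that cor(FW, PLA16) is about
#' 0.93 across accessions; DW is a tenth of FW with extra noise. Root
#' ratios are driven by `m` through separate exponents (pleiotropy), with
#' `n_forced_lateral` top-tolerance accessions forced to increase TLRL
#' under deficiency. Within every replicate the identities
#' `TLRL = LRN * ALRL`, `TRL = PRL + TLRL` and `LRD = LRN / PRL` hold
#' exactly. Shoot B concentration is Uniform(51, 92) mg kg^-1 DW under
#' sufficiency and is multiplied by Uniform(0.12, 0.17) and a tolerance
#' factor under deficiency.
#'
#' @param geno A \linkS4class{GenotypeMatrix} from
#'   \code{\link{simulateGenotypes}}.
#' @param truth the matching truth list (clade assignment, causal
#'   markers).
#' @param cfg a \code{\link{simConfig}}.
#' @return list with `traits` (\linkS4class{TraitMatrix}), `ionome`
#'   (data.frame `accession`, `treatment`, `element`, `concentration`),
#'   and `truth` extended with the latent `m`.
#' @export
simulatePhenotypes <- function(geno, truth, cfg = simConfig()) {
    set.seed(cfg$seed + 1L)
    accs <- accessionNames(geno)
    n <- length(accs)
    z <- cfg$mu + rnorm(n, 0, cfg$eps_sd)
    if (cfg$clade_sd > 0) {
        cladeEff <- rnorm(max(truth$clade), 0, cfg$clade_sd)
        z <- z + cladeEff[truth$clade[accs]]
    }
    if (nrow(truth$causal)) {
        g <- genoCalls(geno)
        for (i in seq_len(nrow(truth$causal))) {
            x <- g[truth$causal$marker[i], accs]
            x[is.na(x)] <- 0L
            z <- z + truth$causal$beta[i] * x
        }
    }
    m <- 1.3 * plogis(z)

    days <- cfg$days
    A <- rlnorm(n, log(30), 0.45)       # day-9 PLA, mm^2
    r <- rnorm(n, 0.374, 0.03)          # sufficient daily RGR
    phase <- function(d) pmax(0, pmin(1, (d - 12) / 2))
    wmat <- outer(m, days[-1], function(mm, d) 1 - (1 - mm) * phase(d))
    logSuff <- outer(r, days - days[1]) + log(A)
    logDef <- log(A) + cbind(0, t(apply(wmat * r, 1, cumsum)))
    pla <- list(sufficient = exp(logSuff), deficient = exp(logDef))

    pla16s <- pla$sufficient[, length(days)]
    pla16d <- pla$deficient[, length(days)]
    fwNoise <- exp(rnorm(n, 0, 0.10))
    fw <- list(sufficient = 0.15 * pla16s * fwNoise,
               deficient = 0.15 * pla16d * m^0.25 *
                   fwNoise * exp(rnorm(n, 0, 0.10)))
    dw <- lapply(fw, function(x) 0.1 * x * exp(rnorm(n, 0, 0.10)))

    prlS <- rlnorm(n, log(5.2), 0.30)
    prlRatio <- pmin(0.95, 0.8 * m^0.55)
    tlrlS <- rlnorm(n, log(4.0), 0.50)
    tlrlRatio <- pmin(0.95 * m^0.9, 0.98)
    forced <- order(-m)[seq_len(cfg$n_forced_lateral)]
    tlrlRatio[forced] <- runif(cfg$n_forced_lateral, 1.01, 1.69)
    lrnS <- rlnorm(n, log(14), 0.30)
    lrnRatio <- pmin(0.95 * m^0.2, 0.98)
    root <- list(
        sufficient = list(PRL = prlS, TLRL = tlrlS, LRN = lrnS),
        deficient = list(PRL = prlS * prlRatio, TLRL = tlrlS * tlrlRatio,
                         LRN = lrnS * lrnRatio))

    reps <- cfg$replicates
    rows <- list()
    addRows <- function(trait, day, trt, meanVals) {
        noisy <- rep(meanVals, each = reps) * replNoise(n * reps, cfg$cv)
        rows[[length(rows) + 1L]] <<- data.frame(
            accession = rep(accs, each = reps), treatment = trt,
            day = day, replicate = rep(seq_len(reps), n),
            trait = trait, value = noisy, stringsAsFactors = FALSE)
    }
    for (trt in TREATMENTS)
        for (j in seq_along(days))
            addRows("PLA", days[j], trt, pla[[trt]][, j])
    for (trt in TREATMENTS) {
        addRows("FW", NA_integer_, trt, fw[[trt]])
        addRows("DW", NA_integer_, trt, dw[[trt]])
        ## roots: noise the free traits, derive the rest exactly
        prlRep <- rep(root[[trt]]$PRL, each = reps) *
            replNoise(n * reps, cfg$cv)
        lrnRep <- rep(root[[trt]]$LRN, each = reps) *
            replNoise(n * reps, cfg$cv)
        alrlMean <- root[[trt]]$TLRL / root[[trt]]$LRN
        alrlRep <- rep(alrlMean, each = reps) * replNoise(n * reps, cfg$cv)
        tlrlRep <- lrnRep * alrlRep
        base <- data.frame(accession = rep(accs, each = reps),
                           treatment = trt, day = NA_integer_,
                           replicate = rep(seq_len(reps), n),
                           stringsAsFactors = FALSE)
        for (tv in list(c("PRL"), c("LRN"), c("ALRL"), c("TLRL"),
                        c("TRL"), c("LRD"))) {
            val <- switch(tv, PRL = prlRep, LRN = lrnRep, ALRL = alrlRep,
                          TLRL = tlrlRep, TRL = prlRep + tlrlRep,
                          LRD = lrnRep / prlRep)
            rows[[length(rows) + 1L]] <- cbind(base, trait = tv,
                                               value = val)
        }
    }
    tm <- TraitMatrix(do.call(rbind, rows))

    bSuff <- runif(n, 51, 92)
    bDef <- bSuff * runif(n, 0.12, 0.17) * (0.75 + 0.5 * pmin(m, 1))
    ionome <- data.frame(
        accession = rep(accs, 2),
        treatment = rep(TREATMENTS, each = n),
        element = "B",
        concentration = c(bDef, bSuff), stringsAsFactors = FALSE)

    truth$m <- setNames(m, accs)
    list(traits = tm, ionome = ionome, truth = truth)
}

#' Generate a complete on-disk fixture
#'
#' Simulates genotypes, phenotypes and ionome under the default study
#' conditions (overridable via `cfg`) and writes: `traits.tsv`,
#' `genotypes.tsv`, `genotypes.vcf`, `ionome.tsv`, `haplotypes.tsv`
#' (synthetic protein-haplotype labels derived from the alleles at three
#' designated candidate-gene markers), `truth_accessions.tsv` (accession,
#' m, clade) and `truth_markers.tsv` (marker, beta).
#'
#' @param seed integer seed (overrides `cfg$seed`).
#' @param out_dir output directory, created if absent.
#' @param cfg a \code{\link{simConfig}}.
#' @return Named character vector of written paths, invisibly.
#' @export
generateFixture <- function(seed, out_dir, cfg = simConfig()) {
    cfg$seed <- as.integer(seed)
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create ", out_dir)
    sim <- simulateGenotypes(cfg)
    phe <- simulatePhenotypes(sim$geno, sim$truth, cfg)
    paths <- c(traits = file.path(out_dir, "traits.tsv"),
               genotypes_tsv = file.path(out_dir, "genotypes.tsv"),
               genotypes_vcf = file.path(out_dir, "genotypes.vcf"),
               ionome = file.path(out_dir, "ionome.tsv"),
               haplotypes = file.path(out_dir, "haplotypes.tsv"),
               truth_accessions = file.path(out_dir,
                                            "truth_accessions.tsv"),
               truth_markers = file.path(out_dir, "truth_markers.tsv"))
    writeTraitTable(phe$traits, paths["traits"])
    writeGenotypes(sim$geno, paths["genotypes_tsv"], "tsv")
    writeGenotypes(sim$geno, paths["genotypes_vcf"], "vcf")
    writeTsv(phe$ionome, paths["ionome"])
    ## synthetic candidate-gene haplotypes: allele at a designated marker
    maf <- markerMAF(sim$geno)
    common <- names(sort(maf, decreasing = TRUE))
    candidates <- unique(c(sim$truth$causal$marker, common))[1:3]
    hap <- do.call(rbind, lapply(seq_along(candidates), function(i) {
        a <- genoCalls(sim$geno)[candidates[i], ]
        data.frame(gene = sprintf("GENE%d", i),
                   haplotype = ifelse(is.na(a), "u",
                                      ifelse(a == 1L, "b", "a")),
                   accession = names(a), stringsAsFactors = FALSE)
    }))
    writeTsv(hap, paths["haplotypes"])
    writeTsv(data.frame(accession = names(phe$truth$m), m = phe$truth$m,
                        clade = phe$truth$clade[names(phe$truth$m)]),
             paths["truth_accessions"])
    writeTsv(phe$truth$causal, paths["truth_markers"])
    invisible(paths)
}
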