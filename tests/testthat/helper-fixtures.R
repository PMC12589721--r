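# shared fixture builders and independent oracles

# long trait table from accession-level treatment means with exact
# replicate values (no noise unless given)
makeTraitRecords <- function(accession, treatment, trait, reps,
                             day = NA_integer_) {
    data.frame(accession = accession, treatment = treatment, day = day,
               replicate = seq_along(reps), trait = trait, value = reps,
               stringsAsFactors = FALSE)
}

# tiny genotype matrix helper: markers x accessions
makeGeno <- function(calls, chrom = NULL, pos = NULL) {
    m <- nrow(calls)
    if (is.null(chrom)) chrom <- rep("1", m)
    if (is.null(pos)) pos <- seq_len(m) * 100L
    if (is.null(colnames(calls)))
        colnames(calls) <- sprintf("acc%02d", seq_len(ncol(calls)))
    GenotypeMatrix(calls, data.frame(
        marker = sprintf("M%s_%08d", chrom, pos), chrom = chrom, pos = pos,
        ref = "A", alt = "T", stringsAsFactors = FALSE))
}

# brute-force Fitch small parsimony: minimum changes over all internal
# (and missing-tip) state assignments
bruteFitch <- function(tree, tipStates) {
    ntip <- length(tree$tip.label)
    states <- tipStates[tree$tip.label]
    freeTips <- which(is.na(states))
    nInternal <- tree$Nnode
    free <- nInternal + length(freeTips)
    best <- Inf
    for (code in 0:(2^free - 1)) {
        bits <- as.integer(intToBits(code))[seq_len(free)]
        s <- c(states, bits[seq_len(nInternal)])
        if (length(freeTips))
            s[freeTips] <- bits[nInternal + seq_along(freeTips)]
        changes <- sum(s[tree$edge[, 1]] != s[tree$edge[, 2]])
        best <- min(best, changes)
    }
    best
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small simulated panel reused across files
smallPanel <- function(seed = 11, n = 40, clades = 4, markers = 300,
                       reps = 4, ...) {
    cfg <- simConfig(n_accessions = n, n_clades = clades,
                     n_markers = markers, replicates = reps, seed = seed,
                     ...)
    sim <- simulateGenotypes(cfg)
    phe <- simulatePhenotypes(sim$geno, sim$truth, cfg)
    list(cfg = cfg, geno = sim$geno, traits = phe$traits,
         ionome = phe$ionome, truth = phe$truth)
}
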