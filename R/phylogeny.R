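#' Pairwise SNP p-distance matrix
#'
#' `d(i, j)` = proportion of mismatching calls over markers where both
#' accessions are non-missing. Errors if an accession has no calls at all
#' or a pair shares no markers.
#'
#' @param geno A \linkS4class{GenotypeMatrix} (>= 2 accessions).
#' @return Symmetric numeric matrix with zero diagonal, entries in [0, 1].
#' @export
snpDistance <- function(geno) {
    g <- genoCalls(geno)
    if (ncol(g) < 2) stop("need >= 2 accessions")
    ok <- !is.na(g)
    allMissing <- colSums(ok) == 0
    if (any(allMissing))
        stop("accession(s) with all-missing genotypes: ",
             paste(colnames(g)[allMissing], collapse = ", "))
    P <- ok * 1
    X <- g; X[!ok] <- 0L
    X1 <- X * P          # presence-masked alt calls
    X0 <- (1 - X) * P    # presence-masked ref calls
    shared <- crossprod(P)
    mism <- crossprod(X1, X0) + crossprod(X0, X1)
    if (any(shared == 0 & upper.tri(shared)))
        stop("accession pair(s) share no non-missing markers")
    d <- mism / shared
    diag(d) <- 0
    d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \code{\link[ape]{nj}}); negative
#' branch lengths are clamped to zero. The result is an unrooted binary
#' tree whose leaves are the accession ids.
#'
#' @param dm symmetric distance matrix with accession dimnames (N >= 3).
#' @return An \code{ape} `phylo` object.
#' @export
njTree <- function(dm) {
    if (anyNA(dm)) stop("distance matrix contains NA")
    if (nrow(dm) < 3) stop("need >= 3 taxa")
    tree <- ape::nj(as.dist(dm))
    tree$edge.length[tree$edge.length < 0] <- 0
    tree
}

#' Fitch small-parsimony score of binary SNP characters on a tree
#'
#' Sums, over markers, the minimum number of state changes needed to
#' explain the 0/1 tip states on the given topology. Missing tip states
#' are treated as the full state set {0, 1}. The score is independent of
#' root placement; trees with a basal trifurcation (unrooted binary trees
#' in `ape` encoding) are handled by implicit rooting.
#'
#' @param tree an `ape` `phylo`; tip labels must be accession ids.
#' @param geno A \linkS4class{GenotypeMatrix} covering all tree leaves.
#' @return Integer parsimony score.
#' @export
fitchScore <- function(tree, geno) {
    g <- genoCalls(geno)
    missingTips <- setdiff(tree$tip.label, colnames(g))
    if (length(missingTips))
        stop("leaf without genotype row: ",
             paste(missingTips, collapse = ", "))
    ntip <- length(tree$tip.label)
    nmark <- nrow(g)
    total <- ntip + tree$Nnode
    ## state bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1} (missing)
    masks <- matrix(0L, total, nmark)
    tipCalls <- g[, tree$tip.label, drop = FALSE]
    for (i in seq_len(ntip)) {
        v <- tipCalls[, i]
        masks[i, ] <- ifelse(is.na(v), 3L, ifelse(v == 1L, 2L, 1L))
    }
    tr <- ape::reorder.phylo(tree, "postorder")
    changes <- integer(nmark)
    touched <- logical(total)
    for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
        cm <- masks[ch, ]
        if (!touched[p]) {
            masks[p, ] <- cm
            touched[p] <- TRUE
        } else {
            inter <- bitwAnd(masks[p, ], cm)
            empty <- inter == 0L
            if (any(empty)) {
                changes[empty] <- changes[empty] + 1L
                inter[empty] <- bitwOr(masks[p, ], cm)[empty]
            }
            masks[p, ] <- inter
        }
    }
    sum(changes)
}

## tip components after removing `drop` edges; returns component id per tip
tipComponents <- function(tree, drop) {
    ntip <- length(tree$tip.label)
    parent <- seq_len(ntip + tree$Nnode)
    find <- function(x) {
        while (parent[x] != x) {
            parent[x] <<- parent[parent[x]]
            x <- parent[x]
        }
        x
    }
    for (e in setdiff(seq_len(nrow(tree$edge)), drop)) {
        a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
        if (a != b) parent[a] <- b
    }
    vapply(seq_len(ntip), find, 0L)
}

#' Cut a tree into clades by removing the longest internal edges
#'
#' Considers internal edges longest-first (ties broken by edge index) and
#' removes an edge only if that splits off a new tip-bearing component,
#' until the leaves fall into `n_clades` groups. Labels are ordered by
#' clade size descending, ties by the smallest member id.
#'
#' @param tree an `ape` `phylo` with branch lengths.
#' @param n_clades number of clades (default 11).
#' @return Named integer vector: accession -> clade in 1..n_clades.
#' @export
cutClades <- function(tree, n_clades = 11L) {
    ntip <- length(tree$tip.label)
    if (n_clades > ntip) stop("n_clades exceeds number of accessions")
    internal <- which(tree$edge[, 1] > ntip & tree$edge[, 2] > ntip)
    if (n_clades - 1L > length(internal))
        stop("not enough internal edges for ", n_clades, " clades")
    o <- internal[order(-tree$edge.length[internal], internal)]
    drop <- integer(0)
    comp <- tipComponents(tree, drop)
    i <- 1L
    while (length(unique(comp)) < n_clades) {
        if (i > length(o))
            stop("tree cannot be cut into ", n_clades, " clades")
        cand <- c(drop, o[i])
        newComp <- tipComponents(tree, cand)
        if (length(unique(newComp)) > length(unique(comp))) {
            drop <- cand
            comp <- newComp
        }
        i <- i + 1L
    }
    groups <- split(tree$tip.label[seq_len(ntip)], comp)
    sizes <- lengths(groups)
    firstId <- vapply(groups, function(g) min(g), "")
    o <- order(-sizes, firstId)
    out <- integer(0)
    for (i in seq_along(o))
        out[groups[[o[i]]]] <- i
    out[tree$tip.label]
}

#' Clade enrichment of an efficiency class
#'
#' Fold enrichment of a class within a clade relative to its population
#' frequency, with an upper-tail hypergeometric p-value
#' `P(X >= k_in)`.
#'
#' @param k_in class members inside the clade.
#' @param n_clade clade size.
#' @param K_class class size in the population.
#' @param N population size.
#' @return list with `fold` and `p`.
#' @export
cladeEnrichment <- function(k_in, n_clade, K_class, N) {
    stopifnot(k_in <= min(n_clade, K_class) || K_class == 0,
              n_clade <= N, K_class <= N)
    fold <- if (K_class == 0) NA_real_ else
        (k_in / n_clade) / (K_class / N)
    p <- phyper(k_in - 1, K_class, N - K_class, n_clade,
                lower.tail = FALSE)
    list(fold = fold, p = p)
}
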