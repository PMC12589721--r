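#' Centre and scale a trait-ratio feature matrix
#'
#' Pivots the long feature table into an accession x feature matrix,
#' imputes missing cells with the column mean (so they become exactly 0
#' after centring), then centres by the column mean and scales by the
#' sample (n-1) SD. Zero-SD columns are dropped with a warning.
#'
#' @param features long feature table (\code{\link{responseFeatures}}) or
#'   an accession x feature numeric matrix.
#' @param feature_list optional character vector restricting / ordering
#'   the features used.
#' @return Numeric matrix, accessions x features, each retained column
#'   with mean 0 and SD 1.
#' @export
centerScale <- function(features, feature_list = NULL) {
    if (is.data.frame(features)) {
        accs <- sort(unique(features$accession))
        feats <- unique(features$feature)
        m <- matrix(NA_real_, length(accs), length(feats),
                    dimnames = list(accs, feats))
        m[cbind(match(features$accession, accs),
                match(features$feature, feats))] <- features$ratio
    } else m <- as.matrix(features)
    if (!is.null(feature_list)) {
        miss <- setdiff(feature_list, colnames(m))
        if (length(miss))
            stop("unknown feature(s): ", paste(miss, collapse = ", "))
        m <- m[, feature_list, drop = FALSE]
    }
    if (nrow(m) < 2) stop("need >= 2 accessions")
    for (j in seq_len(ncol(m))) {
        mu <- mean(m[, j], na.rm = TRUE)
        m[is.na(m[, j]), j] <- mu
    }
    sds <- apply(m, 2, sd)
    drop <- sds == 0 | is.na(sds)
    if (all(drop)) stop("all feature columns have zero SD")
    if (any(drop))
        warning("dropping zero-SD feature(s): ",
                paste(colnames(m)[drop], collapse = ", "), call. = FALSE)
    m <- m[, !drop, drop = FALSE]
    scale(m)[, , drop = FALSE]
}

## k-means++ seeding (Arthur & Vassilvitskii): probability proportional to
## squared distance from the nearest chosen centre
kmeansPlusPlusInit <- function(x, k) {
    n <- nrow(x)
    centers <- integer(k)
    centers[1] <- sample.int(n, 1)
    d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x),
                              byrow = TRUE))^2)
    for (i in seq_len(k - 1L)) {
        prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[i + 1L] <- sample.int(n, 1, prob = prob)
        nd <- rowSums((x - matrix(x[centers[i + 1L], ], n, ncol(x),
                                  byrow = TRUE))^2)
        d2 <- pmin(d2, nd)
    }
    x[centers, , drop = FALSE]
}

#' k-means phenotypic response profiling
#'
#' Lloyd's algorithm with k-means++ initialisation, best of `restarts`
#' runs by total within-cluster sum of squares; deterministic given
#' `seed`. Cluster labels are renumbered by descending cluster size, ties
#' by the smallest member row id.
#'
#' @param pm centred/scaled accession x feature matrix
#'   (\code{\link{centerScale}}).
#' @param k number of clusters (default 12).
#' @param seed integer seed.
#' @param restarts number of initialisations (default 25).
#' @return list with `k`, `cluster` (named integer vector), `centers`,
#'   `size`, `tot_withinss`.
#' @export
kmeansProfile <- function(pm, k = 12L, seed = 1L, restarts = 25L) {
    n <- nrow(pm)
    if (k > n) stop("k must not exceed the number of accessions")
    set.seed(seed)
    best <- NULL
    for (r in seq_len(restarts)) {
        init <- kmeansPlusPlusInit(pm, k)
        fit <- suppressWarnings(
            stats::kmeans(pm, centers = init, iter.max = 100L,
                          algorithm = "Lloyd"))
        if (is.null(best) || fit$tot.withinss < best$tot.withinss)
            best <- fit
    }
    ## renumber: size descending, ties by smallest member id
    firstMember <- vapply(seq_len(k), function(c)
        min(which(best$cluster == c), Inf), 0)
    o <- order(-best$size, firstMember)
    relabel <- integer(k); relabel[o] <- seq_len(k)
    cl <- setNames(relabel[best$cluster], rownames(pm))
    list(k = k, cluster = cl,
         centers = best$centers[o, , drop = FALSE],
         size = as.integer(best$size[o]),
         tot_withinss = best$tot.withinss)
}

#' Per-cluster mean feature profile
#'
#' Means of the centred/scaled features within each cluster (the profile
#' heat-matrix), plus cluster sizes. Empty clusters get `NA` means.
#'
#' @param cp clustering from \code{\link{kmeansProfile}}.
#' @param pm the matrix that was clustered.
#' @return data.frame `cluster`, `n`, then one column per feature.
#' @export
clusterSummary <- function(cp, pm) {
    stopifnot(all(cp$cluster %in% seq_len(cp$k)),
              length(cp$cluster) == nrow(pm))
    rows <- lapply(seq_len(cp$k), function(c) {
        idx <- which(cp$cluster == c)
        mu <- if (length(idx)) colMeans(pm[idx, , drop = FALSE])
              else setNames(rep(NA_real_, ncol(pm)), colnames(pm))
        cbind(data.frame(cluster = c, n = length(idx)),
              as.data.frame(as.list(mu), check.names = FALSE))
    })
    do.call(rbind, rows)
}
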