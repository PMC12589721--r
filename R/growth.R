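## replicate means per accession x treatment x trait x day, with counts
replicateMeans <- function(tm) {
    rec <- traitRecords(tm)
    rec <- rec[!is.na(rec$value), , drop = FALSE]
    key <- interaction(rec$accession, rec$treatment, rec$trait,
                       ifelse(is.na(rec$day), "endpoint", rec$day),
                       drop = TRUE, sep = "\r")
    mu <- tapply(rec$value, key, mean)
    n <- tapply(rec$value, key, length)
    parts <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
    data.frame(accession = parts[, 1], treatment = parts[, 2],
               trait = parts[, 3],
               day = suppressWarnings(as.integer(parts[, 4])),
               mean = as.numeric(mu), n = as.integer(n),
               stringsAsFactors = FALSE)
}

featureName <- function(trait, day)
    ifelse(is.na(day), trait, sprintf("%s_d%02d", trait, day))

#' Deficiency:sufficiency trait ratios
#'
#' For every accession and trait (and day, for daily traits) computes the
#' ratio of arithmetic replicate means, deficient over sufficient. The
#' ratio is `NA` when either side has fewer than `min_reps` replicates or
#' the sufficient mean is zero.
#'
#' @param tm A \linkS4class{TraitMatrix}.
#' @param min_reps minimum replicate count per side (default 3).
#' @return data.frame with columns `accession`, `trait`, `day`, `feature`
#'   (trait or `trait_dNN`), `ratio`.
#' @export
traitRatios <- function(tm, min_reps = 3L) {
    stopifnot(min_reps >= 1)
    rm <- replicateMeans(tm)
    key <- paste(rm$accession, rm$trait, ifelse(is.na(rm$day), "E", rm$day),
                 sep = "\r")
    def <- rm[rm$treatment == "deficient", ]
    suf <- rm[rm$treatment == "sufficient", ]
    kd <- key[rm$treatment == "deficient"]
    ks <- key[rm$treatment == "sufficient"]
    allk <- union(kd, ks)
    i <- match(allk, kd); j <- match(allk, ks)
    num <- def$mean[i]; nnum <- def$n[i]
    den <- suf$mean[j]; nden <- suf$n[j]
    ratio <- num / den
    ratio[is.na(i) | is.na(j) | nnum < min_reps | nden < min_reps |
          den == 0] <- NA_real_
    src <- ifelse(is.na(i), j + nrow(def), i)
    all <- rbind(def, suf)[src, ]
    data.frame(accession = all$accession, trait = all$trait, day = all$day,
               feature = featureName(all$trait, all$day), ratio = ratio,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-accession growth series of mean PLA
#'
#' @param tm A \linkS4class{TraitMatrix}.
#' @param accession,treatment which series to extract.
#' @param trait daily trait name (default `"PLA"`).
#' @return Named numeric vector of replicate-mean values, names = days,
#'   days strictly increasing.
#' @export
growthSeries <- function(tm, accession, treatment, trait = "PLA") {
    rm <- replicateMeans(tm)
    rm <- rm[rm$accession == accession & rm$treatment == treatment &
             rm$trait == trait & !is.na(rm$day), ]
    rm <- rm[order(rm$day), ]
    setNames(rm$mean, rm$day)
}

#' Daily relative growth rate
#'
#' Classical log-scale RGR: for each consecutive day pair,
#' `RGR_d = ln(PLA_d / PLA_(d-1))`, in day^-1. Non-positive values give
#' `NA` for the affected day.
#'
#' @param series named numeric vector of mean PLA, names = days.
#' @return Named numeric vector of daily RGR (named by the later day of
#'   each consecutive pair).
#' @export
dailyRGR <- function(series) {
    days <- as.integer(names(series))
    stopifnot(length(series) >= 2, !is.unsorted(days, strictly = TRUE))
    consec <- which(diff(days) == 1L)
    if (!length(consec)) stop("no consecutive day pairs in series")
    ratio <- series[consec + 1L] / series[consec]
    rgr <- ifelse(series[consec] > 0 & series[consec + 1L] > 0,
                  log(ratio), NA_real_)
    setNames(as.numeric(rgr), days[consec + 1L])
}

#' Interval relative growth rate
#'
#' `RGR_[a,b] = ln(PLA_b / PLA_a) / (b - a)`, in day^-1. Missing endpoints
#' give `NA`; degenerate intervals (a == b) are an error.
#'
#' @param series named numeric vector of mean PLA, names = days.
#' @param intervals list of `c(start_day, end_day)` pairs.
#' @return Numeric vector of interval RGRs named `"a-b"`.
#' @export
intervalRGR <- function(series, intervals) {
    days <- as.integer(names(series))
    vapply(intervals, function(iv) {
        a <- iv[1]; b <- iv[2]
        if (a == b) stop("degenerate interval (", a, ",", b, ")")
        ia <- match(a, days); ib <- match(b, days)
        if (is.na(ia) || is.na(ib)) return(NA_real_)
        if (series[ia] <= 0 || series[ib] <= 0) return(NA_real_)
        log(series[ib] / series[ia]) / (b - a)
    }, 0, USE.NAMES = FALSE) -> r
    setNames(r, vapply(intervals, function(iv) paste(iv, collapse = "-"), ""))
}

#' Slope of daily RGR over time
#'
#' Ordinary-least-squares slope of daily RGR against day (day^-2); more
#' negative means a faster RGR decline. Returns `NA` with fewer than three
#' non-missing points.
#'
#' @param daily named numeric vector of daily RGR, names = days.
#' @return Slope in day^-2, or `NA`.
#' @export
rgrSlope <- function(daily) {
    keep <- !is.na(daily)
    if (sum(keep) < 3) return(NA_real_)
    day <- as.numeric(names(daily))[keep]
    unname(coef(lm(daily[keep] ~ day))[2])
}

#' Range and fold-range of a positive trait vector
#'
#' @param values per-accession trait values, all > 0.
#' @return list with `min`, `max` and `fold = max/min` (report folds to
#'   two decimals in summaries).
#' @export
foldRange <- function(values) {
    values <- values[!is.na(values)]
    if (!length(values) || any(values <= 0))
        stop("fold range requires strictly positive values")
    list(min = min(values), max = max(values),
         fold = max(values) / min(values))
}

#' Pearson correlation with two-sided p-value
#'
#' Pairwise-complete product-moment correlation; p from the t distribution
#' with n - 2 df. Zero variance in either series gives `NA`.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p` and `n` (pairs used).
#' @export
pearsonR <- function(x, y) {
    stopifnot(length(x) == length(y))
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3) stop("need >= 3 complete pairs")
    if (sd(x) == 0 || sd(y) == 0)
        return(list(r = NA_real_, p = NA_real_, n = length(x)))
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Accession-level response features for profiling
#'
#' Builds the full feature table used downstream: deficiency:sufficiency
#' ratios of every measured trait (daily PLA by day, endpoint FW/DW and
#' root traits) plus ratios of daily RGRs and of the 9-12 / 13-16 day
#' interval RGRs, computed per accession from the treatment-mean PLA
#' series.
#'
#' @param tm A \linkS4class{TraitMatrix}.
#' @param min_reps minimum replicate count per ratio side.
#' @return data.frame `accession`, `trait`, `day`, `feature`, `ratio`.
#' @export
responseFeatures <- function(tm, min_reps = 3L) {
    base <- traitRatios(tm, min_reps = min_reps)
    accs <- unique(traitRecords(tm)$accession)
    rm_ <- replicateMeans(tm)
    rm_ <- rm_[rm_$trait == "PLA" & !is.na(rm_$day), ]
    series <- function(a, trt) {
        sub <- rm_[rm_$accession == a & rm_$treatment == trt, ]
        sub <- sub[order(sub$day), ]
        setNames(sub$mean, sub$day)
    }
    extra <- lapply(accs, function(a) {
        sd_ <- series(a, "deficient")
        ss <- series(a, "sufficient")
        if (length(sd_) < 2 || length(ss) < 2) return(NULL)
        rd <- dailyRGR(sd_); rs <- dailyRGR(ss)
        common <- intersect(names(rd), names(rs))
        rows <- data.frame(accession = a, trait = "RGR",
                           day = as.integer(common),
                           feature = sprintf("RGR_d%02d", as.integer(common)),
                           ratio = ifelse(rs[common] != 0,
                                          rd[common] / rs[common], NA_real_),
                           stringsAsFactors = FALSE)
        ivs <- list(c(9, 12), c(13, 16))
        have <- vapply(ivs, function(iv)
            all(as.character(iv) %in% names(sd_)) &&
            all(as.character(iv) %in% names(ss)), TRUE)
        if (any(have)) {
            id_ <- intervalRGR(sd_, ivs[have])
            is_ <- intervalRGR(ss, ivs[have])
            rows <- rbind(rows, data.frame(
                accession = a, trait = "RGRint", day = NA_integer_,
                feature = paste0("RGR_", names(id_)),
                ratio = ifelse(is_ != 0, id_ / is_, NA_real_),
                stringsAsFactors = FALSE))
        }
        rows
    })
    out <- rbind(base, do.call(rbind, extra))
    rownames(out) <- NULL
    out
}
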