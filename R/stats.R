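#' Pearson or Spearman correlation with p-value
#'
#' Pairwise-complete correlation between two vectors.  Pearson p-values come
#' from the usual t approximation on n - 2 degrees of freedom; Spearman
#' rank-transforms both vectors (ties receive average ranks) and applies the
#' same machinery, i.e. the large-sample approximation, never the exact
#' permutation null.  A constant vector gives an undefined-marked result.
#'
#' @param x,y paired numeric vectors.
#' @param method "pearson" or "spearman".
#' @return a list of class \code{CorrStat}: \code{method}, \code{r},
#'   \code{p}, \code{n} (complete pairs), \code{undefined}.
#' @examples
#' correlation(1:5, c(2, 1, 4, 3, 5), "spearman")$r  # 0.8
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    out <- list(method = method, r = NA_real_, p = NA_real_, n = n,
                undefined = FALSE)
    class(out) <- "CorrStat"
    if (n < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
        out$undefined <- TRUE
        return(out)
    }
    if (method == "spearman") {
        x <- rank(x); y <- rank(y)
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
            out$undefined <- TRUE
            return(out)
        }
    }
    r <- stats::cor(x, y)
    out$r <- r
    if (n >= 3L) {
        if (abs(r) >= 1) {
            out$p <- 0
        } else {
            tstat <- r * sqrt((n - 2) / (1 - r^2))
            out$p <- 2 * stats::pt(-abs(tstat), n - 2)
        }
    }
    out
}

#' @export
print.CorrStat <- function(x, ...) {
    cat(sprintf("%s correlation: r = %.4g, p = %.4g, n = %d%s\n",
                x$method, x$r, x$p, x$n,
                if (x$undefined) " [undefined]" else ""))
    invisible(x)
}

#' Mann-Whitney/Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney U test via the normal approximation with tie
#' correction and continuity correction (the approximation is used at every
#' n, so p-values are comparable across group sizes).
#'
#' @param x,y numeric values for the two groups.
#' @return a list: \code{statistic} (U for the first group), \code{p},
#'   \code{n1}, \code{n2}.
#' @export
rankSumTest <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) stop("both groups need at least one value")
    if (length(unique(c(x, y))) == 1L)  # fully tied: no evidence either way
        return(list(statistic = length(x) * length(y) / 2, p = 1,
                    n1 = length(x), n2 = length(y)))
    wt <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         n1 = length(x), n2 = length(y))
}

#' Filter features by standard deviation
#'
#' Retains features whose sample standard deviation (n - 1 denominator,
#' missing values dropped) is strictly greater than the threshold — the
#' probe-variability filter applied before expression heat maps.
#'
#' @param m expression matrix (features x samples).
#' @param threshold log2-units sd cutoff (strict >).
#' @return the filtered matrix.
#' @export
sdFilter <- function(m, threshold = 1) {
    if (ncol(m) < 2L) stop("need at least two samples")
    sds <- apply(m, 1L, stats::sd, na.rm = TRUE)
    m[!is.na(sds) & sds > threshold, , drop = FALSE]
}

#' Correlation-distance complete-linkage clustering of samples
#'
#' Clusters sample columns with distance 1 - Pearson R (computed over the
#' features with no missing values) and complete-linkage agglomeration; ties
#' are broken deterministically by sample order (hclust convention).  The
#' 2-cluster cut gives group labels to compare against the design.
#'
#' @param m expression matrix (features x samples).
#' @param k number of clusters for the cut.
#' @return a list: \code{hclust}, \code{leaf_order} (sample ids),
#'   \code{clusters} (named integer cut labels), \code{newick} (the
#'   dendrogram as a Newick string).
#' @export
hierarchicalCluster <- function(m, k = 2L) {
    if (ncol(m) < 2L) stop("need at least two samples")
    complete <- stats::complete.cases(m)
    if (sum(complete) < 3L)
        stop("fewer than 3 features without missing values")
    cc <- stats::cor(m[complete, , drop = FALSE])
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "complete")
    list(hclust = hc,
         leaf_order = colnames(m)[hc$order],
         clusters = stats::cutree(hc, k = k),
         newick = ape::write.tree(ape::as.phylo(hc)))
}
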