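#' Welch two-sample t-test
#'
#' Unequal-variance two-sided t-test with Welch-Satterthwaite degrees of
#' freedom, the test used for all ADC vs SCC group comparisons.  Missing
#' values are dropped per group first.  With fewer than 2 observed values in
#' either group the result is undefined-marked (all statistics \code{NA})
#' rather than an error, so matrix-wide testing never aborts.  When both
#' groups have zero variance the test degenerates: equal means give t = 0,
#' p = 1; unequal means give infinite t and p = 0, flagged degenerate.
#'
#' @param x,y numeric values for the two groups.
#' @return a list of class \code{welch_test}: \code{statistic} (t), \code{df}
#'   (fractional), \code{p}, \code{n1}, \code{n2}, \code{mean1}, \code{mean2},
#'   \code{degenerate}, \code{undefined}.
#' @examples
#' welchTTest(c(10, 11, 12), c(13, 14, 15))  # t = -3.674, df = 4
#' @export
welchTTest <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    out <- list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                n1 = length(x), n2 = length(y),
                mean1 = if (length(x)) mean(x) else NA_real_,
                mean2 = if (length(y)) mean(y) else NA_real_,
                degenerate = FALSE, undefined = FALSE)
    class(out) <- "welch_test"
    if (length(x) < 2L || length(y) < 2L) {
        out$undefined <- TRUE
        return(out)
    }
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) {
        out$degenerate <- TRUE
        if (mean(x) == mean(y)) {
            out$statistic <- 0; out$p <- 1
        } else {
            out$statistic <- sign(mean(x) - mean(y)) * Inf; out$p <- 0
        }
        return(out)
    }
    tt <- tryCatch(
        stats::t.test(x, y, var.equal = FALSE),
        error = function(e) NULL)
    if (is.null(tt)) {
        ## near-constant data that t.test refuses; apply the formulas directly
        se2 <- vx / length(x) + vy / length(y)
        tstat <- (mean(x) - mean(y)) / sqrt(se2)
        df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                       vy^2 / (length(y)^2 * (length(y) - 1)))
        out$statistic <- tstat; out$df <- df
        out$p <- 2 * stats::pt(-abs(tstat), df)
        out$degenerate <- TRUE
        return(out)
    }
    out$statistic <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- tt$p.value
    out
}

#' @export
print.welch_test <- function(x, ...) {
    cat(sprintf("Welch t-test: t = %.4g, df = %.4g, p = %.4g (n = %d, %d)%s\n",
                x$statistic, x$df, x$p, x$n1, x$n2,
                if (x$degenerate) " [degenerate]"
                else if (x$undefined) " [undefined]" else ""))
    invisible(x)
}

#' Log2 fold change between group means
#'
#' Fold change on the log2 scale, computed as log2(SCC/ADC) of geometric
#' means, i.e. the difference of mean log2 intensities.
#'
#' @param mean_scc,mean_adc mean log2 intensities of the two groups.
#' @return \code{mean_scc - mean_adc}.
#' @export
log2FoldChange <- function(mean_scc, mean_adc) mean_scc - mean_adc

#' Feature-wise differential expression
#'
#' Runs [welchTTest()] on every row of a log2 expression matrix, contrasting
#' the second group level against the first (so \code{log2fc} is
#' log2(group2/group1); with the default design, log2(SCC/ADC)).
#'
#' @param m log2 expression matrix (features x samples).
#' @param groups character vector of group labels, one per column.
#' @param levels optional length-2 character giving the (reference, alternate)
#'   order; default: order of first appearance.
#' @return a \code{data.frame} (class \code{DifferentialTable}) with columns
#'   \code{feature}, \code{mean_<ref>}, \code{mean_<alt>}, \code{log2fc},
#'   \code{t}, \code{df}, \code{p}, \code{called} (initialized \code{FALSE};
#'   see [callSignificant()]).
#' @export
differentialExpression <- function(m, groups, levels = NULL) {
    if (length(groups) != ncol(m))
        stop("groups must have one label per sample column")
    if (is.null(levels)) levels <- unique(as.character(groups))
    if (length(levels) != 2L)
        stop("differential analysis requires exactly two group levels")
    i1 <- which(groups == levels[1]); i2 <- which(groups == levels[2])
    res <- lapply(seq_len(nrow(m)), function(i)
        welchTTest(m[i, i2], m[i, i1]))  # alt vs ref
    m1 <- rowMeans(m[, i1, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(m[, i2, drop = FALSE], na.rm = TRUE)
    out <- data.frame(
        feature = rownames(m),
        mean_ref = m1, mean_alt = m2,
        log2fc = log2FoldChange(m2, m1),
        t = vapply(res, `[[`, 0, "statistic"),
        df = vapply(res, `[[`, 0, "df"),
        p = vapply(res, `[[`, 0, "p"),
        called = FALSE,
        row.names = NULL, stringsAsFactors = FALSE)
    names(out)[2:3] <- paste0("mean_", levels)
    out$log2fc[is.nan(out$log2fc)] <- NA_real_
    attr(out, "levels") <- levels
    class(out) <- c("DifferentialTable", "data.frame")
    out
}

#' Call differentially expressed features
#'
#' Marks a feature significant when p < \code{p_threshold} and, if
#' \code{use_fc}, the linear fold change exceeds \code{fc_linear_threshold}
#' in either direction (> 1.5 or < 1/1.5 = 0.6667 at the default).  All
#' inequalities are strict, and p-values are used as-is (no multiple-testing
#' adjustment); p-only mode (\code{use_fc = FALSE}) reproduces plain
#' "P < 0.05" counts.
#'
#' @param table a [differentialExpression()] result.
#' @param p_threshold p-value cutoff.
#' @param fc_linear_threshold linear fold-change cutoff (> 1).
#' @param use_fc apply the fold-change filter in addition to p.
#' @return the table with its \code{called} column set.
#' @export
callSignificant <- function(table, p_threshold = 0.05,
                            fc_linear_threshold = 1.5, use_fc = TRUE) {
    if (p_threshold <= 0 || fc_linear_threshold <= 0)
        stop("thresholds must be > 0")
    ok_p <- !is.na(table$p) & table$p < p_threshold
    if (use_fc) {
        fc <- 2^table$log2fc
        ok_fc <- !is.na(fc) & (fc > fc_linear_threshold |
                               fc < 1 / fc_linear_threshold)
        table$called <- ok_p & ok_fc
    } else {
        table$called <- ok_p
    }
    table
}
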