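#' Peptide quality filters
#'
#' Applies the peptide-level QC cascade: remove rows with posterior error
#' probability strictly above \code{pep_threshold}, reversed (decoy)
#' sequences, contaminant peptides, and rows with more missing reporter
#' intensities than the larger of the two group sizes.  A row failing several
#' rules is counted once, attributed to the first failing rule in the order
#' pep, reverse, contaminant, missingness, so reports are deterministic.
#'
#' @param pe a \linkS4class{PeptideExperiment}.
#' @param pep_threshold PEP cutoff; rows with \code{pep > pep_threshold} are
#'   removed (strict inequality: a row at exactly the threshold is kept).
#' @param max_missing maximum tolerated missing cells per row; default
#'   \code{max} of the group sizes (for a 3 vs 3 design, rows with more than
#'   3 of 6 missing are removed).
#' @return a list with \code{peptides} (the filtered
#'   \linkS4class{PeptideExperiment}) and \code{report}, a \code{FilterReport}
#'   list: \code{n_input}, per-rule removal counts (\code{removed_pep},
#'   \code{removed_reverse}, \code{removed_contaminant},
#'   \code{removed_missingness}), \code{retained}, and missing-cell totals
#'   before/after.
#' @examples
#' p <- simParams(n_proteins = 30, seed = 1)
#' pe <- simulatePeptideTable(generateGroundTruth(p), p)
#' filterPeptides(pe)$report
#' @export
filterPeptides <- function(pe, pep_threshold = 0.1, max_missing = NULL) {
    stopifnot(is(pe, "PeptideExperiment"))
    if (pep_threshold <= 0) stop("pep_threshold must be > 0")
    groups <- sampleGroups(pe)
    if (is.null(max_missing)) max_missing <- max(table(groups))
    x <- assay(pe, "intensity")
    n_missing <- rowSums(is.na(x))
    pep <- rowData(pe)$pep

    fail_pep <- !is.na(pep) & pep > pep_threshold
    fail_rev <- rowData(pe)$reverse
    fail_con <- rowData(pe)$contaminant
    fail_mis <- n_missing > max_missing
    ## first-rule attribution
    by_pep <- fail_pep
    by_rev <- fail_rev & !by_pep
    by_con <- fail_con & !by_pep & !by_rev
    by_mis <- fail_mis & !by_pep & !by_rev & !by_con
    keep <- !(by_pep | by_rev | by_con | by_mis)

    out <- pe[keep, ]
    report <- list(n_input = nrow(pe),
                   removed_pep = sum(by_pep),
                   removed_reverse = sum(by_rev),
                   removed_contaminant = sum(by_con),
                   removed_missingness = sum(by_mis),
                   retained = sum(keep),
                   missing_cells_before = sum(is.na(x)),
                   missing_cells_after = sum(is.na(x[keep, , drop = FALSE])),
                   pep_threshold = pep_threshold,
                   max_missing = as.integer(max_missing))
    if (!report$retained)
        warning("no peptides retained after filtering")
    list(peptides = out, report = report)
}

#' Log2-transform peptide intensities
#'
#' @param pe a \linkS4class{PeptideExperiment} (linear intensities) or a
#'   plain numeric matrix of positive values.
#' @return numeric matrix of log2 intensities (missing stays missing).
#' @export
log2Transform <- function(pe) {
    x <- if (is(pe, "PeptideExperiment")) assay(pe, "intensity") else
        as.matrix(pe)
    bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-positive intensity at feature '%s', sample '%s'",
                     rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
    log2(x)
}

#' Choose the reference sample for normalization
#'
#' Returns the sample whose mean over non-missing log2 values is closest to
#' the median of all samples' means; ties go to the earlier sample in column
#' order.  All-missing samples are excluded from candidacy with a warning.
#'
#' @param m log2 expression matrix (features x samples).
#' @return a sample id (column name).
#' @export
selectReferenceSample <- function(m) {
    if (ncol(m) < 1L) stop("need at least one sample")
    means <- colMeans(m, na.rm = TRUE)
    if (anyNA(means) || any(!is.finite(means))) {
        warning("excluding all-missing sample(s) from reference candidacy: ",
                paste(colnames(m)[!is.finite(means)], collapse = ", "))
        means <- means[is.finite(means)]
    }
    if (!length(means)) stop("no sample with observed values")
    target <- stats::median(means)
    names(means)[which.min(abs(means - target))]
}

#' Rank-invariant scaling to a reference sample
#'
#' A global log2 offset per sample, estimated iteratively from
#' rank-invariant features (in the spirit of iterative rank-order reference
#' normalization).  For each non-reference sample, over the features observed
#' in both that sample and the reference: features in the extreme
#' \code{trim} fraction of the reference intensity range are discarded, the
#' remaining features are kept when their rank displacement between sample
#' and reference is at most \code{rank_tol} of the feature count, and the
#' offset is the one-step Tukey biweight of the sample-minus-reference
#' differences over the kept set; the offset is subtracted and the procedure
#' repeats until the kept set stabilizes or \code{max_iter} is reached.  The
#' reference column is returned untouched.  With fewer than 20 common
#' features the offset falls back to the median difference, with a warning.
#'
#' @param m log2 expression matrix (features x samples).
#' @param reference reference sample id (see [selectReferenceSample()]).
#' @param trim fraction of features discarded at each intensity extreme.
#' @param rank_tol maximum |rank difference| / n for a feature to be kept.
#' @param max_iter iteration cap.
#' @return a list with \code{matrix} (normalized log2 values) and
#'   \code{offsets} (named per-sample log2 offsets that were subtracted;
#'   0 for the reference).
#' @export
normalizeToReference <- function(m, reference, trim = 0.05, rank_tol = 0.05,
                                 max_iter = 20L) {
    if (!reference %in% colnames(m)) stop("reference sample not in matrix")
    ref <- m[, reference]
    offsets <- setNames(numeric(ncol(m)), colnames(m))
    out <- m
    for (s in setdiff(colnames(m), reference)) {
        x <- m[, s]
        common <- which(!is.na(x) & !is.na(ref))
        n <- length(common)
        if (n < 20L) {
            warning(sprintf(
                "sample '%s': only %d features shared with reference; %s",
                s, n, "using median-difference offset"))
            off <- stats::median(x[common] - ref[common])
            if (!length(common) || is.na(off)) off <- 0
        } else {
            xr <- x[common]; rr <- ref[common]
            rank_ref <- rank(rr)
            lo <- trim * n; hi <- (1 - trim) * n
            in_core <- rank_ref > lo & rank_ref <= hi
            off <- 0
            kept_prev <- NULL
            for (iter in seq_len(max_iter)) {
                cur <- xr - off
                disp <- abs(rank(cur) - rank_ref) / n
                kept <- in_core & disp <= rank_tol
                if (!any(kept)) kept <- in_core
                off <- off + tukeyBiweight(cur[kept] - rr[kept])
                if (identical(kept, kept_prev)) break
                kept_prev <- kept
            }
        }
        offsets[s] <- off
        out[, s] <- x - off
    }
    list(matrix = out, offsets = offsets)
}
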