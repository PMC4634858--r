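#' Map peptides to all possible proteins
#'
#' Builds the many-to-many peptide/protein map with no razor (Occam)
#' assignment: every candidate accession of every peptide is retained, so a
#' protein whose peptides are all shared with a better-supported protein is
#' still quantified.  Peptides with an empty accession list are dropped with
#' a warning.
#'
#' @param pe a (filtered) \linkS4class{PeptideExperiment}.
#' @return an object of class \code{PeptideProteinMap}: a list with
#'   \code{pairs} (data.frame peptide, protein), \code{peptides_of} (named
#'   list protein -> peptide sequences), \code{parent_count} (named integer,
#'   parents per peptide).
#' @export
buildPeptideProteinMap <- function(pe) {
    stopifnot(is(pe, "PeptideExperiment"))
    prot <- peptideProteins(pe)
    npar <- lengths(prot)
    if (any(npar == 0L)) {
        warning(sum(npar == 0L),
                " peptide(s) with no protein accession dropped from the map")
    }
    keep <- npar > 0L
    seqs <- rownames(pe)[keep]
    plist <- as.list(prot[keep])
    pairs <- data.frame(
        peptide = rep.int(seqs, lengths(plist)),
        protein = unlist(plist, use.names = FALSE),
        stringsAsFactors = FALSE)
    pairs <- unique(pairs)
    out <- list(pairs = pairs,
                peptides_of = split(pairs$peptide, pairs$protein),
                parent_count = setNames(lengths(plist), seqs))
    class(out) <- "PeptideProteinMap"
    out
}

#' @export
print.PeptideProteinMap <- function(x, ...) {
    cat("PeptideProteinMap:", length(unique(x$pairs$peptide)), "peptides ->",
        length(x$peptides_of), "proteins (",
        sum(x$parent_count > 1L), "shared peptides )\n")
    invisible(x)
}

#' One-step Tukey biweight location estimate
#'
#' The robust location summary used to roll peptide log2 intensities up to a
#' protein intensity.  With M the median and S the (unscaled) median absolute
#' deviation of the values, each value gets u = (x - M) / (c * S + epsilon)
#' and weight (1 - u^2)^2 when |u| < 1, 0 otherwise; the estimate is the
#' weighted mean (one step, not iterated).  If every weight is zero the
#' median is returned.  The unscaled MAD and the defaults c = 5,
#' epsilon = 1e-4 follow the microarray summarization convention.
#'
#' @param x numeric values (log2 intensities); \code{NA} excluded first.
#' @param c biweight tuning constant.
#' @param epsilon small constant guarding against zero spread.
#' @return the biweight location (a single number within the range of x).
#' @examples
#' tukeyBiweight(c(10, 10.2, 10.4, 14))  # outlier gets weight 0
#' @export
tukeyBiweight <- function(x, c = 5, epsilon = 1e-4) {
    x <- x[!is.na(x)]
    if (!length(x)) stop("tukeyBiweight: no non-missing values")
    M <- stats::median(x)
    S <- stats::median(abs(x - M))
    u <- (x - M) / (c * S + epsilon)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    sw <- sum(w)
    if (sw == 0) M else sum(w * x) / sw
}

#' Roll peptide intensities up to protein intensities
#'
#' For each protein and sample, the protein log2 intensity is the one-step
#' Tukey biweight of the non-missing log2 intensities of all peptides mapped
#' to that protein (shared peptides contribute their full value to every
#' parent; no apportionment).  A protein intensity is missing iff no mapped
#' peptide was observed in that sample.
#'
#' @param m log2 peptide expression matrix (features x samples).
#' @param map a [buildPeptideProteinMap()] result.
#' @param c,epsilon biweight parameters, see [tukeyBiweight()].
#' @return a \linkS4class{ProteinQuant}.
#' @export
rollupProteins <- function(m, map, c = 5, epsilon = 1e-4) {
    stopifnot(inherits(map, "PeptideProteinMap"))
    prots <- sort(names(map$peptides_of))
    ns <- ncol(m)
    out <- matrix(NA_real_, length(prots), ns,
                  dimnames = list(prots, colnames(m)))
    n_pep <- integer(length(prots))
    n_unique <- integer(length(prots))
    all_missing <- character(0)
    for (i in seq_along(prots)) {
        peps <- intersect(map$peptides_of[[prots[i]]], rownames(m))
        n_pep[i] <- length(peps)
        n_unique[i] <- sum(map$parent_count[peps] == 1L)
        if (!n_pep[i]) { all_missing <- c(all_missing, prots[i]); next }
        sub <- m[peps, , drop = FALSE]
        for (j in seq_len(ns)) {
            v <- sub[, j]
            v <- v[!is.na(v)]
            if (length(v)) out[i, j] <- tukeyBiweight(v, c, epsilon)
        }
        if (all(is.na(out[i, ]))) all_missing <- c(all_missing, prots[i])
    }
    if (length(all_missing))
        warning(length(all_missing),
                " protein(s) with no observed value in any sample")
    keep <- n_pep > 0L
    cd <- DataFrame(channel = rep(NA_character_, ns),
                    group = rep(NA_character_, ns),
                    row.names = colnames(m))
    new("ProteinQuant", SummarizedExperiment(
        assays = SimpleList(log2intensity = out[keep, , drop = FALSE]),
        rowData = DataFrame(n_peptides = n_pep[keep],
                            n_unique_peptides = n_unique[keep],
                            single_peptide = n_pep[keep] == 1L,
                            row.names = prots[keep]),
        colData = cd))
}

#' Annotate a ProteinQuant with a sample design
#'
#' @param pq a \linkS4class{ProteinQuant}.
#' @param design a design data.frame ([sampleDesign()]).
#' @return the annotated \linkS4class{ProteinQuant}.
#' @export
setProteinDesign <- function(pq, design) {
    design <- validateDesign(design)
    stopifnot(setequal(colnames(pq), design$sample_id))
    design <- design[match(colnames(pq), design$sample_id), ]
    colData(pq)$channel <- design$channel
    colData(pq)$group <- design$group
    pq
}

#' MaxQuant-style razor summation (benchmark comparator)
#'
#' The summation rollup this pipeline argues against, provided for
#' benchmarking: each shared peptide is assigned to the single parent with
#' the most mapped peptides (razor rule; ties broken by the lexicographically
#' smallest accession), and a protein's intensity per sample is the sum of
#' its assigned peptides' linear intensities over observed values (missing
#' peptides simply drop out of the sum, which is what deflates it).
#'
#' @param m log2 peptide expression matrix.
#' @param map a [buildPeptideProteinMap()] result.
#' @return protein x sample matrix of linear-scale summed intensities
#'   (\code{NA} where no assigned peptide was observed).
#' @export
rollupRazorSum <- function(m, map) {
    stopifnot(inherits(map, "PeptideProteinMap"))
    counts <- lengths(map$peptides_of)
    pairs <- map$pairs[map$pairs$peptide %in% rownames(m), ]
    ## razor assignment: protein with most peptides, then alphabetical
    ord <- order(pairs$peptide, -counts[pairs$protein], pairs$protein)
    pairs <- pairs[ord, ]
    assigned <- pairs[!duplicated(pairs$peptide), ]
    lin <- 2^m
    prots <- sort(unique(assigned$protein))
    out <- matrix(NA_real_, length(prots), ncol(m),
                  dimnames = list(prots, colnames(m)))
    for (i in seq_along(prots)) {
        peps <- assigned$peptide[assigned$protein == prots[i]]
        sub <- lin[peps, , drop = FALSE]
        obs <- colSums(!is.na(sub)) > 0L
        s <- colSums(sub, na.rm = TRUE)
        s[!obs] <- NA_real_
        out[i, ] <- s
    }
    out
}
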