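#' Match microarray probes to quantified proteins
#'
#' Restricts to proteins present in both the protein quantification and the
#' probe map (intersection rule), then, for proteins with several candidate
#' probes, selects the probe with the highest mean expression over
#' non-missing values; exact ties go to the lexicographically smallest probe
#' id, so the choice is invariant to probe row order.
#'
#' @param exprs probe x sample log2 expression matrix.
#' @param map data.frame with \code{probe_id}, \code{protein_id} (see
#'   [readMappingTable()]).
#' @param proteins a \linkS4class{ProteinQuant} or a protein x sample log2
#'   matrix.
#' @return an object of class \code{MatchedPairs}: a list with
#'   \code{protein}, \code{probe} (parallel character vectors),
#'   \code{gene_profile} and \code{protein_profile} (matched-row matrices
#'   over the shared samples).
#' @export
matchProbesToProteins <- function(exprs, map, proteins) {
    pm <- if (is(proteins, "ProteinQuant")) assay(proteins, "log2intensity")
          else as.matrix(proteins)
    samples <- intersect(colnames(exprs), colnames(pm))
    if (!length(samples)) stop("no shared samples between arrays")
    map <- map[map$probe_id %in% rownames(exprs) &
               map$protein_id %in% rownames(pm), , drop = FALSE]
    if (!nrow(map)) stop("empty probe/protein intersection")
    probe_mean <- rowMeans(exprs, na.rm = TRUE)
    ## highest mean, ties to smallest probe id
    ord <- order(map$protein_id, -probe_mean[map$probe_id], map$probe_id)
    map <- map[ord, ]
    chosen <- map[!duplicated(map$protein_id), ]
    out <- list(protein = chosen$protein_id, probe = chosen$probe_id,
                gene_profile = exprs[chosen$probe_id, samples, drop = FALSE],
                protein_profile = pm[chosen$protein_id, samples,
                                     drop = FALSE])
    rownames(out$gene_profile) <- chosen$protein_id
    class(out) <- "MatchedPairs"
    out
}

#' @export
print.MatchedPairs <- function(x, ...) {
    cat("MatchedPairs:", length(x$protein), "protein/probe pairs over",
        ncol(x$gene_profile), "samples\n")
    invisible(x)
}

#' Global (pooled) gene-protein concordance
#'
#' Pools every (gene value, protein value) point across all matched pairs and
#' samples and computes Pearson and Spearman correlations — the
#' all-observations view of mRNA-protein agreement.
#'
#' @param pairs a [matchProbesToProteins()] result.
#' @return a list with \code{pearson} and \code{spearman}
#'   [correlation()] results.
#' @export
globalConcordance <- function(pairs) {
    g <- as.vector(pairs$gene_profile)
    p <- as.vector(pairs$protein_profile)
    list(pearson = correlation(g, p, "pearson"),
         spearman = correlation(g, p, "spearman"))
}

#' Per-pair gene-protein concordance
#'
#' Correlates each matched gene/protein pair across samples (both methods).
#' The mean correlation includes all positive and negative values; pairs with
#' a constant profile are undefined-marked and excluded from the mean with a
#' recorded count.  Also counts pairs significantly concordant at
#' p < \code{p_threshold} and r > \code{r_threshold} (both strict), per
#' method.
#'
#' @param pairs a [matchProbesToProteins()] result.
#' @param p_threshold,r_threshold significance and correlation cutoffs.
#' @return a list of class \code{ConcordanceReport}: \code{per_pair}
#'   (data.frame protein, probe, pearson_r/p, spearman_r/p),
#'   \code{mean_pearson_r}, \code{mean_spearman_r}, \code{n_pairs},
#'   \code{n_undefined}, \code{n_sig_pearson}, \code{n_sig_spearman}.
#' @export
perPairConcordance <- function(pairs, p_threshold = 0.05,
                               r_threshold = 0.5) {
    n <- length(pairs$protein)
    pr <- pp <- sr <- sp <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        cs <- correlation(pairs$gene_profile[i, ], pairs$protein_profile[i, ],
                          "pearson")
        pr[i] <- cs$r; pp[i] <- cs$p
        cs <- correlation(pairs$gene_profile[i, ], pairs$protein_profile[i, ],
                          "spearman")
        sr[i] <- cs$r; sp[i] <- cs$p
    }
    per_pair <- data.frame(protein = pairs$protein, probe = pairs$probe,
                           pearson_r = pr, pearson_p = pp,
                           spearman_r = sr, spearman_p = sp,
                           stringsAsFactors = FALSE)
    out <- list(per_pair = per_pair,
                mean_pearson_r = mean(pr, na.rm = TRUE),
                mean_spearman_r = mean(sr, na.rm = TRUE),
                n_pairs = n,
                n_undefined = sum(is.na(pr)),
                n_sig_pearson = sum(!is.na(pp) & pp < p_threshold &
                                    !is.na(pr) & pr > r_threshold),
                n_sig_spearman = sum(!is.na(sp) & sp < p_threshold &
                                     !is.na(sr) & sr > r_threshold))
    class(out) <- "ConcordanceReport"
    out
}

#' @export
print.ConcordanceReport <- function(x, ...) {
    cat(sprintf(
        "ConcordanceReport: %d pairs (%d undefined); mean R = %.3f, mean rho = %.3f; significant: %d (Pearson), %d (Spearman)\n",
        x$n_pairs, x$n_undefined, x$mean_pearson_r, x$mean_spearman_r,
        x$n_sig_pearson, x$n_sig_spearman))
    invisible(x)
}

#' Venn region counts (and direction agreement) for 2-3 feature sets
#'
#' Computes exclusive and intersection region counts for two or three labeled
#' id sets.  When per-set log2 fold changes are supplied, ids shared by a set
#' pair are split into same-direction and opposite-direction counts by the
#' sign of their fold changes.
#'
#' @param sets named list of 2 or 3 character vectors (duplicates ignored).
#' @param log2fc optional named list (same names) of named numeric vectors
#'   (id -> log2 fold change).
#' @return a list of class \code{OverlapReport}: \code{regions} (named
#'   counts, e.g. \code{"A"}, \code{"A&B"}, ...), \code{union_size},
#'   \code{set_sizes}, and, with fold changes, \code{direction}: per set
#'   pair, \code{shared}, \code{same_direction}, \code{opposite}.
#' @export
overlapSets <- function(sets, log2fc = NULL) {
    if (!length(names(sets)) || any(!nzchar(names(sets))))
        stop("sets must be named")
    if (!length(sets) %in% 2:3) stop("2 or 3 sets supported")
    sets <- lapply(sets, unique)
    ids <- unique(unlist(sets, use.names = FALSE))
    memb <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
    if (!is.matrix(memb)) memb <- matrix(memb, nrow = length(ids))
    key <- apply(memb, 1L, function(z)
        paste(names(sets)[z], collapse = "&"))
    all_keys <- unlist(lapply(seq_along(sets), function(k)
        utils::combn(names(sets), k, paste, collapse = "&", simplify = TRUE)))
    regions <- setNames(integer(length(all_keys)), all_keys)
    tab <- table(key)
    regions[names(tab)] <- as.integer(tab)
    out <- list(regions = regions, union_size = length(ids),
                set_sizes = lengths(sets))
    if (!is.null(log2fc)) {
        prs <- utils::combn(names(sets), 2L, simplify = FALSE)
        out$direction <- lapply(setNames(prs, vapply(prs, paste, "",
                                                     collapse = "&")),
            function(pr) {
                shared <- intersect(sets[[pr[1]]], sets[[pr[2]]])
                a <- log2fc[[pr[1]]][shared]; b <- log2fc[[pr[2]]][shared]
                same <- sum(sign(a) == sign(b), na.rm = TRUE)
                list(shared = length(shared), same_direction = same,
                     opposite = length(shared) - same)
            })
    }
    class(out) <- "OverlapReport"
    out
}

#' Strip a peptide sequence for cross-study matching
#'
#' Uppercases and removes modification annotations (parenthesized or
#' bracketed tags, underscores and other punctuation).  Isoleucine and
#' leucine are kept distinct.
#'
#' @param s character vector of peptide sequences.
#' @return stripped sequences.
#' @export
stripSequence <- function(s) {
    s <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", s)
    gsub("[^A-Z0-9]", "", toupper(s))
}

#' Compare proteomic studies
#'
#' Mirrors the dataset-summary comparison of multi-study proteomics: per
#' study, unique peptide/protein counts, missing-intensity count and
#' fraction, mean peptide length, mean peptides per protein, single-peptide
#' protein count, and differential counts at P < 0.05 / 0.01 / 0.001 plus the
#' fold-change-filtered count; pairwise, the peptide-sequence overlap
#' (uppercase, modifications stripped, I distinct from L), Pearson and
#' Spearman correlation of mean log2 intensities over shared peptides, a
#' rank-sum test of peptide lengths, and differential overlap with direction
#' agreement.
#'
#' @param studies named list (>= 2) of lists, each with \code{peptides} (a
#'   \linkS4class{PeptideExperiment}) and \code{differential} (a
#'   [differentialExpression()] table, fold changes per protein).
#' @param fc_linear_threshold fold-change cutoff for the filtered DE count.
#' @return a list of class \code{CrossStudyReport}: \code{per_study}
#'   (data.frame, one row per study) and \code{pairwise} (list per study
#'   pair: \code{n_shared_peptides}, \code{intensity_pearson_r},
#'   \code{intensity_spearman_r}, \code{length_ranksum_p},
#'   \code{de_overlap}, \code{de_same_direction}, \code{de_opposite}).
#' @export
crossStudyCompare <- function(studies, fc_linear_threshold = 1.5) {
    if (length(studies) < 2L) stop("need at least two studies")
    if (is.null(names(studies))) names(studies) <- paste0("study", seq_along(studies))
    per <- lapply(names(studies), function(nm) {
        st <- studies[[nm]]
        pe <- st$peptides
        x <- assay(pe, "intensity")
        map <- suppressWarnings(buildPeptideProteinMap(pe))
        counts <- lengths(map$peptides_of)
        dt <- st$differential
        data.frame(
            study = nm,
            n_peptides = nrow(pe),
            n_proteins = length(counts),
            missing_cells = sum(is.na(x)),
            missing_fraction = mean(is.na(x)),
            mean_peptide_length = mean(nchar(stripSequence(rownames(pe)))),
            mean_peptides_per_protein = mean(counts),
            n_single_peptide_proteins = sum(counts == 1L),
            de_p05 = sum(dt$p < 0.05, na.rm = TRUE),
            de_p01 = sum(dt$p < 0.01, na.rm = TRUE),
            de_p001 = sum(dt$p < 0.001, na.rm = TRUE),
            de_p05_fc = sum(callSignificant(
                dt, 0.05, fc_linear_threshold, TRUE)$called),
            stringsAsFactors = FALSE)
    })
    per_study <- do.call(rbind, per)
    prs <- utils::combn(names(studies), 2L, simplify = FALSE)
    pairwise <- lapply(setNames(prs, vapply(prs, paste, "", collapse = " vs ")),
        function(pr) {
            a <- studies[[pr[1]]]; b <- studies[[pr[2]]]
            sa <- stripSequence(rownames(a$peptides))
            sb <- stripSequence(rownames(b$peptides))
            shared <- intersect(sa, sb)
            ma <- rowMeans(log2Transform(a$peptides), na.rm = TRUE)[
                match(shared, sa)]
            mb <- rowMeans(log2Transform(b$peptides), na.rm = TRUE)[
                match(shared, sb)]
            da <- callSignificant(a$differential, 0.05, fc_linear_threshold)
            db <- callSignificant(b$differential, 0.05, fc_linear_threshold)
            de_a <- da$feature[da$called]; de_b <- db$feature[db$called]
            de_shared <- intersect(de_a, de_b)
            fa <- setNames(da$log2fc, da$feature)[de_shared]
            fb <- setNames(db$log2fc, db$feature)[de_shared]
            same <- sum(sign(fa) == sign(fb), na.rm = TRUE)
            list(n_shared_peptides = length(shared),
                 intensity_pearson_r =
                     correlation(ma, mb, "pearson")$r,
                 intensity_spearman_r =
                     correlation(ma, mb, "spearman")$r,
                 length_ranksum_p = rankSumTest(
                     nchar(sa), nchar(sb))$p,
                 de_overlap = length(de_shared),
                 de_same_direction = same,
                 de_opposite = length(de_shared) - same)
        })
    out <- list(per_study = per_study, pairwise = pairwise)
    class(out) <- "CrossStudyReport"
    out
}

#' @export
print.CrossStudyReport <- function(x, ...) {
    cat("CrossStudyReport over", nrow(x$per_study), "studies\n")
    print(x$per_study)
    invisible(x)
}
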