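#' Pipeline run configuration
#'
#' Collects every threshold the pipeline applies, with the study's published
#' defaults: PEP filter at 0.1, significance level 0.05 without
#' multiple-testing adjustment, linear fold-change cutoff 1.5 (i.e. > 1.5 or
#' < 0.6667), concordance cutoff R > 0.5, probe sd filter > 1 log2 unit.
#'
#' @param pep_threshold PEP filter cutoff (rows with PEP strictly above are
#'   removed).
#' @param p_threshold significance level.
#' @param fc_linear_threshold linear fold-change cutoff.
#' @param corr_r_threshold per-pair correlation cutoff for "significantly
#'   concordant" counts.
#' @param sd_probe_threshold probe sd cutoff (log2 units) for the gene
#'   clustering stage.
#' @param max_missing missingness filter cutoff; \code{NULL} = larger of the
#'   two group sizes.
#' @param normalization \code{"rank_order_scale"} (default) or \code{"none"}.
#' @param use_fc apply the fold-change filter when calling differential
#'   proteins/genes.
#' @param seed integer seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return a validated list of class \code{RunConfig}.
#' @export
runConfig <- function(pep_threshold = 0.1, p_threshold = 0.05,
                      fc_linear_threshold = 1.5, corr_r_threshold = 0.5,
                      sd_probe_threshold = 1.0, max_missing = NULL,
                      normalization = c("rank_order_scale", "none"),
                      use_fc = TRUE, seed = 1L) {
    normalization <- match.arg(normalization)
    cfg <- list(pep_threshold = pep_threshold, p_threshold = p_threshold,
                fc_linear_threshold = fc_linear_threshold,
                corr_r_threshold = corr_r_threshold,
                sd_probe_threshold = sd_probe_threshold,
                max_missing = max_missing, normalization = normalization,
                use_fc = isTRUE(use_fc), seed = as.integer(seed))
    thr <- c(pep_threshold = pep_threshold, p_threshold = p_threshold,
             fc_linear_threshold = fc_linear_threshold,
             corr_r_threshold = corr_r_threshold,
             sd_probe_threshold = sd_probe_threshold)
    if (any(!is.finite(thr)) || any(thr <= 0))
        stop("all thresholds must be > 0: ",
             paste(names(thr)[!is.finite(thr) | thr <= 0], collapse = ", "))
    class(cfg) <- "RunConfig"
    cfg
}

stageTry <- function(name, expr)
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE))

partitionMatchesDesign <- function(clusters, groups) {
    length(unique(clusters)) == length(unique(groups)) &&
        all(vapply(split(clusters, groups),
                   function(z) length(unique(z)) == 1L, TRUE))
}

#' Run the full proteogenomic pipeline
#'
#' Orchestrates filter, log2 transform, reference normalization, biweight
#' protein rollup, Welch differential testing, protein clustering and, when
#' microarray inputs are given, probe matching, concordance, gene
#' differential testing, probe sd-filtered gene clustering and gene/protein
#' overlap.  Every intermediate table is written as TSV and all counts land
#' in a machine-readable JSON report; the run is deterministic, so identical
#' inputs and config give byte-identical outputs.
#'
#' @param config a [runConfig()].
#' @param peptides path to the peptide TSV (see [readPeptideTable()]).
#' @param design path to the sample design TSV.
#' @param exprs,map optional paths to the probe expression and
#'   probe-to-protein mapping TSVs; both or neither.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the report list (also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config, peptides, design, exprs = NULL, map = NULL,
                        out_dir) {
    stopifnot(inherits(config, "RunConfig"))
    if (xor(is.null(exprs), is.null(map)))
        stop("supply both 'exprs' and 'map', or neither")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)

    des <- stageTry("read", readSampleDesign(design))
    pe <- stageTry("read", readPeptideTable(peptides, des))
    flt <- stageTry("filter",
                    filterPeptides(pe, config$pep_threshold,
                                   config$max_missing))
    writePeptideTable(flt$peptides, file.path(out_dir,
                                              "filtered_peptides.tsv"))
    lm <- stageTry("log2", log2Transform(flt$peptides))
    if (config$normalization == "rank_order_scale") {
        nrm <- stageTry("normalize", {
            ref <- selectReferenceSample(lm)
            c(normalizeToReference(lm, ref), list(reference = ref))
        })
    } else {
        nrm <- list(matrix = lm,
                    offsets = setNames(numeric(ncol(lm)), colnames(lm)),
                    reference = NA_character_)
    }
    writeExpressionMatrix(nrm$matrix,
                          file.path(out_dir, "normalized_peptides.tsv"),
                          id_col = "sequence")
    pq <- stageTry("rollup", {
        ppm <- buildPeptideProteinMap(flt$peptides)
        setProteinDesign(rollupProteins(nrm$matrix, ppm), des)
    })
    pmat <- assay(pq, "log2intensity")
    writeExpressionMatrix(pmat, file.path(out_dir, "proteins.tsv"),
                          id_col = "protein")
    writeTSV(data.frame(protein = rownames(pq),
                        n_peptides = nPeptides(pq),
                        n_unique_peptides = nUniquePeptides(pq),
                        single_peptide = isSinglePeptide(pq)),
             file.path(out_dir, "protein_metadata.tsv"))

    groups <- sampleGroups(pq)
    levels <- unique(des$group)
    dt <- stageTry("differential", callSignificant(
        differentialExpression(pmat, groups, levels),
        config$p_threshold, config$fc_linear_threshold, config$use_fc))
    writeTSV(formatDifferential(dt),
             file.path(out_dir, "differential_proteins.tsv"))

    pclust <- stageTry("cluster", tryCatch(
        hierarchicalCluster(pmat),
        error = function(e) NULL))
    if (!is.null(pclust))
        writeLines(pclust$newick,
                   file.path(out_dir, "protein_dendrogram.nwk"))

    report <- list(
        config = unclass(config)[setdiff(names(config), "max_missing")],
        max_missing = flt$report$max_missing,
        reference_sample = nrm$reference,
        normalization_offsets = as.list(nrm$offsets),
        filter = flt$report,
        proteins = list(
            n_quantified = nrow(pq),
            n_single_peptide = sum(isSinglePeptide(pq)),
            frac_single_peptide = mean(isSinglePeptide(pq)),
            mean_peptides_per_protein = mean(nPeptides(pq))),
        differential_proteins = list(
            n_p05 = sum(dt$p < config$p_threshold, na.rm = TRUE),
            n_called = sum(dt$called)),
        protein_clustering = list(
            available = !is.null(pclust),
            leaf_order = if (is.null(pclust)) character(0) else
                pclust$leaf_order,
            two_cut_matches_design = if (is.null(pclust)) NA else
                partitionMatchesDesign(pclust$clusters, groups)))

    if (!is.null(exprs)) {
        intg <- stageTry("integrate", {
            em <- readExpressionMatrix(exprs)
            pmap <- readMappingTable(map)
            pairs <- matchProbesToProteins(em, pmap, pq)
            gd <- callSignificant(
                differentialExpression(
                    pairs$gene_profile,
                    groups[colnames(pairs$gene_profile)], levels),
                config$p_threshold, config$fc_linear_threshold,
                config$use_fc)
            gclust <- tryCatch(
                hierarchicalCluster(
                    sdFilter(em, config$sd_probe_threshold)),
                error = function(e) NULL)
            list(em = em, pairs = pairs, gd = gd, gclust = gclust,
                 glob = globalConcordance(pairs),
                 per = perPairConcordance(pairs, config$p_threshold,
                                          config$corr_r_threshold))
        })
        writeTSV(intg$per$per_pair,
                 file.path(out_dir, "concordance_per_pair.tsv"))
        writeTSV(formatDifferential(intg$gd),
                 file.path(out_dir, "differential_genes.tsv"))
        ## gene/protein differential overlap at P < threshold, as-printed
        dtp <- callSignificant(dt, config$p_threshold, use_fc = FALSE)
        gdp <- callSignificant(intg$gd, config$p_threshold, use_fc = FALSE)
        ov <- overlapSets(
            list(protein = dtp$feature[dtp$called],
                 gene = gdp$feature[gdp$called]),
            log2fc = list(protein = setNames(dtp$log2fc, dtp$feature),
                          gene = setNames(gdp$log2fc, gdp$feature)))
        report$integration <- list(
            n_probes = nrow(intg$em),
            n_matched_pairs = intg$per$n_pairs,
            global_pearson_r = intg$glob$pearson$r,
            global_pearson_p = intg$glob$pearson$p,
            global_spearman_r = intg$glob$spearman$r,
            global_spearman_p = intg$glob$spearman$p,
            mean_pair_pearson_r = intg$per$mean_pearson_r,
            mean_pair_spearman_r = intg$per$mean_spearman_r,
            n_pairs_undefined = intg$per$n_undefined,
            n_sig_pearson = intg$per$n_sig_pearson,
            n_sig_spearman = intg$per$n_sig_spearman,
            differential_genes = list(
                n_p05 = sum(intg$gd$p < config$p_threshold, na.rm = TRUE),
                n_called = sum(intg$gd$called)),
            de_overlap = list(
                protein_only = unname(ov$regions["protein"]),
                gene_only = unname(ov$regions["gene"]),
                both = unname(ov$regions["protein&gene"]),
                same_direction =
                    ov$direction[["protein&gene"]]$same_direction,
                opposite = ov$direction[["protein&gene"]]$opposite),
            gene_clustering = list(
                available = !is.null(intg$gclust),
                two_cut_matches_design = if (is.null(intg$gclust)) NA else
                    partitionMatchesDesign(
                        intg$gclust$clusters,
                        groups[names(intg$gclust$clusters)])))
    }

    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    invisible(report)
}

formatDifferential <- function(dt) {
    out <- dt
    for (j in which(vapply(out, is.numeric, TRUE)))
        out[[j]] <- fmtNum(out[[j]])
    out
}
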