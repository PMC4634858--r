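#' Simulation parameters for synthetic 6-plex TMT studies
#'
#' Bundles every knob of the synthetic-data generator.  The defaults emulate
#' the 3 vs 3 lung ADC/SCC TMT study design at desk scale: six reporter
#' channels (126-131), ~7 peptides per protein with enough dispersion to give
#' roughly one fifth single-peptide proteins, reporter-ion intensities around
#' 2^20 with ~0.1\% intensity-dependent (MNAR) missingness, low PEP scores for
#' genuine peptides and high scores for decoys, and a matched microarray whose
#' gene profiles correlate with protein profiles at a tunable level.
#'
#' @param n_proteins number of genuine proteins.
#' @param peptides_per_protein length-2 numeric \code{c(mean, dispersion)}:
#'   peptide counts are \code{1 + NegBinomial(mu = mean - 1, size =
#'   dispersion)} (minimum 1).  After shared peptides are added, the defaults
#'   give ~7 mapped peptides per protein and ~20\% single-peptide proteins,
#'   typical of deep TMT studies.
#' @param frac_shared proportion of peptides that map to a second, randomly
#'   chosen parent protein (the protein-inference ambiguity).
#' @param frac_de proportion of proteins with a true group effect; the
#'   realized count is \code{round(frac_de * n_proteins)}.
#' @param de_log2fc absolute true effect size in log2 units; the sign of each
#'   effect is drawn at random.
#' @param protein_baseline length-2 \code{c(mean, sd)} of per-protein baseline
#'   log2 abundance.
#' @param bio_sd per-protein, per-sample biological variability (log2 sd).
#'   Default 0: true abundance is exactly baseline + effect + loading.  Set
#'   > 0 to emulate tissue heterogeneity (needed for non-degenerate
#'   per-protein abundance profiles, e.g. in concordance studies).
#' @param peptide_efficiency_sd log2 sd of per-peptide ionization/labeling
#'   efficiency (constant across channels, so it cancels in fold changes).
#' @param channel_noise_sd per-cell measurement noise (log2 sd).
#' @param sample_loading_offsets per-sample log2 loading shifts (length
#'   \code{2 * n_samples_per_group}); \code{NULL} = all zero.
#' @param missingness length-2 \code{c(alpha, beta)} of the logistic MNAR
#'   model: a cell of log2 intensity x is missing with probability
#'   \code{plogis(alpha - beta * x)}.  \code{beta = 0} gives MCAR at rate
#'   \code{plogis(alpha)}.  The default yields ~0.1\% missing cells at the
#'   default baseline (reporter-ion-like).
#' @param frac_decoy,frac_contaminant decoy (reversed-sequence) and
#'   contaminant rows added, as proportions of the genuine peptide count.
#' @param pep_true length-2 Beta shape parameters for PEP scores of genuine
#'   (and contaminant) peptides; the default has mean ~0.006.
#' @param pep_decoy length-2 Beta shapes for decoy PEP, rescaled into
#'   (0.1, 1) so decoys concentrate above the 0.1 filter threshold.
#' @param probes_per_gene_mean mean probes per gene; counts are
#'   \code{1 + Poisson(mean - 1)}.
#' @param probes_per_gene_model \code{"poisson"} (default) or \code{"fixed"}
#'   (every gene gets exactly \code{round(probes_per_gene_mean)} probes).
#' @param gene_protein_corr construction correlation rho in [-1, 1] between a
#'   gene's latent expression profile and its protein's standardized abundance
#'   profile.
#' @param array_noise_sd per-cell microarray noise (log2 sd).
#' @param probe_affinity_sd sd of the per-probe constant affinity offset.
#' @param gene_baseline mean log2 expression of the array.
#' @param n_samples_per_group samples per group (3 reproduces the 6-plex
#'   3 ADC vs 3 SCC layout).
#' @param seed integer seed; the generator is fully deterministic given the
#'   parameter set.
#' @return an object of class \code{SimParams} (a validated list).
#' @seealso [simParamsTMT()], [simParamsLabelFree()], [generateGroundTruth()]
#' @examples
#' p <- simParams(n_proteins = 50, seed = 7)
#' truth <- generateGroundTruth(p)
#' @export
simParams <- function(n_proteins = 1000,
                      peptides_per_protein = c(mean = 6.5, dispersion = 0.32),
                      frac_shared = 0.1,
                      frac_de = 0.1,
                      de_log2fc = 2,
                      protein_baseline = c(mean = 20, sd = 2),
                      bio_sd = 0,
                      peptide_efficiency_sd = 0.5,
                      channel_noise_sd = 0.25,
                      sample_loading_offsets = NULL,
                      missingness = c(alpha = 3.0932, beta = 0.5),
                      frac_decoy = 0.05,
                      frac_contaminant = 0.02,
                      pep_true = c(0.3, 50),
                      pep_decoy = c(2, 2),
                      probes_per_gene_mean = 2,
                      probes_per_gene_model = c("poisson", "fixed"),
                      gene_protein_corr = 0.35,
                      array_noise_sd = 0.3,
                      probe_affinity_sd = 1,
                      gene_baseline = 8,
                      n_samples_per_group = 3,
                      seed = 1) {
    p <- list(n_proteins = as.integer(n_proteins),
              peptides_per_protein = unname(peptides_per_protein),
              frac_shared = frac_shared, frac_de = frac_de,
              de_log2fc = de_log2fc,
              protein_baseline = unname(protein_baseline),
              bio_sd = bio_sd,
              peptide_efficiency_sd = peptide_efficiency_sd,
              channel_noise_sd = channel_noise_sd,
              sample_loading_offsets = sample_loading_offsets,
              missingness = unname(missingness),
              frac_decoy = frac_decoy, frac_contaminant = frac_contaminant,
              pep_true = unname(pep_true), pep_decoy = unname(pep_decoy),
              probes_per_gene_mean = probes_per_gene_mean,
              probes_per_gene_model = match.arg(probes_per_gene_model),
              gene_protein_corr = gene_protein_corr,
              array_noise_sd = array_noise_sd,
              probe_affinity_sd = probe_affinity_sd,
              gene_baseline = gene_baseline,
              n_samples_per_group = as.integer(n_samples_per_group),
              seed = as.integer(seed))
    class(p) <- "SimParams"
    validateSimParams(p)
}

validateSimParams <- function(p) {
    stopifnot(inherits(p, "SimParams"))
    if (p$n_proteins < 1L) stop("n_proteins must be >= 1")
    props <- c(frac_shared = p$frac_shared, frac_de = p$frac_de,
               frac_decoy = p$frac_decoy,
               frac_contaminant = p$frac_contaminant)
    bad <- props < 0 | props > 1
    if (any(bad))
        stop("proportions must lie in [0, 1]: ",
             paste(names(props)[bad], collapse = ", "))
    sds <- c(p$bio_sd, p$peptide_efficiency_sd, p$channel_noise_sd,
             p$array_noise_sd, p$probe_affinity_sd, p$protein_baseline[2])
    if (any(sds < 0)) stop("standard deviations must be >= 0")
    if (abs(p$gene_protein_corr) > 1)
        stop("gene_protein_corr must lie in [-1, 1]")
    if (p$peptides_per_protein[1] < 1)
        stop("mean peptides per protein must be >= 1")
    if (p$n_samples_per_group < 1L) stop("n_samples_per_group must be >= 1")
    if (!is.null(p$sample_loading_offsets) &&
        length(p$sample_loading_offsets) != 2L * p$n_samples_per_group)
        stop("sample_loading_offsets must have length 2 * n_samples_per_group")
    p
}

#' Reporter-ion-like ("tmt-like") simulation preset
#'
#' Intensity-dependent missingness tuned so that ~0.1\% of cells are missing
#' at the default intensity range, as seen for 6-plex reporter-ion data.
#'
#' @param ... overrides passed to [simParams()].
#' @return a \code{SimParams} object.
#' @export
simParamsTMT <- function(...)
    simParams(missingness = c(alpha = 3.0932, beta = 0.5), ...)

#' Label-free-like simulation preset
#'
#' Same generator with the MNAR logistic shifted so that ~18\% of cells are
#' missing at the default intensity range, emulating label-free precursor
#' quantification where dropout is pervasive.
#'
#' @param ... overrides passed to [simParams()].
#' @return a \code{SimParams} object.
#' @export
simParamsLabelFree <- function(...)
    simParams(missingness = c(alpha = 8.4837, beta = 0.5), ...)

#' @export
print.SimParams <- function(x, ...) {
    cat("SimParams:", x$n_proteins, "proteins,",
        2L * x$n_samples_per_group, "samples,",
        sprintf("%.0f%% DE at |log2FC|=%g,", 100 * x$frac_de, x$de_log2fc),
        sprintf("seed %d\n", x$seed))
    invisible(x)
}
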