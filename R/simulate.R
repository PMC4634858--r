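#' Generate ground truth for a synthetic TMT study
#'
#' Draws the latent quantities every downstream stage is later asked to
#' recover: per-protein baseline log2 abundance, true group effects
#' (log2 fold changes, zero for non-affected proteins), per-sample loading
#' offsets, peptide-to-protein memberships (including shared peptides with two
#' parents), per-peptide efficiencies, and the decoy/contaminant rows to be
#' injected.  The true protein log2 abundance of protein p in sample s is
#'
#'   baseline_p + delta_p * 1[s in group 2] + loading_s + bio_{p,s}
#'
#' with bio ~ Normal(0, bio_sd) (zero by default).  The number of affected
#' proteins is exactly \code{round(frac_de * n_proteins)}.
#'
#' @param params a [simParams()] object.
#' @return an object of class \code{GroundTruth}: a list with the design,
#'   protein ids, \code{baseline}, \code{delta}, the true \code{abundance}
#'   matrix (protein x sample, log2), \code{loading}, a \code{peptides}
#'   data.frame (sequence, parent list, efficiency), and \code{decoys} /
#'   \code{contaminants} data.frames.
#' @examples
#' truth <- generateGroundTruth(simParams(n_proteins = 20, seed = 3))
#' table(truth$delta != 0)
#' @export
generateGroundTruth <- function(params) {
    params <- validateSimParams(params)
    set.seed(params$seed)
    k <- params$n_samples_per_group
    if (k == 3L) {
        design <- sampleDesign()
    } else {
        design <- sampleDesign(
            sample_id = c(paste0("ADC", seq_len(k)), paste0("SCC", seq_len(k))),
            channel = sprintf("ch%02d", seq_len(2L * k)),
            group = rep(c("ADC", "SCC"), each = k))
    }
    n <- params$n_proteins
    protein_ids <- sprintf("PROT%05d", seq_len(n))
    baseline <- stats::rnorm(n, params$protein_baseline[1],
                             params$protein_baseline[2])
    n_de <- round(params$frac_de * n)
    delta <- numeric(n)
    if (n_de > 0) {
        idx <- sample.int(n, n_de)
        delta[idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
            params$de_log2fc
    }
    loading <- params$sample_loading_offsets
    if (is.null(loading)) loading <- numeric(2L * k)
    is_scc <- as.numeric(design$group == design$group[2L * k])
    abundance <- outer(baseline, rep(1, 2L * k)) +
        outer(delta, is_scc) +
        outer(rep(1, n), loading)
    if (params$bio_sd > 0)
        abundance <- abundance +
            matrix(stats::rnorm(n * 2L * k, 0, params$bio_sd), n)
    dimnames(abundance) <- list(protein_ids, design$sample_id)

    npep <- 1L + stats::rnbinom(n, size = params$peptides_per_protein[2],
                                mu = params$peptides_per_protein[1] - 1)
    n_pep <- sum(npep)
    parent1 <- rep.int(seq_len(n), npep)
    parents <- as.list(protein_ids[parent1])
    if (params$frac_shared > 0 && n >= 2L) {
        shared <- which(stats::runif(n_pep) < params$frac_shared)
        for (i in shared) {
            other <- sample.int(n - 1L, 1L)
            if (other >= parent1[i]) other <- other + 1L
            parents[[i]] <- c(parents[[i]], protein_ids[other])
        }
    }
    peptides <- data.frame(sequence = sprintf("PEP%06d", seq_len(n_pep)),
                           stringsAsFactors = FALSE)
    peptides$parents <- parents
    peptides$efficiency <- stats::rnorm(n_pep, 0,
                                        params$peptide_efficiency_sd)

    n_rev <- round(params$frac_decoy * n_pep)
    n_con <- round(params$frac_contaminant * n_pep)
    decoys <- data.frame(
        sequence = sprintf("REV%06d", seq_len(n_rev)),
        protein = sprintf("REV_PROT%05d", seq_len(n_rev)),
        baseline = stats::rnorm(n_rev, params$protein_baseline[1],
                                params$protein_baseline[2]),
        stringsAsFactors = FALSE)
    contaminants <- data.frame(
        sequence = sprintf("CON%06d", seq_len(n_con)),
        protein = sprintf("CON_PROT%05d", seq_len(n_con)),
        baseline = stats::rnorm(n_con, params$protein_baseline[1],
                                params$protein_baseline[2]),
        stringsAsFactors = FALSE)

    out <- list(design = design, protein_ids = protein_ids,
                baseline = baseline, delta = delta, abundance = abundance,
                loading = loading, peptides = peptides, decoys = decoys,
                contaminants = contaminants, params = params)
    class(out) <- "GroundTruth"
    out
}

#' @export
print.GroundTruth <- function(x, ...) {
    cat("GroundTruth:", length(x$protein_ids), "proteins (",
        sum(x$delta != 0), "DE ),", nrow(x$peptides), "peptides,",
        nrow(x$decoys), "decoys,", nrow(x$contaminants), "contaminants,",
        nrow(x$design), "samples\n")
    invisible(x)
}

#' Simulate a 6-plex TMT peptide table from ground truth
#'
#' Each genuine peptide's linear intensity in a sample is the sum of its
#' parent proteins' linear abundances (reporter-ion signal is additive across
#' co-isolated origins) scaled by the peptide's efficiency; log2 of that
#' signal receives Normal(0, channel_noise_sd) measurement noise per channel.
#' Each cell is then independently censored with probability
#' \code{plogis(alpha - beta * log2 intensity)} (missing-not-at-random:
#' dropout rises as intensity falls).  Decoy rows (flagged
#' \code{Reverse = "+"}, PEP concentrated above 0.1) and contaminant rows
#' (flagged \code{Contaminant = "+"}) are appended.  Deterministic given the
#' parameter seed.
#'
#' @param truth a [generateGroundTruth()] result.
#' @param params the same [simParams()] object.
#' @return a \linkS4class{PeptideExperiment} with linear-scale intensities.
#' @export
simulatePeptideTable <- function(truth, params) {
    stopifnot(inherits(truth, "GroundTruth"))
    params <- validateSimParams(params)
    set.seed(params$seed + 1L)
    design <- truth$design
    ns <- nrow(design)
    lin <- 2^truth$abundance

    pep <- truth$peptides
    n_pep <- nrow(pep)
    log2sig <- matrix(NA_real_, n_pep, ns)
    for (i in seq_len(n_pep)) {
        sig <- colSums(lin[pep$parents[[i]], , drop = FALSE])
        log2sig[i, ] <- log2(sig) + pep$efficiency[i]
    }
    pep_scores <- stats::rbeta(n_pep, params$pep_true[1], params$pep_true[2])

    revs <- truth$decoys
    cons <- truth$contaminants
    log2rev <- outer(revs$baseline, rep(1, ns))
    log2con <- outer(cons$baseline, rep(1, ns))
    rev_scores <- 0.1 + 0.9 * stats::rbeta(nrow(revs), params$pep_decoy[1],
                                           params$pep_decoy[2])
    con_scores <- stats::rbeta(nrow(cons), params$pep_true[1],
                               params$pep_true[2])

    log2all <- rbind(log2sig, log2con, log2rev)
    nr <- nrow(log2all)
    if (params$channel_noise_sd > 0)
        log2all <- log2all +
            matrix(stats::rnorm(nr * ns, 0, params$channel_noise_sd), nr)
    a <- params$missingness[1]; b <- params$missingness[2]
    p_miss <- stats::plogis(a - b * log2all)
    drop <- matrix(stats::runif(nr * ns), nr) < p_miss
    intensity <- 2^log2all
    intensity[drop] <- NA_real_
    rownames(intensity) <- c(pep$sequence, cons$sequence, revs$sequence)
    colnames(intensity) <- design$sample_id

    PeptideExperiment(
        intensity,
        proteins = c(pep$parents, as.list(cons$protein),
                     as.list(revs$protein)),
        pep = c(pep_scores, con_scores, rev_scores),
        reverse = c(rep(FALSE, n_pep + nrow(cons)), rep(TRUE, nrow(revs))),
        contaminant = c(rep(FALSE, n_pep), rep(TRUE, nrow(cons)),
                        rep(FALSE, nrow(revs))),
        design = design)
}

#' Simulate a matched microarray and probe-to-protein mapping
#'
#' One gene per genuine protein.  The gene's latent log2 profile is
#' \code{rho * z_p + sqrt(1 - rho^2) * z_g}, where \code{z_p} is the
#' protein's standardized true abundance profile across samples (a zero
#' vector if the profile is constant), \code{z_g} independent standard
#' normal noise, and \code{rho = gene_protein_corr}.  Every gene gets
#' \code{1 + Poisson(probes_per_gene_mean - 1)} probes; each probe adds a
#' constant affinity offset plus Normal(0, array_noise_sd) per cell.  The map
#' pairs every probe with its gene's protein accession.  Deterministic given
#' the parameter seed.
#'
#' @param truth a [generateGroundTruth()] result.
#' @param params the same [simParams()] object.
#' @return a list with \code{exprs} (probe x sample log2 matrix) and
#'   \code{map} (data.frame probe_id, protein_id).
#' @export
simulateMicroarray <- function(truth, params) {
    stopifnot(inherits(truth, "GroundTruth"))
    params <- validateSimParams(params)
    set.seed(params$seed + 2L)
    ab <- truth$abundance
    n <- nrow(ab); ns <- ncol(ab)
    mu <- rowMeans(ab)
    sd <- apply(ab, 1L, stats::sd)
    z_p <- (ab - mu) / ifelse(sd > 0, sd, 1)
    z_p[sd == 0, ] <- 0
    rho <- params$gene_protein_corr
    z_g <- matrix(stats::rnorm(n * ns), n)
    latent <- rho * z_p + sqrt(1 - rho^2) * z_g

    nprobe <- if (identical(params$probes_per_gene_model, "fixed"))
        rep.int(max(1L, as.integer(round(params$probes_per_gene_mean))), n)
    else 1L + stats::rpois(n, max(params$probes_per_gene_mean - 1, 0))
    gene_of_probe <- rep.int(seq_len(n), nprobe)
    np <- length(gene_of_probe)
    affinity <- stats::rnorm(np, 0, params$probe_affinity_sd)
    exprs <- params$gene_baseline + latent[gene_of_probe, , drop = FALSE] +
        affinity
    if (params$array_noise_sd > 0)
        exprs <- exprs + matrix(stats::rnorm(np * ns, 0,
                                             params$array_noise_sd), np)
    probe_ids <- sprintf("PB%06d", seq_len(np))
    dimnames(exprs) <- list(probe_ids, truth$design$sample_id)
    list(exprs = exprs,
         map = data.frame(probe_id = probe_ids,
                          protein_id = truth$protein_ids[gene_of_probe],
                          stringsAsFactors = FALSE))
}

#' Write the true protein effects as TSV
#'
#' Columns: protein, baseline, delta (true log2 group effect; 0 = non-DE).
#'
#' @param truth a [generateGroundTruth()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(truth, path)
    writeTSV(data.frame(protein = truth$protein_ids,
                        baseline = fmtNum(truth$baseline),
                        delta = fmtNum(truth$delta),
                        stringsAsFactors = FALSE), path)

#' Simulate a complete study and write all pipeline inputs
#'
#' Convenience wrapper producing the four TSVs [runPipeline()] consumes
#' (peptides, design, expression, probe map) plus the ground-truth table.
#'
#' @param params a [simParams()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the file paths plus the truth object.
#' @export
writeSimulatedStudy <- function(params, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    truth <- generateGroundTruth(params)
    pe <- simulatePeptideTable(truth, params)
    arr <- simulateMicroarray(truth, params)
    paths <- list(
        peptides = file.path(dir, "peptides.tsv"),
        design = file.path(dir, "design.tsv"),
        exprs = file.path(dir, "expression.tsv"),
        map = file.path(dir, "probe_map.tsv"),
        truth_table = file.path(dir, "truth.tsv"))
    writePeptideTable(pe, paths$peptides)
    writeTSV(truth$design, paths$design)
    writeExpressionMatrix(arr$exprs, paths$exprs, id_col = "probe_id")
    writeMappingTable(arr$map, paths$map)
    writeGroundTruth(truth, paths$truth_table)
    invisible(c(paths, list(truth = truth)))
}
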