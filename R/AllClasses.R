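#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
NULL

#' Peptide-level TMT experiment
#'
#' A \linkS4class{SummarizedExperiment} holding one quantified peptide per row
#' and one TMT reporter channel (sample) per column.  The single assay,
#' \code{"intensity"}, stores reporter-ion intensities on the \emph{linear}
#' scale with \code{NA} for missing reporter signal (a MaxQuant reporter
#' intensity of 0 is read as missing, not as 0).  Row metadata carry the
#' identification annotations used by the quality filters: the candidate
#' protein accessions (\code{proteins}, a \code{CharacterList} because shared
#' peptides map to several proteins), the posterior error probability
#' (\code{pep}), and the decoy/contaminant flags (\code{reverse},
#' \code{contaminant}).  Column metadata carry the TMT channel label and the
#' sample group (e.g. ADC or SCC).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases PeptideExperiment-class
#' @seealso [readPeptideTable()], [filterPeptides()], [simulatePeptideTable()]
#' @export
setClass("PeptideExperiment", contains = "SummarizedExperiment")

setValidity("PeptideExperiment", function(object) {
    msg <- NULL
    if (!"intensity" %in% names(assays(object)))
        msg <- c(msg, "assay 'intensity' is required")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "peptide sequences (rownames) must be present and unique")
    rd <- rowData(object)
    need <- c("proteins", "pep", "reverse", "contaminant")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData must contain: ",
                             paste(miss, collapse = ", ")))
    if ("pep" %in% colnames(rd)) {
        p <- rd$pep
        if (any(!is.na(p) & (p < 0 | p > 1)))
            msg <- c(msg, "pep must lie in [0, 1]")
    }
    cd <- colData(object)
    if (!all(c("channel", "group") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'channel' and 'group'")
    if (nrow(object)) {
        x <- assay(object, "intensity")
        if (any(!is.na(x) & x <= 0))
            msg <- c(msg, "intensities must be missing or strictly positive")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a PeptideExperiment
#'
#' @param intensity numeric matrix of linear reporter intensities
#'   (peptides x samples); \code{NA} = missing.  Rownames are peptide
#'   sequences, colnames are sample ids.
#' @param proteins a \code{CharacterList} (or list of character vectors) of
#'   candidate protein accessions per peptide.
#' @param pep numeric vector of posterior error probabilities.
#' @param reverse,contaminant logical vectors flagging decoy and contaminant
#'   rows.
#' @param design a sample-design \code{data.frame} as returned by
#'   [sampleDesign()]; its \code{sample_id} order defines the column order.
#' @return a \linkS4class{PeptideExperiment}.
#' @examples
#' d <- sampleDesign()
#' m <- matrix(2^rnorm(12, 20), 2, 6,
#'             dimnames = list(c("PEPTIDEA", "PEPTIDEB"), d$sample_id))
#' pe <- PeptideExperiment(m, list("P1", c("P1", "P2")), c(0.01, 0.02),
#'                         c(FALSE, FALSE), c(FALSE, FALSE), d)
#' @export
PeptideExperiment <- function(intensity, proteins, pep, reverse, contaminant,
                              design) {
    design <- validateDesign(design)
    intensity <- as.matrix(intensity)
    storage.mode(intensity) <- "double"
    if (!setequal(colnames(intensity), design$sample_id))
        stop("intensity colnames must match design sample_ids")
    intensity <- intensity[, design$sample_id, drop = FALSE]
    if (!is(proteins, "CharacterList"))
        proteins <- CharacterList(proteins)
    rd <- DataFrame(proteins = proteins, pep = as.numeric(pep),
                    reverse = as.logical(reverse),
                    contaminant = as.logical(contaminant))
    cd <- DataFrame(channel = design$channel, group = design$group,
                    row.names = design$sample_id)
    new("PeptideExperiment",
        SummarizedExperiment(assays = SimpleList(intensity = intensity),
                             rowData = rd, colData = cd))
}

#' Protein-level quantification
#'
#' A \linkS4class{SummarizedExperiment} of rolled-up protein intensities.  The
#' assay \code{"log2intensity"} holds the one-step Tukey biweight of the
#' contributing peptides' log2 intensities, per protein and sample (missing iff
#' no contributing peptide was observed in that sample).  Row metadata record
#' the peptide support: \code{n_peptides} (all mapped peptides),
#' \code{n_unique_peptides} (peptides whose only parent is this protein), and
#' \code{single_peptide} (quantified from exactly one distinct peptide, a
#' standard reliability flag).
#'
#' @aliases ProteinQuant-class
#' @seealso [rollupProteins()]
#' @export
setClass("ProteinQuant", contains = "SummarizedExperiment")

setValidity("ProteinQuant", function(object) {
    msg <- NULL
    if (!"log2intensity" %in% names(assays(object)))
        msg <- c(msg, "assay 'log2intensity' is required")
    rd <- rowData(object)
    need <- c("n_peptides", "n_unique_peptides", "single_peptide")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData must contain: ",
                             paste(miss, collapse = ", ")))
    if (!length(miss)) {
        if (any(rd$n_unique_peptides > rd$n_peptides))
            msg <- c(msg, "n_unique_peptides must be <= n_peptides")
        if (any(xor(rd$single_peptide, rd$n_peptides == 1L)))
            msg <- c(msg, "single_peptide must flag n_peptides == 1")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "PeptideExperiment", function(object) {
    callNextMethod()
    n <- nrow(object)
    if (n) {
        cat(sprintf("decoy rows: %d | contaminant rows: %d\n",
                    sum(rowData(object)$reverse, na.rm = TRUE),
                    sum(rowData(object)$contaminant, na.rm = TRUE)))
        x <- assay(object, "intensity")
        cat(sprintf("missing intensities: %d (%.2f%%)\n",
                    sum(is.na(x)), 100 * mean(is.na(x))))
    }
})

setMethod("show", "ProteinQuant", function(object) {
    callNextMethod()
    if (nrow(object))
        cat(sprintf("single-peptide proteins: %d (%.1f%%)\n",
                    sum(rowData(object)$single_peptide),
                    100 * mean(rowData(object)$single_peptide)))
})
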