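#' Accessors for PeptideExperiment and ProteinQuant
#'
#' Small accessors for the annotation slots used throughout the pipeline, so
#' user code never reaches into \code{rowData}/\code{colData} directly.
#'
#' @param object a \linkS4class{PeptideExperiment} or
#'   \linkS4class{ProteinQuant}.
#' @return \code{peptideProteins}: a \code{CharacterList} of candidate
#'   accessions; \code{peptidePEP}: numeric PEP scores; \code{isReverse},
#'   \code{isContaminant}: logical flags; \code{sampleGroups}: named character
#'   vector of group labels per sample; \code{sampleChannels}: named character
#'   vector of TMT channel labels; \code{nPeptides}, \code{nUniquePeptides}:
#'   integer peptide support per protein; \code{isSinglePeptide}: logical flag.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peptideProteins", function(object) standardGeneric("peptideProteins"))
#' @rdname accessors
#' @export
setMethod("peptideProteins", "PeptideExperiment",
          function(object) {
              p <- rowData(object)$proteins
              names(p) <- rownames(object)
              p
          })

#' @rdname accessors
#' @export
setGeneric("peptidePEP", function(object) standardGeneric("peptidePEP"))
#' @rdname accessors
#' @export
setMethod("peptidePEP", "PeptideExperiment",
          function(object) setNames(rowData(object)$pep, rownames(object)))

#' @rdname accessors
#' @export
setGeneric("isReverse", function(object) standardGeneric("isReverse"))
#' @rdname accessors
#' @export
setMethod("isReverse", "PeptideExperiment",
          function(object) setNames(rowData(object)$reverse, rownames(object)))

#' @rdname accessors
#' @export
setGeneric("isContaminant", function(object) standardGeneric("isContaminant"))
#' @rdname accessors
#' @export
setMethod("isContaminant", "PeptideExperiment",
          function(object) setNames(rowData(object)$contaminant,
                                    rownames(object)))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setMethod("sampleGroups", "SummarizedExperiment",
          function(object) setNames(as.character(colData(object)$group),
                                    colnames(object)))

#' @rdname accessors
#' @export
setGeneric("sampleChannels", function(object) standardGeneric("sampleChannels"))
#' @rdname accessors
#' @export
setMethod("sampleChannels", "SummarizedExperiment",
          function(object) setNames(as.character(colData(object)$channel),
                                    colnames(object)))

#' @rdname accessors
#' @export
setGeneric("nPeptides", function(object) standardGeneric("nPeptides"))
#' @rdname accessors
#' @export
setMethod("nPeptides", "ProteinQuant",
          function(object) setNames(rowData(object)$n_peptides,
                                    rownames(object)))

#' @rdname accessors
#' @export
setGeneric("nUniquePeptides", function(object) standardGeneric("nUniquePeptides"))
#' @rdname accessors
#' @export
setMethod("nUniquePeptides", "ProteinQuant",
          function(object) setNames(rowData(object)$n_unique_peptides,
                                    rownames(object)))

#' @rdname accessors
#' @export
setGeneric("isSinglePeptide", function(object) standardGeneric("isSinglePeptide"))
#' @rdname accessors
#' @export
setMethod("isSinglePeptide", "ProteinQuant",
          function(object) setNames(rowData(object)$single_peptide,
                                    rownames(object)))

#' Extract the sample design from an experiment object
#'
#' @param object a \linkS4class{PeptideExperiment} or other
#'   SummarizedExperiment with \code{channel}/\code{group} column metadata.
#' @return a design \code{data.frame} (see [sampleDesign()]).
#' @export
setGeneric("designOf", function(object) standardGeneric("designOf"))
#' @rdname designOf
#' @export
setMethod("designOf", "SummarizedExperiment", function(object)
    data.frame(sample_id = colnames(object),
               channel = as.character(colData(object)$channel),
               group = as.character(colData(object)$group),
               stringsAsFactors = FALSE))
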