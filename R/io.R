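## Tabular IO.  One dialect everywhere: tab-separated, UTF-8, "." decimal,
## blank cell = missing.  Numbers are written with "%.17g" so a write/read
## round trip reproduces doubles exactly.

fmtNum <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- ""
    out
}

readTSV <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, colClasses = "character",
                      na.strings = NULL, fileEncoding = "UTF-8")
}

writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE, na = "", fileEncoding = "UTF-8")
    invisible(path)
}

reporterColumns <- function(design) paste("Reporter intensity", design$channel)

#' Read a sample design table
#'
#' TSV with columns \code{sample_id}, \code{channel}, \code{group}.
#'
#' @param path file path.
#' @return a validated design \code{data.frame} (see [sampleDesign()]).
#' @export
readSampleDesign <- function(path) {
    df <- readTSV(path)
    validateDesign(df)
}

#' Read a MaxQuant-style peptide table
#'
#' Parses a peptide-level TSV in the dialect of MaxQuant's
#' \code{peptides.txt}: columns \code{Sequence}, \code{Proteins}
#' (";"-separated accessions), \code{PEP}, \code{Reverse} and
#' \code{Contaminant} ("+" flags), plus one \code{"Reporter intensity
#' <channel>"} column per sample in the design.  Reporter intensities of 0 or
#' blank are read as missing (MaxQuant writes 0 for absent reporter signal).
#'
#' @param path file path.
#' @param design sample design (see [sampleDesign()]); its channels select the
#'   reporter columns and its sample_ids name the result columns.
#' @return a \linkS4class{PeptideExperiment}.
#' @export
readPeptideTable <- function(path, design) {
    design <- validateDesign(design)
    df <- readTSV(path)
    rep_cols <- reporterColumns(design)
    need <- c("Sequence", "Proteins", "PEP", "Reverse", "Contaminant",
              rep_cols)
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("peptide table is missing required column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$Sequence))
        stop("duplicate peptide sequence rows (sequences must be ",
             "pre-aggregated): ",
             paste(unique(df$Sequence[duplicated(df$Sequence)])[1:3],
                   collapse = ", "))
    n <- nrow(df)
    intensity <- matrix(NA_real_, n, length(rep_cols),
                        dimnames = list(df$Sequence, design$sample_id))
    for (j in seq_along(rep_cols)) {
        v <- parseNumeric(df[[rep_cols[j]]], rep_cols[j])
        v[!is.na(v) & v == 0] <- NA_real_
        intensity[, j] <- v
    }
    prot <- strsplit(df$Proteins, ";", fixed = TRUE)
    prot <- lapply(prot, function(p) p[nzchar(p)])
    PeptideExperiment(intensity, prot,
                      pep = parseNumeric(df$PEP, "PEP"),
                      reverse = trimws(df$Reverse) == "+",
                      contaminant = trimws(df$Contaminant) == "+",
                      design = design)
}

parseNumeric <- function(x, col) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & nzchar(x))
    if (length(bad))
        stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                     x[bad[1]], col, bad[1]))
    out
}

#' Write a PeptideExperiment as a MaxQuant-style TSV
#'
#' Inverse of [readPeptideTable()]: missing intensities are written as 0 (the
#' MaxQuant convention), flags as "+"/"", accessions ";"-joined.
#'
#' @param pe a \linkS4class{PeptideExperiment}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePeptideTable <- function(pe, path) {
    stopifnot(is(pe, "PeptideExperiment"))
    design <- designOf(pe)
    x <- assay(pe, "intensity")
    df <- data.frame(Sequence = rownames(pe),
                     Proteins = vapply(peptideProteins(pe),
                                       paste, "", collapse = ";"),
                     PEP = fmtNum(peptidePEP(pe)),
                     Reverse = ifelse(isReverse(pe), "+", ""),
                     Contaminant = ifelse(isContaminant(pe), "+", ""),
                     check.names = FALSE, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(x))) {
        v <- fmtNum(x[, j])
        v[v == ""] <- "0"
        df[[paste("Reporter intensity", design$channel[j])]] <- v
    }
    writeTSV(df, path)
}

#' Read a feature-by-sample expression matrix
#'
#' TSV whose first column holds unique feature ids and remaining columns hold
#' numeric values (log2 scale as given); blank cells are missing.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
readExpressionMatrix <- function(path) {
    df <- readTSV(path)
    if (ncol(df) < 2L) stop("expression matrix needs id column plus samples")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate feature id: ", ids[duplicated(ids)][1L])
    m <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                dimnames = list(ids, names(df)[-1L]))
    for (j in 2L:ncol(df)) m[, j - 1L] <- parseNumeric(df[[j]], names(df)[j])
    m
}

#' Write an expression matrix as TSV
#'
#' @param m numeric matrix with rownames/colnames.
#' @param path output file path.
#' @param id_col name for the feature-id column.
#' @return the path, invisibly.
#' @export
writeExpressionMatrix <- function(m, path, id_col = "feature_id") {
    df <- data.frame(rownames(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- id_col
    for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmtNum(m[, j])
    writeTSV(df, path)
}

#' Read a probe-to-protein mapping table
#'
#' Two-column TSV (probe id, protein accession); many-to-many mappings are
#' allowed and exact duplicate pairs are collapsed.
#'
#' @param path file path.
#' @return \code{data.frame} with columns \code{probe_id}, \code{protein_id},
#'   one row per distinct pair.
#' @export
readMappingTable <- function(path) {
    df <- readTSV(path)
    if (ncol(df) < 2L) stop("mapping table needs two columns")
    if (!nrow(df)) stop("mapping table is empty")
    out <- unique(data.frame(probe_id = df[[1L]], protein_id = df[[2L]],
                             stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
}

#' Write a probe-to-protein mapping table
#'
#' @param map data.frame with columns \code{probe_id}, \code{protein_id}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMappingTable <- function(map, path)
    writeTSV(map[, c("probe_id", "protein_id")], path)
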