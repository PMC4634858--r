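#' Sample design for a 6-plex TMT run
#'
#' Builds (and validates) the table linking samples to TMT reporter channels
#' and histology groups.  The default reproduces the 3 vs 3 lung NSCLC layout:
#' three adenocarcinoma (ADC) samples on channels 126-128 and three squamous
#' cell carcinoma (SCC) samples on channels 129-131.
#'
#' @param sample_id character vector of unique sample ids.
#' @param channel character vector of TMT reporter channel labels.
#' @param group character/factor of group labels; differential analysis
#'   requires exactly two levels, each with at least one sample.
#' @return a \code{data.frame} with columns \code{sample_id}, \code{channel},
#'   \code{group} (character).
#' @examples
#' sampleDesign()
#' @export
sampleDesign <- function(sample_id = c(paste0("ADC", 1:3), paste0("SCC", 1:3)),
                         channel = as.character(126:131),
                         group = rep(c("ADC", "SCC"), each = 3)) {
    validateDesign(data.frame(sample_id = as.character(sample_id),
                              channel = as.character(channel),
                              group = as.character(group),
                              stringsAsFactors = FALSE))
}

#' Validate a sample design table
#'
#' @param design a data.frame with columns \code{sample_id}, \code{channel},
#'   \code{group}.
#' @return the design, invisibly unchanged (characters coerced).
#' @keywords internal
#' @export
validateDesign <- function(design) {
    if (!is.data.frame(design) ||
        !all(c("sample_id", "channel", "group") %in% names(design)))
        stop("design must be a data.frame with sample_id, channel, group")
    design$sample_id <- as.character(design$sample_id)
    design$channel <- as.character(design$channel)
    design$group <- as.character(design$group)
    if (anyDuplicated(design$sample_id))
        stop("sample_ids must be unique")
    tab <- table(design$group)
    if (length(tab) < 1L || any(tab < 1L))
        stop("every group must contain at least one sample")
    design
}

## Two ordered group levels for a differential contrast; errors unless the
## design has exactly two.
designGroups <- function(design) {
    lev <- unique(design$group)
    if (length(lev) != 2L)
        stop("differential analysis requires exactly two group levels, got ",
             length(lev))
    lev
}
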