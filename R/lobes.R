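#' Lobe and hemisphere assignment for the 90-region AAL parcellation
#'
#' Returns the packaged mapping from each of the 90 cerebral AAL regions to
#' one of five lobes (frontal, parietal, occipital, temporal, subcortical)
#' and a hemisphere (L/R). The assignment is a widely used convention, not a
#' unique standard; pass your own table of the same shape to any function
#' that accepts a \code{lobe_map} to override it.
#'
#' @param path Optional path to a TSV with columns \code{region},
#'   \code{hemisphere}, \code{lobe}; defaults to the packaged AAL-90 table.
#' @return A data.frame with columns \code{region}, \code{hemisphere},
#'   \code{lobe}, one row per region.
#' @export
#' @examples
#' lm <- aal90_lobe_map()
#' table(lm$lobe, lm$hemisphere)
aal90_lobe_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aal90_lobes.tsv", package = "adnetworks",
                        mustWork = TRUE)
  lm <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_lobe_map(lm)
  lm
}

validate_lobe_map <- function(lm) {
  need <- c("region", "hemisphere", "lobe")
  if (!all(need %in% names(lm)))
    stop("lobe map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(lm$region))
    stop("lobe map assigns some region more than once", call. = FALSE)
  if (!all(lm$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  invisible(lm)
}
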