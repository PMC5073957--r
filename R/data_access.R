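#' Published polarity-by-location count table
#'
#' The 2 x 4 worked-example table of cluster counts by polarity (positive,
#' negative) and location category (domain, N-terminal, interdomain,
#' C-terminal) from a published screen of 197 human-virus proteomes,
#' shipped as `extdata/location_counts.tsv`.  Used as the fixture for the
#' contingency statistics.
#'
#' @return Integer matrix (2 x 4) with polarity row names.
#' @examples
#' published_location_counts()
#' @export
published_location_counts <- function() {
  path <- system.file("extdata", "location_counts.tsv",
                      package = "chargescan", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("domain", "n_terminal", "interdomain",
                        "c_terminal")])
  rownames(m) <- df$polarity
  storage.mode(m) <- "integer"
  m
}
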