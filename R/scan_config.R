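#' Detection parameters for the charge-cluster scan
#'
#' Bundles the sliding-window width `w`, the per-window significance level
#' `alpha`, the background model, and the two charge alphabets.  Defaults
#' follow the standard screen settings: window 20, alpha 1e-5, positive
#' alphabet \{K, R\}, negative alphabet \{D, E\}.  Histidine and the
#' ambiguity letters (B, Z, X, U, O, J) are neutral.
#'
#' @param window_w integer window width (>= 2). Proteins shorter than
#'   `window_w` are evaluated as a single whole-sequence window.
#' @param alpha per-window significance level in (0, 1).
#' @param background_mode how the null class frequency p0 is obtained:
#'   `"proteome"` pools all residues of the input set (default),
#'   `"per_protein"` uses each protein's own composition, `"fixed"` uses
#'   `fixed_p0_pos` / `fixed_p0_neg`.
#' @param fixed_p0_pos,fixed_p0_neg background frequencies for `"fixed"` mode.
#' @param positive_alphabet,negative_alphabet character vectors of single
#'   residue letters; must be disjoint.
#'
#' @return An object of class `scan_config`.
#' @examples
#' scan_config()
#' scan_config(background_mode = "fixed", fixed_p0_pos = 0.05, fixed_p0_neg = 0.06)
#' @export
scan_config <- function(window_w = 20L,
                        alpha = 1e-5,
                        background_mode = c("proteome", "per_protein", "fixed"),
                        fixed_p0_pos = NULL,
                        fixed_p0_neg = NULL,
                        positive_alphabet = c("K", "R"),
                        negative_alphabet = c("D", "E")) {
  background_mode <- match.arg(background_mode)
  window_w <- as.integer(window_w)
  if (is.na(window_w) || window_w < 2L)
    stop("`window_w` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  positive_alphabet <- toupper(as.character(positive_alphabet))
  negative_alphabet <- toupper(as.character(negative_alphabet))
  if (length(intersect(positive_alphabet, negative_alphabet)) > 0L)
    stop("charge alphabets must be disjoint", call. = FALSE)
  for (p0 in list(fixed_p0_pos, fixed_p0_neg)) {
    if (!is.null(p0) && (!is.numeric(p0) || p0 < 0 || p0 > 1))
      stop("fixed background frequencies must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(window_w = window_w, alpha = alpha,
         background_mode = background_mode,
         fixed_p0_pos = fixed_p0_pos, fixed_p0_neg = fixed_p0_neg,
         positive_alphabet = positive_alphabet,
         negative_alphabet = negative_alphabet),
    class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat("charge-cluster scan configuration\n")
  cat("  window width   :", x$window_w, "\n")
  cat("  alpha          :", format(x$alpha), "\n")
  cat("  background     :", x$background_mode, "\n")
  if (x$background_mode == "fixed")
    cat("  fixed p0 (+/-) :", x$fixed_p0_pos, "/", x$fixed_p0_neg, "\n")
  cat("  + alphabet     :", paste(x$positive_alphabet, collapse = ","), "\n")
  cat("  - alphabet     :", paste(x$negative_alphabet, collapse = ","), "\n")
  invisible(x)
}

polarity_alphabet <- function(config, polarity) {
  switch(polarity,
         positive = config$positive_alphabet,
         negative = config$negative_alphabet,
         stop("`polarity` must be \"positive\" or \"negative\"", call. = FALSE))
}

POLARITIES <- c("positive", "negative")
LOCATION_LEVELS <- c("n_terminal", "domain", "interdomain", "c_terminal",
                     "unannotated")
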