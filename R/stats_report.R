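#' Chi-square test of independence on a count table
#'
#' Pearson chi-square with expected counts from the product of marginals;
#' degrees of freedom (r-1)(c-1).  The `"monte_carlo"` method estimates the
#' p-value by resampling tables with fixed margins (at least 1e5 replicates
#' recommended), for small-count tables where the asymptotic tail is
#' doubtful.
#'
#' @param table matrix of non-negative counts, at least 2 x 2, with no
#'   all-zero row or column.
#' @param method `"pearson_chi2"` (default) or `"monte_carlo"`.
#' @param mc_reps number of Monte Carlo resamples.
#' @param mc_seed RNG seed used for the Monte Carlo method.
#' @return A list with `statistic`, `df` (NA for Monte Carlo), `p_value`
#'   and `method`.
#' @examples
#' chi_square_independence(rbind(c(97, 10, 14, 5), c(85, 29, 34, 46)))
#' @export
chi_square_independence <- function(table,
                                    method = c("pearson_chi2", "monte_carlo"),
                                    mc_reps = 1e5, mc_seed = 1L) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integer counts", call. = FALSE)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("table must be at least 2 x 2", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero row or column marginal", call. = FALSE)
  if (method == "pearson_chi2") {
    res <- stats::chisq.test(table, correct = FALSE)
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value), method = method)
  } else {
    res <- withr_seed(mc_seed, stats::chisq.test(
      table, correct = FALSE, simulate.p.value = TRUE, B = as.integer(mc_reps)))
    list(statistic = unname(res$statistic), df = NA_integer_,
         p_value = unname(res$p.value), method = method)
  }
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Compare two groups of lengths
#'
#' Welch two-sample t-test (two-sided) with a Mann-Whitney rank-sum test as
#' a robustness companion; length distributions are heavy-tailed, so the
#' rank test guards the t-test's conclusion.
#'
#' @param lengths_a,lengths_b numeric vectors, each with >= 2 values and
#'   non-zero pooled variance.
#' @return A list with `t_statistic`, `t_df`, `t_p`, `mw_statistic`, `mw_p`.
#' @export
compare_two_groups <- function(lengths_a, lengths_b) {
  if (length(lengths_a) < 2L)
    stop("group A needs at least 2 values", call. = FALSE)
  if (length(lengths_b) < 2L)
    stop("group B needs at least 2 values", call. = FALSE)
  if (stats::var(c(lengths_a, lengths_b)) == 0)
    stop("degenerate input: zero variance across both groups", call. = FALSE)
  tt <- stats::t.test(lengths_a, lengths_b, var.equal = FALSE)
  mw <- suppressWarnings(stats::wilcox.test(lengths_a, lengths_b))
  list(t_statistic = unname(tt$statistic), t_df = unname(tt$parameter),
       t_p = tt$p.value, mw_statistic = unname(mw$statistic),
       mw_p = mw$p.value)
}

#' One-way ANOVA on lengths across groups
#'
#' Fixed-effects one-way analysis of variance: F = MS_between / MS_within
#' with p from the F upper tail.  Used to compare protein or cluster
#' lengths across virus groups or families.
#'
#' @param groups named list mapping group key to a numeric vector of
#'   lengths; >= 2 groups, each with >= 2 values.
#' @return A list with `F_statistic`, `df1`, `df2`, `p_value`.
#' @examples
#' anova_lengths(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # F = 13.5
#' @export
anova_lengths <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("group \"", names(groups)[which(sizes < 2L)[1L]],
         "\" has fewer than 2 values", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes))
  if (all(vapply(groups, stats::var, numeric(1)) == 0) &&
      stats::var(y) == 0)
    stop("degenerate input: zero variance everywhere", call. = FALSE)
  res <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F_statistic = unname(res$statistic),
       df1 = unname(res$parameter[1L]), df2 = unname(res$parameter[2L]),
       p_value = res$p.value)
}

#' Per-family / per-group screen summary
#'
#' One row per virus family and per genome group present in the metadata,
#' plus an `"all"` row: protein counts, cluster counts per polarity, the
#' NCC:PCC ratio (NA-flagged when no PCC), and mean/sd of protein and
#' cluster lengths.  Proteins appearing in clusters but absent from the
#' metadata are grouped under `"unknown"` with a warning.
#'
#' @param clusters cluster data frame.
#' @param classifications classification data frame from [scan_proteome()].
#' @param records protein-record data frame.
#' @param metadata optional metadata data frame (protein_id, virus, family,
#'   group); when NULL only the `"all"` row is produced.
#' @return A list with `by_key` (the summary data frame) and `overall`
#'   (totals, mixed and cc-free counts, min/max cluster size).
#' @export
summarize_screen <- function(clusters, classifications, records,
                             metadata = NULL) {
  prot_len <- stats::setNames(nchar(records$sequence), records$id)
  if (!is.null(metadata)) {
    unknown <- setdiff(unique(clusters$protein_id), metadata$protein_id)
    if (length(unknown) > 0L)
      warning(length(unknown),
              " cluster protein id(s) missing from metadata; grouped as",
              " \"unknown\"", call. = FALSE)
  }
  key_of <- function(ids, col) {
    if (is.null(metadata)) return(rep(NA_character_, length(ids)))
    v <- metadata[[col]][match(ids, metadata$protein_id)]
    ifelse(is.na(v), "unknown", v)
  }
  one_row <- function(key, kind, ids) {
    sub <- clusters[clusters$protein_id %in% ids, , drop = FALSE]
    n_pcc <- sum(sub$polarity == "positive")
    n_ncc <- sum(sub$polarity == "negative")
    data.frame(
      key = key, kind = kind, n_proteins = length(ids),
      n_pcc = n_pcc, n_ncc = n_ncc,
      ncc_pcc_ratio = if (n_pcc > 0L) n_ncc / n_pcc else NA_real_,
      mean_protein_length = mean(prot_len[ids]),
      sd_protein_length = if (length(ids) > 1L) stats::sd(prot_len[ids])
                          else NA_real_,
      mean_cluster_length = if (nrow(sub) > 0L) mean(sub$length) else NA_real_,
      sd_cluster_length = if (nrow(sub) > 1L) stats::sd(sub$length)
                          else NA_real_,
      stringsAsFactors = FALSE)
  }
  rows <- list(one_row("all", "all", records$id))
  if (!is.null(metadata)) {
    for (col in c("family", "group")) {
      keys <- key_of(records$id, col)
      for (k in sort(unique(keys)))
        rows <- c(rows, list(one_row(k, col, records$id[keys == k])))
    }
  }
  by_key <- do.call(rbind, rows)
  rownames(by_key) <- NULL
  lab <- classifications$label
  overall <- list(
    n_proteins = nrow(records),
    n_clusters = nrow(clusters),
    n_pcc = sum(clusters$polarity == "positive"),
    n_ncc = sum(clusters$polarity == "negative"),
    n_mixed = sum(lab == "mixed"),
    n_cc_free = sum(lab == "cc_free"),
    cc_free_fraction = mean(lab == "cc_free"),
    min_cluster_length = if (nrow(clusters) > 0L) min(clusters$length)
                         else NA_integer_,
    max_cluster_length = if (nrow(clusters) > 0L) max(clusters$length)
                         else NA_integer_)
  list(by_key = by_key, overall = overall)
}
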