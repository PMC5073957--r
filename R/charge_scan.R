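#' Binary charge indicator for one polarity
#'
#' Position i is 1 iff residue i belongs to the polarity's alphabet
#' (default K/R for positive, D/E for negative).  Histidine and the
#' ambiguity letters B, Z, X, U, O, J are neutral and map to 0, so they can
#' never seed a spurious cluster.
#'
#' @param sequence upper-case amino-acid string.
#' @param polarity `"positive"` or `"negative"`.
#' @param config a [scan_config()].
#' @return Integer vector of 0/1 with one element per residue.
#' @examples
#' encode_charge("KRDEA", "positive")
#' encode_charge("KRDEA", "negative")
#' @export
encode_charge <- function(sequence, polarity, config = scan_config()) {
  alphabet <- polarity_alphabet(config, polarity)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  as.integer(res %in% alphabet)
}

#' Estimate the background charge-class frequency p0
#'
#' Under `background_mode = "proteome"` (the default) p0 is the pooled
#' frequency of the polarity's alphabet over all residues of all records --
#' the proteome-average null a compositional-bias screen tests against.
#' `"per_protein"` returns one p0 per record; `"fixed"` returns the
#' configured value.
#'
#' @param records protein-record data frame.
#' @inheritParams encode_charge
#' @return A single probability (`"proteome"`/`"fixed"`) or a named vector
#'   with one probability per record (`"per_protein"`).
#' @export
estimate_background <- function(records, polarity, config = scan_config()) {
  mode <- config$background_mode
  if (mode == "fixed") {
    p0 <- switch(polarity, positive = config$fixed_p0_pos,
                 negative = config$fixed_p0_neg)
    if (is.null(p0))
      stop("background_mode \"fixed\" requires fixed_p0_",
           substr(polarity, 1, 3), call. = FALSE)
    return(p0)
  }
  alphabet <- polarity_alphabet(config, polarity)
  pattern <- paste0("[", paste(alphabet, collapse = ""), "]")
  counts <- vapply(gregexpr(pattern, records$sequence),
                   function(m) sum(m > 0L), integer(1))
  totals <- nchar(records$sequence)
  if (sum(totals) == 0L)
    stop("cannot estimate background from zero residues", call. = FALSE)
  if (mode == "proteome") sum(counts) / sum(totals)
  else stats::setNames(counts / totals, records$id)
}

#' Exact binomial upper-tail probability P(X >= k)
#'
#' The per-window significance measure: the probability of observing `k` or
#' more charge-class residues in a window of `n` residues under an i.i.d.
#' background with class frequency `p0`.
#'
#' @param k observed count, 0 <= k <= n.
#' @param n window width.
#' @param p0 background class frequency in \[0, 1\].
#' @return P(X >= k) for X ~ Binomial(n, p0).
#' @examples
#' binomial_tail(10, 20, 0.1)  # ~7.15e-06
#' @export
binomial_tail <- function(k, n, p0) {
  if (any(p0 < 0) || any(p0 > 1))
    stop("`p0` must lie in [0, 1]", call. = FALSE)
  if (any(k < 0) || any(k > n))
    stop("`k` must lie in [0, n]", call. = FALSE)
  stats::pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
}

#' Critical charged-residue count for a window
#'
#' The smallest count k* in \[0, w\] whose binomial upper-tail probability is
#' <= `alpha`; a window triggers iff its count reaches k*.  Returns
#' `NA_integer_` when even a fully charged window is not significant
#' (unattainable).
#'
#' @param w window width.
#' @param p0 background class frequency.
#' @param alpha significance level.
#' @return Integer k*, or `NA_integer_` if unattainable.
#' @examples
#' critical_count(20, 0.1, 1e-5)  # 10
#' critical_count(20, 0.5, 1e-5)  # 20
#' @export
critical_count <- function(w, p0, alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  if (p0 < 0 || p0 > 1) stop("`p0` must lie in [0, 1]", call. = FALSE)
  w <- as.integer(w)
  tails <- binomial_tail(0:w, w, p0)
  hit <- which(tails <= alpha)
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L] - 1L
}

#' Scan one protein for charge clusters of one polarity
#'
#' Every window of width `w` (or the single whole-sequence window when the
#' protein is shorter than `w`) is tested with the exact binomial upper tail
#' against `p0`.  Residues covered by significant windows are merged into
#' maximal contiguous regions; each region is trimmed inward so it starts
#' and ends on a residue of the polarity class, and reported as one cluster
#' with its charged count, net charge (K/R count minus D/E count) and the
#' smallest window tail probability among the significant windows that
#' intersect it.
#'
#' @param record a single protein record (one-row data frame, or a list with
#'   `id` and `sequence`).
#' @param polarity `"positive"` or `"negative"`.
#' @param p0 background class frequency for this polarity.
#' @param config a [scan_config()].
#' @return A cluster data frame (possibly empty), sorted by start; clusters
#'   are pairwise disjoint and each begins and ends with a charged residue.
#' @export
scan_protein <- function(record, polarity, p0, config = scan_config()) {
  id <- record$id[[1L]]
  sequence <- record$sequence[[1L]]
  L <- nchar(sequence)
  if (L < 1L) stop("empty sequence for protein ", id, call. = FALSE)
  ind <- encode_charge(sequence, polarity, config)
  w <- min(config$window_w, L)

  kstar <- critical_count(w, p0, config$alpha)
  empty <- cluster_frame(0L)
  if (is.na(kstar)) return(empty)

  # rolling window counts k_i for windows starting at i = 1 .. L-w+1
  cs <- c(0L, cumsum(ind))
  starts <- seq_len(L - w + 1L)
  k <- cs[starts + w] - cs[starts]
  sig <- which(k >= kstar)
  if (length(sig) == 0L) return(empty)

  # union of positions covered by significant windows
  covered <- logical(L)
  for (s in sig) covered[s:(s + w - 1L)] <- TRUE
  r <- rle(covered)
  region_end <- cumsum(r$lengths)
  region_start <- region_end - r$lengths + 1L
  keep <- r$values
  region_start <- region_start[keep]
  region_end <- region_end[keep]

  pos_all <- which(encode_charge(sequence, "positive", config) == 1L)
  neg_all <- which(encode_charge(sequence, "negative", config) == 1L)
  charged <- which(ind == 1L)

  rows <- vector("list", length(region_start))
  for (j in seq_along(region_start)) {
    inside <- charged[charged >= region_start[j] & charged <= region_end[j]]
    if (length(inside) == 0L) {
      warning("candidate region without charged residues dropped in ", id,
              call. = FALSE)
      next
    }
    start <- inside[1L]
    end <- inside[length(inside)]
    # smallest tail p over significant windows intersecting the region:
    # width is constant, so it is the tail at the largest intersecting count
    touching <- sig[sig <= region_end[j] & (sig + w - 1L) >= region_start[j]]
    min_p <- binomial_tail(max(k[touching]), w, p0)
    rows[[j]] <- data.frame(
      protein_id = id, polarity = polarity,
      start = start, end = end, length = end - start + 1L,
      charged_count = length(inside),
      net_charge = sum(pos_all >= start & pos_all <= end) -
                   sum(neg_all >= start & neg_all <= end),
      min_window_p = min_p,
      location = NA_character_, cpp_candidate = FALSE,
      sequence = substr(sequence, start, end),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(cluster_frame(0L))))
  out[order(out$start), , drop = FALSE]
}

cluster_frame <- function(n) {
  data.frame(protein_id = character(n), polarity = character(n),
             start = integer(n), end = integer(n), length = integer(n),
             charged_count = integer(n), net_charge = integer(n),
             min_window_p = numeric(n), location = rep(NA_character_, n),
             cpp_candidate = logical(n), sequence = character(n),
             stringsAsFactors = FALSE)
}

#' Scan a whole proteome for positive and negative charge clusters
#'
#' Estimates the background once per polarity (per the configured
#' background mode), scans every protein for both polarities independently
#' (opposite-polarity clusters may overlap; there is no cross-polarity
#' suppression), flags cell-penetrating-peptide candidates, and labels every
#' protein `cc_free`, `pcc_only`, `ncc_only` or `mixed`.
#'
#' @param records protein-record data frame from [read_fasta()] or
#'   [generate_proteome()].
#' @param config a [scan_config()].
#' @return A list with `clusters` (cluster data frame, both polarities),
#'   `classification` (data frame protein_id/label) and `background` (the
#'   p0 values used, per polarity).
#' @examples
#' recs <- data.frame(id = "p1", description = "",
#'                    sequence = paste0(strrep("A", 30), strrep("K", 12),
#'                                      strrep("A", 30)))
#' res <- scan_proteome(recs, scan_config(background_mode = "fixed",
#'                                        fixed_p0_pos = 0.05,
#'                                        fixed_p0_neg = 0.05))
#' res$clusters[, 1:6]
#' @export
scan_proteome <- function(records, config = scan_config()) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (anyDuplicated(records$id))
    stop("duplicate protein ids in input", call. = FALSE)
  background <- lapply(stats::setNames(POLARITIES, POLARITIES),
                       function(pol) estimate_background(records, pol, config))
  per_protein <- config$background_mode == "per_protein"
  pieces <- vector("list", 2L * nrow(records))
  for (i in seq_len(nrow(records))) {
    for (pol in POLARITIES) {
      p0 <- if (per_protein) background[[pol]][[records$id[i]]]
            else background[[pol]]
      pieces[[2L * (i - 1L) + match(pol, POLARITIES)]] <-
        scan_protein(records[i, , drop = FALSE], pol, p0, config)
    }
  }
  clusters <- do.call(rbind, c(pieces, list(cluster_frame(0L))))
  rownames(clusters) <- NULL
  clusters <- flag_cpp_candidates(clusters)
  has_pcc <- records$id %in% clusters$protein_id[clusters$polarity == "positive"]
  has_ncc <- records$id %in% clusters$protein_id[clusters$polarity == "negative"]
  label <- ifelse(has_pcc & has_ncc, "mixed",
           ifelse(has_pcc, "pcc_only",
           ifelse(has_ncc, "ncc_only", "cc_free")))
  list(clusters = clusters,
       classification = data.frame(protein_id = records$id, label = label,
                                   stringsAsFactors = FALSE),
       background = background)
}

#' Flag cell-penetrating-peptide candidate clusters
#'
#' Short cationic peptides (7-30 aa) can cross cell membranes; positive
#' clusters in that length window are flagged as CPP candidates.  Negative
#' clusters are never flagged: anionic CPPs do not form a coherent class.
#'
#' @param clusters cluster data frame.
#' @return The same data frame with `cpp_candidate` set.
#' @export
flag_cpp_candidates <- function(clusters) {
  clusters$cpp_candidate <- clusters$polarity == "positive" &
    clusters$length >= 7L & clusters$length <= 30L
  clusters
}
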