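# Independent brute-force reference implementations used as oracles.
# These deliberately avoid the package's code paths: tails by direct pmf
# summation, windows by explicit loops.

oracle_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  i <- k:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# all-window enumeration, union of significant windows, trim to charged
# boundaries; returns list(intervals = data.frame(start, end), covered)
oracle_scan <- function(sequence, polarity, p0, w = 20L, alpha = 1e-5,
                        pos_alphabet = c("K", "R"),
                        neg_alphabet = c("D", "E")) {
  alphabet <- if (polarity == "positive") pos_alphabet else neg_alphabet
  res <- strsplit(sequence, "")[[1]]
  ind <- res %in% alphabet
  L <- length(ind)
  width <- min(w, L)
  covered <- logical(L)
  for (s in 1:(L - width + 1L)) {
    k <- sum(ind[s:(s + width - 1L)])
    if (oracle_tail(k, width, p0) <= alpha)
      covered[s:(s + width - 1L)] <- TRUE
  }
  intervals <- data.frame(start = integer(0), end = integer(0))
  in_run <- FALSE
  for (i in seq_len(L + 1L)) {
    if (i <= L && covered[i] && !in_run) { run_start <- i; in_run <- TRUE }
    if ((i > L || !covered[i]) && in_run) {
      run_end <- i - 1L
      charged <- which(ind[run_start:run_end]) + run_start - 1L
      if (length(charged) > 0L)
        intervals <- rbind(intervals,
                           data.frame(start = charged[1L],
                                      end = charged[length(charged)]))
      in_run <- FALSE
    }
  }
  list(intervals = intervals, covered = covered)
}

random_aa_seq <- function(n, class_freq, alphabet = c("K", "R"),
                          neutral = c("A", "G", "L", "S", "T", "V")) {
  paste(ifelse(runif(n) < class_freq,
               sample(alphabet, n, replace = TRUE),
               sample(neutral, n, replace = TRUE)),
        collapse = "")
}

make_records <- function(sequences, ids = sprintf("p%d", seq_along(sequences))) {
  data.frame(id = ids, description = "", sequence = sequences,
             virus = NA_character_, family = NA_character_,
             group = NA_character_, stringsAsFactors = FALSE)
}

fixed_config <- function(p0 = 0.05, ...) {
  scan_config(background_mode = "fixed", fixed_p0_pos = p0,
              fixed_p0_neg = p0, ...)
}

make_cluster <- function(protein_id = "p1", polarity = "positive",
                         start = 1L, end = 10L, sequence = NULL,
                         min_window_p = 1e-6, location = NA_character_) {
  len <- end - start + 1L
  if (is.null(sequence))
    sequence <- strrep(if (polarity == "positive") "K" else "D", len)
  data.frame(protein_id = protein_id, polarity = polarity,
             start = as.integer(start), end = as.integer(end),
             length = len, charged_count = len, net_charge = 0L,
             min_window_p = min_window_p, location = location,
             cpp_candidate = FALSE, sequence = sequence,
             stringsAsFactors = FALSE)
}
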