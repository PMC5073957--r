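AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default background amino-acid composition for simulation
#'
#' Lys and Arg at 0.05 each (K+R = 0.10) and Asp/Glu at 0.06 each
#' (D+E = 0.12), in the range typical of viral proteomes; the remaining 16
#' letters share the rest uniformly.
#'
#' @return Named frequency vector over the 20 standard residues, summing
#'   to 1.
#' @export
default_background <- function() {
  freq <- stats::setNames(rep((1 - 0.10 - 0.12) / 16, 20), AA20)
  freq[c("K", "R")] <- 0.05
  freq[c("D", "E")] <- 0.06
  freq
}

#' Specification of one planted charge cluster
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param length plant length in residues (realistic range 6-61).
#' @param charge_density fraction in (0, 1\] of planted positions drawn from
#'   the polarity alphabet; the remainder is drawn from the background.
#' @param copies number of distinct proteins receiving the identical planted
#'   sequence (>= 2 makes the plant conserved).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(polarity = "positive", length = 15L,
                       charge_density = 1.0, copies = 1L) {
  polarity <- match.arg(polarity, POLARITIES)
  length <- as.integer(length)
  stopifnot(length >= 1L, copies >= 1L)
  if (charge_density <= 0 || charge_density > 1)
    stop("`charge_density` must lie in (0, 1]", call. = FALSE)
  if (charge_density * length < 1)
    stop("plant must contain at least one expected charged residue",
         call. = FALSE)
  structure(list(polarity = polarity, length = length,
                 charge_density = charge_density,
                 copies = as.integer(copies)),
            class = "plant_spec")
}

#' Simulation configuration for synthetic proteomes
#'
#' Protein lengths are log-normal, moment-matched to a mean of 475 and sd
#' of 572 residues and clipped to \[25, 18212\] -- the observed length range
#' of complete human-virus proteomes.  Background residues are i.i.d. from
#' `background`; domains are placed uniformly with a Poisson count per
#' protein; each protein receives a synthetic family and genome-group label
#' round-robin from `families`.
#'
#' @param n_proteins number of proteins to simulate.
#' @param seed RNG seed (mandatory; the generator is deterministic given
#'   the seed).
#' @param plant_specs list of [plant_spec()] objects.
#' @param background named residue frequency vector summing to 1.
#' @param length_meanlog,length_sdlog log-normal parameters of protein
#'   length.
#' @param length_range clip range for protein lengths.
#' @param min_separation minimum background residues between same-polarity
#'   plants within one protein (default the scan window width, 20).
#' @param domain_lambda Poisson mean of the per-protein domain count.
#' @param domain_length_range uniform range of domain lengths.
#' @param families data frame with columns `family` and `group` defining
#'   the label partition.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins, seed, plant_specs = list(),
                       background = default_background(),
                       length_meanlog = 5.717, length_sdlog = 0.9458,
                       length_range = c(25L, 18212L),
                       min_separation = 20L,
                       domain_lambda = 1.5,
                       domain_length_range = c(30L, 200L),
                       families = data.frame(
                         family = c("Simherpesviridae", "Simpapillomaviridae",
                                    "Simretroviridae", "Simreoviridae",
                                    "Simparvoviridae"),
                         group = c("dsDNA", "dsDNA", "retro-transcribing",
                                   "dsRNA", "ssDNA"),
                         stringsAsFactors = FALSE)) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (abs(sum(background) - 1) > 1e-8)
    stop("background frequencies must sum to 1", call. = FALSE)
  stopifnot(n_proteins >= 1L, length(length_range) == 2L,
            all(length_range >= 1L))
  for (ps in plant_specs)
    if (!inherits(ps, "plant_spec"))
      stop("`plant_specs` must be a list of plant_spec objects",
           call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins), seed = as.integer(seed),
                 plant_specs = plant_specs, background = background,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 length_range = as.integer(length_range),
                 min_separation = as.integer(min_separation),
                 domain_lambda = domain_lambda,
                 domain_length_range = as.integer(domain_length_range),
                 families = families),
            class = "sim_config")
}

#' Generate a synthetic proteome with planted charge clusters
#'
#' Background residues are drawn i.i.d. from the configured composition;
#' each [plant_spec()] is realised at a uniformly chosen admissible
#' position, keeping same-polarity plants within one protein separated by
#' at least `min_separation` background residues and plants of opposite
#' polarity disjoint (a plant never overwrites another).  Plants with `copies > 1`
#' place the identical planted sequence into that many distinct proteins.
#' Planted segments at density < 1 are re-anchored: the recorded truth
#' interval is trimmed to the first and last charged residue of the
#' segment, so truth coordinates are directly comparable to the detector's
#' trimmed clusters.  For the same reason each plant carries a neutral
#' guard zone: background residues of the plant's own charge class within
#' `min_separation` residues of either end are resampled from the neutral
#' alphabet, so the detector's trimming cannot extend a detection past the
#' recorded truth boundary.
#'
#' @param config a [sim_config()].
#' @return A list with `records` (protein data frame), `truths` (planted
#'   ground truth: protein_id, polarity, start, end, planted_sequence),
#'   `domains` and `metadata` data frames.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, generate_proteome_impl(config))
}

generate_proteome_impl <- function(config) {
  n <- config$n_proteins
  len <- round(stats::rlnorm(n, config$length_meanlog, config$length_sdlog))
  len <- as.integer(pmin(pmax(len, config$length_range[1L]),
                         config$length_range[2L]))
  ids <- sprintf("SYN%04d", seq_len(n))
  aa <- names(config$background)
  seqs <- vapply(len, function(L)
    paste(sample(aa, L, replace = TRUE, prob = config$background),
          collapse = ""), character(1))

  # plant realisation -------------------------------------------------
  occupied <- lapply(seq_len(n), function(i)
    list(positive = cbind(start = integer(0), end = integer(0)),
         negative = cbind(start = integer(0), end = integer(0))))
  truths <- list()
  sep <- config$min_separation
  for (si in seq_along(config$plant_specs)) {
    ps <- config$plant_specs[[si]]
    alphabet <- if (ps$polarity == "positive") c("K", "R") else c("D", "E")
    charged <- stats::runif(ps$length) <= ps$charge_density
    if (!any(charged)) charged[1L] <- TRUE
    seg <- ifelse(charged,
                  sample(alphabet, ps$length, replace = TRUE),
                  sample(aa, ps$length, replace = TRUE,
                         prob = config$background))
    seg_str <- paste(seg, collapse = "")
    first_c <- which(charged)[1L]
    last_c <- which(charged)[sum(charged)]

    hosts_used <- integer(0)
    for (copy in seq_len(ps$copies)) {
      placed <- FALSE
      cand_hosts <- sample_vec(setdiff(which(len >= ps$length), hosts_used))
      opp <- setdiff(POLARITIES, ps$polarity)
      for (h in cand_hosts) {
        starts <- admissible_starts(len[h], ps$length,
                                    occupied[[h]][[ps$polarity]], sep,
                                    occupied[[h]][[opp]])
        if (length(starts) == 0L) next
        s <- sample_vec(starts)[1L]
        substr(seqs[h], s, s + ps$length - 1L) <- seg_str
        occupied[[h]][[ps$polarity]] <-
          rbind(occupied[[h]][[ps$polarity]],
                c(start = s, end = s + ps$length - 1L))
        truths[[length(truths) + 1L]] <- data.frame(
          protein_id = ids[h], polarity = ps$polarity,
          start = s + first_c - 1L, end = s + last_c - 1L,
          planted_sequence = substr(seg_str, first_c, last_c),
          stringsAsFactors = FALSE)
        hosts_used <- c(hosts_used, h)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("no protein can host plant spec ", si,
             " (length ", ps$length, ", copy ", copy, ")", call. = FALSE)
    }
  }
  truths <- if (length(truths) > 0L) do.call(rbind, truths)
            else data.frame(protein_id = character(0), polarity = character(0),
                            start = integer(0), end = integer(0),
                            planted_sequence = character(0))

  # guard zones: same-class charged background residues within the
  # separation margin flanking a plant are resampled to neutral letters, so
  # the detector's trimmed boundaries coincide with the recorded truth and
  # identical planted copies yield identical detected sequences
  for (h in seq_len(n)) {
    iv_all <- rbind(occupied[[h]]$positive, occupied[[h]]$negative)
    if (nrow(iv_all) == 0L) next
    chars <- strsplit(seqs[h], "", fixed = TRUE)[[1L]]
    planted <- logical(len[h])
    for (r in seq_len(nrow(iv_all)))
      planted[iv_all[r, "start"]:iv_all[r, "end"]] <- TRUE
    # replacements must be neutral to BOTH classes, or one polarity's guard
    # could inject charged residues into the other's cleaned flank
    neutral <- config$background[
      !names(config$background) %in% c("K", "R", "D", "E")]
    for (pol in POLARITIES) {
      alphabet <- if (pol == "positive") c("K", "R") else c("D", "E")
      iv <- occupied[[h]][[pol]]
      for (r in seq_len(nrow(iv))) {
        s <- iv[r, "start"]; e <- iv[r, "end"]
        flank <- c(seq_range(max(1L, s - sep), s - 1L),
                   seq_range(e + 1L, min(len[h], e + sep)))
        flank <- flank[!planted[flank]]
        bad <- flank[chars[flank] %in% alphabet]
        if (length(bad) > 0L)
          chars[bad] <- sample(names(neutral), length(bad), replace = TRUE,
                               prob = neutral)
      }
    }
    seqs[h] <- paste(chars, collapse = "")
  }

  # domains ------------------------------------------------------------
  dom_rows <- list()
  for (i in seq_len(n)) {
    nd <- stats::rpois(1L, config$domain_lambda)
    if (nd == 0L) next
    for (d in seq_len(nd)) {
      dl <- sample(seq(config$domain_length_range[1L],
                       config$domain_length_range[2L]), 1L)
      dl <- min(dl, len[i])
      s <- sample(seq_len(len[i] - dl + 1L), 1L)
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        protein_id = ids[i], domain_name = sprintf("SYNPF%03d", d),
        start = s, end = s + dl - 1L, stringsAsFactors = FALSE)
    }
  }
  domains <- if (length(dom_rows) > 0L) do.call(rbind, dom_rows)
             else data.frame(protein_id = character(0),
                             domain_name = character(0),
                             start = integer(0), end = integer(0))

  fam_idx <- ((seq_len(n) - 1L) %% nrow(config$families)) + 1L
  metadata <- data.frame(
    protein_id = ids,
    virus = paste0("synthetic virus ", config$families$family[fam_idx]),
    family = config$families$family[fam_idx],
    group = config$families$group[fam_idx],
    stringsAsFactors = FALSE)

  records <- data.frame(id = ids,
                        description = "synthetic protein",
                        sequence = seqs, stringsAsFactors = FALSE)
  records <- attach_metadata(records, metadata)
  list(records = records, truths = truths, domains = domains,
       metadata = metadata)
}

seq_range <- function(from, to) if (from > to) integer(0) else from:to

# sample() treats a scalar n as 1:n; guard against that
sample_vec <- function(x) if (length(x) <= 1L) x else sample(x)

# start positions for a plant of length plen on a protein of length L:
# >= sep residues away from same-polarity intervals, disjoint from
# opposite-polarity intervals (which must never be overwritten)
admissible_starts <- function(L, plen, existing, sep,
                              opposite = cbind(start = integer(0),
                                               end = integer(0))) {
  if (L < plen) return(integer(0))
  ok <- rep(TRUE, L - plen + 1L)
  block_out <- function(lo, hi) {
    block <- seq_range(max(1L, lo), min(L - plen + 1L, hi))
    if (length(block) > 0L) ok[block] <<- FALSE
  }
  for (r in seq_len(nrow(existing)))
    block_out(existing[r, "start"] - sep - plen + 1L,
              existing[r, "end"] + sep)
  for (r in seq_len(nrow(opposite)))
    block_out(opposite[r, "start"] - plen + 1L, opposite[r, "end"])
  which(ok)
}

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  union <- (e1 - s1 + 1L) + (e2 - s2 + 1L) - inter
  inter / union
}

#' Score detected clusters against planted ground truth
#'
#' A truth is recovered when a same-polarity detection in the same protein
#' overlaps it with interval Jaccard >= `min_jaccard`; matching is greedy
#' one-to-one by decreasing Jaccard.  Precision is matched detections over
#' all detections (`NA` when there are no detections); recall is matched
#' truths over all truths.
#'
#' @param truths planted-truth data frame from [generate_proteome()].
#' @param detected cluster data frame from [scan_proteome()].
#' @param min_jaccard minimum interval Jaccard for a match.
#' @return A list with `precision`, `recall`, `n_truths`, `n_detected`,
#'   `matches` (truth row, detection row, jaccard).
#' @export
evaluate_recovery <- function(truths, detected, min_jaccard = 0.5) {
  nt <- nrow(truths); nd <- nrow(detected)
  pairs <- list()
  if (nt > 0L && nd > 0L) {
    for (i in seq_len(nt)) {
      cand <- which(detected$protein_id == truths$protein_id[i] &
                    detected$polarity == truths$polarity[i])
      for (j in cand) {
        jac <- interval_jaccard(truths$start[i], truths$end[i],
                                detected$start[j], detected$end[j])
        if (jac >= min_jaccard)
          pairs[[length(pairs) + 1L]] <- c(i, j, jac)
      }
    }
  }
  matches <- data.frame(truth = integer(0), detection = integer(0),
                        jaccard = numeric(0))
  if (length(pairs) > 0L) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(-pm[, 3L]), , drop = FALSE]
    used_t <- logical(nt); used_d <- logical(nd)
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, 1L]; j <- pm[r, 2L]
      if (used_t[i] || used_d[j]) next
      used_t[i] <- TRUE; used_d[j] <- TRUE
      matches <- rbind(matches,
                       data.frame(truth = i, detection = j,
                                  jaccard = pm[r, 3L]))
    }
  }
  list(precision = if (nd > 0L) nrow(matches) / nd else NA_real_,
       recall = if (nt > 0L) nrow(matches) / nt else NA_real_,
       n_truths = nt, n_detected = nd, matches = matches)
}
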