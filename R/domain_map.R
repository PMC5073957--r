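#' Merge one protein's domain annotations into a clean layout
#'
#' Overlapping or adjacent (zero-gap) domain intervals are merged, sorted by
#' start and clipped to `[1, protein_length]`; an interval lying partly
#' outside the protein raises a warning and is clipped.
#'
#' @param annotations domain-annotation data frame rows for one protein
#'   (columns `start`, `end`; `protein_id`/`domain_name` optional here).
#' @param protein_length length of the protein in residues.
#' @return A `domain_layout` list with `intervals` (two-column matrix
#'   start/end, possibly zero rows) and `protein_length`.
#' @examples
#' normalize_domains(data.frame(start = c(50, 100), end = c(150, 200)), 300)
#' @export
normalize_domains <- function(annotations, protein_length) {
  protein_length <- as.integer(protein_length)
  stopifnot(protein_length >= 1L)
  if (is.null(annotations) || nrow(annotations) == 0L) {
    return(structure(list(intervals = cbind(start = integer(0),
                                            end = integer(0)),
                          protein_length = protein_length),
                     class = "domain_layout"))
  }
  s <- as.integer(annotations$start)
  e <- as.integer(annotations$end)
  if (any(s > e)) stop("domain interval with start > end", call. = FALSE)
  if (any(e > protein_length | s < 1L)) {
    warning("domain interval outside [1, ", protein_length, "] clipped",
            call. = FALSE)
    s <- pmax(s, 1L)
    e <- pmin(e, protein_length)
    keep <- s <= e
    s <- s[keep]; e <- e[keep]
  }
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ms <- s[1L]; me <- e[1L]
  outs <- integer(0); oute <- integer(0)
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= me + 1L) {           # overlap or zero gap
      me <- max(me, e[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- s[i]; me <- e[i]
    }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  structure(list(intervals = cbind(start = outs, end = oute),
                 protein_length = protein_length),
            class = "domain_layout")
}

interval_overlap <- function(a_start, a_end, b_start, b_end) {
  max(0, min(a_end, b_end) - max(a_start, b_start) + 1)
}

#' Locate one cluster relative to a protein's domain layout
#'
#' A cluster on a protein with no domain annotation is `unannotated`.
#' Otherwise a cluster entirely upstream of the first domain is
#' `n_terminal`, entirely downstream of the last is `c_terminal`, entirely
#' inside a gap between domains is `interdomain`.  A cluster overlapping at
#' least one domain residue is assigned by majority overlap between the
#' in-domain residues and each flanking region it touches, ties going to
#' `domain`.
#'
#' @param cluster one cluster row (needs `start`, `end`).
#' @param layout a [normalize_domains()] layout for the same protein.
#' @return One of `"n_terminal"`, `"domain"`, `"interdomain"`,
#'   `"c_terminal"`, `"unannotated"`.
#' @export
locate_cluster <- function(cluster, layout) {
  stopifnot(inherits(layout, "domain_layout"))
  iv <- layout$intervals
  if (nrow(iv) == 0L) return("unannotated")
  cs <- cluster$start[[1L]]
  ce <- cluster$end[[1L]]
  L <- layout$protein_length

  if (ce < iv[1L, "start"]) return("n_terminal")
  if (cs > iv[nrow(iv), "end"]) return("c_terminal")

  dom_overlap <- sum(vapply(seq_len(nrow(iv)), function(i)
    interval_overlap(cs, ce, iv[i, "start"], iv[i, "end"]), numeric(1)))

  # flanking regions: n-terminal, inter-domain gaps, c-terminal
  regions <- list()
  if (iv[1L, "start"] > 1L)
    regions <- c(regions, list(list(cat = "n_terminal", s = 1L,
                                    e = iv[1L, "start"] - 1L)))
  if (nrow(iv) > 1L) {
    for (i in seq_len(nrow(iv) - 1L))
      regions <- c(regions, list(list(cat = "interdomain",
                                      s = iv[i, "end"] + 1L,
                                      e = iv[i + 1L, "start"] - 1L)))
  }
  if (iv[nrow(iv), "end"] < L)
    regions <- c(regions, list(list(cat = "c_terminal",
                                    s = iv[nrow(iv), "end"] + 1L, e = L)))

  if (dom_overlap == 0L) {
    # entirely inside exactly one gap (cannot straddle a domain with 0 overlap)
    for (r in regions)
      if (cs >= r$s && ce <= r$e) return(r$cat)
    return("interdomain")   # unreachable guard
  }
  best_cat <- "domain"
  best <- dom_overlap
  for (r in regions) {
    ov <- interval_overlap(cs, ce, r$s, r$e)
    if (ov > best) { best <- ov; best_cat <- r$cat }   # ties stay with domain
  }
  best_cat
}

#' Assign location categories to all clusters
#'
#' Builds one merged [normalize_domains()] layout per protein and fills the
#' `location` column of the cluster table.  Clusters on proteins without any
#' domain annotation become `unannotated`.
#'
#' @param clusters cluster data frame.
#' @param domains domain-annotation data frame (all proteins).
#' @param records protein-record data frame (for protein lengths).
#' @return The cluster data frame with `location` filled.
#' @export
map_cluster_locations <- function(clusters, domains, records) {
  validate_domains(domains, records)
  lengths <- stats::setNames(nchar(records$sequence), records$id)
  missing <- setdiff(clusters$protein_id, names(lengths))
  if (length(missing) > 0L)
    stop("no sequence record for protein ", missing[1L], call. = FALSE)
  layouts <- new.env(parent = emptyenv())
  for (pid in unique(clusters$protein_id)) {
    ann <- domains[domains$protein_id == pid, , drop = FALSE]
    assign(pid, normalize_domains(ann, lengths[[pid]]), envir = layouts)
  }
  clusters$location <- vapply(seq_len(nrow(clusters)), function(i)
    locate_cluster(clusters[i, , drop = FALSE],
                   get(clusters$protein_id[i], envir = layouts)),
    character(1))
  clusters
}

#' Polarity-by-location contingency table
#'
#' Counts located clusters in a 2 x 4 table with rows positive/negative and
#' columns domain, n_terminal, interdomain, c_terminal.  Unannotated
#' clusters are excluded from the table and reported in the
#' `"excluded_unannotated"` attribute.
#'
#' @param clusters cluster data frame with `location` assigned.
#' @return An integer matrix with the excluded count attached as an
#'   attribute.
#' @export
location_contingency <- function(clusters) {
  if (anyNA(clusters$location))
    stop("clusters have unassigned locations; run map_cluster_locations()",
         call. = FALSE)
  cols <- c("domain", "n_terminal", "interdomain", "c_terminal")
  tab <- matrix(0L, nrow = 2L, ncol = 4L,
                dimnames = list(POLARITIES, cols))
  located <- clusters[clusters$location != "unannotated", , drop = FALSE]
  for (pol in POLARITIES)
    for (loc in cols)
      tab[pol, loc] <- sum(located$polarity == pol & located$location == loc)
  attr(tab, "excluded_unannotated") <-
    sum(clusters$location == "unannotated")
  tab
}
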