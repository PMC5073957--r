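#' Alignment identity between two cluster sequences
#'
#' Global alignment with match +1, mismatch 0 and cost-free linear gaps; the
#' optimal score is then the longest common subsequence of the two strings.
#' Identity is matches divided by the longer sequence length, so length
#' mismatch is penalised and identical sequences score 1.
#'
#' @param a,b cluster rows (or lists) with `sequence` and `polarity`.
#' @return Identity fraction in \[0, 1\].
#' @examples
#' x <- list(sequence = "KKRKK", polarity = "positive")
#' y <- list(sequence = "KKKK", polarity = "positive")
#' cluster_similarity(x, y)  # 0.8
#' @export
cluster_similarity <- function(a, b) {
  pa <- a$polarity[[1L]]; pb <- b$polarity[[1L]]
  if (!identical(pa, pb))
    stop("cannot compare clusters of opposite polarity", call. = FALSE)
  sa <- a$sequence[[1L]]; sb <- b$sequence[[1L]]
  lcs_length(sa, sb) / max(nchar(sa), nchar(sb))
}

lcs_length <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    match_i <- x[i] == y
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (match_i[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Group clusters conserved across proteins
#'
#' Per polarity, two clusters from different proteins are linked when their
#' [cluster_similarity()] is at least `identity_threshold`; connected
#' components containing at least two distinct proteins are reported as
#' conserved groups.  At the default threshold 1 this reduces to exact
#' sequence identity shared by two or more proteins.  Group ids are assigned
#' deterministically by (polarity, smallest member protein id, start).
#'
#' @param clusters cluster data frame.
#' @param identity_threshold fraction in (0, 1\].
#' @return A list of `conserved_group` lists, each with `group_id`,
#'   `polarity`, `members` (row indices into `clusters`), `n_proteins` and
#'   `representative_sequence` (most frequent member sequence, ties broken
#'   lexicographically).
#' @export
group_conserved <- function(clusters, identity_threshold = 1.0) {
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1)
    stop("`identity_threshold` must lie in (0, 1]", call. = FALSE)
  groups <- list()
  for (pol in POLARITIES) {
    idx <- which(clusters$polarity == pol)
    if (length(idx) < 2L) next
    sub <- clusters[idx, , drop = FALSE]
    n <- length(idx)
    edges <- integer(0)
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (sub$protein_id[i] == sub$protein_id[j]) next
        sim <- cluster_similarity(sub[i, ], sub[j, ])
        if (sim >= identity_threshold) edges <- c(edges, i, j)
      }
    }
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      members_local <- which(comp == cid)
      prot <- unique(sub$protein_id[members_local])
      if (length(prot) < 2L) next
      seqs <- sub$sequence[members_local]
      freq <- table(seqs)
      rep_seq <- sort(names(freq)[freq == max(freq)])[1L]
      groups[[length(groups) + 1L]] <- list(
        polarity = pol,
        members = idx[members_local],
        n_proteins = length(prot),
        representative_sequence = rep_seq,
        sort_protein = min(sub$protein_id[members_local]),
        sort_start = min(sub$start[members_local][
          sub$protein_id[members_local] ==
            min(sub$protein_id[members_local])]))
    }
  }
  if (length(groups) == 0L) return(list())
  o <- order(match(vapply(groups, `[[`, character(1), "polarity"), POLARITIES),
             vapply(groups, `[[`, character(1), "sort_protein"),
             vapply(groups, `[[`, numeric(1), "sort_start"))
  groups <- groups[o]
  for (i in seq_along(groups)) {
    groups[[i]]$group_id <- i
    groups[[i]]$sort_protein <- NULL
    groups[[i]]$sort_start <- NULL
  }
  groups
}

#' Summary counts for conserved groups
#'
#' @param groups output of [group_conserved()].
#' @param clusters the cluster data frame the groups index into.
#' @return A data frame with one row per polarity: number of conserved
#'   clusters (total members over groups), number of distinct proteins
#'   carrying them, number of groups, and the largest group size in
#'   proteins.
#' @export
summarize_conservation <- function(groups, clusters) {
  out <- data.frame(polarity = POLARITIES, n_conserved_clusters = 0L,
                    n_proteins = 0L, n_groups = 0L, max_group_proteins = 0L,
                    stringsAsFactors = FALSE)
  for (pol in POLARITIES) {
    gp <- Filter(function(g) g$polarity == pol, groups)
    i <- match(pol, out$polarity)
    out$n_groups[i] <- length(gp)
    if (length(gp) == 0L) next
    members <- unlist(lapply(gp, `[[`, "members"))
    out$n_conserved_clusters[i] <- length(members)
    out$n_proteins[i] <- length(unique(clusters$protein_id[members]))
    out$max_group_proteins[i] <-
      max(vapply(gp, `[[`, integer(1), "n_proteins"))
  }
  out
}

#' Conserved groups as a flat table
#'
#' @inheritParams summarize_conservation
#' @return Data frame with one row per group member: group_id, polarity,
#'   n_proteins, representative_sequence plus the member's cluster fields.
#' @export
conserved_groups_table <- function(groups, clusters) {
  if (length(groups) == 0L) {
    out <- cbind(data.frame(group_id = integer(0), n_proteins = integer(0),
                            representative_sequence = character(0)),
                 cluster_frame(0L))
    return(out)
  }
  rows <- lapply(groups, function(g) {
    cbind(data.frame(group_id = g$group_id, n_proteins = g$n_proteins,
                     representative_sequence = g$representative_sequence,
                     stringsAsFactors = FALSE),
          clusters[g$members, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
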