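#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased on ingestion.  UniProt-style headers of the form
#' `db|ACC|NAME description` are parsed so that the record id is the
#' accession (`ACC`); otherwise the id is the first whitespace-delimited
#' token of the header and the remainder becomes the description.
#'
#' @param path path to a FASTA file.
#' @return A data frame of protein records with columns `id`, `description`,
#'   `sequence`, and placeholder metadata columns `virus`, `family`, `group`
#'   (all `NA` until metadata is attached; see [attach_metadata()]).
#' @seealso [read_metadata_table()], [write_fasta()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P12345|X test protein", "MKRDE"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_header <- startsWith(lines, ">")
  if (!any(is_header))
    stop("no sequences found in FASTA file: ", path, call. = FALSE)
  bad <- which(!is_header & nzchar(trimws(lines)) &
                 grepl("[^A-Za-z]", trimws(lines)))
  if (length(bad) > 0L)
    stop("non-letter character in sequence at line ", bad[1L],
         " of ", path, call. = FALSE)

  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  first_tok <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  # UniProt convention: db|ACC|NAME
  piped <- grepl("^[^|[:space:]]+\\|[^|[:space:]]+\\|", first_tok)
  id <- first_tok
  id[piped] <- vapply(strsplit(first_tok[piped], "|", fixed = TRUE),
                      `[[`, character(1), 2L)
  dup <- id[duplicated(id)]
  if (length(dup) > 0L)
    stop("duplicate sequence id in FASTA: ", dup[1L], call. = FALSE)
  sequence <- toupper(as.character(seqs))
  if (any(!nzchar(sequence)))
    stop("empty sequence for id ", id[which(!nzchar(sequence))[1L]],
         call. = FALSE)
  data.frame(id = id, description = desc, sequence = unname(sequence),
             virus = NA_character_, family = NA_character_,
             group = NA_character_, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Headers are `id description` (description omitted when empty); the
#' write-then-read round trip is the identity on `(id, sequence)`.
#'
#' @param records protein-record data frame as returned by [read_fasta()] or
#'   [generate_proteome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  xs <- Biostrings::AAStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(xs) <- ifelse(nzchar(desc) & !is.na(desc),
                      paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(xs, filepath = path)
  invisible(path)
}

#' Attach virus/family/group metadata to protein records
#'
#' @param records protein-record data frame.
#' @param metadata metadata data frame from [read_table()] with kind
#'   `"metadata"`.
#' @return `records` with `virus`, `family`, `group` filled where available.
#' @export
attach_metadata <- function(records, metadata) {
  i <- match(records$id, metadata$protein_id)
  for (col in c("virus", "family", "group"))
    records[[col]] <- ifelse(is.na(i), records[[col]], metadata[[col]][i])
  records
}

table_columns <- list(
  domains  = c("protein_id", "domain_name", "start", "end"),
  metadata = c("protein_id", "virus", "family", "group"),
  clusters = c("protein_id", "polarity", "start", "end", "length",
               "charged_count", "net_charge", "min_window_p", "location",
               "cpp_candidate", "sequence")
)

#' Read a tab-separated annotation or result table
#'
#' Three kinds are supported: `"domains"` (simplified Pfam hit table with
#' columns protein_id, domain_name, start, end), `"metadata"` (protein_id,
#' virus, family, group) and `"clusters"` (the table written by
#' [write_clusters()]).  Extra columns are ignored; coordinates are parsed
#' as integers; a missing required column or an interval with start > end is
#' an error.
#'
#' @param path path to a TSV file with a header row.
#' @param kind one of `"domains"`, `"metadata"`, `"clusters"`.
#' @return A data frame with the typed required columns, in file order.
#' @export
read_table <- function(path, kind = c("domains", "metadata", "clusters")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- table_columns[[kind]]
  missing_col <- setdiff(required, names(raw))
  if (length(missing_col) > 0L)
    stop("missing required column \"", missing_col[1L], "\" in ", kind,
         " table ", path, call. = FALSE)
  out <- raw[required]
  int_cols <- intersect(c("start", "end", "length", "charged_count",
                          "net_charge"), required)
  for (col in int_cols) {
    v <- suppressWarnings(as.integer(out[[col]]))
    if (anyNA(v) && !all(is.na(out[[col]]) == is.na(v)))
      stop("non-integer value in column \"", col, "\" of ", path,
           call. = FALSE)
    out[[col]] <- v
  }
  if (all(c("start", "end") %in% required)) {
    bad <- which(out$start > out$end)
    if (length(bad) > 0L)
      stop("start > end at row ", bad[1L], " of ", path, call. = FALSE)
    if (any(out$start < 1L, na.rm = TRUE))
      stop("coordinates must be 1-based positive in ", path, call. = FALSE)
  }
  if (kind == "clusters") {
    out$min_window_p <- as.numeric(raw$min_window_p)
    out$cpp_candidate <- as.logical(raw$cpp_candidate)
    out$location[out$location == ""] <- NA_character_
    bad_pol <- setdiff(unique(out$polarity), POLARITIES)
    if (length(bad_pol) > 0L)
      stop("unknown polarity \"", bad_pol[1L], "\" in ", path, call. = FALSE)
  }
  out
}

#' Write a charge-cluster table to TSV
#'
#' Columns: protein_id, polarity, start, end, length, charged_count,
#' net_charge, min_window_p, location, cpp_candidate, sequence.
#' Coordinates are 1-based inclusive; `min_window_p` is written in
#' scientific notation with full precision so that the
#' write-then-[read_table()] round trip is the identity; rows are sorted
#' deterministically by (protein_id, start, polarity).
#'
#' @param clusters cluster data frame from [scan_proteome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  cols <- table_columns$clusters
  clusters <- as.data.frame(clusters)
  for (col in setdiff(cols, names(clusters)))
    clusters[[col]] <- if (col == "cpp_candidate") NA else NA_character_
  clusters <- clusters[cols]
  if (nrow(clusters) > 0L) {
    o <- order(clusters$protein_id, clusters$start, clusters$polarity)
    clusters <- clusters[o, , drop = FALSE]
  }
  out <- clusters
  # 17 significant digits: exact binary round trip for doubles
  out$min_window_p <- sprintf("%.16e", clusters$min_window_p)
  out$location <- ifelse(is.na(clusters$location), "", clusters$location)
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

validate_domains <- function(domains, records = NULL) {
  if (!is.null(records)) {
    len <- stats::setNames(nchar(records$sequence), records$id)
    known <- domains$protein_id %in% names(len)
    over <- known & (domains$end > len[domains$protein_id])
    if (any(over))
      warning("domain interval beyond protein length for ",
              domains$protein_id[which(over)[1L]], "; will be clipped",
              call. = FALSE)
  }
  invisible(domains)
}
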