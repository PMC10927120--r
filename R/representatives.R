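#' Sequence records for clustering
#'
#' Normalises a data frame of sequences into the record layout used by the
#' clustering and representative-selection routines, filling metadata
#' defaults (no previous/manual flags, method `"other"`, unknown resolution
#' and release date).
#'
#' @param df Data frame with at least `id` and `sequence`; optional columns
#'   `is_previous_rep`, `is_manual`, `is_provisional_manual`, `method`
#'   (`xray`, `em`, `nmr`, `other`), `resolution` (Angstrom), `release_date`
#'   (coercible to `Date`).
#' @return Data frame with all metadata columns present and validated.
#' @export
as_seq_records <- function(df) {
  stopifnot(all(c("id", "sequence") %in% names(df)))
  if (anyDuplicated(df$id)) stop("duplicate record ids")
  if (any(nchar(df$sequence) == 0L)) stop("empty sequence")
  if (any(grepl("[^A-Z]", df$sequence)))
    stop("sequences must be uppercase amino-acid strings")
  defaults <- list(is_previous_rep = FALSE, is_manual = FALSE,
                   is_provisional_manual = FALSE, method = "other",
                   resolution = NA_real_, release_date = as.Date(NA))
  for (col in names(defaults))
    if (is.null(df[[col]])) df[[col]] <- defaults[[col]]
  df$release_date <- as.Date(df$release_date)
  stopifnot(all(df$method %in% c("xray", "em", "nmr", "other")))
  df
}

#' Local alignment identity and coverage between two sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 with gap open 11 and gap
#' extend 1. Identity is the fraction of matching positions among aligned
#' columns; each coverage is the aligned span on that sequence divided by
#' its full length.
#'
#' @param a,b Amino-acid strings.
#' @return List with `identity`, `coverage_a`, `coverage_b`.
#' @export
local_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  ncol_aln <- Biostrings::nchar(aln)
  if (ncol_aln == 0L)
    return(list(identity = 0, coverage_a = 0, coverage_b = 0))
  list(identity = Biostrings::nmatch(aln) / ncol_aln,
       coverage_a = Biostrings::width(Biostrings::pattern(aln)) / nchar(a),
       coverage_b = Biostrings::width(Biostrings::subject(aln)) / nchar(b))
}

#' Clustering parameters
#'
#' @param identity Minimum identity to join a cluster, in (0, 1\].
#' @param coverage Minimum coverage, in (0, 1\].
#' @param coverage_mode `"local_query"` (the shorter sequence must reach
#'   the coverage cutoff) or `"bidirectional"` (both must).
#' @param word_size Exact k-mer length used purely as a speed prefilter: a
#'   pair is aligned only if the two sequences share at least one k-mer.
#' @return List of class `cluster_params`.
#' @export
cluster_params <- function(identity, coverage,
                           coverage_mode = c("local_query", "bidirectional"),
                           word_size = 4L) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(identity > 0, identity <= 1, coverage > 0, coverage <= 1,
            word_size >= 2L)
  structure(list(identity = identity, coverage = coverage,
                 coverage_mode = coverage_mode,
                 word_size = as.integer(word_size)),
            class = "cluster_params")
}

#' Parameters of the F-level representative sets
#'
#' The three published redundancy levels: identity/coverage/word-size
#' triples (0.99, 0.9, 5), (0.70, 0.7, 4) and (0.40, 0.7, 2) for F99, F70
#' and F40.
#'
#' @param level One of `"F99"`, `"F70"`, `"F40"`.
#' @return A [cluster_params()].
#' @export
f_level_params <- function(level = c("F99", "F70", "F40")) {
  level <- match.arg(level)
  switch(level,
         F99 = cluster_params(0.99, 0.9, "local_query", 5L),
         F70 = cluster_params(0.70, 0.7, "local_query", 4L),
         F40 = cluster_params(0.40, 0.7, "local_query", 2L))
}

has_shared_kmer <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  ka <- unique(substring(a, seq_len(nchar(a) - k + 1L),
                         seq_len(nchar(a) - k + 1L) + k - 1L))
  kb <- unique(substring(b, seq_len(nchar(b) - k + 1L),
                         seq_len(nchar(b) - k + 1L) + k - 1L))
  length(intersect(ka, kb)) > 0L
}

pair_satisfies <- function(rep_seq, seq, p) {
  li <- local_identity(rep_seq, seq)
  cov_ok <- if (p$coverage_mode == "bidirectional") {
    li$coverage_a >= p$coverage && li$coverage_b >= p$coverage
  } else {
    shorter_cov <- if (nchar(seq) <= nchar(rep_seq)) li$coverage_b else
      li$coverage_a
    shorter_cov >= p$coverage
  }
  list(ok = li$identity >= p$identity && cov_ok, li = li)
}

#' Greedy incremental sequence clustering
#'
#' Records are sorted by length descending (ties by id) and processed in
#' order: each record joins the first existing cluster whose representative
#' it matches at the configured identity and coverage (the representative
#' of a cluster is its founding, i.e. longest, member), otherwise it founds
#' a new cluster. The word-size prefilter skips alignments between pairs
#' sharing no exact k-mer and never changes identity values.
#'
#' @param records Sequence records (see [as_seq_records()]).
#' @param p A [cluster_params()].
#' @param join `"first"` (default, first-fit as in greedy incremental
#'   clustering tools) or `"best"` (highest-identity eligible cluster).
#' @return Data frame with one row per record: `rep_id`, `member_id`,
#'   `identity`, `cov_rep`, `cov_member`.
#' @export
greedy_cluster <- function(records, p, join = c("first", "best")) {
  join <- match.arg(join)
  records <- as_seq_records(records)
  if (nrow(records) == 0L) stop("no records to cluster")
  ord <- order(-nchar(records$sequence), records$id)
  records <- records[ord, , drop = FALSE]
  reps <- integer(0)
  rows <- list()
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    best_j <- NA_integer_
    best <- NULL
    for (j in reps) {
      r <- records$sequence[j]
      if (!has_shared_kmer(r, s, p$word_size)) next
      chk <- pair_satisfies(r, s, p)
      if (chk$ok) {
        if (join == "first") { best_j <- j; best <- chk$li; break }
        if (is.na(best_j) || chk$li$identity > best$identity) {
          best_j <- j
          best <- chk$li
        }
      }
    }
    if (is.na(best_j)) {
      reps <- c(reps, i)
      rows[[length(rows) + 1L]] <- data.frame(
        rep_id = records$id[i], member_id = records$id[i],
        identity = 1, cov_rep = 1, cov_member = 1,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        rep_id = records$id[best_j], member_id = records$id[i],
        identity = best$identity, cov_rep = best$coverage_a,
        cov_member = best$coverage_b, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select a cluster representative by the priority policy
#'
#' Ordered criteria: previous representatives first, then manually curated,
#' then provisional manual; among the rest, x-ray structures are preferred,
#' then lower (better) resolution, then later release date, then the
#' lexicographically smallest id.
#'
#' @param member_ids Ids of the cluster members.
#' @param records Sequence records holding the metadata.
#' @return The selected representative id.
#' @export
select_representative <- function(member_ids, records) {
  records <- as_seq_records(records)
  m <- records[match(member_ids, records$id), , drop = FALSE]
  if (nrow(m) == 0L || anyNA(m$id)) stop("cluster members not in records")
  key <- order(!m$is_previous_rep, !m$is_manual, !m$is_provisional_manual,
               m$method != "xray",
               ifelse(is.na(m$resolution), Inf, m$resolution),
               -ifelse(is.na(m$release_date), -Inf,
                       as.numeric(m$release_date)),
               m$id)
  m$id[key[1L]]
}

#' Redundancy-reduce unassigned domain sequences
#'
#' Clusters domain sequences greedily at 70% identity with a bidirectional
#' 70% coverage cutoff and returns one representative per cluster (the
#' longest member; ties by id -- which is the founding member of each
#' greedy cluster).
#'
#' @param records Sequence records.
#' @param identity Identity threshold; 0.7 by default.
#' @return Character vector of representative ids.
#' @export
reduce_unassigned <- function(records, identity = 0.7) {
  p <- cluster_params(identity, 0.7, "bidirectional", 4L)
  cl <- greedy_cluster(records, p)
  unique(cl$rep_id)
}

#' Audit clustering output against its parameters
#'
#' Recomputes identity and coverage for every non-representative member
#' against its representative and checks the configured constraints hold.
#'
#' @param clusters Output of [greedy_cluster()].
#' @param records The records that were clustered.
#' @param p The [cluster_params()] used.
#' @return `TRUE` invisibly; stops with a message on any violation.
#' @export
audit_clusters <- function(clusters, records, p) {
  records <- as_seq_records(records)
  seqs <- stats::setNames(records$sequence, records$id)
  for (k in seq_len(nrow(clusters))) {
    if (clusters$rep_id[k] == clusters$member_id[k]) next
    chk <- pair_satisfies(seqs[[clusters$rep_id[k]]],
                          seqs[[clusters$member_id[k]]], p)
    if (!chk$ok)
      stop("cluster constraint violated for member ",
           clusters$member_id[k], " vs ", clusters$rep_id[k])
  }
  invisible(TRUE)
}

#' Read or write FASTA sequence records
#'
#' @param path FASTA path.
#' @return `read_fasta_records`: data frame with `id` and `sequence`.
#' @export
read_fasta_records <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @rdname read_fasta_records
#' @param records Data frame with `id` and `sequence`.
#' @export
write_fasta_records <- function(records, path) {
  x <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
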