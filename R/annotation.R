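#' Map obsolete protein records to current ones
#'
#' An obsolete record is superseded by a current record exactly when the
#' two sequences are identical as strings (which implies identical length).
#' When several current records match, the mapping takes the
#' lexicographically smallest current id and sets an ambiguity flag.
#'
#' @param obsolete,current Data frames with `id` and `sequence` columns.
#' @return Data frame with one row per obsolete record: `obsolete_id`,
#'   `current_id` (`NA` when unmatched), `ambiguous`.
#' @export
map_obsolete <- function(obsolete, current) {
  stopifnot(all(c("id", "sequence") %in% names(obsolete)),
            all(c("id", "sequence") %in% names(current)))
  rows <- lapply(seq_len(nrow(obsolete)), function(k) {
    hits <- sort(current$id[current$sequence == obsolete$sequence[k]])
    data.frame(obsolete_id = obsolete$id[k],
               current_id = if (length(hits)) hits[1L] else NA_character_,
               ambiguous = length(hits) > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of a domain covered by sequence annotations
#'
#' Computes the fraction of the domain's residues that fall inside the
#' union of the annotation intervals (all assumed to lie on the same
#' protein), and whether the domain counts as covered at threshold `theta`.
#'
#' @param domain A [residue_range()].
#' @param annotations Data frame of intervals with `start` and `end`
#'   columns (1-based inclusive); may be empty.
#' @param theta Coverage threshold for the binary call. Default 0.5.
#' @return List with `covered_fraction` and `is_covered`.
#' @examples
#' domain_annotation_coverage(parse_range("100-200"),
#'                            data.frame(start = 150, end = 250))
#' @export
domain_annotation_coverage <- function(domain, annotations, theta = 0.5) {
  stopifnot(inherits(domain, "residue_range"))
  res <- range_residues(domain)
  if (is.null(annotations) || nrow(annotations) == 0L)
    return(list(covered_fraction = 0, is_covered = FALSE))
  stopifnot(all(annotations$start <= annotations$end))
  ann <- unique(unlist(mapply(seq.int, annotations$start, annotations$end,
                              SIMPLIFY = FALSE)))
  frac <- length(intersect(res, ann)) / length(res)
  list(covered_fraction = frac, is_covered = frac >= theta)
}

#' Annotation coverage for a table of parsed domains
#'
#' @param domains Region data frame (e.g. from [classify_model()] or
#'   [read_domain_table()]); `model_id` identifies the protein.
#' @param annotations Annotation-interval table (see [read_annotations()]).
#' @param theta Coverage threshold. Default 0.5.
#' @return The `domains` data frame with `covered_fraction` and
#'   `is_covered` columns appended.
#' @export
annotate_domains <- function(domains, annotations, theta = 0.5) {
  domains$covered_fraction <- NA_real_
  domains$is_covered <- NA
  for (k in seq_len(nrow(domains))) {
    ann <- annotations[annotations$protein_id == domains$model_id[k], ,
                       drop = FALSE]
    cov <- domain_annotation_coverage(parse_range(domains$range[k]), ann,
                                      theta)
    domains$covered_fraction[k] <- cov$covered_fraction
    domains$is_covered[k] <- cov$is_covered
  }
  domains
}
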