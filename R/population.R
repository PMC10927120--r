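#' Tally assigned domains by homologous group and stratum
#'
#' Only `ASSIGNED` regions contribute. Each region's model is mapped to a
#' stratum (a species, kingdom, or any other set label) through `strata`,
#' and counts are accumulated per `(h_group, stratum)` cell. Architecture
#' and class roll-ups are available through [rollup_populations()] via the
#' catalog metadata carried on the table.
#'
#' @param regions Classified-region data frame (see [classify_model()]).
#' @param catalog Reference catalog; every assigned `h_group` must appear.
#' @param strata Named character vector mapping `model_id` to stratum label.
#' @return An object of class `population_table`: list with `counts` (a
#'   stratum x group integer matrix) and `groups` (per-group metadata).
#' @export
tally_populations <- function(regions, catalog, strata) {
  asg <- regions[regions$category == "ASSIGNED", , drop = FALSE]
  if (nrow(asg)) {
    unknown <- setdiff(asg$h_group, catalog$h_group)
    if (length(unknown))
      stop("assigned region with unknown h_group: ",
           paste(unknown, collapse = ", "))
    if (!all(asg$model_id %in% names(strata)))
      stop("model without stratum assignment")
  }
  groups <- sort(unique(asg$h_group))
  strata_levels <- unique(strata[names(strata) %in% regions$model_id])
  counts <- matrix(0L, length(strata_levels), length(groups),
                   dimnames = list(strata_levels, groups))
  for (k in seq_len(nrow(asg)))
    counts[strata[[asg$model_id[k]]], asg$h_group[k]] <-
      counts[strata[[asg$model_id[k]]], asg$h_group[k]] + 1L
  meta <- unique(catalog[catalog$h_group %in% groups,
                         c("h_group", "x_group", "architecture", "class5")])
  meta <- meta[match(groups, meta$h_group), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, groups = meta),
            class = "population_table")
}

#' Construct a population table from precomputed counts
#'
#' Convenience constructor for reference-side tables (e.g. representative
#' domain counts of an experimental reference).
#'
#' @param counts Stratum x group matrix, or a named vector (one stratum).
#' @param groups Optional per-group metadata data frame with an `h_group`
#'   column.
#' @return A `population_table`.
#' @export
population_table <- function(counts, groups = NULL) {
  if (is.null(dim(counts)))
    counts <- matrix(counts, 1L, dimnames = list("all", names(counts)))
  stopifnot(all(counts >= 0), !is.null(colnames(counts)))
  structure(list(counts = counts, groups = groups),
            class = "population_table")
}

#' Roll population counts up the hierarchy
#'
#' @param t A `population_table` built by [tally_populations()].
#' @param level One of `"h_group"`, `"architecture"`, `"class5"`.
#' @return Stratum x level count matrix; column sums are conserved across
#'   levels.
#' @export
rollup_populations <- function(t, level = c("h_group", "architecture",
                                            "class5")) {
  level <- match.arg(level)
  if (level == "h_group") return(t$counts)
  if (is.null(t$groups)) stop("no group metadata on this table")
  key <- t$groups[[level]][match(colnames(t$counts), t$groups$h_group)]
  agg <- t(rowsum(t(t$counts), key))
  agg
}

#' Relative population per group within each stratum
#'
#' @param t A `population_table`.
#' @return Matrix of `count / stratum total`, rows summing to 1 (all-zero
#'   strata yield zero rows).
#' @export
relative_populations <- function(t) {
  tot <- rowSums(t$counts)
  sweep(t$counts, 1, ifelse(tot > 0, tot, 1), "/")
}

#' Observed/expected normalisation by stratum and group totals
#'
#' Each cell is normalised by its row (stratum) and column (group) totals:
#' `value(s, h) = count(s, h) * T / (row_total(s) * col_total(h))` with `T`
#' the grand total -- the observed-to-expected ratio under independence.
#' Cells whose row or column total is zero are reported as 0.
#'
#' @param t A `population_table` (or bare count matrix).
#' @return Matrix of ratios with the same dimnames as the counts.
#' @export
stratified_normalize <- function(t) {
  counts <- if (inherits(t, "population_table")) t$counts else as.matrix(t)
  T_ <- sum(counts)
  if (T_ == 0) stop("grand total is zero")
  rs <- rowSums(counts)
  cs <- colSums(counts)
  denom <- outer(rs, cs)
  out <- counts * T_ / ifelse(denom > 0, denom, 1)
  out[denom == 0] <- 0
  out
}

#' Chi-squared test for a 2x2 contingency table
#'
#' Pearson's chi-squared without continuity correction, from the closed
#' form `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with the p-value
#' from the upper tail of the chi-squared distribution with 1 degree of
#' freedom. A table with a zero margin is reported as `chi2 = 0, p = 1`.
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return List with `chi2` and `p`.
#' @examples
#' chi2_2x2(30, 70, 10, 90)  # chi2 = 12.5
#' @export
chi2_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative count")
  N <- a + b + c + d
  if (N == 0) stop("empty table")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) return(list(chi2 = 0, p = 1))
  chi2 <- N * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Compare group populations between two sets
#'
#' For every homologous group in the union of the two tables (strata
#' collapsed; absent groups count 0), a 2x2 table of
#' `[count_obs, total_obs - count_obs; count_ref, total_ref - count_ref]`
#' is tested with [chi2_2x2()]. Significance applies the Bonferroni
#' correction: `p < alpha / m`, where `m` is the number of groups with a
#' positive count in the observed set (`m_mode = "observed"`, the default)
#' or in the union (`m_mode = "union"`).
#'
#' @param obs,ref `population_table` objects (or named count vectors).
#' @param alpha Family-wise significance level. Default 0.05.
#' @param m_mode How to count the number of tests for Bonferroni.
#' @return Data frame with one row per group: `group_id`, `count_obs`,
#'   `total_obs`, `count_ref`, `total_ref`, `chi2`, `p`, `significant`;
#'   sorted by `p` ascending, ties broken by `group_id`.
#' @export
compare_sets <- function(obs, ref, alpha = 0.05,
                         m_mode = c("observed", "union")) {
  m_mode <- match.arg(m_mode)
  as_counts <- function(x) {
    if (inherits(x, "population_table")) colSums(x$counts) else {
      stopifnot(!is.null(names(x)))
      x
    }
  }
  co <- as_counts(obs)
  cr <- as_counts(ref)
  if (length(co) == 0L || sum(co) == 0) stop("empty observed table")
  universe <- sort(union(names(co), names(cr)))
  co <- stats::setNames(ifelse(universe %in% names(co),
                               co[universe], 0), universe)
  cr <- stats::setNames(ifelse(universe %in% names(cr),
                               cr[universe], 0), universe)
  co[is.na(co)] <- 0
  cr[is.na(cr)] <- 0
  total_obs <- sum(co)
  total_ref <- sum(cr)
  m <- if (m_mode == "observed") sum(co > 0) else length(universe)
  rows <- lapply(universe, function(g) {
    ct <- chi2_2x2(co[[g]], total_obs - co[[g]], cr[[g]], total_ref - cr[[g]])
    data.frame(group_id = g, count_obs = co[[g]], total_obs = total_obs,
               count_ref = cr[[g]], total_ref = total_ref,
               chi2 = ct$chi2, p = ct$p,
               significant = ct$p < alpha / m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  out
}
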