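#' Assign secondary-structure states from the Calpha trace
#'
#' A distance-window detector in the P-SEA tradition, using only Calpha
#' geometry: residue `i` is helical (`H`) if `d(i, i+2)` lies in
#' \[5.0, 6.0\] Angstrom and `d(i, i+3)` in \[4.7, 6.1\]; strand (`E`) if
#' `d(i, i+2)` lies in \[5.9, 7.3\] and `d(i, i+3)` in \[9.0, 11.5\] (helix
#' wins where the windows overlap); otherwise coil (`C`). A
#' secondary-structure element is a maximal run of at least 6 `H` or at
#' least 3 `E` within the range; distances are only evaluated inside a
#' contiguous segment of the range.
#'
#' @param model A [predicted_model()].
#' @param range A [residue_range()] within the model (defaults to the whole
#'   chain).
#' @return List with `states` (character vector, one of `H`/`E`/`C` per
#'   residue of the range, named by residue index) and `n_sse` (integer).
#' @export
assign_sse <- function(model, range = NULL) {
  n <- model_length(model)
  if (is.null(range)) range <- residue_range(cbind(1L, n))
  if (range[nrow(range), "end"] > n || range[1L, "start"] < 1L)
    stop("range outside model")
  xyz <- model$ca_coords
  all_states <- character(0)
  n_sse <- 0L
  for (s in seq_len(nrow(range))) {
    res <- range[s, "start"]:range[s, "end"]
    L <- length(res)
    states <- rep("C", L)
    if (L >= 4L) {
      for (k in seq_len(L - 3L)) {
        i <- res[k]
        d2 <- sqrt(sum((xyz[i, ] - xyz[i + 2L, ])^2))
        d3 <- sqrt(sum((xyz[i, ] - xyz[i + 3L, ])^2))
        if (d2 >= 5.0 && d2 <= 6.0 && d3 >= 4.7 && d3 <= 6.1) {
          states[k] <- "H"
        } else if (d2 >= 5.9 && d2 <= 7.3 && d3 >= 9.0 && d3 <= 11.5) {
          states[k] <- "E"
        }
      }
    }
    r <- rle(states)
    n_sse <- n_sse + sum((r$values == "H" & r$lengths >= 6L) |
                           (r$values == "E" & r$lengths >= 3L))
    names(states) <- res
    all_states <- c(all_states, states)
  }
  list(states = all_states, n_sse = n_sse)
}

#' Score a candidate against its homology hits
#'
#' The assignment score is `confidence x ref_coverage` of the best hit
#' (highest product). The provisional label is `ASSIGNED` when the best hit
#' is confident (`>= t$conf_min`) with high reference coverage
#' (`>= t$cov_assign`), `PARTIAL` when confident but with coverage below
#' `t$cov_partial`, and `UNASSIGNED` otherwise -- including the coverage
#' grey zone between the two cutoffs and the no-hit case (score `NA`).
#'
#' @param candidate A `domain_candidate` (its `$hits` already restricted to
#'   the candidate range).
#' @param t Thresholds.
#' @return List with `score`, `label`, `h_group`.
#' @export
score_candidate <- function(candidate, t = default_thresholds()) {
  hits <- candidate$hits
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(score = NA_real_, label = "UNASSIGNED",
                h_group = NA_character_))
  prod <- hits$confidence * hits$ref_coverage
  best <- which.max(prod)
  conf <- hits$confidence[best]
  cov <- hits$ref_coverage[best]
  label <- if (conf >= t$conf_min && cov >= t$cov_assign) "ASSIGNED"
  else if (conf >= t$conf_min && cov < t$cov_partial) "PARTIAL"
  else "UNASSIGNED"
  list(score = prod[best], label = label,
       h_group = if (label == "UNASSIGNED") NA_character_ else
         hits$ref_group_id[best])
}

#' Classify every residue of a model into the six categories
#'
#' Candidates are labelled with a fixed precedence: a candidate whose mean
#' pLDDT falls below `t$plddt_min` is `LOW_CONFIDENCE` regardless of
#' topology or hits; otherwise a candidate with fewer than
#' `t$sse_min_for_globular` secondary-structure elements is `SIMPLE`;
#' otherwise the hit-based label of [score_candidate()] applies. Residues
#' outside all candidates are `LOW_CONFIDENCE` below the pLDDT cutoff and
#' `FLEXIBLE` otherwise. Contiguous runs of equal label are emitted as
#' regions, so every residue is labelled exactly once.
#'
#' @param model A [predicted_model()].
#' @param candidates Candidate list from [parse_domains()].
#' @param flexible_mask Logical mask from [parse_domains()].
#' @param t Thresholds.
#' @return Data frame of classified regions with columns `model_id`,
#'   `range`, `category`, `h_group`, `score`, `mean_plddt`, `n_sse`.
#' @export
classify_model <- function(model, candidates, flexible_mask,
                           t = default_thresholds()) {
  n <- model_length(model)
  seen <- logical(n)
  for (c in candidates) {
    res <- range_residues(c$range)
    if (any(seen[res])) stop("parser contract violated: candidates overlap")
    seen[res] <- TRUE
  }
  rows <- list()
  for (c in candidates) {
    sse <- assign_sse(model, c$range)
    sc <- score_candidate(c, t)
    label <- if (c$mean_plddt < t$plddt_min) "LOW_CONFIDENCE"
    else if (sse$n_sse < t$sse_min_for_globular) "SIMPLE"
    else sc$label
    h_group <- if (label %in% c("ASSIGNED", "PARTIAL")) sc$h_group else
      NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      model_id = model$model_id, range = format_range(c$range),
      category = label, h_group = h_group, score = sc$score,
      mean_plddt = c$mean_plddt, n_sse = sse$n_sse,
      stringsAsFactors = FALSE)
  }
  out <- which(!seen)
  if (length(out)) {
    lab <- ifelse(model$plddt[out] < t$plddt_min, "LOW_CONFIDENCE",
                  "FLEXIBLE")
    brk <- c(0L, which(diff(out) > 1L | lab[-length(lab)] != lab[-1L]),
             length(out))
    for (k in seq_len(length(brk) - 1L)) {
      res <- out[(brk[k] + 1L):brk[k + 1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = model$model_id,
        range = format_range(range_from_residues(res)),
        category = lab[brk[k] + 1L], h_group = NA_character_,
        score = NA_real_, mean_plddt = mean(model$plddt[res]),
        n_sse = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  regions <- do.call(rbind, rows)
  start <- vapply(regions$range, function(s) parse_range(s)[1L, 1L], 1L)
  regions <- regions[order(start), , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

#' Expand classified regions to a per-residue label vector
#'
#' @param regions Region data frame for one model.
#' @param n Model length.
#' @return Character vector of length `n`.
#' @export
region_label_vector <- function(regions, n) {
  labels <- rep(NA_character_, n)
  for (k in seq_len(nrow(regions))) {
    res <- range_residues(parse_range(regions$range[k]))
    labels[res] <- regions$category[k]
  }
  if (anyNA(labels)) stop("regions do not cover every residue")
  labels
}

#' Summarise a proteome's classified regions
#'
#' Residue-weighted counts and fractions per category across all models of
#' a proteome, plus the number of domain-like regions (`ASSIGNED`,
#' `UNASSIGNED`, `PARTIAL` and `SIMPLE` regions each count as one domain).
#'
#' @param regions Region data frame covering one or more models.
#' @param proteome_id Identifier recorded in the summary.
#' @return An object of class `proteome_summary`: list with `proteome_id`,
#'   `counts` and `fractions` (named over the six categories), `n_models`,
#'   `n_domains`, `n_residues`.
#' @export
summarize_proteome <- function(regions, proteome_id = "proteome") {
  if (is.null(regions) || nrow(regions) == 0L) stop("no regions to summarise")
  lens <- vapply(regions$range,
                 function(s) range_length(parse_range(s)), 1L)
  counts <- vapply(region_labels(), function(lab)
    sum(lens[regions$category == lab]), numeric(1))
  total <- sum(counts)
  structure(list(proteome_id = proteome_id, counts = counts,
                 fractions = counts / total,
                 n_models = length(unique(regions$model_id)),
                 n_domains = sum(regions$category %in%
                                   c("ASSIGNED", "UNASSIGNED", "PARTIAL",
                                     "SIMPLE")),
                 n_residues = total),
            class = "proteome_summary")
}

#' @export
print.proteome_summary <- function(x, ...) {
  cat("<proteome_summary> ", x$proteome_id, ": ", x$n_models, " models, ",
      x$n_residues, " residues, ", x$n_domains, " domains\n", sep = "")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Write proteome summaries as a one-row-per-proteome TSV
#'
#' Columns follow the reporting order of the six categories.
#'
#' @param summaries A `proteome_summary` or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  if (inherits(summaries, "proteome_summary")) summaries <- list(summaries)
  rows <- lapply(summaries, function(s) {
    d <- data.frame(proteome_id = s$proteome_id, n_models = s$n_models,
                    n_domains = s$n_domains, n_residues = s$n_residues,
                    stringsAsFactors = FALSE)
    for (lab in region_labels())
      d[[tolower(lab)]] <- sprintf("%.4f", s$fractions[[lab]])
    d
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
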