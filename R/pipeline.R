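#' Parse and classify a set of models
#'
#' Runs [parse_domains()] and [classify_model()] over every model and
#' returns the combined region table.
#'
#' @param models List of [predicted_model()] objects (with PAE).
#' @param hits Combined hit table covering all models.
#' @param pair_model A fitted [fit_pair_model()].
#' @param t Thresholds.
#' @return Region data frame over all models.
#' @export
classify_proteome <- function(models, hits, pair_model,
                              t = default_thresholds()) {
  region_tabs <- lapply(models, function(model) {
    pd <- parse_domains(model,
                        hits[hits$query_id == model$model_id, , drop = FALSE],
                        pair_model, t)
    classify_model(model, pd$candidates, pd$flexible, t)
  })
  out <- do.call(rbind, region_tabs)
  rownames(out) <- NULL
  out
}

#' Score recovery of ground truth by a classification
#'
#' Computes residue-level agreement between predicted and true category
#' labels, and the fraction of true domains recovered by a predicted
#' domain-like region at or above a Jaccard cutoff.
#'
#' @param regions Region table from [classify_proteome()].
#' @param models,truths Parallel lists from [generate_proteome()].
#' @param jaccard_min Jaccard cutoff for counting a true domain as
#'   recovered. Default 0.8.
#' @return List with `residue_agreement`, `domain_recovery` (fraction of
#'   true domains matched), `mean_jaccard` (over best matches),
#'   `n_true_domains`, `n_residues`.
#' @export
evaluate_recovery <- function(regions, models, truths, jaccard_min = 0.8) {
  stopifnot(length(models) == length(truths))
  agree <- 0L
  total <- 0L
  jaccards <- numeric(0)
  for (i in seq_along(models)) {
    model <- models[[i]]
    truth <- truths[[i]]
    n <- model_length(model)
    reg <- regions[regions$model_id == model$model_id, , drop = FALSE]
    pred <- region_label_vector(reg, n)
    agree <- agree + sum(pred == truth$labels)
    total <- total + n
    dom_reg <- reg[reg$category %in% c("ASSIGNED", "UNASSIGNED", "PARTIAL",
                                       "SIMPLE"), , drop = FALSE]
    part <- truth$partition
    for (k in seq_len(nrow(part))) {
      true_rng <- residue_range(cbind(part$start[k], part$end[k]))
      best <- 0
      for (r in dom_reg$range)
        best <- max(best, range_jaccard(true_rng, parse_range(r)))
      jaccards <- c(jaccards, best)
    }
  }
  list(residue_agreement = agree / total,
       domain_recovery = if (length(jaccards))
         mean(jaccards >= jaccard_min) else NA_real_,
       mean_jaccard = if (length(jaccards)) mean(jaccards) else NA_real_,
       n_true_domains = length(jaccards), n_residues = total)
}
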