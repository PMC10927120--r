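#' Pairwise same-domain features
#'
#' Four quantities summarise a residue pair `(i, j)`: the Calpha-Calpha
#' distance, the symmetrised PAE (mean of the `(i,j)` and `(j,i)` entries),
#' and the number of sequence-profile and structure-alignment hits whose
#' query range covers both residues. All four are symmetric in `(i, j)`.
#'
#' @param model A [predicted_model()] with PAE.
#' @param hits Hit data frame for this model (may be empty).
#' @param i,j Residue indices (1-based).
#' @return A named list `d_ca`, `pae_sym`, `n_shared_seq`, `n_shared_str`.
#' @export
compute_pair_features <- function(model, hits, i, j) {
  n <- model_length(model)
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) stop("residue index out of range")
  mats <- pair_feature_matrices(model, hits)
  list(d_ca = mats$d_ca[i, j], pae_sym = mats$pae_sym[i, j],
       n_shared_seq = mats$n_shared_seq[i, j],
       n_shared_str = mats$n_shared_str[i, j])
}

# All four feature matrices at once (n x n); the workhorse behind both
# single-pair queries and whole-model probability matrices.
pair_feature_matrices <- function(model, hits) {
  n <- model_length(model)
  d <- as.matrix(stats::dist(model$ca_coords))
  ps <- pae_sym(model)
  nseq <- matrix(0, n, n)
  nstr <- matrix(0, n, n)
  if (!is.null(hits) && nrow(hits)) {
    hits <- hits[hits$query_id == model$model_id, , drop = FALSE]
    for (h in seq_len(nrow(hits))) {
      cov <- rep(0, n)
      res <- range_residues(parse_range(hits$query_range[h]))
      res <- res[res <= n]
      cov[res] <- 1
      o <- tcrossprod(cov)
      if (hits$source[h] == "sequence_profile") nseq <- nseq + o
      else nstr <- nstr + o
    }
  }
  list(d_ca = d, pae_sym = ps, n_shared_seq = nseq, n_shared_str = nstr)
}

# Fixed feature transforms: distances capped at 40 A and scaled, PAE capped
# at the 31.75 A payload maximum and scaled, counts log1p-compressed.
transform_features <- function(d_ca, pae, n_seq, n_str) {
  cbind(d = pmin(d_ca, 40) / 40,
        pae = pmin(pae, 31.75) / 31.75,
        seq = log1p(n_seq),
        str = log1p(n_str))
}

#' Fit the same-domain pair-probability model
#'
#' Logistic regression of the same-domain label on the four transformed pair
#' features. The training set is typically produced by
#' [make_pair_training()] on a labelled synthetic benchmark; on real data
#' any labelled pair table with the same columns works.
#'
#' @param training Data frame with columns `d_ca`, `pae_sym`,
#'   `n_shared_seq`, `n_shared_str` and `label` (1 = same domain, 0 = not).
#' @param reg L2 (ridge) penalty; 0 gives a plain maximum-likelihood fit.
#'   The small default keeps the weights finite when the benchmark classes
#'   are linearly separable, which well-separated PAE blocks typically are.
#' @param seed Integer seed, recorded with the model (the fit itself is
#'   deterministic).
#' @return An object of class `pair_model` holding the intercept and the
#'   four weights `(w0, w_d, w_pae, w_seq, w_str)`.
#' @export
fit_pair_model <- function(training, reg = 0.01, seed = 1L) {
  stopifnot(all(c("d_ca", "pae_sym", "n_shared_seq", "n_shared_str",
                  "label") %in% names(training)))
  y <- as.numeric(training$label)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  X <- transform_features(training$d_ca, training$pae_sym,
                          training$n_shared_seq, training$n_shared_str)
  if (reg > 0) {
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = reg, standardize = FALSE)
    w <- c(as.numeric(fit$a0), as.numeric(fit$beta))
  } else {
    df <- data.frame(y = y, X)
    fit <- stats::glm(y ~ d + pae + seq + str, data = df,
                      family = stats::binomial())
    w <- unname(stats::coef(fit))
  }
  names(w) <- c("w0", "w_d", "w_pae", "w_seq", "w_str")
  structure(list(weights = w, reg = reg, seed = as.integer(seed),
                 n_training = length(y)),
            class = "pair_model")
}

#' @export
print.pair_model <- function(x, ...) {
  cat("<pair_model> weights:",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights),
            collapse = " "), "\n")
  invisible(x)
}

#' Probability that two residues share a domain
#'
#' @param m A fitted [fit_pair_model()] object.
#' @param f Pair features from [compute_pair_features()].
#' @return Probability in (0, 1).
#' @export
pair_probability <- function(m, f) {
  stopifnot(inherits(m, "pair_model"))
  v <- c(f$d_ca, f$pae_sym, f$n_shared_seq, f$n_shared_str)
  if (any(!is.finite(v))) stop("non-finite feature")
  X <- transform_features(f$d_ca, f$pae_sym, f$n_shared_seq, f$n_shared_str)
  stats::plogis(m$weights[["w0"]] + drop(X %*% m$weights[-1L]))
}

# Whole-model n x n probability matrix.
pair_probability_matrix <- function(m, model, hits) {
  mats <- pair_feature_matrices(model, hits)
  n <- model_length(model)
  X <- transform_features(as.vector(mats$d_ca), as.vector(mats$pae_sym),
                          as.vector(mats$n_shared_seq),
                          as.vector(mats$n_shared_str))
  matrix(stats::plogis(m$weights[["w0"]] + drop(X %*% m$weights[-1L])), n, n)
}

#' Build a labelled pair-feature training table from synthetic models
#'
#' Generates a small benchmark of multi-domain synthetic models and samples
#' residue pairs among ordered (non-linker, non-tail) residues: pairs inside
#' the same domain block are labelled 1, pairs spanning two globular blocks
#' are labelled 0.
#'
#' @param n_models Number of benchmark models.
#' @param pairs_per_class Pairs sampled per class per model.
#' @param seed Integer master seed.
#' @return Data frame suitable for [fit_pair_model()].
#' @export
make_pair_training <- function(n_models = 6L, pairs_per_class = 300L,
                               seed = 1L) {
  prot <- generate_proteome(n_models, seed = as.integer(seed),
                            decoy_rate = 0.1)
  withr::with_seed(as.integer(seed) + 1L, {
    rows <- list()
    for (i in seq_along(prot$models)) {
      model <- prot$models[[i]]
      truth <- prot$truths[[i]]
      blocks <- truth$blocks
      glob <- blocks$kind %in% c("domain", "simple_helix")
      block_of <- rep(seq_len(nrow(blocks)), blocks$length)
      ordered <- glob[block_of]
      mats <- pair_feature_matrices(
        model, prot$hits[prot$hits$query_id == model$model_id, ])
      idx <- which(ordered)
      same <- outer(block_of[idx], block_of[idx], "==")
      pick <- function(mask, k) {
        cand <- which(mask & upper.tri(mask), arr.ind = TRUE)
        cand[sample.int(nrow(cand), min(k, nrow(cand))), , drop = FALSE]
      }
      for (lab in c(1, 0)) {
        sel <- pick(if (lab == 1) same else !same, pairs_per_class)
        ii <- idx[sel[, 1]]
        jj <- idx[sel[, 2]]
        rows[[length(rows) + 1L]] <- data.frame(
          d_ca = mats$d_ca[cbind(ii, jj)],
          pae_sym = mats$pae_sym[cbind(ii, jj)],
          n_shared_seq = mats$n_shared_seq[cbind(ii, jj)],
          n_shared_str = mats$n_shared_str[cbind(ii, jj)],
          label = lab)
      }
    }
    do.call(rbind, rows)
  })
}

#' Serialise or reload a pair model
#'
#' Weights and transforms are written as JSON so a parse run can be
#' reproduced from its manifest.
#'
#' @param m A `pair_model`.
#' @param path JSON path.
#' @return `read_pair_model`: the reloaded `pair_model`.
#' @export
write_pair_model <- function(m, path) {
  stopifnot(inherits(m, "pair_model"))
  jsonlite::write_json(list(weights = as.list(m$weights), reg = m$reg,
                            seed = m$seed, n_training = m$n_training,
                            transforms = "d/40 cap40, pae/31.75 cap, log1p counts"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pair_model
#' @param path JSON path.
#' @export
read_pair_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  w <- unlist(x$weights)
  structure(list(weights = w[c("w0", "w_d", "w_pae", "w_seq", "w_str")],
                 reg = x$reg, seed = x$seed, n_training = x$n_training),
            class = "pair_model")
}
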