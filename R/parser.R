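#' Flag flexible/disordered residues from the PAE matrix
#'
#' A residue is considered part of a rigid, co-folded unit only if enough
#' long-range partners "agree" with it: residue `i` is flagged flexible iff
#' fewer than `t$flex_min_partners` residues `j` with sequence separation
#' greater than `t$flex_seq_sep` have symmetrised PAE below
#' `t$flex_partner_pae` Angstrom. Linkers and disordered tails, whose PAE to
#' everything is high, fail this partner count and are excluded from domain
#' parsing.
#'
#' @param model A [predicted_model()] with PAE attached.
#' @param t Thresholds from [default_thresholds()].
#' @return Logical vector of length n; `TRUE` marks flexible residues.
#' @export
flag_flexible_residues <- function(model, t = default_thresholds()) {
  if (is.null(model$pae)) stop("PAE required")
  ps <- pae_sym(model)
  n <- model_length(model)
  sep <- abs(outer(seq_len(n), seq_len(n), "-")) > t$flex_seq_sep
  partners <- rowSums(sep & (ps < t$flex_partner_pae))
  partners < t$flex_min_partners
}

#' Cut ordered runs into short segments
#'
#' Maximal runs of non-flexible residues are tiled with consecutive
#' segments of `t$segment_len` residues. A remainder shorter than 3 is
#' absorbed into the previous segment (lengths up to `segment_len + 2`); a
#' remainder of 3 or more keeps its own segment. Runs shorter than 3
#' residues yield no segment and are treated as flexible downstream.
#'
#' @param model A [predicted_model()].
#' @param flexible_mask Logical mask from [flag_flexible_residues()].
#' @param t Thresholds.
#' @return Data frame with columns `index`, `start`, `end`.
#' @export
build_segments <- function(model, flexible_mask, t = default_thresholds()) {
  n <- model_length(model)
  stopifnot(length(flexible_mask) == n)
  r <- rle(!flexible_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    L <- r$lengths[k]
    if (L < 3L) next
    s0 <- starts[k]
    if (L < t$segment_len) {
      segs[[length(segs) + 1L]] <- c(s0, s0 + L - 1L)
      next
    }
    nfull <- L %/% t$segment_len
    rem <- L %% t$segment_len
    bnd_start <- s0 + (seq_len(nfull) - 1L) * t$segment_len
    bnd_end <- bnd_start + t$segment_len - 1L
    if (rem == 0L) {
      # exact tiling
    } else if (rem < 3L) {
      bnd_end[nfull] <- bnd_end[nfull] + rem
    } else {
      bnd_start <- c(bnd_start, bnd_end[nfull] + 1L)
      bnd_end <- c(bnd_end, bnd_end[nfull] + rem)
    }
    for (j in seq_along(bnd_start))
      segs[[length(segs) + 1L]] <- c(bnd_start[j], bnd_end[j])
  }
  if (!length(segs))
    return(data.frame(index = integer(0), start = integer(0),
                      end = integer(0)))
  m <- do.call(rbind, segs)
  data.frame(index = seq_len(nrow(m)), start = m[, 1L], end = m[, 2L])
}

# Segment-by-segment affinity: mean same-domain probability over all
# cross-segment residue pairs, computed from the n x n probability matrix.
segment_affinity <- function(segments, prob) {
  k <- nrow(segments)
  n <- nrow(prob)
  S <- matrix(0, k, n)
  for (s in seq_len(k)) S[s, segments$start[s]:segments$end[s]] <- 1
  len <- segments$end - segments$start + 1L
  (S %*% prob %*% t(S)) / outer(len, len)
}

#' Average-linkage agglomeration under a merge threshold
#'
#' The clustering engine behind [cluster_segments()], exposed on a bare
#' affinity matrix. Starting from singletons, the pair of clusters with the
#' highest average affinity (mean over cross-cluster item pairs) is merged
#' while that linkage is at least `cut`. Ties are broken towards the pair
#' whose smallest item index is lowest, then by the other cluster's
#' smallest index, making the result deterministic.
#'
#' @param A Symmetric affinity matrix (only off-diagonal entries are used).
#' @param cut Minimum linkage at which merging continues.
#' @return List of integer vectors (sorted item indices), ordered by each
#'   cluster's smallest index.
#' @export
agglomerate_affinity <- function(A, cut) {
  clusters <- as.list(seq_len(nrow(A)))
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    best <- -Inf
    best_pair <- NULL
    key_old <- NULL
    minid <- vapply(clusters, min, 1L)
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      link <- mean(A[clusters[[a]], clusters[[b]]])
      key_new <- sort(c(minid[a], minid[b]))
      better <- link > best + 1e-12 ||
        (abs(link - best) <= 1e-12 && !is.null(key_old) &&
           (key_new[1] < key_old[1] ||
              (key_new[1] == key_old[1] && key_new[2] < key_old[2])))
      if (better) { best <- link; best_pair <- c(a, b); key_old <- key_new }
    }
    if (best < cut) break
    clusters[[best_pair[1]]] <- c(clusters[[best_pair[1]]],
                                  clusters[[best_pair[2]]])
    clusters[[best_pair[2]]] <- NULL
  }
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, min, 1L))]
}

new_candidate <- function(residues, segment_ids, model, hits) {
  rng <- range_from_residues(residues)
  structure(list(range = rng, segment_ids = sort(segment_ids),
                 mean_plddt = mean(model$plddt[residues]),
                 n_sse = NA_integer_,
                 hits = hits_for_range(hits, model$model_id, rng),
                 score = NA_real_, h_group = NA_character_),
            class = "domain_candidate")
}

# Hits belonging to a candidate: those with the majority of their query
# residues inside the candidate range.
hits_for_range <- function(hits, model_id, rng) {
  if (is.null(hits) || nrow(hits) == 0L) return(hits)
  hits <- hits[hits$query_id == model_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  res <- range_residues(rng)
  keep <- vapply(hits$query_range, function(q) {
    qres <- range_residues(parse_range(q))
    length(intersect(qres, res)) / length(qres) > 0.5
  }, logical(1))
  hits[keep, , drop = FALSE]
}

#' Cluster segments into domain candidates
#'
#' Average-linkage agglomerative clustering of segments under the
#' same-domain pair probability: the affinity between two segments is the
#' mean pair probability over all cross-segment residue pairs, the linkage
#' between two clusters is the mean affinity over their segment pairs, and
#' merging proceeds while the best linkage is at least `t$pair_prob_cut`.
#' Ties are broken deterministically towards the pair containing the lowest
#' segment index. Each final cluster becomes a candidate whose range is the
#' union of its segments (discontinuous domains are therefore supported).
#'
#' @param segments Data frame from [build_segments()].
#' @param model A [predicted_model()] with PAE.
#' @param hits Hit table for this model (may be `NULL`).
#' @param pair_model A fitted [fit_pair_model()].
#' @param t Thresholds.
#' @param prob Optional precomputed n x n probability matrix.
#' @return List of `domain_candidate` objects, ordered by range start.
#' @export
cluster_segments <- function(segments, model, hits, pair_model,
                             t = default_thresholds(), prob = NULL) {
  if (nrow(segments) == 0L) return(list())
  if (is.null(prob)) prob <- pair_probability_matrix(pair_model, model, hits)
  A <- segment_affinity(segments, prob)
  clusters <- agglomerate_affinity(A, t$pair_prob_cut)
  cands <- lapply(clusters, function(cl) {
    res <- unlist(lapply(cl, function(s)
      segments$start[s]:segments$end[s]))
    new_candidate(res, cl, model, hits)
  })
  cands[order(vapply(cands, function(c) c$range[1L, 1L], 1L))]
}

#' Merge or drop short over-split candidates
#'
#' Candidates shorter than `t$min_domain_len` residues are handled smallest
#' first: each is merged into whichever sequence-adjacent candidate has the
#' higher mean inter-candidate pair probability, provided that probability
#' is at least `merge_min_prob`; otherwise the short candidate is dropped
#' and its residues revert to unparsed. The pass iterates until no change.
#'
#' @param candidates List of `domain_candidate` objects (pairwise disjoint).
#' @param model A [predicted_model()] with PAE.
#' @param pair_model A fitted [fit_pair_model()].
#' @param t Thresholds.
#' @param hits Hit table (to refresh candidate hits after merging).
#' @param prob Optional precomputed probability matrix.
#' @param merge_min_prob Minimum inter-candidate probability for a merge.
#' @return Updated candidate list, ordered by range start.
#' @export
merge_small_candidates <- function(candidates, model, pair_model,
                                   t = default_thresholds(), hits = NULL,
                                   prob = NULL, merge_min_prob = 0.3) {
  if (!length(candidates)) return(candidates)
  if (is.null(prob)) prob <- pair_probability_matrix(pair_model, model, hits)
  repeat {
    ord <- order(vapply(candidates, function(c) c$range[1L, 1L], 1L))
    candidates <- candidates[ord]
    lens <- vapply(candidates, function(c) range_length(c$range), 1L)
    smalls <- which(lens < t$min_domain_len)
    if (!length(smalls)) break
    i <- smalls[order(lens[smalls])][1L]
    neigh <- c(i - 1L, i + 1L)
    neigh <- neigh[neigh >= 1L & neigh <= length(candidates)]
    res_i <- range_residues(candidates[[i]]$range)
    inter <- vapply(neigh, function(j) {
      mean(prob[res_i, range_residues(candidates[[j]]$range)])
    }, numeric(1))
    if (length(neigh) && max(inter) >= merge_min_prob) {
      j <- neigh[which.max(inter)]
      merged <- new_candidate(
        c(res_i, range_residues(candidates[[j]]$range)),
        c(candidates[[i]]$segment_ids, candidates[[j]]$segment_ids),
        model, hits)
      candidates <- c(candidates[-c(i, j)], list(merged))
    } else {
      candidates <- candidates[-i]
    }
    if (!length(candidates)) break
  }
  candidates[order(vapply(candidates, function(c) c$range[1L, 1L], 1L))]
}

#' Parse a model into domain candidates
#'
#' Full parsing stage: flag flexible residues from PAE, tile the ordered
#' runs into segments, cluster segments under the pair-probability model,
#' and merge or drop short over-split candidates. Every residue ends up in
#' exactly one of a candidate or the flexible mask (residues of dropped
#' candidates and of runs too short to segment are folded into the mask).
#'
#' @param model A [predicted_model()] with PAE.
#' @param hits Hit table for this model (may be `NULL`).
#' @param pair_model A fitted [fit_pair_model()].
#' @param t Thresholds.
#' @return List with `candidates` (list of `domain_candidate`) and
#'   `flexible` (logical mask over residues).
#' @export
parse_domains <- function(model, hits, pair_model, t = default_thresholds()) {
  flex <- flag_flexible_residues(model, t)
  segments <- build_segments(model, flex, t)
  prob <- pair_probability_matrix(pair_model, model, hits)
  cands <- cluster_segments(segments, model, hits, pair_model, t, prob)
  cands <- merge_small_candidates(cands, model, pair_model, t, hits, prob)
  in_cand <- logical(model_length(model))
  for (c in cands) in_cand[range_residues(c$range)] <- TRUE
  list(candidates = cands, flexible = !in_cand)
}
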