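# Shared fixtures, cached per test run so expensive objects are built once.
.fx <- new.env(parent = emptyenv())

# Pair model fitted on the default synthetic benchmark.
fx_pair_model <- function() {
  if (is.null(.fx$pm))
    .fx$pm <- fit_pair_model(make_pair_training(n_models = 6, seed = 1))
  .fx$pm
}

# The default 50-model synthetic proteome plus its end-to-end
# classification, shared by the recovery and conservation checks.
fx_benchmark <- function() {
  if (is.null(.fx$bench)) {
    prot <- generate_proteome(50, seed = 7)
    regions <- classify_proteome(prot$models, prot$hits, fx_pair_model())
    .fx$bench <- list(prot = prot, regions = regions)
  }
  .fx$bench
}

# A two-domain model with a linker and a disordered tail.
fx_two_domain <- function(seed = 3) {
  spec <- synthetic_spec(data.frame(
    kind = c("domain", "linker", "domain", "disordered_tail"),
    length = c(60, 15, 60, 30),
    group_id = c("H0001", NA, "H0002", NA),
    geometry = c("helix_bundle", NA, "sheet_sandwich", NA),
    scenario = c("assigned", NA, "assigned", NA),
    stringsAsFactors = FALSE), seed = seed)
  generate_model(spec)
}

# Minimal hand-built model: straight-line Calpha trace with a constant PAE
# off the diagonal, for exercising single rules in isolation.
fx_flat_model <- function(n = 50, pae_value = 2, plddt = 90) {
  coords <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  pae <- matrix(pae_value, n, n)
  diag(pae) <- 0.5
  predicted_model("FLAT", paste(rep("A", n), collapse = ""), coords,
                  rep(plddt, n), pae)
}

# Fabricate a domain candidate without running the parser.
fx_candidate <- function(range_text, mean_plddt, hits = NULL) {
  if (is.null(hits))
    hits <- data.frame(source = character(0), query_id = character(0),
                       query_range = character(0),
                       ref_domain_id = character(0),
                       ref_group_id = character(0),
                       confidence = numeric(0), ref_coverage = numeric(0))
  structure(list(range = parse_range(range_text), segment_ids = integer(0),
                 mean_plddt = mean_plddt, n_sse = NA_integer_,
                 hits = hits, score = NA_real_, h_group = NA_character_),
            class = "domain_candidate")
}

fx_hit <- function(query_range, conf, cov, group = "H0001",
                   model_id = "FLAT", source = "sequence_profile") {
  data.frame(source = source, query_id = model_id,
             query_range = query_range, ref_domain_id = paste0(group, "_d1"),
             ref_group_id = group, confidence = conf, ref_coverage = cov,
             stringsAsFactors = FALSE)
}

# ---- independent oracles ---------------------------------------------------

# Naive average-linkage agglomeration: explicit loops, linkage recomputed
# from scratch at every step, no shared code with the package internals.
oracle_agglomerate <- function(A, cut) {
  clusters <- lapply(seq_len(nrow(A)), identity)
  repeat {
    k <- length(clusters)
    if (k < 2) break
    best <- -Inf
    bp <- NULL
    bkey <- NULL
    for (a in seq_len(k - 1)) {
      for (b in seq.int(a + 1, k)) {
        s <- 0
        cnt <- 0
        for (x in clusters[[a]]) for (y in clusters[[b]]) {
          s <- s + A[x, y]
          cnt <- cnt + 1
        }
        link <- s / cnt
        key <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        take <- link > best + 1e-12 ||
          (abs(link - best) <= 1e-12 &&
             (key[1] < bkey[1] || (key[1] == bkey[1] && key[2] < bkey[2])))
        if (take) { best <- link; bp <- c(a, b); bkey <- key }
      }
    }
    if (best < cut) break
    clusters[[bp[1]]] <- c(clusters[[bp[1]]], clusters[[bp[2]]])
    clusters[[bp[2]]] <- NULL
  }
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, min, 1L))]
}

# Exhaustive hierarchical-feasibility check over item subsets (<= 8 items):
# a cluster is buildable iff it can be assembled by pairwise merges whose
# average linkage never drops below the cut.
oracle_buildable <- function(items, A, cut, memo = new.env()) {
  key <- paste(items, collapse = ",")
  if (!is.null(memo[[key]])) return(memo[[key]])
  if (length(items) == 1) { memo[[key]] <- TRUE; return(TRUE) }
  ok <- FALSE
  n <- length(items)
  for (mask in seq_len(2^(n - 1) - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    s1 <- items[sel]
    s2 <- items[!sel]
    if (mean(A[s1, s2, drop = FALSE]) >= cut &&
        oracle_buildable(s1, A, cut, memo) &&
        oracle_buildable(s2, A, cut, memo)) { ok <- TRUE; break }
  }
  memo[[key]] <- ok
  ok
}

# Brute-force Pearson chi-squared: observed vs expected over all 4 cells.
oracle_pearson_2x2 <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

# Rank-based AUROC (Mann-Whitney), independent of any fitted path.
oracle_auroc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

random_residue_range <- function(max_res = 200, max_segs = 4) {
  k <- sample.int(max_segs, 1)
  bounds <- sort(sample.int(max_res, 2 * k))
  residue_range(matrix(bounds, ncol = 2, byrow = TRUE))
}
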