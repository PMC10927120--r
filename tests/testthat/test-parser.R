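test_that("PAE partner counting flags flexible residues", {
  all_far <- fx_flat_model(n = 50, pae_value = 30)
  expect_true(all(flag_flexible_residues(all_far)))
  all_near <- fx_flat_model(n = 50, pae_value = 2)
  expect_false(any(flag_flexible_residues(all_near)))
  no_pae <- predicted_model("x", "MKV", cbind(c(0, 3.8, 7.6), 0, 0),
                            rep(90, 3))
  expect_error(flag_flexible_residues(no_pae), "PAE required")
})

test_that("linker residues are flagged, domain cores are not", {
  gm <- fx_two_domain(seed = 3)
  flex <- flag_flexible_residues(gm$model)
  blk <- rep(1:4, c(60, 15, 60, 30))
  expect_gte(mean(flex[blk == 2]), 0.8)   # linker
  expect_lte(mean(flex[blk == 1]), 0.05)  # domain cores
  expect_lte(mean(flex[blk == 3]), 0.05)
})

test_that("ordered runs tile into segments with the remainder rule", {
  m <- fx_flat_model(n = 20)
  mask <- rep(TRUE, 20)
  mask[1:12] <- FALSE
  seg <- build_segments(m, mask)
  expect_equal(seg$start, c(1L, 6L))
  expect_equal(seg$end, c(5L, 12L))  # remainder 2 absorbed into last segment
  mask <- rep(TRUE, 20)
  mask[1:5] <- FALSE
  seg <- build_segments(m, mask)
  expect_equal(nrow(seg), 1L)
  mask <- rep(TRUE, 20)
  mask[1:9] <- FALSE
  seg <- build_segments(m, mask)
  expect_equal(seg$end - seg$start + 1L, c(5L, 4L))  # remainder 4 kept
  # a 2-residue ordered run is too short for any segment
  mask <- rep(TRUE, 20)
  mask[10:11] <- FALSE
  expect_equal(nrow(build_segments(m, mask)), 0L)
})

test_that("segment clustering follows average linkage with the stated cut", {
  # two segments with unanimous probabilities
  m <- fx_flat_model(n = 10, pae_value = 2)
  seg <- data.frame(index = 1:2, start = c(1L, 6L), end = c(5L, 10L))
  pm <- fx_pair_model()
  one <- cluster_segments(seg, m, NULL, pm, prob = matrix(1, 10, 10))
  expect_equal(length(one), 1L)
  expect_equal(format_range(one[[1]]$range), "1-10")
  two <- cluster_segments(seg, m, NULL, pm, prob = matrix(0, 10, 10))
  expect_equal(length(two), 2L)
  expect_equal(cluster_segments(seg[0, ], m, NULL, pm), list())
})

test_that("hand-traced three-segment linkage merges into one cluster", {
  # affinities A-B = 0.9, B-C = 0.9, A-C = 0.2; after merging {A,B} the
  # average linkage to C is (0.9 + 0.2) / 2 = 0.55 >= 0.5, so all merge
  A <- rbind(c(1, 0.9, 0.2), c(0.9, 1, 0.9), c(0.2, 0.9, 1))
  expect_equal(agglomerate_affinity(A, 0.5), list(1:3))
  # at a higher cut the third segment stays out
  expect_equal(agglomerate_affinity(A, 0.6), list(1:2, 3L))
})

test_that("agglomeration matches the brute-force oracle on random instances", {
  set.seed(2024)
  for (rep in 1:60) {
    k <- sample(2:8, 1)
    A <- matrix(stats::runif(k * k), k, k)
    A <- (A + t(A)) / 2
    diag(A) <- 1
    cut <- stats::runif(1, 0.3, 0.7)
    got <- agglomerate_affinity(A, cut)
    expect_identical(got, oracle_agglomerate(A, cut))
    # result is maximal: no two final clusters are mergeable
    if (length(got) > 1) {
      for (a in seq_len(length(got) - 1)) for (b in seq.int(a + 1, length(got)))
        expect_lt(mean(A[got[[a]], got[[b]]]), cut)
    }
    # every final cluster is hierarchically buildable at the cut
    for (cl in got)
      expect_true(oracle_buildable(cl, A, cut))
  }
})

test_that("short candidates merge into their best neighbour or drop", {
  m <- fx_flat_model(n = 90, pae_value = 2)
  pm <- fx_pair_model()
  small <- fx_candidate("1-10", 90)
  big <- fx_candidate("11-90", 90)
  high <- matrix(0.8, 90, 90)
  merged <- merge_small_candidates(list(small, big), m, pm, prob = high)
  expect_equal(length(merged), 1L)
  expect_equal(format_range(merged[[1]]$range), "1-90")
  low <- matrix(0.1, 90, 90)
  dropped <- merge_small_candidates(list(small, big), m, pm, prob = low)
  expect_equal(length(dropped), 1L)
  expect_equal(format_range(dropped[[1]]$range), "11-90")
  ok <- list(fx_candidate("1-30", 90), fx_candidate("31-90", 90))
  kept <- merge_small_candidates(ok, m, pm, prob = low)
  expect_equal(vapply(kept, function(c) format_range(c$range), ""),
               c("1-30", "31-90"))
})

test_that("parse_domains recovers single domains and partitions residues", {
  catalog <- make_reference_catalog(5, seed = 1)
  spec <- synthetic_spec(data.frame(
    kind = "domain", length = 60, group_id = unique(catalog$h_group)[1],
    geometry = "helix_bundle", stringsAsFactors = FALSE), seed = 3)
  gm <- generate_model(spec)
  hits <- generate_hits(gm$truth, catalog, query_id = gm$model$model_id,
                        seed = 3)
  pd <- parse_domains(gm$model, hits, fx_pair_model())
  expect_equal(length(pd$candidates), 1L)
  covered <- range_residues(pd$candidates[[1]]$range)
  expect_gte(length(intersect(covered, 1:60)) / 60, 0.9)

  # all-disordered model: no candidates, everything flexible
  coil <- synthetic_spec(data.frame(kind = "disordered_tail", length = 50,
                                    group_id = NA, stringsAsFactors = FALSE),
                         seed = 4)
  gm2 <- generate_model(coil)
  pd2 <- parse_domains(gm2$model, NULL, fx_pair_model())
  expect_equal(length(pd2$candidates), 0L)
  expect_true(all(pd2$flexible))
})

test_that("candidates and the flexible mask partition every residue", {
  gm <- fx_two_domain(seed = 21)
  pd <- parse_domains(gm$model, NULL, fx_pair_model())
  n <- model_length(gm$model)
  coverage <- rep(0L, n)
  for (c in pd$candidates)
    coverage[range_residues(c$range)] <- coverage[range_residues(c$range)] + 1L
  coverage[pd$flexible] <- coverage[pd$flexible] + 1L
  expect_true(all(coverage == 1L))
})

test_that("raising the linkage cut never reduces the cluster count", {
  gm <- fx_two_domain(seed = 9)
  pm <- fx_pair_model()
  flex <- flag_flexible_residues(gm$model)
  seg <- build_segments(gm$model, flex)
  prob <- afdomain:::pair_probability_matrix(pm, gm$model, NULL)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(cut) {
    t <- default_thresholds(pair_prob_cut = cut)
    length(cluster_segments(seg, gm$model, NULL, pm, t, prob))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
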