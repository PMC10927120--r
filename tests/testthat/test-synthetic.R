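test_that("reference catalogs cover the five classes deterministically", {
  catalog <- make_reference_catalog(5, seed = 1)
  expect_equal(length(unique(catalog$h_group)), 5L)
  by_group <- catalog[!duplicated(catalog$h_group), ]
  expect_setequal(by_group$class5, class5_levels())
  expect_true(all(catalog$length >= 40 & catalog$length <= 300))
  expect_setequal(unique(catalog$kingdom), c("eukaryote", "bacteria"))
  expect_identical(make_reference_catalog(5, seed = 1), catalog)
  expect_error(make_reference_catalog(0), ">= 1")
})

test_that("generated models carry block-faithful ground truth", {
  spec <- synthetic_spec(data.frame(
    kind = c("domain", "disordered_tail"), length = c(60, 20),
    group_id = c("H0001", NA), geometry = c("helix_bundle", NA),
    stringsAsFactors = FALSE), seed = 3)
  gm <- generate_model(spec)
  expect_equal(model_length(gm$model), 80L)
  expect_equal(gm$truth$labels,
               c(rep("ASSIGNED", 60), rep("LOW_CONFIDENCE", 20)))
  expect_equal(nrow(gm$truth$partition), 1L)
  # determinism: identical spec and seed reproduce the model exactly
  gm2 <- generate_model(spec)
  expect_identical(gm$model, gm2$model)
  expect_identical(gm$truth, gm2$truth)
  # PAE invariants: clipped to the AFDB payload window, diagonal <= 1
  expect_true(all(gm$model$pae >= 0.2 & gm$model$pae <= 31.75))
  expect_true(all(diag(gm$model$pae) <= 1))
  expect_error(generate_model(
    synthetic_spec(data.frame(kind = "domain", length = 0,
                              group_id = "H1"))))
})

test_that("within-domain PAE sits well below between-domain PAE", {
  gm <- fx_two_domain(seed = 11)
  ps <- (gm$model$pae + t(gm$model$pae)) / 2
  blk <- rep(1:4, c(60, 15, 60, 30))
  ordered <- blk %in% c(1, 3)
  ut <- upper.tri(ps)
  within <- ps[outer(blk, blk, "==") & outer(ordered, ordered, "&") & ut]
  between <- ps[outer(blk, blk, "!=") & outer(ordered, ordered, "&") & ut]
  expect_gt(length(within), 1e4 / 4)
  expect_lt(mean(within), mean(between))
  # distribution overlap across the midpoint is below 1%
  mid <- mean(c(4, 20))
  overlap <- (sum(within > mid) + sum(between < mid)) /
    (length(within) + length(between))
  expect_lt(overlap, 0.01)
})

test_that("hit tables follow the ground truth and scenario flags", {
  catalog <- make_reference_catalog(10, seed = 1)
  groups <- unique(catalog$h_group)
  spec <- synthetic_spec(data.frame(
    kind = c("domain", "linker", "domain"), length = c(60, 12, 60),
    group_id = c(groups[1], NA, groups[2]), geometry = "helix_bundle",
    scenario = c("assigned", NA, "partial"), stringsAsFactors = FALSE),
    seed = 11)
  gm <- generate_model(spec)
  hits <- generate_hits(gm$truth, catalog, decoy_rate = 0, seed = 11)
  # with no decoys every hit points at its block's true group
  expect_true(all(hits$ref_group_id %in% c(groups[1], groups[2])))
  part <- hits[hits$ref_group_id == groups[2], ]
  best <- part[which.max(part$confidence * part$ref_coverage), ]
  expect_gte(best$confidence, 0.8)
  expect_lt(best$ref_coverage, 0.5)
  expect_identical(generate_hits(gm$truth, catalog, decoy_rate = 0,
                                 seed = 11), hits)
  bad_truth <- gm$truth
  bad_truth$partition$group_id[1] <- "H9999"
  expect_error(generate_hits(bad_truth, catalog), "absent from catalog")
})

test_that("unassigned-scenario blocks emit no hits", {
  catalog <- make_reference_catalog(4, seed = 2)
  spec <- synthetic_spec(data.frame(
    kind = "domain", length = 60, group_id = unique(catalog$h_group)[1],
    geometry = "helix_bundle", scenario = "unassigned",
    stringsAsFactors = FALSE), seed = 5)
  gm <- generate_model(spec)
  hits <- generate_hits(gm$truth, catalog, seed = 5)
  expect_equal(nrow(hits), 0L)
})

test_that("proteome generation respects the category mix", {
  expect_error(generate_proteome(2, mix = c(assigned = 0.5, flexible = 0.4)),
               "sum to 1")
  one <- generate_proteome(1, mix = c(assigned = 1), seed = 5)
  expect_equal(unname(one$expected_fractions[["assigned"]]), 1)
  bench <- fx_benchmark()
  prot <- bench$prot
  expect_equal(length(prot$models), 50L)
  # ground-truth labels partition every residue of every model
  for (i in seq_along(prot$models))
    expect_equal(length(prot$truths[[i]]$labels),
                 model_length(prot$models[[i]]))
  # realised category fractions track the requested mix
  expect_true(all(abs(prot$expected_fractions - prot$mix) <= 0.05))
  # determinism of the whole bundle
  again <- generate_proteome(3, seed = 7)
  again2 <- generate_proteome(3, seed = 7)
  expect_identical(again$models, again2$models)
  expect_identical(again$hits, again2$hits)
})

test_that("synthetic families have high intra- and low inter-similarity", {
  fam <- make_sequence_families(3, 4, seed = 9)
  expect_equal(nrow(fam), 12L)
  within <- local_identity(fam$sequence[1], fam$sequence[2])
  expect_gt(within$identity, 0.85)
  expect_gt(within$coverage_a, 0.95)
  a <- fam$sequence[fam$family == "F01"][1]
  b <- fam$sequence[fam$family == "F02"][1]
  inter <- local_identity(a, b)
  # unrelated parents never satisfy the joint identity+coverage criterion
  expect_false(inter$identity >= 0.7 && inter$coverage_a >= 0.7 &&
                 inter$coverage_b >= 0.7)
})
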