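# Ideal geometries built independently of the package's generator.
ideal_helix <- function(n, rise = 1.5, radius = 2.3, twist = 100) {
  th <- (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * (seq_len(n) - 1))
}

test_that("the Calpha detector finds helices and ignores straight chains", {
  xyz <- ideal_helix(20)
  # the stated distance windows hold on the ideal geometry itself
  d2 <- sqrt(sum((xyz[1, ] - xyz[3, ])^2))
  d3 <- sqrt(sum((xyz[1, ] - xyz[4, ])^2))
  expect_true(d2 >= 5.0 && d2 <= 6.0)
  expect_true(d3 >= 4.7 && d3 <= 6.1)
  m <- predicted_model("helix", paste(rep("A", 20), collapse = ""),
                       xyz, rep(90, 20))
  sse <- assign_sse(m)
  expect_equal(sse$n_sse, 1L)
  expect_true(all(sse$states[1:17] == "H"))

  line <- fx_flat_model(n = 20)  # 3.8 A spacing: d(i,i+2) = 7.6, no window
  expect_equal(assign_sse(line)$n_sse, 0L)
  expect_equal(assign_sse(line, parse_range("1-4"))$n_sse, 0L)
  expect_error(assign_sse(line, parse_range("15-25")), "outside model")
})

test_that("strand geometry is detected as extended structure", {
  t <- 0:11
  xyz <- cbind(3.3 * t, 0.9 * (-1)^t, 0)
  m <- predicted_model("strand", paste(rep("V", 12), collapse = ""),
                       xyz, rep(90, 12))
  sse <- assign_sse(m)
  expect_equal(sse$n_sse, 1L)
  expect_true(all(sse$states[1:9] == "E"))
})

test_that("candidate scoring applies the confidence/coverage rules", {
  t <- default_thresholds()
  c1 <- fx_candidate("1-60", 90, hits = fx_hit("1-60", 0.95, 0.9))
  s1 <- score_candidate(c1, t)
  expect_equal(s1$score, 0.855)
  expect_equal(s1$label, "ASSIGNED")
  c2 <- fx_candidate("1-60", 90, hits = fx_hit("1-60", 0.9, 0.3))
  expect_equal(score_candidate(c2, t)$label, "PARTIAL")
  c3 <- fx_candidate("1-60", 90)
  s3 <- score_candidate(c3, t)
  expect_equal(s3$label, "UNASSIGNED")
  expect_true(is.na(s3$score))
  # the coverage grey zone between cov_partial and cov_assign is unassigned
  c4 <- fx_candidate("1-60", 90, hits = fx_hit("1-60", 0.95, 0.6))
  expect_equal(score_candidate(c4, t)$label, "UNASSIGNED")
  # best hit is chosen by confidence x coverage
  c5 <- fx_candidate("1-60", 90,
                     hits = rbind(fx_hit("1-60", 0.5, 0.9),
                                  fx_hit("1-60", 0.9, 0.85, group = "H0002")))
  s5 <- score_candidate(c5, t)
  expect_equal(s5$h_group, "H0002")
})

test_that("classification precedence is low-confidence, simple, then hits", {
  helix <- predicted_model("H1", paste(rep("A", 30), collapse = ""),
                           ideal_helix(30), rep(90, 30))
  # rule 1: low mean pLDDT wins regardless of structure or hits
  lowc <- fx_candidate("1-30", 50, hits = fx_hit("1-30", 0.95, 0.9,
                                                 model_id = "H1"))
  reg <- classify_model(helix, list(lowc), rep(FALSE, 30))
  expect_equal(reg$category, "LOW_CONFIDENCE")
  # rule 2: a single-helix candidate is SIMPLE even with a confident hit
  simp <- fx_candidate("1-30", 90, hits = fx_hit("1-30", 0.95, 0.9,
                                                 model_id = "H1"))
  reg <- classify_model(helix, list(simp), rep(FALSE, 30))
  expect_equal(reg$category, "SIMPLE")
  expect_true(is.na(reg$h_group))
  # residues outside candidates: FLEXIBLE above the cutoff, else demoted
  m <- fx_flat_model(n = 10, plddt = 85)
  m$plddt[6:10] <- 50
  reg <- classify_model(m, list(), rep(TRUE, 10))
  expect_equal(reg$category, c("FLEXIBLE", "LOW_CONFIDENCE"))
  expect_equal(reg$range, c("1-5", "6-10"))
  # overlapping candidates violate the parser contract
  expect_error(
    classify_model(m, list(fx_candidate("1-6", 90), fx_candidate("5-10", 90)),
                   rep(FALSE, 10)),
    "parser contract")
})

test_that("every residue receives exactly one label", {
  gm <- fx_two_domain(seed = 13)
  pd <- parse_domains(gm$model, NULL, fx_pair_model())
  reg <- classify_model(gm$model, pd$candidates, pd$flexible)
  labels <- region_label_vector(reg, model_length(gm$model))
  expect_false(anyNA(labels))
  expect_true(all(labels %in% region_labels()))
})

test_that("proteome summaries conserve counts and fractions", {
  regions <- data.frame(
    model_id = "M1", range = c("1-60", "61-100"),
    category = c("ASSIGNED", "FLEXIBLE"), stringsAsFactors = FALSE)
  s <- summarize_proteome(regions, "toy")
  expect_equal(unname(s$fractions[["ASSIGNED"]]), 0.6)
  expect_equal(unname(s$fractions[["FLEXIBLE"]]), 0.4)
  expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
  expect_equal(sum(s$counts), 100)
  expect_equal(s$n_domains, 1L)
  expect_error(summarize_proteome(regions[0, ]), "no regions")
})

test_that("raising the pLDDT cutoff never shrinks the demoted fraction", {
  gm <- fx_two_domain(seed = 17)
  pd <- parse_domains(gm$model, NULL, fx_pair_model())
  fracs <- vapply(c(50, 60, 70, 80, 90), function(cut) {
    t <- default_thresholds(plddt_min = cut)
    reg <- classify_model(gm$model, pd$candidates, pd$flexible, t)
    summarize_proteome(reg)$fractions[["LOW_CONFIDENCE"]]
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})
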