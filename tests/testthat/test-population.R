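fake_regions <- function(groups, model_ids = NULL) {
  n <- length(groups)
  if (is.null(model_ids)) model_ids <- paste0("M", seq_len(n))
  data.frame(model_id = model_ids,
             range = sprintf("%d-%d", 1 + 100 * (seq_len(n) - 1),
                             100 * seq_len(n)),
             category = "ASSIGNED", h_group = groups,
             stringsAsFactors = FALSE)
}

test_that("assigned regions tally into relative populations", {
  catalog <- make_reference_catalog(4, seed = 1)
  g <- unique(catalog$h_group)
  regions <- fake_regions(c(g[1], g[1], g[1], g[2]))
  strata <- stats::setNames(rep("all", 4), regions$model_id)
  tab <- tally_populations(regions, catalog, strata)
  rel <- relative_populations(tab)
  expect_equal(unname(rel["all", g[1]]), 0.75)
  expect_equal(unname(rel["all", g[2]]), 0.25)
  # non-assigned regions never contribute
  regions2 <- regions
  regions2$category[1] <- "PARTIAL"
  tab2 <- tally_populations(regions2, catalog, strata)
  expect_equal(sum(tab2$counts), 3)
  # unknown group is an error; empty input an empty table
  bad <- fake_regions("H9999")
  expect_error(tally_populations(bad, catalog,
                                 c(M1 = "all")), "unknown h_group")
  none <- regions
  none$category <- "FLEXIBLE"
  expect_equal(sum(tally_populations(none, catalog, strata)$counts), 0)
})

test_that("roll-ups conserve totals across hierarchy levels", {
  catalog <- make_reference_catalog(7, seed = 3)
  g <- unique(catalog$h_group)
  set.seed(5)
  regions <- fake_regions(sample(g, 30, replace = TRUE))
  strata <- stats::setNames(sample(c("spA", "spB"), 30, TRUE),
                            regions$model_id)
  tab <- tally_populations(regions, catalog, strata)
  for (level in c("architecture", "class5")) {
    up <- rollup_populations(tab, level)
    expect_equal(sum(up), sum(tab$counts))
    expect_equal(unname(rowSums(up)), unname(rowSums(tab$counts)))
  }
})

test_that("stratified normalisation gives observed/expected ratios", {
  m <- matrix(c(2, 0, 0, 2), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("h1", "h2")))
  expect_equal(unname(stratified_normalize(m)),
               matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
  u <- matrix(1, 2, 2, dimnames = list(c("s1", "s2"), c("h1", "h2")))
  expect_true(all(stratified_normalize(u) == 1))
  # algebraic identity: sum over cells of value * row * col / T equals T
  set.seed(8)
  for (k in 1:20) {
    counts <- matrix(rpois(12, 5), 3, 4,
                     dimnames = list(paste0("s", 1:3), paste0("h", 1:4)))
    if (sum(counts) == 0) next
    v <- stratified_normalize(counts)
    T_ <- sum(counts)
    back <- sum(v * outer(rowSums(counts), colSums(counts)) / T_)
    expect_equal(back, T_, tolerance = 1e-9)
  }
  expect_error(stratified_normalize(matrix(0, 2, 2,
                                           dimnames = list(1:2, 1:2))),
               "grand total")
})

test_that("the closed-form chi-squared matches hand and brute-force values", {
  ct <- chi2_2x2(30, 70, 10, 90)
  expect_equal(ct$chi2, 12.5)
  expect_equal(chi2_2x2(10, 90, 10, 90)$chi2, 0)
  expect_equal(chi2_2x2(10, 90, 10, 90)$p, 1)
  expect_equal(chi2_2x2(0, 0, 5, 5), list(chi2 = 0, p = 1))
  expect_error(chi2_2x2(-1, 5, 5, 5), "negative")
  set.seed(99)
  for (k in 1:1000) {
    x <- rpois(4, sample(c(3, 20, 80), 1)) + 1
    got <- chi2_2x2(x[1], x[2], x[3], x[4])
    expect_equal(got$chi2, oracle_pearson_2x2(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-9)
  }
  # spot-check p-values against the stock test without continuity correction
  for (k in 1:25) {
    x <- rpois(4, 30) + 5
    ref <- stats::chisq.test(matrix(x, 2, byrow = TRUE), correct = FALSE)
    got <- chi2_2x2(x[1], x[2], x[3], x[4])
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("set comparison applies the Bonferroni rule over observed groups", {
  obs <- c(gA = 300, gB = 100, gC = 600)
  ref <- c(gA = 100, gB = 110, gC = 790)
  out <- compare_sets(obs, ref, alpha = 0.05)
  expect_equal(attr(out, "m"), 3L)
  expect_true(all(diff(out$p) >= 0))
  # identical proportions are never significant
  same <- compare_sets(c(g1 = 50, g2 = 50), c(g1 = 50, g2 = 50))
  expect_false(any(same$significant))
  # a 0.30 vs 0.10 proportion at totals 1000 vs 1000 is significant at m=10
  obs10 <- stats::setNames(c(300, rep(700 / 9, 9)), paste0("g", 1:10))
  ref10 <- stats::setNames(c(100, rep(100, 9)), paste0("g", 1:10))
  out10 <- compare_sets(obs10, ref10)
  row <- out10[out10$group_id == "g1", ]
  expect_gt(row$chi2, 100)
  expect_true(row$significant)
  expect_error(compare_sets(c(g1 = 0), ref), "empty observed")
})

test_that("the significant set shrinks as the test count grows", {
  set.seed(13)
  obs <- stats::setNames(rpois(40, 25) + 1, paste0("g", 1:40))
  ref <- stats::setNames(rpois(40, 20) + 1, paste0("g", 1:40))
  out <- compare_sets(obs, ref, alpha = 0.05)
  p <- out$p
  n_sig <- vapply(c(1, 5, 10, 40, 100, 1000),
                  function(m) sum(p < 0.05 / m), numeric(1))
  expect_true(all(diff(n_sig) <= 0))
  # union mode tests at least as many groups as observed mode
  obs_missing <- obs[1:30]
  m_obs <- attr(compare_sets(obs_missing, ref, m_mode = "observed"), "m")
  m_uni <- attr(compare_sets(obs_missing, ref, m_mode = "union"), "m")
  expect_lte(m_obs, m_uni)
  sig_obs <- sum(compare_sets(obs_missing, ref, m_mode = "observed")$significant)
  sig_uni <- sum(compare_sets(obs_missing, ref, m_mode = "union")$significant)
  expect_gte(sig_obs, sig_uni)
})
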