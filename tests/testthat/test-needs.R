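test_that("simple scoring hits the floor, midpoint and ceiling exactly", {
  expect_true(all(whodas_scores(rep(0, 32)) == 0))
  expect_true(all(whodas_scores(rep(4, 32)) == 100))
  expect_true(all(whodas_scores(rep(2, 32)) == 50))
})

test_that("scoring is affine per item and invariant to within-domain permutation", {
  set.seed(7)
  map <- whodas_domain_map()
  items <- sample(0:4, 32, replace = TRUE)
  base <- whodas_scores(items, map)
  # raising one item by 1 adds exactly 100 / (4 * n_d) to its domain
  for (it in c(1, 10, 32)) {
    if (items[it] == 4) next
    bumped <- items; bumped[it] <- bumped[it] + 1
    d <- map[it]
    delta <- whodas_scores(bumped, map)[[paste0("d", d)]] -
      base[[paste0("d", d)]]
    expect_equal(delta, 100 / (4 * sum(map == d)))
  }
  # permuting items within a domain leaves every score unchanged
  perm <- unlist(lapply(1:6, function(d) sample(which(map == d))))
  expect_equal(whodas_scores(items[perm], map[perm]), base)
})

test_that("responses outside 0-4 and malformed maps are rejected", {
  expect_error(whodas_scores(c(rep(2, 31), 5)), "0, 1, 2, 3, 4")
  expect_error(whodas_scores(rep(2, 30)), "32 items")
  expect_error(whodas_scores(rep(2, 32), rep(1:5, length.out = 32)),
               "domains")
})

test_that("stratification reproduces the published group profiles", {
  # group mean scores of the high-need and general-demand cohorts
  high_means <- data.frame(d1 = 95.35, d2 = 94.45, d3 = 95.11,
                           summary = 89.43)
  gen_means <- data.frame(d1 = 61.17, d2 = 44.64, d3 = 40.05,
                          summary = 54.56)
  expect_equal(stratify_case(high_means), "high_level_of_need")
  expect_equal(stratify_case(gen_means), "general_demand")
  # the inequalities are strict: exactly at a cutoff is still general demand
  at_cut <- data.frame(d1 = 77.5, d2 = 90, d3 = 90, summary = 90)
  expect_equal(stratify_case(at_cut), "general_demand")
})

test_that("the Domain 2 footnote cutoff is reachable through configuration", {
  x <- data.frame(d1 = 80, d2 = 78.3, d3 = 60, summary = 70)
  expect_equal(stratify_case(x, needs_cutoffs()), "general_demand")
  expect_equal(stratify_case(x, needs_cutoffs(d2 = 78)), "high_level_of_need")
})

test_that("cohort stratification partitions and scores items when needed", {
  cases <- make_case_rows(10)
  sc <- data.frame(d1 = rep(c(90, 60), c(4, 6)), d2 = rep(c(90, 60), c(4, 6)),
                   d3 = rep(c(90, 40), c(4, 6)), d4 = 50, d5 = 50, d6 = 50,
                   summary = rep(c(90, 50), c(4, 6)))
  res <- stratify_cohort(cbind(cases, sc))
  expect_equal(unname(res$counts), c(6, 4))
  expect_equal(sum(res$counts), nrow(cases))
  expect_equal(nrow(res$general) + nrow(res$high), nrow(cases))

  # item-only cohort: all-4 responses must stratify high
  items <- as.data.frame(matrix(4, 2, 32))
  names(items) <- paste0("item_", 1:32)
  res_items <- stratify_cohort(cbind(make_case_rows(2), items))
  expect_equal(unname(res_items$counts), c(0, 2))

  # neither scores nor items is an error; empty cohort is fine
  expect_error(stratify_cohort(make_case_rows(2)), "domain scores")
  empty <- stratify_cohort(cbind(cases, sc)[0, ])
  expect_equal(unname(empty$counts), c(0, 0))
})

test_that("raising any single domain score never demotes a case", {
  set.seed(42)
  for (i in 1:200) {
    sc <- data.frame(d1 = runif(1, 0, 100), d2 = runif(1, 0, 100),
                     d3 = runif(1, 0, 100), summary = runif(1, 0, 100))
    before <- stratify_case(sc)
    col <- sample(names(sc), 1)
    sc[[col]] <- min(100, sc[[col]] + runif(1, 0, 40))
    after <- stratify_case(sc)
    if (before == "high_level_of_need")
      expect_equal(after, "high_level_of_need")
  }
})

test_that("generated cohorts stratify back to the target mixture", {
  cohort <- gen_whodas_cohort(n = 1000, p_high = 0.3, seed = 1)
  res <- stratify_cohort(cohort)
  bounds <- binom_bounds(1000, 0.3)
  expect_gte(res$counts[["high_level_of_need"]], bounds[1])
  expect_lte(res$counts[["high_level_of_need"]], bounds[2])
  # generating labels are recovered exactly (components are truncated to the
  # correct side of the cutoffs)
  expect_equal(res$cases$needs_group, cohort$true_group)
})
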