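make_fit <- function(breakpoints, slopes, bin_width = 50, sig = NULL) {
  structure(list(k = length(breakpoints), breakpoints = breakpoints,
                 intercept = 0, slopes = slopes,
                 slope_changes = diff(slopes), rss = 0,
                 n = 40, bin_width = bin_width, min_seg = 3,
                 x = NULL, y = NULL, fitted = NULL, selection = NULL,
                 significance = if (!is.null(sig))
                   data.frame(breakpoint = breakpoints,
                              slope_change = diff(slopes),
                              p_value = ifelse(sig, 0, 1),
                              significant = sig),
                 note = NULL),
            class = "joinpoint_fit")
}

test_that("PWD and TLD are the first significant down- and up-turns", {
  fit <- make_fit(c(300, 1500), c(2, -1, 0.5), sig = c(TRUE, TRUE))
  ind <- extract_pwd_tld(fit)
  expect_equal(ind$pwd, 300)
  expect_equal(ind$tld, 1500)

  # all slopes positive -> neither indicator
  up <- make_fit(c(300, 1500), c(1, 2, 3), sig = c(TRUE, TRUE))
  expect_true(is.na(extract_pwd_tld(up)$pwd))
  expect_true(is.na(extract_pwd_tld(up)$tld))

  # single downturn -> PWD only
  down <- make_fit(650, c(1, -1), sig = TRUE)
  expect_equal(extract_pwd_tld(down)$pwd, 650)
  expect_true(is.na(extract_pwd_tld(down)$tld))

  # non-significant breaks are passed over
  ns <- make_fit(c(300, 1500), c(2, -1, 0.5), sig = c(FALSE, TRUE))
  expect_true(is.na(extract_pwd_tld(ns)$pwd))
  expect_equal(extract_pwd_tld(ns)$tld, 1500)

  # k = 0 -> neither
  expect_true(is.na(extract_pwd_tld(make_fit(numeric(0), 1))$pwd))
})

test_that("reported indicators land on the bin-width grid", {
  fit <- make_fit(c(325, 1475), c(2, -1, 0.5), sig = c(TRUE, TRUE))
  ind <- extract_pwd_tld(fit)
  expect_equal(ind$pwd %% 50, 0)
  expect_equal(ind$tld %% 50, 0)
  expect_lte(abs(ind$pwd - 325), 50)
  expect_lte(abs(ind$tld - 1475), 50)
})

test_that("areas classify by indicator presence as published", {
  expect_equal(classify_area(650, 1200), "both")        # Taipei City
  expect_equal(classify_area(150, NA), "only_pwd")      # Hsinchu City
  expect_equal(classify_area(NA, 6250), "only_tld")     # Yunlin County
  expect_equal(classify_area(NA, NA), "neither")        # Penghu County
  expect_equal(classify_area(c(650, NA), c(1200, NA)), c("both", "neither"))
})

test_that("service density reproduces the published ratios", {
  expect_equal(service_density(1564, 162), 9.65)   # Taipei City
  expect_equal(service_density(3, 6), 0.50)        # Lienchiang County
  expect_equal(service_density(7, 7), 1.00)
  expect_true(is.na(service_density(10, 0)))       # undefined, not zero
  expect_error(service_density(-1, 5), "non-negative")
})

test_that("zones split at inclusive PWD/TLD bounds", {
  expect_equal(classify_zone(100, 650, 1200), "profitable")
  expect_equal(classify_zone(650, 650, 1200), "profitable")   # boundary
  expect_equal(classify_zone(1200, 650, 1200), "tolerable")   # boundary
  expect_equal(classify_zone(5000, 650, 1200), "beyond_tolerance")
  # missing bounds skip the corresponding comparison
  expect_equal(classify_zone(c(800, 2000), NA, 1200),
               c("tolerable", "beyond_tolerance"))
  expect_equal(classify_zone(c(100, 800), 650, NA),
               c("profitable", "unclassified"))
  expect_error(classify_zone(100, NA, NA), "no indicator")
})

test_that("priority ranking follows the three-tier rule with TLD descending", {
  res <- data.frame(
    area_code = c("Yunlin", "Taitung", "Changhua", "Taipei", "HsinchuC",
                  "Penghu"),
    category = c("only_tld", "only_tld", "both", "both", "only_pwd",
                 "neither"),
    tld = c(6250, 1300, 4750, 1200, NA, NA),
    density_ratio = c(5.39, 2.62, 4.62, 9.65, 3.46, 2.46),
    stringsAsFactors = FALSE)
  ranked <- rank_priorities(res)
  expect_equal(ranked$area_code,
               c("Yunlin", "Taitung", "Changhua", "Taipei", "HsinchuC",
                 "Penghu"))
  expect_equal(ranked$priority_rank, 1:6)
  # total order: output is a permutation of the input
  expect_setequal(ranked$area_code, res$area_code)
  expect_error(rank_priorities(rbind(res, res[1, ])), "duplicate")
})

test_that("ties break by density then area code; single area ranks first", {
  res <- data.frame(area_code = c("B", "A", "C"),
                    category = rep("neither", 3),
                    tld = NA_real_,
                    density_ratio = c(2, 5, 2),
                    stringsAsFactors = FALSE)
  expect_equal(rank_priorities(res)$area_code, c("A", "B", "C"))
  one <- rank_priorities(res[1, ])
  expect_equal(one$priority_rank, 1)
})

test_that("category summaries reproduce the published national counts", {
  long <- taiwan_indicators_long()
  results <- area_results_from_indicators(long)
  sm <- summarize_categories(results)
  all_row <- sm[sm$group == "all", ]
  expect_equal(all_row$both, 15)
  expect_equal(all_row$only_pwd, 2)
  expect_equal(all_row$only_tld, 2)
  expect_equal(all_row$neither, 3)
  high_row <- sm[sm$group == "high_level_of_need", ]
  expect_equal(high_row$both, 4)
  expect_equal(high_row$only_pwd, 1)
  expect_equal(high_row$only_tld, 4)
  expect_equal(high_row$neither, 13)
  # counts always sum to the number of areas
  expect_true(all(sm$both + sm$only_pwd + sm$only_tld + sm$neither ==
                    sm$n_areas))
  expect_true(all(sm$n_areas == 22))
  # empty input -> all-zero counts
  empty <- summarize_categories(results[0, ])
  expect_equal(empty$n_areas, 0)
})
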