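# WHODAS 2.0 simple scoring and needs stratification.

#' Default WHODAS 2.0 item-to-domain map (32-item administration)
#'
#' The 36-item instrument minus the four employment/study items, leaving 32
#' items over six domains: cognition (6 items), mobility (5), self-care (4),
#' getting along (5), life activities — household part only (4), and
#' participation (8). Items are assumed ordered by domain.
#'
#' @return Integer vector of length 32; element `i` is the domain (1-6) of
#'   `item_i`.
#' @export
whodas_domain_map <- function() {
  rep(1:6, times = c(6L, 5L, 4L, 5L, 4L, 8L))
}

#' WHODAS 2.0 simple (sum-and-rescale) scoring
#'
#' Converts ordinal item responses (0 = no difficulty ... 4 = extreme
#' difficulty) into 0-100 domain scores and a summary score. Each domain
#' score is `100 * sum(items in domain) / (4 * n items in domain)`; the
#' summary is the same rescaling over all items. Higher scores mean more
#' disability.
#'
#' @param items A numeric vector of length `length(domain_map)` or a matrix /
#'   data frame with one row per respondent and one column per item
#'   (`item_1`, `item_2`, ... order). Responses must be integers in 0-4.
#' @param domain_map Item-to-domain assignment; see [whodas_domain_map()].
#' @return A data frame with columns `d1`..`d6` and `summary`, one row per
#'   respondent.
#' @examples
#' whodas_scores(rep(2, 32))   # mid-scale responses -> all scores 50
#' @export
whodas_scores <- function(items, domain_map = whodas_domain_map()) {
  if (is.vector(items) && !is.list(items)) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != length(domain_map))
    stop("domain_map covers ", length(domain_map), " items but ",
         ncol(items), " responses supplied", call. = FALSE)
  domains <- sort(unique(domain_map))
  if (!identical(domains, 1:6))
    stop("domain_map must assign items to domains 1..6", call. = FALSE)
  if (anyNA(items) || !all(items %in% 0:4))
    stop("item responses must all be in 0, 1, 2, 3, 4", call. = FALSE)

  out <- lapply(1:6, function(d) {
    idx <- which(domain_map == d)
    100 * rowSums(items[, idx, drop = FALSE]) / (4 * length(idx))
  })
  names(out) <- paste0("d", 1:6)
  out$summary <- 100 * rowSums(items) / (4 * ncol(items))
  as.data.frame(out)
}

#' Needs-stratification cutoffs
#'
#' Domain-score thresholds separating general demand from high level of need.
#' The defaults are the published institutionalisation-risk cutoffs for
#' dementia cohorts: cognition > 77.5, mobility > 78.5, self-care > 55 and
#' summary > 66.5, combined conjunctively (all four must be exceeded;
#' inequalities are strict). `rule = "any"` switches to a disjunctive
#' combination for sensitivity analyses.
#'
#' @param d1,d2,d3,summary Cutoffs on the 0-100 score scale.
#' @param rule `"all"` (default) or `"any"`.
#' @return An object of class `needs_cutoffs`.
#' @export
needs_cutoffs <- function(d1 = 77.5, d2 = 78.5, d3 = 55, summary = 66.5,
                          rule = c("all", "any")) {
  rule <- match.arg(rule)
  vals <- c(d1 = d1, d2 = d2, d3 = d3, summary = summary)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100))
    stop("cutoffs must lie in [0, 100]", call. = FALSE)
  structure(list(d1 = d1, d2 = d2, d3 = d3, summary = summary, rule = rule),
            class = "needs_cutoffs")
}

#' @export
print.needs_cutoffs <- function(x, ...) {
  cat(sprintf("Needs cutoffs (%s of): D1 > %s, D2 > %s, D3 > %s, summary > %s\n",
              x$rule, x$d1, x$d2, x$d3, x$summary))
  invisible(x)
}

#' Assign cases to a needs group
#'
#' A case is `high_level_of_need` iff its scores exceed the cutoffs under the
#' cutoff rule (strictly); otherwise `general_demand`.
#'
#' @param scores A data frame with columns `d1`, `d2`, `d3` and `summary`
#'   (extra columns ignored), one row per case.
#' @param cutoffs A [needs_cutoffs()] object.
#' @return Character vector: `"high_level_of_need"` or `"general_demand"`.
#' @export
stratify_case <- function(scores, cutoffs = needs_cutoffs()) {
  stopifnot(inherits(cutoffs, "needs_cutoffs"))
  scores <- as.data.frame(scores)
  need <- c("d1", "d2", "d3", "summary")
  if (!all(need %in% names(scores)))
    stop("scores must contain columns d1, d2, d3, summary", call. = FALSE)
  tests <- cbind(scores$d1 > cutoffs$d1,
                 scores$d2 > cutoffs$d2,
                 scores$d3 > cutoffs$d3,
                 scores$summary > cutoffs$summary)
  high <- if (cutoffs$rule == "all") rowSums(tests) == 4 else rowSums(tests) > 0
  ifelse(high, "high_level_of_need", "general_demand")
}

#' Stratify a cohort into general-demand and high-need groups
#'
#' Cases carrying domain scores are stratified directly; cases with only raw
#' item responses (`item_1`..`item_32`) are scored first via
#' [whodas_scores()]. Cases with neither are rejected.
#'
#' @param cases Case data frame (see [read_cases()]).
#' @param cutoffs A [needs_cutoffs()] object.
#' @param domain_map Item-to-domain map used when scores must be computed.
#' @return A list: `cases` (input plus a `needs_group` column), `general` and
#'   `high` (the two partitions) and `counts`, a named integer vector that
#'   always sums to `nrow(cases)`.
#' @export
stratify_cohort <- function(cases, cutoffs = needs_cutoffs(),
                            domain_map = whodas_domain_map()) {
  score_cols <- c("d1", "d2", "d3", "summary")
  item_cols <- paste0("item_", seq_along(domain_map))
  if (nrow(cases) == 0) {
    cases$needs_group <- character(0)
  } else if (all(score_cols %in% names(cases)) &&
             !anyNA(cases$d1) && !anyNA(cases$d2) &&
             !anyNA(cases$d3) && !anyNA(cases$summary)) {
    cases$needs_group <- stratify_case(cases, cutoffs)
  } else if (all(item_cols %in% names(cases))) {
    sc <- whodas_scores(as.matrix(cases[item_cols]), domain_map)
    cases[names(sc)] <- sc
    cases$needs_group <- stratify_case(sc, cutoffs)
  } else {
    stop("cases must carry either domain scores (d1..d6, summary) or item ",
         "responses (item_1..item_", length(domain_map), ")", call. = FALSE)
  }
  general <- cases[cases$needs_group == "general_demand", , drop = FALSE]
  high <- cases[cases$needs_group == "high_level_of_need", , drop = FALSE]
  list(cases = cases, general = general, high = high,
       counts = c(general_demand = nrow(general),
                  high_level_of_need = nrow(high)))
}
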