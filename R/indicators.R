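# PWD/TLD extraction, area classification, service density, accessibility
# zones and the priority ranking.

round_to_bin <- function(d, bin_width) {
  # report indicators on the bin-width grid (round half up)
  floor(d / bin_width + 0.5) * bin_width
}

#' Extract PWD and TLD from a joinpoint fit
#'
#' The **PWD** (profit willing distance) is the smallest significant
#' breakpoint where the slope changes from positive to negative — the
#' distance band holding the maximum supply of matched providers. The
#' **TLD** (tolerance limited distance) is the smallest significant
#' breakpoint where the slope changes from negative to positive — past it,
#' services are effectively out of users' reach. Either or both may be
#' absent; absence is a valid outcome, not an error. Reported values are
#' rounded to the bin-width grid (multiples of 50 m by default).
#'
#' @param fit A `joinpoint_fit`, normally from [select_joinpoints()] so that
#'   significance flags are attached.
#' @param significant Optional logical vector overriding the per-breakpoint
#'   significance flags (defaults to `fit$significance$significant`; all
#'   breakpoints are treated as significant when no flags exist).
#' @return A list with `pwd` and `tld` in metres (`NA` when absent).
#' @export
extract_pwd_tld <- function(fit, significant = NULL) {
  stopifnot(inherits(fit, "joinpoint_fit"))
  k <- fit$k
  if (k == 0) return(list(pwd = NA_real_, tld = NA_real_))
  if (is.null(significant)) {
    significant <- if (!is.null(fit$significance))
      fit$significance$significant else rep(TRUE, k)
  }
  stopifnot(length(significant) == k)
  before <- fit$slopes[seq_len(k)]
  after <- fit$slopes[seq_len(k) + 1]
  pwd_i <- which(significant & before > 0 & after < 0)
  tld_i <- which(significant & before < 0 & after > 0)
  w <- fit$bin_width
  list(pwd = if (length(pwd_i)) round_to_bin(fit$breakpoints[min(pwd_i)], w)
       else NA_real_,
       tld = if (length(tld_i)) round_to_bin(fit$breakpoints[min(tld_i)], w)
       else NA_real_)
}

#' Classify an area by which indicators exist
#'
#' @param pwd,tld Indicator values in metres (`NA` when absent); vectorised.
#' @return Character vector: `"both"`, `"only_pwd"`, `"only_tld"` or
#'   `"neither"`.
#' @export
classify_area <- function(pwd, tld) {
  has_pwd <- !is.na(pwd)
  has_tld <- !is.na(tld)
  out <- rep("neither", length(has_pwd))
  out[has_pwd & has_tld] <- "both"
  out[has_pwd & !has_tld] <- "only_pwd"
  out[!has_pwd & has_tld] <- "only_tld"
  out
}

#' Service density: cases per provider
#'
#' @param n_cases,n_providers Non-negative counts; vectorised.
#' @return `round(n_cases / n_providers, 2)`; `NA` where `n_providers` is 0
#'   (density undefined, distinct from 0).
#' @examples
#' service_density(1564, 162)  # 9.65
#' @export
service_density <- function(n_cases, n_providers) {
  if (any(n_cases < 0) || any(n_providers < 0))
    stop("counts must be non-negative", call. = FALSE)
  ifelse(n_providers > 0, round(n_cases / n_providers, 2), NA_real_)
}

#' Assign a distance to an accessibility zone
#'
#' With both indicators: `distance <= pwd` is `"profitable"` (providers
#' willingly serve), `pwd < distance <= tld` is `"tolerable"` (users still
#' bear the trip) and `distance > tld` is `"beyond_tolerance"`. Bounds are
#' inclusive. With only a TLD the profitable band does not exist; with only
#' a PWD the region past it cannot be classified and is returned as
#' `"unclassified"`.
#'
#' @param distance Distance(s) in metres, >= 0; vectorised.
#' @param pwd,tld Area indicators (scalar, `NA` when absent; not both `NA`).
#' @return Character vector of zones.
#' @export
classify_zone <- function(distance, pwd, tld) {
  if (is.na(pwd) && is.na(tld))
    stop("no indicator available: both pwd and tld are absent",
         call. = FALSE)
  stopifnot(all(distance >= 0))
  if (!is.na(pwd) && !is.na(tld)) {
    ifelse(distance <= pwd, "profitable",
           ifelse(distance <= tld, "tolerable", "beyond_tolerance"))
  } else if (is.na(pwd)) {
    ifelse(distance <= tld, "tolerable", "beyond_tolerance")
  } else {
    ifelse(distance <= pwd, "profitable", "unclassified")
  }
}

#' Rank areas for resource-allocation priority
#'
#' Applies the planning rule: areas with only a TLD come first (demand is
#' expressed but no profitable supply band exists), larger TLD first; then
#' areas with both indicators, larger TLD first; then only-PWD areas; then
#' areas with neither indicator. Ties are broken by larger service density,
#' then by area code.
#'
#' @param results Data frame with one row per area: `area_code`, `category`,
#'   `tld` and optionally `density_ratio`.
#' @return The input reordered with a `priority_rank` column (1 = first).
#' @export
rank_priorities <- function(results) {
  stopifnot(all(c("area_code", "category") %in% names(results)))
  if (anyDuplicated(results$area_code))
    stop("duplicate area codes in results", call. = FALSE)
  tier <- match(results$category, c("only_tld", "both", "only_pwd", "neither"))
  if (anyNA(tier)) stop("unknown category value", call. = FALSE)
  tld <- if ("tld" %in% names(results)) results$tld else
    rep(NA_real_, nrow(results))
  dens <- if ("density_ratio" %in% names(results)) results$density_ratio else
    rep(NA_real_, nrow(results))
  tld[is.na(tld)] <- -Inf
  dens[is.na(dens)] <- -Inf
  ord <- order(tier, -tld, -dens, results$area_code)
  out <- results[ord, , drop = FALSE]
  out$priority_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Count areas per indicator category
#'
#' @param results Data frame with `category` and optionally `group` columns.
#' @return A data frame with one row per group (a single `"all"` row when no
#'   `group` column is present) and columns `both`, `only_pwd`, `only_tld`,
#'   `neither`, `n_areas`. Counts always sum to the number of areas.
#' @export
summarize_categories <- function(results) {
  cats <- c("both", "only_pwd", "only_tld", "neither")
  grp <- if ("group" %in% names(results)) results$group else
    rep("all", nrow(results))
  groups <- unique(grp)
  if (length(groups) == 0) groups <- "all"
  rows <- lapply(groups, function(g) {
    sub <- results$category[grp == g]
    counts <- vapply(cats, function(cc) sum(sub == cc), integer(1))
    cbind(data.frame(group = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)),
          data.frame(n_areas = length(sub)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build an area-result table from known indicator values
#'
#' Entry point for classifying and ranking areas whose PWD/TLD values are
#' already known (for example a published national profile), bypassing the
#' spatial and joinpoint stages.
#'
#' @param df Data frame with `area_code`, `pwd`, `tld` (`NA` for absent) and
#'   optionally `group`, `n_cases`, `n_providers`.
#' @return The input with `category` and (when counts are present)
#'   `density_ratio` columns added.
#' @export
area_results_from_indicators <- function(df) {
  stopifnot(all(c("area_code", "pwd", "tld") %in% names(df)))
  df$category <- classify_area(df$pwd, df$tld)
  if (all(c("n_cases", "n_providers") %in% names(df)))
    df$density_ratio <- service_density(df$n_cases, df$n_providers)
  df
}
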