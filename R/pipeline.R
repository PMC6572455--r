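# End-to-end orchestration: filters -> stratification -> spatial join ->
# curves -> joinpoint fits -> indicators -> classification -> ranking.

#' Pipeline configuration
#'
#' @param bin_width Distance-bin width in metres (default 50).
#' @param cutoffs Needs-stratification cutoffs ([needs_cutoffs()]).
#' @param k_max,method,alpha,n_perm Joinpoint selection settings
#'   ([select_joinpoints()]).
#' @param seed Master seed; every stochastic stage derives its seed from it
#'   and the seed is recorded in the run manifest.
#' @param metric `"euclidean"` (projected metres) or `"haversine"`
#'   (lon/lat degrees).
#' @param min_seg Minimum bins per joinpoint segment.
#' @param same_area Restrict case-provider matches to the same area.
#' @param out_dir Optional directory; when set, every result table plus a
#'   run manifest is written under it.
#' @param verbose Log one line per stage with input/output counts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_width = 50, cutoffs = needs_cutoffs(),
                            k_max = 4, method = c("permutation", "bic"),
                            alpha = 0.05, n_perm = 999, seed = 1,
                            metric = c("euclidean", "haversine"),
                            min_seg = 3, same_area = TRUE, out_dir = NULL,
                            verbose = FALSE) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  stopifnot(bin_width > 0, inherits(cutoffs, "needs_cutoffs"))
  structure(list(bin_width = bin_width, cutoffs = cutoffs, k_max = k_max,
                 method = method, alpha = alpha, n_perm = n_perm,
                 seed = as.integer(seed), metric = metric, min_seg = min_seg,
                 same_area = same_area, out_dir = out_dir,
                 verbose = verbose),
            class = "pipeline_config")
}

pipe_log <- function(config, stage, ...) {
  if (isTRUE(config$verbose))
    message(sprintf("[%s] %s", stage, sprintf(...)))
  invisible(NULL)
}

#' Run the full accessibility pipeline
#'
#' Executes the stages in order: community filter, provider deduplication,
#' needs stratification, within-area nearest-provider join, distance-curve
#' construction per area and stratum (`all`, `general_demand`,
#' `high_level_of_need`), joinpoint selection, PWD/TLD extraction, area
#' classification, service densities and priority ranking. Cases and
#' providers may be data frames or file paths understood by [read_cases()] /
#' [read_providers()].
#'
#' Areas without providers complete the run as `neither`; an empty case
#' table completes with empty result tables. Reruns with an identical
#' configuration are deterministic.
#'
#' @param cases Case table or path.
#' @param providers Provider table or path.
#' @param config A [pipeline_config()].
#' @return A list (class `careaccess_run`): `reports` (filter reports),
#'   `cases`, `providers`, `matches`, `unserved`, `curves`, `fits` (both
#'   keyed `area|group`), `results` (one row per area x group with `pwd`,
#'   `tld`, `category`, `density_ratio`), `ranking` (per group), `summary`
#'   and `config`.
#' @export
run_pipeline <- function(cases, providers, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(cases))
    cases <- read_cases(cases, if (config$metric == "euclidean")
      "projected_m" else "lonlat")
  if (is.character(providers))
    providers <- read_providers(providers, if (config$metric == "euclidean")
      "projected_m" else "lonlat")

  reports <- list()

  if ("residence" %in% names(cases)) {
    fc <- filter_community(cases)
    cases <- fc$cases
    reports$community_filter <- fc$report
    pipe_log(config, "filter", "community filter: %d in, %d excluded, %d kept",
             fc$report$n_input, fc$report$n_excluded, fc$report$n_retained)
  }
  dp <- dedupe_providers(providers)
  providers <- dp$providers
  reports$provider_dedupe <- dp$report
  pipe_log(config, "dedupe", "providers: %d in, %d duplicates, %d kept",
           dp$report$n_input, dp$report$n_excluded, dp$report$n_retained)

  has_needs <- nrow(cases) > 0 &&
    (all(c("d1", "d2", "d3", "summary") %in% names(cases)) ||
       all(paste0("item_", 1:32) %in% names(cases)))
  if (has_needs) {
    strat <- stratify_cohort(cases, config$cutoffs)
    cases <- strat$cases
    pipe_log(config, "stratify", "general %d, high-need %d",
             strat$counts[1], strat$counts[2])
  } else {
    cases$needs_group <- rep(NA_character_, nrow(cases))
  }

  matches <- nearest_distances(cases, providers, metric = config$metric,
                               same_area = config$same_area)
  unserved <- attr(matches, "unserved")
  pipe_log(config, "join", "%d matches, %d cases in provider-less areas",
           nrow(matches), nrow(unserved))

  groups <- c("all", if (has_needs) c("general_demand", "high_level_of_need"))
  areas <- sort(unique(c(cases$area_code, providers$area_code)))
  needs_by_case <- stats::setNames(cases$needs_group, cases$case_id)

  curves <- list()
  fits <- list()
  rows <- list()
  fit_seed <- config$seed
  for (area in areas) {
    n_prov <- sum(providers$area_code == area)
    for (grp in groups) {
      m <- matches[matches$area_code == area, , drop = FALSE]
      if (grp != "all")
        m <- m[!is.na(needs_by_case[m$case_id]) &
                 needs_by_case[m$case_id] == grp, , drop = FALSE]
      n_cases <- if (grp == "all") sum(cases$area_code == area) else
        sum(cases$area_code == area & !is.na(cases$needs_group) &
              cases$needs_group == grp)
      key <- paste(area, grp, sep = "|")
      curve <- build_distance_curve(m$distance, config$bin_width,
                                    area_code = area, group = grp)
      curves[[key]] <- curve
      fit_seed <- (fit_seed + 997L) %% .Machine$integer.max
      if (length(curve$counts) >= 2) {
        fit <- select_joinpoints(curve, k_max = config$k_max,
                                 method = config$method,
                                 alpha = config$alpha,
                                 n_perm = config$n_perm,
                                 seed = fit_seed,
                                 min_seg = config$min_seg)
        fits[[key]] <- fit
        ind <- extract_pwd_tld(fit)
      } else {
        ind <- list(pwd = NA_real_, tld = NA_real_)
      }
      rows[[key]] <- data.frame(
        area_code = area, group = grp,
        n_cases = n_cases, n_providers = n_prov, n_matched = nrow(m),
        pwd = ind$pwd, tld = ind$tld,
        category = classify_area(ind$pwd, ind$tld),
        density_ratio = service_density(n_cases, n_prov),
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(area_code = character(), group = character(),
               n_cases = integer(), n_providers = integer(),
               n_matched = integer(), pwd = numeric(), tld = numeric(),
               category = character(), density_ratio = numeric(),
               stringsAsFactors = FALSE)
  rownames(results) <- NULL
  pipe_log(config, "indicators", "%d area x group results", nrow(results))

  ranking <- lapply(stats::setNames(groups, groups), function(grp)
    rank_priorities(results[results$group == grp, , drop = FALSE]))
  summary_tab <- summarize_categories(results)

  bundle <- structure(list(reports = reports, cases = cases,
                           providers = providers, matches = matches,
                           unserved = unserved, curves = curves, fits = fits,
                           results = results, ranking = ranking,
                           summary = summary_tab, config = config),
                      class = "careaccess_run")
  if (!is.null(config$out_dir)) write_run(bundle, config$out_dir)
  bundle
}

#' @export
print.careaccess_run <- function(x, ...) {
  cat("Accessibility pipeline run\n")
  cat(sprintf("  cases: %d   providers: %d   matches: %d\n",
              nrow(x$cases), nrow(x$providers), nrow(x$matches)))
  cat(sprintf("  areas x groups: %d\n", nrow(x$results)))
  print(x$summary)
  invisible(x)
}

# persist every result table plus a manifest recording config and versions
write_run <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(bundle$results, file.path(out_dir, "results.csv"))
  write_results(bundle$matches, file.path(out_dir, "matches.csv"))
  curves_tab <- do.call(rbind, lapply(bundle$curves, as.data.frame))
  if (!is.null(curves_tab))
    write_results(curves_tab, file.path(out_dir, "curves.csv"))
  rank_tab <- do.call(rbind, bundle$ranking)
  if (!is.null(rank_tab)) {
    rownames(rank_tab) <- NULL
    write_results(rank_tab, file.path(out_dir, "ranking.csv"))
  }
  write_results(bundle$summary, file.path(out_dir, "summary.json"),
                format = "json")
  fits <- lapply(bundle$fits, function(f)
    f[c("k", "breakpoints", "intercept", "slopes", "slope_changes", "rss",
        "bin_width", "note")])
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  manifest <- list(
    package = "careaccess",
    version = as.character(utils::packageVersion("careaccess")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(bundle$config)[setdiff(names(bundle$config),
                                            c("cutoffs", "out_dir"))],
    cutoffs = unclass(bundle$config$cutoffs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Bundled national reference profile
#'
#' Two small reference tables describing dementia-care supply and demand
#' across Taiwan's 22 administrative areas (2012-2013 registry period), as
#' published in the national accessibility profile this package
#' operationalises: `taiwan_profile()` gives per-area provider and case
#' counts (overall and by needs group) with the area surface; and
#' `taiwan_indicators()` gives the published PWD/TLD values (metres, `NA`
#' where the indicator was absent) per area and needs stratum. They feed the
#' classification and ranking entry points without access to the restricted
#' case coordinates.
#'
#' @return A data frame.
#' @export
taiwan_profile <- function() {
  path <- system.file("extdata", "taiwan_area_profile.csv",
                      package = "careaccess", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname taiwan_profile
#' @export
taiwan_indicators <- function() {
  path <- system.file("extdata", "taiwan_area_indicators.csv",
                      package = "careaccess", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
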