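# Seeded generators for every input the pipeline consumes: distance curves
# with known breakpoints, area point patterns whose nearest-distance
# distribution follows a target curve, and WHODAS cohorts with a stated
# high-need mixture. All generators are pure functions of (spec, seed).

# truncated normal via inverse-CDF; bounds may be -Inf/Inf
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

piecewise_values <- function(x, breakpoints, slopes, intercept) {
  stopifnot(length(slopes) == length(breakpoints) + 1)
  if (length(breakpoints) && any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing", call. = FALSE)
  y <- intercept + slopes[1] * x
  if (length(breakpoints)) {
    gamma <- diff(slopes)
    for (i in seq_along(breakpoints))
      y <- y + gamma[i] * pmax(x - breakpoints[i], 0)
  }
  y
}

#' Generate a distance-frequency curve with known breakpoints
#'
#' Evaluates a continuous piecewise-linear curve at the bin midpoints, adds
#' Gaussian noise, floors at zero and rounds to integer counts. With
#' `noise_sd = 0` the counts are exactly the (rounded) piecewise values, so
#' breakpoint-recovery tests have a known truth.
#'
#' @param breakpoints Strictly increasing breakpoint distances in metres.
#' @param slopes `length(breakpoints) + 1` segment slopes (counts per metre).
#' @param intercept Curve value at distance 0.
#' @param n_bins Number of bins.
#' @param bin_width Bin width in metres (default 50).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Optional integer seed.
#' @param area_code,group Labels carried on the curve.
#' @return A `distance_curve`.
#' @examples
#' gen_frequency_curve(c(300, 1500), c(0.4, -0.1, 0.05), 10,
#'                     n_bins = 50, seed = 1)
#' @export
gen_frequency_curve <- function(breakpoints, slopes, intercept, n_bins,
                                bin_width = 50, noise_sd = 0, seed = NULL,
                                area_code = "SYN", group = "all") {
  stopifnot(n_bins >= 1, bin_width > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  x <- (seq_len(n_bins) - 0.5) * bin_width
  mu <- piecewise_values(x, breakpoints, slopes, intercept)
  if (any(mu < 0))
    stop("piecewise curve takes negative values; adjust slopes/intercept",
         call. = FALSE)
  y <- mu + if (noise_sd > 0) stats::rnorm(n_bins, 0, noise_sd) else 0
  counts <- as.integer(round(pmax(y, 0)))
  structure(list(area_code = area_code, group = group,
                 bin_width = bin_width, counts = counts, n = sum(counts)),
            class = "distance_curve")
}

#' Specification of one synthetic administrative area
#'
#' @param area_code Area identifier.
#' @param n_providers,n_cases Point counts (>= 0).
#' @param extent Bounding box `c(xmin, ymin, xmax, ymax)` in metres.
#' @param provider_layout `"uniform"` or `"clustered"`.
#' @param cluster_k,cluster_spread Number of cluster centres and the
#'   within-cluster standard deviation (metres), for the clustered layout.
#' @param target_curve Optional list (`breakpoints`, `slopes`, `intercept`,
#'   `n_bins`, `bin_width`) describing the nearest-distance frequency curve
#'   case placement should reproduce.
#' @param p_high Probability that a generated case is high-need.
#' @param seed Integer seed.
#' @return A list of class `area_spec`.
#' @export
area_spec <- function(area_code, n_providers, n_cases,
                      extent = c(0, 0, 50000, 50000),
                      provider_layout = c("uniform", "clustered"),
                      cluster_k = 3, cluster_spread = 500,
                      target_curve = NULL, p_high = 0.32, seed = 1) {
  provider_layout <- match.arg(provider_layout)
  stopifnot(n_providers >= 0, n_cases >= 0, p_high >= 0, p_high <= 1,
            length(extent) == 4, extent[3] > extent[1], extent[4] > extent[2])
  if (!is.null(target_curve)) {
    stopifnot(all(c("breakpoints", "slopes", "intercept", "n_bins")
                  %in% names(target_curve)))
    if (is.null(target_curve$bin_width)) target_curve$bin_width <- 50
    if (any(diff(target_curve$breakpoints) <= 0))
      stop("target breakpoints must be strictly increasing", call. = FALSE)
  }
  structure(list(area_code = area_code, n_providers = n_providers,
                 n_cases = n_cases, extent = extent,
                 provider_layout = provider_layout,
                 cluster_k = cluster_k, cluster_spread = cluster_spread,
                 target_curve = target_curve, p_high = p_high, seed = seed),
            class = "area_spec")
}

#' Generate provider and case points for one area
#'
#' Providers are placed per the layout; when a `target_curve` is supplied
#' they are additionally forced at least two curve-supports apart (rejection
#' sampling, grid fallback) so that a case sampled at distance `d` from its
#' parent provider keeps that provider as its nearest. Each case then picks a
#' random provider, a distance drawn from the binned target density (bin by
#' probability, uniform within the bin) and a uniform bearing, which makes
#' the empirical nearest-distance curve multinomial around the target.
#' Without a target curve, cases are uniform over the extent.
#'
#' @param spec An [area_spec()].
#' @return A list with `providers` and `cases` data frames in the schemas
#'   [read_providers()] / [read_cases()] produce (cases carry only identity,
#'   area and coordinates; join WHODAS attributes from
#'   [gen_whodas_cohort()]). Reproducible per seed.
#' @export
gen_area_points <- function(spec) {
  stopifnot(inherits(spec, "area_spec"))
  set.seed(spec$seed)
  ext <- spec$extent
  tc <- spec$target_curve

  min_sep <- if (!is.null(tc)) 2 * tc$n_bins * tc$bin_width else 0
  prov_xy <- place_providers(spec, min_sep)
  providers <- data.frame(
    provider_id = sprintf("%s_P%04d", spec$area_code,
                          seq_len(spec$n_providers)),
    area_code = rep(spec$area_code, spec$n_providers),
    x = prov_xy[, 1], y = prov_xy[, 2],
    service_type = rep("daycare", spec$n_providers),
    stringsAsFactors = FALSE)

  n <- spec$n_cases
  if (n == 0) {
    cases <- data.frame(case_id = character(), area_code = character(),
                        x = numeric(), y = numeric(),
                        stringsAsFactors = FALSE)
    return(list(providers = providers, cases = cases))
  }
  if (!is.null(tc)) {
    if (spec$n_providers == 0)
      stop("a target curve needs at least one provider", call. = FALSE)
    w <- tc$bin_width
    x_mid <- (seq_len(tc$n_bins) - 0.5) * w
    dens <- piecewise_values(x_mid, tc$breakpoints, tc$slopes, tc$intercept)
    dens <- pmax(dens, 0)
    if (sum(dens) <= 0)
      stop("infeasible target: all-zero curve with n_cases > 0",
           call. = FALSE)
    bin <- sample.int(tc$n_bins, n, replace = TRUE, prob = dens)
    d <- (bin - 1) * w + stats::runif(n) * w
    theta <- stats::runif(n, 0, 2 * pi)
    parent <- sample.int(spec$n_providers, n, replace = TRUE)
    cx <- providers$x[parent] + d * cos(theta)
    cy <- providers$y[parent] + d * sin(theta)
  } else {
    cx <- stats::runif(n, ext[1], ext[3])
    cy <- stats::runif(n, ext[2], ext[4])
  }
  cases <- data.frame(
    case_id = sprintf("%s_C%05d", spec$area_code, seq_len(n)),
    area_code = spec$area_code,
    x = cx, y = cy,
    stringsAsFactors = FALSE)
  list(providers = providers, cases = cases)
}

place_providers <- function(spec, min_sep) {
  n <- spec$n_providers
  ext <- spec$extent
  if (n == 0) return(matrix(numeric(0), 0, 2))
  draw <- function(m) {
    if (spec$provider_layout == "uniform") {
      cbind(stats::runif(m, ext[1], ext[3]), stats::runif(m, ext[2], ext[4]))
    } else {
      centres <- cbind(stats::runif(spec$cluster_k, ext[1], ext[3]),
                       stats::runif(spec$cluster_k, ext[2], ext[4]))
      id <- sample.int(spec$cluster_k, m, replace = TRUE)
      centres[id, , drop = FALSE] +
        matrix(stats::rnorm(2 * m, 0, spec$cluster_spread), m, 2)
    }
  }
  if (min_sep <= 0) return(draw(n))
  # rejection sampling for the separation constraint, then a jittered grid
  # fallback when the extent is too tight for rejection to converge
  for (attempt in 1:50) {
    pts <- draw(n)
    if (n == 1 || min(stats::dist(pts)) >= min_sep) return(pts)
  }
  side <- ceiling(sqrt(n))
  gx <- ext[1] + (seq_len(side) - 0.5) * max(min_sep, diff(ext[c(1, 3)]) / side)
  gy <- ext[2] + (seq_len(side) - 0.5) * max(min_sep, diff(ext[c(2, 4)]) / side)
  grid <- as.matrix(expand.grid(gx, gy))[seq_len(n), , drop = FALSE]
  dimnames(grid) <- NULL
  grid
}

# Table-derived mixture components for the WHODAS generator: domain means and
# SDs of the general-demand and high-need groups in the national dementia
# cohort, truncated to [0, 100]; the cutoff-relevant margins are further
# truncated to the correct side of each cutoff so generated labels are exact.
whodas_mixture_params <- function() {
  list(
    general = list(
      d1 = c(61.17, 23.89), d2 = c(44.64, 31.62), d3 = c(40.05, 29.16),
      d4 = c(59.21, 28.86), d5 = c(75.37, 29.45), d6 = c(43.33, 22.33),
      summary = c(54.56, 19.60),
      age = c(76.98, 9.93), p_female = 0.627,
      severity = c(mild = 0.383, moderate = 0.407, severe = 0.066,
                   extremely_serious = 0.144)),
    high = list(
      d1 = c(95.35, 7.02), d2 = c(94.45, 10.41), d3 = c(95.11, 7.15),
      d4 = c(94.35, 11.02), d5 = c(99.37, 5.28), d6 = c(70.74, 22.36),
      summary = c(89.43, 7.58),
      age = c(82.10, 8.48), p_female = 0.635,
      severity = c(mild = 0.065, moderate = 0.299, severe = 0.097,
                   extremely_serious = 0.539)))
}

#' Generate a WHODAS 2.0 cohort with a known high-need fraction
#'
#' Draws domain and summary scores from a two-component truncated-normal
#' mixture moment-matched to a national dementia cohort: the high-need
#' component lies strictly above the stratification cutoffs on D1, D2, D3 and
#' the summary score, the general-demand component strictly at or below the
#' summary cutoff, so [stratify_case()] recovers the generating label
#' exactly. Demographics (age, sex, disability severity) are drawn from the
#' matching group profiles; all cases are community-dwelling.
#'
#' @param n Number of cases (>= 0).
#' @param p_high Probability a case is drawn from the high-need component.
#' @param seed Integer seed.
#' @param cutoffs A [needs_cutoffs()] object the components are anchored to.
#' @return A case data frame (`case_id`, `area_code = NA`, demographics,
#'   `residence = "community"`, `d1`..`d6`, `summary`) with the generating
#'   label in `true_group`.
#' @export
gen_whodas_cohort <- function(n, p_high = 0.32, seed = 1,
                              cutoffs = needs_cutoffs()) {
  stopifnot(n >= 0, p_high >= 0, p_high <= 1)
  set.seed(seed)
  pars <- whodas_mixture_params()
  high <- stats::runif(n) < p_high

  draw_group <- function(par, m, is_high) {
    if (m == 0) {
      return(data.frame(d1 = numeric(0), d2 = numeric(0), d3 = numeric(0),
                        d4 = numeric(0), d5 = numeric(0), d6 = numeric(0),
                        summary = numeric(0), age = numeric(0),
                        sex = character(0), severity = character(0),
                        stringsAsFactors = FALSE))
    }
    tr <- function(nm, lo = 0, hi = 100)
      rtrunc_norm(m, par[[nm]][1], par[[nm]][2], lo, hi)
    if (is_high) {
      sc <- data.frame(d1 = tr("d1", lo = cutoffs$d1),
                       d2 = tr("d2", lo = cutoffs$d2),
                       d3 = tr("d3", lo = cutoffs$d3),
                       d4 = tr("d4"), d5 = tr("d5"), d6 = tr("d6"),
                       summary = tr("summary", lo = cutoffs$summary))
    } else {
      sc <- data.frame(d1 = tr("d1"), d2 = tr("d2"), d3 = tr("d3"),
                       d4 = tr("d4"), d5 = tr("d5"), d6 = tr("d6"),
                       summary = tr("summary", hi = cutoffs$summary))
    }
    sc$age <- round(rtrunc_norm(m, par$age[1], par$age[2], 18, 110))
    sc$sex <- ifelse(stats::runif(m) < par$p_female, "female", "male")
    sc$severity <- sample(names(par$severity), m, replace = TRUE,
                          prob = par$severity)
    sc
  }

  out <- data.frame(case_id = sprintf("SYN_C%06d", seq_len(n)),
                    area_code = NA_character_,
                    stringsAsFactors = FALSE)
  sc <- rbind(draw_group(pars$general, sum(!high), FALSE),
              draw_group(pars$high, sum(high), TRUE))
  # interleave back into original order: general rows first in sc
  idx <- integer(n)
  idx[!high] <- seq_len(sum(!high))
  idx[high] <- sum(!high) + seq_len(sum(high))
  sc <- sc[idx, , drop = FALSE]
  rownames(sc) <- NULL
  out <- cbind(out, sc)
  out$residence <- rep("community", n)
  out$true_group <- ifelse(high, "high_level_of_need", "general_demand")
  out
}

#' Generate a complete multi-area study dataset
#'
#' Convenience wrapper combining [gen_area_points()] (geometry) and
#' [gen_whodas_cohort()] (needs attributes) over several area
#' specifications, yielding case and provider tables ready for
#' [run_pipeline()].
#'
#' @param specs List of [area_spec()] objects; each spec's own seed is
#'   replaced by one derived from `seed` and its position.
#' @param seed Master integer seed.
#' @return A list with `cases` and `providers` data frames.
#' @export
gen_study_data <- function(specs, seed = 1) {
  stopifnot(length(specs) > 0)
  case_parts <- list()
  prov_parts <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    stopifnot(inherits(spec, "area_spec"))
    spec$seed <- (seed * 1000L + i) %% .Machine$integer.max
    pts <- gen_area_points(spec)
    if (nrow(pts$cases) > 0) {
      cohort <- gen_whodas_cohort(nrow(pts$cases), spec$p_high,
                                  seed = spec$seed + 1L)
      cohort$case_id <- pts$cases$case_id
      cohort$area_code <- pts$cases$area_code
      cohort$x <- pts$cases$x
      cohort$y <- pts$cases$y
      case_parts[[i]] <- cohort
    }
    prov_parts[[i]] <- pts$providers
  }
  cases <- if (length(case_parts)) do.call(rbind, case_parts) else NULL
  providers <- do.call(rbind, prov_parts)
  rownames(providers) <- NULL
  if (!is.null(cases)) rownames(cases) <- NULL
  list(cases = cases, providers = providers)
}
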