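# Nearest-provider matching within administrative areas and the 50 m-binned
# distance-frequency curve.

#' Pairwise point distances
#'
#' `"euclidean"` treats `x`/`y` as planar metre coordinates; `"haversine"`
#' treats them as longitude/latitude degrees and returns great-circle metres
#' (via \pkg{geosphere}).
#'
#' @param x1,y1 Coordinates of the first point set.
#' @param x2,y2 Coordinates of the second point set (recycled as in
#'   [base::pmax()]).
#' @param metric `"euclidean"` or `"haversine"`.
#' @return Numeric vector of distances in metres.
#' @keywords internal
point_distance <- function(x1, y1, x2, y2,
                           metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    sqrt((x1 - x2)^2 + (y1 - y2)^2)
  } else {
    geosphere::distHaversine(cbind(x1, y1), cbind(x2, y2))
  }
}

#' Nearest provider for a single case
#'
#' Exhaustively scans `providers` and returns the one minimising the metric;
#' ties are broken by the smallest `provider_id`.
#'
#' @param case One-row data frame (or list) with `x`, `y` and `case_id`.
#' @param providers Provider data frame, all in the case's area.
#' @param metric See [point_distance()].
#' @return One-row data frame `case_id`, `provider_id`, `area_code`,
#'   `distance`, or `NULL` when `providers` is empty (no-supply signal,
#'   distinct from a zero distance).
#' @export
nearest_provider <- function(case, providers,
                             metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  if (is.null(providers) || nrow(providers) == 0) return(NULL)
  d <- point_distance(case$x, case$y, providers$x, providers$y, metric)
  best <- which(d == min(d))
  if (length(best) > 1)
    best <- best[order(providers$provider_id[best])][1]
  data.frame(case_id = case$case_id,
             provider_id = providers$provider_id[best],
             area_code = if (!is.null(case$area_code)) case$area_code else
               providers$area_code[best],
             distance = d[best],
             stringsAsFactors = FALSE)
}

#' Nearest-provider distances, joined within administrative areas
#'
#' For every case, finds the nearest provider among those sharing its
#' `area_code` (the within-area spatial join; set `same_area = FALSE` to let
#' cases match providers anywhere, for sensitivity analysis). Cases living in
#' areas with no provider cannot be matched and are returned separately.
#'
#' @param cases Case data frame with `case_id`, `area_code`, `x`, `y`.
#' @param providers Provider data frame with `provider_id`, `area_code`,
#'   `x`, `y`.
#' @param metric See [point_distance()].
#' @param same_area Restrict matches to the case's own area (default TRUE).
#' @return A data frame of matches (`case_id`, `provider_id`, `area_code`,
#'   `distance`), one row per matchable case, with the unmatched cases in the
#'   `unserved` attribute.
#' @export
nearest_distances <- function(cases, providers,
                              metric = c("euclidean", "haversine"),
                              same_area = TRUE) {
  metric <- match.arg(metric)
  empty <- data.frame(case_id = character(), provider_id = character(),
                      area_code = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(cases) == 0) {
    attr(empty, "unserved") <- cases
    return(empty)
  }

  match_block <- function(cs, pv) {
    # distance matrix cases x providers, computed per area; areas hold at
    # most a few thousand points so the dense matrix is cheap
    if (metric == "euclidean") {
      dm <- outer(cs$x, pv$x, "-")^2 + outer(cs$y, pv$y, "-")^2
      dm <- sqrt(dm)
    } else {
      dm <- t(apply(cbind(cs$x, cs$y), 1, function(p)
        geosphere::distHaversine(p, cbind(pv$x, pv$y))))
      dm <- matrix(dm, nrow = nrow(cs))
    }
    ord <- order(pv$provider_id)   # so which.min resolves ties to smallest id
    dm <- dm[, ord, drop = FALSE]
    idx <- apply(dm, 1, which.min)
    data.frame(case_id = cs$case_id,
               provider_id = pv$provider_id[ord][idx],
               area_code = cs$area_code,
               distance = dm[cbind(seq_len(nrow(cs)), idx)],
               stringsAsFactors = FALSE)
  }

  if (!same_area) {
    out <- match_block(cases, providers)
    attr(out, "unserved") <- cases[0, , drop = FALSE]
    return(out)
  }

  parts <- list()
  unserved <- list()
  for (area in unique(cases$area_code)) {
    cs <- cases[cases$area_code == area, , drop = FALSE]
    pv <- providers[providers$area_code == area, , drop = FALSE]
    if (nrow(pv) == 0) unserved[[area]] <- cs else parts[[area]] <- match_block(cs, pv)
  }
  out <- if (length(parts)) do.call(rbind, parts) else empty
  rownames(out) <- NULL
  un <- if (length(unserved)) do.call(rbind, unserved) else
    cases[0, , drop = FALSE]
  rownames(un) <- NULL
  attr(out, "unserved") <- un
  out
}

#' Bin nearest distances into a frequency curve
#'
#' Distances are grouped into contiguous half-open bins `[k*w, (k+1)*w)`
#' anchored at zero (default width 50 m); a distance exactly on an edge falls
#' in the upper bin. Trailing empty bins are truncated, so the curve runs
#' from 0 to the last non-empty bin.
#'
#' @param distances Numeric vector of distances in metres, or a match table
#'   from [nearest_distances()] (its `distance` column is used).
#' @param bin_width Bin width in metres (> 0), default 50.
#' @param area_code,group Labels carried on the curve.
#' @return A `distance_curve`: list with `area_code`, `group`, `bin_width`,
#'   `counts` (integer, `sum(counts) == n`) and `n`.
#' @examples
#' build_distance_curve(c(10, 60, 70, 120))$counts  # 1, 2, 1
#' @export
build_distance_curve <- function(distances, bin_width = 50,
                                 area_code = NA_character_, group = "all") {
  if (is.data.frame(distances)) {
    if (is.na(area_code) && "area_code" %in% names(distances) &&
        length(unique(distances$area_code)) == 1)
      area_code <- distances$area_code[1]
    distances <- distances$distance
  }
  stopifnot(bin_width > 0)
  if (any(distances < 0)) stop("distances must be non-negative", call. = FALSE)
  if (length(distances) == 0) {
    counts <- integer(0)
  } else {
    bin <- floor(distances / bin_width) + 1L
    counts <- tabulate(bin, nbins = max(bin))
  }
  structure(list(area_code = area_code, group = group,
                 bin_width = bin_width, counts = as.integer(counts),
                 n = length(distances)),
            class = "distance_curve")
}

#' Bin midpoints of a distance curve
#'
#' @param curve A `distance_curve`.
#' @return Numeric vector: 25, 75, 125, ... for 50 m bins.
#' @export
curve_midpoints <- function(curve) {
  stopifnot(inherits(curve, "distance_curve"))
  (seq_along(curve$counts) - 0.5) * curve$bin_width
}

#' @export
print.distance_curve <- function(x, ...) {
  cat(sprintf("Distance-frequency curve [%s, %s]: %d matches in %d x %g m bins\n",
              x$area_code, x$group, x$n, length(x$counts), x$bin_width))
  invisible(x)
}

#' @export
as.data.frame.distance_curve <- function(x, ...) {
  k <- seq_along(x$counts)
  data.frame(area_code = rep(x$area_code, length(k)),
             group = rep(x$group, length(k)),
             bin_lo = (k - 1) * x$bin_width, bin_hi = k * x$bin_width,
             count = x$counts, stringsAsFactors = FALSE)
}
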