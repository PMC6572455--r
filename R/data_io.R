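# Reading, validating and writing the point tables the pipeline consumes.

CASE_COLUMNS <- c("case_id", "area_code", "x", "y", "age", "sex",
                  "severity", "residence")
PROVIDER_COLUMNS <- c("provider_id", "area_code", "x", "y")
SCORE_COLUMNS <- c("d1", "d2", "d3", "d4", "d5", "d6", "summary")

#' Read a case (service-user) table
#'
#' Reads a CSV or GeoJSON point table of service users. Required columns:
#' `case_id`, `area_code`, `x`, `y`, `age`, `sex`, `severity`, `residence`.
#' WHODAS 2.0 domain scores may be supplied either as `d1`..`d6` plus
#' `summary` (0-100 scales) or as raw item responses `item_1`..`item_32`
#' (each 0-4); both are optional at read time but stratification needs one of
#' them.
#'
#' Rows that cannot be parsed (non-numeric or non-finite coordinates,
#' non-numeric or under-18 age) are dropped and reported, with their source
#' line numbers, in the `row_errors` attribute of the returned data frame; a
#' missing required column is a hard error.
#'
#' @param path Path to a `.csv` file or a GeoJSON `FeatureCollection` of
#'   Points (`.geojson`/`.json`; properties carry the non-coordinate columns).
#' @param coord_system `"projected_m"` for planar coordinates in metres
#'   (default) or `"lonlat"` for geographic degrees. Recorded on the result
#'   and used downstream to pick the distance metric.
#' @return A data frame of cases with attributes `coord_system` and
#'   `row_errors` (a data frame with columns `line`, `field`, `message`).
#' @seealso [read_providers()], [filter_community()]
#' @export
read_cases <- function(path, coord_system = c("projected_m", "lonlat")) {
  coord_system <- match.arg(coord_system)
  raw <- read_point_table(path)
  check_columns(raw, CASE_COLUMNS, path)

  errors <- list()
  note <- function(line, field, message) {
    errors[[length(errors) + 1L]] <<- data.frame(
      line = line, field = field, message = message,
      stringsAsFactors = FALSE)
  }

  # header is line 1, data rows start at line 2
  line_no <- seq_len(nrow(raw)) + 1L
  bad <- rep(FALSE, nrow(raw))
  for (col in c("x", "y", "age")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    fail <- which(!is.finite(val))
    for (i in fail) note(line_no[i], col, sprintf("non-numeric %s: %s",
                                                  col, raw[[col]][i]))
    bad[fail] <- TRUE
    raw[[col]] <- val
  }
  underage <- which(!bad & raw$age < 18)
  for (i in underage) note(line_no[i], "age", "age below 18")
  bad[underage] <- TRUE

  numeric_opt <- intersect(c(SCORE_COLUMNS, paste0("item_", 1:32)),
                           names(raw))
  for (col in numeric_opt) raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))

  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coord_system") <- coord_system
  attr(out, "row_errors") <- if (length(errors)) do.call(rbind, errors) else
    data.frame(line = integer(), field = character(), message = character(),
               stringsAsFactors = FALSE)
  out
}

#' Read a provider table
#'
#' Reads a CSV or GeoJSON point table of service providers. Required columns:
#' `provider_id`, `area_code`, `x`, `y`; `service_type` is optional free text.
#' Rows with unparseable coordinates or an empty `area_code` are dropped into
#' the `row_errors` attribute, as in [read_cases()].
#'
#' @inheritParams read_cases
#' @return A data frame of providers with `coord_system` and `row_errors`
#'   attributes.
#' @export
read_providers <- function(path, coord_system = c("projected_m", "lonlat")) {
  coord_system <- match.arg(coord_system)
  raw <- read_point_table(path)
  check_columns(raw, PROVIDER_COLUMNS, path)

  errors <- list()
  line_no <- seq_len(nrow(raw)) + 1L
  bad <- rep(FALSE, nrow(raw))
  for (col in c("x", "y")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    fail <- which(!is.finite(val))
    for (i in fail) {
      errors[[length(errors) + 1L]] <- data.frame(
        line = line_no[i], field = col,
        message = sprintf("non-numeric %s: %s", col, raw[[col]][i]),
        stringsAsFactors = FALSE)
    }
    bad[fail] <- TRUE
    raw[[col]] <- val
  }
  empty_area <- which(!bad & (is.na(raw$area_code) | raw$area_code == ""))
  for (i in empty_area) {
    errors[[length(errors) + 1L]] <- data.frame(
      line = line_no[i], field = "area_code", message = "empty area_code",
      stringsAsFactors = FALSE)
  }
  bad[empty_area] <- TRUE

  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coord_system") <- coord_system
  attr(out, "row_errors") <- if (length(errors)) do.call(rbind, errors) else
    data.frame(line = integer(), field = character(), message = character(),
               stringsAsFactors = FALSE)
  out
}

read_point_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    read_geojson_points(path)
  } else {
    utils::read.csv(path, colClasses = "character",
                    stringsAsFactors = FALSE, check.names = FALSE)
  }
}

# GeoJSON Point FeatureCollection -> flat table (geometry becomes x/y)
read_geojson_points <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection: ", path, call. = FALSE)
  rows <- lapply(gj$features, function(f) {
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    coords <- f$geometry$coordinates
    c(props, list(x = as.character(coords[[1]]), y = as.character(coords[[2]])))
  })
  cols <- unique(unlist(lapply(rows, names)))
  out <- lapply(cols, function(cl)
    vapply(rows, function(r) {
      v <- r[[cl]]
      if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
    }, character(1)))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("required column missing in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

filter_report <- function(n_input, n_excluded, rule) {
  data.frame(n_input = n_input, n_excluded = n_excluded,
             n_retained = n_input - n_excluded, rule = rule,
             stringsAsFactors = FALSE)
}

#' Keep only community-dwelling cases
#'
#' Drops cases whose `residence` is `"institution"`, retaining the
#' community-dwelling cohort that can actually travel to providers.
#'
#' @param cases Case data frame with a `residence` column
#'   (`"community"`/`"institution"`).
#' @return A list with `cases` (the retained records) and `report`, a one-row
#'   data frame (`n_input`, `n_excluded`, `n_retained`, `rule`) whose counts
#'   always reconcile.
#' @examples
#' cases <- data.frame(case_id = 1:4,
#'                     residence = c("community", "institution",
#'                                   "community", "community"))
#' filter_community(cases)$report
#' @export
filter_community <- function(cases) {
  stopifnot("residence" %in% names(cases))
  keep <- cases$residence == "community"
  out <- cases[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(cases = out,
       report = filter_report(nrow(cases), sum(!keep),
                              "residence == community"))
}

#' Deduplicate providers sharing exact coordinates
#'
#' Providers listed at bitwise-identical `(x, y)` coordinates (e.g. several
#' services registered at one address) are collapsed to a single
#' representative: the first record in input order. Equality is exact — no
#' tolerance is applied.
#'
#' @param providers Provider data frame with numeric `x`, `y`.
#' @return A list with `providers` (deduplicated, input order preserved) and
#'   `report` as in [filter_community()]. Idempotent.
#' @export
dedupe_providers <- function(providers) {
  stopifnot(all(c("x", "y") %in% names(providers)))
  dup <- duplicated(cbind(providers$x, providers$y), MARGIN = 1)
  out <- providers[!dup, , drop = FALSE]
  rownames(out) <- NULL
  list(providers = out,
       report = filter_report(nrow(providers), sum(dup),
                              "unique (x, y); first record kept"))
}

#' Write a result table to CSV or JSON
#'
#' @param results A data frame (matches, curves, area results, ...).
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (row-oriented records).
#' @return The path, invisibly. `read_results()` round-trips the file.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  if (format == "csv") {
    utils::write.csv(results, path, row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  }
}
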