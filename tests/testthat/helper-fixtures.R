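# Shared fixtures and independent oracles used across the suite.

# write a minimal case CSV and return its path
write_case_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  write.csv(rows, path, row.names = FALSE)
  path
}

make_case_rows <- function(n, area = "A", x = NULL, y = NULL) {
  data.frame(case_id = sprintf("C%03d", seq_len(n)),
             area_code = rep(area, length.out = n),
             x = if (is.null(x)) seq_len(n) * 100 else x,
             y = if (is.null(y)) rep(0, n) else y,
             age = rep(70, n), sex = rep("female", n),
             severity = rep("moderate", n),
             residence = rep("community", n),
             stringsAsFactors = FALSE)
}

make_provider_rows <- function(n, area = "A", x = NULL, y = NULL) {
  data.frame(provider_id = sprintf("P%03d", seq_len(n)),
             area_code = rep(area, length.out = n),
             x = if (is.null(x)) seq_len(n) * 1000 else x,
             y = if (is.null(y)) rep(0, n) else y,
             service_type = rep("daycare", n),
             stringsAsFactors = FALSE)
}

# brute-force nearest provider: plain double loop, smallest id on ties
oracle_nearest <- function(cases, providers) {
  out <- lapply(seq_len(nrow(cases)), function(i) {
    pv <- providers[providers$area_code == cases$area_code[i], , drop = FALSE]
    if (nrow(pv) == 0) return(NULL)
    d <- sqrt((cases$x[i] - pv$x)^2 + (cases$y[i] - pv$y)^2)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[which.min(pv$provider_id[best])]
    data.frame(case_id = cases$case_id[i], provider_id = pv$provider_id[best],
               distance = d[best], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# exhaustive joinpoint oracle: enumerate every candidate combination with
# nested loops and score it with stats::lm.fit
oracle_piecewise <- function(curve, k, min_seg = 3) {
  x <- (seq_along(curve$counts) - 0.5) * curve$bin_width
  y <- as.numeric(curve$counts)
  n <- length(y)
  cand <- min_seg:(n - min_seg + 1)
  combos <- if (k == 1) {
    lapply(cand, identity)
  } else if (k == 2) {
    out <- list()
    for (a in cand) for (b in cand)
      if (b - a >= min_seg) out[[length(out) + 1]] <- c(a, b)
    out
  } else stop("oracle supports k in 1:2")
  best <- list(rss = Inf, bps = NULL)
  for (cb in combos) {
    X <- cbind(1, x)
    for (b in x[cb]) X <- cbind(X, pmax(x - b, 0))
    rss <- sum(stats::lm.fit(X, y)$residuals^2)
    if (rss < best$rss - 1e-9) best <- list(rss = rss, bps = x[cb])
  }
  best
}

# two-sided binomial confidence bounds on a count
binom_bounds <- function(n, p, level = 0.99) {
  a <- (1 - level) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p))
}

# long-format published indicator table: one row per area x stratum
taiwan_indicators_long <- function() {
  tw <- taiwan_indicators()
  do.call(rbind, lapply(
    list(c("all", "pwd_all", "tld_all"),
         c("general_demand", "pwd_general", "tld_general"),
         c("high_level_of_need", "pwd_high", "tld_high")),
    function(g) data.frame(area_code = tw$area_code, group = g[1],
                           n_providers = tw$n_providers,
                           pwd = tw[[g[2]]], tld = tw[[g[3]]],
                           stringsAsFactors = FALSE)))
}
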