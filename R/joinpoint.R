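# Continuous piecewise-linear (joinpoint) regression on distance-frequency
# curves: exhaustive grid search over bin-midpoint breakpoints, permutation
# or BIC model selection, and slope-change significance tests.

# hinge design: columns 1, x, (x - bp1)+, (x - bp2)+, ...
jp_design <- function(x, bps) {
  X <- cbind(1, x)
  for (b in bps) X <- cbind(X, pmax(x - b, 0))
  X
}

# Candidate breakpoint positions for a curve of n bins: all interior bin
# midpoints respecting the minimum segment length. For very long curves the
# exhaustive grid of k-combinations is combinatorially infeasible, so the
# candidate set is thinned evenly to keep the combination count below
# max_combos; short curves (the regime the exhaustive-oracle checks cover)
# always use the full grid.
jp_candidates <- function(n, k, min_seg = 3, max_combos = 20000) {
  cand <- seq.int(min_seg, n - min_seg + 1L)
  if (k <= 1 || length(cand) <= k) return(cand)
  m <- length(cand)
  while (m > k && choose(m, k) > max_combos) m <- m - 1L
  if (m < length(cand))
    cand <- cand[unique(round(seq(1, length(cand), length.out = m)))]
  cand
}

# all breakpoint index combinations of size k respecting the minimum segment
# length, in lexicographic order (columns)
jp_combos <- function(n, k, min_seg = 3, max_combos = 20000) {
  if (k == 0) return(matrix(integer(0), nrow = 0, ncol = 1))
  cand <- jp_candidates(n, k, min_seg, max_combos)
  if (length(cand) < k) return(matrix(integer(0), nrow = k, ncol = 0))
  cm <- utils::combn(cand, k)
  if (k > 1) {
    ok <- apply(cm, 2, function(j) all(diff(j) >= min_seg))
    cm <- cm[, ok, drop = FALSE]
  }
  cm
}

jp_grid <- function(x, k, min_seg = 3, max_combos = 20000) {
  list(combos = jp_combos(length(x), k, min_seg, max_combos),
       p = 2L + k, x = x)
}

# orthonormal bases for a block of candidate designs
jp_q_block <- function(x, combos, cols) {
  p <- 2L + nrow(combos)
  n <- length(x)
  Q <- matrix(0, n, length(cols) * p)
  for (i in seq_along(cols)) {
    bps <- if (nrow(combos) > 0) x[combos[, cols[i]]] else numeric(0)
    Q[, ((i - 1L) * p + 1L):(i * p)] <- qr.Q(qr(jp_design(x, bps)))
  }
  Q
}

# minimum RSS over a grid for each column of Y (n x B); the orthonormal
# bases are built lazily in chunks to bound memory
jp_min_rss <- function(grid, Y) {
  Y <- as.matrix(Y)
  B <- ncol(Y)
  tot <- colSums(Y^2)
  p <- grid$p
  C <- max(1L, ncol(grid$combos))  # k = 0 grid has a single (empty) combo
  best <- rep(Inf, B)
  best_idx <- rep(1L, B)
  chunk <- max(1L, as.integer(5e6 / (p * (B + length(grid$x)) + 1)))
  for (s in seq(1L, C, by = chunk)) {
    e <- min(C, s + chunk - 1L)
    Q <- jp_q_block(grid$x, grid$combos, s:e)
    M <- crossprod(Q, Y)
    proj <- rowsum(M * M, rep(seq_len(e - s + 1L), each = p))
    rss <- matrix(tot, nrow = e - s + 1L, ncol = B, byrow = TRUE) - proj
    mins <- max.col(-t(rss), ties.method = "first")
    vals <- rss[cbind(mins, seq_len(B))]
    upd <- vals < best
    best_idx[upd] <- (s - 1L) + mins[upd]
    best[upd] <- vals[upd]
  }
  list(rss = pmax(best, 0), idx = best_idx)
}

#' Fit a continuous piecewise-linear model with a fixed number of breakpoints
#'
#' Least-squares fit of a continuous segmented line to the per-bin counts of
#' a distance-frequency curve, with `k` breakpoints. Candidate breakpoints
#' are the bin midpoints; every combination respecting a minimum segment
#' length of `min_seg` bins is scored and the global RSS minimiser returned,
#' so the fit is exhaustively optimal over the candidate grid and
#' deterministic for a fixed input. For very long curves, where the full
#' grid is combinatorially infeasible, the candidate set is thinned evenly
#' (at most 20000 combinations are scored); curves of ordinary length (up to
#' roughly 200 bins at `k = 2`) always use the full grid.
#'
#' @param curve A [build_distance_curve()] object (or any `distance_curve`).
#' @param k Number of breakpoints (>= 0); `k = 0` is the ordinary
#'   least-squares line.
#' @param min_seg Minimum number of bins per segment (default 3).
#' @return A `joinpoint_fit`: `k`, `breakpoints` (bin-midpoint distances, in
#'   metres), `intercept`, `slopes` (`k + 1` counts-per-metre values),
#'   `slope_changes`, `rss`, `n`, `bin_width`, plus the fitted `x`/`y`.
#' @export
fit_piecewise <- function(curve, k, min_seg = 3) {
  stopifnot(inherits(curve, "distance_curve"), k >= 0, min_seg >= 2)
  x <- curve_midpoints(curve)
  y <- as.numeric(curve$counts)
  n <- length(y)
  if (n < max(2, (k + 1) * min_seg) ||
      (k > 0 && ncol(jp_combos(n, k, min_seg)) == 0))
    stop("infeasible fit: ", n, " bins cannot support ", k,
         " breakpoints with segments of ", min_seg, " bins",
         call. = FALSE)
  grid <- jp_grid(x, k, min_seg)
  opt <- jp_min_rss(grid, matrix(y, ncol = 1))
  bps <- if (k > 0) x[grid$combos[, opt$idx]] else numeric(0)
  X <- jp_design(x, bps)
  coefs <- stats::.lm.fit(X, y)$coefficients
  slopes <- cumsum(c(coefs[2], if (k > 0) coefs[3:(2 + k)]))
  structure(list(k = k,
                 breakpoints = bps,
                 intercept = coefs[1],
                 slopes = slopes,
                 slope_changes = if (k > 0) diff(slopes) else numeric(0),
                 rss = opt$rss[1],
                 n = n,
                 bin_width = curve$bin_width,
                 min_seg = min_seg,
                 x = x, y = y,
                 fitted = as.numeric(X %*% coefs),
                 selection = NULL, significance = NULL,
                 note = NULL),
            class = "joinpoint_fit")
}

#' @export
print.joinpoint_fit <- function(x, ...) {
  cat(sprintf("Joinpoint fit: k = %d, rss = %.4g over %d bins\n",
              x$k, x$rss, x$n))
  if (x$k > 0) {
    cat("  breakpoints (m):", paste(signif(x$breakpoints, 6), collapse = ", "),
        "\n")
    cat("  slopes:", paste(signif(x$slopes, 4), collapse = ", "), "\n")
  } else {
    cat("  slope:", signif(x$slopes, 4), "\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# one sequential permutation test: H0 "fit_red suffices" vs Ha "k_full
# breakpoints"; permute residuals of the reduced fit and compare the RSS
# ratio after full grid searches on each permuted response
jp_perm_test <- function(x, y, fit_red, k_full, min_seg, n_perm) {
  grid_red <- jp_grid(x, fit_red$k, min_seg)
  grid_full <- jp_grid(x, k_full, min_seg)
  rss_red <- fit_red$rss
  rss_full <- jp_min_rss(grid_full, matrix(y, ncol = 1))$rss[1]
  eps <- 1e-10 * max(1, sum(y^2))
  if (rss_red <= eps) return(1)                # nothing left to explain
  t_obs <- rss_red / max(rss_full, eps)
  res <- y - fit_red$fitted
  Ystar <- matrix(fit_red$fitted, length(y), n_perm) +
    vapply(seq_len(n_perm), function(i) sample(res), numeric(length(y)))
  red_star <- jp_min_rss(grid_red, Ystar)$rss
  full_star <- jp_min_rss(grid_full, Ystar)$rss
  t_star <- red_star / pmax(full_star, eps)
  (1 + sum(t_star >= t_obs - 1e-12)) / (n_perm + 1)
}

#' Select the number of joinpoints
#'
#' Chooses `k` for a distance-frequency curve either by the sequential
#' permutation test (default; the forward analogue of the NCI joinpoint
#' procedure: test `k` vs `k - 1` by permuting the reduced-model residuals
#' and comparing RSS ratios, stepping up while the test rejects at `alpha`)
#' or by minimising `BIC = n log(rss / n) + p log(n)` with
#' `p = 2 + 2k` parameters. After selection, per-breakpoint slope-change
#' significance is attached (permutation test under `method = "permutation"`,
#' t-test under `"bic"`).
#'
#' A degenerate curve (all counts equal) returns the flat `k = 0` line with a
#' note; a curve too short for any breakpoint returns `k = 0`.
#'
#' @inheritParams fit_piecewise
#' @param k_max Maximum number of breakpoints considered (default 4).
#' @param method `"permutation"` or `"bic"`.
#' @param alpha Test level for the sequential procedure (default 0.05).
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed; required for `method = "permutation"` and for
#'   the attached permutation significance tests. Identical seeds give
#'   identical results.
#' @return A `joinpoint_fit` with `selection` metadata (method, alpha,
#'   per-step p-values or BIC values, seed) and a `significance` data frame
#'   (`breakpoint`, `slope_change`, `p_value`, `significant`).
#' @export
select_joinpoints <- function(curve, k_max = 4,
                              method = c("permutation", "bic"),
                              alpha = 0.05, n_perm = 999, seed = NULL,
                              min_seg = 3) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "distance_curve"), k_max >= 0)
  y <- as.numeric(curve$counts)
  n <- length(y)

  if (n < 2) {
    fit <- degenerate_fit(curve, "fewer than 2 bins")
    return(finish_selection(fit, curve, method, alpha, n_perm, seed, NULL))
  }
  if (diff(range(y)) == 0) {
    fit <- fit_piecewise(curve, 0, min_seg = min(min_seg, n))
    fit$note <- "degenerate curve: all counts equal; k = 0"
    return(finish_selection(fit, curve, method, alpha, n_perm, seed, NULL))
  }

  feasible <- Filter(function(k) n >= (k + 1) * min_seg &&
                       (k == 0 || ncol(jp_combos(n, k, min_seg)) > 0),
                     0:k_max)
  x <- curve_midpoints(curve)

  if (method == "bic") {
    fits <- lapply(feasible, function(k) fit_piecewise(curve, k, min_seg))
    bic <- vapply(fits, function(f)
      f$n * log(max(f$rss, 1e-8) / f$n) + (2 + 2 * f$k) * log(f$n),
      numeric(1))
    fit <- fits[[which.min(bic)]]
    info <- list(method = "bic", k_max = k_max,
                 bic = stats::setNames(bic, paste0("k", feasible)))
  } else {
    if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
    if (is.null(seed)) stop("permutation selection requires a seed",
                            call. = FALSE)
    set.seed(seed)
    fit <- fit_piecewise(curve, 0, min_seg)
    pvals <- numeric(0)
    for (k in setdiff(feasible, 0)) {
      p <- jp_perm_test(x, y, fit, k, min_seg, n_perm)
      pvals[paste0("k", k)] <- p
      if (p < alpha) fit <- fit_piecewise(curve, k, min_seg) else break
    }
    info <- list(method = "permutation", k_max = k_max, alpha = alpha,
                 n_perm = n_perm, seed = seed, p_values = pvals)
  }
  finish_selection(fit, curve, method, alpha, n_perm, seed, info)
}

degenerate_fit <- function(curve, why) {
  y <- as.numeric(curve$counts)
  structure(list(k = 0L, breakpoints = numeric(0),
                 intercept = if (length(y)) mean(y) else NA_real_,
                 slopes = 0, slope_changes = numeric(0),
                 rss = if (length(y)) sum((y - mean(y))^2) else NA_real_,
                 n = length(y), bin_width = curve$bin_width,
                 min_seg = NA_integer_,
                 x = curve_midpoints(curve), y = y,
                 fitted = rep(if (length(y)) mean(y) else NA_real_, length(y)),
                 selection = NULL, significance = NULL,
                 note = paste0("degenerate curve: ", why)),
            class = "joinpoint_fit")
}

finish_selection <- function(fit, curve, method, alpha, n_perm, seed, info) {
  fit$selection <- info
  sig_method <- if (method == "bic") "t" else "permutation"
  fit$significance <- slope_change_significance(
    fit, curve, method = sig_method, alpha = alpha, n_perm = n_perm,
    seed = if (sig_method == "permutation" && !is.null(seed))
      seed + 104729L else NULL)
  fit
}

#' Test the significance of each slope change
#'
#' For each breakpoint, tests the two-sided null that the slope change across
#' it is zero, holding the breakpoint locations fixed. `method = "t"` uses
#' the t-statistic of the hinge coefficient from the segmented linear model;
#' `method = "permutation"` drops the hinge, permutes the reduced-model
#' residuals and compares the refitted hinge coefficient magnitudes.
#'
#' @param fit A `joinpoint_fit` produced from `curve`.
#' @param curve The fitted `distance_curve`.
#' @param method `"permutation"` or `"t"`.
#' @param alpha Flagging level (default 0.05).
#' @param n_perm Permutations for the permutation path.
#' @param seed Seed for the permutation path (deterministic given seed).
#' @return A data frame with one row per breakpoint: `breakpoint`,
#'   `slope_change`, `p_value`, `significant`.
#' @export
slope_change_significance <- function(fit, curve,
                                      method = c("permutation", "t"),
                                      alpha = 0.05, n_perm = 999,
                                      seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "joinpoint_fit"))
  k <- fit$k
  empty <- data.frame(breakpoint = numeric(0), slope_change = numeric(0),
                      p_value = numeric(0), significant = logical(0))
  if (k == 0) return(empty)
  x <- fit$x
  y <- fit$y
  n <- length(y)
  X <- jp_design(x, fit$breakpoints)
  p <- ncol(X)
  scale_eps <- 1e-10 * max(1, sum(y^2))

  pvals <- numeric(k)
  if (method == "t") {
    ls <- stats::lm.fit(X, y)
    rss <- sum(ls$residuals^2)
    df <- n - p
    XtXinv <- chol2inv(chol(crossprod(X)))
    for (i in seq_len(k)) {
      gamma <- fit$slope_changes[i]
      if (rss <= scale_eps || df <= 0) {
        pvals[i] <- if (abs(gamma) > 1e-8) 0 else 1
      } else {
        se <- sqrt(rss / df * XtXinv[2 + i, 2 + i])
        pvals[i] <- 2 * stats::pt(-abs(gamma / se), df)
      }
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    XtXinv <- chol2inv(chol(crossprod(X)))
    for (i in seq_len(k)) {
      gamma_obs <- fit$slope_changes[i]
      Xr <- X[, -(2 + i), drop = FALSE]
      red <- stats::lm.fit(Xr, y)
      res <- red$residuals
      if (sum(res^2) <= scale_eps) {       # reduced model already exact
        pvals[i] <- if (abs(gamma_obs) > 1e-8) 0 else 1
        next
      }
      Ystar <- matrix(y - res, n, n_perm) +
        vapply(seq_len(n_perm), function(b) sample(res), numeric(n))
      gam_star <- (XtXinv %*% crossprod(X, Ystar))[2 + i, ]
      pvals[i] <- (1 + sum(abs(gam_star) >= abs(gamma_obs) - 1e-12)) /
        (n_perm + 1)
    }
  }
  data.frame(breakpoint = fit$breakpoints,
             slope_change = fit$slope_changes,
             p_value = pvals,
             significant = pvals < alpha)
}
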