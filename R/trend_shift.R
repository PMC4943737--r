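#' Mann-Kendall test for a monotonic trend
#'
#' Computes the Mann-Kendall score `S = sum_{i<j} sign(x_j - x_i)`, the
#' tie-corrected Kendall tau, and a two-sided p-value: a normal
#' approximation with continuity correction and tie-corrected variance for
#' `n >= 10`, the exact permutation distribution for `n <= 8`, and a
#' seeded Monte-Carlo permutation p-value for `n = 9`.  Being a rank
#' statistic, the result is invariant under strictly increasing transforms
#' of the values.
#'
#' @param x Numeric series in time order (missing values dropped).
#' @param alpha Significance level used only to label `direction`.
#' @return An object of class `mann_kendall`: `S`, `tau`, `var_s`, `p`,
#'   `n`, `direction` (`"up"`, `"down"` or `"none"`), `method`.
#' @export
#' @examples
#' mann_kendall(c(1, 2, 3, 4))$S
mann_kendall <- function(x, alpha = 0.05) {
  obs <- x[!is.na(x)]
  n <- length(obs)
  if (n < 4) abort("need at least 4 observations")
  s <- mk_score(obs)
  ties <- table(obs)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  n0 <- n * (n - 1) / 2
  n1 <- sum(ties * (ties - 1) / 2)
  denom <- sqrt((n0 - n1) * n0)
  tau <- if (denom == 0) 0 else s / denom
  if (denom == 0) {
    p <- 1
    method <- "degenerate"
  } else if (n >= 10) {
    zstat <- (s - sign(s)) / sqrt(var_s)
    p <- 2 * pnorm(-abs(zstat))
    method <- "normal approximation"
  } else if (n <= 8) {
    null_s <- vapply(all_permutations(n), function(idx) mk_score(obs[idx]),
                     numeric(1))
    p <- mean(abs(null_s) >= abs(s))
    method <- "exact permutation"
  } else {
    null_s <- with_private_seed(571, {
      vapply(seq_len(1e4), function(i) mk_score(sample(obs)), numeric(1))
    })
    p <- (1 + sum(abs(null_s) >= abs(s))) / (1e4 + 1)
    method <- "Monte-Carlo permutation"
  }
  direction <- if (p < alpha && s > 0) "up"
  else if (p < alpha && s < 0) "down"
  else "none"
  structure(list(S = s, tau = tau, var_s = var_s, p = p, n = n,
                 direction = direction, method = method),
            class = "mann_kendall")
}

mk_score <- function(x) {
  d <- sign(outer(x, x, "-"))
  sum(d[lower.tri(d)])
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (p in sub) {
      k <- k + 1
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' @export
print.mann_kendall <- function(x, ...) {
  cat("<mann_kendall> S =", x$S, " tau =", signif(x$tau, 4),
      " p =", signif(x$p, 4), paste0("(", x$method, ")"),
      " direction:", x$direction, "\n")
  invisible(x)
}

#' @export
#' @method tidy mann_kendall
tidy.mann_kendall <- function(x, ...) {
  tibble::tibble(S = x$S, tau = x$tau, var_s = x$var_s, p.value = x$p,
                 n = x$n, direction = x$direction, method = x$method)
}

#' Mann-Kendall trends for every indicator series
#'
#' @param zscores A z-score tibble from [preprocess_indicators()] (the
#'   test is rank-based, so whole-series z-scores and transformed values
#'   give identical results).
#' @param alpha Significance level for the `direction` label.
#' @return A tibble `dataset`, `indicator`, `S`, `tau`, `p.value`,
#'   `direction`.
#' @export
trend_test <- function(zscores, alpha = 0.05) {
  zscores |>
    dplyr::group_by(.data$dataset, .data$indicator) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$year)
      tidy(mann_kendall(d$z, alpha = alpha)) |>
        dplyr::select("S", "tau", "p.value", "direction")
    }) |>
    dplyr::ungroup()
}

#' F-test for a variance shift at a split year
#'
#' Compares the sample variance after a split year to the variance before
#' it: `F = s2_post / s2_pre` with `(n_post - 1, n_pre - 1)` degrees of
#' freedom.  The one-sided p-value tests for a variance increase after the
#' split; a two-sided p-value is also returned.
#'
#' @param x Numeric series in year order.
#' @param split_year First year of the post period.
#' @param years Years aligned with `x` (defaults to positions).
#' @return A list of class `variance_shift`: `F`, `df_post`, `df_pre`,
#'   `p_increase`, `p_two_sided`, `split_year`.
#' @export
variance_shift_test <- function(x, split_year, years = seq_along(x)) {
  stopifnot(length(x) == length(years))
  keep <- !is.na(x)
  x <- x[keep]
  years <- years[keep]
  pre <- x[years < split_year]
  post <- x[years >= split_year]
  if (length(pre) < 3 || length(post) < 3) {
    abort("need at least 3 years with data on each side of the split")
  }
  v_pre <- var(pre)
  v_post <- var(post)
  if (v_pre == 0) abort("zero pre-split variance")
  f <- v_post / v_pre
  df_post <- length(post) - 1
  df_pre <- length(pre) - 1
  p1 <- pf(f, df_post, df_pre, lower.tail = FALSE)
  structure(list(F = f, df_post = df_post, df_pre = df_pre,
                 p_increase = p1, p_two_sided = min(1, 2 * min(p1, 1 - p1)),
                 split_year = split_year),
            class = "variance_shift")
}

#' @export
print.variance_shift <- function(x, ...) {
  cat("<variance_shift> F(", x$df_post, ",", x$df_pre, ") =",
      signif(x$F, 4), " p(increase) =", signif(x$p_increase, 4), "\n")
  invisible(x)
}

#' @export
#' @method tidy variance_shift
tidy.variance_shift <- function(x, ...) {
  tibble::tibble(statistic = x$F, df_post = x$df_post, df_pre = x$df_pre,
                 p.value = x$p_increase, p.two.sided = x$p_two_sided,
                 split_year = x$split_year)
}

#' Chronologically constrained clustering of a multivariate series
#'
#' Partitions a years x indicators matrix into homogeneous groups of
#' consecutive years.  Candidate boundaries are placed by constrained
#' binary segmentation: within each segment the boundary maximizing the
#' between-group dispersion (equivalently minimizing the pooled
#' within-group sum of squares of the two adjacent year groups, Euclidean
#' distances) is located, and its significance is assessed by a
#' permutation test whose null distribution is that of the
#' maximally-selected statistic -- the years of the segment are permuted
#' and the best boundary re-located each time, so choosing the split from
#' the data does not bias the p-value.  A split is kept when `p <= alpha`
#' and both sides are searched recursively; `alpha` therefore acts as the
#' clustering sensitivity, with larger values yielding finer partitions.
#' A final linkage pass re-joins adjacent groups that remain substantially
#' connected: if at least `connectedness` of their inter-group distances
#' fall below the median pairwise distance of the whole series, the
#' boundary is dissolved.  First years of the final groups 2..G are the
#' reported breakpoints.
#'
#' Permutation seeds are derived deterministically from each segment's
#' composition, so results are reproducible and identical segment tests
#' agree across `alpha` levels.
#'
#' @param m Numeric matrix (years x indicators, no missing cells; z-scores
#'   on a whole-series baseline are the intended input) or a data frame.
#' @param years Years labelling the rows.
#' @param alpha Clustering sensitivity: the level of the permutation test
#'   gating each split.
#' @param connectedness Proportion in (0, 1] of below-median inter-group
#'   links required for two adjacent groups to be re-joined.
#' @param n_permutations Permutations per segment test.
#' @param seed Base seed for the permutation streams.
#' @return A list of class `chron_clust`: `breakpoints` (first years of
#'   groups 2..G), `groups` (tibble `year`, `group`), `alpha`,
#'   `connectedness`.
#' @export
chronological_clustering <- function(m, years = NULL, alpha = 0.05,
                                     connectedness = 0.5,
                                     n_permutations = 999, seed = 1) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (is.null(years)) {
    years <- if (!is.null(rownames(m))) as.integer(rownames(m)) else
      seq_len(n)
  }
  if (n < 6) abort("need at least 6 years")
  if (anyNA(m)) abort("missing cells: impute before clustering")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (connectedness <= 0 || connectedness > 1) {
    abort("connectedness must be in (0, 1]")
  }
  bounds <- sort(segment_boundaries(m, 1, n, alpha, n_permutations, seed))
  # linkage pass: dissolve boundaries between groups that are still
  # connected at the median-distance level
  dist_full <- as.matrix(stats::dist(m))
  med <- median(dist_full[upper.tri(dist_full)])
  repeat {
    if (length(bounds) == 0) break
    cuts <- c(1, bounds, n + 1)
    joined <- FALSE
    for (j in seq_along(bounds)) {
      a <- seq(cuts[j], cuts[j + 1] - 1)
      b <- seq(cuts[j + 1], cuts[j + 2] - 1)
      linked <- mean(dist_full[a, b] < med)
      if (linked >= connectedness) {
        bounds <- bounds[-j]
        joined <- TRUE
        break
      }
    }
    if (!joined) break
  }
  group_id <- rep(seq_len(length(bounds) + 1),
                  diff(c(1, bounds, n + 1)))
  structure(list(breakpoints = years[bounds],
                 groups = tibble::tibble(year = years, group = group_id),
                 alpha = alpha, connectedness = connectedness),
            class = "chron_clust")
}

# Between-group dispersion at every admissible boundary of x, via
# cumulative sums: between(b) = |C_b|^2/b + |C_n - C_b|^2/(n-b) - |C_n|^2/n.
max_between_stat <- function(x) {
  n <- nrow(x)
  cs <- apply(x, 2, cumsum)
  tot <- cs[n, ]
  b <- seq_len(n - 1)
  lead <- rowSums(cs[b, , drop = FALSE]^2) / b
  trail <- rowSums((matrix(tot, n - 1, ncol(x), byrow = TRUE) -
                      cs[b, , drop = FALSE])^2) / (n - b)
  between <- lead + trail - sum(tot^2) / n
  list(stat = max(between), boundary = which.max(between) + 1L)
}

# Recursive constrained segmentation with a maximally-selected-statistic
# permutation test per segment; returns boundaries as absolute row indices.
segment_boundaries <- function(m, from, to, alpha, n_permutations, seed) {
  n <- to - from + 1
  if (n < 4) return(integer(0))
  x <- m[from:to, , drop = FALSE]
  obs <- max_between_stat(x)
  seg_seed <- (seed + 7919 * from + 104729 * to) %% 2147483647
  exceed <- with_private_seed(seg_seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      max_between_stat(x[sample.int(n), , drop = FALSE])$stat >= obs$stat
    }, logical(1)))
  })
  p <- (1 + exceed) / (n_permutations + 1)
  if (p > alpha) return(integer(0))
  cut <- from + obs$boundary - 1L
  c(segment_boundaries(m, from, cut - 1L, alpha, n_permutations, seed),
    cut,
    segment_boundaries(m, cut, to, alpha, n_permutations, seed))
}

#' @export
print.chron_clust <- function(x, ...) {
  cat("<chron_clust> alpha =", x$alpha, " groups =",
      max(x$groups$group), "\n")
  if (length(x$breakpoints) > 0) {
    cat("  breakpoints:", paste(x$breakpoints, collapse = ", "), "\n")
  } else {
    cat("  no breakpoints\n")
  }
  invisible(x)
}

#' Breakpoint years per dataset and sensitivity level
#'
#' Runs [chronological_clustering()] on the z-score matrix of every
#' dataset at each requested `alpha`.
#'
#' @param zscores A z-score tibble from [preprocess_indicators()]
#'   (whole-series baseline, gaps imputed).
#' @param alphas Sensitivity levels.
#' @inheritParams chronological_clustering
#' @return A tibble `dataset`, `alpha`, `year` (one row per breakpoint).
#' @export
detect_breakpoints <- function(zscores, alphas = c(0.01, 0.05, 0.1),
                               connectedness = 0.5, n_permutations = 999,
                               seed = 1) {
  zscores |>
    dplyr::group_by(.data$dataset) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(d, id_cols = "year",
                                 names_from = "indicator",
                                 values_from = "z") |>
        dplyr::arrange(.data$year)
      m <- as.matrix(wide[, -1])
      purrr::map_dfr(alphas, function(a) {
        cc <- chronological_clustering(m, years = wide$year, alpha = a,
                                       connectedness = connectedness,
                                       n_permutations = n_permutations,
                                       seed = seed)
        tibble::tibble(alpha = a, year = cc$breakpoints)
      })
    }) |>
    dplyr::ungroup()
}
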