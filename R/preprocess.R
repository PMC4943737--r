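#' Fit a Box-Cox transformation by maximum likelihood
#'
#' Indicator series are strongly right-skewed (lognormal-like), so all
#' downstream analysis runs on Box-Cox transformed values.  The exponent
#' `lambda` is chosen by profile maximum likelihood on
#' `lambda in [-2, 3]` (tolerance 1e-4).  Series containing zeros (ratios
#' can be exactly 0) are shifted by half the smallest positive value
#' before transforming; the shift is recorded so the transform can be
#' inverted.
#'
#' @param x Numeric series; at least 5 non-missing values, not constant.
#' @param lambda_range Search interval for `lambda`.
#' @param shift Additive offset applied before transforming; by default 0
#'   when all values are positive, otherwise half the smallest positive
#'   value.
#' @return An object of class `boxcox_transform`: a list with `lambda`,
#'   `shift`, `transformed` (same length as `x`), and `loglik`.
#' @seealso [boxcox_transform()], [boxcox_inverse()]
#' @export
#' @examples
#' fit <- boxcox_fit(rlnorm(50))
#' fit$lambda
boxcox_fit <- function(x, lambda_range = c(-2, 3), shift = NULL) {
  obs <- x[!is.na(x)]
  if (length(obs) < 5) abort("need at least 5 non-missing values")
  if (diff(range(obs)) == 0) {
    abort("constant series: Box-Cox exponent is undefined")
  }
  if (is.null(shift)) {
    shift <- if (min(obs) > 0) 0 else min(obs[obs > 0]) / 2
  }
  y <- obs + shift
  if (min(y) <= 0) abort("values (plus shift) must be positive")
  n <- length(y)
  ll <- function(lambda) {
    z <- boxcox_transform(y, lambda)
    -n / 2 * log(mean((z - mean(z))^2)) + (lambda - 1) * sum(log(y))
  }
  opt <- optimize(ll, lambda_range, maximum = TRUE, tol = 1e-4)
  structure(list(lambda = opt$maximum, shift = shift,
                 transformed = boxcox_transform(x + shift, opt$maximum),
                 loglik = opt$objective),
            class = "boxcox_transform")
}

#' Apply or invert a Box-Cox transformation
#'
#' `boxcox_transform()` computes `(x^lambda - 1)/lambda` (the natural log
#' at `lambda = 0`); `boxcox_inverse()` maps transformed values back to the
#' original scale, subtracting `shift`.
#'
#' @param x,y Numeric vectors (original / transformed scale).
#' @param lambda Box-Cox exponent.
#' @param shift Additive offset applied before the forward transform.
#' @return A numeric vector.
#' @export
boxcox_transform <- function(x, lambda, shift = 0) {
  x <- x + shift
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @export
boxcox_inverse <- function(y, lambda, shift = 0) {
  out <- if (abs(lambda) < 1e-12) exp(y) else (lambda * y + 1)^(1 / lambda)
  out - shift
}

#' @export
print.boxcox_transform <- function(x, ...) {
  cat("<boxcox_transform> lambda =", signif(x$lambda, 4),
      " shift =", signif(x$shift, 4), "\n")
  invisible(x)
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' Tests a series against a normal distribution whose mean and standard
#' deviation are estimated from the same data.  Because estimating the
#' parameters makes the plain Kolmogorov-Smirnov p-value anti-conservative,
#' the null distribution of the statistic is obtained by Monte-Carlo
#' simulation (the Lilliefors correction), under a fixed internal seed so
#' results are reproducible.
#'
#' Short series carry too little information for a meaningful normality
#' verdict: series below `n_min` years (default 12) are reported as not
#' eligible rather than tested.
#'
#' @param x Numeric series (missing values dropped).
#' @param n_min Minimum number of observations for eligibility.
#' @param n_sim Monte-Carlo replicates for the null distribution.
#' @param seed Seed for the Monte-Carlo draw; the caller's RNG state is
#'   left untouched.
#' @return A list of class `ks_normality` with `eligible`, `n`,
#'   `statistic` (the Lilliefors D) and `p`.
#' @export
ks_normality <- function(x, n_min = 12, n_sim = 1e4, seed = 194) {
  obs <- x[!is.na(x)]
  n <- length(obs)
  if (n < n_min) {
    return(structure(list(eligible = FALSE, n = n, statistic = NA_real_,
                          p = NA_real_), class = "ks_normality"))
  }
  d <- lilliefors_stat(obs)
  d_null <- with_private_seed(seed, {
    vapply(seq_len(n_sim), function(i) lilliefors_stat(rnorm(n)), numeric(1))
  })
  p <- (1 + sum(d_null >= d)) / (n_sim + 1)
  structure(list(eligible = TRUE, n = n, statistic = d, p = p),
            class = "ks_normality")
}

lilliefors_stat <- function(x) {
  n <- length(x)
  p <- pnorm(sort(x), mean(x), sd(x))
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

#' @export
print.ks_normality <- function(x, ...) {
  if (!x$eligible) {
    cat("<ks_normality> n =", x$n, "- not eligible for testing\n")
  } else {
    cat("<ks_normality> n =", x$n, " D =", signif(x$statistic, 4),
        " p =", signif(x$p, 4), "\n")
  }
  invisible(x)
}

#' Impute gaps by iterative eigenvector filtering
#'
#' Completes a years x indicators matrix by EM-style reconstruction from
#' its leading principal axes: gaps are initialised with column means, the
#' standardized matrix is decomposed, cells are reconstructed from the
#' smallest number of axes explaining at least `var_explained` of the
#' variance (capped at `max_axes`), the gap cells are replaced and the
#' cycle repeats until the imputed values change by less than `tol`
#' (relative) or `max_iter` iterations.  Observed cells are never altered.
#'
#' @param m Numeric matrix, years in rows, indicators in columns, `NA` for
#'   gaps.  Each column must be at least `min_obs_frac` observed and no
#'   column may be entirely missing; at least two columns are required.
#' @param max_axes Cap on the number of principal axes used.
#' @param var_explained Proportion of variance the retained axes must
#'   explain.
#' @param tol Relative convergence tolerance on imputed cells.
#' @param max_iter Iteration cap; exceeding it is an error (the iteration
#'   trace is attached to the condition).
#' @param min_obs_frac Minimum observed fraction per column.
#' @return The completed matrix, with attributes `imputed` (logical mask),
#'   `iterations` and `axes`.
#' @export
evf_impute <- function(m, max_axes = 3, var_explained = 0.8, tol = 1e-6,
                       max_iter = 500, min_obs_frac = 0.6) {
  m <- as.matrix(m)
  if (ncol(m) < 2) abort("need at least 2 indicator columns")
  gaps <- is.na(m)
  if (any(colSums(!gaps) == 0)) abort("column with all values missing")
  frac <- colMeans(!gaps)
  if (any(frac < min_obs_frac)) {
    abort(paste0("column(s) with more than ", round(100 * (1 - min_obs_frac)),
                 "% missing: ",
                 paste(colnames(m)[frac < min_obs_frac], collapse = ", ")))
  }
  if (!any(gaps)) {
    attr(m, "imputed") <- gaps
    attr(m, "iterations") <- 0L
    attr(m, "axes") <- 0L
    return(m)
  }
  x <- m
  for (j in seq_len(ncol(x))) {
    x[gaps[, j], j] <- mean(m[, j], na.rm = TRUE)
  }
  trace <- numeric(0)
  axes <- NA_integer_
  for (iter in seq_len(max_iter)) {
    mu <- colMeans(x)
    sg <- apply(x, 2, sd)
    sg[sg == 0] <- 1
    z <- sweep(sweep(x, 2, mu), 2, sg, "/")
    dec <- svd(z)
    vexp <- cumsum(dec$d^2) / sum(dec$d^2)
    axes <- min(which(vexp >= var_explained)[1], max_axes, na.rm = TRUE)
    zhat <- dec$u[, seq_len(axes), drop = FALSE] %*%
      diag(dec$d[seq_len(axes)], axes) %*%
      t(dec$v[, seq_len(axes), drop = FALSE])
    xhat <- sweep(sweep(zhat, 2, sg, "*"), 2, mu, "+")
    new <- x
    new[gaps] <- xhat[gaps]
    delta <- max(abs(new[gaps] - x[gaps])) /
      max(abs(new[gaps]), .Machine$double.eps)
    trace <- c(trace, delta)
    x <- new
    if (delta < tol) {
      attr(x, "imputed") <- gaps
      attr(x, "iterations") <- iter
      attr(x, "axes") <- axes
      return(x)
    }
  }
  abort(message = c(
    paste0("eigenvector-filtering imputation did not converge in ",
           max_iter, " iterations"),
    i = paste0("last relative change: ", signif(tail(trace, 1), 4))
  ))
}

#' Controlling mean and standard deviation for a baseline window
#'
#' A baseline holds the controlling mean and standard deviation of a
#' (transformed) indicator series, estimated either from the entire series
#' or from a reference-condition year window, together with the window
#' that produced them.
#'
#' @param years Integer years of the series.
#' @param values (Transformed) indicator values, aligned with `years`.
#' @param window `NULL` for a whole-series baseline, or `c(start, end)`
#'   years.
#' @param kind Baseline label: `"entire"`, `"refcon_chl"` or
#'   `"refcon_fish"`.
#' @param min_years Minimum number of non-missing years in the window.
#' @return An object of class `zoo_baseline`: `mu`, `sigma`, `kind`,
#'   `start_year`, `end_year`, `n_years`.
#' @export
make_baseline <- function(years, values, window = NULL, kind = "entire",
                          min_years = 5) {
  stopifnot(length(years) == length(values))
  if (is.null(window)) window <- range(years)
  keep <- years >= window[1] & years <= window[2] & !is.na(values)
  n <- sum(keep)
  if (n < min_years) {
    abort(paste0("baseline window contains only ", n,
                 " year(s) with data (minimum ", min_years, ")"))
  }
  sigma <- sd(values[keep])
  if (!is.finite(sigma) || sigma <= 0) {
    abort("baseline standard deviation must be positive")
  }
  structure(list(mu = mean(values[keep]), sigma = sigma, kind = kind,
                 start_year = window[1], end_year = window[2], n_years = n),
            class = "zoo_baseline")
}

#' @export
print.zoo_baseline <- function(x, ...) {
  cat("<zoo_baseline>", x$kind, paste0("[", x$start_year, "-", x$end_year,
                                       "]"),
      " mu =", signif(x$mu, 4), " sigma =", signif(x$sigma, 4),
      " n =", x$n_years, "\n")
  invisible(x)
}

#' Standardize a series against a baseline
#'
#' Computes `z = (x - mu) / sigma` for every year, including years outside
#' the baseline window, so that departures from the reference state are
#' expressed in baseline standard deviations.
#'
#' @param x (Transformed) indicator values.
#' @param baseline A [make_baseline()] object, or a list with `mu` and
#'   `sigma`.
#' @return Numeric z-scores.
#' @export
standardize <- function(x, baseline) {
  if (!is.finite(baseline$sigma) || baseline$sigma <= 0) {
    abort("baseline sigma must be positive")
  }
  (x - baseline$mu) / baseline$sigma
}

#' Coefficient of variation, percent
#'
#' `100 * sd(x) / |mean(x)|`, with the sample (n-1) standard deviation;
#' used to compare indicator variability before and after transformation.
#'
#' @param x Numeric series (missing values dropped).
#' @return The CV in percent.
#' @export
cv_percent <- function(x) {
  obs <- x[!is.na(x)]
  m <- mean(obs)
  if (m == 0) abort("coefficient of variation undefined for zero mean")
  100 * sd(obs) / abs(m)
}

#' Transform, impute and standardize an indicator table
#'
#' The preprocessing pipeline behind all chart and model fitting: per
#' dataset, each indicator series is Box-Cox transformed, the years x
#' indicators matrix of transformed values is completed by
#' [evf_impute()] (missing years inside the observed span become gap
#' rows), and every series is standardized against a baseline -- the
#' entire series by default, or a reference-condition window per dataset.
#'
#' @param indicators Long indicator tibble from
#'   [compute_indicator_suite()].
#' @param refcon `NULL` for whole-series baselines, or a reference-window
#'   tibble ([read_refcon()]) with a single `kind`, one row per dataset.
#' @param impute Impute gaps before standardizing?  If `FALSE`, gap years
#'   keep missing z-scores.
#' @param min_years Minimum years with data in a baseline window.
#' @param lambda_range Box-Cox search interval.
#' @return A tibble `dataset`, `year`, `indicator`, `value`, `transformed`,
#'   `z`, `imputed`, `baseline_kind`, with a `baselines` attribute (tibble
#'   of `lambda`, `shift`, `mu`, `sigma` and window per dataset x
#'   indicator).
#' @export
preprocess_indicators <- function(indicators, refcon = NULL, impute = TRUE,
                                  min_years = 5, lambda_range = c(-2, 3)) {
  if (!is.null(refcon)) {
    kinds <- unique(refcon$kind)
    if (length(kinds) != 1) {
      abort("refcon must contain a single reference kind; filter first")
    }
    if (anyDuplicated(refcon$dataset)) {
      abort("refcon must have one window per dataset")
    }
    kind <- kinds
  } else {
    kind <- "entire"
  }
  res <- indicators |>
    dplyr::group_by(.data$dataset) |>
    dplyr::group_map(function(d, key) {
      window <- NULL
      if (!is.null(refcon)) {
        row <- refcon[refcon$dataset == key$dataset, ]
        if (nrow(row) == 0) {
          abort(paste0("no reference window for dataset ", key$dataset))
        }
        window <- c(row$start_year, row$end_year)
      }
      preprocess_one(d, key$dataset, window, kind, impute, min_years,
                     lambda_range)
    }) |>
    purrr::transpose()
  out <- dplyr::bind_rows(res$table)
  attr(out, "baselines") <- dplyr::bind_rows(res$baselines)
  out
}

preprocess_one <- function(d, dataset, window, kind, impute, min_years,
                           lambda_range) {
  years <- seq(min(d$year), max(d$year))
  wide <- tidyr::pivot_wider(d, id_cols = "year", names_from = "indicator",
                             values_from = "value") |>
    dplyr::right_join(tibble::tibble(year = years), by = "year") |>
    dplyr::arrange(.data$year)
  ind_names <- intersect(INDICATOR_LEVELS, names(wide))
  raw <- as.matrix(wide[ind_names])
  rownames(raw) <- wide$year
  fits <- purrr::map(ind_names, function(nm) {
    boxcox_fit(raw[, nm], lambda_range = lambda_range)
  })
  names(fits) <- ind_names
  trans <- raw
  for (nm in ind_names) {
    trans[, nm] <- boxcox_transform(raw[, nm], fits[[nm]]$lambda,
                                    fits[[nm]]$shift)
  }
  gaps <- is.na(trans)
  if (impute && any(gaps)) trans <- evf_impute(trans)
  baselines <- purrr::map(ind_names, function(nm) {
    make_baseline(years, trans[, nm], window = window, kind = kind,
                  min_years = min_years)
  })
  names(baselines) <- ind_names
  z <- trans
  for (nm in ind_names) z[, nm] <- standardize(trans[, nm], baselines[[nm]])
  tab <- tibble::tibble(
    dataset = dataset,
    year = rep(years, times = length(ind_names)),
    indicator = factor(rep(ind_names, each = length(years)),
                       levels = INDICATOR_LEVELS),
    value = as.vector(raw),
    transformed = as.vector(trans),
    z = as.vector(z),
    imputed = as.vector(gaps),
    baseline_kind = kind
  )
  bl <- tibble::tibble(
    dataset = dataset,
    indicator = factor(ind_names, levels = INDICATOR_LEVELS),
    lambda = purrr::map_dbl(fits, "lambda"),
    shift = purrr::map_dbl(fits, "shift"),
    mu = purrr::map_dbl(baselines, "mu"),
    sigma = purrr::map_dbl(baselines, "sigma"),
    start_year = purrr::map_dbl(baselines, "start_year"),
    end_year = purrr::map_dbl(baselines, "end_year"),
    n_years = purrr::map_int(baselines, "n_years"),
    baseline_kind = kind
  )
  list(table = tab, baselines = bl)
}
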