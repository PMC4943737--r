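test_that("Box-Cox limits and round trip are exact", {
  x <- c(0.5, 1, 2, 5, 10)
  expect_equal(boxcox_transform(x, 1), x - 1)
  expect_equal(boxcox_transform(x, 0), log(x))
  for (lambda in c(-1.5, -0.5, 0, 0.3, 1, 2.7)) {
    y <- boxcox_transform(x, lambda, shift = 0.25)
    expect_equal(boxcox_inverse(y, lambda, shift = 0.25), x,
                 tolerance = 1e-8)
  }
})

test_that("Box-Cox MLE recovers the log transform for lognormal data", {
  set.seed(42)
  x <- rlnorm(200)
  fit <- boxcox_fit(x)
  expect_gt(fit$lambda, -0.3)
  expect_lt(fit$lambda, 0.3)
  expect_equal(fit$shift, 0)
  # cross-check the profile-likelihood optimum against MASS::boxcox
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-1, 1, 0.01), plotit = FALSE)
  expect_lt(abs(fit$lambda - bc$x[which.max(bc$y)]), 0.02)
})

test_that("Box-Cox guards degenerate input and shifts zeros", {
  expect_error(boxcox_fit(rep(3, 10)), "constant")
  expect_error(boxcox_fit(c(1, 2, 3)), "5 non-missing")
  fit <- boxcox_fit(c(0, 0.4, 1, 2, 3, 8))
  expect_equal(fit$shift, 0.2)   # half the smallest positive value
  expect_true(all(is.finite(fit$transformed)))
})

test_that("short series are not eligible for normality testing", {
  res <- ks_normality(rnorm(6))
  expect_false(res$eligible)
  expect_true(is.na(res$p))
})

test_that("the Lilliefors statistic matches the reference implementation", {
  set.seed(9)
  for (i in 1:5) {
    x <- rlnorm(30)
    expect_equal(ks_normality(x, n_sim = 10)$statistic,
                 unname(nortest::lillie.test(x)$statistic))
  }
})

test_that("the normality test separates normal from exponential samples", {
  set.seed(101)
  p_norm <- replicate(30, ks_normality(rnorm(300), n_sim = 500)$p)
  p_expo <- replicate(30, ks_normality(rexp(300), n_sim = 500)$p)
  expect_gte(mean(p_norm > 0.05), 0.9)
  expect_true(all(p_expo < 0.01))
})

test_that("the normality test is deterministic and leaves the RNG alone", {
  x <- rlnorm(20)
  set.seed(5)
  before <- rnorm(3)
  set.seed(5)
  p1 <- ks_normality(x)$p
  after <- rnorm(3)
  expect_identical(before, after)
  expect_identical(p1, ks_normality(x)$p)
})

test_that("eigenvector filtering restores structured gaps", {
  # a complete matrix is returned unchanged
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10))
  out <- evf_impute(m)
  expect_equal(out, m, ignore_attr = TRUE)
  expect_equal(attr(out, "iterations"), 0L)

  # rank-1 completion is exact
  set.seed(3)
  col1 <- rlnorm(20)
  m2 <- cbind(a = col1, b = 2 * col1)
  m2g <- m2
  m2g[7, "b"] <- NA
  out2 <- evf_impute(m2g)
  expect_equal(unname(out2[7, "b"]), 2 * col1[7], tolerance = 1e-4)
  expect_equal(out2[-7, ], m2[-7, ])   # observed cells untouched

  # idempotence
  out3 <- evf_impute(unclass(out2))
  expect_equal(out3, out2, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("eigenvector filtering beats column-mean imputation under
           correlation", {
  set.seed(11)
  wins <- replicate(200, {
    n <- 30
    p <- 5
    f <- rnorm(n)
    m <- sqrt(0.9) * matrix(f, n, p) + sqrt(0.1) * matrix(rnorm(n * p), n, p)
    rows <- sample(n, 4)
    cols <- sample(2:p, 4, replace = TRUE)
    idx <- cbind(rows, cols)
    truth <- m[idx]
    mg <- m
    mg[idx] <- NA
    filled <- evf_impute(mg)
    col_means <- colMeans(mg, na.rm = TRUE)
    mean(abs(filled[idx] - truth)) <
      mean(abs(col_means[cols] - truth))
  })
  expect_gte(mean(wins), 0.8)
})

test_that("imputation input contracts are enforced", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(NA, NA, NA, 4, 5))
  expect_error(evf_impute(m), "missing")
  expect_error(evf_impute(cbind(a = c(1, NA, 3), b = rep(NA_real_, 3))),
               "all values missing")
  expect_error(evf_impute(matrix(1:5, ncol = 1)), "2 indicator columns")
})

test_that("standardization matches the z-score definition", {
  set.seed(8)
  x <- rnorm(30, mean = 10, sd = 2)
  bl <- make_baseline(seq_along(x), x)
  expect_equal(standardize(bl$mu, bl), 0)
  expect_equal(standardize(bl$mu + 2 * bl$sigma, bl), 2)
  z <- standardize(x, bl)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
})

test_that("standardization is affine invariant", {
  set.seed(12)
  x <- rlnorm(25)
  years <- seq_along(x)
  z1 <- standardize(x, make_baseline(years, x))
  for (i in 1:5) {
    a <- runif(1, 0.1, 10)
    b <- rnorm(1, 0, 5)
    y <- a * x + b
    expect_equal(standardize(y, make_baseline(years, y)), z1,
                 tolerance = 1e-9)
  }
})

test_that("baseline construction enforces its contracts", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_error(make_baseline(1:8, x, window = c(1, 3)), "minimum")
  expect_error(make_baseline(1:8, rep(2, 8)), "positive")
  bl <- make_baseline(1:8, x, window = c(2, 7), kind = "refcon_chl")
  expect_equal(bl$n_years, 6L)
  expect_equal(bl$mu, mean(2:7))
})

test_that("cv_percent follows the n-1 definition", {
  expect_equal(cv_percent(c(10, 10, 10)), 0)
  expect_equal(cv_percent(c(8, 12)), 100 * 2 * sqrt(2) / 10)
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("Box-Cox transformation reduces the CV of lognormal series", {
  set.seed(303)
  reduced <- replicate(200, {
    x <- rlnorm(30, sdlog = 1)
    fit <- boxcox_fit(x)
    cv_raw <- cv_percent(x)
    shifted <- fit$transformed - min(fit$transformed) + 1  # positive scale
    cv_percent(shifted) < cv_raw
  })
  expect_gte(mean(reduced), 0.9)
})

test_that("preprocess_indicators standardizes, imputes and reports
           baselines", {
  sim <- generate_dataset(generator_config(n_years = 20, seed = 31,
                                           missing_year_prob = 0))
  ind <- compute_indicators(sim$samples, sim$traits)
  # punch one year out of one indicator to exercise the imputation path
  ind$value[ind$indicator == "TZB" & ind$year == 1990] <- NA
  zs <- preprocess_indicators(ind)
  expect_setequal(unique(zs$baseline_kind), "entire")
  stats <- zs |>
    dplyr::summarise(m = mean(z), s = sd(z), .by = "indicator")
  expect_equal(stats$m, rep(0, 9), tolerance = 1e-9)
  expect_equal(stats$s, rep(1, 9), tolerance = 1e-9)
  expect_true(zs$imputed[zs$indicator == "TZB" & zs$year == 1990])
  expect_false(is.na(zs$z[zs$indicator == "TZB" & zs$year == 1990]))
  bl <- attr(zs, "baselines")
  expect_equal(nrow(bl), 9)
  expect_true(all(bl$sigma > 0))
})

test_that("reference-window baselines centre the window, not the series", {
  sim <- generate_dataset(generator_config(n_years = 20, seed = 32,
                                           shift_year = 12,
                                           shift_factor = 0.4,
                                           missing_year_prob = 0))
  ind <- compute_indicators(sim$samples, sim$traits)
  rc <- tibble::tibble(dataset = "SYN1", kind = "refcon_fish",
                       start_year = 1980, end_year = 1990)
  zs <- preprocess_indicators(ind, refcon = rc)
  expect_setequal(unique(zs$baseline_kind), "refcon_fish")
  win <- zs |>
    dplyr::filter(year <= 1990) |>
    dplyr::summarise(m = mean(z), .by = "indicator")
  expect_equal(win$m, rep(0, 9), tolerance = 1e-9)
  # post-shift TZB is clearly below the reference baseline
  post <- zs$z[zs$indicator == "TZB" & zs$year >= 1993]
  expect_lt(mean(post), -1)
})

test_that("z-scores of transformed generator output look normal", {
  ok <- vapply(1:8, function(s) {
    sim <- generate_dataset(generator_config(n_years = 25, seed = 400 + s,
                                             missing_year_prob = 0))
    ind <- compute_indicators(sim$samples, sim$traits)
    zs <- preprocess_indicators(ind)
    z <- zs$z[zs$indicator == "TZB"]
    ks_normality(z, n_sim = 500)$p > 0.2
  }, logical(1))
  expect_gt(mean(ok), 0.5)
})
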