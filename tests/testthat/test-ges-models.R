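test_that("the intercept-only model reproduces the log-odds of prevalence", {
  d <- tibble::tibble(in_control = c(rep(1, 7), rep(0, 3)))
  fit <- fit_logistic(d)
  expect_equal(unname(fit$beta), log(7 / 3), tolerance = 1e-6)
})

test_that("model summaries satisfy their defining identities", {
  set.seed(90)
  n <- 60
  d <- tibble::tibble(MeanSize = rnorm(n), TZA = rnorm(n))
  d$in_control <- rbinom(n, 1, plogis(0.5 + d$MeanSize))
  fit <- fit_logistic(d, c("MeanSize", "TZA"))
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik, tolerance = 1e-6)
  expect_equal(unname(fit$wald), unname((fit$beta / fit$se)^2),
               tolerance = 1e-6)
  td <- tidy(fit)
  expect_equal(td$odds.ratio, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$aic, fit$aic)
  expect_gt(gl$pearson_chi2, 0)
})

test_that("flipping the response coding negates all coefficients", {
  set.seed(91)
  n <- 50
  d <- tibble::tibble(MeanSize = rnorm(n), TZB = rnorm(n))
  d$in_control <- rbinom(n, 1, plogis(d$MeanSize - 0.3 * d$TZB))
  f1 <- fit_logistic(d, c("MeanSize", "TZB"))
  d2 <- dplyr::mutate(d, in_control = 1 - in_control)
  f2 <- fit_logistic(d2, c("MeanSize", "TZB"))
  expect_equal(unname(f1$beta), -unname(f2$beta), tolerance = 1e-8)
})

test_that("the IRLS fit matches a direct likelihood maximizer", {
  set.seed(92)
  for (i in 1:10) {
    n <- 80
    x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(n, 1, plogis(0.3 + x %*% c(1, -0.7)))
    d <- tibble::tibble(a = x[, 1], b = x[, 2], in_control = y)
    fit <- fit_logistic(d, c("a", "b"))
    oracle <- oracle_logistic(x, y)
    expect_equal(unname(fit$beta), oracle, tolerance = 1e-4)
  }
})

test_that("complete separation is flagged, not silent", {
  d <- tibble::tibble(x = c(-(5:1), 1:5),
                      in_control = c(rep(0, 5), rep(1, 5)))
  expect_warning(fit <- fit_logistic(d, "x"), "separation")
  expect_true(fit$separation)
})

test_that("class balance and predictor checks are enforced", {
  d <- tibble::tibble(x = rnorm(10), in_control = c(1, 1, rep(0, 8)))
  expect_error(fit_logistic(d, "x"), "3 years")
  d2 <- tibble::tibble(x = rnorm(10),
                       in_control = rep(c(0, 1), 5))
  expect_error(fit_logistic(d2, "y"), "not in data")
})

test_that("variance inflation follows 1 / (1 - R2)", {
  n <- 40
  t_ <- seq_len(n)
  x1 <- scale(sin(t_))[, 1]
  resid <- scale(stats::resid(lm(cos(t_) ~ x1)))[, 1]
  # orthogonal pair: VIF = 1
  d <- tibble::tibble(a = x1, b = resid)
  expect_equal(unname(vif_scores(d, c("a", "b"))), c(1, 1),
               tolerance = 1e-9)
  # exact sample correlation 0.8: VIF = 1 / (1 - 0.64)
  d$c <- 0.8 * d$a + sqrt(1 - 0.64) * d$b
  v <- vif_scores(d, c("a", "c"))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-9)
  # duplicated predictor: infinite VIF
  d$dup <- d$a
  expect_true(is.infinite(suppressWarnings(vif_scores(d, c("a", "dup")))["a"]))
  expect_error(vif_scores(d, "a"), "at least 2")
})

test_that("AIC search screens collinear candidates and prefers parsimony", {
  set.seed(93)
  n <- 60
  d <- tibble::tibble(MeanSize = rnorm(n))
  d$TZB <- d$MeanSize + rnorm(n, sd = 0.2)   # heavily collinear pair
  d$CB <- rnorm(n)
  d$in_control <- rbinom(n, 1, plogis(1.5 * d$MeanSize))
  s <- aic_model_search(d, c("MeanSize", "TZB", "CB"))
  expect_lt(length(s$screened), 3)
  expect_true(length(s$dropped) >= 1)

  # the winner admits no simpler nested competitor within the AIC window
  win_terms <- s$winner$predictors
  rk <- s$ranking
  near <- rk[rk$delta_aic <= 2 & rk$n_terms < length(win_terms), ]
  if (nrow(near) > 0) {
    for (j in seq_len(nrow(near))) {
      simpler <- strsplit(near$predictors[j], " \\+ ")[[1]]
      simpler <- simpler[simpler != "(intercept)"]
      if (all(simpler %in% win_terms)) {
        lrt <- 2 * (s$winner$loglik - near$logLik[j])
        df <- length(win_terms) - length(simpler)
        expect_lte(pchisq(lrt, df, lower.tail = FALSE), 0.05)
      }
    }
  }
})

test_that("a strong single predictor is recovered by the search", {
  set.seed(94)
  hits <- replicate(40, {
    n <- 40
    d <- tibble::tibble(MeanSize = rnorm(n), TZA = rnorm(n), CB = rnorm(n))
    d$in_control <- rbinom(n, 1, plogis(1.5 * d$MeanSize))
    s <- tryCatch(aic_model_search(d, c("MeanSize", "TZA", "CB")),
                  error = function(e) NULL)
    !is.null(s) && "MeanSize" %in% s$winner$predictors
  })
  expect_gte(mean(hits), 0.7)
})

test_that("pure-noise predictors mostly collapse to the intercept model", {
  set.seed(95)
  nulls <- replicate(40, {
    n <- 40
    d <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    d$in_control <- rbinom(n, 1, 0.5)
    s <- tryCatch(aic_model_search(d, c("a", "b", "c")),
                  error = function(e) NULL)
    !is.null(s) && length(s$winner$predictors) == 0
  })
  expect_gte(mean(nulls), 0.6)
})

test_that("the dataset term enters as a categorical covariate", {
  set.seed(96)
  n <- 40
  d <- tibble::tibble(
    dataset = rep(c("A", "B"), each = n / 2),
    MeanSize = rnorm(n))
  d$in_control <- rbinom(n, 1, plogis(d$MeanSize +
                                        ifelse(d$dataset == "B", 1, -1)))
  fit <- fit_logistic(d, c("MeanSize", "dataset"))
  expect_true(any(grepl("dataset", names(fit$beta))))
})

test_that("classification metrics match a hand-built confusion table", {
  # perfectly separable fixture
  d <- tibble::tibble(x = c(-(5:1), 1:5),
                      in_control = c(rep(0, 5), rep(1, 5)))
  fit <- suppressWarnings(fit_logistic(d, "x"))
  m <- classification_metrics(fit)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$overall, 100)

  # intercept-only, 70% prevalence: everything predicted in-control
  d2 <- tibble::tibble(in_control = c(rep(1, 7), rep(0, 3)))
  m2 <- classification_metrics(fit_logistic(d2))
  expect_equal(m2$overall, 70)
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$specificity, 0)

  # general case equals a brute-force count
  set.seed(97)
  n <- 100
  d3 <- tibble::tibble(x = rnorm(n))
  d3$in_control <- rbinom(n, 1, plogis(d3$x))
  fit3 <- fit_logistic(d3, "x")
  m3 <- classification_metrics(fit3)
  pr <- as.integer(predict(fit3$fit, type = "response") >= 0.5)
  expect_equal(m3$overall, 100 * mean(pr == d3$in_control))
  expect_equal(m3$sensitivity,
               100 * mean(pr[d3$in_control == 1] == 1))
  expect_equal(m3$specificity,
               100 * mean(pr[d3$in_control == 0] == 0))
})

test_that("MSTS quadrants follow the two-dimensional GES definition", {
  combos <- tidyr::expand_grid(zs = c(-2, -0.5, 0, 0.5, 2),
                               zt = c(-2, -0.5, 0, 0.5, 2))
  res <- msts_classify(combos$zs, combos$zt, threshold = 0)
  want <- ifelse(combos$zs >= 0 & combos$zt >= 0, "green",
          ifelse(combos$zs < 0 & combos$zt >= 0, "orange_size_only",
          ifelse(combos$zs >= 0 & combos$zt < 0, "orange_stock_only",
                 "red")))
  expect_equal(as.character(res$status), want)

  # missing component -> undetermined status
  na_res <- msts_classify(c(NA, 1), c(1, NA))
  expect_true(all(is.na(na_res$status)))

  # monotone: raising z_size never moves the status away from green
  rank <- c(green = 0, orange_size_only = 1, orange_stock_only = 1, red = 2)
  set.seed(98)
  for (i in 1:50) {
    z1 <- rnorm(1); z2 <- rnorm(1); d <- runif(1, 0, 3)
    s_lo <- as.character(msts_classify(z1, z2)$status)
    s_hi <- as.character(msts_classify(z1 + d, z2)$status)
    expect_lte(rank[s_hi], rank[s_lo])
  }
  p <- autoplot(msts_classify(rnorm(10), rnorm(10)))
  expect_s3_class(p, "ggplot")
})

test_that("ges_model_frame joins labels to wide z-scores", {
  sim <- generate_dataset(generator_config(n_years = 20, seed = 99,
                                           shift_year = 11,
                                           shift_factor = 0.4,
                                           missing_year_prob = 0))
  rt <- make_refcon_truth(generator_config(n_years = 20, seed = 99,
                                           shift_year = 11,
                                           shift_factor = 0.4,
                                           missing_year_prob = 0),
                          sim$truth)
  res <- suppressMessages(assess_dataset(sim$samples, sim$traits,
                                         refcon = rt$window))
  zs_entire <- suppressMessages(
    preprocess_indicators(res$indicators))
  mf <- ges_model_frame(zs_entire, res$labels)
  expect_true(all(INDICATOR_LEVELS %in% names(mf)))
  expect_true(all(mf$in_control %in% 0:1))
  expect_equal(nrow(mf), 20)
})
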