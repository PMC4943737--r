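#' Assemble a model frame for GES prediction
#'
#' Joins whole-series z-scores (the predictors) with the in/out-of-control
#' year labels derived from a reference-condition CuSum assessment (the
#' response), one row per dataset x year.
#'
#' @param zscores A z-score tibble from [preprocess_indicators()] with a
#'   whole-series baseline.
#' @param labels Output of [classify_years_by_refcon()] (columns `dataset`,
#'   `year`, `status`).
#' @return A tibble with `dataset`, `year`, `in_control` (1 in-control / 0
#'   out-of-control) and one column per indicator.
#' @export
ges_model_frame <- function(zscores, labels) {
  wide <- zscores |>
    tidyr::pivot_wider(id_cols = c("dataset", "year"),
                       names_from = "indicator", values_from = "z")
  labels |>
    dplyr::mutate(in_control = as.integer(.data$status == "in_control")) |>
    dplyr::select("dataset", "year", "in_control") |>
    dplyr::inner_join(wide, by = c("dataset", "year"))
}

#' Fit a logistic GES-prediction model
#'
#' Standard binomial regression of the binary in-control label (1 =
#' in-control, 0 = out-of-control year) on indicator z-scores, fitted by
#' iteratively reweighted least squares.  The scaled deviance and Pearson
#' chi-square are reported for goodness of fit.  Complete separation is
#' detected and flagged (coefficients diverge); the fit is returned with a
#' warning rather than silently.
#'
#' @param data A model frame such as from [ges_model_frame()].
#' @param predictors Character vector of predictor columns (may include
#'   `"dataset"` as a categorical covariate); empty for an intercept-only
#'   model.
#' @param response Name of the 0/1 response column.
#' @return An object of class `ges_logistic` wrapping the `glm` fit, with
#'   coefficient table, AIC, log-likelihood, scaled deviance, Pearson
#'   chi-square and a `separation` flag.  Use [tidy()] and [glance()] to
#'   extract tables.
#' @export
fit_logistic <- function(data, predictors = character(0),
                         response = "in_control") {
  y <- data[[response]]
  if (is.null(y)) abort(paste0("no response column ", response))
  if (sum(y == 1) < 3 || sum(y == 0) < 3) {
    abort("need at least 3 years in each class")
  }
  miss <- setdiff(predictors, names(data))
  if (length(miss) > 0) {
    abort(paste0("predictor(s) not in data: ", paste(miss, collapse = ", ")))
  }
  rhs <- if (length(predictors) == 0) "1" else
    paste(paste0("`", predictors, "`"), collapse = " + ")
  fml <- as.formula(paste(response, "~", rhs))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = data,
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    warn("complete or quasi-complete separation: coefficients diverge")
  }
  sm <- summary(fit)$coefficients
  structure(list(
    fit = fit,
    predictors = predictors,
    response = response,
    beta = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    wald = (sm[, "Estimate"] / sm[, "Std. Error"])^2,
    p = sm[, "Pr(>|z|)"],
    aic = AIC(fit),
    loglik = as.numeric(logLik(fit)),
    n_params = attr(logLik(fit), "df"),
    scaled_deviance = fit$deviance,
    pearson_chi2 = sum(residuals(fit, type = "pearson")^2),
    n = length(fit$y),
    separation = separation
  ), class = "ges_logistic")
}

#' @export
print.ges_logistic <- function(x, ...) {
  cat("<ges_logistic>",
      if (length(x$predictors) == 0) "(intercept only)"
      else paste(x$predictors, collapse = " + "),
      "\n  AIC =", signif(x$aic, 6), " logLik =", signif(x$loglik, 6),
      if (x$separation) " [separation]" else "", "\n")
  invisible(x)
}

#' @export
#' @importFrom stats residuals
#' @method tidy ges_logistic
tidy.ges_logistic <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 std.error = unname(x$se), statistic = unname(x$wald),
                 p.value = unname(x$p),
                 odds.ratio = exp(unname(x$beta)))
}

#' @export
#' @method glance ges_logistic
glance.ges_logistic <- function(x, ...) {
  tibble::tibble(aic = x$aic, logLik = x$loglik, n_params = x$n_params,
                 scaled_deviance = x$scaled_deviance,
                 pearson_chi2 = x$pearson_chi2, n = x$n,
                 separation = x$separation)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor
#' `j` on the remaining predictors; used to screen candidate indicator
#' sets for multicollinearity before model search (predictors with VIF of
#' 3 or more are dropped by default, well below the conventional cut-off
#' of 10).  Perfect collinearity is reported as `Inf`.
#'
#' @param data Data frame holding the predictors.
#' @param predictors At least two predictor column names.
#' @return Named numeric vector of VIFs.
#' @export
vif_scores <- function(data, predictors) {
  if (length(predictors) < 2) abort("need at least 2 predictors")
  x <- data[predictors]
  if (nrow(x) <= length(predictors) + 1) {
    abort("need more observations than predictors + 1")
  }
  vapply(predictors, function(p) {
    fit <- lm(as.formula(paste0("`", p, "` ~ .")), data = x)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Exhaustive AIC model search with a parsimony rule
#'
#' Screens the candidate indicators by variance inflation (dropping the
#' worst predictor until all VIF are below `vif_cutoff`), fits every
#' subset of up to `max_terms` predictors (including the intercept-only
#' model), and ranks the fits by AIC.  A simpler model nested in the AIC
#' winner whose likelihood-ratio test against the winner is not
#' significant (`p > lrt_alpha`) and whose AIC is within `aic_window` of
#' the winner is preferred over the winner, mirroring the convention that
#' near-equivalent models should be resolved in favour of parsimony.
#'
#' @param data Model frame ([ges_model_frame()]).
#' @param candidates Candidate predictor columns.
#' @param response 0/1 response column name.
#' @param max_terms Largest subset size.
#' @param vif_cutoff Screening threshold (`Inf` disables screening).
#' @param aic_window "Similar AIC" window for the parsimony rule.
#' @param lrt_alpha Significance level of the likelihood-ratio test.
#' @return A list of class `ges_model_search`: `winner` (a `ges_logistic`),
#'   `ranking` (tibble with `predictors`, `n_terms`, `aic`, `delta_aic`,
#'   `logLik`), `screened` (candidates surviving VIF screening),
#'   `dropped` (screened out).
#' @export
aic_model_search <- function(data, candidates, response = "in_control",
                             max_terms = 3, vif_cutoff = 3,
                             aic_window = 2, lrt_alpha = 0.05) {
  screened <- candidates
  dropped <- character(0)
  while (length(screened) >= 2) {
    v <- vif_scores(data, screened)
    if (max(v) < vif_cutoff) break
    worst <- names(v)[which.max(v)]
    screened <- setdiff(screened, worst)
    dropped <- c(dropped, worst)
  }
  subsets <- list(character(0))
  for (sz in seq_len(min(max_terms, length(screened)))) {
    subsets <- c(subsets,
                 apply(combn(screened, sz), 2, identity, simplify = FALSE))
  }
  fits <- purrr::map(subsets, function(ps) {
    tryCatch(suppressWarnings(fit_logistic(data, ps, response = response)),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) abort("no candidate model converged")
  fits <- fits[ok]
  subsets <- subsets[ok]
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  lls <- vapply(fits, function(f) f$loglik, numeric(1))
  sizes <- lengths(subsets)
  ord <- order(aics)
  best_i <- ord[1]
  winner_i <- best_i
  near <- which(aics - aics[best_i] <= aic_window & sizes < sizes[best_i])
  near <- near[vapply(near, function(i) {
    all(subsets[[i]] %in% subsets[[best_i]])
  }, logical(1))]
  for (i in near[order(sizes[near])]) {
    lrt <- 2 * (lls[best_i] - lls[i])
    df <- sizes[best_i] - sizes[i]
    p <- pchisq(lrt, df, lower.tail = FALSE)
    if (p > lrt_alpha) {
      winner_i <- i
      break
    }
  }
  ranking <- tibble::tibble(
    predictors = vapply(subsets, function(p) {
      if (length(p) == 0) "(intercept)" else paste(p, collapse = " + ")
    }, character(1)),
    n_terms = sizes,
    aic = aics,
    delta_aic = aics - min(aics),
    logLik = lls
  )[ord, ]
  structure(list(winner = fits[[winner_i]], ranking = ranking,
                 screened = screened, dropped = dropped),
            class = "ges_model_search")
}

#' @export
print.ges_model_search <- function(x, ...) {
  cat("<ges_model_search> winner:",
      if (length(x$winner$predictors) == 0) "(intercept only)"
      else paste(x$winner$predictors, collapse = " + "), "\n")
  print(head(x$ranking, 5))
  invisible(x)
}

#' In-sample classification accuracy of a GES model
#'
#' Confusion-table summary at a probability cutoff: sensitivity is the
#' percentage of in-control years predicted in-control, specificity the
#' percentage of out-of-control years predicted out-of-control, plus the
#' overall percentage correct and the odds ratio of the 2x2 confusion
#' table.  Evaluation is in-sample (no held-out years).
#'
#' @param model A `ges_logistic` fit.
#' @param cutoff Probability cutoff (predicted in-control when the fitted
#'   probability is at least `cutoff`).
#' @return A one-row tibble `cutoff`, `sensitivity`, `specificity`,
#'   `overall` (percentages), `odds_ratio`.
#' @export
classification_metrics <- function(model, cutoff = 0.5) {
  y <- model$fit$y
  pred <- as.integer(fitted(model$fit) >= cutoff)
  sens <- if (sum(y == 1) == 0) NA_real_ else
    100 * mean(pred[y == 1] == 1)
  spec <- if (sum(y == 0) == 0) NA_real_ else
    100 * mean(pred[y == 0] == 0)
  a <- sum(y == 1 & pred == 1)
  b <- sum(y == 1 & pred == 0)
  c_ <- sum(y == 0 & pred == 1)
  d <- sum(y == 0 & pred == 0)
  or <- if (b * c_ == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c_)
  tibble::tibble(cutoff = cutoff, sensitivity = sens, specificity = spec,
                 overall = 100 * mean(pred == y), odds_ratio = or)
}

#' Two-dimensional mean-size / total-stock (MSTS) status
#'
#' Classifies community state from the z-scores of MeanSize and of total
#' stock (TZA or TZB) against a reference baseline.  Both components at or
#' above `threshold` is in-GES (`green`); both below is sub-GES (`red`);
#' the orange classes mark states where exactly one component fails --
#' `orange_size_only` when MeanSize alone is below threshold,
#' `orange_stock_only` when the stock alone is.  The default threshold of
#' 0 z-units is the baseline mean; "adequate" is read as not falling below
#' the reference-period average.
#'
#' @param z_size MeanSize z-scores (reference-condition baseline).
#' @param z_stock Stock z-scores (TZA or TZB, same baseline).
#' @param threshold Boundary in z units.
#' @param stock_metric Which stock metric `z_stock` is.
#' @return A tibble of class `msts_status` with `z_size`, `z_stock`,
#'   `stock_metric`, `threshold`, `status` (factor `green`,
#'   `orange_size_only`, `orange_stock_only`, `red`; `NA` when a component
#'   is missing).
#' @export
#' @examples
#' msts_classify(z_size = c(1, -1, -1), z_stock = c(1, 1, -2))
msts_classify <- function(z_size, z_stock, threshold = 0,
                          stock_metric = c("TZB", "TZA")) {
  stock_metric <- match.arg(stock_metric)
  stopifnot(length(z_size) == length(z_stock))
  size_ok <- z_size >= threshold
  stock_ok <- z_stock >= threshold
  status <- dplyr::case_when(
    is.na(size_ok) | is.na(stock_ok) ~ NA_character_,
    size_ok & stock_ok ~ "green",
    !size_ok & stock_ok ~ "orange_size_only",
    size_ok & !stock_ok ~ "orange_stock_only",
    TRUE ~ "red"
  )
  out <- tibble::tibble(
    z_size = z_size, z_stock = z_stock, stock_metric = stock_metric,
    threshold = threshold,
    status = factor(status, levels = c("green", "orange_size_only",
                                       "orange_stock_only", "red"))
  )
  class(out) <- c("msts_status", class(out))
  out
}

#' Plot the MSTS quadrant diagram
#'
#' @param object An [msts_classify()] tibble.
#' @param ... Unused.
#' @return A ggplot object: stock vs size z-scores with the four status
#'   quadrants shaded.
#' @export
#' @method autoplot msts_status
autoplot.msts_status <- function(object, ...) {
  thr <- object$threshold[1]
  lim <- max(abs(c(object$z_size, object$z_stock, thr)), na.rm = TRUE) * 1.2
  quad <- tibble::tibble(
    xmin = c(thr, -lim, thr, -lim), xmax = c(lim, thr, lim, thr),
    ymin = c(thr, thr, -lim, -lim), ymax = c(lim, lim, thr, thr),
    fill = c("darkgreen", "orange", "orange", "firebrick")
  )
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(data = quad,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax),
                       fill = quad$fill, alpha = 0.25) +
    ggplot2::geom_point(ggplot2::aes(x = .data$z_size, y = .data$z_stock)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "MeanSize (z)",
                  y = paste0("Total stock, ", object$stock_metric[1],
                             " (z)")) +
    ggplot2::theme_minimal()
}
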