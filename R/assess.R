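#' Full status assessment from samples to year labels
#'
#' Chains the whole pipeline: indicator computation
#' ([compute_indicators()]), Box-Cox transformation, gap imputation and
#' baselining ([preprocess_indicators()]), combined Shewhart/CuSum charts
#' ([control_chart()]), out-of-control period extraction and -- when a
#' reference window is supplied -- per-year in/out-of-control labels
#' ([classify_years_by_refcon()]).
#'
#' @param samples Sample tibble ([read_samples()] or
#'   [generate_dataset()]).
#' @param traits Trait registry.
#' @param refcon Optional reference-window tibble (single kind); `NULL`
#'   uses whole-series baselines.
#' @param params Control-chart parameters ([cusum_params()]).
#' @param months Summer months.
#' @param min_run Minimum run length for reported out-of-control periods.
#' @param ... Passed to [compute_indicators()].
#' @return A list with `indicators`, `zscores`, `chart`, `periods` and
#'   (with a reference window) `labels`.
#' @export
#' @examples
#' sim <- generate_dataset(generator_config(n_years = 20, seed = 7))
#' res <- assess_dataset(sim$samples, sim$traits)
#' res$periods
assess_dataset <- function(samples, traits, refcon = NULL,
                           params = cusum_params(), months = 6:9,
                           min_run = 4, ...) {
  ind <- compute_indicators(samples, traits, months = months, ...)
  zs <- preprocess_indicators(ind, refcon = refcon)
  chart <- control_chart(zs, params = params)
  out <- list(indicators = ind, zscores = zs, chart = chart,
              periods = detect_out_of_control_periods(chart,
                                                      min_run = min_run))
  if (!is.null(refcon)) out$labels <- classify_years_by_refcon(chart)
  out
}
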