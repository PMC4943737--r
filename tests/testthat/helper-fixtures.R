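# In-code fixtures shared across the suite.

# A minimal trait registry covering the common functional groups.
fixture_traits <- function() {
  tibble::tibble(
    taxon = c("Acartia", "Cyclops", "Bosmina", "Cercopagis", "Synchaeta",
              "Fritillaria", "Microsetella"),
    major_group = c("copepod", "copepod", "cladoceran", "cladoceran",
                    "rotifer", "appendicularian", "harpacticoid"),
    is_calanoid = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_predatory_cladoceran = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                                FALSE),
    is_microphagous = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
}

# Annual per-taxon means ready for compute_group_aggregates(): biomass in
# mg WW m^-3 for one dataset-year.
fixture_annual <- function(copepod = 50, herb_clad = 30, rotifer = 10,
                           pred_clad = 5, year = 2000) {
  tibble::tibble(
    dataset = "D1", year = year,
    taxon = c("Acartia", "Bosmina", "Synchaeta", "Cercopagis"),
    stage = "adult",
    biomass = c(copepod, herb_clad, rotifer, pred_clad),
    abundance = c(copepod, herb_clad, rotifer, pred_clad) * 100
  )
}

# Write a samples CSV and return its path.
write_samples_csv <- function(df, path = withr::local_tempfile(
                                fileext = ".csv",
                                .local_envir = parent.frame())) {
  readr::write_csv(df, path)
  path
}

# A tiny valid samples table.
fixture_samples_df <- function() {
  tibble::tibble(
    dataset = "D1", station = "S1",
    date = c("2000-06-10", "2000-07-10", "2000-08-10"),
    taxon = "Acartia", stage = "adult",
    abundance = c(1000, 2000, 1500), ind_mass = 5,
    biomass = NA_real_
  )
}

# Direct, independently coded DI-CuSum recursion used as the oracle.
oracle_cusum <- function(z, k) {
  sp <- Reduce(function(s, zi) max(0, s + zi - k), z, accumulate = TRUE,
               init = 0)[-1]
  sm <- Reduce(function(s, zi) min(0, s + zi + k), z, accumulate = TRUE,
               init = 0)[-1]
  list(s_plus = sp, s_minus = sm)
}

# Simulate the run length to first two-sided decision-interval alarm.
cusum_run_length <- function(k = 0.5, h = 5, shift = 0, max_n = 1e5) {
  sp <- sm <- 0
  for (i in seq_len(max_n)) {
    z <- rnorm(1, mean = shift)
    sp <- max(0, sp + z - k)
    sm <- min(0, sm + z + k)
    if (sp > h || sm < -h) return(i)
  }
  max_n
}

# Shifted multivariate fixture for breakpoint tests: `n` years, mean
# jumps by `delta` from year `shift_at` on, noise sd `sd`.
shift_matrix <- function(n = 20, shift_at = 11, delta = 3, sd = 0.5,
                         p = 2) {
  mu <- rep(c(0, delta), c(shift_at - 1, n - shift_at + 1))
  matrix(rnorm(n * p, mean = mu, sd = sd), n, p)
}

# Brute-force best two-group split: the boundary maximizing between-group
# separation (minimizing pooled within-group SS).
best_split_year <- function(m) {
  n <- nrow(m)
  ssw <- vapply(2:n, function(b) {
    a <- m[seq_len(b - 1), , drop = FALSE]
    c_ <- m[b:n, , drop = FALSE]
    sum(scale(a, scale = FALSE)^2) + sum(scale(c_, scale = FALSE)^2)
  }, numeric(1))
  (2:n)[which.min(ssw)]
}

# Direct log-likelihood maximizer for logistic regression (oracle).
oracle_logistic <- function(x, y) {
  nll <- function(beta) {
    eta <- drop(cbind(1, x) %*% beta)
    -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  fit <- optim(rep(0, ncol(x) + 1), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  fit$par
}
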