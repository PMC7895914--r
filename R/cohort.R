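#' Synthetic patient cohorts for the coarsening pipeline
#'
#' The empirical use case of the model is a cohort of young children
#' hospitalized with an RSV respiratory infection, a minority of whom also
#' have bacterial pneumonia; a classifier's output gives each patient a
#' posterior probability of bacterial co-infection, and the smoothed
#' distribution of these posteriors is the signal distribution fed to the
#' coarsening analysis. Such clinical data cannot be redistributed, so
#' this module generates synthetic cohorts with the same pipeline shape:
#' true posteriors are drawn from a right-skewed beta family whose mean is
#' matched to the cohort prevalence, and bacterial/viral labels are drawn
#' `Bernoulli(p)` per patient, which makes the posteriors calibrated by
#' construction.
#'
#' @param n Cohort size.
#' @param prevalence Probability of bacterial co-infection (the mean of
#'   the generated posteriors); defaults mirror a cohort of 1202 children
#'   with 235 bacterial cases.
#' @param shape1 First beta shape parameter of the posterior family;
#'   `shape2` is solved from the mean constraint
#'   `shape2 = shape1 * (1 - prevalence) / prevalence`. The default 0.8
#'   gives a right-skewed density concentrated at low probabilities.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 1202L, prevalence = 235 / 1202,
                          shape1 = 0.8, seed = 1L) {
  stopifnot(n >= 1, shape1 > 0)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 shape1 = shape1,
                 shape2 = shape1 * (1 - prevalence) / prevalence,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> n=%d prevalence=%.4f posterior family Beta(%.3g, %.3g) seed=%d\n",
    x$n, x$prevalence, x$shape1, x$shape2, x$seed))
  invisible(x)
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` true posteriors from the configured beta family (mean equal
#' to the prevalence by construction) and a bacterial/viral label per
#' patient as `Bernoulli(p)`.
#'
#' @param config A [cohort_config] object.
#' @return data.frame with columns `id`, `p` (true posterior) and `label`
#'   (`"B"` bacterial, `"N"` non-bacterial).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  p <- stats::rbeta(config$n, config$shape1, config$shape2)
  # beta draws can underflow to exactly 0 or 1 for extreme shapes
  eps <- .Machine$double.eps
  p <- pmin(pmax(p, eps), 1 - eps)
  label <- ifelse(stats::runif(config$n) < p, "B", "N")
  data.frame(id = seq_len(config$n), p = p, label = label)
}

#' Estimate the signal distribution from a cohort
#'
#' Smooths the cohort's posterior probabilities into a density on
#' `(0, 1)`: a logit-scale kernel density estimate with a small additive
#' floor constant, renormalized (see [signal_empirical()]).
#'
#' @param records A cohort data.frame from [generate_cohort()] (or any
#'   data.frame with a `p` column), or a bare numeric vector of
#'   posteriors.
#' @param floor_const Additive density floor.
#' @param bandwidth Logit-scale bandwidth, `NULL` for Silverman's rule.
#' @return A [signal_dist] of family `"empirical"`.
#' @export
estimate_signal_density <- function(records, floor_const = 1e-4,
                                    bandwidth = NULL) {
  p <- if (is.data.frame(records)) records$p else as.numeric(records)
  signal_empirical(p, floor_const = floor_const, bandwidth = bandwidth)
}

#' End-to-end synthetic cohort pipeline
#'
#' Runs generate -> smooth -> coarsening profile -> minimal stable
#' threshold, mirroring the analysis one would perform on a real cohort of
#' classifier posteriors. The analytic minimal stable threshold of the
#' generating beta family is included for parameter-recovery checks.
#'
#' @param config A [cohort_config] object.
#' @param grid_n Number of thresholds in the profile grid.
#' @param tol Tolerance of [min_stable_threshold()].
#' @return An object of class `cohort_report`: list with `cohort`,
#'   `dist` (estimated signal), `profile`, `min_T` (estimated minimal
#'   stable threshold, `NA` if none), `min_T_true` (analytic value for the
#'   generating family) and `E_p` (estimated prior).
#' @export
cohort_pipeline <- function(config, grid_n = 999L, tol = 1e-6) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- generate_cohort(config)
  dist <- estimate_signal_density(cohort)
  grid <- seq(1 / (grid_n + 1), grid_n / (grid_n + 1), length.out = grid_n)
  profile <- threshold_profile(dist, grid)
  min_T <- min_stable_threshold(dist, tol = tol)
  gen <- signal_beta(config$shape1, config$shape2)
  structure(list(cohort = cohort, dist = dist, profile = profile,
                 min_T = min_T,
                 min_T_true = min_stable_threshold(gen, tol = tol),
                 E_p = dist$mean, config = config),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  print(x$config)
  cat(sprintf("  estimated E(p): %.4f (cohort B-fraction %.4f)\n",
              x$E_p, mean(x$cohort$label == "B")))
  cat("  minimal stable threshold:",
      if (is.na(x$min_T)) "none" else format(x$min_T, digits = 4),
      "| analytic (generating family):",
      if (is.na(x$min_T_true)) "none" else format(x$min_T_true, digits = 4),
      "\n")
  invisible(x)
}
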