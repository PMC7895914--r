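#' Dichotomize a continuous infection signal at a threshold
#'
#' Replaces the continuous signal with a two-valued signal: "high" when the
#' patient's posterior exceeds the threshold `T`, "low" otherwise. The high
#' signal appears with probability `q_H = 1 - F(T)` and induces the
#' posterior `p_H`, the conditional mean of `p` above `T`; symmetrically
#' for the low signal.
#'
#' @param dist A [signal_dist] object.
#' @param threshold Coarsening threshold `T`, with `0 < F(T) < 1` so that
#'   both signals occur with positive probability.
#' @return An object of class `coarse_signal`: a list with elements
#'   `threshold`, `q_H`, `q_L`, `p_H`, `p_L` and `h = p_H - p_L`.
#' @examples
#' coarsen(signal_uniform(), 0.5)  # q_H = 0.5, p_H = 0.75, p_L = 0.25
#' @export
coarsen <- function(dist, threshold) {
  stopifnot(inherits(dist, "signal_dist"), length(threshold) == 1L)
  q <- coarse_quantities(dist, threshold)
  if (is.na(q$p_H[1]))
    stop("degenerate threshold: both signals must occur with positive ",
         "probability (0 < F(T) < 1)", call. = FALSE)
  structure(c(list(threshold = threshold), q, list(h = q$p_H - q$p_L)),
            class = "coarse_signal")
}

# tail-stable computation of (q_H, q_L, p_H, p_L); degenerate thresholds
# yield NA posteriors
coarse_quantities <- function(dist, threshold) {
  q_H <- signal_sf(dist, threshold)
  q_L <- signal_cdf(dist, threshold)
  pe_hi <- partial_mean(dist, threshold)
  pe_lo <- partial_mean_lower(dist, threshold)
  bad <- q_H <= 0 | q_L <= 0
  p_H <- ifelse(bad, NA_real_, pe_hi / q_H)
  p_L <- ifelse(bad, NA_real_, pe_lo / q_L)
  list(q_H = q_H, q_L = q_L, p_H = p_H, p_L = p_L)
}

#' @export
print.coarse_signal <- function(x, ...) {
  cat("<coarse_signal> T =", format(x$threshold, digits = 6), "\n")
  cat(sprintf("  high: q_H = %.6f, p_H = %.6f\n", x$q_H, x$p_H))
  cat(sprintf("  low:  q_L = %.6f, p_L = %.6f\n", x$q_L, x$p_L))
  cat(sprintf("  h = p_H - p_L = %.6f\n", x$h))
  invisible(x)
}

#' Stability gap of the coarsened treat-high-only policy
#'
#' The policy "treat only patients with a high signal at every
#' effectiveness state" is a Markov perfect equilibrium of the coarsened
#' game exactly when `p_H - p_L >= E(p)`: the posterior separation induced
#' by the dichotomous signal must be at least the prior probability of
#' bacterial infection. This function returns the signed slack
#' `h(T) - E(p)`, where `h(T) = p_H - p_L`; the policy is stable iff the
#' gap is nonnegative.
#'
#' @param dist A [signal_dist] object.
#' @param threshold Vector of coarsening thresholds with `0 < F(T) < 1`.
#' @return Numeric vector of gaps, one per threshold.
#' @export
stability_gap <- function(dist, threshold) {
  stopifnot(inherits(dist, "signal_dist"))
  q <- coarse_quantities(dist, threshold)
  if (anyNA(q$p_H))
    stop("degenerate threshold: 0 < F(T) < 1 required", call. = FALSE)
  q$p_H - q$p_L - dist$mean
}

#' Minimal stable coarsening threshold
#'
#' Locates the infimum of the set of thresholds `T` for which the
#' stability condition `p_H - p_L >= E(p)` holds (within `-tol`), by a
#' grid scan of step `step` over `(0, support_max)` followed by bisection
#' refinement to absolute tolerance `tol`. Returns `NA` when no threshold
#' on the grid satisfies the condition.
#'
#' @param dist A [signal_dist] object.
#' @param tol Positive refinement tolerance (also the slack allowed on the
#'   weak inequality).
#' @param step Grid step of the initial scan.
#' @return The infimum threshold (possibly ~0), or `NA_real_` if the
#'   stable set is empty on the grid.
#' @export
min_stable_threshold <- function(dist, tol = 1e-6, step = 1e-3) {
  stopifnot(inherits(dist, "signal_dist"), tol > 0, step > 0)
  smax <- dist$support_max
  grid <- seq(step, smax - step, by = step)
  grid <- grid[signal_cdf(dist, grid) > 0 & signal_sf(dist, grid) > 0]
  if (!length(grid)) return(NA_real_)
  q <- coarse_quantities(dist, grid)
  stable <- (q$p_H - q$p_L - dist$mean) >= -tol
  if (!any(stable)) return(NA_real_)
  hi <- grid[which(stable)[1]]
  lo <- 0
  is_stable <- function(T) {
    qq <- coarse_quantities(dist, T)
    if (is.na(qq$p_H)) return(NA)
    (qq$p_H - qq$p_L - dist$mean) >= -tol
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    s <- is_stable(mid)
    if (is.na(s)) lo <- mid          # F(mid) still 0: move up
    else if (s) hi <- mid else lo <- mid
  }
  hi
}

#' Coarsening profile over a grid of thresholds
#'
#' Evaluates the dichotomization at each threshold of a grid and reports
#' the induced signal probabilities and posteriors, the posterior
#' separation `h`, the prior `E(p)`, the stability gap `h - E(p)` and a
#' stability flag. This is the standard visual diagnostic: plotting `h`
#' against `E(p)` over `T` shows at a glance which thresholds support the
#' treat-high-only equilibrium.
#'
#' @param dist A [signal_dist] object.
#' @param grid Thresholds strictly inside `(0, support_max)`; default a
#'   999-point grid.
#' @param tol Slack on the weak stability inequality for the flag.
#' @return A data.frame with columns `T, q_H, p_H, p_L, h, E_p, gap,
#'   stable`.
#' @export
threshold_profile <- function(dist, grid = NULL, tol = 1e-9) {
  stopifnot(inherits(dist, "signal_dist"))
  smax <- dist$support_max
  if (is.null(grid))
    grid <- seq(smax / 1000, smax * 999 / 1000, length.out = 999L)
  q <- coarse_quantities(dist, grid)
  if (any(grid <= 0 | grid >= smax) || anyNA(q$p_H))
    stop("profile grid must lie strictly inside (0, support_max) with ",
         "0 < F(T) < 1", call. = FALSE)
  gap <- q$p_H - q$p_L - dist$mean
  data.frame(T = grid, q_H = q$q_H, p_H = q$p_H, p_L = q$p_L,
             h = q$p_H - q$p_L, E_p = dist$mean, gap = gap,
             stable = gap >= -tol)
}
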