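#' Signal distributions for the posterior probability of bacterial infection
#'
#' A `signal_dist` object represents the information system of the
#' prescribing problem: the distribution, across patients, of the posterior
#' probability `p` that a patient's infection is bacterial. Three families
#' are supported:
#'
#' * [signal_beta()] -- a beta density on `[0, 1]`;
#' * [signal_uniform()] -- a uniform density on a sub-interval `(lo, hi)`;
#' * [signal_empirical()] -- a smoothed density estimated from a sample of
#'   posterior probabilities.
#'
#' Every `signal_dist` exposes a density, a CDF, a mean (the prior
#' probability of bacterial infection, `P(B) = E(p)`), a partial
#' expectation ("the expected posterior mass above a threshold",
#' [partial_mean()]), a random sampler, and `support_max`, the supremum of
#' the support. Threshold decision rules downstream are restricted to
#' `[0, support_max]`.
#'
#' @name signal_dist
#' @keywords internal
NULL

new_signal_dist <- function(family, params, support_max, mean, extra = list()) {
  structure(
    c(list(family = family, params = params,
           support_max = support_max, mean = mean), extra),
    class = "signal_dist"
  )
}

#' Beta-distributed infection signal
#'
#' @param shape1,shape2 Positive beta shape parameters.
#' @return A `signal_dist` object.
#' @examples
#' d <- signal_beta(2, 8)
#' mean(d)                # 0.2
#' partial_mean(d, 0.3)   # expected posterior mass above 0.3
#' @export
signal_beta <- function(shape1, shape2) {
  stopifnot(is.numeric(shape1), is.numeric(shape2),
            length(shape1) == 1L, length(shape2) == 1L)
  if (!is.finite(shape1) || !is.finite(shape2) || shape1 <= 0 || shape2 <= 0)
    stop("beta shape parameters must be positive and finite", call. = FALSE)
  new_signal_dist("beta", c(shape1 = shape1, shape2 = shape2),
                  support_max = 1, mean = shape1 / (shape1 + shape2))
}

#' Uniform infection signal on a sub-interval
#'
#' Density `1/(hi - lo)` on `(lo, hi)` and zero elsewhere. With
#' `lo = 0, hi = 1` this is the standard uniform signal; smaller intervals
#' model settings where only a restricted range of infection probabilities
#' occurs. `support_max` equals `hi`.
#'
#' @param lo,hi Interval endpoints, `0 <= lo < hi <= 1`.
#' @return A `signal_dist` object.
#' @export
signal_uniform <- function(lo = 0, hi = 1) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo >= 0 && hi <= 1 && lo < hi))
    stop("uniform signal requires 0 <= lo < hi <= 1", call. = FALSE)
  new_signal_dist("uniform", c(lo = lo, hi = hi),
                  support_max = hi, mean = (lo + hi) / 2)
}

#' Smoothed empirical infection signal
#'
#' Estimates a density on `(0, 1)` from observed posterior probabilities.
#' Smoothing is performed by a Gaussian kernel density estimate on the
#' logit scale (which avoids boundary bias at 0 and 1), mapped back to the
#' probability scale. A small positive floor constant is then added and the
#' density renormalized, so that the support is all of `(0, 1)` even when
#' the sample clusters away from the endpoints.
#'
#' @param p Numeric vector of posterior probabilities, all strictly inside
#'   `(0, 1)`; at least 10 values.
#' @param floor_const Additive density floor (default `1e-4`).
#' @param bandwidth Kernel bandwidth on the logit scale, or `NULL` for
#'   Silverman's rule of thumb.
#' @param n_grid Number of grid points used for the internal tabulation.
#' @return A `signal_dist` object.
#' @export
signal_empirical <- function(p, floor_const = 1e-4, bandwidth = NULL,
                             n_grid = 4001L) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("empirical signal values must lie strictly inside (0, 1)",
         call. = FALSE)
  if (length(p) < 10L)
    stop("empirical signal estimation needs at least 10 values", call. = FALSE)
  stopifnot(floor_const > 0)

  x <- stats::qlogis(p)
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(x) else bandwidth
  stopifnot(bw > 0)

  # interior grid: evaluate the logit-scale KDE and change variables back
  grid <- seq(0, 1, length.out = n_grid)
  gi <- grid[-c(1L, n_grid)]
  kde <- numeric(n_grid)  # density is finite 0 at the endpoints pre-floor
  lg <- stats::qlogis(gi)
  # direct Gaussian kernel evaluation; n * n_grid is small enough
  kde[-c(1L, n_grid)] <- vapply(
    seq_along(lg),
    function(i) mean(stats::dnorm(lg[i], mean = x, sd = bw)) / (gi[i] * (1 - gi[i])),
    numeric(1)
  )
  f <- kde + floor_const
  f <- f / trapz_all(grid, f)

  Fg <- cum_trapz(grid, f)
  Fg <- Fg / Fg[n_grid]                       # exact renormalization
  # upper tails accumulated from the right end for far-tail accuracy
  Sg <- rev(cum_trapz(rev(grid), rev(f)) * -1)
  Sg <- (Sg - Sg[n_grid]) / Sg[1]
  peg <- rev(cum_trapz(rev(grid), rev(grid * f)) * -1)  # int_a^1 p f(p) dp
  peg <- peg - peg[n_grid]                    # force PE(1) = 0 exactly
  mu <- peg[1]

  new_signal_dist("empirical",
                  c(floor_const = floor_const, bandwidth = bw,
                    n = length(p)),
                  support_max = 1, mean = mu,
                  extra = list(grid = grid, fg = f, Fg = Fg, Sg = Sg,
                               peg = peg))
}

trapz_all <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

cum_trapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' @export
print.signal_dist <- function(x, ...) {
  cat("<signal_dist> family:", x$family, "\n")
  cat("  params:", paste(names(x$params), signif(unname(x$params), 6),
                         sep = "=", collapse = ", "), "\n")
  cat("  mean E(p):", format(x$mean, digits = 6),
      " support_max:", x$support_max, "\n")
  invisible(x)
}

#' @export
mean.signal_dist <- function(x, ...) x$mean

#' Supremum of the support of a signal distribution
#' @param dist A `signal_dist`.
#' @return A probability.
#' @export
support_max <- function(dist) {
  stopifnot(inherits(dist, "signal_dist"))
  dist$support_max
}

#' Density of a signal distribution
#' @param dist A `signal_dist`.
#' @param p Vector of probabilities.
#' @return Density values `f(p)`.
#' @export
signal_density <- function(dist, p) {
  stopifnot(inherits(dist, "signal_dist"))
  switch(dist$family,
    beta = stats::dbeta(p, dist$params[["shape1"]], dist$params[["shape2"]]),
    uniform = stats::dunif(p, dist$params[["lo"]], dist$params[["hi"]]),
    empirical = {
      out <- stats::approx(dist$grid, dist$fg, xout = p, rule = 2)$y
      out[p < 0 | p > 1] <- 0
      out
    }
  )
}

#' Cumulative distribution function of a signal distribution
#' @inheritParams signal_density
#' @return `F(p)`, the probability that a random patient's posterior is at
#'   most `p`.
#' @export
signal_cdf <- function(dist, p) {
  stopifnot(inherits(dist, "signal_dist"))
  switch(dist$family,
    beta = stats::pbeta(p, dist$params[["shape1"]], dist$params[["shape2"]]),
    uniform = stats::punif(p, dist$params[["lo"]], dist$params[["hi"]]),
    empirical = {
      out <- stats::approx(dist$grid, dist$Fg, xout = p, rule = 2)$y
      out[p <= 0] <- 0; out[p >= 1] <- 1
      out
    }
  )
}

# survival function 1 - F(p), computed in the upper tail directly so that
# conditional means above far-tail thresholds stay accurate
signal_sf <- function(dist, p) {
  switch(dist$family,
    beta = stats::pbeta(p, dist$params[["shape1"]], dist$params[["shape2"]],
                        lower.tail = FALSE),
    uniform = {
      lo <- dist$params[["lo"]]; hi <- dist$params[["hi"]]
      pmin(pmax((hi - p) / (hi - lo), 0), 1)
    },
    empirical = {
      out <- stats::approx(dist$grid, dist$Sg, xout = p, rule = 2)$y
      out[p <= 0] <- 1; out[p >= 1] <- 0
      out
    }
  )
}

# lower partial expectation: int_0^a p f(p) dp, again tail-stable
partial_mean_lower <- function(dist, a) {
  switch(dist$family,
    beta = dist$mean *
      stats::pbeta(a, dist$params[["shape1"]] + 1, dist$params[["shape2"]]),
    uniform = {
      lo <- dist$params[["lo"]]; hi <- dist$params[["hi"]]
      aa <- pmin(pmax(a, lo), hi)
      (aa^2 - lo^2) / (2 * (hi - lo))
    },
    empirical = dist$mean - stats::approx(dist$grid, dist$peg, xout = a,
                                          rule = 2)$y
  )
}

#' Partial expectation of the posterior above a threshold
#'
#' Computes `PE(a) = integral from a to 1 of p f(p) dp`, the expected
#' posterior mass among treated patients when the treatment threshold is
#' `a`. `PE(0)` equals the distribution mean and `PE(1) = 0`.
#'
#' For the beta family the incomplete-moment identity
#' `PE(a) = E(p) * (1 - pbeta(a, shape1 + 1, shape2))` is used; for the
#' uniform family the closed form; for empirical signals the tabulated
#' trapezoid integral of the smoothed density.
#'
#' @param dist A `signal_dist`.
#' @param a Threshold(s) in `[0, 1]`.
#' @return Nonnegative partial expectations, vectorized over `a`.
#' @export
partial_mean <- function(dist, a) {
  stopifnot(inherits(dist, "signal_dist"))
  if (any(a < 0 | a > 1)) stop("threshold must lie in [0, 1]", call. = FALSE)
  switch(dist$family,
    beta = dist$mean *
      stats::pbeta(a, dist$params[["shape1"]] + 1, dist$params[["shape2"]],
                   lower.tail = FALSE),
    uniform = {
      lo <- dist$params[["lo"]]; hi <- dist$params[["hi"]]
      aa <- pmin(pmax(a, lo), hi)
      (hi^2 - aa^2) / (2 * (hi - lo))
    },
    empirical = stats::approx(dist$grid, dist$peg, xout = a, rule = 2)$y
  )
}

#' Sample posterior probabilities from a signal distribution
#'
#' Beta and uniform families use their exact samplers; empirical signals
#' are sampled by inversion of the tabulated CDF. Draws are reproducible
#' under [set.seed()]; pass `seed` for convenience.
#'
#' @param dist A `signal_dist`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A numeric vector of `n` probabilities.
#' @export
signal_sample <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "signal_dist"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  switch(dist$family,
    beta = stats::rbeta(n, dist$params[["shape1"]], dist$params[["shape2"]]),
    uniform = stats::runif(n, dist$params[["lo"]], dist$params[["hi"]]),
    empirical = stats::approx(dist$Fg, dist$grid, xout = stats::runif(n),
                              ties = "ordered", rule = 2)$y
  )
}
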