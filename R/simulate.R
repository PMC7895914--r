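#' Monte Carlo simulation of the repeated prescribing game
#'
#' Plays out the two-physician game: starting from a given effectiveness
#' state, in each period each physician draws an independent patient
#' signal from the signal distribution and treats iff it reaches the
#' state's threshold. The effectiveness state drops by the number of
#' treatments administered that period, and the game ends once it reaches
#' zero or below. Payoffs accrue in the expected form `p * k * U` per
#' treatment (the payoff definition of the model); an exploratory
#' `realized` mode instead draws the patient's bacterial condition
#' (Bernoulli with probability `p`) and the drug's effectiveness
#' (Bernoulli with probability `k * alpha`) and pays `r2 - r1` on success.
#'
#' Patients' true conditions are always drawn alongside the signals so
#' that the joint health-state frequencies (both bacterial, one bacterial,
#' neither) can be reported; in expected-payoff mode they do not affect
#' payoffs.
#'
#' @param d1,d2 Threshold strategies of the two physicians (vectors of
#'   length `M`; element `k` applies with `k` doses left).
#' @param cfg A [game_config] object.
#' @param n_runs Number of independent replicate games.
#' @param seed Optional integer seed.
#' @param start_state Initial effectiveness state (default `M`).
#' @param realized Use realized-outcome payoffs instead of expected ones.
#' @param max_periods Guard against non-depleting strategy profiles: runs
#'   still alive after this many periods are flagged `capped`.
#' @return An object of class `sim_result`: list with `runs` (per-run
#'   data.frame: `payoff1, payoff2, doses, periods, capped`), `visits`
#'   (per-state visit counts), `hstate_counts` (named BB/BN/NB/NN), and
#'   `summary` (mean payoffs with standard errors).
#' @export
simulate_game <- function(d1, d2, cfg, n_runs = 1L, seed = NULL,
                          start_state = cfg$M, realized = FALSE,
                          max_periods = 1e6) {
  stopifnot(inherits(cfg, "game_config"), n_runs >= 1,
            start_state >= 1, start_state <= cfg$M)
  check_strategy(d1, cfg); check_strategy(d2, cfg)
  if (!is.null(seed)) set.seed(seed)
  U1 <- cfg$params$alpha * (cfg$params$r2 - cfg$params$r1)  # payoff per p*k
  k <- rep.int(as.integer(start_state), n_runs)
  pay1 <- pay2 <- numeric(n_runs)
  doses <- integer(n_runs)
  periods <- integer(n_runs)
  visits <- integer(cfg$M)
  hs <- c(BB = 0L, BN = 0L, NB = 0L, NN = 0L)
  iter <- 0L
  while (any(k > 0L) && iter < max_periods) {
    iter <- iter + 1L
    a <- which(k > 0L)
    ka <- k[a]
    visits_k <- tabulate(ka, nbins = cfg$M)
    visits <- visits + visits_k
    p1 <- signal_sample(cfg$dist, length(a))
    p2 <- signal_sample(cfg$dist, length(a))
    b1 <- stats::runif(length(a)) < p1
    b2 <- stats::runif(length(a)) < p2
    hs <- hs + c(BB = sum(b1 & b2), BN = sum(b1 & !b2),
                 NB = sum(!b1 & b2), NN = sum(!b1 & !b2))
    t1 <- p1 >= d1[ka]
    t2 <- p2 >= d2[ka]
    if (realized) {
      e1 <- stats::runif(length(a)) < ka * cfg$params$alpha
      e2 <- stats::runif(length(a)) < ka * cfg$params$alpha
      gain <- cfg$params$r2 - cfg$params$r1
      pay1[a] <- pay1[a] + ifelse(t1 & b1 & e1, gain, 0)
      pay2[a] <- pay2[a] + ifelse(t2 & b2 & e2, gain, 0)
    } else {
      pay1[a] <- pay1[a] + ifelse(t1, p1 * ka * U1, 0)
      pay2[a] <- pay2[a] + ifelse(t2, p2 * ka * U1, 0)
    }
    doses[a] <- doses[a] + t1 + t2
    periods[a] <- periods[a] + 1L
    k[a] <- ka - t1 - t2
  }
  capped <- k > 0L
  runs <- data.frame(payoff1 = pay1, payoff2 = pay2, doses = doses,
                     periods = periods, capped = capped)
  structure(list(
    runs = runs, visits = visits, hstate_counts = hs,
    start_state = start_state, realized = realized,
    summary = data.frame(
      player = 1:2,
      mean_payoff = c(mean(pay1), mean(pay2)),
      se = c(stats::sd(pay1), stats::sd(pay2)) / sqrt(n_runs))),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", nrow(x$runs), "runs from state", x$start_state,
      if (x$realized) "(realized payoffs)" else "(expected payoffs)", "\n")
  print(x$summary)
  if (any(x$runs$capped)) cat("  WARNING:", sum(x$runs$capped),
                              "runs hit the period cap\n")
  invisible(x)
}

#' Monte Carlo estimate of symmetric strategy values
#'
#' Empirical counterpart of [symmetric_value_table()]: simulates the game
#' under a symmetric strategy from every starting effectiveness state and
#' reports the mean cumulative payoff of a physician with its standard
#' error. Used as an independent oracle for the value recursion.
#'
#' @param thresholds Symmetric strategy `d^1..d^M`.
#' @param cfg A [game_config] object.
#' @param n_runs Replicates per starting state.
#' @param seed Optional integer seed.
#' @param states Starting states to estimate (default all `1:M`).
#' @return data.frame with columns `k, estimate, se, n_runs`.
#' @export
mc_value_estimate <- function(thresholds, cfg, n_runs = 1e4, seed = NULL,
                              states = seq_len(cfg$M)) {
  stopifnot(inherits(cfg, "game_config"))
  check_strategy(thresholds, cfg)
  if (!is.null(seed)) set.seed(seed)
  est <- se <- numeric(length(states))
  for (i in seq_along(states)) {
    sim <- simulate_game(thresholds, thresholds, cfg, n_runs = n_runs,
                         start_state = states[i])
    est[i] <- sim$summary$mean_payoff[1]
    se[i] <- sim$summary$se[1]
  }
  data.frame(k = states, estimate = est, se = se, n_runs = n_runs)
}
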