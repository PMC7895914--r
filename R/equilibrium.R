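#' Equilibrium and planner solvers for the prescribing game
#'
#' Backward-induction computation of (i) the socially optimal symmetric
#' policy, by dynamic programming over threshold decision rules, and
#' (ii) a symmetric pure-strategy Markov perfect equilibrium (MPE), by the
#' constructive stage-equilibrium argument: at each effectiveness state,
#' either treating everyone is stable, or the equilibrium threshold is the
#' supremum of thresholds from which an upward one-stage deviation is
#' profitable, located by bisection on the sign of the marginal deviation
#' gain.
#'
#' @name equilibrium_solvers
#' @keywords internal
NULL

# symmetric stage value at state k given continuation values v1, v2;
# survival-function algebra keeps the far tail accurate
sym_stage_value <- function(d, k, v1, v2, cfg) {
  S <- signal_sf(cfg$dist, d)
  pe <- partial_mean(cfg$dist, d)
  (k * cfg$params$U * pe / S + 2 * (1 - S) * v1 + S * v2) / (2 - S)
}

# one-stage deviation payoff at state k given continuations (vectorized in
# d_dev); same algebra as deviation_value() but with explicit v1, v2
dev_stage_value <- function(d_dev, d_sym, k, v1, v2, cfg) {
  Ss <- signal_sf(cfg$dist, d_sym)
  Sd <- signal_sf(cfg$dist, d_dev)
  pe <- partial_mean(cfg$dist, d_dev)
  A1 <- Sd * (1 - Ss) + (1 - Sd) * Ss
  A2 <- Sd * Ss
  (k * cfg$params$U * pe + A1 * v1 + A2 * v2) / (Sd + Ss - Sd * Ss)
}

#' Socially optimal symmetric policy
#'
#' Dynamic programming over effectiveness states: with planner values
#' `sigma^0 = sigma^{-1} = 0`, state `k`'s threshold maximizes the
#' symmetric stage value with continuations `sigma^{k-1}, sigma^{k-2}`.
#' The search runs over a threshold grid on `[0, support_max)` with
#' golden-section refinement around the best grid point, plus the
#' boundary policy "treat (almost) no one", whose value is the continuity
#' limit `k U support_max / 2 + sigma^{k-1}` (reported as threshold 1 when
#' the support reaches 1). Ties are broken toward the larger threshold,
#' i.e. toward less treatment.
#'
#' @param cfg A [game_config] object.
#' @param grid_step Step of the initial threshold grid.
#' @param tol Relative tolerance of the refinement.
#' @return An object of class `solver_report` with elements `thresholds`
#'   (the policy `d_hat^1..d_hat^M`), `values` (planner values
#'   `sigma^1..sigma^M`) and `per_k` (a data.frame of diagnostics).
#' @export
solve_social_optimum <- function(cfg, grid_step = 1e-3, tol = 1e-8) {
  stopifnot(inherits(cfg, "game_config"), grid_step > 0, tol > 0)
  smax <- cfg$dist$support_max
  dg <- seq(0, smax, by = grid_step)
  dg <- dg[signal_sf(cfg$dist, dg) > 0]
  d_boundary <- if (smax >= 1) 1 else smax  # label of the treat-no-one limit
  Sg <- signal_sf(cfg$dist, dg)
  peg <- partial_mean(cfg$dist, dg)
  U <- cfg$params$U
  M <- cfg$M
  sigma <- numeric(M)
  d_hat <- numeric(M)
  at_boundary <- logical(M)
  for (k in seq_len(M)) {
    v1 <- vk(sigma, k - 1)
    v2 <- vk(sigma, k - 2)
    W <- (k * U * peg / Sg + 2 * (1 - Sg) * v1 + Sg * v2) / (2 - Sg)
    scale <- max(1, abs(max(W)))
    # largest grid maximizer (tie-break toward less treatment)
    i <- max(which(W >= max(W) - 1e-12 * scale))
    lo <- dg[max(1L, i - 1L)]
    hi <- dg[min(length(dg), i + 1L)]
    opt <- stats::optimize(function(d) sym_stage_value(d, k, v1, v2, cfg),
                           lower = lo, upper = hi, maximum = TRUE,
                           tol = tol)
    cand_d <- opt$maximum
    cand_v <- opt$objective
    if (W[i] > cand_v) { cand_d <- dg[i]; cand_v <- W[i] }
    w_bound <- k * U * smax / 2 + v1
    if (w_bound >= cand_v - 1e-12 * scale) {
      d_hat[k] <- d_boundary
      sigma[k] <- w_bound
      at_boundary[k] <- TRUE
    } else {
      d_hat[k] <- cand_d
      sigma[k] <- cand_v
    }
  }
  structure(list(thresholds = d_hat,
                 values = structure(sigma, class = "value_table",
                                    role = "optimum"),
                 per_k = data.frame(k = seq_len(M), d = d_hat,
                                    value = sigma,
                                    boundary = at_boundary),
                 kind = "social_optimum", tol = tol),
            class = "solver_report")
}

#' Symmetric pure-strategy Markov perfect equilibrium
#'
#' Constructs the equilibrium by backward induction. At each state `k`,
#' given the equilibrium continuation values: if no upward one-stage
#' deviation from the profile (0, 0) is profitable, the stage equilibrium
#' is to treat everyone. Otherwise the stage-equilibrium threshold is
#' located by bisection on the sign of the marginal deviation gain
#' `G(d) = d/d_dev v^k(d_dev, d)` at `d_dev = d` (central finite
#' difference): `G > 0` means a physician gains by withholding slightly
#' more than the symmetric rule, `G < 0` by treating slightly more; the
#' equilibrium is the sign change. Strong unimodality of the deviation
#' payoff makes this marginal test sufficient.
#'
#' @param cfg A [game_config] object.
#' @param tol Absolute bisection tolerance on the threshold.
#' @param fd_step Finite-difference step for the marginal gain.
#' @return A `solver_report` with elements `thresholds`
#'   (`d_tilde^1..d_tilde^M`), `values`, and `per_k` diagnostics
#'   (bracketing interval and marginal gain at the solution).
#' @export
solve_mpe <- function(cfg, tol = 1e-10, fd_step = 1e-6) {
  stopifnot(inherits(cfg, "game_config"), tol > 0)
  smax <- cfg$dist$support_max
  dmax <- smax - 1e-9
  U <- cfg$params$U
  M <- cfg$M
  v <- numeric(M)
  d_tilde <- numeric(M)
  gain0 <- numeric(M)
  bracket_hi <- numeric(M)
  for (k in seq_len(M)) {
    v1 <- vk(v, k - 1)
    v2 <- vk(v, k - 2)
    G <- function(d) {
      h <- min(fd_step, d, dmax - d)
      if (h <= 0) h <- fd_step
      lo <- max(0, d - h); hi <- min(dmax, d + h)
      (dev_stage_value(hi, d, k, v1, v2, cfg) -
         dev_stage_value(lo, d, k, v1, v2, cfg)) / (hi - lo)
    }
    # is treating everyone a stage equilibrium? scan deviation payoffs
    scan <- c(seq(0, dmax, length.out = 257L), dmax)
    dev0 <- dev_stage_value(scan, 0, k, v1, v2, cfg)
    base0 <- dev_stage_value(0, 0, k, v1, v2, cfg)
    g0 <- max(dev0) - base0
    gain0[k] <- g0
    if (g0 <= 1e-12 * max(1, abs(base0))) {
      d_tilde[k] <- 0
      v[k] <- sym_stage_value(0, k, v1, v2, cfg)
      bracket_hi[k] <- NA_real_
      next
    }
    # bracket the sign change of G on (0, dmax]
    hi <- NA_real_
    lo <- 0
    for (d in seq(dmax / 64, dmax, length.out = 64L)) {
      if (G(d) < 0) { hi <- d; break } else lo <- d
    }
    if (is.na(hi))
      stop("bisection bracket failure at state k = ", k,
           ": marginal deviation gain positive up to the support limit",
         call. = FALSE)
    bracket_hi[k] <- hi
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (G(mid) < 0) hi <- mid else lo <- mid
    }
    d_tilde[k] <- (lo + hi) / 2
    v[k] <- sym_stage_value(d_tilde[k], k, v1, v2, cfg)
  }
  structure(list(thresholds = d_tilde,
                 values = structure(v, class = "value_table",
                                    role = "equilibrium"),
                 per_k = data.frame(k = seq_len(M), d = d_tilde,
                                    value = v, gain_at_zero = gain0,
                                    bracket_hi = bracket_hi),
                 kind = "mpe", tol = tol),
            class = "solver_report")
}

#' Verify a symmetric strategy against one-stage deviations
#'
#' For each effectiveness state, evaluates the one-stage deviation payoff
#' over a grid of deviating thresholds (endpoints 0 and
#' `support_max - 1e-9` always included, plus the strategy's own
#' threshold) and reports the maximal deviation gain and its argmax. The
#' strategy is certified as an MPE when every state's maximal gain is at
#' most `tol`.
#'
#' @param thresholds Symmetric strategy `d^1..d^M`.
#' @param cfg A [game_config] object.
#' @param grid_size Number of grid points per state.
#' @param tol Certification tolerance in payoff units.
#' @return A `solver_report` with `certified` flag and `per_k` data.frame
#'   (columns `k, d, value, max_gain, argmax_gain`).
#' @export
verify_mpe <- function(thresholds, cfg, grid_size = 999L, tol = 1e-8) {
  stopifnot(inherits(cfg, "game_config"))
  check_strategy(thresholds, cfg)
  v <- symmetric_value_table(thresholds, cfg)
  dmax <- cfg$dist$support_max - 1e-9
  max_gain <- numeric(cfg$M)
  arg_gain <- numeric(cfg$M)
  for (k in seq_len(cfg$M)) {
    v1 <- vk(v, k - 1)
    v2 <- vk(v, k - 2)
    dd <- unique(sort(c(seq(0, dmax, length.out = grid_size),
                        thresholds[k])))
    gains <- dev_stage_value(dd, thresholds[k], k, v1, v2, cfg) - v[k]
    j <- which.max(gains)
    max_gain[k] <- gains[j]
    arg_gain[k] <- dd[j]
  }
  structure(list(thresholds = thresholds, values = v,
                 per_k = data.frame(k = seq_len(cfg$M), d = thresholds,
                                    value = as.numeric(v),
                                    max_gain = max_gain,
                                    argmax_gain = arg_gain),
                 certified = all(max_gain <= tol),
                 kind = "verification", tol = tol),
            class = "solver_report")
}

#' @export
print.solver_report <- function(x, ...) {
  cat("<solver_report>", x$kind, "\n")
  if (!is.null(x$certified))
    cat("  certified MPE:", x$certified, "(tol", x$tol, ")\n")
  print(utils::head(x$per_k, 10))
  if (nrow(x$per_k) > 10) cat("  ...", nrow(x$per_k), "states total\n")
  invisible(x)
}

#' Stage-equilibrium tests of the dichotomous game
#'
#' Under a signal coarsened at `T`, each stage offers two decision rules:
#' treat everyone (threshold 0) or treat high-signal patients only
#' (threshold `T`). This function evaluates, for each state `k`, the two
#' stage-equilibrium conditions obtained from the one-stage deviation
#' principle:
#'
#' * treat-everyone is stable iff `k U p_L >= v^{k-1} - v^{k-2}`
#'   (continuations from the treat-everyone profile);
#' * treat-high-only is stable iff
#'   `k U ((1 + F(T)) p_L - F(T) p_H) / (1 - F(T)) <= v^{k-1} - v^{k-2}`
#'   (continuations from the treat-high-only profile).
#'
#' @param T Coarsening threshold with `0 < F(T) < 1`.
#' @param cfg A [game_config] object.
#' @return A data.frame with per-state condition sides and stability
#'   flags `treat_all_stable`, `treat_high_stable`.
#' @export
dichotomous_stage_equilibrium <- function(T, cfg) {
  stopifnot(inherits(cfg, "game_config"))
  cs <- coarsen(cfg$dist, T)
  FT <- cs$q_L
  U <- cfg$params$U
  M <- cfg$M
  v00 <- dichotomous_values(T, cfg, "both-all")
  vTT <- dichotomous_values(T, cfg, "both-high")
  k <- seq_len(M)
  d00 <- vapply(k, function(j) vk(v00, j - 1) - vk(v00, j - 2), numeric(1))
  dTT <- vapply(k, function(j) vk(vTT, j - 1) - vk(vTT, j - 2), numeric(1))
  lhs_all <- k * U * cs$p_L
  lhs_high <- k * U * ((1 + FT) * cs$p_L - FT * cs$p_H) / (1 - FT)
  eps <- 1e-10 * max(1, U * M)
  data.frame(k = k,
             lhs_all = lhs_all, rhs_all = d00,
             treat_all_stable = lhs_all >= d00 - eps,
             lhs_high = lhs_high, rhs_high = dTT,
             treat_high_stable = lhs_high <= dTT + eps)
}

#' Cross-check of the coarsening stability criterion
#'
#' The distribution-level criterion `p_H - p_L >= E(p)` characterizes
#' exactly when treating only high-signal patients at every state is an
#' MPE of the coarsened game. This function evaluates both sides of that
#' equivalence independently: the sign of the [stability_gap()] and the
#' exhaustive per-state stage-equilibrium conditions of
#' [dichotomous_stage_equilibrium()]. The two booleans must agree.
#'
#' @param dist A [signal_dist] object (replaces `cfg$dist`).
#' @param T Coarsening threshold with `0 < F(T) < 1`.
#' @param cfg A [game_config] object supplying `M` and the utilities.
#' @return A list with `condition_holds` (gap criterion),
#'   `all_states_stable` (per-state checks) and `agree`.
#' @export
coarse_mpe_agreement <- function(dist, T, cfg) {
  stopifnot(inherits(dist, "signal_dist"), inherits(cfg, "game_config"))
  cfg <- game_config(cfg$M, dist, cfg$params)
  gap <- stability_gap(dist, T)
  per_k <- dichotomous_stage_equilibrium(T, cfg)
  cond <- gap >= -1e-10
  allk <- all(per_k$treat_high_stable)
  list(condition_holds = cond, all_states_stable = allk,
       agree = cond == allk, gap = gap)
}
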