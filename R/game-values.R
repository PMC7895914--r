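#' Configuration of the two-physician prescribing game
#'
#' Bundles the horizon (number of effectiveness states `M`), the signal
#' distribution and the utility parameters. The dynamic game assumes the
#' treatment-risk parameter `c = 0`, under which withholding yields 0 and
#' treating yields `p * k * U`; the initial effectiveness `e0 = M * alpha`
#' must not exceed 1.
#'
#' @param M Number of effectiveness states (positive integer).
#' @param dist A [signal_dist] object.
#' @param params A [utility_params] object with `c = 0`. By default,
#'   `alpha` is set to `1 / M` so that `e0 = 1`.
#' @return An object of class `game_config`.
#' @examples
#' cfg <- game_config(10, signal_uniform())
#' @export
game_config <- function(M, dist, params = NULL) {
  stopifnot(length(M) == 1L, M >= 1, M == round(M),
            inherits(dist, "signal_dist"))
  if (is.null(params)) params <- utility_params(r1 = 0, r2 = 1, r3 = 2,
                                                c = 0, alpha = 1 / M)
  stopifnot(inherits(params, "utility_params"))
  if (params$c != 0)
    stop("the dynamic game requires c = 0; positive treatment risk is ",
         "supported in the static analysis only", call. = FALSE)
  if (M * params$alpha > 1 + 1e-12)
    stop("initial effectiveness M * alpha must not exceed 1", call. = FALSE)
  structure(list(M = as.integer(M), dist = dist, params = params),
            class = "game_config")
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config> M =", x$M, "(e0 =", x$M * x$params$alpha, ")\n")
  print(x$dist); print(x$params)
  invisible(x)
}

# value lookup with the convention v^k = 0 for k <= 0
vk <- function(v, k) if (k <= 0) 0 else v[[k]]

check_strategy <- function(thresholds, cfg, allow_one = FALSE) {
  stopifnot(is.numeric(thresholds), length(thresholds) == cfg$M)
  smax <- cfg$dist$support_max
  ok <- thresholds >= 0 &
    (thresholds <= smax + 1e-12 | (allow_one & thresholds == 1))
  if (!all(ok))
    stop("thresholds must lie in [0, support_max]",
         if (allow_one) " (or equal 1 in the planner problem)", call. = FALSE)
  invisible(thresholds)
}

#' Cumulative expected payoffs of a symmetric strategy
#'
#' Computes, bottom-up for `k = 1, ..., M`, the expected cumulative payoff
#' `v^k` of each physician when both apply the threshold `d^k` at
#' effectiveness state `k`:
#' \deqn{v^k = \frac{kU\,PE(d^k) + 2F(1-F)\,v^{k-1} + (1-F)^2\,v^{k-2}}{1 - F^2},}
#' with `F = F(d^k)`, `PE` the partial expectation, and `v^k = 0` for
#' `k <= 0`. The denominator accounts for the stage repeating itself while
#' both physicians withhold. The boundary rule `d^k = 1` (treat no one) is
#' admissible for symmetric policies via its continuity limit
#' `v^k = k U / 2 + v^{k-1}`.
#'
#' @param thresholds Numeric vector `d^1, ..., d^M`, each in
#'   `[0, support_max]` or exactly 1.
#' @param cfg A [game_config] object.
#' @return An object of class `value_table`: numeric vector `v^1..v^M`
#'   with attribute `role = "symmetric"`.
#' @export
symmetric_value_table <- function(thresholds, cfg) {
  stopifnot(inherits(cfg, "game_config"))
  check_strategy(thresholds, cfg, allow_one = TRUE)
  U <- cfg$params$U
  v <- numeric(cfg$M)
  for (k in seq_len(cfg$M)) {
    d <- thresholds[k]
    if (d == 1) {
      v[k] <- k * U / 2 + vk(v, k - 1)
    } else {
      # survival-function form of the recursion, stable near the support edge
      S <- signal_sf(cfg$dist, d)
      pe <- partial_mean(cfg$dist, d)
      v[k] <- (k * U * pe / S + 2 * (1 - S) * vk(v, k - 1) +
                 S * vk(v, k - 2)) / (2 - S)
    }
  }
  structure(v, class = "value_table", role = "symmetric")
}

#' One-stage deviation payoff
#'
#' Expected cumulative payoff at state `k` of a physician who applies
#' threshold `d_dev` this stage while the opponent applies `d_sym`, both
#' conforming to the symmetric profile (with continuation values `values`)
#' thereafter:
#' \deqn{v^k(\bar d, d) = \frac{kU\,PE(\bar d) + A_1 v^{k-1} + A_2 v^{k-2}}
#'   {1 - A_0},}
#' where `A_j` is the probability that exactly `j` physicians treat
#' (`A_0 = F(\bar d)F(d)` etc.). Continuation values are always taken from
#' the symmetric table, per the one-stage deviation principle.
#'
#' @param k Effectiveness state, `1 <= k <= M`.
#' @param d_dev Deviating threshold(s) (vectorized), each in
#'   `[0, support_max)` with `F < 1` unless `F(d_sym) < 1`.
#' @param d_sym Symmetric threshold played by the opponent.
#' @param values A [symmetric_value_table()] result (or numeric vector)
#'   providing `v^{k-1}` and `v^{k-2}`.
#' @param cfg A [game_config] object.
#' @return Deviation payoffs, one per `d_dev`.
#' @export
deviation_value <- function(k, d_dev, d_sym, values, cfg) {
  stopifnot(inherits(cfg, "game_config"), k >= 1, k <= cfg$M,
            length(d_sym) == 1L)
  Ss <- signal_sf(cfg$dist, d_sym)
  Sd <- signal_sf(cfg$dist, d_dev)
  if (any(Sd <= 0 & Ss <= 0))
    stop("undefined limit: both thresholds cannot exhaust the support ",
         "in the asymmetric evaluation", call. = FALSE)
  U <- cfg$params$U
  v1 <- vk(values, k - 1)
  v2 <- vk(values, k - 2)
  pe <- partial_mean(cfg$dist, d_dev)
  A1 <- Sd * (1 - Ss) + (1 - Sd) * Ss   # exactly one physician treats
  A2 <- Sd * Ss                          # both treat
  (k * U * pe + A1 * v1 + A2 * v2) / (Sd + Ss - Sd * Ss)
}

#' Normalized deviation-payoff index
#'
#' The auxiliary function `g_d(d_dev)` used in the equilibrium analysis:
#' a normalized contrast between the deviation payoff at `d_dev` and the
#' symmetric payoff at `d`, depending only on the signal distribution,
#' \deqn{g_d(\bar d) = \frac{(1-F(d)^2)PE(\bar d) - (1-F(d)F(\bar d))PE(d)}
#'   {(1-F(d))^2 (F(d) - F(\bar d))},}
#' with the continuity limit at `d_dev = d`
#' \deqn{g_d(d) = \frac{1+F(d)}{1-F(d)} d - \frac{F(d) PE(d)}{(1-F(d))^2}.}
#' `g_d` is strictly increasing in `d_dev`, a property exploited when
#' comparing equilibrium and socially optimal thresholds.
#'
#' @param dist A [signal_dist] object.
#' @param d Symmetric threshold, `0 <= d < 1` with `F(d) < 1`.
#' @param d_dev Deviating threshold(s); values equal (or numerically equal)
#'   to `d` use the limit form.
#' @return Numeric vector of index values.
#' @export
deviation_index <- function(dist, d, d_dev) {
  stopifnot(inherits(dist, "signal_dist"), length(d) == 1L)
  S <- signal_sf(dist, d)
  if (d >= 1 || S <= 0)
    stop("d must satisfy F(d) < 1", call. = FALSE)
  ped <- partial_mean(dist, d)
  Sb <- signal_sf(dist, d_dev)
  peb <- partial_mean(dist, d_dev)
  out <- numeric(length(d_dev))
  at_d <- abs(Sb - S) < 1e-12
  out[at_d] <- (2 - S) / S * d - (1 - S) * ped / S^2
  i <- !at_d
  out[i] <- (S * (2 - S) * peb[i] - (S + Sb[i] - S * Sb[i]) * ped) /
    (S^2 * (Sb[i] - S))
  out
}

#' Value recursions of the dichotomous-signal game
#'
#' Closed-form per-state payoffs when the signal has been coarsened at
#' threshold `T`, so each stage decision is "treat everyone" (threshold 0)
#' or "treat high-signal patients only" (threshold `T`). Four profiles are
#' available:
#'
#' * `"both-all"`: both treat everyone; `v^k = kU E(p) + v^{k-2}`.
#' * `"both-high"`: both treat high only;
#'   `v^k = (kU p_H + 2F v^{k-1} + (1-F) v^{k-2}) / (1 + F)`.
#' * `"deviate-all-vs-high"`: payoff of a physician treating everyone for
#'   one stage while the opponent (and both, thereafter) treat high only.
#' * `"high-vs-deviate-all"`: payoff of a physician treating high only for
#'   one stage while the opponent deviates to treating everyone, both
#'   conforming to "treat everyone" thereafter.
#'
#' For the deviation profiles the continuation values are those of the
#' symmetric profile being tested (one-stage deviation semantics):
#' `"both-high"` continuations for `"deviate-all-vs-high"`, `"both-all"`
#' continuations for `"high-vs-deviate-all"`.
#'
#' @param T Coarsening threshold with `0 < F(T) < 1`.
#' @param cfg A [game_config] object.
#' @param profile One of `"both-all"`, `"both-high"`,
#'   `"deviate-all-vs-high"`, `"high-vs-deviate-all"`.
#' @return A `value_table` (numeric vector `v^1..v^M`) with `role` set to
#'   the profile.
#' @export
dichotomous_values <- function(T, cfg,
                               profile = c("both-all", "both-high",
                                           "deviate-all-vs-high",
                                           "high-vs-deviate-all")) {
  profile <- match.arg(profile)
  stopifnot(inherits(cfg, "game_config"))
  cs <- coarsen(cfg$dist, T)
  FT <- cs$q_L
  U <- cfg$params$U
  M <- cfg$M
  v <- numeric(M)
  if (profile == "both-all") {
    for (k in seq_len(M))
      v[k] <- k * U * cfg$dist$mean + vk(v, k - 2)
  } else if (profile == "both-high") {
    for (k in seq_len(M))
      v[k] <- (k * U * cs$p_H + 2 * FT * vk(v, k - 1) +
                 (1 - FT) * vk(v, k - 2)) / (1 + FT)
  } else if (profile == "deviate-all-vs-high") {
    cont <- dichotomous_values(T, cfg, "both-high")
    for (k in seq_len(M))
      v[k] <- FT * (k * U * cs$p_L + vk(cont, k - 1)) +
        (1 - FT) * (k * U * cs$p_H + vk(cont, k - 2))
  } else {
    cont <- dichotomous_values(T, cfg, "both-all")
    for (k in seq_len(M))
      v[k] <- FT * vk(cont, k - 1) +
        (1 - FT) * (k * U * cs$p_H + vk(cont, k - 2))
  }
  structure(v, class = "value_table", role = profile)
}

#' @export
print.value_table <- function(x, ...) {
  cat("<value_table> role:", attr(x, "role"), "\n")
  print(stats::setNames(as.numeric(x), paste0("v", seq_along(x))))
  invisible(x)
}

#' Export a value table as a data.frame
#' @param x A `value_table`.
#' @param ... Unused.
#' @return data.frame with columns `k`, `v_k`, `role`.
#' @export
as.data.frame.value_table <- function(x, ...) {
  data.frame(k = seq_along(x), v_k = as.numeric(x),
             role = attr(x, "role") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
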