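#' Utility parameters of the prescribing problem
#'
#' Three outcome utilities order the single-patient problem:
#' `r1` (bacterial infection, untreated) < `r2` (bacterial infection,
#' effectively treated) < `r3` (no bacterial infection). `c` is the
#' probability that unnecessary treatment induces an opportunistic
#' infection, and `alpha` is the per-dose depletion of antibiotic
#' effectiveness. The derived net-benefit unit is `U = alpha * (r2 - r1)`,
#' the immediate value of one effectiveness step applied to a certainly
#' bacterial case.
#'
#' The dynamic game modules require `c = 0` (treatment carries no direct
#' risk); `c > 0` is supported in the static, single-patient analysis
#' only.
#'
#' @param r1,r2,r3 Outcome utilities with `r3 > r2 > r1`.
#' @param c Probability of treatment-induced infection, in `[0, 1]`.
#' @param alpha Per-dose effectiveness depletion, in `(0, 1]`.
#' @return An object of class `utility_params`.
#' @examples
#' utility_params(r1 = 0, r2 = 0.5, r3 = 1, c = 0.05, alpha = 0.05)
#' @export
utility_params <- function(r1 = 0, r2 = 0.5, r3 = 1, c = 0, alpha = 0.05) {
  stopifnot(is.numeric(r1), is.numeric(r2), is.numeric(r3))
  if (!(r3 > r2 && r2 > r1))
    stop("utility ordering violated: r3 > r2 > r1 is required ",
         "(untreated bacterial infection must be the worst outcome)",
         call. = FALSE)
  if (c < 0 || c > 1) stop("c must lie in [0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  structure(list(r1 = r1, r2 = r2, r3 = r3, c = c, alpha = alpha,
                 U = alpha * (r2 - r1)),
            class = "utility_params")
}

#' @export
print.utility_params <- function(x, ...) {
  cat(sprintf("<utility_params> r1=%g r2=%g r3=%g c=%g alpha=%g (U=%g)\n",
              x$r1, x$r2, x$r3, x$c, x$alpha, x$U))
  invisible(x)
}

#' Treatment-threshold probability from four outcome utilities
#'
#' The classical threshold of decision analysis: the disease probability
#' at which treating and withholding have equal expected utility,
#' `T = net_risk / (net_benefit + net_risk)`, where
#' `net_benefit = u_disease_treated - u_disease_untreated` and
#' `net_risk = u_healthy_untreated - u_healthy_treated`. Treat when the
#' disease probability is at least `T`.
#'
#' @param u_disease_treated,u_disease_untreated Utilities with disease.
#' @param u_healthy_treated,u_healthy_untreated Utilities without disease.
#' @return A probability in `[0, 1)`.
#' @export
treatment_threshold <- function(u_disease_treated, u_disease_untreated,
                                u_healthy_treated, u_healthy_untreated) {
  benefit <- u_disease_treated - u_disease_untreated
  risk <- u_healthy_untreated - u_healthy_treated
  if (risk < 0 || benefit <= 0 && risk <= 0 || benefit + risk <= 0)
    stop("degenerate threshold: treatment must benefit diseased patients ",
         "and carry nonnegative net risk for healthy ones", call. = FALSE)
  risk / (benefit + risk)
}

#' Static treatment threshold at a given effectiveness level
#'
#' Adjusts the classical threshold for the current antibiotic
#' effectiveness `e` and the treatment-induced infection risk `c`:
#' `T = c (r3 - r1) / (e (r2 - r1) + c (r3 - r1))`. With `c = 0` the
#' threshold is 0: treatment is then a dominant action for the single
#' patient.
#'
#' @param params A [utility_params] object.
#' @param e Current effectiveness, in `(0, 1]`.
#' @return A probability threshold.
#' @export
static_threshold <- function(params, e) {
  stopifnot(inherits(params, "utility_params"))
  if (any(e <= 0 | e > 1)) stop("effectiveness e must lie in (0, 1]",
                                call. = FALSE)
  num <- params$c * (params$r3 - params$r1)
  den <- e * (params$r2 - params$r1) + num
  if (any(den == 0))
    stop("degenerate threshold: zero net benefit and net risk", call. = FALSE)
  num / den
}

#' Immediate expected payoff of administering treatment
#'
#' The net expected utility of treating a patient whose posterior
#' probability of bacterial infection is `p`, at effectiveness state `k`:
#' `p * k * alpha * (r2 - r1) - (1 - p) * c * (r3 - r1)`. Withholding
#' yields 0. With `c = 0` this reduces to `p * k * U`.
#'
#' @param p Posterior probability (vectorized).
#' @param k Effectiveness state index, `k >= 1`.
#' @param params A [utility_params] object.
#' @return Expected payoff(s).
#' @export
immediate_payoff <- function(p, k, params) {
  stopifnot(inherits(params, "utility_params"), all(k >= 1))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  p * k * params$alpha * (params$r2 - params$r1) -
    (1 - p) * params$c * (params$r3 - params$r1)
}

#' Myopic treatment policy
#'
#' The policy of a physician who optimizes each patient in isolation:
#' at effectiveness state `k` the threshold is the static one evaluated at
#' `e = k * alpha`, ignoring depletion. With `c = 0` every threshold is 0,
#' i.e. the myopic physician treats every patient.
#'
#' @param params A [utility_params] object.
#' @param M Number of effectiveness states (initial `e0 = M * alpha <= 1`).
#' @return Numeric vector of thresholds `d^1, ..., d^M` (element `k` is
#'   the rule with `k` doses left).
#' @export
myopic_policy <- function(params, M) {
  stopifnot(inherits(params, "utility_params"), M >= 1)
  if (M * params$alpha > 1 + 1e-12)
    stop("initial effectiveness M * alpha must not exceed 1", call. = FALSE)
  static_threshold(params, (1:M) * params$alpha)
}
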