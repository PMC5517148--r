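#' Model parameters
#'
#' Collects every dynamical constant of the model in one validated list.
#' The defaults are the global parameter set used for all mapping-type
#' simulations: `n = 200` terminals, `i = 30000` iterations, adaptation gain
#' `mu = 0.006`, resetting constant `lambda = 0.0045` and history window
#' `h = 10`. Scenario builders override individual entries (for example the
#' in-silico gap assays switch the fiber-fiber ramp off, `C0 = 1`, and use
#' `n = 12`, `i = 2000`).
#'
#' @param mu adaptation gain \eqn{\mu} of the adaptation coefficient
#'   \eqn{a(i) = 1 + \ln(1 + \mu \bar D)} where \eqn{\bar D} is the
#'   linearly weighted mean of the recent guidance-potential history.
#' @param lambda Hookian resetting constant \eqn{\lambda}; the resetting
#'   force \eqn{f = \lambda (S(0) - S(i))} pulls sensors back to baseline.
#' @param h length of the guidance-potential history window.
#' @param n_terminals number of fiber terminals `n`.
#' @param n_iterations number of iterations `i`.
#' @param C0 ceiling of the fiber-fiber interaction weight `C(i)`. With
#'   `ramp_on = TRUE`, `C(i) = C0 * clamp((i - j_onset)/ramp_len, 0, 1)`;
#'   with `ramp_on = FALSE` the ramp is "switched off" and `C(i) == C0`
#'   at every iteration (the sparse in-vitro scenarios use `C0 = 1`).
#' @param j_onset iteration at which the fiber-fiber ramp starts (`j`).
#' @param ramp_len iterations over which `C(i)` rises to `C0`.
#' @param ramp_on logical; see `C0`.
#' @param q_x forward-step base probability of the biased walk, the "slight
#'   inherent bias to avoid prolonged dwelling" (default 0.37); the three
#'   remaining directions share `1 - q_x` equally wherever the bias
#'   applies; elsewhere all four directions start from 1/4.
#' @param q_x_scope where the forward bias applies: `"cue_free"` (only at
#'   positions whose footprint senses no target cue: pre-target corridors)
#'   or `"everywhere"` (the whole arena; used by the in-vitro gap assays,
#'   where axons have an inherent forward growth drive across the printed
#'   substrate).
#' @param beta sharpness of the move-probability rule: a candidate position
#'   is selected with probability proportional to
#'   `base_prob * exp(-beta * D(candidate))`. Calibrated jointly with
#'   `retinal_gamma`; see the package vignette.
#' @param kappa relaxation rate of the canonical-adaptation variant, in
#'   which each sensor channel independently matches the local target cue.
#' @param sigma_frac Gaussian footprint sigma as a fraction of the radius.
#' @param radius disc radius of a fiber terminal in field units (the
#'   terminals are discs of diameter about seven units).
#' @param retinal_gamma steepness of the exponential retinal and tectal
#'   countergradients (see [retinal_sensor_levels()]).
#' @param adaptation_mode one of `"coadaptation"` (common coefficient for
#'   both sensors plus resetting force), `"canonical"` (independent
#'   negative feedback per channel) or `"none"`.
#' @param seed integer seed for the single RNG stream of a simulation.
#' @param record_stride record traces every this many iterations
#'   (0 = final state only).
#' @param do_move diagnostic switch; `FALSE` freezes all positions so the
#'   pure sensor dynamics can be inspected.
#' @param hold_off_target logical; if `TRUE`, sensors are held constant
#'   while a terminal stands on cue-free ground, modeling a pre-adapting
#'   factor in the optic tract that keeps the approaching population
#'   desensitized until it is inside the target (tectal-entry scenario).
#' @param sensor_floor numeric floor keeping sensors strictly positive.
#'
#' @return A list of class `coadapt_params`.
#' @examples
#' p <- model_params(n_terminals = 12, n_iterations = 2000, C0 = 1,
#'                   ramp_on = FALSE)
#' p$mu
#' @export
model_params <- function(mu = 0.006, lambda = 0.0045, h = 10L,
                         n_terminals = 200L, n_iterations = 30000L,
                         C0 = 40, j_onset = 10000L, ramp_len = 5000L,
                         ramp_on = TRUE, q_x = 0.37,
                         q_x_scope = c("cue_free", "everywhere"),
                         beta = 8,
                         kappa = 0.05, sigma_frac = 0.5, radius = 3.5,
                         retinal_gamma = 3,
                         adaptation_mode = c("coadaptation", "canonical",
                                             "none"),
                         seed = 1L, record_stride = 0L, do_move = TRUE,
                         hold_off_target = FALSE, sensor_floor = 1e-9) {
  adaptation_mode <- match.arg(adaptation_mode)
  q_x_scope <- match.arg(q_x_scope)
  stopifnot(mu >= 0, lambda >= 0, h >= 1, n_terminals >= 1,
            n_iterations >= 1, C0 >= 0, j_onset >= 0, ramp_len >= 1,
            q_x >= 0, q_x <= 1, beta >= 0, kappa >= 0, sigma_frac > 0,
            radius > 0, retinal_gamma > 0, sensor_floor > 0)
  p <- list(mu = mu, lambda = lambda, h = as.integer(h),
            n_terminals = as.integer(n_terminals),
            n_iterations = as.integer(n_iterations), C0 = C0,
            j_onset = as.integer(j_onset), ramp_len = as.integer(ramp_len),
            ramp_on = isTRUE(ramp_on), q_x = q_x,
            q_x_scope = q_x_scope, beta = beta,
            kappa = kappa, sigma_frac = sigma_frac, radius = radius,
            retinal_gamma = retinal_gamma, adaptation_mode = adaptation_mode,
            seed = as.integer(seed),
            record_stride = as.integer(record_stride),
            do_move = isTRUE(do_move),
            hold_off_target = isTRUE(hold_off_target),
            sensor_floor = sensor_floor)
  class(p) <- "coadapt_params"
  p
}

# merge override lists (builder overrides, then user overrides) onto defaults
resolve_params <- function(...) {
  p <- as.list(model_params())
  for (ov in list(...)) {
    if (is.null(ov)) next
    ov <- as.list(ov)
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown model parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  do.call(model_params, p[setdiff(names(p), character(0))])
}

#' Fiber-fiber interaction weight C(i)
#'
#' The influence of trans fiber-fiber signals increases with iteration
#' number to reflect the developmental increase in terminal number and
#' size: `C(i) = C0 * clamp((i - j_onset)/ramp_len, 0, 1)`. When the ramp
#' is switched off (sparse in-vitro scenarios) `C(i) == C0` throughout.
#'
#' @param iteration iteration number (0-based, vectorised).
#' @param params a [model_params()] list.
#' @return Numeric vector of weights.
#' @examples
#' fiber_weight(0, model_params())                  # before onset: 0
#' fiber_weight(20000, model_params())              # fully ramped: C0
#' fiber_weight(5, model_params(ramp_on = FALSE, C0 = 1))
#' @export
fiber_weight <- function(iteration, params = model_params()) {
  stopifnot(all(iteration >= 0))
  if (!params$ramp_on) return(rep(params$C0, length(iteration)))
  r <- (iteration - params$j_onset) / params$ramp_len
  params$C0 * pmin(pmax(r, 0), 1)
}
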