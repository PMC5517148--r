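#' Run a simulation
#'
#' Executes the stochastic dynamics for a scenario: at every iteration and
#' for every mobile terminal the guidance potential (Eq. form of
#' [guidance_potential()]) is evaluated at the current position and pushed
#' onto the history, the adaptation coefficient is computed, the sensor
#' update of the chosen adaptation mode is applied, and one biased
#' random-walk step is proposed and executed. Terminals are processed in a
#' fixed order and consume random draws in that order, so identical
#' `(seed, params, scenario)` reproduce the result bit-identically.
#'
#' @param scenario a scenario object from one of the builders
#'   ([mapping_scenario()], [gap_assay_scenario()],
#'   [tectal_entry_scenario()], [knockin_scenario()],
#'   [innervation_scenario()]) or anything with `field`, `terminals`,
#'   `params_overrides`, `hints`, `tag`.
#' @param params named list of parameter overrides applied on top of the
#'   scenario's own overrides (e.g. `list(seed = 7)`).
#' @param record_stride record position/sensor/potential traces every this
#'   many iterations; 0 (default) keeps only the final state plus the
#'   running summaries. Overrides the parameter of the same name.
#' @return Object of class `coadapt_sim`: list with `final` (data.frame of
#'   final terminal states), `max_x` (running per-terminal maximum of the
#'   x position, used by stopping metrics), `max_ratio_dev` (largest
#'   relative deviation of `R_F/L_F` from baseline seen anywhere in the
#'   run), `trace` (if recorded), `params`, `hints`, `tag`.
#' @examples
#' sc <- mapping_scenario(n = 10)
#' res <- simulate(sc, params = list(n_iterations = 200L, seed = 42))
#' head(res$final)
#' @export
simulate <- function(scenario, params = list(), record_stride = NULL) {
  stopifnot(inherits(scenario, "coadapt_scenario"))
  p <- resolve_params(scenario$params_overrides, params)
  if (!is.null(record_stride)) p$record_stride <- as.integer(record_stride)
  term <- scenario$terminals
  stopifnot(nrow(term) >= 1)
  mode <- match(p$adaptation_mode, c("coadaptation", "canonical", "none")) - 1L
  cp <- list(mu = p$mu, lambda = p$lambda, h = p$h, beta = p$beta,
             q_x = p$q_x,
             q_x_everywhere = identical(p$q_x_scope, "everywhere"), kappa = p$kappa, C0 = p$C0, j_onset = p$j_onset,
             ramp_len = p$ramp_len, ramp_on = p$ramp_on, do_move = p$do_move,
             hold_off_target = p$hold_off_target,
             radius = p$radius, sigma_frac = p$sigma_frac,
             sensor_floor = p$sensor_floor, mode = mode)
  set.seed(p$seed)
  raw <- cpp_simulate(scenario$field, as.list(term), cp,
                      p$n_iterations, p$record_stride)
  final <- data.frame(terminal_id = seq_len(nrow(term)),
                      origin_u = term$origin_u, x = raw$x, y = raw$y,
                      R_F = raw$R_F, L_F = raw$L_F, D = raw$D,
                      class = term$class, mobile = term$mobile,
                      stringsAsFactors = FALSE)
  trace <- if (p$record_stride > 0) raw$trace else NULL
  structure(list(final = final, max_x = raw$max_x,
                 max_ratio_dev = raw$max_ratio_dev, trace = trace,
                 params = p, hints = scenario$hints, tag = scenario$tag),
            class = "coadapt_sim")
}

#' @export
print.coadapt_sim <- function(x, ...) {
  cat(sprintf("<coadapt_sim '%s'>  n = %d terminals, i = %d iterations, mode = %s\n",
              x$tag, nrow(x$final), x$params$n_iterations,
              x$params$adaptation_mode))
  cat(sprintf("  final x in [%.2f, %.2f]; max ratio deviation %.3g\n",
              min(x$final$x), max(x$final$x), max(x$max_ratio_dev)))
  invisible(x)
}

#' Tidy per-iteration records of a simulation
#'
#' Flattens the recorded trace (see `record_stride` in [simulate()]) into
#' the tidy long format `iteration, terminal_id, origin_u, x, y, R_F, L_F,
#' D`; with no trace recorded, the final state is returned as a single
#' pseudo-iteration block.
#'
#' @param x a `coadapt_sim` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return A data.frame.
#' @export
as.data.frame.coadapt_sim <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  n <- nrow(x$final)
  if (is.null(x$trace)) {
    return(data.frame(iteration = x$params$n_iterations,
                      terminal_id = seq_len(n),
                      origin_u = x$final$origin_u, x = x$final$x,
                      y = x$final$y, R_F = x$final$R_F, L_F = x$final$L_F,
                      D = x$final$D))
  }
  tr <- x$trace
  nr <- length(tr$iteration)
  data.frame(iteration = rep(tr$iteration, times = n),
             terminal_id = rep(seq_len(n), each = nr),
             origin_u = rep(x$final$origin_u, each = nr),
             x = as.vector(tr$x), y = as.vector(tr$y),
             R_F = as.vector(tr$R_F), L_F = as.vector(tr$L_F),
             D = as.vector(tr$D))
}
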