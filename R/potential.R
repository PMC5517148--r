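#' Create a fiber terminal
#'
#' A growth-cone fiber terminal is a circular disc (diameter about seven
#' field units) with a continuous center position, a retinal origin `u`,
#' and baseline/current amounts of its two guidance sensors: EphA
#' receptors (`R_F`) and ephrin-A ligands (`L_F`). Baselines follow the
#' retinal countergradients of [retinal_sensor_levels()]; an EphA3
#' knock-in adds `knockin_R` receptor and reduces the axonal ligand
#' reciprocally, `L_F0 / (1 + R_ki / R_F0)`.
#'
#' @param u retinal origin in `[0, 1]` (0 nasal, 1 temporal).
#' @param x,y center position in field units.
#' @param params [model_params()] list (supplies `retinal_gamma`).
#' @param knockin_R added receptor `R_ki` (0 for wild type).
#' @param deflect common multiplicative deflection applied to both current
#'   sensor levels (tectal-entry scenarios use 30); baselines are kept, so
#'   the resetting force relaxes the deflection away.
#' @param mobile logical; immobile terminals (resident fibers) contribute
#'   cue fields but neither move nor adapt.
#' @return One-row data.frame with the terminal state.
#' @examples
#' fiber_terminal(0.5, x = 25.3, y = 4.1)
#' @export
fiber_terminal <- function(u, x, y, params = model_params(), knockin_R = 0,
                           deflect = 1, mobile = TRUE) {
  base <- retinal_sensor_levels(u, params$retinal_gamma)
  R0 <- base$R_F0 + knockin_R
  L0 <- if (knockin_R > 0) base$L_F0 / (1 + knockin_R / base$R_F0) else
    base$L_F0
  data.frame(origin_u = u, x = x, y = y, R_F0 = R0, L_F0 = L0,
             R_F = deflect * R0, L_F = deflect * L0,
             knockin_R = knockin_R, mobile = mobile,
             class = if (knockin_R > 0) "ki" else "wt",
             stringsAsFactors = FALSE)
}

#' Gaussian footprint of a terminal on the unit-square lattice
#'
#' Weights are a truncated 2D Gaussian profile (`sigma = sigma_frac *
#' radius`) evaluated at the centers of the unit squares whose centers lie
#' within the terminal disc, normalised to peak weight 1. Sensor amounts
#' are surface *densities*: the per-square density is `weight * R_F` (or
#' `L_F`), so the square under the disc center carries about the full
#' sensor density and it competes one-to-one with the target cue level --
#' the semantics implied by the reduced potential
#' `D = |ln(1/(L_T/L_F + 1))|` that the full equation collapses to for a
#' single axon on homogeneous ephrin (see the package vignette for why
#' sum-normalised weights would contradict it). Squares outside the field
#' are dropped without renormalisation: a disc hanging over the field edge
#' presents less total sensor, its local density is unchanged.
#'
#' @param terminal one-row terminal data.frame (or list with `x`, `y`).
#' @param field a [build_target_field()] object.
#' @param params [model_params()] (radius and `sigma_frac`).
#' @return data.frame with 0-based square indices `ix`, `iy` and `weight`;
#'   zero rows (with a warning) if the disc misses the field entirely.
#' @examples
#' f <- build_target_field(50, 8, gradient_spec("none"),
#'                         gradient_spec("none"))
#' fp <- terminal_footprint(fiber_terminal(0.5, 25.2, 4.4), f)
#' max(fp$weight)  # 1 at the disc center
#' @export
terminal_footprint <- function(terminal, field, params = model_params()) {
  radius <- params$radius
  sigma <- params$sigma_frac * radius
  cx <- terminal$x; cy <- terminal$y
  r <- ceiling(radius) + 1
  g <- expand.grid(dx = -r:r, dy = -r:r)
  ox <- g$dx + 0.5 - (cx - floor(cx))
  oy <- g$dy + 0.5 - (cy - floor(cy))
  d2 <- ox^2 + oy^2
  keep <- d2 <= radius^2
  ix <- floor(cx) + g$dx[keep]
  iy <- floor(cy) + g$dy[keep]
  w <- exp(-d2[keep] / (2 * sigma^2))
  infield <- ix >= 0 & ix < field$width & iy >= 0 & iy < field$height
  if (!any(infield)) {
    warning("terminal footprint lies entirely outside the field")
    return(data.frame(ix = integer(), iy = integer(), weight = numeric()))
  }
  ix <- ix[infield]; iy <- iy[infield]; w <- w[infield]
  data.frame(ix = as.integer(ix), iy = as.integer(iy),
             weight = w / max(exp(-d2[keep] / (2 * sigma^2))))
}

# per-square cue densities contributed by a set of terminals
fiber_density_fields <- function(terminals, field, params = model_params()) {
  Lf <- field$resident_L
  Rf <- field$resident_R
  if (!is.null(terminals) && nrow(terminals)) {
    for (i in seq_len(nrow(terminals))) {
      fp <- terminal_footprint(terminals[i, ], field, params)
      for (k in seq_len(nrow(fp))) {
        Lf[fp$ix[k] + 1, fp$iy[k] + 1] <-
          Lf[fp$ix[k] + 1, fp$iy[k] + 1] + fp$weight[k] * terminals$L_F[i]
        Rf[fp$ix[k] + 1, fp$iy[k] + 1] <-
          Rf[fp$ix[k] + 1, fp$iy[k] + 1] + fp$weight[k] * terminals$R_F[i]
      }
    }
  }
  list(L_f = Lf, R_f = Rf)
}

#' Guidance potential D
#'
#' The guidance potential of a terminal is the absolute log-ratio of total
#' reverse to total forward signaling summed over its footprint squares x:
#' \deqn{D = \left| \ln \frac{\sum_x L_F(x)\,[R_T(x) + R_F(x) + C R_f(x)]}
#'                        {\sum_x R_F(x)\,[L_T(x) + L_F(x) + C L_f(x)]}
#'       \right|}
#' where `L_F(x)`, `R_F(x)` are the terminal's own per-square sensor
#' densities (footprint weight times sensor amount), `R_f`, `L_f` the
#' summed densities of all *other* terminals (plus resident fields), and
#' `C` the fiber-fiber weight. `D >= 0`, with `D = 0` exactly when total
#' reverse equals total forward signaling -- the terminal has arrived.
#'
#' This is the plain R reference implementation; the simulation loop uses
#' an equivalent compiled path, and the two are cross-checked in the test
#' suite.
#'
#' @param terminal one-row terminal data.frame.
#' @param field a [build_target_field()] object.
#' @param others data.frame of the remaining terminals (or `NULL`).
#' @param C fiber-fiber interaction weight (see [fiber_weight()]).
#' @param params [model_params()].
#' @return Non-negative scalar; `Inf` (with a warning) if one signalling
#'   channel vanishes entirely.
#' @examples
#' # naive terminal in front of a homogeneous ephrin-A field:
#' f <- build_target_field(10, 1, gradient_spec("uniform", level = 4),
#'                         gradient_spec("none"))
#' t1 <- fiber_terminal(0.5, 5.5, 0.5, model_params(radius = 0.4))
#' guidance_potential(t1, f, params = model_params(radius = 0.4)) # ln 5
#' @export
guidance_potential <- function(terminal, field, others = NULL, C = 0,
                               params = model_params()) {
  fp <- terminal_footprint(terminal, field, params)
  if (!nrow(fp)) return(Inf)
  dens <- fiber_density_fields(others, field, params)
  idx <- cbind(fp$ix + 1, fp$iy + 1)
  lf <- fp$weight * terminal$L_F
  rf <- fp$weight * terminal$R_F
  num <- sum(lf * (field$R_T[idx] + rf + C * dens$R_f[idx]))
  den <- sum(rf * (field$L_T[idx] + lf + C * dens$L_f[idx]))
  if (num <= 0 || den <= 0) {
    warning("one signalling channel is zero; guidance potential undefined")
    return(Inf)
  }
  abs(log(num / den))
}

#' Adaptation coefficient a(i)
#'
#' Computed from the recent history of the guidance potential with weights
#' that increase linearly toward the most recent value:
#' \deqn{a = 1 + \ln\!\left(1 + \mu \frac{\sum_{k=1}^h k\,D_k}{\sum_{k=1}^h k}\right)}
#' where \eqn{D_h} is the newest entry. Histories shorter than `h` are
#' padded with zeros at the old end (terminals begin unadapted), so
#' `a >= 1` always and `a` is non-decreasing in every history entry.
#'
#' @param history numeric vector of recent `D` values, oldest first,
#'   length at most `h`.
#' @param params [model_params()] (`mu` and `h`).
#' @return Scalar adaptation coefficient.
#' @examples
#' adaptation_coefficient(rep(0, 10))          # 1
#' adaptation_coefficient(2)                   # single recent spike
#' @export
adaptation_coefficient <- function(history, params = model_params()) {
  h <- params$h
  if (length(history) > h)
    stop("history longer than the window h = ", h)
  if (any(history < 0)) stop("guidance potentials in history must be >= 0")
  d <- c(rep(0, h - length(history)), history)
  k <- seq_len(h)
  1 + log1p(params$mu * sum(k * d) / sum(k))
}

#' Hookian resetting force
#'
#' `f = lambda * (S0 - S)`: opposes any deflection of a sensor from its
#' baseline and thereby re-sensitizes terminals once the driving guidance
#' potential subsides.
#'
#' @param S current sensor amount.
#' @param S0 baseline sensor amount.
#' @param params [model_params()] (`lambda`).
#' @return Signed force.
#' @export
resetting_force <- function(S, S0, params = model_params()) {
  params$lambda * (S0 - S)
}

#' Apply one co-adaptation update
#'
#' The same coefficient `a` multiplies both sensor species in the same
#' iteration, and the resetting force pulls each back to its baseline:
#' `S <- a * S + lambda * (S0 - S)`. Because both channels share `a` and
#' start at baseline, the ratio `R_F / L_F` -- the terminal's topographic
#' identity -- is invariant over time; only the common relative deflection
#' `g(i) = S(i)/S(0)` changes.
#'
#' @param terminal one-row terminal data.frame.
#' @param a adaptation coefficient (`>= 1`).
#' @param params [model_params()].
#' @return The terminal with updated `R_F`, `L_F`.
#' @export
apply_coadaptation <- function(terminal, a, params = model_params()) {
  stopifnot(a >= 1)
  terminal$R_F <- max(a * terminal$R_F +
                        params$lambda * (terminal$R_F0 - terminal$R_F),
                      params$sensor_floor)
  terminal$L_F <- max(a * terminal$L_F +
                        params$lambda * (terminal$L_F0 - terminal$L_F),
                      params$sensor_floor)
  terminal
}

#' Apply one canonical-adaptation update
#'
#' The comparison variant: each channel independently relaxes toward the
#' footprint-weighted local target cue of the *matching* species
#' (`R_F` toward local `R_T`, `L_F` toward local `L_T`), with rate
#' `kappa` and no coupling between channels. This destroys the sensor
#' ratio and with it topographic identity.
#'
#' @param terminal one-row terminal data.frame.
#' @param local_R_T,local_L_T footprint-weighted mean target cues at the
#'   terminal's position.
#' @param params [model_params()].
#' @return The terminal with updated `R_F`, `L_F`.
#' @export
apply_canonical_adaptation <- function(terminal, local_R_T, local_L_T,
                                       params = model_params()) {
  terminal$R_F <- max(terminal$R_F + params$kappa * (local_R_T - terminal$R_F),
                      params$sensor_floor)
  terminal$L_F <- max(terminal$L_F + params$kappa * (local_L_T - terminal$L_F),
                      params$sensor_floor)
  terminal
}

#' Propose and execute one biased random-walk step
#'
#' Candidate positions are the four unit displacements of the current
#' center. Each admissible candidate (staying within the field) is chosen
#' with probability proportional to
#' `base_prob(direction) * exp(-beta * D(candidate))`. Base probabilities
#' are uniform (1/4) except where the forward walk bias applies (cue-free
#' ground under the terminal center, or the whole arena when
#' `q_x_scope = "everywhere"`): there the forward step gets `q_x` and the
#' remaining mass is split equally over the other three directions. Moves
#' leaving the field are rejected and the probability mass renormalised;
#' if no candidate is admissible the terminal stays.
#'
#' @param terminal one-row terminal data.frame.
#' @param field a [build_target_field()] object.
#' @param others data.frame of other terminals (or `NULL`).
#' @param C fiber-fiber weight.
#' @param params [model_params()].
#' @return The terminal, moved.
#' @export
propose_and_move <- function(terminal, field, others = NULL, C = 0,
                             params = model_params()) {
  dirs <- cbind(x = c(1, -1, 0, 0), y = c(0, 0, 1, -1))
  cx <- floor(terminal$x) + 1; cy <- floor(terminal$y) + 1
  cue_free <- identical(params$q_x_scope, "everywhere") ||
    cx < 1 || cx > field$width || cy < 1 || cy > field$height ||
    (field$L_T[cx, cy] + field$R_T[cx, cy]) < 1e-9
  base <- if (cue_free)
    c(params$q_x, rep((1 - params$q_x) / 3, 3)) else rep(0.25, 4)
  w <- numeric(4)
  Dc <- rep(Inf, 4)
  for (d in 1:4) {
    cand <- terminal
    cand$x <- terminal$x + dirs[d, "x"]
    cand$y <- terminal$y + dirs[d, "y"]
    if (cand$x < 0 || cand$x >= field$width ||
        cand$y < 0 || cand$y >= field$height) next
    Dc[d] <- suppressWarnings(
      guidance_potential(cand, field, others, C, params))
    w[d] <- base[d]
  }
  fin <- is.finite(Dc)
  if (!any(w > 0)) return(terminal)
  mn <- if (any(fin)) min(Dc[fin]) else 0
  w <- w * exp(-params$beta * (Dc - mn))
  w[!is.finite(w)] <- 0
  if (sum(w) <= 0) return(terminal)
  pick <- sample.int(4, 1, prob = w)
  terminal$x <- terminal$x + dirs[pick, "x"]
  terminal$y <- terminal$y + dirs[pick, "y"]
  terminal
}
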