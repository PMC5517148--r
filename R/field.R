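#' Guidance-cue gradient specification
#'
#' Describes the distribution of one guidance cue along the x-axis of a
#' target field (or along the naso-temporal axis of the retina). Four
#' shapes are supported: exponential countergradients (`exponential_counter`,
#' used for tectal innervation and mapping), `step` functions (used for the
#' in-silico gap assays), a homogeneous `uniform` level, and `none` (cue
#' free).
#'
#' For `exponential_counter` the cue evaluates to
#' `level * exp(s * steepness * (x/axis_length - 1/2))` with `s = +1`
#' (`slope = "increasing"`, e.g. tectal ephrin-A, posterior high) or
#' `s = -1` (`slope = "decreasing"`, e.g. tectal EphA, anterior high).
#' For `step`, `segments` is a list of `c(from, to, level)` triples on the
#' x-axis; the cue is `level` on `[from, to)` and 0 elsewhere, and the
#' intervals must not overlap.
#'
#' @param shape one of `"exponential_counter"`, `"step"`, `"uniform"`,
#'   `"none"`.
#' @param steepness exponent scale (gamma) for exponential gradients.
#' @param level plateau value for `uniform`; amplitude for exponentials.
#' @param segments list of `c(from, to, level)` for `step`.
#' @param slope `"increasing"` or `"decreasing"` (exponentials only).
#' @param axis_length length over which the exponential is normalised;
#'   defaults to the field width at evaluation time.
#' @return An object of class `gradient_spec`.
#' @examples
#' gradient_spec("exponential_counter", steepness = 4, slope = "increasing")
#' gradient_spec("step", segments = list(c(20, 60, 4)))
#' @export
gradient_spec <- function(shape = c("exponential_counter", "step", "uniform",
                                    "none"),
                          steepness = 4, level = 1, segments = NULL,
                          slope = c("increasing", "decreasing"),
                          axis_length = NULL) {
  shape <- match.arg(shape)
  slope <- match.arg(slope)
  stopifnot(steepness > 0, level >= 0)
  if (shape == "step") {
    if (is.null(segments) || !length(segments))
      stop("step gradients need at least one c(from, to, level) segment")
    segs <- lapply(segments, function(s) {
      if (length(s) != 3 || s[2] <= s[1] || s[3] < 0)
        stop("invalid step segment; expected c(from, to, level) with ",
             "to > from and level >= 0")
      as.numeric(s)
    })
    # non-overlap check
    o <- order(vapply(segs, `[`, 0, 1))
    segs <- segs[o]
    if (length(segs) > 1) {
      from <- vapply(segs, `[`, 0, 1)
      to <- vapply(segs, `[`, 0, 2)
      if (any(from[-1] < to[-length(to)]))
        stop("step segments overlap")
    }
    segments <- segs
  }
  structure(list(shape = shape, steepness = steepness, level = level,
                 segments = segments, slope = slope,
                 axis_length = axis_length),
            class = "gradient_spec")
}

# evaluate a gradient_spec at x positions (field units)
eval_gradient <- function(spec, x, axis_length) {
  stopifnot(inherits(spec, "gradient_spec"))
  if (!is.null(spec$axis_length)) axis_length <- spec$axis_length
  switch(spec$shape,
    none = rep(0, length(x)),
    uniform = rep(spec$level, length(x)),
    exponential_counter = {
      s <- if (spec$slope == "increasing") 1 else -1
      spec$level * exp(s * spec$steepness * (x / axis_length - 0.5))
    },
    step = {
      v <- numeric(length(x))
      for (seg in spec$segments) {
        inside <- x >= seg[1] & x < seg[2]
        v[inside] <- seg[3]
      }
      v
    })
}

#' Build a rectangular target field
#'
#' The projection target is a rectangular array of `width x height` unit
#' squares carrying the guidance cues `L_T` (target ephrin-A) and `R_T`
#' (target EphA) along the x-axis; cues are constant along y. Cue values
#' are evaluated at each unit square's x-center. Mapping scenarios use a
#' 50 x 8 field, gap scenarios 200 x 8. The square with index `(ix, iy)`
#' (0-based) spans `[ix, ix+1) x [iy, iy+1)`.
#'
#' @param width,height field extent in unit squares.
#' @param L_spec,R_spec [gradient_spec()] objects for ephrin-A and EphA.
#' @return Object of class `target_field`: a list with `width`, `height`,
#'   matrices `L_T`, `R_T` (width x height) and resident-fiber cue fields
#'   `resident_L`, `resident_R` (zero unless a scenario adds immobile
#'   resident fibers).
#' @examples
#' f <- build_target_field(50, 8,
#'   gradient_spec("exponential_counter", slope = "increasing"),
#'   gradient_spec("exponential_counter", slope = "decreasing"))
#' f$L_T[1, 1] < f$L_T[50, 1]  # ephrin-A rises toward posterior
#' @export
build_target_field <- function(width, height, L_spec, R_spec) {
  stopifnot(width >= 1, height >= 1)
  width <- as.integer(width); height <- as.integer(height)
  xc <- seq_len(width) - 0.5
  L <- matrix(eval_gradient(L_spec, xc, width), nrow = width, ncol = height)
  R <- matrix(eval_gradient(R_spec, xc, width), nrow = width, ncol = height)
  if (any(L < 0) || any(R < 0)) stop("cue values must be non-negative")
  structure(list(width = width, height = height, L_T = L, R_T = R,
                 resident_L = matrix(0, width, height),
                 resident_R = matrix(0, width, height)),
            class = "target_field")
}

#' @export
print.target_field <- function(x, ...) {
  cat(sprintf("<target_field %d x %d>  L_T in [%.3g, %.3g], R_T in [%.3g, %.3g]\n",
              x$width, x$height, min(x$L_T), max(x$L_T), min(x$R_T),
              max(x$R_T)))
  invisible(x)
}

#' Baseline sensor levels of a retinal fiber
#'
#' The retina bears exponential counter-distributions of the two sensor
#' species: EphA receptors `R_F0 = exp(gamma * (u - 1/2))` rise from nasal
#' (`u = 0`) to temporal (`u = 1`), ephrin-A ligands
#' `L_F0 = exp(-gamma * (u - 1/2))` run the opposite way. The ratio
#' `R_F0 / L_F0 = exp(2 * gamma * (u - 1/2))` is the fiber's topographic
#' identity.
#'
#' @param u naso-temporal retinal origin in `[0, 1]` (vectorised).
#' @param gamma gradient steepness (defaults to the global model value).
#' @return List with components `R_F0` and `L_F0`.
#' @examples
#' retinal_sensor_levels(0.5)           # symmetry point: R_F0 == L_F0
#' retinal_sensor_levels(1, gamma = 2)  # R_F0 = e, L_F0 = 1/e
#' @export
retinal_sensor_levels <- function(u, gamma = model_params()$retinal_gamma) {
  if (any(u < 0 | u > 1)) stop("retinal origin u must lie in [0, 1]")
  list(R_F0 = exp(gamma * (u - 0.5)), L_F0 = exp(-gamma * (u - 0.5)))
}
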