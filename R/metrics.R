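# Quantitative summaries of simulation results. All metrics are pure
# functions of a finished `coadapt_sim` (they never mutate or re-run it).

ideal_position <- function(u, width) (1 - u) * width

#' Summarise topographic order of a mapping run
#'
#' The mapping plot shows the anterior-posterior final position of every
#' terminal against its naso-temporal retinal origin; perfect topography
#' puts all terminals on the main diagonal (temporal -> anterior). The
#' summary reports the Spearman rank correlation between origin and final
#' position (signed so that correct topography is positive), the fraction
#' of terminals within a tolerance band of the ideal diagonal
#' `x/W = 1 - u`, and the fraction of the field width covered by the final
#' positions.
#'
#' @param result a `coadapt_sim`.
#' @param tolerance half-width of the diagonal band as a fraction of the
#'   field width (default 0.1).
#' @param width field width; defaults to the extent recorded in the
#'   scenario hints.
#' @return List of class `mapping_summary` with `rank_correlation`
#'   (`NA` for fewer than 3 mobile terminals), `diagonal_fraction`,
#'   `coverage_span`, `tolerance` and the plotted `pairs`.
#' @examples
#' sc <- mapping_scenario(n = 12)
#' s <- simulate(sc, params = list(n_iterations = 500L))
#' mapping_summary(s)$rank_correlation
#' @export
mapping_summary <- function(result, tolerance = 0.1, width = NULL) {
  stopifnot(inherits(result, "coadapt_sim"))
  fin <- result$final[result$final$mobile, ]
  if (is.null(width))
    width <- if (!is.null(result$hints$target_end))
      result$hints$target_end else max(fin$x)
  rho <- if (nrow(fin) >= 3)
    suppressWarnings(stats::cor(fin$origin_u, width - fin$x,
                                method = "spearman")) else NA_real_
  ideal <- ideal_position(fin$origin_u, width)
  diag_frac <- mean(abs(fin$x - ideal) / width <= tolerance)
  span <- (max(fin$x) - min(fin$x)) / width
  structure(list(rank_correlation = rho, diagonal_fraction = diag_frac,
                 coverage_span = span, tolerance = tolerance,
                 pairs = data.frame(origin_u = fin$origin_u, x = fin$x)),
            class = "mapping_summary")
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat(sprintf("mapping: rho = %.3f, diagonal fraction = %.2f (tol %.2f), span = %.2f\n",
              x$rank_correlation, x$diagonal_fraction, x$tolerance,
              x$coverage_span))
  invisible(x)
}

#' Fraction of terminals stopping in front of a boundary
#'
#' A terminal counts as stopping if its running maximum x position never
#' exceeded `boundary + penetration` during the whole run; entering the
#' leading `penetration` units (default 2) of a cue field does not count
#' as crossing it.
#'
#' @param result a `coadapt_sim`.
#' @param boundary x coordinate of the field boundary; defaults to
#'   `hints$second_field_start` (adapted gap assays) and falls back to
#'   `hints$first_field_start` (naive assays).
#' @param penetration tolerated penetration depth in field units.
#' @return Fraction in `[0, 1]`.
#' @export
stopping_fraction <- function(result, boundary = NULL, penetration = 2) {
  stopifnot(inherits(result, "coadapt_sim"))
  if (is.null(boundary))
    boundary <- if (!is.null(result$hints$second_field_start))
      result$hints$second_field_start else result$hints$first_field_start
  if (is.null(boundary)) stop("no boundary given and none in the hints")
  mob <- result$final$mobile
  mean(result$max_x[mob] <= boundary + penetration)
}

#' Fraction of terminals that entered the target field
#'
#' @param result a `coadapt_sim` from a scenario with a pre-target
#'   corridor.
#' @param target_start entry threshold; defaults to `hints$target_start`.
#' @return Fraction of mobile terminals whose final x position lies at or
#'   beyond the threshold.
#' @export
entry_fraction <- function(result, target_start = NULL) {
  stopifnot(inherits(result, "coadapt_sim"))
  if (is.null(target_start)) target_start <- result$hints$target_start
  if (is.null(target_start)) stop("no entry threshold available")
  fin <- result$final[result$final$mobile, ]
  if (!nrow(fin)) stop("no mobile terminals in result")
  mean(fin$x >= target_start)
}

#' Mean displacement of wild-type and knock-in fibers
#'
#' Signed mean deviation of the final x position from the unperturbed
#' ideal diagonal, computed separately for the `"wt"` and `"ki"` classes
#' of a knock-in simulation. Positive values are posterior displacements.
#'
#' @param result a `coadapt_sim` from a [knockin_scenario()].
#' @return List with `mean_shift_wt` and `mean_shift_ki` (`NA` if the run
#'   contains no knock-in fibers).
#' @export
knockin_displacement <- function(result) {
  stopifnot(inherits(result, "coadapt_sim"))
  fin <- result$final[result$final$mobile, ]
  if (!all(c("wt") %in% fin$class))
    stop("result carries no wild-type class labels")
  width <- if (!is.null(result$hints$target_end)) result$hints$target_end
    else max(fin$x)
  dev <- fin$x - ideal_position(fin$origin_u, width)
  list(mean_shift_wt = mean(dev[fin$class == "wt"]),
       mean_shift_ki = if (any(fin$class == "ki"))
         mean(dev[fin$class == "ki"]) else NA_real_)
}

#' Flat metric report for a simulation
#'
#' Convenience collector used by the command-line interface: computes the
#' metrics that apply to the scenario type and returns them as a flat
#' named list (suitable for JSON/CSV export), keyed by scenario tag and
#' seed.
#'
#' @param result a `coadapt_sim`.
#' @return Named list.
#' @export
metric_report <- function(result) {
  out <- list(tag = result$tag, seed = result$params$seed)
  ms <- mapping_summary(result)
  out$rank_correlation <- ms$rank_correlation
  out$diagonal_fraction <- ms$diagonal_fraction
  out$coverage_span <- ms$coverage_span
  if (!is.null(result$hints$first_field_start) ||
      !is.null(result$hints$second_field_start))
    out$stopping_fraction <- stopping_fraction(result)
  if (!is.null(result$hints$target_start) && result$hints$target_start > 0)
    out$entry_fraction <- entry_fraction(result)
  if (any(result$final$class == "ki")) {
    kd <- knockin_displacement(result)
    out$mean_shift_wt <- kd$mean_shift_wt
    out$mean_shift_ki <- kd$mean_shift_ki
  }
  out
}
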