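# Scenario builders: target field + terminal population + parameter
# overrides for each simulated experiment. Builders are deterministic given
# their `seed` argument (used only for initial placement); the walk itself
# is seeded by the simulation parameters.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (had) assign(".Random.seed", old, envir = .GlobalEnv)
            else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
    set.seed(seed)
  }
  force(code)
}

new_scenario <- function(field, terminals, params_overrides, hints, tag,
                         builder, args) {
  stopifnot(inherits(field, "target_field"), nrow(terminals) >= 1)
  bad <- vapply(hints, function(h) is.numeric(h) &&
                  (h < 0 || h > field$width), FALSE)
  if (any(bad)) stop("analysis hint outside the field: ",
                     paste(names(hints)[bad], collapse = ", "))
  structure(list(field = field, terminals = terminals,
                 params_overrides = params_overrides, hints = hints,
                 tag = tag, call_info = list(builder = builder, args = args)),
            class = "coadapt_scenario")
}

#' @export
print.coadapt_scenario <- function(x, ...) {
  cat(sprintf("<coadapt_scenario '%s'>  field %d x %d, %d terminals\n",
              x$tag, x$field$width, x$field$height, nrow(x$terminals)))
  invisible(x)
}

# stack fiber_terminal() rows for a vector of origins/positions
make_terminals <- function(u, x, y, params, knockin_R = 0, deflect = 1,
                           mobile = TRUE) {
  do.call(rbind, lapply(seq_along(u), function(i)
    fiber_terminal(u[i], x[i], y[i], params,
                   knockin_R = if (length(knockin_R) > 1) knockin_R[i] else
                     knockin_R,
                   deflect = deflect,
                   mobile = if (length(mobile) > 1) mobile[i] else mobile)))
}

graded_field <- function(width, height, gamma, axis_length = NULL) {
  build_target_field(width, height,
    gradient_spec("exponential_counter", steepness = gamma,
                  slope = "increasing", axis_length = axis_length),
    gradient_spec("exponential_counter", steepness = gamma,
                  slope = "decreasing", axis_length = axis_length))
}

#' Topographic mapping scenario
#'
#' The standard mapping experiment: a 50 x 8 target field carrying
#' exponential countergradients of ephrin-A (posterior high) and EphA
#' (anterior high); `n` terminals sampled equally from the naso-temporal
#' retinal axis, initially placed uniformly at random on the field; the
#' fiber-fiber weight ramp active. With co-adaptation the population finds
#' its topographically ordered positions; with canonical adaptation the
#' map disintegrates.
#'
#' @param n number of terminals.
#' @param adaptation_mode `"coadaptation"`, `"canonical"` or `"none"`.
#' @param seed seed for the initial placement.
#' @return A `coadapt_scenario`.
#' @examples
#' mapping_scenario(n = 20)
#' @export
mapping_scenario <- function(n = 200,
                             adaptation_mode = c("coadaptation", "canonical",
                                                 "none"),
                             seed = 1L) {
  adaptation_mode <- match.arg(adaptation_mode)
  stopifnot(n >= 1)
  p <- model_params()
  field <- graded_field(50, 8, p$retinal_gamma)
  u <- (seq_len(n) - 0.5) / n
  term <- with_seed(seed, make_terminals(
    u, x = runif(n, 0, 50), y = runif(n, 0, 8), params = p))
  new_scenario(field, term,
               list(n_terminals = as.integer(n),
                    adaptation_mode = adaptation_mode),
               hints = list(target_start = 0, target_end = 50),
               tag = paste0("mapping_", adaptation_mode),
               builder = "mapping_scenario",
               args = list(n = n, adaptation_mode = adaptation_mode,
                           seed = seed))
}

#' In-silico gap assay scenario
#'
#' Two rectangular step fields of one cue each (level 4), separated by a
#' cue-free gap, on a 200 x 8 field. Naive terminals start on a cue-free
#' corridor in front of the first field and are scored at the first
#' boundary; adapted terminals start on the first field (which abuts the
#' arena wall so they must adapt before reaching the gap) and are scored
#' at the second boundary. The fiber-fiber ramp is switched off (`C0 = 1`)
#' and the cue-free walk carries the forward bias `q_x = 0.37`. Defaults
#' `n = 12`, `i = 2000`.
#'
#' Terminals originate from mid-retina (`origin_u = 0.5`) by default, so
#' their two sensor baselines are equal and a field of ephrin-A repels
#' naive terminals exactly as strongly as a field of EphA; single- and
#' double-cue assays are then directly comparable, which is the structure
#' of the double-cue prediction. Double-cue assays combine different cues
#' on either side of the gap.
#'
#' Adapted populations start with both sensors deflected by a common
#' factor (default 30, the same adapted deflection used in the
#' tectal-entry simulations): they represent axons that have grown on the
#' first cue field long enough to reach their co-adaptation equilibrium
#' before the assay window begins. The deflection then decays under the
#' resetting force while the terminal crosses the cue-free gap, which is
#' what makes stopping return with increasing gap width.
#'
#' @param first_cue,second_cue `"ephrin"` or `"Eph"`.
#' @param gap gap width in field units (the standard panels use 20, 40, 100).
#' @param naive logical; see above.
#' @param adapted_deflection initial common sensor deflection of adapted
#'   terminals (ignored for naive populations).
#' @param origin_u retinal origin of the assay population.
#' @param seed placement seed.
#' @return A `coadapt_scenario` whose hints carry the field boundaries.
#' @examples
#' gap_assay_scenario("ephrin", "ephrin", gap = 40)
#' @export
gap_assay_scenario <- function(first_cue = c("ephrin", "Eph"),
                               second_cue = c("ephrin", "Eph"), gap = 20,
                               naive = FALSE, adapted_deflection = 30,
                               origin_u = 0.5, seed = 1L) {
  first_cue <- match.arg(first_cue)
  second_cue <- match.arg(second_cue)
  stopifnot(gap >= 0)
  W <- 200L; H <- 8L
  field_w <- 40
  corridor <- if (naive) 20 else 0
  f1 <- corridor; f1e <- f1 + field_w
  f2 <- f1e + gap; f2e <- f2 + field_w
  if (f2e > W) stop("gap too wide for the 200-unit field")
  segs_L <- list(); segs_R <- list()
  if (first_cue == "ephrin") segs_L <- c(segs_L, list(c(f1, f1e, 4)))
  else segs_R <- c(segs_R, list(c(f1, f1e, 4)))
  if (second_cue == "ephrin") segs_L <- c(segs_L, list(c(f2, f2e, 4)))
  else segs_R <- c(segs_R, list(c(f2, f2e, 4)))
  Ls <- if (length(segs_L)) gradient_spec("step", segments = segs_L) else
    gradient_spec("none")
  Rs <- if (length(segs_R)) gradient_spec("step", segments = segs_R) else
    gradient_spec("none")
  field <- build_target_field(W, H, Ls, Rs)
  p <- model_params()
  n <- 12L
  u <- rep(origin_u, n)
  term <- with_seed(seed, {
    x0 <- if (naive) runif(n, 0, corridor) else runif(n, f1e - 20, f1e)
    make_terminals(u, x = x0, y = runif(n, 0, H), params = p,
                   deflect = if (naive) 1 else adapted_deflection)
  })
  new_scenario(field, term,
               list(n_terminals = n, n_iterations = 2000L, C0 = 1,
                    ramp_on = FALSE, q_x_scope = "everywhere"),
               hints = list(first_field_start = f1, first_field_end = f1e,
                            second_field_start = f2, second_field_end = f2e,
                            gap = gap),
               tag = sprintf("gap_%s_%s_%d%s", first_cue, second_cue, gap,
                             if (naive) "_naive" else ""),
               builder = "gap_assay_scenario",
               args = list(first_cue = first_cue, second_cue = second_cue,
                           gap = gap, naive = naive,
                           adapted_deflection = adapted_deflection,
                           origin_u = origin_u, seed = seed))
}

#' Tectal-entry scenario
#'
#' A graded 50 x 8 tectal target preceded by a 30-unit cue-free corridor;
#' terminals are placed on the corridor directly in front of the target.
#' The adapted population has both sensors deflected by a common factor
#' (default 30), which desensitizes the terminals against the steep
#' reverse-signaling boundary at the target entrance while leaving their
#' ephrin-A/EphA ratio -- and hence their mapping -- untouched;
#' `deflection = 1` gives the non-adapted control that largely fails to
#' enter. Fiber-fiber interactions are excluded (`C0 = 0`), mirroring the
#' experimental finding that they are required neither for target entry
#' nor for mapping.
#'
#' While a terminal stands on the cue-free corridor its sensors are held
#' constant (`hold_off_target`), modeling the pre-adapting factor the
#' co-adaptation account postulates in the optic tract: the tract keeps
#' the arriving population desensitized, and sensor dynamics (resetting
#' and re-adaptation) begin once the terminal is on the target.
#'
#' The target gradients carry an anterior margin: the cue levels at the
#' entry edge lie `gamma * margin / 50` log-units above the balance point
#' of the most temporal fiber, so no axon's target position sits exactly
#' on the edge and every naive fiber faces a positive reverse-signaling
#' barrier there (the map inside is shifted posteriorly by the margin;
#' rank order is unaffected). Without the margin, fibers whose balance
#' lies at the anterior pole would walk in regardless of adaptation.
#'
#' @param n number of terminals.
#' @param deflection common initial multiplier of `R_F` and `L_F`.
#' @param anterior_margin gradient offset in field units (see above).
#' @param seed placement seed.
#' @return A `coadapt_scenario`; `hints$target_start` is the entry
#'   threshold.
#' @examples
#' tectal_entry_scenario(n = 20, deflection = 30)
#' @export
tectal_entry_scenario <- function(n = 200, deflection = 30,
                                  anterior_margin = 10, seed = 1L) {
  stopifnot(deflection >= 1, n >= 1, anterior_margin >= 0)
  p <- model_params()
  corridor <- 30
  target_w <- 50L
  W <- as.integer(corridor + target_w); H <- 8L
  # graded cues only on [corridor, W): evaluate the 50-unit gradient there
  xc <- seq_len(W) - 0.5
  on_target <- xc >= corridor
  Lv <- Rv <- numeric(W)
  off <- anterior_margin / target_w
  Lv[on_target] <- exp(p$retinal_gamma *
                         ((xc[on_target] - corridor) / target_w - 0.5 - off))
  Rv[on_target] <- exp(-p$retinal_gamma *
                         ((xc[on_target] - corridor) / target_w - 0.5 - off))
  field <- build_target_field(W, H, gradient_spec("none"),
                              gradient_spec("none"))
  field$L_T <- matrix(Lv, W, H)
  field$R_T <- matrix(Rv, W, H)
  u <- (seq_len(n) - 0.5) / n
  # "placed in front of the target": directly before the entrance, so the
  # initial deflection has not decayed away before terminals meet the
  # reverse-signaling boundary
  term <- with_seed(seed, make_terminals(
    u, x = runif(n, corridor - 10, corridor - 0.5), y = runif(n, 0, H),
    params = p, deflect = deflection))
  new_scenario(field, term,
               list(n_terminals = as.integer(n), C0 = 0, ramp_on = FALSE,
                    hold_off_target = TRUE),
               hints = list(target_start = corridor, target_end = W),
               tag = sprintf("entry_deflect%g", deflection),
               builder = "tectal_entry_scenario",
               args = list(n = n, deflection = deflection,
                           anterior_margin = anterior_margin, seed = seed))
}

#' EphA3 knock-in scenario
#'
#' Mapping scenario in which every second fiber carries an added receptor
#' amount `R_ki` (heterozygous knock-in: `R_ki = 2`; homozygous:
#' `R_ki = 4`); the axonal ligand on knock-in fibers is reduced
#' reciprocally to the added receptor, `L_F0 / (1 + R_ki / R_F0)`.
#' `R_ki = 0` reduces to the plain mapping scenario.
#'
#' @param R_ki added receptor on knock-in fibers.
#' @param n number of terminals.
#' @param seed placement seed.
#' @return A `coadapt_scenario`; terminal `class` labels are `"wt"`/`"ki"`.
#' @export
knockin_scenario <- function(R_ki = 2, n = 200, seed = 1L) {
  stopifnot(R_ki >= 0)
  p <- model_params()
  field <- graded_field(50, 8, p$retinal_gamma)
  u <- (seq_len(n) - 0.5) / n
  ki <- rep(c(0, R_ki), length.out = n)
  term <- with_seed(seed, make_terminals(
    u, x = runif(n, 0, 50), y = runif(n, 0, 8), params = p,
    knockin_R = ki))
  new_scenario(field, term,
               list(n_terminals = as.integer(n)),
               hints = list(target_start = 0, target_end = 50),
               tag = sprintf("knockin_Rki%g", R_ki),
               builder = "knockin_scenario",
               args = list(R_ki = R_ki, n = n, seed = seed))
}

#' Innervation-plasticity scenarios
#'
#' Builders for the classical regeneration-style experiments:
#' \describe{
#'   \item{single_fibers}{one fiber of random retinal origin on the full
#'     graded field (pool many runs with [single_fiber_ensemble()]).}
#'   \item{expansion}{100 fibers from the nasal half-retina on a full
#'     field; with fiber-fiber interactions they eventually cover the
#'     whole tectum.}
#'   \item{no_expansion_remnants}{the same half-retinal population growing
#'     into a field still containing the immobile remnants of a previous
#'     full innervation; no expansion occurs.}
#'   \item{compression}{200 fibers from the whole retina on an anterior
#'     half-field (the 25 anterior units of the 50-unit gradient).}
#'   \item{mismatch}{100 nasal fibers on the anterior, non-matching,
#'     half-field.}
#'   \item{reversal}{100 nasal fibers growing into a field that already
#'     contains a properly mapped nasal projection; fiber-fiber
#'     interactions start early (`j = 2000`).}
#' }
#'
#' @param variant one of the names above.
#' @param seed placement seed.
#' @return A `coadapt_scenario`.
#' @export
innervation_scenario <- function(variant = c("single_fibers", "expansion",
                                             "no_expansion_remnants",
                                             "compression", "mismatch",
                                             "reversal"),
                                 seed = 1L) {
  variant <- match.arg(variant)
  p <- model_params()
  full <- function() graded_field(50, 8, p$retinal_gamma)
  half <- function() graded_field(25, 8, p$retinal_gamma, axis_length = 50)
  resident_pop <- function(u, field) {
    # immobile, properly mapped residents at their ideal positions
    W <- field$width
    x <- pmin(pmax((1 - u) * W, 0.5), W - 0.5) + 1e-3
    make_terminals(u, x = x, y = runif(length(u), 0, field$height),
                   params = p, mobile = FALSE)
  }
  sc <- with_seed(seed, switch(variant,
    single_fibers = {
      field <- full()
      u <- runif(1)
      term <- make_terminals(u, x = runif(1, 0, 50), y = runif(1, 0, 8),
                             params = p)
      list(field = field, term = term, ov = list(n_terminals = 1L, C0 = 1,
                                                 ramp_on = FALSE))
    },
    expansion = {
      field <- full()
      n <- 100
      u <- (seq_len(n) - 0.5) / n * 0.5          # nasal half
      term <- make_terminals(u, x = runif(n, 0, 50), y = runif(n, 0, 8),
                             params = p)
      list(field = field, term = term, ov = list(n_terminals = 100L))
    },
    no_expansion_remnants = {
      field <- full()
      n <- 100
      u <- (seq_len(n) - 0.5) / n * 0.5
      res_u <- (seq_len(200) - 0.5) / 200
      res <- resident_pop(res_u, field)
      term <- rbind(make_terminals(u, x = runif(n, 0, 50),
                                   y = runif(n, 0, 8), params = p), res)
      list(field = field, term = term,
           ov = list(n_terminals = as.integer(nrow(term))))
    },
    compression = {
      field <- half()
      n <- 200
      u <- (seq_len(n) - 0.5) / n
      term <- make_terminals(u, x = runif(n, 0, 25), y = runif(n, 0, 8),
                             params = p)
      list(field = field, term = term, ov = list(n_terminals = 200L))
    },
    mismatch = {
      field <- half()
      n <- 100
      u <- (seq_len(n) - 0.5) / n * 0.5
      term <- make_terminals(u, x = runif(n, 0, 25), y = runif(n, 0, 8),
                             params = p)
      list(field = field, term = term, ov = list(n_terminals = 100L))
    },
    reversal = {
      field <- full()
      n <- 100
      u <- (seq_len(n) - 0.5) / n * 0.5
      res <- resident_pop((seq_len(100) - 0.5) / 100 * 0.5, field)
      term <- rbind(make_terminals(u, x = runif(n, 0, 50),
                                   y = runif(n, 0, 8), params = p), res)
      list(field = field, term = term,
           ov = list(n_terminals = as.integer(nrow(term)),
                     j_onset = 2000L))
    }))
  new_scenario(sc$field, sc$term, sc$ov,
               hints = list(target_start = 0, target_end = sc$field$width),
               tag = paste0("innervation_", variant),
               builder = "innervation_scenario",
               args = list(variant = variant, seed = seed))
}

#' Pool independent single-fiber simulations
#'
#' Runs `n_runs` one-terminal simulations with random retinal origins and
#' pools the final positions, emulating repeated single-fiber labelling
#' experiments.
#'
#' @param n_runs number of independent runs.
#' @param params parameter overrides passed to every [simulate()] call.
#' @param seed base seed; run `k` uses `seed + k`.
#' @return data.frame with `origin_u` and final `x` per run.
#' @export
single_fiber_ensemble <- function(n_runs = 200, params = list(), seed = 1L) {
  res <- lapply(seq_len(n_runs), function(k) {
    sc <- innervation_scenario("single_fibers", seed = seed + k)
    s <- simulate(sc, params = utils::modifyList(list(seed = seed + k),
                                                 params))
    data.frame(origin_u = s$final$origin_u, x = s$final$x)
  })
  do.call(rbind, res)
}
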