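# simulation engine: determinism, equivalence with the R reference
# dynamics, ratio invariance, record plumbing

test_that("identical seed and scenario reproduce the result bit-identically", {
  sc <- mapping_scenario(n = 15, seed = 5)
  r1 <- simulate(sc, params = list(n_iterations = 400L, seed = 9),
                 record_stride = 50)
  r2 <- simulate(sc, params = list(n_iterations = 400L, seed = 9),
                 record_stride = 50)
  expect_identical(r1$final, r2$final)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$max_x, r2$max_x)
  r3 <- simulate(sc, params = list(n_iterations = 400L, seed = 10))
  expect_false(identical(r1$final$x, r3$final$x))
})

test_that("compiled sensor dynamics match the R reference operations", {
  # immobile terminals isolate the per-iteration adaptation pipeline:
  # D (Eq. 1) -> history -> a (Eq. 3) -> sensor update (Eqs. 2, 4),
  # sequential within-iteration order
  p <- model_params(C0 = 1.5, ramp_on = FALSE)
  f <- build_target_field(20, 8,
    gradient_spec("exponential_counter", steepness = 3,
                  slope = "increasing"),
    gradient_spec("exponential_counter", steepness = 3,
                  slope = "decreasing"))
  tm <- rbind(fiber_terminal(0.2, 5.3, 3.2, p),
              fiber_terminal(0.5, 9.7, 4.6, p),
              fiber_terminal(0.9, 14.1, 2.9, p))
  tm$mobile <- FALSE
  ref <- oracle_immobile_dynamics(tm, f, 6, p)

  tm2 <- tm; tm2$mobile <- TRUE
  sc <- structure(list(field = f, terminals = tm2,
                       params_overrides = list(n_terminals = 3L, C0 = 1.5,
                                               ramp_on = FALSE,
                                               do_move = FALSE),
                       hints = list(), tag = "ref", call_info = list()),
                  class = "coadapt_scenario")
  r <- simulate(sc, params = list(n_iterations = 6L, seed = 1),
                record_stride = 1)
  expect_equal(r$final$R_F, ref$terminals$R_F, tolerance = 1e-12)
  expect_equal(r$final$L_F, ref$terminals$L_F, tolerance = 1e-12)
  expect_equal(unname(r$trace$D), unname(ref$D), tolerance = 1e-12)
})

test_that("co-adaptation preserves the sensor ratio over a long run", {
  sc <- mapping_scenario(n = 5, seed = 2)
  r <- simulate(sc, params = list(n_iterations = 30000L, seed = 2))
  expect_lt(max(r$max_ratio_dev), 1e-12)
})

test_that("do_move = FALSE freezes positions; immobile residents never
          move or adapt", {
  p <- model_params()
  sc <- mapping_scenario(n = 8, seed = 3)
  r <- simulate(sc, params = list(n_iterations = 100L, seed = 1,
                                  do_move = FALSE))
  expect_equal(r$final$x, sc$terminals$x)
  expect_equal(r$max_x, sc$terminals$x)

  sc2 <- innervation_scenario("no_expansion_remnants", seed = 1)
  res_idx <- which(!sc2$terminals$mobile)
  r2 <- simulate(sc2, params = list(n_iterations = 50L, seed = 1))
  expect_equal(r2$final$x[res_idx], sc2$terminals$x[res_idx])
  expect_equal(r2$final$R_F[res_idx], sc2$terminals$R_F[res_idx])
})

test_that("with adaptation off on a cue-free field sensors stay at
          baseline and the walk is a pure biased random walk", {
  f <- build_target_field(120, 12, gradient_spec("none"),
                          gradient_spec("none"))
  tm <- do.call(rbind, lapply(1:6, function(i)
    fiber_terminal(0.5, 60.3, 6.2)))
  sc <- structure(list(field = f, terminals = tm,
                       params_overrides = list(n_terminals = 6L, C0 = 0,
                                               ramp_on = FALSE,
                                               adaptation_mode = "none"),
                       hints = list(), tag = "walk", call_info = list()),
                  class = "coadapt_scenario")
  r <- simulate(sc, params = list(n_iterations = 300L, seed = 4))
  expect_equal(r$final$R_F, tm$R_F)
  expect_gt(mean(r$final$x), 60.3)  # q_x drives the walk forward
})

test_that("trace records have consistent shapes and tidy export works", {
  sc <- mapping_scenario(n = 4, seed = 1)
  r <- simulate(sc, params = list(n_iterations = 120L, seed = 1),
                record_stride = 40)
  expect_equal(dim(r$trace$x), c(3, 4))
  expect_equal(r$trace$iteration, c(40L, 80L, 120L))
  df <- as.data.frame(r)
  expect_equal(nrow(df), 12)
  expect_named(df, c("iteration", "terminal_id", "origin_u", "x", "y",
                     "R_F", "L_F", "D"))
  r0 <- simulate(sc, params = list(n_iterations = 50L, seed = 1))
  expect_equal(nrow(as.data.frame(r0)), 4)
})
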