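# scenario builders and configuration round trips

test_that("mapping scenario samples the retina equally and fits the field", {
  sc <- mapping_scenario(n = 20, seed = 2)
  expect_equal(nrow(sc$terminals), 20)
  expect_equal(sc$terminals$origin_u, ((1:20) - 0.5) / 20)
  expect_true(all(sc$terminals$x >= 0 & sc$terminals$x <= 50))
  expect_equal(sc$field$width, 50)
  expect_identical(sc$params_overrides$adaptation_mode, "coadaptation")
})

test_that("gap scenario geometry and parameter overrides are correct", {
  sc <- gap_assay_scenario("ephrin", "ephrin", gap = 40, seed = 1)
  h <- sc$hints
  expect_equal(h$second_field_start - h$first_field_end, 40)
  expect_equal(sc$field$width, 200)
  xc <- seq_len(200) - 0.5
  on1 <- xc >= h$first_field_start & xc < h$first_field_end
  expect_true(all(sc$field$L_T[on1, 1] == 4))
  expect_true(all(sc$field$L_T[!on1 &
    !(xc >= h$second_field_start & xc < h$second_field_end), 1] == 0))
  expect_equal(sc$params_overrides$n_iterations, 2000L)
  expect_equal(sc$params_overrides$C0, 1)
  expect_false(sc$params_overrides$ramp_on)
  # adapted start on the trailing 20 units of the first field
  expect_true(all(sc$terminals$x >= h$first_field_end - 20 &
                    sc$terminals$x <= h$first_field_end))
  expect_error(gap_assay_scenario(gap = 200), "too wide")
})

test_that("double-cue scenarios place the second cue on the other species", {
  sc <- gap_assay_scenario("ephrin", "Eph", gap = 20, seed = 1)
  h <- sc$hints
  xc <- seq_len(200) - 0.5
  on2 <- xc >= h$second_field_start & xc < h$second_field_end
  expect_true(all(sc$field$R_T[on2, 1] == 4))
  expect_true(all(sc$field$L_T[on2, 1] == 0))
})

test_that("adapted and naive gap populations share the sensor ratio", {
  ad <- gap_assay_scenario("ephrin", "ephrin", 20, naive = FALSE, seed = 1)
  nv <- gap_assay_scenario("ephrin", "ephrin", 20, naive = TRUE, seed = 1)
  expect_equal(ad$terminals$R_F / ad$terminals$L_F,
               nv$terminals$R_F / nv$terminals$L_F)
  expect_equal(ad$terminals$R_F, 30 * ad$terminals$R_F0)
  expect_equal(nv$terminals$R_F, nv$terminals$R_F0)
})

test_that("tectal entry deflects both sensors and flags the tract hold", {
  sc <- tectal_entry_scenario(n = 10, deflection = 30, seed = 1)
  expect_equal(sc$terminals$R_F, 30 * sc$terminals$R_F0)
  expect_equal(sc$terminals$L_F, 30 * sc$terminals$L_F0)
  expect_true(sc$params_overrides$hold_off_target)
  expect_equal(sc$hints$target_start, 30)
  # corridor cue free, target graded
  expect_true(all(sc$field$L_T[1:30, ] == 0))
  expect_true(all(sc$field$L_T[31:80, ] > 0))
  expect_true(all(diff(sc$field$R_T[31:80, 1]) < 0))
})

test_that("knock-in marks every second fiber and is null at R_ki = 0", {
  sc <- knockin_scenario(2, n = 10, seed = 3)
  expect_equal(sc$terminals$class, rep(c("wt", "ki"), 5))
  ki <- sc$terminals[sc$terminals$class == "ki", ]
  base <- retinal_sensor_levels(ki$origin_u)
  expect_equal(ki$R_F0, base$R_F0 + 2)
  expect_equal(ki$L_F0, base$L_F0 / (1 + 2 / base$R_F0))
  null <- knockin_scenario(0, n = 10, seed = 3)
  map <- mapping_scenario(n = 10, seed = 3)
  expect_equal(null$terminals[names(map$terminals)], map$terminals)
})

test_that("innervation variants assemble their populations", {
  exp_sc <- innervation_scenario("expansion", seed = 1)
  expect_equal(nrow(exp_sc$terminals), 100)
  expect_true(all(exp_sc$terminals$origin_u < 0.5))

  rem <- innervation_scenario("no_expansion_remnants", seed = 1)
  expect_equal(sum(!rem$terminals$mobile), 200)

  comp <- innervation_scenario("compression", seed = 1)
  expect_equal(comp$field$width, 25)
  expect_equal(nrow(comp$terminals), 200)
  # anterior half-field: same anterior cue values as the full field
  full <- innervation_scenario("expansion", seed = 1)$field
  expect_equal(comp$field$L_T[1:25, 1], full$L_T[1:25, 1])

  rev <- innervation_scenario("reversal", seed = 1)
  expect_equal(rev$params_overrides$j_onset, 2000L)
  expect_error(innervation_scenario("bogus"))
})

test_that("scenarios round-trip through config serialization", {
  builders <- list(mapping_scenario(n = 12, seed = 7),
                   gap_assay_scenario("Eph", "ephrin", 40, naive = TRUE,
                                      seed = 2),
                   tectal_entry_scenario(8, 30, seed = 3),
                   knockin_scenario(4, n = 8, seed = 4),
                   innervation_scenario("mismatch", seed = 5))
  for (sc in builders) {
    cfg <- tempfile(fileext = ".json")
    write_scenario_config(sc, cfg)
    sc2 <- scenario_from_config(read_scenario_config(cfg))
    expect_equal(sc2, sc)
  }
  expect_error(read_scenario_config(tempfile()), "not found")
  expect_error(scenario_from_config(list(builder = "rm_rf", args = list())),
               "unknown scenario builder")
})

test_that("single-fiber ensemble pools independent runs", {
  df <- single_fiber_ensemble(n_runs = 3,
                              params = list(n_iterations = 50L), seed = 1)
  expect_equal(nrow(df), 3)
  expect_true(all(df$origin_u >= 0 & df$origin_u <= 1))
  expect_gt(length(unique(df$origin_u)), 1)
})
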