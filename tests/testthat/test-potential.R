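# guidance potential, footprints, adaptation operations

test_that("footprint is a peak-normalised Gaussian profile on the disc", {
  f <- build_target_field(50, 8, gradient_spec("none"),
                          gradient_spec("none"))
  p <- model_params()
  fp <- terminal_footprint(fiber_terminal(0.5, 25.2, 4.4), f, p)
  expect_equal(max(fp$weight), 1)
  expect_true(all(fp$weight > 0))
  # all covered squares lie within the disc
  d <- sqrt((fp$ix + 0.5 - 25.2)^2 + (fp$iy + 0.5 - 4.4)^2)
  expect_true(all(d <= p$radius))
  # center equidistant from two squares along x -> equal weights
  fp2 <- terminal_footprint(fiber_terminal(0.5, 25, 4.3), f, p)
  left <- fp2$weight[fp2$ix == 24 & fp2$iy == 4]
  right <- fp2$weight[fp2$ix == 25 & fp2$iy == 4]
  expect_equal(left, right)
})

test_that("degenerate footprints behave as documented", {
  f <- build_target_field(10, 4, gradient_spec("none"),
                          gradient_spec("none"))
  tiny <- model_params(radius = 0.4)
  fp <- terminal_footprint(fiber_terminal(0.5, 5.5, 2.5), f, tiny)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$weight, 1)
  far <- fiber_terminal(0.5, 30.5, 2.5)
  expect_warning(fp2 <- terminal_footprint(far, f, model_params()),
                 "outside")
  expect_equal(nrow(fp2), 0)
})

test_that("guidance potential matches the reduced closed form on a single
          square", {
  tiny <- model_params(radius = 0.4)
  set.seed(11)
  for (k in 1:100) {
    L_T <- runif(1, 0.1, 8)
    L_F <- runif(1, 0.1, 8)
    f <- build_target_field(9, 1, gradient_spec("uniform", level = L_T),
                            gradient_spec("none"))
    t1 <- fiber_terminal(0.5, 4.5, 0.5, tiny)
    t1$L_F <- L_F; t1$R_F <- runif(1, 0.1, 8)
    expect_equal(guidance_potential(t1, f, params = tiny),
                 abs(log(1 / (L_T / L_F + 1))), tolerance = 1e-12)
  }
  # ln 5 and ln 2 worked cases
  f4 <- build_target_field(9, 1, gradient_spec("uniform", level = 4),
                           gradient_spec("none"))
  t1 <- fiber_terminal(0.5, 4.5, 0.5, tiny)  # L_F = R_F = 1
  expect_equal(guidance_potential(t1, f4, params = tiny), log(5))
  f1 <- build_target_field(9, 1, gradient_spec("uniform", level = 1),
                           gradient_spec("none"))
  expect_equal(guidance_potential(t1, f1, params = tiny), log(2))
})

test_that("guidance potential is zero iff reverse and forward balance", {
  tiny <- model_params(radius = 0.4)
  f <- build_target_field(9, 1, gradient_spec("uniform", level = 2),
                          gradient_spec("uniform", level = 2))
  t1 <- fiber_terminal(0.5, 4.5, 0.5, tiny)  # equal sensors
  expect_equal(guidance_potential(t1, f, params = tiny), 0)
})

test_that("R implementation, compiled path and brute force agree on random
          multi-terminal instances", {
  p <- model_params()
  set.seed(42)
  for (k in 1:100) {
    W <- sample(10:25, 1); H <- sample(4:8, 1)
    f <- build_target_field(W, H,
      gradient_spec(sample(c("uniform", "exponential_counter"), 1),
                    steepness = runif(1, 1, 4), level = runif(1, 0.5, 4)),
      gradient_spec("uniform", level = runif(1, 0, 4)))
    n <- sample(2:4, 1)
    tm <- do.call(rbind, lapply(seq_len(n), function(i)
      fiber_terminal(runif(1), runif(1, 1, W - 1), runif(1, 1, H - 1), p)))
    tm$L_F <- tm$L_F * runif(n, 0.5, 5)
    tm$R_F <- tm$R_F * runif(n, 0.5, 5)
    C <- runif(1, 0, 2)
    D_r <- guidance_potential(tm[1, ], f, tm[-1, ], C, p)
    D_cpp <- cpp_eval_potential(f, as.list(tm), 1L, C, p$radius,
                                p$sigma_frac)
    D_oracle <- oracle_potential(tm, 1, f, C, p$radius, p$sigma_frac)
    expect_equal(D_r, D_oracle, tolerance = 1e-10)
    expect_equal(D_cpp, D_oracle, tolerance = 1e-10)
    expect_gte(D_r, 0)
  }
})

test_that("adaptation coefficient follows the weighted-history formula", {
  p <- model_params()
  expect_equal(adaptation_coefficient(rep(0, 10), p), 1)
  # constant history: linear weights normalise out
  expect_equal(adaptation_coefficient(rep(2, 10), p),
               1 + log1p(p$mu * 2))
  # single recent spike: weighted mean = h * d / (h(h+1)/2)
  expect_equal(adaptation_coefficient(c(rep(0, 9), 2), p),
               1 + log1p(0.006 * 20 / 55))
  expect_equal(adaptation_coefficient(c(rep(0, 9), 2), p), 1.0021793,
               tolerance = 1e-6)
  # short histories are padded with zeros at the old end
  expect_equal(adaptation_coefficient(2, p),
               adaptation_coefficient(c(rep(0, 9), 2), p))
  expect_error(adaptation_coefficient(c(0, -1), p), ">= 0")
  expect_error(adaptation_coefficient(rep(1, 11), p), "longer")
})

test_that("adaptation coefficient is >= 1 and monotone in each entry", {
  p <- model_params()
  set.seed(7)
  for (k in 1:50) {
    h1 <- runif(10, 0, 4)
    a1 <- adaptation_coefficient(h1, p)
    expect_gte(a1, 1)
    h2 <- h1
    j <- sample(10, 1)
    h2[j] <- h2[j] + runif(1, 0.1, 2)
    expect_gt(adaptation_coefficient(h2, p), a1)
  }
})

test_that("resetting force opposes deflection from baseline", {
  p <- model_params()
  expect_equal(resetting_force(1, 1, p), 0)
  expect_equal(resetting_force(2, 1, p), -0.0045)
  expect_equal(resetting_force(2, 1, model_params(lambda = 0)), 0)
  expect_gt(resetting_force(0.5, 1, p), 0)
})

test_that("co-adaptation fixed point matches the closed form", {
  p <- model_params()
  t1 <- fiber_terminal(0.5, 10, 4)
  # a = 1, S = S0: fixed point of the unperturbed system
  expect_equal(apply_coadaptation(t1, 1, p)$R_F, t1$R_F)
  # constant a with a - 1 < lambda: S* = lambda S0 / (lambda + 1 - a)
  a <- 1 + p$lambda / 2
  t2 <- t1
  for (i in 1:10000) t2 <- apply_coadaptation(t2, a, p)
  Sstar <- p$lambda * t1$R_F0 / (p$lambda + 1 - a)
  expect_equal(t2$R_F, Sstar, tolerance = 1e-6)
  expect_equal(t2$L_F, p$lambda * t1$L_F0 / (p$lambda + 1 - a),
               tolerance = 1e-6)
})

test_that("co-adaptation preserves the sensor ratio exactly in structure", {
  p <- model_params()
  t1 <- fiber_terminal(0.8, 10, 4)
  r0 <- t1$R_F / t1$L_F
  set.seed(3)
  for (i in 1:200) {
    t1 <- apply_coadaptation(t1, 1 + runif(1, 0, 0.01), p)
    expect_equal(t1$R_F / t1$L_F, r0, tolerance = 1e-12)
  }
})

test_that("canonical adaptation relaxes each channel to local cues", {
  p <- model_params(kappa = 0.01)
  t1 <- fiber_terminal(0.5, 10, 4)
  # matched: no change
  expect_equal(apply_canonical_adaptation(t1, t1$R_F, t1$L_F, p)$R_F,
               t1$R_F)
  # kappa = 1: jump to local levels
  j <- apply_canonical_adaptation(t1, 3, 0.5, model_params(kappa = 1))
  expect_equal(j$R_F, 3); expect_equal(j$L_F, 0.5)
  t1$R_F <- 1
  expect_equal(apply_canonical_adaptation(t1, 2, t1$L_F, p)$R_F, 1.01)
})
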