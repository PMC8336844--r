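test_that("schedules are right-continuous step functions of hours", {
  expect_equal(schedule_value(make_schedule(7), c(0, 100)), c(7, 7))
  K <- make_schedule(rbind(c(0, 1500), c(25, 1000)))
  expect_equal(schedule_value(K, 24.99), 1500)
  expect_equal(schedule_value(K, 25), 1000)
  expect_error(make_schedule(rbind(c(5, 1), c(0, 2))), "increasing|time 0")
  expect_error(make_schedule(rbind(c(0, 1), c(3, 2), c(3, 4))), "increasing")
})

test_that("noise-switch schedules reproduce the published regime", {
  sA <- make_schedule(rbind(c(0, 90), c(20, 0)))
  sM <- make_schedule(rbind(c(0, 0), c(20, 0.05)))
  expect_equal(schedule_value(sA, c(10, 19.99, 20, 30)), c(90, 90, 0, 0))
  expect_equal(schedule_value(sM, c(10, 19.99, 20, 30)), c(0, 0, 0.05, 0.05))
})

test_that("zero-noise fBm walk is constant; reflecting bounds confine the path", {
  spec0 <- model_spec("FBM_WALK", sigma_A = 0)
  out <- simulate_fbm_walk(1000, spec0, 50, generate_fgn(50, 0.38, 1L))
  expect_equal(out$values, rep(1000, 51))
  expect_equal(out$status, "completed")

  spec_r <- model_spec("FBM_WALK", sigma_A = 90,
                       boundary = boundary_spec("reflecting", 0, 2500))
  out_r <- simulate_fbm_walk(1290, spec_r, 1e4, generate_fgn(1e4, 0.38, 2L))
  expect_equal(out_r$status, "completed")
  expect_true(all(out_r$values >= 0 & out_r$values <= 2500))
  expect_length(out_r$values, 1e4 + 1L)
})

test_that("absorbing bounds end the series at the first exit frame", {
  spec_a <- model_spec("FBM_WALK", sigma_A = 500,
                       boundary = boundary_spec("absorbing", 0, 2500))
  noise <- generate_fgn(1000, 0.38, 3L)
  out <- simulate_fbm_walk(1, spec_a, 1000, noise)
  expect_true(out$status %in% c("absorbed_low", "absorbed_high"))
  expect_lt(length(out$values), 1001L)
  # brute-force oracle: first frame at which the raw walk exits
  raw <- 1 + 500 * cumsum(noise$increments)
  first_exit <- which(raw <= 0 | raw >= 2500)[1]
  expect_equal(length(out$values), first_exit + 1L)
  expect_error(simulate_fbm_walk(3000, spec_a, 10, noise), "inside")
})

test_that("zero-noise logistic integration matches the closed form within 1%", {
  # the log-space family holds the bound through r = 0.03 per frame; the
  # O-space additive form is checked at its published rates (up to 0.025)
  cases <- list(SLE_COMBINED = c(0.005, 0.02, 0.03),
                SLE_ADDITIVE = c(0.005, 0.02, 0.025))
  for (m in names(cases)) {
    for (r in cases[[m]]) {
      for (O0 in c(100, 300, 2000)) {
        spec <- model_spec(m, r = r, K = 1290, sigma_A = 0, sigma_M = 0)
        out <- integrate_sle(O0, spec, 480)
        tt <- 0:480
        closed <- 1290 * O0 * exp(r * tt) / (1290 + O0 * (exp(r * tt) - 1))
        expect_lt(max(abs(out$values - closed) / closed), 0.01)
      }
    }
  }
})

test_that("all zero-noise non-Allee variants converge to K(t_final)", {
  specs <- list(
    model_spec("SLE_MULTIPLICATIVE", r = 0.02, K = 1290),
    model_spec("SLE_TIME_K", r = 0.02, K = rbind(c(0, 1500), c(25, 1000)))
  )
  for (spec in specs) {
    for (O0 in c(100, 2500)) {
      out <- integrate_sle(O0, spec, 720)  # 60 h
      K_end <- schedule_value(spec$K, 60)
      expect_lt(abs(tail(out$values, 1) - K_end) / K_end, 0.005)
    }
  }
})

test_that("Allee fixed points sit at 0, A and K with the expected stability", {
  spec <- model_spec("SLE_ALLEE", r = 0.025, K = 1290, sigma_A = 0,
                     sigma_M = 0, allee_A = 1000, allee_on_time = 0)
  up <- integrate_sle(1050, spec, 1200)     # just above A -> K
  expect_lt(abs(tail(up$values, 1) - 1290) / 1290, 0.01)
  down <- integrate_sle(500, spec, 1200)    # below A -> collapse to zero
  expect_lt(tail(down$values, 1), 1)
  at_A <- integrate_sle(1000, spec, 100)    # unstable equilibrium: zero drift
  expect_equal(tail(at_A$values, 1), 1000, tolerance = 1e-10)
})

test_that("multiplicative noise amplifies fluctuations above the carrying capacity", {
  spec <- model_spec("SLE_MULTIPLICATIVE", r = 0.005, K = 1290, sigma_M = 0.05)
  out <- integrate_sle(1290, spec, 2e4, noise2 = generate_fgn(2e4, 0.38, 9L))
  o <- out$values
  dO <- diff(o)
  above <- abs(dO[head(o, -1) > 1290])
  below <- abs(dO[head(o, -1) < 1290])
  expect_gt(sd(above), sd(below))
})

test_that("log-space models refuse non-positive starts; additive model absorbs at zero", {
  spec <- model_spec("SLE_COMBINED", r = 0.01, K = 1290, sigma_A = 90)
  expect_error(integrate_sle(0, spec, 10, generate_fgn(10, 0.38, 1L)), "positive")
  spec_add <- model_spec("SLE_ADDITIVE", r = 0.02, K = 1290, sigma_A = 500)
  out <- integrate_sle(10, spec_add, 1000, generate_fgn(1000, 0.38, 4L))
  expect_equal(out$status, "absorbed_low")
  expect_equal(tail(out$values, 1), 0)
})

test_that("presets carry the published parameter values", {
  p3 <- preset("fig3_additive")$all
  expect_equal(p3$model, "SLE_ADDITIVE")
  expect_equal(schedule_value(p3$r, 10), 0.02)
  expect_equal(schedule_value(p3$K, 10), 1290)
  expect_equal(schedule_value(p3$sigma_A, 10), 90)
  expect_equal(p3$hurst, 0.38)

  p3m <- preset("fig3_multiplicative")$all
  expect_equal(schedule_value(p3m$r, 0), 0.005)
  expect_equal(schedule_value(p3m$sigma_M, 0), 0.0045)

  p4 <- preset("fig4_noise_switch")
  expect_equal(schedule_value(p4$pluripotent$sigma_A, c(19, 21)), c(90, 0))
  expect_equal(schedule_value(p4$pluripotent$sigma_M, c(19, 21)), c(0, 0.05))
  expect_equal(schedule_value(p4$differentiated$K, 30), 1000)
  expect_equal(schedule_value(p4$differentiated$sigma_A, 30), 90)

  p5 <- preset("fig5_time_K")
  expect_equal(schedule_value(p5$pluripotent$K, c(24, 26)), c(1500, 1000))
  expect_equal(schedule_value(p5$differentiated$K, c(24, 26)), c(1100, 1000))

  p6k <- preset("fig6_time_K_differentiation")
  expect_equal(schedule_value(p6k$differentiated$K, c(20, 30, 50)),
               c(1100, 1000, 300))
  expect_equal(schedule_value(p6k$differentiated$r, c(40, 44)), c(0.015, 0.008))

  p6a <- preset("fig6_allee")$all
  expect_equal(p6a$allee_A, 1000)
  expect_equal(p6a$allee_on_time, 43)
  expect_equal(schedule_value(p6a$sigma_A, 0), 35)
  expect_error(preset("no_such_regime"))
})

test_that("fate classification requires an Allee trajectory and splits on the threshold", {
  init <- quick_init(seed = 21L)
  traj <- run_colony(init, preset("fig3_multiplicative"), 30, seed = 21L)
  expect_error(classify_fates_allee(traj), "Allee")
})
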