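test_that("threshold bisection brackets a genuine flip in the response", {
  ch <- get_chain("second")
  sig0 <- modulating_signal(ch$S0, 0, omega = 1)
  delta <- 2 * ch$thr$tol
  pt_hi <- fixed_pulse_train(500, ch$thr$I_th + delta, duration = 1000)
  pt_lo <- fixed_pulse_train(500, ch$thr$I_th - delta, duration = 1000)
  ## So close to threshold the spike latency can exceed the relay window;
  ## the flip is judged on whether a response exists at all.
  expect_identical(nrow(suppressWarnings(
    simulate_relay(ch$model, pt_hi, sig0, dt = 0.05))$responses), 1L)
  expect_identical(nrow(simulate_relay(ch$model, pt_lo, sig0,
                                       dt = 0.05)$responses), 0L)
  expect_equal(ch$thr$v_th,
               ch$lin$x_eq[1] + ch$thr$I_th / ch$model$params$C_m)
})

test_that("threshold voltage is approximately affine in the modulating offset", {
  m <- get_model("second")
  S0g <- seq(0.1, 0.3, by = 0.04)
  vth <- vapply(S0g, function(s) threshold_current(m, s)$v_th, numeric(1))
  fit <- stats::lm(vth ~ S0g)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("tonic and bursting operating points have distinct validated thresholds", {
  thb <- get_chain("bursting")$thr
  tht <- get_chain("tonic")$thr
  expect_gt(abs(thb$I_th - tht$I_th), 10 * thb$tol)
  for (ch in list(get_chain("bursting"), get_chain("tonic"))) {
    sig0 <- modulating_signal(ch$S0, 0, omega = 1)
    d <- 2 * ch$thr$tol
    expect_identical(nrow(suppressWarnings(
      simulate_relay(ch$model,
                     fixed_pulse_train(500, ch$thr$I_th + d, duration = 1000),
                     sig0, dt = 0.05))$responses), 1L)
    expect_identical(nrow(simulate_relay(
      ch$model, fixed_pulse_train(500, ch$thr$I_th - d, duration = 1000),
      sig0, dt = 0.05)$responses), 0L)
  }
})

test_that("the two-pulse protocol is self-consistent around T_ref", {
  ch <- get_chain("second")
  tref <- get_tref("second")
  sig0 <- modulating_signal(ch$S0, 0, omega = 1)
  two <- function(lag) {
    pt <- fixed_pulse_train(c(500, 500 + lag), base_alpha("second"))
    sum(simulate_relay(ch$model, pt, sig0, dt = 0.05)$relayed)
  }
  expect_identical(two(tref$T_ref / 2), 1L)   # second pulse refractory
  expect_identical(two(2 * tref$T_ref), 2L)   # fully recovered
  expect_error(refractory_period(ch$model, ch$S0, 0.5 * ch$thr$I_th),
               "below threshold")
})

test_that("refractory period varies smoothly along a pulse-height grid", {
  m <- get_model("second")
  tr <- vapply(c(9, 10, 11), function(a) {
    refractory_period(m, 0.1, a, tol = 0.5)$T_ref
  }, numeric(1))
  expect_true(all(diff(tr) < 0))           # stronger pulses recover sooner
  expect_lt(max(abs(diff(diff(tr)))), 30)  # no bisection chatter
})

test_that("critical-point eigenstructure is a valid unstable decomposition", {
  for (which in c("second", "bursting", "tonic")) {
    ch <- get_chain(which)
    cr <- ch$crit
    n <- ch$model$n
    expect_lt(max(Mod(cr$W %*% cr$V - diag(n))), 1e-8)
    Mrec <- cr$V %*% diag(cr$values, n) %*% cr$W
    expect_lt(max(Mod(Mrec - cr$M)), 1e-8)
    expect_gt(cr$lambda1, 0)
    expect_false(cr$complex_leading)
  }
})

test_that("perturbing across the hypersurface flips the response", {
  ch <- get_chain("second")
  eps <- 0.05
  cfg <- relaybounds:::.resolve_config(NULL, ch$model)
  up <- relaybounds:::.pulse_succeeds(ch$model, ch$S0,
                                      ch$thr$x_c + c(eps, 0), 0, cfg)
  dn <- relaybounds:::.pulse_succeeds(ch$model, ch$S0,
                                      ch$thr$x_c - c(eps, 0), 0, cfg)
  expect_true(up)
  expect_false(dn)
  ## The leading-mode coefficient has opposite signs on the two sides.
  w1 <- ch$crit$w1
  expect_gt(sum(w1 * c(eps, 0)), 0)
  expect_lt(sum(w1 * c(-eps, 0)), 0)
})

test_that("success-phase interval handles the degenerate no-modulation cases", {
  ch <- get_chain("second")
  sig0 <- modulating_signal(ch$S0, 0, freq_hz = 25)
  full <- success_phase_interval(ch$model, ch$lin, ch$thr, sig0,
                                 ch$thr$I_th + 1, crit = ch$crit)
  expect_equal(full$width, 2 * pi)
  expect_equal(prob_success(full), 1)
  empty <- success_phase_interval(ch$model, ch$lin, ch$thr, sig0,
                                  ch$thr$I_th - 1, crit = ch$crit)
  expect_equal(empty$width, 0)
  expect_equal(prob_success(empty), 0)
  half <- structure(list(start = 1, width = pi, P_S = 0.5, K0 = 0, Z = 1i,
                         fallback = FALSE), class = "success_phase")
  expect_equal(prob_success(half), 0.5)
})

test_that("success probability falls with inhibition and rises with frequency", {
  m <- get_model("second")
  alpha <- base_alpha("second")
  ## Non-increasing in S0 at fixed frequency.
  ps_s0 <- vapply(c(0.08, 0.1, 0.12, 0.14), function(s) {
    ch <- get_chain("second", S0 = s)
    sig <- modulating_signal(s, base_S1, freq_hz = 25)
    success_phase_interval(m, ch$lin, ch$thr, sig, alpha, crit = ch$crit)$P_S
  }, numeric(1))
  expect_true(all(diff(ps_s0) <= 0))
  ## Non-decreasing in omega wherever the gain decays (it does here).
  ch <- get_chain("second")
  ps_om <- vapply(c(8, 14, 25, 50, 96), function(f) {
    sig <- modulating_signal(0.1, base_S1, freq_hz = f)
    success_phase_interval(m, ch$lin, ch$thr, sig, alpha, crit = ch$crit)$P_S
  }, numeric(1))
  expect_true(all(diff(ps_om) >= 0))
})

test_that("P_S approaches 0 and 1 continuously at the band edges", {
  ch <- get_chain("second")
  sig <- modulating_signal(0.1, base_S1, freq_hz = 25)
  ps <- function(a) success_phase_interval(ch$model, ch$lin, ch$thr, sig, a,
                                           crit = ch$crit)$P_S
  ## Locate the edges from the analytic constants.
  mid <- success_phase_interval(ch$model, ch$lin, ch$thr, sig,
                                ch$thr$I_th, crit = ch$crit)
  band <- Mod(mid$Z) / (ch$crit$w1[1] / ch$model$params$C_m)
  a_lo <- ch$thr$I_th - mid$K0 / (ch$crit$w1[1] / ch$model$params$C_m) - band
  expect_equal(ps(a_lo - 1e-6), 0)
  expect_lt(ps(a_lo + 0.01 * band), 0.07)
  expect_equal(ps(a_lo + 2 * band + 1e-6), 1)
  expect_gt(ps(a_lo + 1.99 * band), 0.93)
})
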