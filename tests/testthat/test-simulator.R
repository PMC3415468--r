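test_that("delta-pulse jump moves only the voltage, by alpha/C_m", {
  x <- c(-70, 0.3, 0.1)
  expect_identical(apply_pulse_jump(x, 0, 1), x)
  expect_equal(apply_pulse_jump(c(-70, 0.3), 2.5, 2.5), c(-69, 0.3))
  expect_equal(apply_pulse_jump(x, 6, 1.5), c(-66, 0.3, 0.1))
})

test_that("narrow rectangular pulses converge to the delta-pulse jump", {
  ch <- get_chain("second")
  m <- ch$model
  alpha <- 3; S0 <- ch$S0
  ## Sub-threshold pulse so the comparison is of smooth trajectories.
  jump <- relaybounds:::.integrate(m, apply_pulse_jump(ch$lin$x_eq, alpha,
                                                       m$params$C_m),
                                   seq(0, 60, 0.1), S0, 0, 0)
  err <- vapply(c(4, 1, 0.25), function(w) {
    f <- function(t, y, parms) {
      d <- m$rhs(y, S0)
      if (t < w) d[1] <- d[1] + alpha / w / m$params$C_m
      list(d)
    }
    out <- deSolve::ode(ch$lin$x_eq, seq(0, 60 + w, 0.1), f, NULL,
                        rtol = 1e-10, atol = 1e-10)
    ## Compare at matched times after the pulse ends.
    approx(out[, 1] - w, out[, 2], xout = 30)$y - approx(jump[, 1], jump[, 2],
                                                         xout = 30)$y
  }, numeric(1))
  expect_true(all(diff(abs(err)) < 0))  # error shrinks with width
  expect_lt(abs(err[3]), 0.05)
})

test_that("without pulses the neuron never responds and settles on a periodic orbit", {
  ch <- get_chain("second")
  sig <- modulating_signal(0.1, 0.02, freq_hz = 25)
  pt <- fixed_pulse_train(numeric(0), alpha = 0, duration = 2000)
  sim <- simulate_relay(ch$model, pt, sig, duration = 2000, dt = 0.1)
  expect_identical(nrow(sim$responses), 0L)
  expect_identical(nrow(sim$spontaneous), 0L)
  ## Late-time trajectory repeats with the modulating period.
  Tp <- 2 * pi / sig$omega
  v <- function(t) approx(sim$times, sim$states[, 1], xout = t)$y
  tt <- seq(1500, 1500 + Tp, length.out = 40)
  expect_lt(max(abs(v(tt) - v(tt + Tp))), 1e-3)
})

test_that("far above threshold every pulse outside the refractory zone relays", {
  ch <- get_chain("second")
  tref <- get_tref("second")
  sig <- modulating_signal(0.1, 0.02, freq_hz = 25)
  times <- 500 + (0:9) * (tref$T_ref + 100)  # all pulses recovered
  pt <- fixed_pulse_train(times, alpha = ch$thr$I_th + 12)
  sim <- simulate_relay(ch$model, pt, sig, dt = 0.05)
  expect_true(all(sim$relayed))
  expect_equal(sim$R_emp, 1)
  ## Far below threshold: nothing relays.
  pt0 <- fixed_pulse_train(times, alpha = 0.5)
  sim0 <- simulate_relay(ch$model, pt0, sig, dt = 0.05)
  expect_equal(sim0$R_emp, 0)
})

test_that("response detection merges bursts and attributes by the latest-preceding rule", {
  cfg <- response_config(detect_level = -40, relay_window = 25,
                         merge_window = 10)
  tt <- seq(0, 400, 0.1)
  spike_at <- function(t0) 50 * pmax(0, 1 - abs(tt - t0) / 2)  # 4 ms triangle
  ## A burst of 4 spikes with 4 ms gaps merges into one response.
  v <- -80 + spike_at(105) + spike_at(109) + spike_at(113) + spike_at(117)
  det <- detect_responses(tt, v, pulse_times = 100, cfg)
  expect_identical(nrow(det$responses), 1L)
  expect_identical(det$responses$n_spikes[1], 4L)
  expect_true(det$relayed[1])
  ## A spike just beyond the relay window does not relay its pulse.
  v2 <- -80 + spike_at(100 + 25 + 1)
  det2 <- detect_responses(tt, v2, pulse_times = 100, cfg)
  expect_false(det2$relayed[1])
  expect_true(is.na(det2$responses$pulse[1]))
  ## Three pulses, responses after pulses 1 and 3: R = 2/3.
  v3 <- -80 + spike_at(110) + spike_at(310)
  det3 <- detect_responses(tt, v3, pulse_times = c(100, 200, 300), cfg)
  expect_identical(det3$relayed, c(TRUE, FALSE, TRUE))
  ## Two pulses inside one window: the later one gets the response.
  v4 <- -80 + spike_at(118)
  det4 <- detect_responses(tt, v4, pulse_times = c(100, 110), cfg)
  expect_identical(det4$relayed, c(FALSE, TRUE))
})

test_that("relay flags are invariant under whole-period time translation", {
  ch <- get_chain("second")
  sig <- modulating_signal(0.1, 0.02, freq_hz = 25)
  Tp <- 2 * pi / sig$omega
  set.seed(8)
  base <- 500 + cumsum(5 + stats::rexp(30, 0.005))
  pt1 <- fixed_pulse_train(base, alpha = 7.9)
  pt2 <- fixed_pulse_train(base + 10 * Tp, alpha = 7.9)
  s1 <- simulate_relay(ch$model, pt1, sig, dt = 0.05)
  s2 <- simulate_relay(ch$model, pt2, sig, dt = 0.05)
  expect_identical(s1$relayed, s2$relayed)
})

test_that("empirical reliability is robust to solver tolerances", {
  ch <- get_chain("second")
  sig <- modulating_signal(0.1, 0.02, freq_hz = 25)
  e1 <- empirical_reliability(ch$model, sig, 7.9, base_lam, base_TR,
                              n_pulses = 200, n_trials = 1, seed = 5,
                              rtol = 1e-6, atol = 1e-6)
  e2 <- empirical_reliability(ch$model, sig, 7.9, base_lam, base_TR,
                              n_pulses = 200, n_trials = 1, seed = 5,
                              rtol = 5e-7, atol = 5e-7)
  expect_lt(abs(e1$mean - e2$mean), 1 / 200 + 1e-9)
})

test_that("empirical reliability collapses in the all-relay and no-relay regimes", {
  ch <- get_chain("second")
  sig <- modulating_signal(0.1, 0.02, freq_hz = 25)
  hi <- empirical_reliability(ch$model, sig, alpha = ch$thr$I_th + 12,
                              lam = 1 / 900, T_R_drive = 200, n_pulses = 25,
                              n_trials = 3, seed = 2)
  expect_equal(hi$mean, 1)
  expect_equal(hi$sd, 0)
  lo <- empirical_reliability(ch$model, sig, alpha = 0.5, lam = base_lam,
                              T_R_drive = base_TR, n_pulses = 25,
                              n_trials = 3, seed = 2)
  expect_equal(lo$mean, 0)
  expect_equal(lo$sd, 0)
})
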