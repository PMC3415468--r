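test_that("equilibrium satisfies the root condition and tracks S0", {
  ch <- get_chain("second")
  expect_lt(max(abs(ch$model$rhs(ch$lin$x_eq, ch$S0))), 1e-10)
  ## Stronger inhibition pulls the equilibrium toward the synaptic reversal.
  S0g <- c(0.05, 0.1, 0.2, 0.4)
  veq <- vapply(S0g, function(s) find_equilibrium(get_model("second"), s)[1],
                numeric(1))
  expect_true(all(diff(veq) < 0))
  expect_true(all(veq > get_model("second")$params$v_rev))
})

test_that("both third-order operating points have a single equilibrium; bistable settings error", {
  for (which in c("bursting", "tonic")) {
    expect_silent(x <- find_equilibrium(get_model(which), 0.05))
    expect_length(x, 3)
  }
  ## A depolarized external current with weak inhibition creates extra
  ## equilibria, violating the stable-neuron premise.
  m_bad <- load_model("third_order", overrides = list(I_ext = 0.5))
  expect_error(find_equilibrium(m_bad, 0.05), "not a stable neuron")
})

test_that("undriven trajectories converge to the equilibrium (validated)", {
  set.seed(12)
  expect_silent(find_equilibrium(get_model("second"), 0.1, validate = TRUE))
})

test_that("transfer gain matches the closed-form 2x2 inverse to machine precision", {
  A <- matrix(c(-0.31, 0.042, -1.7, -0.011), 2, 2)  # column-major
  B <- c(2.4, 0)
  lin <- structure(list(x_eq = c(-70, 0.2), A = A, B = B, C = c(1, 0),
                        eigenvalues = eigen(A)$values, S0 = 0.1,
                        stable = TRUE, model_name = "handmade"),
                   class = "linearization")
  for (om in c(0, 0.05, 0.3, 2)) {
    s <- 1i * om
    det2 <- (s - A[1, 1]) * (s - A[2, 2]) - A[1, 2] * A[2, 1]
    G_closed <- B[1] * (s - A[2, 2]) / det2
    expect_equal(transfer_gain(lin, om), G_closed, tolerance = 1e-14)
  }
})

test_that("static gain equals the finite-difference equilibrium shift", {
  ch <- get_chain("second")
  G0 <- Re(transfer_gain(ch$lin, 0))
  h <- 1e-4
  dv <- (find_equilibrium(ch$model, ch$S0 + h)[1] -
         find_equilibrium(ch$model, ch$S0 - h)[1]) / (2 * h)
  expect_equal(G0, dv, tolerance = 1e-3)
})

test_that("the gain is low-pass: monotone decay to zero beyond the corner", {
  ch <- get_chain("second")
  om <- 2 * pi * c(20, 50, 100, 200, 500, 1000) / 1000
  g <- Mod(transfer_gain(ch$lin, om))
  expect_true(all(diff(g) < 0))
  expect_lt(g[length(g)], 0.05 * Mod(transfer_gain(ch$lin, 0)))
})

test_that("steady-state orbit degenerates to the equilibrium when S1 = 0", {
  ch <- get_chain("second")
  orb <- steady_state_orbit(ch$model, ch$lin,
                            modulating_signal(0.1, 0, freq_hz = 25))
  expect_equal(orb$state(13.7), ch$lin$x_eq)
  expect_equal(orb$amplitude, rep(0, 2))
})

test_that("linearized orbit matches the simulated loop in amplitude and phase", {
  ch <- get_chain("second")
  sig <- modulating_signal(0.1, base_S1, freq_hz = 25)
  orb <- steady_state_orbit(ch$model, ch$lin, sig)
  out <- relaybounds:::.integrate(ch$model, ch$lin$x_eq, seq(0, 2500, 0.1),
                                  sig$S0, sig$S1, sig$omega)
  late <- out[, 1] > 1500
  tt <- out[late, 1]; vv <- out[late, 2]
  fit <- stats::lm(vv ~ sin(sig$omega * tt) + cos(sig$omega * tt))
  amp_sim <- sqrt(sum(stats::coef(fit)[2:3]^2))
  ph_sim <- atan2(stats::coef(fit)[3], stats::coef(fit)[2])
  expect_lt(abs(orb$amplitude[1] - amp_sim) / amp_sim, 0.05)
  dphi <- abs(orb$phase[1] - ph_sim) %% (2 * pi)
  expect_lt(min(dphi, 2 * pi - dphi), 5 * pi / 180)
})

test_that("the simulated orbit obeys small-signal superposition and centering", {
  ch <- get_chain("second")
  ## Small S1 so quadratic rectification is negligible.
  S1a <- 0.005
  sim_amp_mean <- function(S1) {
    om <- 2 * pi * 25 / 1000
    out <- relaybounds:::.integrate(ch$model, ch$lin$x_eq, seq(0, 2500, 0.1),
                                    0.1, S1, om)
    late <- out[, 1] > 1500
    tt <- out[late, 1]; vv <- out[late, 2]
    fit <- stats::lm(vv ~ sin(om * tt) + cos(om * tt))
    c(sqrt(sum(stats::coef(fit)[2:3]^2)), mean(vv))
  }
  a1 <- sim_amp_mean(S1a)
  a2 <- sim_amp_mean(2 * S1a)
  expect_lt(abs(a2[1] / a1[1] - 2), 0.02 * 2)
  expect_lt(abs(a1[2] - ch$lin$x_eq[1]), 0.02 * a1[1])
})

test_that("gain surface reduces to transfer_gain and varies along g_L", {
  m <- get_model("second")
  om <- 2 * pi * 25 / 1000
  one <- gain_surface(m, om, g_T = m$params$g_T, g_L = m$params$g_L, S0 = 0.1)
  expect_equal(one$gain, Mod(transfer_gain(get_chain("second")$lin, om)),
               tolerance = 1e-8)
  ## High-frequency band: |G| ~ |B|/omega, monotone in the leak only
  ## through the equilibrium; check it responds systematically to g_L.
  surf <- gain_surface(m, 2 * pi * 80 / 1000, g_T = m$params$g_T,
                       g_L = c(0.03, 0.05, 0.08, 0.12), S0 = 0.1)
  expect_true(all(surf$ok))
  expect_true(all(diff(surf$gain) > 0) || all(diff(surf$gain) < 0))
})
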