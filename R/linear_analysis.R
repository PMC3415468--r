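#' Central finite-difference Jacobian
#'
#' @param f Function mapping an n-vector to an n-vector.
#' @param x Point of evaluation.
#' @param eps Relative step (default 1e-6); the absolute step per component
#'   is `eps * max(1, |x_j|)`.
#' @return The n x n Jacobian matrix.
#' @export
numeric_jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    hstep <- eps * max(1, abs(x[j]))
    xp <- x; xm <- x
    xp[j] <- xp[j] + hstep
    xm[j] <- xm[j] - hstep
    J[, j] <- (f(xp) - f(xm)) / (2 * hstep)
  }
  J
}

#' Undriven equilibrium of a stable relay neuron
#'
#' Locates the equilibrium of the undriven system (constant modulating
#' conductance `S0`, no pulses).  At any equilibrium the gate variables sit
#' on their steady-state curves, so the problem reduces to a scalar root in
#' the voltage, scanned over the physiological range; this also detects
#' violations of the stable-neuron assumption (multiple equilibria).
#'
#' @param model A [load_model()] object (needs `gate_inf`).
#' @param S0 Constant modulating conductance (mS/cm^2).
#' @param v_range Voltage bracket (mV) scanned for roots.
#' @param validate If `TRUE`, additionally integrate the undriven system
#'   from 5 random physiological initial states and check convergence to
#'   the root (slow; off by default).
#' @return Equilibrium state vector `x_eq` (voltage first).
#' @export
find_equilibrium <- function(model, S0, v_range = c(-120, -20),
                             validate = FALSE) {
  stopifnot(inherits(model, "neuron_model"))
  if (is.null(model$gate_inf)) {
    stop("model has no gate steady-state map; cannot reduce to a scalar root",
         call. = FALSE)
  }
  fv <- function(v) model$rhs(c(v, model$gate_inf(v)), S0)[1]
  vg <- seq(v_range[1], v_range[2], by = 0.02)
  Fv <- vapply(vg, fv, numeric(1))
  sc <- which(diff(sign(Fv)) != 0)
  if (!length(sc)) {
    stop(sprintf("no equilibrium found in [%g, %g] mV at S0 = %g",
                 v_range[1], v_range[2], S0), call. = FALSE)
  }
  roots <- vapply(sc, function(i) {
    uniroot(fv, c(vg[i], vg[i + 1]), tol = 1e-13)$root
  }, numeric(1))
  roots <- roots[!duplicated(round(roots, 6))]
  if (length(roots) > 1) {
    stop(sprintf("found %d equilibria (v = %s): not a stable neuron at S0 = %g",
                 length(roots), paste(signif(roots, 5), collapse = ", "), S0),
         call. = FALSE)
  }
  x_eq <- c(roots, model$gate_inf(roots))
  if (validate) {
    for (k in 1:5) {
      x0 <- c(stats::runif(1, -100, -40),
              stats::runif(model$n - 1, 0.01, 0.99))
      out <- .integrate(model, x0, seq(0, 5000, 5), S0, 0, 0)
      xf <- unname(out[nrow(out), -1])
      if (max(abs(xf - x_eq)) > 0.5) {
        stop(sprintf("undriven trajectory from (%s) did not converge to the equilibrium",
                     paste(signif(x0, 4), collapse = ", ")), call. = FALSE)
      }
    }
  }
  x_eq
}

#' Linearize the relay neuron about its undriven equilibrium
#'
#' First-order expansion about `(x_eq, S0)`: state matrix `A` (Jacobian of
#' the vector field), input vector `B` (the modulating conductance enters
#' only the voltage equation, with coefficient `-(v_eq - v_rev)/C_m`), and
#' output selector `C` picking the voltage.  The gain from modulating
#' conductance to voltage is `G(jw) = C (jwI - A)^{-1} B`.
#'
#' @param model A [load_model()] object.
#' @param S0 Operating-point modulating conductance (mS/cm^2).
#' @param x_eq Optional precomputed equilibrium.
#' @return Object of class `linearization`: `x_eq`, `A`, `B`, `C`,
#'   `eigenvalues`, `S0`, `stable`.
#' @export
linearize <- function(model, S0, x_eq = NULL) {
  if (is.null(x_eq)) x_eq <- find_equilibrium(model, S0)
  A <- if (!is.null(model$jac)) {
    model$jac(x_eq, S0)
  } else {
    numeric_jacobian(function(x) model$rhs(x, S0), x_eq)
  }
  B <- c(-(x_eq[1] - model$params$v_rev) / model$params$C_m,
         rep(0, model$n - 1))
  Cv <- c(1, rep(0, model$n - 1))
  ev <- eigen(A, only.values = TRUE)$values
  stable <- all(Re(ev) < 0)
  if (!stable) {
    warning(sprintf("equilibrium at S0 = %g is not linearly stable (max Re = %.4g)",
                    S0, max(Re(ev))), call. = FALSE)
  }
  structure(list(x_eq = x_eq, A = A, B = B, C = Cv, eigenvalues = ev,
                 S0 = S0, stable = stable, model_name = model$name),
            class = "linearization")
}

#' @export
print.linearization <- function(x, ...) {
  cat(sprintf("<linearization> %s at S0 = %g: v_eq = %.3f mV, eigenvalues %s\n",
              x$model_name, x$S0, x$x_eq[1],
              paste(sprintf("%.4g%+.4gi", Re(x$eigenvalues), Im(x$eigenvalues)),
                    collapse = ", ")))
  invisible(x)
}

#' Transfer gain from modulating conductance to membrane voltage
#'
#' Evaluates `G(jw) = C (jwI - A)^{-1} B` by direct linear solve.  For
#' these membrane models `|G|` is low-pass: it decays to zero as the
#' frequency grows, which is what makes fast modulating inputs permissive
#' for relay.
#'
#' @param lin A [linearize()] result.
#' @param omega Angular frequency/frequencies (rad/ms), `>= 0`; vectorized.
#' @param full If `TRUE`, return the full state transfer vector
#'   `(jwI - A)^{-1} B` (matrix with one column per omega) instead of the
#'   voltage component.
#' @return Complex gain(s).
#' @export
transfer_gain <- function(lin, omega, full = FALSE) {
  stopifnot(inherits(lin, "linearization"), all(omega >= 0))
  n <- length(lin$B)
  gv <- vapply(omega, function(om) {
    M <- 1i * om * diag(n) - lin$A
    tryCatch(solve(M, lin$B + 0i),
             error = function(e) stop(sprintf("jwI - A is singular at omega = %g (cannot happen for a stable A): %s",
                                              om, conditionMessage(e)), call. = FALSE))
  }, complex(n))
  gv <- matrix(gv, nrow = n)
  if (full) gv else as.complex(lin$C %*% gv)[seq_along(omega)]
}

#' Linearized steady-state orbit and orbit tube
#'
#' Under the sinusoidal modulating input the state settles onto a small
#' periodic orbit around the equilibrium; per component `j` the orbit is
#' `x_eq_j + S1 |Gv_j| sin(w t + arg Gv_j)` with `Gv = (jwI - A)^{-1} B`.
#' The orbit tube is this loop thickened by `epsilon`.
#'
#' @param model,lin,sig Model, its linearization at `sig$S0`, and the
#'   modulating signal.
#' @param epsilon Tube radius (mV-scale); default 10% of the orbit's
#'   voltage amplitude with a 0.1 mV floor.
#' @param guard_fraction Warn if the orbit's voltage amplitude exceeds this
#'   fraction of the distance to the threshold voltage `v_th` (only checked
#'   when `v_th` is supplied).
#' @param v_th Optional threshold voltage for the small-signal guard.
#' @return Object of class `orbit_tube`: `state(t)` (orbit point(s), one
#'   row per time), `amplitude`, `phase` (per component), `period`,
#'   `epsilon`, `contains(x, t)` membership test.
#' @export
steady_state_orbit <- function(model, lin, sig, epsilon = NULL,
                               guard_fraction = 0.5, v_th = NULL) {
  stopifnot(inherits(lin, "linearization"), inherits(sig, "modulating_signal"))
  if (sig$omega == 0) stop("omega must be positive for an orbit", call. = FALSE)
  Gv <- transfer_gain(lin, sig$omega, full = TRUE)[, 1]
  amp <- sig$S1 * Mod(Gv)
  ph <- Arg(Gv)
  if (!is.null(v_th) && amp[1] > guard_fraction * abs(v_th - lin$x_eq[1])) {
    warning(sprintf("orbit voltage amplitude %.3g mV exceeds %g%% of the distance to threshold: linearization regime suspect",
                    amp[1], 100 * guard_fraction), call. = FALSE)
  }
  x_eq <- lin$x_eq
  state <- function(t) {
    out <- t(vapply(t, function(tt) x_eq + amp * sin(sig$omega * tt + ph),
                    numeric(length(x_eq))))
    if (length(t) == 1) drop(out) else out
  }
  eps <- if (is.null(epsilon)) max(0.1 * amp[1], 0.1) else epsilon
  contains <- function(x, t) {
    sqrt(sum((x - state(t))^2)) <= eps
  }
  structure(list(state = state, amplitude = amp, phase = ph,
                 period = 2 * pi / sig$omega, epsilon = eps,
                 x_eq = x_eq, sig = sig, contains = contains),
            class = "orbit_tube")
}

#' @export
print.orbit_tube <- function(x, ...) {
  cat(sprintf("<orbit_tube> period %.3g ms, voltage amplitude %.4g mV, epsilon = %.3g\n",
              x$period, x$amplitude[1], x$epsilon))
  invisible(x)
}

#' Gain magnitude over a frequency and conductance grid
#'
#' Recomputes equilibrium and linearization for every conductance pair and
#' tabulates `|G(jw)|`, the surface that shows how T-type and leak
#' conductances shape the neuron's low-pass filtering of the modulating
#' input.
#'
#' @param model Base model (conductances overridden per point).
#' @param omega Angular frequencies (rad/ms).
#' @param g_T,g_L Conductance grids (mS/cm^2); defaults are the fixture
#'   values (single point).
#' @param S0 Operating point.
#' @return Tidy data.frame: `g_T`, `g_L`, `omega`, `freq_hz`, `gain`,
#'   `phase_deg`, `ok`, `message`.
#' @export
gain_surface <- function(model, omega, g_T = model$params$g_T,
                         g_L = model$params$g_L, S0 = model$defaults$S0) {
  grid <- expand.grid(g_T = g_T, g_L = g_L)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    m <- load_model(model$name, overrides = list(g_T = grid$g_T[i],
                                                 g_L = grid$g_L[i]))
    m$params$I_ext <- model$params$I_ext
    ans <- try({
      lin <- linearize(m, S0)
      G <- transfer_gain(lin, omega)
      data.frame(g_T = grid$g_T[i], g_L = grid$g_L[i], omega = omega,
                 freq_hz = 1000 * omega / (2 * pi), gain = Mod(G),
                 phase_deg = Arg(G) * 180 / pi, ok = TRUE, message = "")
    }, silent = TRUE)
    if (inherits(ans, "try-error")) {
      data.frame(g_T = grid$g_T[i], g_L = grid$g_L[i], omega = NA_real_,
                 freq_hz = NA_real_, gain = NA_real_, phase_deg = NA_real_,
                 ok = FALSE, message = conditionMessage(attr(ans, "condition")))
    } else ans
  })
  do.call(rbind, res)
}
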