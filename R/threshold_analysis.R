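## Single-pulse protocol on the undriven system (S1 = 0): integrate from x0
## with a voltage jump alpha/C_m and report whether a successful response
## (upward crossing of the detection level) occurs.
.pulse_succeeds <- function(model, S0, x0, alpha, config, t_max = 400,
                            dt = 0.05, rtol = 1e-8, atol = 1e-8) {
  x0 <- apply_pulse_jump(x0, alpha, model$params$C_m)
  if (x0[1] > config$detect_level) {
    ## Jumped straight across the level: success only if the field still
    ## drives the voltage upward there (regenerative), not a passive
    ## overshoot that decays back.
    return(model$rhs(x0, S0)[1] > 0)
  }
  out <- .integrate(model, x0, seq(0, t_max, dt), S0, 0, 0,
                    rtol = rtol, atol = atol)
  v <- out[, 2]
  i <- which(v[-length(v)] <= config$detect_level & v[-1] > config$detect_level)
  any(vapply(i, function(k) k + 2 > length(v) || v[k + 2] >= v[k + 1],
             logical(1)))
}

#' Threshold current and threshold voltage
#'
#' Bisects on the pulse height applied at the undriven equilibrium (no
#' modulation) for the smallest height that elicits a successful response.
#' The threshold current `I_th` is that height; the threshold voltage is
#' the post-jump landing voltage `v_th = v_eq + I_th / C_m`, and the
#' critical point `x_c` (a point on the critical hypersurface separating
#' successful from unsuccessful responses) is the post-jump state at
#' threshold: gates at their equilibrium values, voltage at `v_th`.
#'
#' @param model A [load_model()] object.
#' @param S0 Constant modulating conductance at which the threshold is
#'   measured (the threshold structure depends on the operating point).
#' @param alpha_max Upper end of the bisection bracket (error if even this
#'   height fails).
#' @param tol Bisection tolerance in pulse-height units.
#' @param config A [response_config()] or `NULL`.
#' @param t_max Per-probe integration horizon (ms).
#' @return Object of class `threshold_info`: `I_th`, `v_th`, `x_c`,
#'   `x_eq`, `S0`, `tol`.
#' @export
threshold_current <- function(model, S0, alpha_max = 80, tol = 1e-3,
                              config = NULL, t_max = 400) {
  config <- .resolve_config(config, model)
  x_eq <- find_equilibrium(model, S0)
  ## Keep the probe landing voltage below the detection level: beyond that
  ## the level-crossing surrogate cannot distinguish a passive overshoot
  ## from an evoked spike.
  alpha_max <- min(alpha_max,
                   model$params$C_m * (config$detect_level - x_eq[1]) - 0.5)
  if (.pulse_succeeds(model, S0, x_eq, 0, config, t_max)) {
    stop("model responds with zero pulse height: not a threshold element at this operating point",
         call. = FALSE)
  }
  if (!.pulse_succeeds(model, S0, x_eq, alpha_max, config, t_max)) {
    stop(sprintf("no successful response up to alpha = %g at S0 = %g; bracket failed",
                 alpha_max, S0), call. = FALSE)
  }
  lo <- 0; hi <- alpha_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.pulse_succeeds(model, S0, x_eq, mid, config, t_max)) hi <- mid else lo <- mid
  }
  I_th <- hi
  structure(list(I_th = I_th, v_th = x_eq[1] + I_th / model$params$C_m,
                 x_c = apply_pulse_jump(x_eq, I_th, model$params$C_m),
                 x_eq = x_eq, S0 = S0, tol = tol,
                 detect_level = config$detect_level, model_name = model$name),
            class = "threshold_info")
}

#' @export
print.threshold_info <- function(x, ...) {
  cat(sprintf("<threshold_info> %s at S0 = %g: I_th = %.4f, v_th = %.3f mV (v_eq = %.3f)\n",
              x$model_name, x$S0, x$I_th, x$v_th, x$x_eq[1]))
  invisible(x)
}

#' Refractory period after a successful response
#'
#' Two-pulse protocol on the undriven system: a first supra-threshold pulse
#' elicits a successful response; a second identical pulse is applied at a
#' varying lag and the smallest lag at which it is again successful is the
#' refractory period `T_ref` (to bisection tolerance).  After an
#' unsuccessful response the time in the refractory zone is shorter but
#' never computed - the reliability bounds bracket it between 0 and
#' `T_ref`.
#'
#' @param model,S0 Model and operating point.
#' @param alpha Pulse height, must exceed the threshold current.
#' @param lag_max Largest lag probed (ms); error if the neuron has not
#'   recovered by then.
#' @param tol Bisection tolerance (ms).
#' @param config A [response_config()] or `NULL`.
#' @return Object of class `refractory_info`: `T_ref`, `alpha`, `S0`, `tol`.
#' @export
refractory_period <- function(model, S0, alpha, lag_max = 2000, tol = 0.1,
                              config = NULL) {
  config <- .resolve_config(config, model)
  x_eq <- find_equilibrium(model, S0)
  if (!.pulse_succeeds(model, S0, x_eq, alpha, config)) {
    stop("alpha is below threshold: no first response to recover from",
         call. = FALSE)
  }
  ## Trajectory after the first pulse, sampled densely so the second-pulse
  ## state at any lag is available by direct lookup.
  dt <- 0.05
  x1 <- apply_pulse_jump(x_eq, alpha, model$params$C_m)
  traj <- .integrate(model, x1, seq(0, lag_max, dt), S0, 0, 0)
  state_at <- function(lag) unname(traj[max(1, round(lag / dt) + 1), -1])
  second_ok <- function(lag) {
    .pulse_succeeds(model, S0, state_at(lag), alpha, config)
  }
  if (!second_ok(lag_max)) {
    stop(sprintf("no recovery within %g ms: not a relay neuron at these settings",
                 lag_max), call. = FALSE)
  }
  ## The lag ladder starts once the first response has ended (voltage back
  ## below the detection level).  Recovery need not be monotone: right
  ## after a burst the calcium envelope can still carry an extra response
  ## before the state sinks into the refractory zone proper.  The
  ## refractory period is the time to LEAVE the zone, i.e. the last
  ## fail-to-success transition on the lag axis, refined by bisection.
  v1 <- traj[, 2]
  above <- which(v1 > config$detect_level)
  if (!length(above)) {
    stop("first response not visible on the detection level; inconsistent settings",
         call. = FALSE)
  }
  lag_min <- traj[max(above), 1] + config$merge_window
  lags <- seq(lag_min, lag_max, length.out = 41)
  ok <- vapply(lags, second_ok, logical(1))
  if (all(ok)) {
    stop("second pulse successful at every probed lag; refractory period below resolution",
         call. = FALSE)
  }
  i_last_fail <- max(which(!ok))
  lo <- lags[i_last_fail]
  hi <- lags[i_last_fail + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (second_ok(mid)) hi <- mid else lo <- mid
  }
  structure(list(T_ref = hi, alpha = alpha, S0 = S0, tol = tol,
                 lag_min = lag_min, model_name = model$name),
            class = "refractory_info")
}

#' @export
print.refractory_info <- function(x, ...) {
  cat(sprintf("<refractory_info> %s: T_ref = %.2f ms at alpha = %g, S0 = %g\n",
              x$model_name, x$T_ref, x$alpha, x$S0))
  invisible(x)
}

#' Linearization and eigenstructure at the critical point
#'
#' Jacobian `M` of the undriven vector field at the critical point `x_c`,
#' with eigenvalues sorted by descending real part and bi-orthonormalized
#' right/left eigenvectors (`w_i' v_j = delta_ij`).  On the critical
#' hypersurface trajectories divert, so the leading eigenvalue `lambda_1`
#' has positive real part; its left eigenvector `w_1` is the local normal
#' along which success or failure is decided.
#'
#' @param model,x_c,S0 Model, critical point (from [threshold_current()]),
#'   operating point.
#' @return Object of class `critical_linearization`: `M`, `values`
#'   (sorted), `V` (right eigenvectors, columns), `W` (left eigenvectors,
#'   rows), `lambda1`, `w1` (oriented so that a pure depolarizing
#'   perturbation has positive projection), `complex_leading` flag.
#' @export
critical_linearization <- function(model, x_c, S0) {
  M <- if (!is.null(model$jac)) model$jac(x_c, S0) else {
    numeric_jacobian(function(x) model$rhs(x, S0), x_c)
  }
  ed <- eigen(M)
  ord <- order(Re(ed$values), decreasing = TRUE)
  values <- ed$values[ord]
  V <- ed$vectors[, ord, drop = FALSE]
  if (abs(det(V)) < 1e-12) stop("defective Jacobian at x_c", call. = FALSE)
  W <- solve(V)  # rows satisfy W V = I (bi-orthonormal)
  complex_leading <- abs(Im(values[1])) > 1e-9
  lambda1 <- Re(values[1])
  w1 <- if (complex_leading) NULL else {
    w <- Re(W[1, ])
    v1 <- Re(V[, 1])
    ## Orient so a depolarizing kick (the success side of the hypersurface)
    ## projects positively: the decision is the sign of the first component
    ## of the leading-mode coefficient, i.e. sign((w1' dx) * v1_1).
    w * sign(v1[1])
  }
  structure(list(M = M, values = values, V = V, W = W, lambda1 = lambda1,
                 w1 = w1, complex_leading = complex_leading, x_c = x_c,
                 S0 = S0), class = "critical_linearization")
}

#' @export
print.critical_linearization <- function(x, ...) {
  cat(sprintf("<critical_linearization> lambda1 = %.4f%s, eigenvalues: %s\n",
              x$lambda1, if (x$complex_leading) " (complex!)" else "",
              paste(sprintf("%.4g%+.4gi", Re(x$values), Im(x$values)),
                    collapse = ", ")))
  invisible(x)
}

#' Success-phase interval of the modulating cycle
#'
#' For a pulse arriving on the steady-state orbit at modulating phase
#' `phi = omega t mod 2pi`, success is decided by the sign of the leading
#' (unstable) mode coefficient at the critical point: combining the
#' linearized orbit with the local eigenstructure, the criterion takes the
#' form `K0 + |Z| sin(phi + arg Z) > 0` with
#' `K0 = w1'(x_eq - x_c) + alpha w1_1 / C_m` and
#' `Z = S1 (w1' (jwI - A)^{-1} B + (w1' B_c) / (lambda1 - jw))`,
#' where `B_c` is the input direction evaluated at `x_c`.  The solution set
#' is a single (possibly wrapped, possibly empty or full) phase interval.
#'
#' If the leading eigenvalue at `x_c` is complex the analytic form is not
#' valid; the interval is then estimated by the brute-force phase scan and
#' flagged `fallback = TRUE`.
#'
#' @param model A [load_model()] object.
#' @param lin [linearize()] result at `sig$S0`.
#' @param thr [threshold_current()] result at `sig$S0`.
#' @param sig Modulating signal.
#' @param alpha Driving pulse height.
#' @param crit Optional precomputed [critical_linearization()].
#' @return Object of class `success_phase`: `start`, `width` (radians,
#'   wrapped representation), `P_S`, `K0`, `Z` (complex), `fallback`.
#' @export
success_phase_interval <- function(model, lin, thr, sig, alpha, crit = NULL) {
  stopifnot(inherits(lin, "linearization"), inherits(thr, "threshold_info"))
  if (is.null(crit)) crit <- critical_linearization(model, thr$x_c, thr$S0)
  if (crit$complex_leading) {
    cls <- success_phase_scan(model, sig, alpha)
    return(structure(list(start = NA_real_, width = 2 * pi * mean(cls$success),
                          P_S = mean(cls$success), K0 = NA_real_,
                          Z = NA_complex_, fallback = TRUE, scan = cls),
                     class = "success_phase"))
  }
  w1 <- crit$w1
  C_m <- model$params$C_m
  K0 <- sum(w1 * (lin$x_eq - thr$x_c)) + alpha * w1[1] / C_m
  if (sig$S1 == 0 || sig$omega == 0) {
    full <- K0 > 0
    return(structure(list(start = 0, width = if (full) 2 * pi else 0,
                          P_S = as.numeric(full), K0 = K0, Z = 0 + 0i,
                          fallback = FALSE), class = "success_phase"))
  }
  Gv <- transfer_gain(lin, sig$omega, full = TRUE)[, 1]
  Bc <- c(-(thr$x_c[1] - model$params$v_rev) / C_m, rep(0, model$n - 1))
  Z <- sig$S1 * (sum(w1 * Gv) + sum(w1 * Bc) / (crit$lambda1 - 1i * sig$omega))
  c0 <- -K0 / Mod(Z)
  if (!is.finite(c0) || c0 <= -1) {
    start <- 0; width <- 2 * pi
  } else if (c0 >= 1) {
    start <- 0; width <- 0
  } else {
    ## sin(phi + psi) > c0 on (asin(c0) - psi, pi - asin(c0) - psi)
    start <- (asin(c0) - Arg(Z)) %% (2 * pi)
    width <- pi - 2 * asin(c0)
  }
  structure(list(start = start, width = width, P_S = width / (2 * pi),
                 K0 = K0, Z = Z, fallback = FALSE), class = "success_phase")
}

#' @export
print.success_phase <- function(x, ...) {
  cat(sprintf("<success_phase> P_S = %.4f (width %.4f rad%s)\n", x$P_S,
              x$width, if (x$fallback) ", numeric-fallback" else ""))
  invisible(x)
}

#' Does a phase lie in the success interval?
#'
#' @param interval A [success_phase_interval()] result (analytic form).
#' @param phi Phase(s) in radians; vectorized.
#' @return Logical vector.
#' @export
success_phase_contains <- function(interval, phi) {
  stopifnot(inherits(interval, "success_phase"))
  if (interval$fallback) {
    stop("membership is not defined for a numeric-fallback interval",
         call. = FALSE)
  }
  d <- (phi - interval$start) %% (2 * pi)
  d < interval$width
}

#' Probability of pulse success given arrival on the orbit
#'
#' The success-phase interval length divided by the full cycle: with
#' stationary pulse arrivals the phase at arrival is uniform on the
#' modulating period, so `P_S = measure(Phi) / 2pi`.
#'
#' @param interval A [success_phase_interval()] result.
#' @return `P_S` in `[0, 1]`.
#' @export
prob_success <- function(interval) {
  stopifnot(inherits(interval, "success_phase"))
  interval$width / (2 * pi)
}

#' Brute-force phase scan of pulse success
#'
#' Settles the neuron onto its steady-state orbit by direct simulation,
#' then delivers one pulse at each of `n_phase` equally spaced modulating
#' phases and classifies each response by simulation.  Serves as the
#' independent check of the analytic success-phase interval and as its
#' numeric fallback when the leading eigenvalue is complex.
#'
#' @param model,sig Model and modulating signal.
#' @param alpha Pulse height.
#' @param n_phase Number of probe phases.
#' @param config A [response_config()] or `NULL`.
#' @param t_settle Minimum settling time (ms); rounded up to whole periods.
#' @param t_probe Post-pulse classification horizon (ms).
#' @return List: `phi` (phases), `success` (logical), `P_S`.
#' @export
success_phase_scan <- function(model, sig, alpha, n_phase = 64,
                               config = NULL, t_settle = 500, t_probe = 300) {
  config <- .resolve_config(config, model)
  period <- 2 * pi / sig$omega
  warm <- ceiling(max(5 * period, t_settle) / period) * period  # phase 0 at warm
  lin <- linearize(model, sig$S0)
  x_start <- if (sig$S1 > 0) {
    steady_state_orbit(model, lin, sig)$state(0)
  } else lin$x_eq
  phi <- 2 * pi * (seq_len(n_phase) - 1) / n_phase
  ## One settling integration covering warm plus a full period, sampled at
  ## the probe phases.
  probe_t <- warm + phi / sig$omega
  tgrid <- sort(unique(c(seq(0, warm, by = 0.5), probe_t)))
  traj <- .integrate(model, x_start, tgrid, sig$S0, sig$S1, sig$omega)
  idx <- match(probe_t, tgrid)
  succ <- vapply(seq_len(n_phase), function(k) {
    y <- apply_pulse_jump(unname(traj[idx[k], -1]), alpha, model$params$C_m)
    t0 <- probe_t[k]
    out <- .integrate(model, y, seq(t0, t0 + t_probe, 0.05),
                      sig$S0, sig$S1, sig$omega)
    v <- out[, 2]
    v[1] > config$detect_level ||
      any(v[-1] > config$detect_level & v[-length(v)] <= config$detect_level)
  }, logical(1))
  list(phi = phi, success = succ, P_S = mean(succ))
}
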