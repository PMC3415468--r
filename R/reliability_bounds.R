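#' Bounds on the probability of arriving inside the orbit tube
#'
#' After a response the state needs time to return to the orbit tube; a
#' pulse arriving earlier cannot be relayed.  With inter-pulse intervals
#' `T_R_drive + Exp(lam)` and the stationarity recursion
#' `P_T = p R + q (1 - R)`, `R = P_S P_T`, where `p` is the interval
#' survival at the post-success refractory period `T_ref` and `q` the
#' survival at the (unknown) post-failure refractory period, bracketing the
#' latter between `T_ref` and 0 gives
#' `P_T_lb = p` and `P_T_ub = 1 / (1 + P_S (1 - p))`.
#'
#' @param lam,T_R_drive Driving-interval parameters (1/ms, ms).
#' @param T_ref Refractory period after a successful response (ms).
#' @param P_S Success probability given arrival on the orbit.
#' @return List: `P_T_lb`, `P_T_ub`, `p` (interval survival at `T_ref`).
#' @export
prob_in_tube_bounds <- function(lam, T_R_drive, T_ref, P_S) {
  stopifnot(lam > 0, T_R_drive >= 0, T_ref >= 0, P_S >= 0, P_S <= 1)
  p <- interval_survival(lam, T_R_drive, T_ref)
  list(P_T_lb = p, P_T_ub = 1 / (1 + P_S * (1 - p)), p = p)
}

#' Closed-form bounds on relay reliability
#'
#' Composes the success-phase probability with the orbit-tube bracket:
#' `R = P(X in S) = P_S P(X in T)`, so `R_lb = P_S p` and
#' `R_ub = P_S / (1 + P_S (1 - p))` with `p` the interval survival at
#' `T_ref`.  In the sparse-pulse limit (`lam (T_ref - T_R_drive) -> 0`,
#' i.e. `p -> 1`) both bounds collapse to `P_S`; in the dense-pulse limit
#' with `P_S = 1` the upper bound saturates at 1/2 (every success is
#' followed by exactly one refractory-censored pulse) and the lower bound
#' falls to 0.
#'
#' @param P_S Success-phase probability (from [prob_success()] or a
#'   [success_phase_interval()] object).
#' @param T_ref Refractory period (ms), a [refractory_period()] object or
#'   a number.
#' @param lam,T_R_drive Driving-input interval parameters.
#' @param inputs Optional named list echoed into the result (alpha, S0,
#'   S1, omega, ...).
#' @return Object of class `reliability_bounds`: `R_lb`, `R_ub` (clamped
#'   to `[0, 1]`), `R_lb_raw`, `R_ub_raw`, `P_S`, `p`, `P_T_lb`, `P_T_ub`,
#'   `T_ref`, `lam`, `T_R_drive`, `inputs`.
#' @export
reliability_bounds <- function(P_S, T_ref, lam, T_R_drive, inputs = list()) {
  if (inherits(P_S, "success_phase")) P_S <- P_S$P_S
  if (inherits(T_ref, "refractory_info")) T_ref <- T_ref$T_ref
  pt <- prob_in_tube_bounds(lam, T_R_drive, T_ref, P_S)
  R_lb_raw <- P_S * pt$P_T_lb
  R_ub_raw <- P_S * pt$P_T_ub
  structure(list(R_lb = min(max(R_lb_raw, 0), 1),
                 R_ub = min(max(R_ub_raw, 0), 1),
                 R_lb_raw = R_lb_raw, R_ub_raw = R_ub_raw,
                 P_S = P_S, p = pt$p, P_T_lb = pt$P_T_lb, P_T_ub = pt$P_T_ub,
                 T_ref = T_ref, lam = lam, T_R_drive = T_R_drive,
                 inputs = inputs),
            class = "reliability_bounds")
}

#' @export
print.reliability_bounds <- function(x, ...) {
  cat(sprintf("<reliability_bounds> P_S = %.4f, p = %.4f, R in [%.4f, %.4f]\n",
              x$P_S, x$p, x$R_lb, x$R_ub))
  invisible(x)
}

#' Reliability bounds and empirical reliability along a parameter sweep
#'
#' For each value of the swept parameter, recomputes equilibrium,
#' linearization, threshold structure and refractory period (cached where
#' the swept parameter cannot affect them), evaluates the analytic bounds,
#' and (optionally) measures empirical reliability over repeated
#' simulations.  This is the machinery behind the bound-containment and
#' trend analyses.
#'
#' Caching policy: equilibrium/linearization and threshold are recomputed
#' when `S0`, `g_T` or `g_L` change; the refractory period additionally
#' when `alpha` changes; the success-phase interval is recomputed at every
#' point.
#'
#' @param model A [load_model()] object.
#' @param var Swept parameter: one of `"freq_hz"`, `"omega"`, `"S0"`,
#'   `"lam"`, `"alpha"`, `"g_T"`, `"g_L"`.
#' @param values Sweep grid.
#' @param alpha,lam,T_R_drive,S0,S1 Baseline input parameters.
#' @param freq_hz,omega Baseline modulating frequency (exactly one unless
#'   it is the swept variable).
#' @param n_trials,n_pulses Empirical-reliability settings.
#' @param seed Base seed (advanced per point).
#' @param with_empirical If `FALSE`, skip simulations (bounds only).
#' @param config A [response_config()] or `NULL`.
#' @param thr_tol,tref_tol Bisection tolerances for `I_th` (pulse-height
#'   units) and `T_ref` (ms).
#' @param dt Trajectory sampling step for the empirical simulations.
#' @return Tidy data.frame, one row per sweep point: the swept value,
#'   `P_S`, `I_th`, `T_ref`, `p`, `R_lb`, `R_ub`, `R_emp_mean`,
#'   `R_emp_sd`, `contained` (is `R_emp_mean +/- sd` inside the bounds),
#'   `ok`, `message`.
#' @export
sweep_bounds <- function(model, var, values, alpha, lam, T_R_drive, S0, S1,
                         freq_hz = NULL, omega = NULL,
                         n_trials = 20, n_pulses = 200, seed = 1L,
                         with_empirical = TRUE, config = NULL,
                         thr_tol = 1e-3, tref_tol = 0.5, tref_alpha_margin = 0.5,
                         dt = 0.1) {
  var <- match.arg(var, c("freq_hz", "omega", "S0", "lam", "alpha",
                          "g_T", "g_L"))
  if (var %in% c("freq_hz", "omega")) {
    base_omega <- NA_real_
  } else {
    if (is.null(omega) == is.null(freq_hz)) {
      stop("give exactly one of `omega` or `freq_hz`", call. = FALSE)
    }
    base_omega <- if (is.null(omega)) 2 * pi * freq_hz / 1000 else omega
  }
  config <- .resolve_config(config, model)
  cache <- new.env(parent = emptyenv())

  one_point <- function(i, val) {
    pars <- list(alpha = alpha, lam = lam, T_R_drive = T_R_drive, S0 = S0,
                 S1 = S1, omega = base_omega)
    m <- model
    if (var == "freq_hz") pars$omega <- 2 * pi * val / 1000
    else if (var == "omega") pars$omega <- val
    else if (var %in% c("g_T", "g_L")) {
      m <- load_model(model$name, overrides = stats::setNames(list(val), var))
      m$params$I_ext <- model$params$I_ext
    } else pars[[var]] <- val

    model_key <- if (var %in% c("g_T", "g_L")) sprintf("%s=%.8g", var, val) else "base"
    lin_key <- sprintf("lin|%s|S0=%.8g", model_key, pars$S0)
    if (is.null(cache[[lin_key]])) {
      lin <- linearize(m, pars$S0)
      thr <- threshold_current(m, pars$S0, tol = thr_tol, config = config)
      crit <- critical_linearization(m, thr$x_c, pars$S0)
      cache[[lin_key]] <- list(lin = lin, thr = thr, crit = crit)
    }
    lt <- cache[[lin_key]]
    sig <- modulating_signal(pars$S0, pars$S1, omega = pars$omega)
    ph <- success_phase_interval(m, lt$lin, lt$thr, sig, pars$alpha,
                                 crit = lt$crit)
    if (ph$P_S == 0) {
      ## No success at any phase: both bounds are zero and the undriven
      ## two-pulse protocol is undefined (alpha below threshold).
      T_ref <- NA_real_
      b <- reliability_bounds(0, 0, pars$lam, pars$T_R_drive, inputs = pars)
    } else {
      ## The undriven refractory protocol needs a supra-threshold pulse;
      ## when alpha sits in the lower modulation band (successes only at
      ## favorable phases), measure T_ref just above threshold instead.
      alpha_eff <- max(pars$alpha, lt$thr$I_th + tref_alpha_margin)
      tref_key <- sprintf("tref|%s|S0=%.8g|a=%.8g", model_key, pars$S0, alpha_eff)
      if (is.null(cache[[tref_key]])) {
        cache[[tref_key]] <- refractory_period(m, pars$S0, alpha_eff,
                                               tol = tref_tol, config = config)
      }
      T_ref <- cache[[tref_key]]$T_ref
      b <- reliability_bounds(ph$P_S, T_ref, pars$lam, pars$T_R_drive,
                              inputs = pars)
    }
    if (with_empirical) {
      emp <- empirical_reliability(m, sig, pars$alpha, pars$lam,
                                   pars$T_R_drive, n_pulses = n_pulses,
                                   n_trials = n_trials,
                                   seed = seed + 1000L * i,
                                   config = config, dt = dt)
      emp_mean <- emp$mean; emp_sd <- emp$sd
    } else {
      emp_mean <- NA_real_; emp_sd <- NA_real_
    }
    contained <- if (is.na(emp_mean)) NA else {
      (emp_mean - emp_sd) <= b$R_ub && (emp_mean + emp_sd) >= b$R_lb
    }
    data.frame(var = var, value = val, P_S = ph$P_S, I_th = lt$thr$I_th,
               T_ref = T_ref, p = b$p, R_lb = b$R_lb, R_ub = b$R_ub,
               R_emp_mean = emp_mean, R_emp_sd = emp_sd,
               contained = contained, fallback = ph$fallback,
               ok = TRUE, message = "")
  }

  rows <- lapply(seq_along(values), function(i) {
    ans <- try(one_point(i, values[i]), silent = TRUE)
    if (inherits(ans, "try-error")) {
      data.frame(var = var, value = values[i], P_S = NA_real_,
                 I_th = NA_real_, T_ref = NA_real_, p = NA_real_,
                 R_lb = NA_real_, R_ub = NA_real_, R_emp_mean = NA_real_,
                 R_emp_sd = NA_real_, contained = NA, fallback = NA,
                 ok = FALSE,
                 message = conditionMessage(attr(ans, "condition")))
    } else ans
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Approximate reliability adjustment for spontaneous firing
#'
#' Spontaneously firing relay cells can be treated as receiving an extra
#' periodic noise pulse train (period `T_noise`) whose successful responses
#' are undesirable.  Counting those successes against the desirable ones
#' rescales reliability by `1 - (T_R_drive + 1/lam) / T_noise`.  The
#' adjustment is approximate by construction; it reduces to the unadjusted
#' bounds as `T_noise` grows and turns negative when noise pulses outpace
#' driving pulses (`T_noise << 1/lam`).  Values are reported raw - never
#' clamped - together with the approximation flag.
#'
#' @param bounds A [reliability_bounds()] object.
#' @param T_noise Noise pulse period (ms), `> 0`.
#' @return List: `R_lb_adj`, `R_ub_adj`, `factor`, `T_noise`,
#'   `approximate = TRUE`.
#' @export
spontaneous_extension <- function(bounds, T_noise) {
  stopifnot(inherits(bounds, "reliability_bounds"), T_noise > 0)
  mean_iv <- bounds$T_R_drive + 1 / bounds$lam
  fac <- 1 - mean_iv / T_noise
  list(R_lb_adj = bounds$R_lb * fac, R_ub_adj = bounds$R_ub * fac,
       factor = fac, T_noise = T_noise, approximate = TRUE)
}
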