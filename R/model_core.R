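#' @useDynLib relaybounds
#' @importFrom stats uniroot setNames sd
NULL

## Sigmoid gate primitives shared by both built-in models.  Rising form for
## activation gates, falling form for inactivation gates.
.sig_up <- function(v, vhalf, k) 1 / (1 + exp(-(v - vhalf) / k))
.sig_down <- function(v, vhalf, k) 1 / (1 + exp((v - vhalf) / k))

.check_state <- function(x, n, what = "state") {
  if (length(x) != n) {
    stop(sprintf("%s must have length %d, got %d", what, n, length(x)), call. = FALSE)
  }
  bad <- which(!is.finite(x))
  if (length(bad)) {
    stop(sprintf("non-finite %s in component(s) %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Right-hand side of the second-order relay neuron model
#'
#' Evaluates the vector field of the two-state relay neuron: membrane
#' voltage driven by a low-threshold T-type calcium current (instantaneous
#' activation, dynamic inactivation gate `h`) and a passive leak, with the
#' modulating input entering as a synaptic conductance `s` with reversal
#' potential `v_rev`.
#'
#' @param x State vector `c(v, h)`: voltage (mV) and T-channel inactivation.
#' @param s Modulating conductance value (mS/cm^2).
#' @param params Named parameter list as produced by [load_model()]
#'   (`model$params`).
#' @return Length-2 derivative `c(dv/dt, dh/dt)` in mV/ms and 1/ms.
#' @seealso [load_model()], [rhs_third_order()]
#' @export
rhs_second_order <- function(x, s, params) {
  .check_state(x, 2L)
  p <- params
  v <- x[[1]]; h <- x[[2]]
  pinf <- .sig_up(v, p$p_vhalf, p$p_k)
  hinf <- .sig_down(v, p$h_vhalf, p$h_k)
  tauh <- p$tau_h_base + p$tau_h_amp * exp(-(v - p$tau_h_vhalf) / p$tau_h_k)
  I_T <- p$g_T * pinf^2 * h * (v - p$E_T)
  I_L <- p$g_L * (v - p$E_L)
  c((-I_T - I_L + p$I_ext - s * (v - p$v_rev)) / p$C_m,
    p$phi_h * (hinf - h) / tauh)
}

#' Right-hand side of the third-order thalamocortical relay model
#'
#' Evaluates the three-state reduced thalamocortical cell: leak, fast sodium
#' (instantaneous activation `m`, inactivation `h`), potassium (gated by the
#' `n = k_n (1 - h)` reduction) and low-threshold T-type calcium current
#' (instantaneous activation `p`, inactivation `r`).  Depending on the
#' external current `I_ext` the cell responds to driving pulses with a
#' rebound burst (hyperpolarized operating point) or a single spike
#' (depolarized operating point).
#'
#' @param x State vector `c(v, h, r)`.
#' @param s Modulating conductance value (mS/cm^2).
#' @param params Named parameter list (`model$params`).
#' @return Length-3 derivative in (mV/ms, 1/ms, 1/ms).
#' @export
rhs_third_order <- function(x, s, params) {
  .check_state(x, 3L)
  p <- params
  v <- x[[1]]; h <- x[[2]]; r <- x[[3]]
  minf <- .sig_up(v, p$m_vhalf, p$m_k)
  hinf <- .sig_down(v, p$h_vhalf, p$h_k)
  a_h <- p$a_h_amp * exp(-(v - p$a_h_vhalf) / p$a_h_k)
  b_h <- p$b_h_amp / (1 + exp(-(v - p$b_h_vhalf) / p$b_h_k))
  tauh <- 1 / (a_h + b_h)
  pinf <- .sig_up(v, p$p_vhalf, p$p_k)
  rinf <- .sig_down(v, p$r_vhalf, p$r_k)
  taur <- p$tau_r_base + p$tau_r_amp * exp(-(v - p$tau_r_vhalf) / p$tau_r_k)
  ngate <- p$k_n * (1 - h)
  I_L <- p$g_L * (v - p$E_L)
  I_Na <- p$g_Na * minf^3 * h * (v - p$E_Na)
  I_K <- p$g_K * ngate^4 * (v - p$E_K)
  I_T <- p$g_T * pinf^2 * r * (v - p$E_T)
  c((-I_L - I_Na - I_K - I_T + p$I_ext - s * (v - p$v_rev)) / p$C_m,
    p$phi_h * (hinf - h) / tauh,
    p$phi_r * (rinf - r) / taur)
}

.model_fixture_path <- function(name) {
  system.file("extdata", paste0(name, ".yaml"), package = "relaybounds",
              mustWork = TRUE)
}

#' Load a packaged relay neuron model
#'
#' Builds a fully parameterized neuron model from its plain-text fixture
#' file, optionally overriding individual parameters.  The returned object
#' carries the vector field, the gate steady-state map used for equilibrium
#' localization, and pointers to the compiled right-hand side used by the
#' simulator.
#'
#' @param name `"second_order"` (T-type calcium + leak) or `"third_order"`
#'   (bursting thalamocortical cell).
#' @param overrides Named list of parameter overrides; names must exist in
#'   the fixture file.
#' @param mode For the third-order model, `"bursting"` (hyperpolarized,
#'   default) or `"tonic"` (depolarized): selects the corresponding fixture
#'   `I_ext`.  Ignored (must be `NULL`) for the second-order model.
#' @return An object of class `neuron_model` with elements `name`, `n`
#'   (state dimension), `params`, `rhs(x, s)`, `gate_inf(v)`,
#'   `state_names`, `detect_level`, `defaults` (baseline `S0`, `S1`) and
#'   `compiled` (deSolve symbol table).
#' @examples
#' m <- load_model("second_order")
#' m$rhs(c(-70, 0.1), 0.1)
#' @export
load_model <- function(name = c("second_order", "third_order"),
                       overrides = list(), mode = NULL) {
  name <- match.arg(name)
  params <- yaml::read_yaml(.model_fixture_path(name))
  if (!is.null(mode)) {
    if (name != "third_order") {
      stop("`mode` applies only to the third-order model", call. = FALSE)
    }
    mode <- match.arg(mode, c("bursting", "tonic"))
    params$I_ext <- params[[paste0("I_ext_", mode)]]
  }
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(params))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop(sprintf("unknown parameter(s) %s; valid keys: %s",
                   paste(bad, collapse = ", "),
                   paste(names(params), collapse = ", ")), call. = FALSE)
    }
    params[names(overrides)] <- overrides
  }
  .validate_params(params, name)

  if (name == "second_order") {
    model <- list(
      name = name, n = 2L, params = params,
      state_names = c("v", "h"),
      rhs = function(x, s) rhs_second_order(x, s, params),
      gate_inf = function(v) .sig_down(v, params$h_vhalf, params$h_k),
      compiled = list(func = "relay2_derivs", initfunc = "relay2_init",
                      dllname = "relaybounds", pack = .pack_parms2)
    )
  } else {
    model <- list(
      name = name, n = 3L, params = params,
      state_names = c("v", "h", "r"),
      rhs = function(x, s) rhs_third_order(x, s, params),
      gate_inf = function(v) c(.sig_down(v, params$h_vhalf, params$h_k),
                               .sig_down(v, params$r_vhalf, params$r_k)),
      compiled = list(func = "relay3_derivs", initfunc = "relay3_init",
                      dllname = "relaybounds", pack = .pack_parms3)
    )
  }
  model$detect_level <- params$detect_level
  model$relay_window <- params$relay_window
  model$defaults <- list(S0 = params$S0_default, S1 = params$S1_default)
  class(model) <- "neuron_model"
  model
}

.validate_params <- function(p, name) {
  stopifnot(p$C_m > 0)
  gkeys <- grep("^g_", names(p), value = TRUE)
  if (any(unlist(p[gkeys]) < 0)) {
    stop("conductances must be non-negative", call. = FALSE)
  }
  vgrid <- seq(-120, 60, by = 1)
  if (name == "second_order") {
    tau <- p$tau_h_base + p$tau_h_amp * exp(-(vgrid - p$tau_h_vhalf) / p$tau_h_k)
    if (any(tau <= 0)) stop("tau_h(v) must be positive on [-120, 60] mV", call. = FALSE)
  } else {
    a_h <- p$a_h_amp * exp(-(vgrid - p$a_h_vhalf) / p$a_h_k)
    b_h <- p$b_h_amp / (1 + exp(-(vgrid - p$b_h_vhalf) / p$b_h_k))
    tau <- p$tau_r_base + p$tau_r_amp * exp(-(vgrid - p$tau_r_vhalf) / p$tau_r_k)
    if (any(1 / (a_h + b_h) <= 0) || any(tau <= 0)) {
      stop("gate time constants must be positive on [-120, 60] mV", call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("<neuron_model> %s (n = %d; states: %s)\n", x$name, x$n,
              paste(x$state_names, collapse = ", ")))
  cat(sprintf("  I_ext = %g uA/cm2, v_rev = %g mV, detect level = %g mV\n",
              x$params$I_ext, x$params$v_rev, x$detect_level))
  invisible(x)
}

## deSolve parameter packing; order must match src/relay_models.c.
.pack_parms2 <- function(p, S0, S1, omega) {
  c(p$C_m, p$g_T, p$E_T, p$g_L, p$E_L, p$I_ext, p$v_rev, p$phi_h,
    p$p_vhalf, p$p_k, p$h_vhalf, p$h_k,
    p$tau_h_base, p$tau_h_amp, p$tau_h_vhalf, p$tau_h_k,
    S0, S1, omega)
}

.pack_parms3 <- function(p, S0, S1, omega) {
  c(p$C_m, p$g_L, p$E_L, p$g_Na, p$E_Na, p$g_K, p$E_K, p$g_T, p$E_T,
    p$I_ext, p$v_rev, p$phi_h, p$phi_r, p$k_n,
    p$m_vhalf, p$m_k, p$h_vhalf, p$h_k,
    p$a_h_amp, p$a_h_vhalf, p$a_h_k, p$b_h_amp, p$b_h_vhalf, p$b_h_k,
    p$p_vhalf, p$p_k, p$r_vhalf, p$r_k,
    p$tau_r_base, p$tau_r_amp, p$tau_r_vhalf, p$tau_r_k,
    S0, S1, omega)
}
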