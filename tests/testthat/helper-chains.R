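## Shared fixtures for the test suite.  The analysis chain (equilibrium,
## linearization, threshold, critical-point eigenstructure) is deterministic
## and moderately expensive, so it is computed once per (model, S0) and
## cached for all test files in the session.

.chain_cache <- new.env(parent = emptyenv())

get_model <- function(which = c("second", "bursting", "tonic")) {
  which <- match.arg(which)
  key <- paste0("model_", which)
  if (is.null(.chain_cache[[key]])) {
    .chain_cache[[key]] <- switch(which,
      second = load_model("second_order"),
      bursting = load_model("third_order", mode = "bursting"),
      tonic = load_model("third_order", mode = "tonic"))
  }
  .chain_cache[[key]]
}

## Baseline operating points used across the suite (the study conditions).
base_S0 <- function(which) if (which == "second") 0.1 else 0.05
base_S1 <- 0.02
base_lam <- 0.005
base_TR <- 5
base_alpha <- function(which) {
  switch(which, second = 7.9, bursting = 12.5, tonic = 11.7)
}

get_chain <- function(which = "second", S0 = base_S0(which)) {
  key <- sprintf("chain_%s_%.6g", which, S0)
  if (is.null(.chain_cache[[key]])) {
    m <- get_model(which)
    lin <- linearize(m, S0)
    thr <- threshold_current(m, S0)
    crit <- critical_linearization(m, thr$x_c, S0)
    .chain_cache[[key]] <- list(model = m, lin = lin, thr = thr, crit = crit,
                                S0 = S0)
  }
  .chain_cache[[key]]
}

get_tref <- function(which = "second", alpha = base_alpha(which),
                     S0 = base_S0(which), tol = 0.5) {
  key <- sprintf("tref_%s_%.6g_%.6g", which, S0, alpha)
  if (is.null(.chain_cache[[key]])) {
    .chain_cache[[key]] <- refractory_period(get_model(which), S0, alpha,
                                             tol = tol)
  }
  .chain_cache[[key]]
}

## Independent renewal-process Monte-Carlo oracle for the in-tube /
## reliability bracket: pulses with intervals T_R + Exp(lam); a pulse is in
## the tube iff the interval since the previous pulse exceeds that pulse's
## refractory duration (T_ref after a success, T_ref_u otherwise); an
## in-tube pulse succeeds with probability P_S (uniform arrival phase).
renewal_mc <- function(n_pulses, lam, T_R, T_ref, P_S, T_ref_u, seed) {
  set.seed(seed)
  iv <- T_R + stats::rexp(n_pulses, lam)
  phase_ok <- stats::runif(n_pulses) < P_S
  succ <- logical(n_pulses)
  in_tube <- logical(n_pulses)
  prev_refrac <- 0
  for (i in seq_len(n_pulses)) {
    in_tube[i] <- iv[i] > prev_refrac
    succ[i] <- in_tube[i] && phase_ok[i]
    prev_refrac <- if (succ[i]) T_ref else T_ref_u
  }
  ## Batch-mean standard error (the sequence is Markov-correlated), with a
  ## binomial floor so rare-success cases are not underestimated.
  nb <- 100L
  bs <- tapply(succ, rep(seq_len(nb), length.out = n_pulses), mean)
  R <- mean(succ)
  se_binom <- sqrt(max(R, 1 / n_pulses) * (1 - min(R, 1 - 1 / n_pulses)) /
                   n_pulses)
  list(R = R, P_T = mean(in_tube),
       se = max(stats::sd(bs) / sqrt(nb), se_binom))
}

## Deterministic pulse train at given times (bypasses the generator).
fixed_pulse_train <- function(times, alpha, duration = max(times) + 100) {
  structure(list(times = times, alpha = alpha, lam = NA_real_,
                 T_R_drive = NA_real_, duration = duration,
                 seed = NA_integer_), class = "pulse_train")
}
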