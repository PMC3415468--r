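#' Sinusoidal modulating conductance
#'
#' Constructs the modulating input `s(t) = S0 + S1 sin(omega t)`, the
#' deterministic ensemble-IPSP conductance that gates relay.  Frequencies
#' may be given either as an angular frequency in rad/ms or in Hz
#' (`omega = 2 * pi * freq_hz / 1000`).
#'
#' @param S0 DC conductance offset (mS/cm^2), `S0 >= 0`.
#' @param S1 Oscillation amplitude (mS/cm^2), `0 <= S1 <= S0` so that
#'   `s(t) >= 0` for all `t`.
#' @param omega Angular frequency (rad/ms); give exactly one of `omega`,
#'   `freq_hz`.
#' @param freq_hz Frequency in Hz.
#' @return An object of class `modulating_signal`.
#' @examples
#' sig <- modulating_signal(S0 = 0.1, S1 = 0.02, freq_hz = 25)
#' modulating_value(sig, c(0, 10, 20))
#' @export
modulating_signal <- function(S0, S1, omega = NULL, freq_hz = NULL) {
  if (is.null(omega) == is.null(freq_hz)) {
    stop("give exactly one of `omega` (rad/ms) or `freq_hz`", call. = FALSE)
  }
  if (is.null(omega)) omega <- 2 * pi * freq_hz / 1000
  if (S0 < 0) stop("S0 must be non-negative", call. = FALSE)
  if (S1 < 0 || S1 > S0) {
    stop("need 0 <= S1 <= S0 so the conductance s(t) stays non-negative",
         call. = FALSE)
  }
  if (omega < 0) stop("omega must be non-negative", call. = FALSE)
  structure(list(S0 = S0, S1 = S1, omega = omega), class = "modulating_signal")
}

#' Evaluate the modulating conductance
#'
#' @param sig A [modulating_signal()].
#' @param t Time(s) in ms; vectorized.
#' @return `S0 + S1 sin(omega t)` (mS/cm^2).
#' @export
modulating_value <- function(sig, t) {
  stopifnot(inherits(sig, "modulating_signal"))
  sig$S0 + sig$S1 * sin(sig$omega * t)
}

#' @export
print.modulating_signal <- function(x, ...) {
  cat(sprintf("<modulating_signal> S0 = %g, S1 = %g mS/cm2, omega = %g rad/ms (%.3g Hz)\n",
              x$S0, x$S1, x$omega, 1000 * x$omega / (2 * pi)))
  invisible(x)
}

#' Generate a refractory-Poisson driving pulse train
#'
#' Draws pulse times whose inter-pulse intervals are `T_R_drive + Exp(lam)`:
#' a hard refractory floor plus an exponential tail, the driving-input class
#' of the relay analysis.  The first pulse falls one full interval after
#' `t = 0`, so a sparse train leaves the neuron time to settle onto its
#' steady-state orbit before the first event.
#'
#' @param alpha Pulse height (uA*ms/cm^2); a pulse kicks the voltage by
#'   `alpha / C_m` mV.
#' @param lam Exponential rate (1/ms); the mean inter-pulse interval is
#'   `T_R_drive + 1/lam`.
#' @param T_R_drive Driving refractory period (ms), `>= 0`.
#' @param duration Train duration (ms); pulses beyond it are dropped.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `pulse_train` with fields `times`, `alpha`,
#'   `lam`, `T_R_drive`, `duration`, `seed`.
#' @examples
#' pt <- generate_pulse_train(alpha = 7, lam = 0.02, T_R_drive = 5,
#'                            duration = 1000, seed = 1)
#' diff(pt$times) # all >= 5
#' @export
generate_pulse_train <- function(alpha, lam, T_R_drive, duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (lam <= 0) stop("lam must be positive", call. = FALSE)
  if (T_R_drive < 0) stop("T_R_drive must be non-negative", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  mean_iv <- T_R_drive + 1 / lam
  times <- numeric(0)
  t_last <- 0
  repeat {
    n_draw <- max(16L, ceiling((duration - t_last) / mean_iv * 1.5))
    iv <- T_R_drive + stats::rexp(n_draw, rate = lam)
    new <- t_last + cumsum(iv)
    times <- c(times, new)
    t_last <- times[length(times)]
    if (t_last > duration) break
  }
  structure(list(times = times[times <= duration], alpha = alpha, lam = lam,
                 T_R_drive = T_R_drive, duration = duration,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d pulses in %g ms (alpha = %g, lam = %g /ms, T_R = %g ms)\n",
              length(x$times), x$duration, x$alpha, x$lam, x$T_R_drive))
  invisible(x)
}

#' Survival function of the inter-pulse interval
#'
#' `P(T > tau)` for intervals `T = T_R_drive + Exp(lam)`: equal to 1 up to
#' the refractory floor and exponentially decaying beyond it.  This is the
#' quantity `p` entering the reliability bounds, evaluated at the neuron's
#' refractory period.
#'
#' @param lam Exponential rate (1/ms).
#' @param T_R_drive Refractory floor (ms).
#' @param tau Time(s) (ms); vectorized.
#' @return Probability in (0, 1].
#' @export
interval_survival <- function(lam, T_R_drive, tau) {
  stopifnot(lam > 0, T_R_drive >= 0, all(tau >= 0))
  ifelse(tau <= T_R_drive, 1, exp(-lam * (tau - T_R_drive)))
}

#' Write / read a pulse train event file
#'
#' Plain-text dialect: comment header lines starting with `#` carrying the
#' train metadata (`lam`, `T_R_drive`, `duration`, `seed`), then one
#' `time height` pair per line, whitespace-separated, times in ms.
#'
#' @param pt A [generate_pulse_train()] object.
#' @param file Path.
#' @return `write_pulse_train` returns `file` invisibly; `read_pulse_train`
#'   returns a `pulse_train`.
#' @export
write_pulse_train <- function(pt, file) {
  stopifnot(inherits(pt, "pulse_train"))
  hdr <- c("# relaybounds pulse train (time_ms height)",
           sprintf("# lam=%.17g T_R_drive=%.17g duration=%.17g seed=%s",
                   pt$lam, pt$T_R_drive, pt$duration,
                   ifelse(is.na(pt$seed), "NA", as.character(pt$seed))))
  writeLines(c(hdr, sprintf("%.17g %.17g", pt$times,
                            rep(pt$alpha, length(pt$times)))), file)
  invisible(file)
}

#' @rdname write_pulse_train
#' @export
read_pulse_train <- function(file) {
  lines <- readLines(file)
  meta_line <- grep("^# lam=", lines, value = TRUE)
  meta <- list(lam = NA_real_, T_R_drive = NA_real_, duration = NA_real_,
               seed = NA_integer_)
  if (length(meta_line)) {
    kv <- regmatches(meta_line[1],
                     gregexpr("[A-Za-z_]+=[-0-9.eNA+]+", meta_line[1]))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      meta[[parts[1]]] <- suppressWarnings(as.numeric(parts[2]))
    }
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  dat <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                               function(x) as.numeric(x[1:2])))
  if (is.null(dat)) dat <- matrix(numeric(0), ncol = 2)
  alpha <- if (nrow(dat)) dat[1, 2] else NA_real_
  structure(list(times = dat[, 1], alpha = alpha, lam = meta$lam,
                 T_R_drive = meta$T_R_drive,
                 duration = if (is.na(meta$duration) && nrow(dat))
                   max(dat[, 1]) else meta$duration,
                 seed = meta$seed),
            class = "pulse_train")
}
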