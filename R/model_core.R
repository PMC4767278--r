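#' Wilson-Cowan unit parameters
#'
#' Bundles the parameters of a single Wilson-Cowan unit: the intra-unit
#' coupling weights between the excitatory (E) and inhibitory (I)
#' populations, the background activity levels, the population time
#' constants, and the shape of the sigmoidal response function.
#'
#' The defaults generate stable oscillatory behaviour in the alpha band when
#' combined with the default background levels: \code{w_ee = 23},
#' \code{w_ii = 0}, \code{w_ei = 35}, \code{w_ie = -15}, \code{e0 = 0.5},
#' \code{i0 = -5}, sigmoid gain \code{m = 1} and offset \code{n = 4}. Time
#' constants are in seconds; the defaults of 14 ms (E) and 13 ms (I) put the
#' intrinsic resonance of a noise-driven unit near 13 Hz.
#'
#' @param w_ee E-to-E intra-unit weight (dimensionless).
#' @param w_ie I-to-E intra-unit weight; appears in the E equation and is
#'   negative for an inhibitory influence.
#' @param w_ei E-to-I intra-unit weight; appears in the I equation.
#' @param w_ii I-to-I intra-unit weight.
#' @param e0,i0 Background activity levels of the E and I populations.
#' @param tau_e,tau_i Time constants of the E and I populations, in seconds.
#'   Must be positive.
#' @param gain Sigmoid steepness \code{m}; must be positive.
#' @param offset Sigmoid offset \code{n} (input level of the half-maximum).
#'
#' @return An object of class \code{wc_unit_params} (a named list).
#' @examples
#' p <- unit_params()
#' p$tau_e
#' @export
unit_params <- function(w_ee = 23, w_ie = -15, w_ei = 35, w_ii = 0,
                        e0 = 0.5, i0 = -5,
                        tau_e = 0.014, tau_i = 0.013,
                        gain = 1, offset = 4) {
  stopifnot(tau_e > 0, tau_i > 0, gain > 0)
  structure(list(w_ee = w_ee, w_ie = w_ie, w_ei = w_ei, w_ii = w_ii,
                 e0 = e0, i0 = i0, tau_e = tau_e, tau_i = tau_i,
                 gain = gain, offset = offset),
            class = "wc_unit_params")
}

#' Pulse-train stimulus kernel parameters
#'
#' Parameters of the gamma-shaped spiking input kernel
#' \eqn{f(t) = q (t/w)^{shape} e^{-t/w}} used to build periodic drive trains.
#' \code{shape} is the kernel exponent (distinct from the sigmoid offset) and
#' \code{w} is the kernel time scale in milliseconds; with the defaults the
#' kernel peaks \code{shape * w = 11.1} ms after each pulse onset.
#'
#' @param q Amplitude (dimensionless, non-negative).
#' @param shape Kernel exponent (positive).
#' @param w Kernel time scale in milliseconds (positive).
#' @return An object of class \code{wc_kernel_params}.
#' @examples
#' k <- stimulus_kernel_params()
#' stimulus_kernel(k$shape * k$w, k)  # kernel maximum
#' @export
stimulus_kernel_params <- function(q = 0.5, shape = 3.0, w = 3.7) {
  stopifnot(q >= 0, shape > 0, w > 0)
  structure(list(q = q, shape = shape, w = w), class = "wc_kernel_params")
}

#' Sigmoidal response function
#'
#' \eqn{\sigma(x) = 1 / (1 + e^{-gain (x - offset)})}, strictly increasing
#' with values in (0, 1). The exponent argument is clamped to +/-500 so the
#' function saturates instead of overflowing.
#'
#' @param x Input (any real; vectorized).
#' @param gain Steepness, positive.
#' @param offset Input value at which the output is 0.5.
#' @return Numeric vector of the same length as \code{x}, in (0, 1).
#' @examples
#' sigmoid(4, 1, 4)  # 0.5 at the offset
#' @export
sigmoid <- function(x, gain = 1, offset = 4) {
  stopifnot(gain > 0)
  a <- gain * (x - offset)
  a[a > 500] <- 500
  a[a < -500] <- -500
  1 / (1 + exp(-a))
}

#' Time derivatives of one Wilson-Cowan unit
#'
#' Evaluates the coupled rate equations
#' \deqn{\tau_E dE/dt = -E + \sigma(w_{EE} E + w_{IE} I + E_0 + ext_E)}
#' \deqn{\tau_I dI/dt = -I + \sigma(w_{EI} E + w_{II} I + I_0 + ext_I)}
#' where \code{ext_e} aggregates every extrinsic input to the E population
#' (delayed coupling, periodic drive, scaled noise) and \code{ext_i} the
#' delayed coupling into the I population.
#'
#' @param e,i Current E and I activity.
#' @param ext_e,ext_i Aggregated extrinsic inputs to the E and I sigmoid
#'   arguments.
#' @param p A \code{\link{unit_params}} object.
#' @return Named numeric vector \code{c(de_dt, di_dt)} in units of 1/s.
#' @export
unit_derivatives <- function(e, i, ext_e = 0, ext_i = 0, p = unit_params()) {
  if (!all(is.finite(c(e, i, ext_e, ext_i))))
    stop("non-finite state or input in unit_derivatives (numerical blow-up?)")
  de <- (-e + sigmoid(p$w_ee * e + p$w_ie * i + p$e0 + ext_e,
                      p$gain, p$offset)) / p$tau_e
  di <- (-i + sigmoid(p$w_ei * e + p$w_ii * i + p$i0 + ext_i,
                      p$gain, p$offset)) / p$tau_i
  c(de_dt = de, di_dt = di)
}

#' Fixed point of an uncoupled unit
#'
#' Solves \eqn{E = \sigma(w_{EE}E + w_{IE}I + E_0)},
#' \eqn{I = \sigma(w_{EI}E + w_{II}I + I_0)} with zero external input by
#' damped fixed-point iteration followed by a Newton polish of the 2x2
#' system. For the default (oscillatory) parameters the relevant fixed point
#' is a low-activity unstable spiral around which the limit cycle runs; the
#' damped iterates approach it and then spiral away, so the solver keeps the
#' smallest-residual iterate and polishes it with Newton steps, which lands
#' on the low-activity point rather than the coexisting high-activity node.
#'
#' @param p A \code{\link{unit_params}} object.
#' @param start Numeric length-2 starting state \code{c(e, i)}.
#' @param damping Step fraction of the damped iteration, in (0, 1].
#' @param tol Residual tolerance on the derivatives (default 1e-12).
#' @param max_iter Iteration budget before the Newton polish.
#' @return Named numeric vector \code{c(e_star, i_star)} with residual of
#'   \code{\link{unit_derivatives}} below \code{tol}.
#' @examples
#' s <- uncoupled_fixed_point(unit_params())
#' unit_derivatives(s[1], s[2])  # ~ 0
#' @export
uncoupled_fixed_point <- function(p = unit_params(), start = c(0, 0),
                                  damping = 0.2, tol = 1e-12,
                                  max_iter = 5000L) {
  stopifnot(damping > 0, damping <= 1)
  s <- as.numeric(start)
  g <- function(s) {
    c(sigmoid(p$w_ee * s[1] + p$w_ie * s[2] + p$e0, p$gain, p$offset),
      sigmoid(p$w_ei * s[1] + p$w_ii * s[2] + p$i0, p$gain, p$offset))
  }
  # A short damped-iteration phase smooths wild starting points; it is cut
  # off early because around a spiral-unstable fixed point the iterates
  # approach and then depart again toward a coexisting stable high-activity
  # node, which is not the operating point of the oscillation.
  best <- s
  best_res <- max(abs(g(s) - s))
  for (it in seq_len(min(max_iter, 25L))) {
    Fs <- g(s) - s
    res <- max(abs(Fs))
    if (res < best_res) { best <- s; best_res <- res }
    if (best_res < 1e-13) break
    s <- s + damping * Fs
  }
  s <- best
  # Newton polish on F(s) = g(s) - s; handles spiral-unstable fixed points
  # that damped iteration alone cannot converge onto.
  for (it in seq_len(100L)) {
    Fs <- g(s) - s
    if (max(abs(Fs)) < tol / 10) break
    ae <- p$gain * (p$w_ee * s[1] + p$w_ie * s[2] + p$e0 - p$offset)
    ai <- p$gain * (p$w_ei * s[1] + p$w_ii * s[2] + p$i0 - p$offset)
    dse <- p$gain * stats::plogis(ae) * (1 - stats::plogis(ae))
    dsi <- p$gain * stats::plogis(ai) * (1 - stats::plogis(ai))
    J <- rbind(c(dse * p$w_ee - 1, dse * p$w_ie),
               c(dsi * p$w_ei, dsi * p$w_ii - 1))
    step <- tryCatch(solve(J, -Fs), error = function(e) NULL)
    if (is.null(step)) break
    # damp overlong Newton steps to stay on the local branch
    if (max(abs(step)) > 0.2) step <- step * 0.2 / max(abs(step))
    s <- s + step
  }
  d <- unit_derivatives(s[1], s[2], 0, 0, p)
  if (max(abs(d)) * max(p$tau_e, p$tau_i) >= 1e-10)
    stop("uncoupled_fixed_point did not converge (oscillatory regime?); ",
         "residual = ", format(max(abs(d))))
  c(e_star = s[1], i_star = s[2])
}

#' Stimulus kernel
#'
#' Causal gamma-shaped pulse kernel
#' \eqn{f(t) = q (t/w)^{shape} e^{-t/w}} evaluated at time \code{t}
#' (milliseconds) since pulse onset; zero for \code{t < 0}.
#'
#' @param t Time since pulse onset, milliseconds (vectorized).
#' @param k A \code{\link{stimulus_kernel_params}} object.
#' @return Kernel values (dimensionless).
#' @examples
#' stimulus_kernel(11.1, stimulus_kernel_params())  # peak value ~0.672
#' @export
stimulus_kernel <- function(t, k = stimulus_kernel_params()) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- k$q * (t[pos] / k$w)^k$shape * exp(-t[pos] / k$w)
  out
}

#' Periodic pulse-train drive
#'
#' Samples a repetitive stimulus at frequency \code{freq}: the kernel is
#' restarted at each cycle onset (multiples of \code{1/freq}, rounded to the
#' integration grid) and evaluated at the elapsed time since the most recent
#' onset. Deterministic for fixed arguments.
#'
#' @param freq Driving frequency in Hz; must be positive and below the
#'   Nyquist frequency \code{1/(2 dt)}.
#' @param n_steps Number of samples to generate.
#' @param dt Integration step in seconds (default 1 ms).
#' @param k A \code{\link{stimulus_kernel_params}} object.
#' @return Numeric vector of length \code{n_steps}.
#' @examples
#' d <- periodic_drive(10, 500)
#' max(d)  # ~ kernel maximum, cycles are longer than the kernel peak time
#' @export
periodic_drive <- function(freq, n_steps, dt = 0.001,
                           k = stimulus_kernel_params()) {
  stopifnot(n_steps >= 1)
  if (freq <= 0 || freq >= 1 / (2 * dt))
    stop("freq must lie in (0, Nyquist); Nyquist = ", 1 / (2 * dt), " Hz")
  period_steps <- 1 / (freq * dt)
  t_idx <- 0:(n_steps - 1)
  cycle <- floor(t_idx / period_steps + 1e-9)
  # a grid-rounded onset of the next cycle can precede t when the true onset
  # lies within half a step above t; advance the cycle index there
  bump <- round((cycle + 1) * period_steps) <= t_idx
  cycle[bump] <- cycle[bump] + 1
  onset <- round(cycle * period_steps)
  elapsed_ms <- (t_idx - onset) * dt * 1000
  stimulus_kernel(elapsed_ms, k)
}
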