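#' Noise configuration
#'
#' Macrocolumn-shared Gaussian white noise: at every integration step each
#' macrocolumn receives one standard-normal draw, shared by all its units
#' and independent across macrocolumns and steps. The draw enters the E
#' population's sigmoid argument scaled by \code{z}.
#'
#' @param z Noise SD multiplier (>= 0), defined at the reference sampling
#'   interval \code{ref_dt}. Typical protocol values are 0.05
#'   (driven-network and delay experiments) and 0.07 (degree experiments).
#' @param seed Integer seed for the noise stream.
#' @param ref_dt Reference step (seconds) at which \code{z} is calibrated
#'   (default 0.001). When integrating at a different step the per-step SD
#'   is \code{z * sqrt(ref_dt / dt)}, which keeps the noise power per unit
#'   time -- and hence the operating regime -- invariant under step
#'   halving/doubling.
#' @return An object of class \code{wc_noise_config}.
#' @export
noise_config <- function(z = 0.05, seed = 1L, ref_dt = 0.001) {
  stopifnot(z >= 0, ref_dt > 0)
  structure(list(z = z, seed = as.integer(seed), ref_dt = ref_dt),
            class = "wc_noise_config")
}

#' Simulation configuration
#'
#' @param dt Integration step in seconds (default 0.001 = 1 ms).
#' @param n_steps Number of integration steps (>= 1).
#' @param initial_state \code{"zeros"} (default) or \code{"fixed_point"}.
#'   With the default oscillatory unit parameters the uncoupled fixed point
#'   is an unstable spiral, so starting at zeros joins the limit cycle
#'   faster; \code{"fixed_point"} falls back to zeros if the solver fails.
#' @param burn_in Steps to discard from the front of every returned series
#'   (default 0; whole trials are analyzed).
#' @return An object of class \code{wc_sim_config}.
#' @export
sim_config <- function(dt = 0.001, n_steps = 2000L,
                       initial_state = c("zeros", "fixed_point"),
                       burn_in = 0L) {
  stopifnot(dt > 0, n_steps >= 1, burn_in >= 0, burn_in < n_steps)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 initial_state = match.arg(initial_state),
                 burn_in = as.integer(burn_in)),
            class = "wc_sim_config")
}

resolve_initial_state <- function(sim, p) {
  if (sim$initial_state == "fixed_point") {
    fp <- tryCatch(uncoupled_fixed_point(p), error = function(e) c(0, 0))
    c(fp[[1]], fp[[2]])
  } else c(0, 0)
}

#' Simulate one stochastic trial of the coupled network
#'
#' Integrates the delay-coupled Wilson-Cowan lattice with fixed-step
#' (Euler-Maruyama) updating at \code{sim$dt}. Within each step the whole E
#' field is updated first and the I field then uses the freshly updated E
#' for its intra-unit term (staggered updating); inter-unit coupling reads
#' the excitatory history at \code{t - delay}, with pre-history equal to the
#' initial E value. The periodic drive, when present, is added inside the E
#' sigmoid argument of masked units only; macrocolumn-shared noise scaled by
#' \code{noise$z} enters the same argument for every unit.
#'
#' The production path is a compiled circular-buffer integrator; it is
#' contractually identical (to numerical round-off) to the plain full-history
#' reference \code{\link{simulate_trial_reference}}.
#'
#' @param network A \code{\link{build_network}} result.
#' @param p \code{\link{unit_params}}.
#' @param noise \code{\link{noise_config}}; the trial draws its noise matrix
#'   from \code{noise$seed}.
#' @param drive Numeric drive series of length \code{sim$n_steps}, or
#'   \code{NULL} for spontaneous activity. Must come with \code{mask}.
#' @param mask \code{\link{subnetwork_mask}} of driven units, or \code{NULL}
#'   (whole lattice is used for averaging, no drive).
#' @param sim \code{\link{sim_config}}.
#' @param keep_units Keep the full per-unit activity matrix (time x units)?
#'   Off by default; the mask-averaged series is always returned.
#' @return A list of class \code{wc_trial}: \code{mask_mean} (length
#'   \code{n_steps - burn_in}), \code{e_series} (matrix or \code{NULL}),
#'   \code{drive_freq} attribute left to callers, plus the configs used.
#' @export
simulate_trial <- function(network, p = unit_params(),
                           noise = noise_config(), drive = NULL,
                           mask = NULL, sim = sim_config(),
                           keep_units = FALSE) {
  if (!is.null(drive) && is.null(mask))
    stop("a drive series requires a mask of driven units")
  n <- network$spec$side^2
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (!is.null(drive) && length(drive) != sim$n_steps)
    stop("drive length must equal sim$n_steps")
  n_mc <- max(network$macrocolumn_of)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  noise_mat <- matrix(stats::rnorm(sim$n_steps * n_mc), sim$n_steps, n_mc)
  s0 <- resolve_initial_state(sim, p)
  res <- .sim_core(n,
                   network$exc$src - 1L, network$exc$dst - 1L,
                   network$exc$weight, network$exc$delay,
                   network$inh$src - 1L, network$inh$dst - 1L,
                   network$inh$weight, network$inh$delay,
                   c(p$w_ee, p$w_ie, p$w_ei, p$w_ii, p$e0, p$i0,
                     p$tau_e, p$tau_i, p$gain, p$offset),
                   noise_mat, noise$z * sqrt(noise$ref_dt / sim$dt),
                   network$macrocolumn_of - 1L,
                   if (is.null(drive)) numeric(0) else drive,
                   as.logical(mask), sim$dt,
                   rep(s0[1], n), rep(s0[2], n), keep_units)
  keep <- if (sim$burn_in > 0) -(seq_len(sim$burn_in)) else TRUE
  structure(list(mask_mean = res$mask_mean[keep],
                 e_series = if (keep_units) res$e_series[keep, , drop = FALSE]
                 else NULL,
                 mask = mask, sim = sim, noise = noise),
            class = "wc_trial")
}

#' Reference full-history integrator (plain R)
#'
#' A deliberately naive implementation of the identical update rule used by
#' \code{\link{simulate_trial}}: the complete excitatory history is kept as
#' a dense matrix and every coupling term is looked up directly, with no
#' circular buffering or edge grouping. Used as the oracle in equivalence
#' tests; impractically slow beyond toy networks.
#'
#' @inheritParams simulate_trial
#' @return As \code{\link{simulate_trial}} with \code{keep_units = TRUE}.
#' @export
simulate_trial_reference <- function(network, p = unit_params(),
                                     noise = noise_config(), drive = NULL,
                                     mask = NULL, sim = sim_config()) {
  n <- network$spec$side^2
  if (is.null(mask)) mask <- rep(TRUE, n)
  n_mc <- max(network$macrocolumn_of)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  noise_mat <- matrix(stats::rnorm(sim$n_steps * n_mc), sim$n_steps, n_mc)
  s0 <- resolve_initial_state(sim, p)
  E <- rep(s0[1], n); I <- rep(s0[2], n)
  hist_E <- matrix(s0[1], sim$n_steps + 1, n)  # row t+1 = state at start of step t
  out <- matrix(NA_real_, sim$n_steps, n)
  edges <- rbind(cbind(network$exc, pop = "E"), cbind(network$inh, pop = "I"))
  for (t in seq_len(sim$n_steps)) {
    hist_E[t, ] <- E
    ext_e <- numeric(n); ext_i <- numeric(n)
    for (k in seq_len(nrow(edges))) {
      td <- t - edges$delay[k]
      val <- if (td < 1) s0[1] else hist_E[td, edges$src[k]]
      if (edges$pop[k] == "E")
        ext_e[edges$dst[k]] <- ext_e[edges$dst[k]] + edges$weight[k] * val
      else
        ext_i[edges$dst[k]] <- ext_i[edges$dst[k]] + edges$weight[k] * val
    }
    xi <- noise_mat[t, network$macrocolumn_of]
    drv <- if (is.null(drive)) 0 else drive[t] * as.numeric(mask)
    E_new <- E + sim$dt * (-E + sigmoid(p$w_ee * E + p$w_ie * I + p$e0 +
                                          ext_e + drv +
                                            noise$z *
                                              sqrt(noise$ref_dt / sim$dt) * xi,
                                        p$gain, p$offset)) / p$tau_e
    I <- I + sim$dt * (-I + sigmoid(p$w_ei * E_new + p$w_ii * I + p$i0 +
                                      ext_i, p$gain, p$offset)) / p$tau_i
    E <- E_new
    out[t, ] <- E
  }
  keep <- if (sim$burn_in > 0) -(seq_len(sim$burn_in)) else TRUE
  structure(list(mask_mean = rowMeans(out[, mask, drop = FALSE])[keep],
                 e_series = out[keep, , drop = FALSE],
                 mask = mask, sim = sim, noise = noise),
            class = "wc_trial")
}

# deterministic per-trial seed derivation: independent substreams from
# (base_seed, k), kept well inside 32-bit integer range
derive_seed <- function(base_seed, k) {
  as.integer((as.numeric(base_seed) %% 94007 * 20011 +
                as.numeric(k) * 7919 + 104729) %% 2147483629) + 1L
}

#' Run repeated stochastic trials
#'
#' Trial \code{k} uses the noise seed derived deterministically from
#' \code{(base_seed, k)}; the connectivity realization is fixed (it belongs
#' to \code{network}). By default only the mask-averaged series are kept,
#' as a \code{n_steps x n_trials} matrix.
#'
#' @inheritParams simulate_trial
#' @param n_trials Number of trials (>= 1).
#' @param base_seed Integer seed from which per-trial noise seeds derive.
#' @param z Noise SD multiplier.
#' @return Matrix (time x trials) of mask-averaged excitatory activity.
#' @export
run_trials <- function(network, n_trials, base_seed, p = unit_params(),
                       z = 0.05, drive = NULL, mask = NULL,
                       sim = sim_config()) {
  stopifnot(n_trials >= 1)
  out <- matrix(NA_real_, sim$n_steps - sim$burn_in, n_trials)
  for (k in seq_len(n_trials)) {
    tr <- simulate_trial(network, p, noise_config(z, derive_seed(base_seed, k)),
                         drive, mask, sim)
    out[, k] <- tr$mask_mean
  }
  out
}

#' Average activity over the masked units
#'
#' @param trial A \code{wc_trial} with \code{e_series} kept.
#' @param mask Optional logical mask; defaults to the trial's own mask.
#' @return Numeric time series (mean over masked units per step).
#' @export
mask_average <- function(trial, mask = NULL) {
  if (is.null(mask)) mask <- trial$mask
  if (is.null(trial$e_series))
    stop("trial was run without keep_units; per-unit series unavailable")
  if (sum(mask) == 0) stop("empty mask")
  rowMeans(trial$e_series[, mask, drop = FALSE])
}
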