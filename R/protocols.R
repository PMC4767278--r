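#' @name protocols
#' @title Seeded resonance-probing protocols
#'
#' @description Runnable reproductions of the simulation experiments: the
#' size experiment (two driven sub-networks of a 50x50 sheet), the
#' connectivity profile of growing sub-networks, the transmission-delay scan,
#' the excitatory/inhibitory degree scans, the single-unit time-constant
#' scan, and the noise/connection-strength scans. Every protocol takes a
#' single integer \code{seed} from which all connectivity, noise and
#' bootstrap seeds derive, and a \code{scale} multiplier in (0, 1] applied
#' to the trial count only -- model parameters are never rescaled.
NULL

scaled_trials <- function(n_trials, scale) {
  stopifnot(scale > 0, scale <= 1)
  max(5L, as.integer(round(n_trials * scale)))
}

# per-condition response matrix: trials x drive frequencies
response_matrix <- function(network, p, freqs, n_trials, base_seed, z, sim,
                            mask, kernel = stimulus_kernel_params()) {
  rmat <- matrix(NA_real_, n_trials, length(freqs))
  slist <- vector("list", length(freqs))
  for (j in seq_along(freqs)) {
    drive <- periodic_drive(freqs[j], sim$n_steps, sim$dt, kernel)
    series <- run_trials(network, n_trials, derive_seed(base_seed, j),
                         p, z, drive, mask, sim)
    specs <- lapply(seq_len(n_trials), function(k)
      power_spectrum(series[, k], sim$dt))
    slist[[j]] <- specs
    rmat[, j] <- vapply(specs, response_power_at, numeric(1), f = freqs[j])
  }
  list(rmat = rmat, spectra = slist)
}

#' Size experiment: resonance of driven sub-networks
#'
#' Builds a \code{side x side} sheet, applies lateral inhibition around each
#' centred mask, drives the masked units with the pulse train at every
#' frequency of the grid, and bootstraps the normalized response power at
#' the drive bin of the mask-averaged series. The driving frequency of
#' maximal bootstrap-mean response estimates the sub-network's resonance.
#'
#' @param seed Master integer seed.
#' @param scale Trial-count multiplier in (0, 1].
#' @param side Sheet side (default 50).
#' @param mask_sides Sides of the driven centred squares (default 10 and 30).
#' @param freqs Driving frequency grid in Hz (default 10-15 in 0.5 steps).
#' @param n_trials Trials per frequency at scale 1 (default 100).
#' @param n_steps Samples per trial (default 2000 at 1 ms).
#' @param z Noise multiplier (default 0.05).
#' @param delay_per_step Delay per unit distance (default 10 steps).
#' @param n_boot Bootstrap resamples (default 1000).
#' @return List with per-mask \code{\link{resonance_curve}}s, the peak
#'   driving frequencies, and the realized configuration.
#' @export
run_size_resonance <- function(seed = 1L, scale = 1, side = 50,
                               mask_sides = c(10, 30),
                               freqs = seq(10, 15, by = 0.5),
                               n_trials = 100L, n_steps = 2000L,
                               z = 0.05, delay_per_step = 10,
                               n_boot = 1000L) {
  n_tr <- scaled_trials(n_trials, scale)
  sim <- sim_config(n_steps = n_steps)
  spec <- lattice_spec(side)
  p <- unit_params()
  curves <- list(); peaks <- numeric(0)
  for (ci in seq_along(mask_sides)) {
    ms <- mask_sides[ci]
    cfg <- connectivity_config(seed = derive_seed(seed, 500000 + ci))
    net <- build_network(spec, cfg, delay_per_step)
    mask <- subnetwork_mask(spec, ms)
    net <- apply_lateral_inhibition(net, mask)
    rm_ <- response_matrix(net, p, freqs, n_tr,
                           derive_seed(seed, 1000 * ci), z, sim, mask)
    boots <- lapply(seq_along(freqs), function(j)
      bootstrap_statistic(rm_$spectra[[j]], freqs[j], n_boot,
                          seed = derive_seed(seed, 900000 + 100 * ci + j)))
    curve <- resonance_curve(freqs,
                             vapply(boots, `[[`, numeric(1), "mean"),
                             vapply(boots, `[[`, numeric(1), "sd"))
    key <- paste0(ms, "x", ms)
    curves[[key]] <- curve
    peaks[key] <- peak_driving_frequency(curve)
  }
  list(curves = curves, peaks = peaks,
       config = list(seed = seed, scale = scale, n_trials = n_tr,
                     side = side, mask_sides = mask_sides, freqs = freqs,
                     n_steps = n_steps, z = z,
                     delay_per_step = delay_per_step, n_boot = n_boot))
}

#' Connectivity profile of growing sub-networks
#'
#' Builds one sheet and reports the mean node degree and mean transmission
#' delay of centred sub-networks of increasing side (edges with both
#' endpoints inside the sub-network only). Both grow steeply while the
#' sub-network is comparable to the local-connection Gaussian and slowly
#' once it is much larger.
#'
#' @param seed Master integer seed.
#' @param side Sheet side (default 100).
#' @param sub_sides Sub-network sides (default 2, 4, ..., side).
#' @param delay_per_step Delay per unit distance (default 10).
#' @return Data frame with columns \code{side}, \code{mean_degree},
#'   \code{mean_delay}.
#' @export
run_connectivity_profile <- function(seed = 1L, side = 100,
                                     sub_sides = seq(2, side, by = 2),
                                     delay_per_step = 10) {
  spec <- lattice_spec(side)
  cfg <- connectivity_config(seed = derive_seed(seed, 500001))
  net <- build_network(spec, cfg, delay_per_step)
  rows <- lapply(sub_sides, function(s) {
    st <- subnetwork_connectivity_stats(net, subnetwork_mask(spec, s))
    data.frame(side = s, mean_degree = st$mean_degree,
               mean_delay = st$mean_delay)
  })
  do.call(rbind, rows)
}

# shared engine for parameter scans estimating resonance per condition
scan_resonance <- function(conditions, make_network, seed, scale, freqs,
                           n_trials, n_steps, z, n_boot, p = unit_params()) {
  n_tr <- scaled_trials(n_trials, scale)
  sim <- sim_config(n_steps = n_steps)
  means <- numeric(length(conditions)); sds <- numeric(length(conditions))
  for (ci in seq_along(conditions)) {
    net <- make_network(conditions[ci], derive_seed(seed, 500000 + ci))
    mask <- subnetwork_mask(net$spec)  # whole network driven
    rm_ <- response_matrix(net, p, freqs, n_tr,
                           derive_seed(seed, 1000 * ci), z, sim, mask)
    bt <- bootstrap_statistic(rm_$spectra, freqs, n_boot,
                              seed = derive_seed(seed, 900000 + ci),
                              statistic = "peak_drive_freq")
    means[ci] <- bt$mean; sds[ci] <- bt$sd
  }
  fit <- if (length(conditions) >= 3) linear_fit(conditions, means) else NULL
  list(table = data.frame(value = conditions, resonance_mean = means,
                          resonance_sd = sds),
       fit = fit,
       config = list(seed = seed, scale = scale, n_trials = n_tr,
                     freqs = freqs, n_steps = n_steps, z = z,
                     n_boot = n_boot))
}

#' Transmission-delay scan
#'
#' Varies the per-unit-distance transmission delay on a fully driven sheet
#' and estimates the resonance frequency per delay as the bootstrap-mean
#' driving frequency of maximal response, then fits resonance against
#' delay by ordinary least squares. Longer delays lower the resonance.
#'
#' @inheritParams run_size_resonance
#' @param delays Delay-per-unit-distance grid (default 10-100 step 10).
#' @param side Sheet side (default 30).
#' @return List with the per-delay table, the \code{\link{linear_fit}}, and
#'   the configuration.
#' @export
run_delay_scan <- function(seed = 1L, scale = 1,
                           delays = seq(10, 100, by = 10),
                           freqs = seq(12, 14, by = 0.2), side = 30,
                           n_trials = 100L, n_steps = 5000L, z = 0.05,
                           n_boot = 1000L) {
  spec <- lattice_spec(side)
  mk <- function(d, cseed)
    build_network(spec, connectivity_config(seed = cseed),
                  delay_per_step = d)
  scan_resonance(delays, mk, seed, scale, freqs, n_trials, n_steps, z,
                 n_boot)
}

#' Local node-degree scans
#'
#' Varies the local excitatory (or inhibitory) out-degree from 0 to 9 with
#' the other kind fixed at 5, under instantaneous transmission so the mean
#' delay cannot grow with the extra edges, and with the long-range edge
#' count held at its degree-5 value. Resonance per degree is the
#' bootstrap-mean peak driving frequency; a linear fit summarizes the trend
#' (negative slope for excitatory degree, positive for inhibitory).
#'
#' @inheritParams run_size_resonance
#' @param varied Which local degree to vary: \code{"exc"} or \code{"inh"}.
#' @param degrees Degree grid (default 0:9).
#' @param fixed_degree Value of the non-varied degree (default 5).
#' @param side Sheet side (default 30).
#' @return As \code{\link{run_delay_scan}}.
#' @export
run_degree_scan <- function(varied = c("exc", "inh"), seed = 1L, scale = 1,
                            degrees = 0:9, fixed_degree = 5,
                            freqs = seq(12, 17, by = 0.2), side = 30,
                            n_trials = 1000L, n_steps = 5000L, z = 0.07,
                            n_boot = 1000L) {
  varied <- match.arg(varied)
  spec <- lattice_spec(side)
  # long-range count frozen at its mid-value (local excitatory degree 5)
  n_lr <- round(0.25 * spec$side^2 * 5)
  mk <- function(g, cseed) {
    k_exc <- if (varied == "exc") g else fixed_degree
    k_inh <- if (varied == "inh") g else fixed_degree
    build_network(spec,
                  connectivity_config(k_exc = k_exc, k_inh = k_inh,
                                      seed = cseed),
                  delay_per_step = 0, n_long_range = n_lr)
  }
  scan_resonance(degrees, mk, seed, scale, freqs, n_trials, n_steps, z,
                 n_boot)
}

# a network holding one isolated unit (k = 0, no long-range); the minimal
# 2x2 lattice is used and a single unit is masked for analysis
single_unit_network <- function(seed) {
  build_network(lattice_spec(2),
                connectivity_config(k_exc = 0, k_inh = 0,
                                    long_range_fraction = 0, seed = seed),
                delay_per_step = 0)
}

#' Single-unit time-constant scan
#'
#' Simulates one uncoupled unit under white noise for each inhibitory time
#' constant, reporting the peak of the trial-averaged normalized spectrum
#' (the unit's intrinsic resonance), and optionally the driven response
#' curve over a frequency grid, whose maximum falls at that resonance.
#'
#' @inheritParams run_size_resonance
#' @param tau_is Inhibitory time constants in seconds
#'   (default 0.017 down to 0.013).
#' @param tau_e Excitatory time constant in seconds (default 0.018).
#' @param n_trials Trials per condition at scale 1 (default 100).
#' @param n_steps Samples per trial (default 5000).
#' @param drive_freqs Entrainment grid in Hz (default 6-13 step 0.2);
#'   \code{NULL} skips the driven runs.
#' @return List with a table (tau_i, spontaneous peak Hz, peak power) and,
#'   when requested, one \code{\link{resonance_curve}} per tau_i.
#' @export
run_single_unit_tau_scan <- function(seed = 1L, scale = 1,
                                     tau_is = seq(0.017, 0.013, by = -0.001),
                                     tau_e = 0.018, n_trials = 100L,
                                     n_steps = 5000L, z = 0.05,
                                     drive_freqs = seq(6, 13, by = 0.2),
                                     n_boot = 1000L) {
  n_tr <- scaled_trials(n_trials, scale)
  sim <- sim_config(n_steps = n_steps)
  net <- single_unit_network(derive_seed(seed, 500002))
  mask <- structure(c(TRUE, FALSE, FALSE, FALSE), side = 2L, sub_side = 1L,
                    class = "wc_mask")
  rows <- list(); curves <- list()
  for (ci in seq_along(tau_is)) {
    p <- unit_params(tau_e = tau_e, tau_i = tau_is[ci])
    series <- run_trials(net, n_tr, derive_seed(seed, 3000 + ci), p, z,
                         drive = NULL, mask = mask, sim = sim)
    avg <- Reduce(`+`, lapply(seq_len(n_tr), function(k)
      power_spectrum(series[, k], sim$dt)$power)) / n_tr
    fr <- power_spectrum(series[, 1], sim$dt)$freqs
    rows[[ci]] <- data.frame(tau_i = tau_is[ci],
                             peak_hz = fr[which.max(avg)],
                             peak_power = max(avg))
    if (!is.null(drive_freqs)) {
      rm_ <- response_matrix(net, p, drive_freqs, n_tr,
                             derive_seed(seed, 4000 + 100 * ci), z, sim,
                             mask)
      boots <- lapply(seq_along(drive_freqs), function(j)
        bootstrap_statistic(rm_$spectra[[j]], drive_freqs[j], n_boot,
                            seed = derive_seed(seed, 910000 + 100 * ci + j)))
      curves[[as.character(tau_is[ci])]] <-
        resonance_curve(drive_freqs,
                        vapply(boots, `[[`, numeric(1), "mean"),
                        vapply(boots, `[[`, numeric(1), "sd"))
    }
  }
  list(table = do.call(rbind, rows), curves = curves,
       config = list(seed = seed, scale = scale, n_trials = n_tr,
                     tau_is = tau_is, tau_e = tau_e, z = z,
                     n_steps = n_steps))
}

#' Noise-level and connection-strength scans
#'
#' Spontaneous (undriven) activity of a sheet while scanning (a) the noise
#' multiplier z and (b) each inter-unit connection strength with z fixed,
#' reporting the peak frequency and peak power of the trial-averaged
#' spectrum per value. The peak frequency rises with noise level over the
#' scanned range and with either connection strength.
#'
#' @inheritParams run_size_resonance
#' @param side Sheet side (default 30).
#' @param z_grid Noise multipliers to scan.
#' @param cs_grid Connection strengths to scan (applied to the excitatory
#'   and, separately, the inhibitory strength).
#' @param z_fixed Noise level used during the strength scans.
#' @param n_trials Trials per value at scale 1 (default 100).
#' @return List of three data frames: \code{noise}, \code{cs_exc},
#'   \code{cs_inh}.
#' @export
run_noise_strength_scan <- function(seed = 1L, scale = 1, side = 30,
                                    z_grid = seq(0.01, 0.11, by = 0.02),
                                    cs_grid = seq(0.05, 0.30, by = 0.05),
                                    z_fixed = 0.05, n_trials = 100L,
                                    n_steps = 5000L) {
  n_tr <- scaled_trials(n_trials, scale)
  sim <- sim_config(n_steps = n_steps)
  spec <- lattice_spec(side)
  p <- unit_params()
  spont_peak <- function(net, z, bseed) {
    series <- run_trials(net, n_tr, bseed, p, z, NULL, NULL, sim)
    specs <- lapply(seq_len(n_tr), function(k) {
      tryCatch(power_spectrum(series[, k], sim$dt), error = function(e) NULL)
    })
    specs <- Filter(Negate(is.null), specs)
    if (length(specs) == 0) return(c(NA_real_, NA_real_))
    avg <- Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs)
    c(specs[[1]]$freqs[which.max(avg)], max(avg))
  }
  noise_rows <- lapply(seq_along(z_grid), function(ci) {
    net <- build_network(spec,
                         connectivity_config(seed = derive_seed(seed, 600000 + ci)),
                         delay_per_step = 10)
    pk <- spont_peak(net, z_grid[ci], derive_seed(seed, 5000 + ci))
    data.frame(z = z_grid[ci], peak_hz = pk[1], peak_power = pk[2])
  })
  cs_rows <- function(kind, base) lapply(seq_along(cs_grid), function(ci) {
    cfg <- if (kind == "exc")
      connectivity_config(ce_strength = cs_grid[ci],
                          seed = derive_seed(seed, base + 100 + ci))
    else
      connectivity_config(ci_strength = cs_grid[ci],
                          seed = derive_seed(seed, base + 200 + ci))
    net <- build_network(spec, cfg, delay_per_step = 10)
    pk <- spont_peak(net, z_fixed, derive_seed(seed, base + 300 + ci))
    data.frame(cs = cs_grid[ci], peak_hz = pk[1], peak_power = pk[2])
  })
  list(noise = do.call(rbind, noise_rows),
       cs_exc = do.call(rbind, cs_rows("exc", 700000)),
       cs_inh = do.call(rbind, cs_rows("inh", 800000)),
       config = list(seed = seed, scale = scale, n_trials = n_tr,
                     side = side, z_grid = z_grid, cs_grid = cs_grid,
                     z_fixed = z_fixed, n_steps = n_steps))
}
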