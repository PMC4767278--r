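#' Area-normalized power spectrum
#'
#' Removes the mean, takes \code{|FFT|^2} at the positive frequencies
#' (the zero-frequency bin is dropped: the statistics of interest are
#' oscillatory and the DC offset of the activity would otherwise dominate
#' the normalization), and divides by the total so the powers sum to one.
#'
#' @param series Numeric time series (length >= 2, finite, non-constant).
#' @param dt Sampling step in seconds.
#' @return A list of class \code{wc_spectrum} with \code{freqs} (Hz,
#'   \code{1/(n dt)} spacing up to the Nyquist bin) and \code{power}
#'   (non-negative, sums to 1).
#' @examples
#' s <- power_spectrum(sin(2 * pi * 12.5 * (1:2000) / 1000), dt = 0.001)
#' s$freqs[which.max(s$power)]  # 12.5
#' @export
power_spectrum <- function(series, dt = 0.001) {
  stopifnot(length(series) >= 2)
  if (!all(is.finite(series))) stop("series contains non-finite values")
  x <- series - mean(series)
  tot <- sum(x^2)
  if (tot == 0) stop("constant series: zero total power after mean removal")
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  half <- 2:(floor(n / 2) + 1)
  p <- P[half]
  structure(list(freqs = (half - 1) / (n * dt), power = p / sum(p)),
            class = "wc_spectrum")
}

#' Normalized power at the bin nearest a frequency
#'
#' @param spec A \code{\link{power_spectrum}}.
#' @param f Target frequency in Hz (within the grid range).
#' @return Normalized power of the nearest frequency bin.
#' @export
response_power_at <- function(spec, f) {
  spec$power[which.min(abs(spec$freqs - f))]
}

#' Steady-state response power: three-nearest-bin maximum
#'
#' The steady-state evoked response statistic: the maximum normalized power
#' over the three frequency bins closest to the stimulus frequency. Robust
#' to the response landing one bin off the nominal drive frequency.
#'
#' @inheritParams response_power_at
#' @return Maximum normalized power over the three nearest bins.
#' @export
ssep_response_power <- function(spec, f) {
  stopifnot(length(spec$freqs) >= 3)
  idx <- order(abs(spec$freqs - f))[1:3]
  max(spec$power[idx])
}

#' Bootstrap a spectral statistic over trials
#'
#' Resamples \code{sample_size} trial spectra with replacement \code{n_boot}
#' times; each resample is averaged into one spectrum and the statistic is
#' evaluated on it. For \code{statistic = "response_at_drive"},
#' \code{spectra} is a list of \code{wc_spectrum} for one condition and
#' \code{f_drive} a single frequency. For \code{"peak_drive_freq"},
#' \code{spectra} is a list over driving frequencies (each element the list
#' of trial spectra for that condition), \code{f_drive} the matching grid,
#' and each resample records the drive frequency of maximal response, with
#' ties broken toward the lower frequency.
#'
#' @param spectra List of \code{wc_spectrum}, or list of such lists (see
#'   Details).
#' @param f_drive Driving frequency (Hz) or grid of frequencies.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Seed of the bootstrap RNG (independent of simulation RNG).
#' @param statistic \code{"response_at_drive"} or \code{"peak_drive_freq"}.
#' @param sample_size Trials per resample; defaults to the number of trials.
#' @return Named list \code{list(mean =, sd =)} over resamples.
#' @export
bootstrap_statistic <- function(spectra, f_drive, n_boot = 1000L,
                                seed = 1L,
                                statistic = c("response_at_drive",
                                              "peak_drive_freq"),
                                sample_size = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(n_boot >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (statistic == "response_at_drive") {
    stopifnot(length(spectra) >= 1, length(f_drive) == 1)
    r <- vapply(spectra, response_power_at, numeric(1), f = f_drive)
    n <- length(r)
    if (is.null(sample_size)) sample_size <- n
    # power at one bin of an average of per-trial normalized spectra equals
    # the average of the per-trial bin powers
    vals <- vapply(seq_len(n_boot), function(b)
      mean(r[sample.int(n, sample_size, replace = TRUE)]), numeric(1))
  } else {
    stopifnot(length(spectra) == length(f_drive))
    rmat <- vapply(seq_along(f_drive), function(j)
      vapply(spectra[[j]], response_power_at, numeric(1), f = f_drive[j]),
      numeric(length(spectra[[1]])))
    n <- nrow(rmat)
    if (is.null(sample_size)) sample_size <- n
    vals <- vapply(seq_len(n_boot), function(b) {
      resp <- vapply(seq_along(f_drive), function(j)
        mean(rmat[sample.int(n, sample_size, replace = TRUE), j]),
        numeric(1))
      f_drive[which.max(resp)]  # which.max takes the first = lowest on ties
    }, numeric(1))
  }
  list(mean = mean(vals), sd = if (n_boot > 1) stats::sd(vals) else 0)
}

#' Resonance curve container
#'
#' @param drive_freqs Driving frequency grid (Hz).
#' @param mean_response,sd_response Bootstrap mean and SD of the response
#'   statistic per driving frequency.
#' @param statistic Which statistic the curve holds.
#' @return An object of class \code{wc_resonance_curve} (also a data frame).
#' @export
resonance_curve <- function(drive_freqs, mean_response, sd_response,
                            statistic = "response_at_drive") {
  stopifnot(length(drive_freqs) == length(mean_response),
            length(mean_response) == length(sd_response),
            all(sd_response >= 0))
  structure(data.frame(drive_hz = drive_freqs, mean = mean_response,
                       sd = sd_response),
            statistic = statistic,
            class = c("wc_resonance_curve", "data.frame"))
}

#' Driving frequency of maximal mean response
#'
#' Ties are broken toward the lower frequency.
#'
#' @param curve A \code{\link{resonance_curve}}.
#' @return Driving frequency (Hz) with the largest mean response.
#' @export
peak_driving_frequency <- function(curve) {
  stopifnot(nrow(curve) >= 1)
  ord <- order(curve$drive_hz)
  curve$drive_hz[ord][which.max(curve$mean[ord])]
}

#' Ordinary least-squares linear fit
#'
#' Simple linear regression of \code{y} on \code{x} with the coefficient of
#' determination and the two-sided t-test p-value of the slope.
#'
#' @param x,y Numeric vectors, length >= 3; \code{x} must not be constant.
#' @return List of class \code{wc_fit}: \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{p_value}.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("degenerate x: no variance")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; those are legitimate inputs here
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4]),
            class = "wc_fit")
}

#' Export a spectrum or resonance curve as CSV
#'
#' Spectra get columns \code{(freq_hz, power)}; resonance curves
#' \code{(drive_hz, mean, sd)}.
#'
#' @param x A \code{wc_spectrum} or \code{wc_resonance_curve}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum_csv <- function(x, path) {
  if (inherits(x, "wc_spectrum"))
    utils::write.csv(data.frame(freq_hz = x$freqs, power = x$power),
                     path, row.names = FALSE)
  else if (inherits(x, "wc_resonance_curve"))
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  else stop("unsupported object")
  invisible(path)
}

#' Score externally recorded epochs
#'
#' Applies the steady-state response statistic to a plain numeric matrix of
#' trial epochs (time x trials/channels), e.g. loaded from a text file, so
#' recorded data can be scored with the same machinery as simulations.
#'
#' @param mat Numeric matrix, time by trials.
#' @param f Stimulus frequency in Hz.
#' @param dt Sampling step in seconds.
#' @return Numeric vector of per-column \code{\link{ssep_response_power}}.
#' @export
score_epochs <- function(mat, f, dt = 0.001) {
  mat <- as.matrix(mat)
  apply(mat, 2, function(col) ssep_response_power(power_spectrum(col, dt), f))
}
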