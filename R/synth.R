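# Latent AR(2) oscillators and mixture models for synthetic multichannel
# series. Channels are linear mixtures Y(t) = A Z(t) + c eps(t) of independent
# AR(2) latent processes with spectral peaks at chosen frequencies, plus iid
# Gaussian sensor noise. This is the standard generative model for
# frequency-specific dependence ("oscillatory communities") in EEG-like data.

#' AR(2) coefficients from characteristic-root magnitude and phase
#'
#' An oscillatory AR(2) process `Z(t) = phi1 Z(t-1) + phi2 Z(t-2) + W(t)` has
#' characteristic roots `M exp(+-i 2 pi psi)` of `Phi(r) = 1 - phi1 r - phi2 r^2`.
#' Solving for the coefficients gives `phi1 = (2 / M) cos(2 pi psi)` and
#' `phi2 = -1 / M^2`. The spectrum of the process peaks near frequency
#' `psi * SR` Hz; magnitudes `M` slightly above 1 concentrate the spectrum
#' tightly around the peak.
#'
#' @param M root magnitude, must exceed 1 (causality).
#' @param psi phase in cycles per sample, strictly inside (0, 0.5).
#' @return named numeric vector `c(phi1, phi2)`.
#' @examples
#' ar2_coefficients(M = 2, psi = 0.25)  # phi1 = 0, phi2 = -0.25
#' @export
ar2_coefficients <- function(M, psi) {
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M <= 1)
    stop("`M` must be a single finite number > 1 (causal roots)")
  if (!is.numeric(psi) || length(psi) != 1L || !is.finite(psi) ||
      psi <= 0 || psi >= 0.5)
    stop("`psi` must lie strictly inside (0, 0.5)")
  c(phi1 = (2 / M) * cos(2 * pi * psi), phi2 = -1 / M^2)
}

#' Specify a latent AR(2) oscillator
#'
#' @param peak_freq spectral peak frequency in Hz.
#' @param sampling_rate sampling rate in Hz; the phase is
#'   `psi = peak_freq / sampling_rate` and must fall in (0, 0.5),
#'   i.e. the peak must be below Nyquist.
#' @param root_magnitude characteristic root magnitude `M > 1`; values close
#'   to 1 give a sharp spectral peak. Default 1.05.
#' @param innovation_sd standard deviation of the white-noise innovations.
#' @return an object of class `ar2_spec` with the derived `psi`, `phi1`, `phi2`.
#' @export
ar2_spec <- function(peak_freq, sampling_rate, root_magnitude = 1.05,
                     innovation_sd = 1) {
  if (innovation_sd <= 0) stop("`innovation_sd` must be positive")
  psi <- peak_freq / sampling_rate
  co <- ar2_coefficients(root_magnitude, psi)
  structure(
    list(peak_freq = peak_freq, sampling_rate = sampling_rate,
         root_magnitude = root_magnitude, innovation_sd = innovation_sd,
         psi = psi, phi1 = unname(co["phi1"]), phi2 = unname(co["phi2"])),
    class = "ar2_spec")
}

#' @export
print.ar2_spec <- function(x, ...) {
  cat(sprintf(
    "AR(2) oscillator: peak %.3g Hz @ SR %.3g Hz (psi = %.4f), M = %.4g\n",
    x$peak_freq, x$sampling_rate, x$psi, x$root_magnitude))
  cat(sprintf("  phi1 = %.6f, phi2 = %.6f, innovation sd = %.3g\n",
              x$phi1, x$phi2, x$innovation_sd))
  invisible(x)
}

#' Closed-form AR(2) spectral density
#'
#' Evaluates `sigma^2 / |1 - phi1 e^{-i w} - phi2 e^{-2 i w}|^2` at
#' `w = 2 pi f / SR` for each requested frequency `f` (Hz).
#'
#' @param spec an [ar2_spec()].
#' @param freqs frequencies in Hz, within `[0, SR/2]`.
#' @return numeric vector of non-negative spectral densities.
#' @export
ar2_spectrum <- function(spec, freqs) {
  stopifnot(inherits(spec, "ar2_spec"))
  if (any(freqs < 0 | freqs > spec$sampling_rate / 2))
    stop("`freqs` must lie within [0, SR/2]")
  omega <- 2 * pi * freqs / spec$sampling_rate
  denom <- Mod(1 - spec$phi1 * exp(-1i * omega) -
                 spec$phi2 * exp(-2i * omega))^2
  spec$innovation_sd^2 / denom
}

#' Simulate a stationary AR(2) sample path
#'
#' Wraps [stats::arima.sim()] with an explicit burn-in so that the returned
#' path is (numerically) stationary. Deterministic given `seed`; with
#' `seed = NULL` the current RNG stream is used, which lets callers drive
#' several simulations from one seeded stream.
#'
#' @param spec an [ar2_spec()].
#' @param n number of samples returned (after burn-in).
#' @param seed optional integer seed.
#' @param burn_in samples discarded at the start; default 500, ample for the
#'   root magnitudes used here (|1/M| decay below 1e-10 within 500 lags for
#'   M >= 1.05).
#' @return numeric vector of length `n`.
#' @export
simulate_ar2 <- function(spec, n, seed = NULL, burn_in = 500) {
  stopifnot(inherits(spec, "ar2_spec"), n >= 1)
  sim <- function() {
    as.numeric(stats::arima.sim(
      model = list(ar = c(spec$phi1, spec$phi2)), n = n,
      sd = spec$innovation_sd, n.start = burn_in))
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Define a latent-mixture model for multichannel series
#'
#' @param mixing P x Q mixing matrix `A`; channel i observes
#'   `sum_q A[i,q] Z_q(t)`. No row may be all zero.
#' @param latents list of Q [ar2_spec()] objects (all must share one
#'   sampling rate).
#' @param sensor_noise_sd scale `c >= 0` of the iid standard-Gaussian sensor
#'   noise added to every channel.
#' @return object of class `mixture_model` carrying the ground-truth
#'   shared-latent adjacency (TRUE where two channels load on at least one
#'   common latent; diagonal TRUE).
#' @export
mixture_model <- function(mixing, latents, sensor_noise_sd = 0) {
  mixing <- as.matrix(mixing)
  if (!all(vapply(latents, inherits, logical(1), "ar2_spec")))
    stop("`latents` must be a list of ar2_spec objects")
  if (ncol(mixing) != length(latents))
    stop("ncol(mixing) must equal the number of latent specs")
  if (any(rowSums(abs(mixing)) == 0))
    stop("`mixing` has an all-zero row: every channel must observe signal")
  if (sensor_noise_sd < 0) stop("`sensor_noise_sd` must be >= 0")
  srs <- vapply(latents, function(s) s$sampling_rate, numeric(1))
  if (length(unique(srs)) != 1L)
    stop("all latents must share one sampling rate")
  loads <- abs(mixing) > 0
  adj <- (loads %*% t(loads)) > 0
  diag(adj) <- TRUE
  structure(
    list(mixing = mixing, latents = latents,
         sensor_noise_sd = sensor_noise_sd,
         sampling_rate = srs[1], ground_truth_adjacency = adj),
    class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Latent AR(2) mixture: %d channels x %d latents, noise sd %.3g, SR %.3g Hz\n",
              nrow(x$mixing), ncol(x$mixing), x$sensor_noise_sd,
              x$sampling_rate))
  invisible(x)
}

#' Simulate a multichannel series from a mixture model
#'
#' Draws independent latent AR(2) paths and iid Gaussian sensor noise, and
#' forms `Y(t) = A Z(t) + c eps(t)`. Deterministic given `seed`.
#'
#' @param model a [mixture_model()].
#' @param n number of time samples.
#' @param seed integer seed (required: every simulation is reproducible).
#' @param burn_in burn-in per latent path, see [simulate_ar2()].
#' @return object of class `simulated_series`: a list with `data`
#'   (P x n matrix, channels in rows), `sampling_rate`, `model`, `seed`.
#' @export
simulate_mixture <- function(model, n, seed, burn_in = 500) {
  stopifnot(inherits(model, "mixture_model"), n >= 1)
  P <- nrow(model$mixing)
  Q <- ncol(model$mixing)
  dat <- withr::with_seed(seed, {
    Z <- matrix(0, Q, n)
    for (q in seq_len(Q))
      Z[q, ] <- simulate_ar2(model$latents[[q]], n, seed = NULL,
                             burn_in = burn_in)
    noise <- matrix(stats::rnorm(P * n), P, n)
    model$mixing %*% Z + model$sensor_noise_sd * noise
  })
  rownames(dat) <- sprintf("ch%d", seq_len(P))
  structure(list(data = dat, sampling_rate = model$sampling_rate,
                 model = model, seed = seed),
            class = "simulated_series")
}

#' @export
print.simulated_series <- function(x, ...) {
  cat(sprintf("Simulated series: %d channels x %d samples @ %.3g Hz (seed %s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, x$seed))
  invisible(x)
}

# Printed mixing matrices for the preset examples (prefactor 1/2 applied for
# the 9-channel designs). Rows are channels, columns latents.
.preset_mixing <- function(name) {
  switch(name,
    # 9 channels over 8 latents: a 4-cycle on channels 1-4 and a second
    # cyclic community on channels 5-9.
    example1 = 0.5 * matrix(c(
      1, 1, 0, 0, 0, 0, 0, 0,
      0, 1, 1, 0, 0, 0, 0, 0,
      0, 0, 1, 1, 0, 0, 0, 0,
      1, 0, 0, 1, 0, 0, 0, 0,
      0, 0, 0, 1, 1, 0, 0, 0,
      0, 0, 0, 0, 1, 1, 0, 0,
      0, 0, 0, 0, 0, 1, 1, 0,
      0, 0, 0, 0, 0, 0, 1, 1,
      0, 0, 0, 0, 1, 0, 0, 1), 9, 8, byrow = TRUE),
    # 9 channels over 5 latents: a cycle on channels 1-4 (+ bridge channel 5)
    # and a complete block of 4 channels (6-9) that all observe latent 5 only.
    example2 = 0.5 * matrix(c(
      1, 1, 0, 0, 0,
      0, 1, 1, 0, 0,
      0, 0, 1, 1, 0,
      1, 0, 0, 1, 0,
      0, 0, 0, 1, 1,
      0, 0, 0, 0, 2,
      0, 0, 0, 0, 2,
      0, 0, 0, 0, 2,
      0, 0, 0, 0, 2), 9, 5, byrow = TRUE),
    # 6 channels, 6 latent copies, cyclic sharing: y_i = Z_{i-1} + Z_i.
    example3_group1 = matrix(c(
      1, 0, 0, 0, 0, 1,
      1, 1, 0, 0, 0, 0,
      0, 1, 1, 0, 0, 0,
      0, 0, 1, 1, 0, 0,
      0, 0, 0, 1, 1, 0,
      0, 0, 0, 0, 1, 1), 6, 6, byrow = TRUE),
    # 6 channels, 6 latent copies, non-cyclic ("random") sharing.
    example3_group2 = matrix(c(
      0, 0, 1, 1, 0, 1,
      0, 1, 0, 0, 0, 1,
      1, 0, 0, 0, 0, 0,
      1, 1, 1, 0, 0, 0,
      0, 0, 0, 1, 1, 0,
      0, 0, 0, 0, 1, 0), 6, 6, byrow = TRUE),
    stop(sprintf("unknown preset '%s'", name)))
}

#' Preset mixture models with cyclic / clique dependence patterns
#'
#' Returns one of four ready-made latent-mixture designs used throughout the
#' package. `"example1"` (9 channels, 8 latents) carries two cyclic
#' communities; `"example2"` (9 channels, 5 latents) carries one cycle plus a
#' complete block of four channels that observe a single shared latent;
#' `"example3_group1"` and `"example3_group2"` (6 channels, 6 latent copies)
#' contrast a cyclic sharing pattern with a non-cyclic one. All latents are
#' iid copies of one oscillator spec.
#'
#' @param name one of `"example1"`, `"example2"`, `"example3_group1"`,
#'   `"example3_group2"`.
#' @param c sensor-noise scale (>= 0).
#' @param peak_freq,sampling_rate,root_magnitude,innovation_sd parameters of
#'   the shared latent oscillator spec; defaults put the spectral peak at
#'   10 Hz (alpha band) for a 100 Hz sampling rate with a sharp peak.
#' @return a [mixture_model()].
#' @export
preset_example <- function(name = c("example1", "example2",
                                    "example3_group1", "example3_group2"),
                           c = 0.05, peak_freq = 10, sampling_rate = 100,
                           root_magnitude = 1.05, innovation_sd = 1) {
  name <- match.arg(name)
  A <- .preset_mixing(name)
  latents <- replicate(ncol(A),
                       ar2_spec(peak_freq, sampling_rate, root_magnitude,
                                innovation_sd),
                       simplify = FALSE)
  mixture_model(A, latents, sensor_noise_sd = c)
}

#' Theoretical coherence of a mixture model at one frequency
#'
#' Closed-form squared coherence implied by the latent mixture: with latent
#' spectra `f_q` at the given frequency and noise spectrum `c^2`,
#' `C_ij = |sum_q A_iq A_jq f_q|^2 / ((sum_q A_iq^2 f_q + c^2)(sum_q A_jq^2 f_q + c^2))`.
#' Serves as the analytic oracle for the spectral-estimation stage. Note that
#' two channels sharing one of their two unit-weight latents have coherence
#' 1/4, not 1, even at `c = 0`.
#'
#' @param model a [mixture_model()].
#' @param freq frequency in Hz.
#' @return symmetric P x P matrix with unit diagonal, entries in `[0, 1]`.
#' @export
theoretical_coherence <- function(model, freq) {
  stopifnot(inherits(model, "mixture_model"), length(freq) == 1L)
  f <- vapply(model$latents, ar2_spectrum, numeric(1), freqs = freq)
  A <- model$mixing
  cross <- A %*% (f * t(A))          # A diag(f) A'
  auto <- diag(cross) + model$sensor_noise_sd^2
  C <- Mod(cross)^2 / outer(auto, auto)
  diag(C) <- 1
  C
}
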