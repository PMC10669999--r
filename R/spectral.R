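# Spectral estimation: Fourier coefficients, smoothed cross-periodogram,
# band-limited coherence, and the coherence-based dependence distance that
# feeds the Vietoris-Rips filtration.

.signal_matrix <- function(x) {
  if (inherits(x, "simulated_series")) x$data
  else if (is.matrix(x)) x
  else stop("`x` must be a simulated_series or a channels-by-time matrix")
}

#' Fourier coefficients of a multichannel series
#'
#' Computes `d(w_k) = (1/T) sum_t X(t) exp(-i w_k t)` at the Fourier
#' frequencies `w_k = 2 pi k / T`, `k = 0..floor(T/2)`, per channel. Channel
#' means are removed first so that the mean structure does not leak into the
#' zero-frequency bin and its neighbours under smoothing. The 1/T
#' normalisation is immaterial for coherence (constant factors cancel in the
#' spectral ratio).
#'
#' @param x a `simulated_series` or a P x T numeric matrix (channels in rows).
#' @param sampling_rate sampling rate in Hz; taken from the series object when
#'   available.
#' @return object of class `fourier_coeffs`: complex matrix `coeffs`
#'   (frequency bins in rows, channels in columns), `freqs` in Hz, `n_time`.
#' @export
fourier_coeffs <- function(x, sampling_rate = NULL) {
  if (inherits(x, "simulated_series") && is.null(sampling_rate))
    sampling_rate <- x$sampling_rate
  dat <- .signal_matrix(x)
  if (is.null(sampling_rate))
    stop("`sampling_rate` is required for a plain matrix input")
  if (!all(is.finite(dat))) stop("input contains non-finite values")
  n <- ncol(dat)
  if (n < 2) stop("need at least 2 time samples")
  centered <- dat - rowMeans(dat)
  d_full <- stats::mvfft(t(centered)) / n       # T x P, channels in columns
  keep <- seq_len(floor(n / 2) + 1L)
  structure(
    list(coeffs = d_full[keep, , drop = FALSE],
         freqs = (keep - 1L) * sampling_rate / n,
         n_time = n, sampling_rate = sampling_rate,
         labels = rownames(dat)),
    class = "fourier_coeffs")
}

# Truncated, renormalised running mean down columns of a matrix.
.runmean_truncated <- function(m, span) {
  h <- (span - 1L) / 2L
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2L, cumsum))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' Smoothed cross-periodogram
#'
#' Forms the per-frequency cross-periodogram matrices `d(w) d(w)*` and
#' averages them over `span` neighbouring Fourier bins with a rectangular
#' (Daniell) kernel whose weights sum to one; windows are truncated and
#' renormalised at the edges of the frequency range. `span = 1` returns the
#' raw cross-periodogram, which is rank one per frequency — coherence
#' computed from it is identically 1, so estimation requires `span > 1`.
#'
#' @param fc a [fourier_coeffs()] object.
#' @param span odd number of bins to average; default 9.
#' @param kernel smoothing kernel; only `"rectangular"` is provided.
#' @return object of class `spectral_matrix`: complex array `values` of
#'   dimension P x P x n_freq (Hermitian slices), `freqs`, `span`.
#' @export
smoothed_periodogram <- function(fc, span = 9, kernel = "rectangular") {
  stopifnot(inherits(fc, "fourier_coeffs"))
  kernel <- match.arg(kernel, "rectangular")
  nf <- nrow(fc$coeffs)
  if (span %% 2 == 0) stop("`span` must be odd")
  if (span < 1 || span >= nf)
    stop("`span` must satisfy 1 <= span < number of Fourier bins")
  P <- ncol(fc$coeffs)
  d <- fc$coeffs
  # cross[k, (i-1)*P + j] = d_i(w_k) * Conj(d_j(w_k))
  idx <- expand.grid(j = seq_len(P), i = seq_len(P))
  cross <- d[, idx$i, drop = FALSE] * Conj(d[, idx$j, drop = FALSE])
  sm <- .runmean_truncated(Re(cross), span) +
    1i * .runmean_truncated(Im(cross), span)
  vals <- array(t(sm), dim = c(P, P, nf))
  structure(
    list(values = vals, freqs = fc$freqs, span = span, kernel = kernel,
         labels = fc$labels, sampling_rate = fc$sampling_rate),
    class = "spectral_matrix")
}

# In-band Fourier bin selector: half-open [low, high), excluding the
# zero-frequency bin and Nyquist.
.band_bins <- function(sp, band) {
  if (length(band) != 2L || band[1] >= band[2])
    stop("`band` must be c(low, high) with low < high")
  nf <- length(sp$freqs)
  interior <- seq_len(nf) > 1L &
    sp$freqs < sp$sampling_rate / 2
  which(interior & sp$freqs >= band[1] & sp$freqs < band[2])
}

# Per-frequency squared coherence for the selected bins, unclipped.
# Returns P x P x nbins array.
.raw_coherence <- function(sp, bins) {
  v <- sp$values[, , bins, drop = FALSE]
  P <- dim(v)[1]
  out <- array(NA_real_, dim(v))
  for (b in seq_along(bins)) {
    f <- v[, , b]
    auto <- Re(diag(f))
    if (any(auto <= 0))
      stop("zero diagonal spectrum in band: signals constant there")
    out[, , b] <- Mod(f)^2 / outer(auto, auto)
  }
  out
}

#' Band-averaged coherence matrix
#'
#' Per-frequency squared coherence `|f_ij|^2 / (f_ii f_jj)` averaged
#' uniformly over the Fourier bins inside the half-open band `[low, high)`
#' (bin 0 and Nyquist excluded). Requires a smoothing span > 1, since the
#' unsmoothed estimate is identically 1. Values are clipped to `[0, 1]`
#' against floating-point overshoot; the pre-clipping maximum over pairs and
#' in-band frequencies is attached as attribute `max_raw`.
#'
#' @param sp a [smoothed_periodogram()] result.
#' @param band numeric `c(low, high)` in Hz; see [band_presets()].
#' @return symmetric P x P matrix of class `coherence_matrix`, unit diagonal,
#'   entries in `[0, 1]`, with attributes `band` and `max_raw`.
#' @export
coherence <- function(sp, band) {
  stopifnot(inherits(sp, "spectral_matrix"))
  if (sp$span <= 1)
    stop("coherence requires smoothing span > 1 (raw periodogram coherence is identically 1)")
  bins <- .band_bins(sp, band)
  if (length(bins) == 0) stop("band contains no Fourier frequencies")
  raw <- .raw_coherence(sp, bins)
  C <- apply(raw, c(1, 2), mean)
  max_raw <- max(raw[rep(!diag(dim(C)[1]), length(bins))])
  C <- pmin(pmax(C, 0), 1)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- list(sp$labels, sp$labels)
  structure(C, band = band, span = sp$span, max_raw = max_raw,
            class = c("coherence_matrix", "matrix", "array"))
}

#' Maximum per-frequency coherence before clipping
#'
#' Maximum of the estimated squared coherence over all off-diagonal channel
#' pairs and the selected frequencies, with no clipping applied: the spectral
#' ratio is mathematically bounded by 1, and this diagnostic checks that the
#' estimator respects the bound up to floating point.
#'
#' @param sp a [smoothed_periodogram()] result.
#' @param band optional `c(low, high)` in Hz; defaults to all interior bins.
#' @return a single number.
#' @export
max_coherence <- function(sp, band = NULL) {
  stopifnot(inherits(sp, "spectral_matrix"))
  bins <- if (is.null(band)) {
    which(seq_along(sp$freqs) > 1L & sp$freqs < sp$sampling_rate / 2)
  } else .band_bins(sp, band)
  raw <- .raw_coherence(sp, bins)
  P <- dim(raw)[1]
  off <- !diag(P)
  max(vapply(seq_along(bins), function(b) max(raw[, , b][off]), numeric(1)))
}

#' Dependence distance from a coherence matrix
#'
#' Applies a decreasing map `G` (default `G(x) = 1 - x`) entrywise to the
#' coherence matrix: strongly coherent channels become close, incoherent ones
#' distant. With the default map, distances lie in `[0, 1]`. `G` is checked
#' for monotone decrease on a probe grid at call time.
#'
#' @param C a [coherence()] matrix (or any symmetric matrix with unit
#'   diagonal and entries in `[0, 1]`).
#' @param G decreasing function on `[0, 1]`.
#' @return symmetric P x P matrix of class `dependence_distance` with zero
#'   diagonal.
#' @export
distance_matrix <- function(C, G = function(x) 1 - x) {
  probe <- G(seq(0, 1, length.out = 101))
  if (any(diff(probe) > 0) || probe[1] <= probe[101])
    stop("`G` must be a decreasing function on [0, 1]")
  D <- matrix(G(as.numeric(C)), nrow(C), ncol(C))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- dimnames(C)
  structure(D, band = attr(C, "band"),
            class = c("dependence_distance", "matrix", "array"))
}

#' Canonical EEG frequency bands
#'
#' The five conventional bands, in Hz: delta (0.5-4), theta (4-8),
#' alpha (8-12), beta (12-30), gamma (30-50). Bands are used half-open
#' `[low, high)` so that adjacent bands partition the axis without double
#' counting shared endpoints.
#'
#' @param name optional single band name; omitted returns the full named list.
#' @return a named list of `c(low, high)` pairs, or one pair.
#' @export
band_presets <- function(name = NULL) {
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                beta = c(12, 30), gamma = c(30, 50))
  if (is.null(name)) return(bands)
  if (!name %in% names(bands))
    stop(sprintf("unknown band '%s' (use %s)", name,
                 paste(names(bands), collapse = ", ")))
  bands[[name]]
}

#' One-call coherence distance
#'
#' Convenience chain: Fourier coefficients, smoothed periodogram, band
#' coherence, distance. This is the per-subject estimation step of the
#' network-topology pipeline.
#'
#' @inheritParams fourier_coeffs
#' @inheritParams coherence
#' @inheritParams smoothed_periodogram
#' @inheritParams distance_matrix
#' @return a `dependence_distance` matrix.
#' @export
coherence_distance <- function(x, band, sampling_rate = NULL, span = 9,
                               G = function(x) 1 - x) {
  sp <- smoothed_periodogram(fourier_coeffs(x, sampling_rate), span = span)
  distance_matrix(coherence(sp, band), G = G)
}
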