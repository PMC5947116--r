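# Multitaper (DPSS) spectral analysis of subthreshold membrane-potential
# traces: power spectra, spectrograms, peak frequency, the theta spectral
# ratio and per-band normalised powers.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the symmetric tridiagonal commuting matrix (Sturm-sequence
#' bisection for the leading eigenvalues, inverse iteration for the
#' eigenvectors); unit-energy columns.
#'
#' @param n sequence length.
#' @param nw time-bandwidth product.
#' @param k number of tapers (at most `2 nw - 1` for good concentration).
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 5, k = 9) {
  stopifnot(n > 2 * k, nw > 0, k >= 1)
  dpss_cpp(as.integer(n), as.numeric(nw), as.integer(k))
}

#' Decimate a trace for spectral analysis
#'
#' Anti-alias low-pass (windowed-sinc FIR at 80 percent of the target
#' Nyquist) followed by subsampling to `fs_out`.  Raw integration output at
#' 100 kHz carries no information of interest above a few hundred Hz; all
#' spectral operations work at 1 kHz by default.
#'
#' @param trace a `stellate_trace` (or list with `t`, `V` on a uniform grid).
#' @param fs_out output sampling rate (Hz).
#' @param n_taps FIR length (odd).
#' @return list with `V` (decimated samples), `fs` (Hz), `t` (ms).
#' @export
decimate_trace <- function(trace, fs_out = 1000, n_taps = 127) {
  dt <- diff(trace$t[1:2]) # ms
  fs_in <- 1000 / dt
  if (fs_in < fs_out) stop("trace is sampled below the requested output rate")
  fac <- fs_in / fs_out
  if (abs(fac - round(fac)) > 1e-8)
    stop("input rate must be an integer multiple of the output rate")
  fac <- as.integer(round(fac))
  V <- trace$V
  if (fac > 1L) {
    fc <- 0.8 * (fs_out / 2) / fs_in # normalised cutoff (cycles/sample)
    m <- (n_taps - 1) / 2
    x <- seq(-m, m)
    h <- 2 * fc * sinc(2 * fc * x) * (0.54 + 0.46 * cos(pi * x / m)) # Hamming
    h <- h / sum(h)
    # reflect-pad to avoid edge transients
    pad <- c(rev(V[2:(m + 1)]), V, rev(V[(length(V) - m):(length(V) - 1)]))
    Vf <- stats::filter(pad, h, sides = 2)
    V <- as.numeric(Vf[(m + 1):(m + length(V))])
    V <- V[seq(1, length(V), by = fac)]
  }
  list(V = V, fs = fs_out, t = trace$t[seq(1, length(trace$t), by = fac)][seq_along(V)])
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Multitaper power spectral density
#'
#' Average of the eigenspectra over `n_tapers` DPSS tapers at
#' time-bandwidth product `time_bandwidth`; one-sided density scaled so
#' that the integral over frequency equals the signal variance (Parseval).
#' The mean is removed before tapering.
#'
#' @param x a `stellate_trace` (decimated internally to `fs`), or a numeric
#'   vector sampled at `fs`.
#' @param fs sampling rate in Hz (ignored when `x` is a trace).
#' @param n_tapers number of DPSS tapers.
#' @param time_bandwidth time-bandwidth product NW.
#' @return an object of class `power_spectrum`: data frame
#'   (`frequency` Hz, `power` mV^2/Hz) with metadata attributes.
#' @export
multitaper_psd <- function(x, fs = 1000, n_tapers = 9, time_bandwidth = 5) {
  if (inherits(x, "stellate_trace")) {
    d <- decimate_trace(x, fs_out = fs)
    x <- d$V
    fs <- d$fs
  }
  n <- length(x)
  if (n < 8 * n_tapers) stop("trace shorter than the taper support")
  x <- x - mean(x)
  tap <- dpss_tapers(n, nw = time_bandwidth, k = n_tapers)
  X <- mvfft(tap * x)
  nf <- floor(n / 2) + 1
  S <- rowMeans(Mod(X[1:nf, , drop = FALSE])^2) / fs
  # one-sided: double everything except DC (and Nyquist when n is even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  S <- S * dbl
  out <- data.frame(frequency = (seq_len(nf) - 1) * fs / n, power = S)
  structure(out, class = c("power_spectrum", "data.frame"),
            n_tapers = n_tapers, time_bandwidth = time_bandwidth,
            fs = fs, n = n)
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum>  %d bins to %.4g Hz (%d tapers, NW = %g)\n",
              nrow(x), max(x$frequency), attr(x, "n_tapers"),
              attr(x, "time_bandwidth")))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, xlim = c(0, 50), ...) {
  graphics::plot(x$frequency, x$power, type = "l", xlim = xlim,
                 xlab = "frequency (Hz)", ylab = "power (mV^2/Hz)", ...)
  invisible(x)
}

#' Peak frequency of a spectrum
#'
#' Frequency of maximum power inside `band`, refined by parabolic
#' interpolation around the maximal bin.  A peak is flagged as not
#' dominant when the in-band maximum is less than `prominence` times the
#' in-band median (attribute `dominant`).
#'
#' @param spectrum a `power_spectrum`.
#' @param band search band (Hz).
#' @param prominence max/median ratio required to declare a dominant peak.
#' @return peak frequency (Hz) with attribute `dominant` (logical).
#' @export
peak_frequency <- function(spectrum, band = c(1, 50), prominence = 2) {
  sel <- spectrum$frequency >= band[1] & spectrum$frequency <= band[2]
  if (!any(sel)) stop("empty search band")
  f <- spectrum$frequency[sel]
  p <- spectrum$power[sel]
  i <- which.max(p)
  fpk <- f[i]
  if (i > 1 && i < length(p)) { # parabolic refinement
    y1 <- p[i - 1]; y2 <- p[i]; y3 <- p[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) fpk <- f[i] + 0.5 * (y1 - y3) / den * (f[2] - f[1])
  }
  structure(fpk, dominant = max(p) / median(p) >= prominence)
}

band_integral <- function(spectrum, band) {
  sel <- spectrum$frequency >= band[1] & spectrum$frequency <= band[2]
  if (sum(sel) < 2) stop("insufficient bandwidth for band [", band[1], ", ",
                         band[2], "] Hz")
  f <- spectrum$frequency[sel]
  p <- spectrum$power[sel]
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Theta spectral ratio
#'
#' Total theta-band (4-12 Hz) power over total broadband (1-300 Hz) power,
#' by trapezoidal integration of the density.
#'
#' @param spectrum a `power_spectrum` covering 1-300 Hz.
#' @return ratio in [0, 1].
#' @export
theta_ratio <- function(spectrum) {
  if (max(spectrum$frequency) < 300)
    stop("spectrum does not cover the 1-300 Hz broadband")
  band_integral(spectrum, c(4, 12)) / band_integral(spectrum, c(1, 300))
}

#' Band powers normalised by bandwidth
#'
#' Total power in the delta (1-3 Hz), theta (4-12 Hz), beta (15-30 Hz) and
#' gamma (30-300 Hz) bands, each divided by its width in Hz.
#'
#' @param spectrum a `power_spectrum` covering 1-300 Hz.
#' @return named numeric vector (`delta`, `theta`, `beta`, `gamma`).
#' @export
band_powers <- function(spectrum) {
  bands <- list(delta = c(1, 3), theta = c(4, 12), beta = c(15, 30),
                gamma = c(30, 300))
  vapply(bands, function(b) band_integral(spectrum, b) / diff(b), 0)
}

#' Multitaper spectrogram
#'
#' Multitaper PSD in sliding windows.
#'
#' @param trace a `stellate_trace` or numeric vector.
#' @param fs sampling rate (Hz; traces are decimated to this).
#' @param window window length (ms).
#' @param overlap fractional overlap in [0, 1).
#' @param n_tapers,time_bandwidth taper configuration.
#' @return an object of class `stellate_spectrogram`: list with `t` (window
#'   centres, ms), `frequency` (Hz), `power` (frequency x time matrix).
#' @export
spectrogram <- function(trace, fs = 1000, window = 2000, overlap = 0.5,
                        n_tapers = 9, time_bandwidth = 5) {
  if (inherits(trace, "stellate_trace")) {
    d <- decimate_trace(trace, fs_out = fs)
    x <- d$V
  } else x <- as.numeric(trace)
  nwin <- round(window * fs / 1000)
  if (nwin > length(x)) stop("window longer than the trace")
  hop <- max(1, round(nwin * (1 - overlap)))
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  tap <- dpss_tapers(nwin, nw = time_bandwidth, k = n_tapers)
  nf <- floor(nwin / 2) + 1
  P <- matrix(0, nf, length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nwin - 1)]
    seg <- seg - mean(seg)
    X <- mvfft(tap * seg)
    S <- rowMeans(Mod(X[1:nf, , drop = FALSE])^2) / fs
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nwin %% 2 == 0) dbl[nf] <- 1
    P[, i] <- S * dbl
  }
  structure(list(t = (starts - 1 + nwin / 2) / fs * 1000,
                 frequency = (seq_len(nf) - 1) * fs / nwin, power = P),
            class = "stellate_spectrogram")
}

#' @export
print.stellate_spectrogram <- function(x, ...) {
  cat(sprintf("<stellate_spectrogram>  %d windows x %d frequencies (to %.4g Hz)\n",
              ncol(x$power), nrow(x$power), max(x$frequency)))
  invisible(x)
}
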