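## Processing chain: periodic Hann window -> FFT -> exact-bin harmonic
## magnitudes -> H3/H5 ratio -> repeat averaging -> SNR gate.

#' Periodic Hann window
#'
#' `w[j] = 0.5 * (1 - cos(2 pi j / n))` for `j = 0..n-1`. The periodic (DFT)
#' form keeps on-bin tones exactly on-bin over the record, and its coherent
#' gain (mean weight) is exactly 0.5.
#'
#' @param n Window length, >= 2.
#' @return Numeric weight vector of length `n`.
#' @export
hann_window <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  j <- 0:(n - 1)
  0.5 * (1 - cos(2 * pi * j / n))
}

#' One-sided amplitude spectrum of a windowed trace
#'
#' Magnitudes of the DFT of the Hann-windowed voltage, indexed by frequency
#' bin 0..n/2 with bin width `delta_f = fs / n` (10 Hz for the default 0.1 s
#' record at 1 MS/s). Magnitudes are raw bin moduli: no window-gain or
#' amplifier-gain correction is applied, since both cancel in the H3/H5
#' ratio; absolute values are instrument-scale.
#'
#' @param trace An [acquisition_trace()], or a numeric voltage vector (then
#'   `fs` is required).
#' @param fs Sampling rate (Hz) when `trace` is a bare vector.
#' @return Object of class `harmonic_spectrum`: list with `magnitude`
#'   (length `n/2 + 1`, bins 0..n/2), `delta_f`, `fs`, `n`.
#' @export
amplitude_spectrum <- function(trace, fs = NULL) {
  if (inherits(trace, "acquisition_trace")) {
    v <- trace$voltage
    fs <- trace$meta$fs
    if (is.null(fs)) fs <- 1 / diff(trace$time[1:2])
    dt <- diff(trace$time)
    if (length(dt) && any(abs(dt - dt[1L]) > 1e-9 * dt[1L])) {
      stop("trace time grid is not uniform", call. = FALSE)
    }
  } else if (is.numeric(trace)) {
    v <- trace
    if (is.null(fs)) stop("`fs` is required for a bare voltage vector", call. = FALSE)
  } else {
    stop("`trace` must be an acquisition_trace or numeric vector", call. = FALSE)
  }
  n <- length(v)
  w <- hann_window(n)
  X <- fft(w * v)
  structure(list(magnitude = Mod(X[1:(n %/% 2 + 1)]), delta_f = fs / n,
                 fs = fs, n = n),
            class = "harmonic_spectrum")
}

#' @export
print.harmonic_spectrum <- function(x, ...) {
  cat(sprintf("<harmonic_spectrum> n = %d, delta_f = %g Hz, fs = %g Hz\n",
              x$n, x$delta_f, x$fs))
  invisible(x)
}

#' Bin index of harmonic k
#'
#' The k-th harmonic of `f0` must fall exactly on a bin (`k * f0` an integer
#' multiple of `delta_f`) and below Nyquist; otherwise an error is raised.
#'
#' @param spectrum A `harmonic_spectrum`.
#' @param f0 Fundamental frequency (Hz).
#' @param k Harmonic order.
#' @return Zero-based bin index (`k * f0 / delta_f`).
#' @export
harmonic_bin <- function(spectrum, f0, k) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  f <- k * f0
  if (f >= spectrum$fs / 2) {
    stop(sprintf("harmonic %d at %g Hz is at or above Nyquist (%g Hz)",
                 k, f, spectrum$fs / 2), call. = FALSE)
  }
  idx <- f / spectrum$delta_f
  if (abs(idx - round(idx)) > 1e-6) {
    stop(sprintf(paste0("harmonic %d at %g Hz is not an integer multiple of ",
                        "the bin width delta_f = %g Hz"),
         k, f, spectrum$delta_f), call. = FALSE)
  }
  as.integer(round(idx))
}

#' Single-bin harmonic magnitude
#'
#' Magnitude of the FFT bin exactly at `k * f0`: no interpolation and no
#' neighbor-bin summation. The Hann window spreads tone energy into the two
#' adjacent bins, but the spread factor is identical for every on-bin
#' harmonic and so cancels in the ratio.
#'
#' @inheritParams harmonic_bin
#' @return Bin magnitude (instrument-scale).
#' @export
harmonic_amplitude <- function(spectrum, f0, k) {
  spectrum$magnitude[harmonic_bin(spectrum, f0, k) + 1L]
}

#' Third-to-fifth harmonic ratio
#'
#' The diagnostic metric `R = H3 / H5`. Window gain, amplifier gain, coil
#' sensitivity and particle concentration all scale H3 and H5 equally, so R
#' is self-normalized. If H5 does not exceed `noise_floor` the ratio is
#' undefined and an error is raised rather than a number returned.
#'
#' @inheritParams harmonic_bin
#' @param noise_floor Magnitude floor below which H5 is considered lost in
#'   noise. Default 0 (always defined).
#' @return The ratio R (dimensionless).
#' @export
harmonic_ratio <- function(spectrum, f0, noise_floor = 0) {
  h3 <- harmonic_amplitude(spectrum, f0, 3L)
  h5 <- harmonic_amplitude(spectrum, f0, 5L)
  if (h5 <= noise_floor) {
    stop(sprintf("low signal: H5 = %g does not exceed the noise floor %g; ratio undefined",
                 h5, noise_floor), call. = FALSE)
  }
  h3 / h5
}

#' Average per-repeat ratios
#'
#' Arithmetic mean and sample standard deviation over the repeat
#' acquisitions of one sample. For a single repeat the dispersion is
#' reported as 0 by convention.
#'
#' @param per_repeat Nonempty numeric vector of per-repeat ratios.
#' @return List with `mean` and `sd`.
#' @export
average_ratio <- function(per_repeat) {
  if (!is.numeric(per_repeat) || length(per_repeat) == 0L) {
    stop("`per_repeat` must be a nonempty numeric vector", call. = FALSE)
  }
  list(mean = mean(per_repeat),
       sd = if (length(per_repeat) > 1L) sd(per_repeat) else 0)
}

#' Signal-to-noise quality gate
#'
#' Passes when both H3 and H5 exceed `noise_floor`. The floor is a
#' configuration value standing in for the instrument's detection limit;
#' `margin` is the smaller of H3/floor and H5/floor (Inf at floor 0).
#'
#' @inheritParams harmonic_bin
#' @param noise_floor Magnitude floor, >= 0.
#' @return List with `pass` (logical) and `margin`.
#' @export
snr_gate <- function(spectrum, f0, noise_floor) {
  stopifnot(is.numeric(noise_floor), length(noise_floor) == 1L, noise_floor >= 0)
  h3 <- harmonic_amplitude(spectrum, f0, 3L)
  h5 <- harmonic_amplitude(spectrum, f0, 5L)
  margin <- if (noise_floor == 0) Inf else min(h3, h5) / noise_floor
  list(pass = h3 > noise_floor && h5 > noise_floor, margin = margin)
}

#' Analyze one acquisition trace
#'
#' @param trace An [acquisition_trace()].
#' @param f0 Fundamental frequency (Hz); taken from the trace metadata when
#'   omitted.
#' @param noise_floor SNR gate floor.
#' @return One-row data frame: sample_id, repeat_index, h3, h5, ratio,
#'   qc_pass, margin.
#' @export
analyze_trace <- function(trace, f0 = NULL, noise_floor = 0) {
  stopifnot(inherits(trace, "acquisition_trace"))
  if (is.null(f0)) f0 <- trace$meta$f0
  if (is.null(f0)) stop("`f0` not given and absent from trace metadata", call. = FALSE)
  sp <- amplitude_spectrum(trace)
  gate <- snr_gate(sp, f0, noise_floor)
  data.frame(sample_id = trace$sample_id, repeat_index = trace$repeat_index,
             h3 = harmonic_amplitude(sp, f0, 3L),
             h5 = harmonic_amplitude(sp, f0, 5L),
             ratio = if (gate$pass) harmonic_ratio(sp, f0, noise_floor) else NA_real_,
             qc_pass = gate$pass, margin = gate$margin)
}

#' Analyze a set of traces into per-sample ratio results
#'
#' Ratios are computed per repeat and then averaged per sample (mean and
#' sample standard deviation), following the repeat-averaging protocol.
#'
#' @param traces List of [acquisition_trace()] objects.
#' @param f0 Fundamental frequency (Hz); trace metadata is used when omitted.
#' @param noise_floor SNR gate floor.
#' @return Object of class `ratio_results`: list with `samples` (one row per
#'   sample: sample_id, n_repeats, mean_ratio, std_ratio, h3, h5, qc_pass)
#'   and `repeats` (the per-repeat table).
#' @export
analyze_traces <- function(traces, f0 = NULL, noise_floor = 0) {
  if (!is.list(traces) || length(traces) == 0L) {
    stop("`traces` must be a nonempty list of acquisition traces", call. = FALSE)
  }
  rep_tab <- do.call(rbind, lapply(traces, analyze_trace, f0 = f0,
                                   noise_floor = noise_floor))
  rownames(rep_tab) <- NULL
  ids <- unique(rep_tab$sample_id)
  samples <- do.call(rbind, lapply(ids, function(id) {
    rr <- rep_tab[rep_tab$sample_id == id, ]
    ok <- all(rr$qc_pass)
    avg <- if (ok) average_ratio(rr$ratio) else list(mean = NA_real_, sd = NA_real_)
    data.frame(sample_id = id, n_repeats = nrow(rr), mean_ratio = avg$mean,
               std_ratio = avg$sd, h3 = mean(rr$h3), h5 = mean(rr$h5),
               qc_pass = ok)
  }))
  rownames(samples) <- NULL
  structure(list(samples = samples, repeats = rep_tab), class = "ratio_results")
}

#' @export
print.ratio_results <- function(x, ...) {
  cat(sprintf("<ratio_results> %d samples, %d traces\n",
              nrow(x$samples), nrow(x$repeats)))
  print(x$samples, digits = 4)
  invisible(x)
}
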