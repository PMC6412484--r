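#' Phenotype stage configuration
#'
#' Parameters of the frequency-domain fusion distinguishing the
#' shuffling-forward from the trembling-in-place FOG phenotype.
#'
#' @param fir_cutoff_hz Cut-off of the linear-phase FIR low-pass applied to
#'   the per-leg product traces (Hz, default 2): shuffling content lies
#'   below 2 Hz.
#' @param fir_taps Number of FIR taps (odd integer, default 101) so the
#'   group delay is an integer number of samples and can be compensated
#'   exactly.
#' @param psd_band_hz Half-open analysis band `(low, high]` of the PSD in
#'   Hz (default `c(0, 2)`): the DC bin is excluded so the product's offset
#'   cannot dominate the index.
#' @param psd_method `"welch"` (default; 4-s Hann segments, 50% overlap,
#'   used when the episode holds at least two segments) or
#'   `"periodogram"` (plain mean-removed periodogram; also the automatic
#'   fallback for short episodes).
#' @param welch_segment_s Welch segment length in seconds (default 4).
#' @param geomean_floor Floor applied inside the geometric mean so
#'   `log(0)` never occurs (default 1e-12).
#' @param pi_threshold Decision level on PI (default 20, near the geometric
#'   midpoint of the two phenotype classes): `PI >= pi_threshold` labels
#'   shuffling, below labels trembling.
#' @return A list of class `phenotype_config`.
#' @export
phenotype_config <- function(fir_cutoff_hz = 2, fir_taps = 101L,
                             psd_band_hz = c(0, 2),
                             psd_method = c("welch", "periodogram"),
                             welch_segment_s = 4, geomean_floor = 1e-12,
                             pi_threshold = 20) {
  psd_method <- match.arg(psd_method)
  fir_taps <- as.integer(fir_taps)
  if (fir_taps < 3L || fir_taps %% 2L == 0L)
    stop("phenotype_config: fir_taps must be an odd integer >= 3",
         call. = FALSE)
  if (length(psd_band_hz) != 2L || psd_band_hz[1] < 0 ||
      psd_band_hz[2] <= psd_band_hz[1])
    stop("phenotype_config: psd_band_hz must be an increasing (low, high]",
         call. = FALSE)
  if (pi_threshold <= 1)
    stop("phenotype_config: pi_threshold must be > 1", call. = FALSE)
  if (geomean_floor <= 0)
    stop("phenotype_config: geomean_floor must be > 0", call. = FALSE)
  structure(list(fir_cutoff_hz = fir_cutoff_hz, fir_taps = fir_taps,
                 psd_band_hz = psd_band_hz, psd_method = psd_method,
                 welch_segment_s = welch_segment_s,
                 geomean_floor = geomean_floor,
                 pi_threshold = pi_threshold),
            class = "phenotype_config")
}

#' Pointwise product of the sEMG envelope and the normalized gyro trace
#'
#' First fusion step: the product of the two normalized traces of one leg
#' over a FOG episode. In shuffling episodes the sEMG maxima coincide with
#' the gyro negative minima, so the product shows a series of negative
#' peaks; in trembling episodes it varies randomly around zero.
#'
#' @param envelope A `semg_envelope` [signal_trace()].
#' @param gyro_norm The session-normalized gyro [signal_trace()] of the
#'   same side, on the same grid.
#' @return A [signal_trace()] with `channel = "fused"`.
#' @export
fuse_product <- function(envelope, gyro_norm) {
  stopifnot(inherits(envelope, "signal_trace"),
            inherits(gyro_norm, "signal_trace"))
  if (envelope$side != gyro_norm$side)
    stop("fuse_product: traces must come from the same side", call. = FALSE)
  if (length(envelope$values) != length(gyro_norm$values) ||
      envelope$fs != gyro_norm$fs)
    stop("fuse_product: traces must share the sample grid", call. = FALSE)
  signal_trace(envelope$values * gyro_norm$values, envelope$fs,
               channel = "fused", side = envelope$side,
               muscle = envelope$muscle, units = "normalized",
               t0 = envelope$t0)
}

#' Linear-phase FIR low-pass with group-delay compensation
#'
#' Hamming-windowed FIR design (unity DC gain). The output is shifted back
#' by the `(taps - 1) / 2` sample group delay so it stays aligned with the
#' input grid; the trace is zero-padded at the edges.
#'
#' @param trace A [signal_trace()].
#' @param cfg A [phenotype_config()].
#' @return The filtered [signal_trace()], same length and grid.
#' @export
fir_lowpass <- function(trace, cfg = phenotype_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$values
  n <- length(x)
  if (cfg$fir_taps >= n)
    stop("fir_lowpass: fir_taps must be smaller than the trace length",
         call. = FALSE)
  if (trace$fs <= 2 * cfg$fir_cutoff_hz)
    stop("fir_lowpass: fs must exceed twice the cutoff", call. = FALSE)
  b <- signal::fir1(cfg$fir_taps - 1L, cfg$fir_cutoff_hz / (trace$fs / 2),
                    type = "low")
  b <- as.numeric(b) / sum(b)  # enforce exactly unity DC gain
  d <- (cfg$fir_taps - 1L) %/% 2L
  y_full <- stats::convolve(x, rev(b), type = "open")  # full convolution
  out <- trace
  out$values <- y_full[(d + 1L):(d + n)]
  out$normalized <- FALSE
  out
}

#' Right-minus-left bilateral difference
#'
#' Third fusion step: subtracting the left-leg filtered product from the
#' right-leg one. Antiphase periodic legs (shuffling) reinforce into a
#' sinusoid-like trace of doubled fundamental amplitude; independent random
#' legs (trembling) yield an incoherent residual.
#'
#' @param right,left Filtered product [signal_trace()]s of the right and
#'   left leg on the same grid.
#' @return A [signal_trace()] `right - left` (carries `side = "right"`).
#' @export
bilateral_subtract <- function(right, left) {
  stopifnot(inherits(right, "signal_trace"), inherits(left, "signal_trace"))
  if (length(right$values) != length(left$values) || right$fs != left$fs)
    stop("bilateral_subtract: traces must share the sample grid",
         call. = FALSE)
  out <- right
  out$values <- right$values - left$values
  out$normalized <- FALSE
  out
}

.hann <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

.periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x)
  nf <- n %/% 2L + 1L
  p <- (Mod(X[1:nf])^2) / (fs * n)
  mult <- rep(2, nf)
  mult[1] <- 1
  if (n %% 2L == 0L) mult[nf] <- 1
  list(freqs = (0:(nf - 1)) * fs / n, psd = p * mult)
}

.welch <- function(x, fs, seg_len) {
  n <- length(x)
  step <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- .hann(seg_len)
  U <- sum(w^2)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    acc <- acc + (Mod(X[1:nf])^2) / (fs * U)
  }
  p <- acc / length(starts)
  mult <- rep(2, nf)
  mult[1] <- 1
  if (seg_len %% 2L == 0L) mult[nf] <- 1
  list(freqs = (0:(nf - 1)) * fs / seg_len, psd = p * mult)
}

#' One-sided power spectral density of a fused trace
#'
#' Welch's method (Hann window, 50% overlap, mean removed per segment) when
#' the trace holds at least two segments, otherwise a plain mean-removed
#' periodogram. The periodogram satisfies Parseval's relation exactly:
#' `sum(psd) * df == mean((x - mean(x))^2)`.
#'
#' @param trace A [signal_trace()] of at least 2 s of samples.
#' @param cfg A [phenotype_config()].
#' @return A list with `freqs` (Hz), `psd` (units^2/Hz, nonnegative), `df`
#'   (frequency resolution) and `method` actually used.
#' @export
compute_psd <- function(trace, cfg = phenotype_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$values
  fs <- trace$fs
  if (length(x) < 2 * fs)
    stop("compute_psd: episode shorter than 2 s, PI unreliable",
         call. = FALSE)
  seg_len <- as.integer(round(cfg$welch_segment_s * fs))
  if (cfg$psd_method == "welch" && length(x) >= 2L * seg_len) {
    r <- .welch(x, fs, seg_len)
    method <- "welch"
  } else {
    r <- .periodogram(x, fs)
    method <- "periodogram"
  }
  list(freqs = r$freqs, psd = r$psd, df = r$freqs[2] - r$freqs[1],
       method = method)
}

#' Phenotype index: band-limited max over geometric mean of the PSD
#'
#' `PI = max(PSD) / geometric_mean(PSD)` over the half-open band
#' `(low, high]`. A single dominant spectral line (shuffling) drives PI far
#' above one; a flat, incoherent spectrum (trembling) keeps it near one.
#' PSD values are floored at `geomean_floor` inside the logarithm.
#'
#' @param psd Numeric vector of PSD values.
#' @param freqs Matching frequency grid in Hz.
#' @param cfg A [phenotype_config()].
#' @return The scalar PI, always `>= 1`.
#' @export
phenotype_index <- function(psd, freqs, cfg = phenotype_config()) {
  if (length(psd) != length(freqs))
    stop("phenotype_index: psd and freqs must have equal length",
         call. = FALSE)
  band <- cfg$psd_band_hz
  sel <- freqs > band[1] + 1e-9 & freqs <= band[2] + 1e-9
  if (sum(sel) < 4L)
    stop("phenotype_index: fewer than 4 PSD bins inside the analysis band",
         call. = FALSE)
  v <- pmax(psd[sel], cfg$geomean_floor)
  max(v) / exp(mean(log(v)))
}

#' Phenotype label from a PI value
#'
#' @param PI Phenotype index (`>= 1`).
#' @param cfg A [phenotype_config()].
#' @return `"shuffling"` when `PI >= pi_threshold` (ties to shuffling),
#'   else `"trembling"`.
#' @export
classify_phenotype <- function(PI, cfg = phenotype_config()) {
  if (PI >= cfg$pi_threshold) "shuffling" else "trembling"
}

#' Phenotype analysis of one episode
#'
#' Runs the full fusion chain on a session over the time interval
#' `[start_s, end_s)`: per leg, the product of the TA sEMG envelope and the
#' session-normalized gyro trace, FIR low-pass at 2 Hz, right-minus-left
#' subtraction, PSD, and the phenotype index with its label.
#'
#' @param session A [recording_session()] holding TA gyro and sEMG traces
#'   for both sides.
#' @param start_s,end_s Episode bounds in seconds (at least 2 s long).
#' @param cfg A [phenotype_config()].
#' @param pre_cfg A [preprocess_config()] for the envelopes.
#' @param muscle Device used (default `"TA"`).
#' @return A list of class `phenotype_result` with `freqs`, `psd`, `PI`,
#'   `label`, `start_s`, `end_s` and the fused `diff` trace.
#' @export
phenotype_episode <- function(session, start_s, end_s,
                              cfg = phenotype_config(),
                              pre_cfg = preprocess_config(),
                              muscle = "TA") {
  legs <- lapply(c("right", "left"), function(side) {
    gyro <- normalize_abs_max(get_trace(session, side, muscle, "gyro_z"))
    env <- semg_envelope(get_trace(session, side, muscle, "semg_raw"),
                         pre_cfg)
    prod <- fuse_product(slice_trace(env, start_s, end_s),
                         slice_trace(gyro, start_s, end_s))
    fir_lowpass(prod, cfg)
  })
  d <- bilateral_subtract(legs[[1]], legs[[2]])
  spec <- compute_psd(d, cfg)
  PI <- phenotype_index(spec$psd, spec$freqs, cfg)
  structure(list(freqs = spec$freqs, psd = spec$psd, df = spec$df,
                 method = spec$method, PI = PI,
                 label = classify_phenotype(PI, cfg),
                 start_s = start_s, end_s = end_s, diff = d),
            class = "phenotype_result")
}

#' @export
print.phenotype_result <- function(x, ...) {
  cat(sprintf("<phenotype_result> [%.2f, %.2f) s: PI = %.2f -> %s (%s)\n",
              x$start_s, x$end_s, x$PI, x$label, x$method))
  invisible(x)
}
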