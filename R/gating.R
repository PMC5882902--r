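#' Image-based cardiac motion signal
#'
#' For each pair of consecutive frames the signal mixes (i) one minus the
#' Pearson correlation of the two frames (decorrelation grows with motion)
#' and (ii) the sum of negative gradient magnitudes of the first frame
#' (image sharpness drops during fast motion), weighted by `alpha_g`:
#' \deqn{s(n) = \alpha_g [1 - corr(I_n, I_{n+1})] + (1-\alpha_g) \sum -|\nabla I_n|}
#' Intensities are normalized to \[0,1\] first so the two terms are
#' comparable across acquisitions.
#'
#' @param seq an `image_sequence` with at least 2 frames
#' @param alpha_g mixture weight in \[0, 1\]
#' @return numeric vector s(n), n = 1..N-1
#' @export
motion_signal <- function(seq, alpha_g = 0.5) {
  stopifnot(inherits(seq, "image_sequence"), alpha_g >= 0, alpha_g <= 1,
            length(seq$frames) >= 2)
  fr <- lapply(seq$frames, normalize_intensity)
  N <- length(fr)
  s <- numeric(N - 1)
  for (n in seq_len(N - 1)) {
    a <- fr[[n]]; b <- fr[[n + 1]]
    sa <- stats::sd(a); sb <- stats::sd(b)
    # constant frame (sigma = 0): degenerate, the correlation term is 0
    corr_term <- if (sa == 0 || sb == 0) 0 else
      1 - stats::cor(as.vector(a), as.vector(b))
    gx <- a[, c(2:ncol(a), ncol(a))] - a
    gy <- a[c(2:nrow(a), nrow(a)), ] - a
    grad <- -sum(sqrt(gx^2 + gy^2)) / length(a)
    s[n] <- alpha_g * corr_term + (1 - alpha_g) * grad
  }
  s
}

# zero-phase low-pass by hard cutoff in the FFT domain
lowpass_fft <- function(x, fc, fs) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)            # two-sided
  X[freq > fc] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n + mean(x)
}

local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
}

#' Cardiac gating of a motion signal
#'
#' Extracts the mean cardiac frequency as the dominant spectral mode of the
#' motion signal within the physiological band 0.75-1.66 Hz, low-pass
#' filters the signal with cut-frequency 1.4 f_m (zero-phase FFT cutoff),
#' and takes the minima of the filtered signal as end-diastolic frames.  The
#' minima are then refined iteratively: the cut-frequency is raised as
#' f_c = (k + 0.4) f_m and each minimum is snapped to the nearest local
#' minimum of the re-filtered signal, until positions are stable (or k =
#' 10); duplicates from collapsed minima are merged.  Frames are labeled
#' with a per-beat phase index (1..S, S = shortest beat length in frames);
#' later frames of longer beats (the variable T-P interval) stay unlabeled.
#'
#' @param signal motion signal from [motion_signal()]
#' @param frame_rate acquisition rate (Hz)
#' @param band physiological heart-rate band (Hz)
#' @param max_refine maximum refinement iterations
#' @return a `gating_result`: list with `mean_cardiac_freq` (Hz),
#'   `end_diastolic_indices`, `phase_labels`, `low_pass_signal`, `beats`,
#'   `n_phases`
#' @export
gate <- function(signal, frame_rate, band = c(0.75, 1.66), max_refine = 10) {
  n <- length(signal)
  if (n < 2 * frame_rate / band[1])
    stop("signal shorter than two cardiac periods")
  X <- Mod(stats::fft(signal - mean(signal)))[1:(n %/% 2 + 1)]
  freq <- (0:(n %/% 2)) / n * frame_rate
  inband <- which(freq >= band[1] & freq <= band[2])
  if (!length(inband) || all(X[inband] <= 0))
    stop("gating failure: no spectral peak inside the physiological band")
  pk <- inband[which.max(X[inband])]
  if (X[pk] < 1e-12) stop("gating failure: no spectral peak inside the physiological band")
  f_m <- freq[pk]

  sl <- lowpass_fft(signal, 1.4 * f_m, frame_rate)
  minima <- local_minima(sl)
  if (!length(minima)) stop("gating failure: no minima in the low-pass signal")
  for (k in seq_len(max_refine)) {
    fc <- (k + 0.4) * f_m
    slk <- lowpass_fft(signal, fc, frame_rate)
    cand <- local_minima(slk)
    if (!length(cand)) break
    new_min <- vapply(minima, function(m) cand[which.min(abs(cand - m))],
                      integer(1))
    new_min <- sort(unique(new_min))       # collapsed duplicates merged
    if (length(new_min) == length(minima) && all(new_min == minima)) {
      minima <- new_min
      break
    }
    minima <- new_min
  }

  # per-beat phase labels over the (stable) leading part of each beat
  nfr <- n + 1L
  phase <- rep(NA_integer_, nfr)
  beat <- rep(NA_integer_, nfr)
  if (length(minima) >= 2) {
    lens <- diff(minima)
    S <- max(1L, min(lens))
    for (b in seq_len(length(minima) - 1)) {
      idx <- minima[b] + 0:(S - 1L)
      phase[idx] <- seq_len(S)
      beat[idx] <- b
    }
  } else S <- NA_integer_
  structure(list(mean_cardiac_freq = f_m,
                 end_diastolic_indices = minima,
                 phase_labels = phase, beats = beat, n_phases = S,
                 low_pass_signal = sl, signal = signal,
                 frame_rate = frame_rate),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("gating_result: f_m = %.3f Hz, %d end-diastolic frames, S = %s phases\n",
              x$mean_cardiac_freq, length(x$end_diastolic_indices),
              x$n_phases))
  invisible(x)
}

#' Gating table (frame, beat, phase, end-diastole flag)
#' @param g a `gating_result`
#' @return data.frame suitable for CSV export
#' @export
gating_table <- function(g) {
  nfr <- length(g$phase_labels)
  data.frame(frame = seq_len(nfr),
             beat = g$beats,
             phase = g$phase_labels,
             is_end_diastole = seq_len(nfr) %in% g$end_diastolic_indices)
}
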