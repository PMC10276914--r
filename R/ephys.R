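# Template-fit detection and summarisation of spontaneous / miniature
# excitatory postsynaptic currents (sEPSC / mEPSC). Events are inward
# (negative-going) deflections; amplitudes are reported as positive
# magnitudes.

#' Construct an event template from kinetics
#'
#' @param rise_tau_ms,decay_tau_ms Time constants (decay > rise).
#' @param sample_rate_hz Sampling rate the template is sampled at.
#' @return An `epsc_template`: unit-peak-magnitude difference-of-exponentials
#'   waveform (negative-going) with kinetics metadata.
#' @export
epsc_template <- function(rise_tau_ms, decay_tau_ms, sample_rate_hz) {
  w <- epsc_kernel(rise_tau_ms, decay_tau_ms, sample_rate_hz)
  structure(list(waveform = as.numeric(w),
                 peak_index = attr(w, "peak_index"),
                 rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
                 sample_rate_hz = sample_rate_hz,
                 n_source_events = NA_integer_),
            class = "epsc_template")
}

#' @export
print.epsc_template <- function(x, ...) {
  cat(sprintf("<epsc_template> rise tau %.3g ms, decay tau %.3g ms, %g Hz, %d samples%s\n",
              x$rise_tau_ms, x$decay_tau_ms, x$sample_rate_hz,
              length(x$waveform),
              if (is.na(x$n_source_events)) "" else
                sprintf(", averaged from %d events", x$n_source_events)))
  invisible(x)
}

#' Build an event template from representative events
#'
#' Baseline-subtracted snippets around the supplied candidate onsets are
#' peak-aligned, averaged and normalised to unit peak magnitude; rise and
#' decay constants are then fitted to the average. Between 10 and 20
#' candidates are required, the number of representative events a template
#' is refined from.
#'
#' @param trace An `epsc_trace` (tibble `time_s`, `current_pa` with a
#'   `sample_rate_hz` attribute) from [generate_trace()] or [read_trace()].
#' @param candidate_times_s Onset times (seconds) of 10-20 representative
#'   events.
#' @param pre_ms Baseline window before each onset (median-estimated),
#'   default 5 ms.
#' @param post_ms Snippet length after onset, default 40 ms.
#' @return An `epsc_template` with fitted kinetics and `n_source_events`.
#' @export
build_template <- function(trace, candidate_times_s, pre_ms = 5,
                           post_ms = 40) {
  n_cand <- length(candidate_times_s)
  if (n_cand < 10 || n_cand > 20)
    abort(sprintf("a template is built from 10-20 representative events, got %d.",
                  n_cand))
  fs <- attr(trace, "sample_rate_hz")
  if (is.null(fs)) abort("trace lacks a sample_rate_hz attribute.")
  y <- trace$current_pa
  npre <- round(pre_ms / 1000 * fs)
  npost <- round(post_ms / 1000 * fs)
  snips <- matrix(NA_real_, n_cand, npost)
  peaks <- integer(n_cand)
  for (i in seq_len(n_cand)) {
    i0 <- floor(candidate_times_s[i] * fs) + 1L
    if (i0 - npre < 1 || i0 + npost - 1 > length(y))
      abort("candidate event too close to the trace boundary.")
    base <- median(y[(i0 - npre):(i0 - 1)])
    s <- y[i0:(i0 + npost - 1)] - base
    snips[i, ] <- s
    peaks[i] <- which.min(s)
  }
  if (max(abs(snips)) == 0)
    abort("degenerate (flat) candidate events: cannot build a template.")
  # peak-align on the median peak position
  ref <- round(median(peaks))
  for (i in seq_len(n_cand)) {
    shift <- peaks[i] - ref
    snips[i, ] <- if (shift > 0) c(snips[i, -seq_len(shift)], rep(0, shift))
    else if (shift < 0) c(rep(0, -shift), snips[i, seq_len(npost + shift)])
    else snips[i, ]
  }
  avg <- colMeans(snips)
  pk <- which.min(avg)
  if (avg[pk] >= 0) abort("averaged candidates have no negative-going peak.")
  w <- avg / abs(avg[pk])

  taus <- fit_event_kinetics(w, fs, pk)
  structure(list(waveform = w, peak_index = pk,
                 rise_tau_ms = taus[["rise_tau_ms"]],
                 decay_tau_ms = taus[["decay_tau_ms"]],
                 sample_rate_hz = fs, n_source_events = n_cand),
            class = "epsc_template")
}

# fit a difference of exponentials to a unit-magnitude negative waveform
fit_event_kinetics <- function(w, fs, peak_index) {
  t_ms <- (seq_along(w) - 1) / fs * 1000
  # onset: last sample before the peak with |w| < 2% of peak
  pre <- which(abs(w[seq_len(peak_index)]) < 0.02)
  t0 <- if (length(pre)) t_ms[max(pre)] else 0
  df <- data.frame(t = t_ms, y = w)
  df <- df[df$t >= t0, ]
  start <- list(td = max(t_ms[peak_index] - t0, 0.5) * 3, tr = max(t_ms[peak_index] - t0, 0.5) / 2,
                s = 1)
  model <- function(t, s, tr, td) {
    tt <- pmax(t - t0, 0)
    -s * (exp(-tt / td) - exp(-tt / tr))
  }
  fit <- tryCatch({
    if (requireNamespace("minpack.lm", quietly = TRUE)) {
      minpack.lm::nlsLM(y ~ model(t, s, tr, td), data = df, start = start,
                        lower = c(td = 1e-3, tr = 1e-4, s = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      nls(y ~ model(t, s, tr, td), data = df, start = start,
          algorithm = "port", lower = c(td = 1e-3, tr = 1e-4, s = 1e-3))
    }
  }, error = function(e) abort(paste0("kinetics fit failed: ", conditionMessage(e))))
  cf <- coef(fit)
  c(rise_tau_ms = min(cf[["tr"]], cf[["td"]]),
    decay_tau_ms = max(cf[["tr"]], cf[["td"]]))
}

#' Detect synaptic events by sliding template fit
#'
#' At every offset the template is fitted to the trace by least squares with
#' free scale and offset; the detection criterion is the fitted scale
#' divided by its standard error. Local criterion maxima above
#' `criterion_threshold` become candidate events; candidates closer than the
#' template's time-to-peak are merged keeping the higher criterion, and any
#' event with fitted amplitude at or below `amp_min_pa` (the 0-10 pA band)
#' is discarded. Analysis is restricted to `window_s` seconds starting at
#' `offset_s`. Detection is invariant to a constant holding-current offset.
#'
#' @param trace An `epsc_trace`.
#' @param template An `epsc_template`; a sampling-rate mismatch with the
#'   trace is resolved by linear resampling (messaged).
#' @param criterion_threshold Detection criterion threshold (default 3).
#' @param amp_min_pa Amplitude gate in pA (default 10): events with fitted
#'   amplitude in `(0, amp_min_pa]` are discarded.
#' @param window_s Analysis window length in seconds (default 60).
#' @param offset_s Window start (default 0).
#' @return Tibble of event records: `time_s` (onset), `amplitude_pa`
#'   (positive magnitude), `rise_10_90_ms`, `decay_tau_ms`, `fit_score`.
#' @export
detect_events <- function(trace, template, criterion_threshold = 3,
                          amp_min_pa = 10, window_s = 60, offset_s = 0) {
  stopifnot(inherits(template, "epsc_template"))
  fs <- attr(trace, "sample_rate_hz")
  if (is.null(fs)) abort("trace lacks a sample_rate_hz attribute.")
  y_all <- trace$current_pa
  i0 <- round(offset_s * fs) + 1L
  i1 <- min(length(y_all), i0 + round(window_s * fs) - 1L)
  if (i1 - i0 + 1 < length(template$waveform))
    abort("trace shorter than the analysis window/template.")
  y <- y_all[i0:i1]

  w <- template$waveform
  if (!isTRUE(all.equal(template$sample_rate_hz, fs))) {
    message(sprintf("resampling template from %g Hz to %g Hz",
                    template$sample_rate_hz, fs))
    old_t <- (seq_along(w) - 1) / template$sample_rate_hz
    new_t <- seq(0, max(old_t), by = 1 / fs)
    w <- stats::approx(old_t, w, xout = new_t)$y
  }
  L <- length(w)
  n <- length(y)
  nw <- n - L + 1L

  # sliding least-squares fit of y ~ a*w + b via running sums
  Sx <- sum(w); Sxx <- sum(w^2)
  cy <- c(0, cumsum(y)); cyy <- c(0, cumsum(y^2))
  Sy <- cy[(L + 1):(n + 1)] - cy[1:nw]
  Syy <- cyy[(L + 1):(n + 1)] - cyy[1:nw]
  Sxy <- cross_corr(y, w)
  denom <- L * Sxx - Sx^2
  a <- (L * Sxy - Sx * Sy) / denom
  b <- (Sy - a * Sx) / L
  sse <- Syy + a^2 * Sxx + L * b^2 + 2 * a * b * Sx - 2 * a * Sxy - 2 * b * Sy
  sse[sse < 0] <- 0
  se <- sqrt(sse / (L - 2) / (Sxx - Sx^2 / L))
  crit <- ifelse(se > 0, a / se, 0)

  # one candidate per contiguous above-threshold segment of the criterion:
  # the criterion stays elevated along an event's decay tail, so accepting
  # every local maximum would double-count; a new event requires the
  # criterion to fall below threshold and rise again
  above <- crit > criterion_threshold & a > 0
  if (!any(above)) return(empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- which(r$values)
  cand <- vapply(segs, function(s) {
    i <- starts[s]:ends[s]
    i[which.max(crit[i])]
  }, integer(1))
  # merge candidates within one template time-to-peak, keep higher criterion
  merge_win <- template$peak_index
  cand <- cand[order(crit[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (ci in cand) {
    if (!length(kept) || all(abs(kept - ci) > merge_win)) kept <- c(kept, ci)
  }
  kept <- sort(kept)

  rows <- lapply(kept, function(ci) {
    amp <- a[ci]
    kin <- event_kinetics(y, ci, w, amp, b[ci], fs, template$peak_index)
    tibble::tibble(time_s = (i0 - 1 + ci - 1) / fs,
                   amplitude_pa = amp,
                   rise_10_90_ms = kin[["rise"]],
                   decay_tau_ms = kin[["decay"]],
                   fit_score = crit[ci])
  })
  ev <- dplyr::bind_rows(rows)
  ev <- ev[ev$amplitude_pa > amp_min_pa, , drop = FALSE]
  class(ev) <- c("epsc_events", class(ev))
  ev
}

empty_events <- function() {
  ev <- tibble::tibble(time_s = numeric(0), amplitude_pa = numeric(0),
                       rise_10_90_ms = numeric(0), decay_tau_ms = numeric(0),
                       fit_score = numeric(0))
  class(ev) <- c("epsc_events", class(ev))
  ev
}

# cross-correlation Sxy(i) = sum_j w_j * y_{i+j-1}, i = 1..n-L+1 (FFT-based)
cross_corr <- function(y, w) {
  n <- length(y); L <- length(w)
  m <- stats::nextn(n + L, 2)
  Y <- stats::fft(c(y, rep(0, m - n)))
  W <- stats::fft(c(w, rep(0, m - L)))
  full <- Re(stats::fft(Y * Conj(W), inverse = TRUE)) / m
  full[1:(n - L + 1)]
}

# per-event rise 10-90% and single-exponential decay tau from the raw trace
event_kinetics <- function(y, onset, w, amp, base, fs, peak_index) {
  L <- length(w)
  seg <- y[onset:min(length(y), onset + L - 1)] - base
  pk <- which.min(seg[seq_len(min(length(seg), peak_index * 3))])
  rise <- NA_real_
  if (pk > 1) {
    mag <- -seg[seq_len(pk)]
    t10 <- crossing_time(mag, 0.1 * abs(amp))
    t90 <- crossing_time(mag, 0.9 * abs(amp))
    if (!is.na(t10) && !is.na(t90) && t90 >= t10)
      rise <- (t90 - t10) / fs * 1000
  }
  decay <- NA_real_
  post <- -seg[pk:length(seg)]
  # fit the contiguous 100% -> 20% stretch of the decay (single-exponential
  # regime, before the tail sinks into the noise)
  below <- which(post < 0.2 * abs(amp))
  last <- if (length(below)) max(2L, below[1] - 1L) else length(post)
  keep <- which(post[seq_len(last)] > 0)
  if (length(keep) >= 5) {
    tt <- (keep - 1) / fs * 1000
    fitc <- stats::lm.fit(cbind(1, tt), log(post[keep]))$coefficients
    if (is.finite(fitc[2]) && fitc[2] < 0) decay <- -1 / unname(fitc[2])
  }
  c(rise = unname(rise), decay = unname(decay))
}

# first (interpolated) index at which `mag` crosses `level` from below
crossing_time <- function(mag, level) {
  above <- which(mag >= level)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1) return(0)
  frac <- (level - mag[i - 1]) / (mag[i] - mag[i - 1])
  (i - 2) + frac
}

#' Summarise detected events over the analysis window
#'
#' @param events An `epsc_events` tibble from [detect_events()].
#' @param window_s Analysis window in seconds (default 60: frequency is the
#'   event count over exactly this window).
#' @return One-row tibble: `n_events`, `frequency_hz`, `mean_amplitude_pa`,
#'   `mean_rise_10_90_ms`, `mean_decay_tau_ms`, `kinetics_defined` (FALSE
#'   when no event was detected: means are `NA`).
#' @export
summarize_events <- function(events, window_s = 60) {
  check_scalar(window_s, "window_s", min = 0, strict = TRUE)
  n <- nrow(events)
  tibble::tibble(
    n_events = n,
    frequency_hz = n / window_s,
    mean_amplitude_pa = if (n) mean(events$amplitude_pa) else NA_real_,
    mean_rise_10_90_ms = if (n) mean(events$rise_10_90_ms, na.rm = TRUE) else NA_real_,
    mean_decay_tau_ms = if (n) mean(events$decay_tau_ms, na.rm = TRUE) else NA_real_,
    kinetics_defined = n > 0)
}
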