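# Kinematics: sensor frame -> vertical displacement -> strides -> features.

#' Rotate a sensor trace into the horse/gravity frame
#'
#' Applies the per-sample rotation given by the trace's Euler angles and
#' returns the gravity-aligned vertical acceleration with gravity removed.
#' The world frame is right-handed with x positive forward, z positive up
#' (aligned with gravity) and y to the left of the horse; in that frame a
#' positive pitch of 90 degrees maps the sensor x axis onto world z (nose-up
#' rotation), and roll is a right-handed rotation about x.
#'
#' @param trace A sensor trace: data frame with columns `t`, `ax`, `ay`,
#'   `az` (m/s^2) and Euler angles `roll`, `pitch`, `yaw` (degrees), e.g.
#'   from [simulate_landmark_signal()] or [read_sensor_trace()].
#' @return Numeric vector of vertical acceleration \[m/s^2\], gravity
#'   subtracted.
#' @export
#' @examples
#' tr <- data.frame(t = 0:9 / 100, ax = 0, ay = 0, az = 9.81,
#'                  roll = 0, pitch = 0, yaw = 0)
#' rotate_to_horse_frame(tr) # all zero
rotate_to_horse_frame <- function(trace) {
  need <- c("ax", "ay", "az")
  if (!all(need %in% names(trace))) {
    abort("Trace must contain acceleration columns ax, ay, az.",
      class = "lungesym_error_schema"
    )
  }
  if (!all(c("roll", "pitch", "yaw") %in% names(trace))) {
    abort(
      paste(
        "Trace has no orientation channels (roll, pitch, yaw).",
        "Supply orientation angles, or add zero-angle columns if the data",
        "are already gravity-aligned."
      ),
      class = "lungesym_error_orientation"
    )
  }
  r <- trace$roll * pi / 180
  p <- trace$pitch * pi / 180
  # world-z row of R = Rz(yaw) Ry(-pitch) Rx(roll); yaw does not enter z
  sin(p) * trace$ax + cos(p) * sin(r) * trace$ay + cos(p) * cos(r) * trace$az -
    GRAVITY
}

# zero-phase high-pass: order-2 Butterworth run forward and backward
# (4th-order net response).
highpass_zero_phase <- function(x, cutoff_hz, sample_rate) {
  wc <- cutoff_hz / (sample_rate / 2)
  stopifnot(wc > 0, wc < 1)
  bf <- signal::butter(2, wc, type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

# cumulative trapezoid with a symmetric spectral correction: the trapezoid
# rule attenuates a component at digital frequency theta by 1 - theta^2/12;
# pre-filtering the integrand with the zero-phase kernel (-1, 14, -1)/12
# (response 1 + theta^2/12 + O(theta^4)) cancels that bias to fourth order
# while staying single-chain and bounded up to Nyquist.
cumtrapz_corr <- function(x, dt) {
  n <- length(x)
  if (n >= 3) {
    xc <- x
    xc[2:(n - 1)] <- (14 * x[2:(n - 1)] - x[1:(n - 2)] - x[3:n]) / 12
    x <- xc
  }
  c(0, cumsum((x[-1] + x[-n]) / 2)) * dt
}

#' Double-integrate vertical acceleration to displacement
#'
#' Cumulative trapezoidal double integration with drift suppression: a
#' zero-phase fourth-order Butterworth high-pass (cutoff at one quarter of
#' the stride frequency) is applied to the acceleration and again to the
#' velocity; the displacement is then reduced to two zero-phase pass bands
#' around the stride frequency and its double (the tones that carry the
#' per-stride feature content of trot displacement) and de-meaned over the
#' record. The quarter-stride high-pass cutoff keeps the amplitude loss of
#' the stride-frequency component below about 1% while removing
#' integration drift; the tone bands reject wide-band sensor noise.
#'
#' @param acc_z Vertical acceleration \[m/s^2\], gravity removed.
#' @param sample_rate Sampling rate \[Hz\].
#' @param stride_freq_hint Approximate stride frequency \[Hz\] (strides per
#'   second); see [estimate_stride_frequency()].
#' @param tone_bands Apply the stride-tone pass bands (default `TRUE`).
#'   Disable to keep the broadband displacement, e.g. for stride
#'   segmentation of strongly jittered gait where the tone sidebands are
#'   wide.
#' @return Vertical displacement \[mm\], zero mean over the record.
#' @export
#' @examples
#' fs <- 100; t <- seq(0, 10, by = 1 / fs)
#' acc <- -0.03 * (2 * pi / 0.75)^2 * sin(2 * pi * t / 0.75)
#' d <- integrate_to_displacement(acc, fs, stride_freq_hint = 1 / 0.75)
integrate_to_displacement <- function(acc_z, sample_rate, stride_freq_hint,
                                      tone_bands = TRUE) {
  bad <- which(!is.finite(acc_z))
  if (length(bad) > 0) {
    abort(paste0("Non-finite acceleration sample at index ", bad[1], "."),
      class = "lungesym_error_nonfinite"
    )
  }
  if (stride_freq_hint <= 0) {
    abort("`stride_freq_hint` must be > 0.", class = "lungesym_error_params")
  }
  cutoff <- 0.25 * stride_freq_hint
  dt <- 1 / sample_rate
  acc_f <- highpass_zero_phase(acc_z, cutoff, sample_rate)
  vel <- cumtrapz_corr(acc_f, dt)
  vel_f <- highpass_zero_phase(vel, cutoff, sample_rate)
  disp <- cumtrapz_corr(vel_f, dt)
  # matched smoothing: the per-stride feature content of trot displacement
  # lives in the stride frequency and its double, so the displacement is
  # reduced to two zero-phase pass bands centred on those tones (geometric
  # edge factors 1.2 and 1.15, wide enough for stride-time jitter and the
  # autocorrelation period quantization). Out-of-band sensor noise is
  # rejected; out-of-band gait harmonics are a documented non-goal of the
  # feature set.
  band <- function(x, centre, s) {
    # geometric band edges put the Butterworth response peak on the tone
    bf <- signal::butter(2, c(centre / s, centre * s) / (sample_rate / 2),
      type = "pass")
    as.numeric(signal::filtfilt(bf, x))
  }
  f1 <- stride_freq_hint
  if (tone_bands && 2.3 * f1 < 0.5 * sample_rate) {
    disp <- band(disp, f1, 1.2) + band(disp, 2 * f1, 1.15)
  }
  (disp - mean(disp)) * 1000
}

#' Estimate the stride frequency of a cyclic signal
#'
#' Autocorrelation-based estimate of the dominant oscillation period; for
#' midline trot signals (two vertical oscillations per stride) the stride
#' period is twice the dominant period. The first autocorrelation peak above
#' 0.5 at lags between 0.2 and 0.8 s is taken as the oscillation period.
#'
#' @param x Signal (vertical acceleration or displacement) of a midline
#'   landmark.
#' @param sample_rate Sampling rate \[Hz\].
#' @return Stride frequency \[Hz\].
#' @export
estimate_stride_frequency <- function(x, sample_rate) {
  if (sd(x) < 1e-12) {
    abort("Signal has no cycles (constant input).", class = "lungesym_error_segmentation")
  }
  max_lag <- min(length(x) - 2, ceiling(0.9 * sample_rate))
  # suppress wide-band sensor noise before the autocorrelation; trot
  # harmonics live below ~8 Hz
  if (sample_rate > 20) {
    bf <- signal::butter(2, 8 / (sample_rate / 2), type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  a <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
  lags <- seq_along(a) - 1
  lo <- ceiling(0.2 * sample_rate)
  # local maxima of the acf
  cand <- which(diff(sign(diff(a))) < 0) # interior peaks, index into a
  cand <- cand[lags[cand] >= lo & a[cand] > 0.5]
  if (length(cand) == 0) {
    abort("No periodicity found between 0.2 and 0.8 s; cannot segment.",
      class = "lungesym_error_segmentation"
    )
  }
  step_period <- lags[cand[1]] / sample_rate
  1 / (2 * step_period)
}

#' Segment a displacement series into strides
#'
#' Picks stride boundaries as displacement minima of a midline landmark
#' (sacrum preferred): the stride period is estimated by autocorrelation
#' (twice the dominant oscillation period), local minima are selected
#' phase-locked tracking from the deepest trough outward (one boundary per
#' estimated period, jitter-tolerant search window), and
#' consecutive selected minima delimit strides. Strides whose duration
#' deviates more than 25% from the running median are discarded as
#' non-steady-state.
#'
#' @param displacement Vertical displacement \[mm\] of a midline landmark.
#' @param sample_rate Sampling rate \[Hz\].
#' @param min_strides Minimum number of retained strides (default 15).
#' @return Object of class `stride_set`: tibble with columns `stride_id`,
#'   `start`, `end` (sample indices, half-open `[start, end)`) and
#'   `stride_time` \[ms\]; attributes `n_discarded` and `stride_freq` \[Hz\].
#' @export
#' @examples
#' fs <- 100; t <- seq(0, 15 - 1 / fs, by = 1 / fs)
#' d <- -30 * cos(2 * pi * t / 0.375)
#' segment_strides(d, fs, min_strides = 10)
segment_strides <- function(displacement, sample_rate, min_strides = 15) {
  f_stride <- estimate_stride_frequency(displacement, sample_rate)
  period <- round(sample_rate / f_stride) # samples per stride
  n <- length(displacement)

  d <- displacement
  is_min <- c(FALSE, d[2:(n - 1)] < d[1:(n - 2)] & d[2:(n - 1)] <= d[3:n], FALSE)
  # only troughs of the oscillation, not noise wiggles near the mean
  depth_cut <- quantile(d, 0.35)
  cand <- which(is_min & d < depth_cut)
  if (length(cand) < 2) {
    abort("No cycles found in displacement; cannot segment.",
      class = "lungesym_error_segmentation"
    )
  }
  # anchor at the deepest trough, then walk outward one stride at a time,
  # accepting the deepest candidate within a jitter-tolerant window around
  # one period; this keeps the boundary phase-locked to the same
  # within-cycle landmark even when the two troughs of a stride are almost
  # equally deep
  # earliest of the near-deepest troughs (ties within 0.25 mm), so a
  # perfectly symmetric gait still anchors deterministically
  cmin <- min(d[cand])
  anchor <- cand[d[cand] <= cmin + 0.25][1]
  walk <- function(from, step) {
    out <- integer(0)
    cur <- from
    repeat {
      gaps <- (cand - cur) * step
      w <- cand[gaps >= 0.7 * period & gaps <= 1.35 * period]
      if (length(w) == 0) {
        # tolerate one missed trough: skip a stride, flagged later by the
        # stride-time outlier rule
        w <- cand[gaps >= 1.65 * period & gaps <= 2.4 * period]
      }
      if (length(w) == 0) break
      cur <- w[which.min(d[w])]
      out <- c(out, cur)
    }
    out
  }
  bounds <- sort(c(walk(anchor, -1), anchor, walk(anchor, 1)))
  if (length(bounds) < 2) {
    abort("Fewer than 2 stride boundaries found.", class = "lungesym_error_segmentation")
  }

  stride_time <- diff(bounds) / sample_rate * 1000
  k <- min(7L, length(stride_time) - (length(stride_time) + 1) %% 2)
  run_med <- if (length(stride_time) >= 3) {
    runmed(stride_time, max(3L, k))
  } else {
    rep(median(stride_time), length(stride_time))
  }
  ok <- abs(stride_time - run_med) / run_med <= 0.25

  strides <- tibble(
    stride_id = cumsum(ok) * ok, # 0 for discarded, renumber kept below
    start = bounds[-length(bounds)],
    end = bounds[-1],
    stride_time = stride_time
  )[ok, ] %>%
    mutate(stride_id = row_number())

  if (nrow(strides) < min_strides) {
    abort(
      paste0(
        "Only ", nrow(strides), " steady-state strides retained; ",
        min_strides, " required."
      ),
      class = "lungesym_error_too_few_strides"
    )
  }
  attr(strides, "n_discarded") <- sum(!ok)
  attr(strides, "stride_freq") <- f_stride
  class(strides) <- c("stride_set", class(strides))
  strides
}

# Extremum of d over window [lo, hi] (sample indices, clamped); returns the
# argmin/argmax, or NA if it lies on the window edge (no clear trough/peak).
window_extremum <- function(d, lo, hi, maximum = FALSE) {
  lo <- max(1L, round(lo)); hi <- min(length(d), round(hi))
  if (hi - lo < 2) return(NA_integer_)
  w <- d[lo:hi]
  i <- if (maximum) which.max(w) else which.min(w)
  if (i == 1 || i == length(w)) return(NA_integer_)
  lo + i - 1L
}

#' Extract per-stride displacement features
#'
#' Trot displacement of a midline landmark alternates minimum / maximum
#' every quarter stride, and segmentation cuts at minima; each of the four
#' extrema is therefore located as the extremum of a quarter-stride-centred
#' search window, which is robust to a few samples of boundary jitter
#' between landmarks.
#'
#' For every retained stride and midline landmark: the two local minima, two
#' local maxima and two upward amplitudes (each maximum minus its
#' immediately preceding minimum), attributed to the left or right diagonal
#' step via the per-sample step-side labels. For each tuber coxae: the
#' upward amplitude during the contralateral hind stance (the step matching
#' the landmark's own side label) and the total vertical range of motion.
#' Strides lacking a clear pair of extrema for a landmark are dropped for
#' that landmark; the number dropped is recorded in the `n_dropped`
#' attribute.
#'
#' @param displacement Long tibble with columns `sample`, `landmark`,
#'   `disp_mm` covering all samples of the record.
#' @param strides A `stride_set` from [segment_strides()].
#' @param step_side Character vector, one of `"left"`/`"right"` per sample:
#'   the diagonal step active at that sample (ground-truth labels from the
#'   simulator, or [attribute_steps()] on real data).
#' @return Tidy tibble: `stride_id`, `landmark`, `feature` (`min`, `max`,
#'   `up` for midline; `up_contra`, `rom` for tuber coxae), `side`
#'   (`left`/`right`), `value_mm`.
#' @export
extract_stride_features <- function(displacement, strides, step_side) {
  stopifnot(all(c("sample", "landmark", "disp_mm") %in% names(displacement)))
  n_dropped <- 0L
  res <- list()
  for (lm in unique(displacement$landmark)) {
    d <- displacement$disp_mm[displacement$landmark == lm]
    for (si in seq_len(nrow(strides))) {
      s0 <- strides$start[si]
      L <- strides$end[si] - s0
      if (L < 8) { n_dropped <- n_dropped + 1L; next }
      if (lm %in% MIDLINE_LANDMARKS) {
        # minima near phases 0 and 0.5, maxima near 0.25 and 0.75
        min1 <- window_extremum(d, s0 - 0.15 * L, s0 + 0.3 * L)
        max1 <- window_extremum(d, s0 + 0.05 * L, s0 + 0.5 * L, maximum = TRUE)
        min2 <- window_extremum(d, s0 + 0.3 * L, s0 + 0.75 * L)
        max2 <- window_extremum(d, s0 + 0.55 * L, s0 + L, maximum = TRUE)
        pts <- c(min1, max1, min2, max2)
        if (any(is.na(pts)) || any(diff(pts) <= 0)) { n_dropped <- n_dropped + 1L; next }
        # minima sit on step transitions, so their own labels are fragile;
        # each maximum is mid-step, and a step's minimum precedes its
        # maximum, so the pair (min_i, max_i) shares the maximum's label
        side1 <- step_side[max1]
        side2 <- step_side[max2]
        if (side1 == side2) {
          n_dropped <- n_dropped + 1L
          next
        }
        res[[length(res) + 1]] <- tibble(
          stride_id = strides$stride_id[si], landmark = lm,
          feature = rep(c("min", "max", "up"), each = 2),
          side = c(side1, side2, side1, side2, side1, side2),
          value_mm = c(
            d[min1], d[min2], d[max1], d[max2],
            d[max1] - d[min1], d[max2] - d[min2]
          )
        )
      } else {
        own_side <- if (lm == "left_tuber_coxae") "left" else "right"
        win <- seq(s0, min(length(d), s0 + L - 1))
        # hike maximum: highest point during the step matching the
        # landmark's own side (= its contralateral hind stance)
        own <- win[step_side[win] == own_side]
        if (length(own) < 3) { n_dropped <- n_dropped + 1L; next }
        mx <- own[which.max(d[own])]
        # hike amplitude relative to the stride minimum: symmetric between
        # the two tuber coxae, so noise-induced extremum bias cancels in HHD
        up <- d[mx] - min(d[win])
        res[[length(res) + 1]] <- tibble(
          stride_id = strides$stride_id[si], landmark = lm,
          feature = c("up_contra", "rom"), side = own_side,
          value_mm = c(up, max(d[win]) - min(d[win]))
        )
      }
    }
  }
  out <- bind_rows(res)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Attribute samples to left or right diagonal steps from tuber coxae phase
#'
#' Each tuber coxae rises toward its hike maximum during the contralateral
#' hind stance, so the smoothed difference between the right and left tuber
#' coxae displacement is positive during the left (left fore / right hind)
#' step. A centred moving average of half a stride suppresses the
#' two-per-stride component before taking the sign.
#'
#' @param left_tc,right_tc Vertical displacement \[mm\] of the left and
#'   right tuber coxae.
#' @param sample_rate Sampling rate \[Hz\].
#' @param stride_freq Stride frequency \[Hz\].
#' @return Character vector of `"left"`/`"right"` per sample.
#' @export
attribute_steps <- function(left_tc, right_tc, sample_rate, stride_freq) {
  d <- right_tc - left_tc
  w <- max(3L, round(sample_rate / (2 * stride_freq)))
  if (w %% 2 == 0) w <- w + 1L
  sm <- stats::filter(d, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- 0
  ifelse(as.numeric(sm) > 0, "left", "right")
}
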