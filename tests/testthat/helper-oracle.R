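# Straight-line brute-force reimplementation of the preprocessing chain,
# sharing no code with the package. Used as the independent reference for
# small sessions: every step below is written as plain loops and explicit
# formulas.

oracle_preprocess <- function(session, cutoff_hz = 1, order = 2,
                              threshold_pct = 30, pre_s = 5, post_s = 25,
                              pad_s = 5) {
  fs <- session$sample_rate_hz
  x <- session$left_velocity
  y <- session$right_velocity
  n <- length(x)

  # --- peak detection: local maxima above the median, >= 0.3 s apart ----
  med <- stats::median(x)
  min_dist <- max(2, round(0.3 * fs))
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1] && x[i] > med) {
      cand <- c(cand, i)
    }
  }
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) == 0 || i - peaks[length(peaks)] >= min_dist) {
      peaks <- c(peaks, i)
    }
  }

  # --- cycle boundaries: minimum between successive peaks ---------------
  bounds <- integer(0)
  for (j in seq_len(length(peaks) - 1)) {
    seg <- peaks[j]:peaks[j + 1]
    bounds <- c(bounds, seg[which.min(x[seg])])
  }
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  keep <- ((ends - starts) / fs) >= 60 / 200 & ((ends - starts) / fs) <= 2
  starts <- starts[keep]
  ends <- ends[keep]

  # --- per-cycle means over [start, end) on both channels ---------------
  m_l <- numeric(length(starts))
  m_r <- numeric(length(starts))
  mid <- numeric(length(starts))
  for (j in seq_along(starts)) {
    idx <- starts[j]:(ends[j] - 1)
    m_l[j] <- sum(x[idx]) / length(idx)
    m_r[j] <- sum(y[idx]) / length(idx)
    mid[j] <- (session$time_s[starts[j]] + session$time_s[ends[j]]) / 2
  }

  # --- linear interpolation at cycle midpoints, constant at the ends ----
  interp <- function(vals) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      t <- session$time_s[i]
      if (t <= mid[1]) {
        out[i] <- vals[1]
      } else if (t >= mid[length(mid)]) {
        out[i] <- vals[length(vals)]
      } else {
        k <- max(which(mid <= t))
        w <- (t - mid[k]) / (mid[k + 1] - mid[k])
        out[i] <- (1 - w) * vals[k] + w * vals[k + 1]
      }
    }
    out
  }
  sx <- interp(m_l)
  sy <- interp(m_r)

  # --- epoch extraction and percent-change normalization ----------------
  pre_n <- round(pre_s * fs)
  post_n <- round(post_s * fs)
  onsets <- session$events$onset_s[session$events$kind == "target"]
  dv_l <- list()
  dv_r <- list()
  for (onset in onsets) {
    i0 <- round(onset * fs) + 1
    if (i0 - pre_n < 1 || i0 + post_n > n) next
    idx <- (i0 - pre_n):(i0 + post_n)
    vb_l <- mean(sx[idx[1:pre_n]])
    vb_r <- mean(sy[idx[1:pre_n]])
    dv_l[[length(dv_l) + 1]] <- 100 * (sx[idx] - vb_l) / vb_l
    dv_r[[length(dv_r) + 1]] <- 100 * (sy[idx] - vb_r) / vb_r
  }

  # --- +/-30% screen, then pointwise average of good epochs -------------
  good <- logical(length(dv_l))
  for (j in seq_along(dv_l)) {
    good[j] <- max(abs(dv_l[[j]]), abs(dv_r[[j]])) <= threshold_pct
  }
  ml <- Reduce(`+`, dv_l[good]) / sum(good)
  mr <- Reduce(`+`, dv_r[good]) / sum(good)

  # --- zero-phase Butterworth, closed-form bilinear design --------------
  stopifnot(order == 2)
  K <- tan(pi * cutoff_hz / fs)
  Q <- 1 / sqrt(2)
  nrm <- 1 + K / Q + K^2
  b <- c(K^2, 2 * K^2, K^2) / nrm
  a <- c(1, 2 * (K^2 - 1) / nrm, (1 - K / Q + K^2) / nrm)
  iir <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      acc <- b[1] * v[i]
      if (i >= 2) acc <- acc + b[2] * v[i - 1] - a[2] * out[i - 1]
      if (i >= 3) acc <- acc + b[3] * v[i - 2] - a[3] * out[i - 2]
      out[i] <- acc
    }
    out
  }
  filtfilt_pad <- function(v) {
    nn <- length(v)
    p <- min(round(pad_s * fs), nn - 1)
    vp <- c(2 * v[1] - v[(p + 1):2], v, 2 * v[nn] - v[(nn - 1):(nn - p)])
    w <- iir(vp)
    w <- rev(iir(rev(w)))
    w[(p + 1):(p + nn)]
  }

  list(dv_left = dv_l, dv_right = dv_r, good = good,
       mean_left_raw = ml, mean_right_raw = mr,
       mean_left_filt = filtfilt_pad(ml), mean_right_filt = filtfilt_pad(mr))
}
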