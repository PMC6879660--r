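# Independent brute-force oracles and small fixture builders.
# Oracles are written as plain loops, deliberately avoiding the vectorized
# code paths used inside the package.

# exhaustive M/L window scan over wrapped slices of a 144-slot waveform
oracle_ml <- function(values, m_slots, l_slots) {
  p <- length(values)
  wrap <- c(values, values)
  m_means <- numeric(p)
  l_means <- numeric(p)
  for (i in seq_len(p)) {
    m_means[i] <- mean(wrap[i:(i + m_slots - 1)])
    l_means[i] <- mean(wrap[i:(i + l_slots - 1)])
  }
  best_m <- 1L
  for (i in seq_len(p)) if (m_means[i] > m_means[best_m] + 1e-12) best_m <- i
  best_l <- 1L
  for (i in seq_len(p)) if (l_means[i] < l_means[best_l] - 1e-12) best_l <- i
  list(M_level = m_means[best_m], M_onset = (best_m - 1L) * 10,
       L_level = l_means[best_l], L_onset = (best_l - 1L) * 10)
}

# single-pass IQD rule applied literally, one epoch at a time
oracle_iqd_mask <- function(values, valid) {
  idx <- which(valid & !is.na(values))
  x <- values[idx]
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqd <- q[2] - q[1]
  out <- valid
  if (iqd == 0) return(out)
  for (k in 2:length(idx)) {
    if (abs(x[k] - x[k - 1]) > iqd) out[idx[k]] <- FALSE
  }
  out
}

# convenience: a channel series of n epochs starting at midnight Monday
toy_series <- function(values, variable = "A", valid = NULL,
                       epoch_minutes = 10, start = "2019-11-25 00:00:00") {
  channel_series(variable, start, values, valid = valid,
                 epoch_minutes = epoch_minutes)
}

# n full days of a given 144-slot daily profile
days_of <- function(daily, n_days, variable = "A") {
  toy_series(rep(daily, n_days), variable = variable)
}

week_start <- lubridate::ymd_hms("2019-11-25 00:00:00")  # a Monday
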