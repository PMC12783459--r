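# Independent brute-force re-computation of the DMX score: a literal
# second-by-second loop that re-derives cumulative profitabilities from
# the segment table at every second and ranks by counting. Shares no
# code with the package engine (no rank(), no cumulative matrices).
oracle_dmx_values <- function(log, catalog) {
  n_sec <- as.integer(log$duration_s)
  gids <- catalog$game_id
  seg <- log$segments
  occ <- rep(NA_character_, n_sec)
  for (t in seq_len(n_sec)) {
    if (nrow(seg) == 0L) break
    ov <- pmin(seg$end_s, t) - pmax(seg$start_s, t - 1)
    ov[ov < 0] <- 0
    if (any(ov > 0)) {
      occ[t] <- seg$game_id[which.max(ov)]
    } else {
      upcoming <- which(seg$start_s >= t)
      occ[t] <- if (length(upcoming) > 0L) seg$game_id[upcoming[1L]]
                else seg$game_id[nrow(seg)]
    }
  }
  v <- numeric(n_sec)
  for (t in seq_len(n_sec)) {
    rates <- vapply(gids, function(g) {
      s <- seg[seg$game_id == g, , drop = FALSE]
      if (nrow(s) == 0L) return(NA_real_)
      dur <- pmin(s$end_s, t - 1) - s$start_s
      dur[dur < 0] <- 0
      if (sum(dur) <= 0) return(NA_real_)
      sum(s$tickets * dur / (s$end_s - s$start_s)) / sum(dur)
    }, numeric(1L))
    if (all(is.na(rates))) {
      v[t] <- 50
      next
    }
    rates[is.na(rates)] <- mean(rates, na.rm = TRUE)
    x <- rates[[occ[t]]]
    rk <- sum(rates > x) + (sum(rates == x) + 1) / 2
    v[t] <- 100 * (length(gids) - rk) / (length(gids) - 1)
  }
  v
}

oracle_dmx <- function(log, catalog) mean(oracle_dmx_values(log, catalog))
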