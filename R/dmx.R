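#' Tie-averaged descending ranks
#'
#' Ranks a profitability vector so that rank 1 is the most profitable
#' option and tied values receive the average of the ranks they occupy
#' (two values sharing positions 12 and 13 both get 12.5). The ranks of
#' an n-vector always sum to n(n+1)/2 — 231 for the 21-game arcade.
#'
#' @param values numeric vector of finite profitabilities.
#' @return numeric vector of tie-averaged ranks, largest value = rank 1.
#' @export
rank_with_ties <- function(values) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric vector")
  }
  if (any(!is.finite(values))) stop("`values` must be finite")
  rank(-values, ties.method = "average")
}

#' Share normalization of profitabilities
#'
#' The alternative (and rejected-by-default) normalization: divide each
#' game's profitability by the total over all games, so the values sum
#' to 1. With a single dominant game this collapses every other option
#' to a near-zero share, which is why the rank normalization is the
#' default for scoring.
#'
#' @param values numeric vector of non-negative profitabilities.
#' @return shares summing to 1.
#' @export
sum_normalize <- function(values) {
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("`values` must be finite and non-negative")
  }
  total <- sum(values)
  if (total <= 0) stop("normalization undefined: values sum to 0")
  values / total
}

#' Map a rank to a 0-100 decision value
#'
#' The per-second decision value is an affine rescaling of the
#' tie-averaged rank: rank 1 (best-known game) is worth 100, rank 21
#' (worst) is worth 0, and the all-tie rank 11 — the state before any
#' information has been gathered — is worth exactly 50. This 0-100
#' convention is a documented package choice; see the methods vignette.
#'
#' @param rank tie-averaged rank(s) in \[1, n_games\].
#' @param n_games number of options (21 for the reference arcade).
#' @return decision value(s) in \[0, 100\].
#' @export
decision_value <- function(rank, n_games = 21L) {
  if (any(rank < 1 - 1e-9 | rank > n_games + 1e-9)) {
    stop("rank must lie in [1, ", n_games, "]")
  }
  100 * (n_games - rank) / (n_games - 1)
}

#' Impute unplayed games' profitability
#'
#' Played games keep their experienced tickets-per-second rate; games
#' not yet sampled are assigned the arithmetic mean of the experienced
#' rates — the participant can only assume unexplored machines are, on
#' average, like the ones already tried. Before any game has been
#' played every entry is tied at an arbitrary common value.
#'
#' @param observed numeric vector, one entry per game: the experienced
#'   tickets/second for played games, `NA` for unplayed games.
#' @return numeric vector with `NA` entries replaced by the mean of the
#'   observed entries. If no game has been played, a zero vector tagged
#'   with attribute `all_tie = TRUE` (every option tied).
#' @export
profitability_vector <- function(observed) {
  if (!is.numeric(observed)) stop("`observed` must be numeric")
  played <- !is.na(observed)
  if (!any(played)) {
    return(structure(rep(0, length(observed)), all_tie = TRUE))
  }
  observed[!played] <- mean(observed[played])
  observed
}

#' Experienced profitability of one game at a time point
#'
#' Cumulative tickets earned in a game strictly before time `t`,
#' divided by cumulative seconds spent playing it strictly before `t`
#' (tickets are interpolated uniformly within a segment, since logs
#' record per-segment totals). Undefined (`NA`) while the game is
#' unplayed.
#'
#' @param log a [session_log()].
#' @param game_id game to evaluate.
#' @param t time in seconds from session start.
#' @param catalog optional [game_catalog()]; when supplied, `game_id`
#'   is validated against it.
#' @return tickets/second, or `NA_real_` if the game has zero play time
#'   before `t`.
#' @export
observed_profitability <- function(log, game_id, t, catalog = NULL) {
  if (!is.null(catalog)) game_index(catalog, game_id)
  if (t < 0 || t > log$duration_s) {
    stop("t must lie in [0, ", log$duration_s, "]")
  }
  seg <- log$segments[log$segments$game_id == game_id, , drop = FALSE]
  if (nrow(seg) == 0L) return(NA_real_)
  dur <- pmax(0, pmin(seg$end_s, t) - seg$start_s)
  secs <- sum(dur)
  if (secs <= 0) return(NA_real_)
  sum(seg$tickets * dur / (seg$end_s - seg$start_s)) / secs
}

# Per-second occupancy and accrual grid for a cleaned log.
# Second t (t = 1..duration) covers the half-open interval [t-1, t).
# Returns tickets and play-seconds accrued per second per game, and the
# game the participant is "deciding for" each second: the game being
# played, or — during travel — the destination game; trailing idle
# seconds keep the last game. Seconds before the first segment are
# attributed to the first destination.
second_grid <- function(log, catalog) {
  n_sec <- as.integer(ceiling(log$duration_s))
  g <- nrow(catalog)
  tick <- matrix(0, n_sec, g)
  psec <- matrix(0, n_sec, g)
  occ <- rep(NA_integer_, n_sec)
  ovmax <- rep(0, n_sec)
  seg <- log$segments
  if (nrow(seg) > 0L) {
    gi <- game_index(catalog, seg$game_id)
    for (k in seq_len(nrow(seg))) {
      s <- seg$start_s[k]; e <- seg$end_s[k]
      secs <- (floor(s) + 1L):min(n_sec, ceiling(e))
      ov <- pmin(e, secs) - pmax(s, secs - 1)
      ov[ov < 0] <- 0
      j <- gi[k]
      tick[secs, j] <- tick[secs, j] + seg$tickets[k] * ov / (e - s)
      psec[secs, j] <- psec[secs, j] + ov
      upd <- secs[ov > ovmax[secs]]
      occ[upd] <- j
      ovmax[secs] <- pmax(ovmax[secs], ov)
    }
  }
  # travel gaps -> destination (next occupied game); trailing -> previous
  filled <- fill_next(occ)
  filled <- fill_prev(filled)
  list(tick = tick, psec = psec, occupied = filled)
}

# carry the next non-NA value backward (travel -> destination game)
fill_next <- function(x) {
  rev(fill_prev(rev(x)))
}

# carry the previous non-NA value forward (idle -> keep last game)
fill_prev <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  out <- x
  out[idx > 0L] <- x[idx[idx > 0L]]
  out
}

# Tie-averaged descending ranks for every row of a matrix, by column
# sweeps (O(g^2) vector ops instead of an apply over rows).
row_ranks_desc <- function(m) {
  g <- ncol(m)
  out <- matrix(0, nrow(m), g)
  for (j in seq_len(g)) {
    gt <- rowSums(m > m[, j])
    eq <- rowSums(m == m[, j])
    out[, j] <- gt + (eq + 1) / 2
  }
  out
}

#' Per-second decision timeline
#'
#' Reconstructs, for every second of a cleaned session, the occupied
#' game, the learned profitability estimate of all games (experienced
#' rates for played games, the mean of those rates imputed to unplayed
#' games), the tie-averaged rank vector, and the 0-100 decision value
#' of the occupied game. The estimate used at second `t` includes only
#' information strictly before `t`, so the first second of the session
#' is always valued under the all-tie state (value 50).
#'
#' @param log a cleaned [session_log()].
#' @param catalog a [game_catalog()]; defaults to the built-in arcade.
#' @return list with `occupied` (game ids, one per second), `ranks`
#'   (seconds x games matrix of tie-averaged ranks), `values` (per-second
#'   decision values), and `shares` (the sum-normalized profitability of
#'   the occupied game, for the share variant).
#' @export
dmx_timeline <- function(log, catalog = default_catalog()) {
  if (nrow(log$segments) > 0L && max(log$segments$end_s) > log$duration_s + 1e-9) {
    stop("log extends past its duration budget; run clean_session_log() first")
  }
  grid <- second_grid(log, catalog)
  n_sec <- nrow(grid$tick)
  g <- ncol(grid$tick)
  # cumulative accrual strictly before each second's decision point
  cumT <- apply(grid$tick, 2L, cumsum)
  cumS <- apply(grid$psec, 2L, cumsum)
  cumT <- rbind(0, cumT[-n_sec, , drop = FALSE])
  cumS <- rbind(0, cumS[-n_sec, , drop = FALSE])
  vals <- cumT / cumS
  vals[cumS == 0] <- NA
  imput <- rowMeans(vals, na.rm = TRUE)      # NaN when nothing played yet
  nap <- which(is.na(vals), arr.ind = TRUE)
  vals[nap] <- imput[nap[, 1L]]
  vals[is.na(vals)] <- 0                     # all-tie rows: any common value
  ranks <- row_ranks_desc(vals)
  occ <- grid$occupied
  if (anyNA(occ)) occ[is.na(occ)] <- 1L      # empty log: occupant irrelevant (all tie)
  sel <- cbind(seq_len(n_sec), occ)
  totals <- rowSums(vals)
  shares <- ifelse(totals > 0, vals[sel] / totals, 1 / g)
  list(occupied = catalog$game_id[occ],
       ranks = ranks,
       values = decision_value(ranks[sel], n_games = g),
       shares = shares)
}

#' DMX decision-making-expertise score
#'
#' Scores a cleaned session by valuing each of its per-second stay/switch
#' decisions. Each second, the occupied game is valued by its standing
#' among all 21 games' learned profitabilities — by tie-averaged rank
#' (`normalization = "rank"`, the default) or by its share of the summed
#' profitabilities (`"sum"`, retained for comparison only). Per-second
#' values lie in \[0, 100\]; the DMX score is their mean over the
#' session's seconds, so an uninformative session (e.g. one game played
#' throughout, leaving every profitability tied) scores exactly 50, and
#' consistently exploiting the best-known game pushes the score toward
#' 100. Deterministic given the log.
#'
#' @param log a cleaned [session_log()].
#' @param normalization `"rank"` (default) or `"sum"`.
#' @param catalog a [game_catalog()].
#' @return A `dmx_result`: list with `dmx_score`, `decision_values`
#'   (the per-second vector), and `normalization`.
#' @export
dmx_score <- function(log, normalization = c("rank", "sum"),
                      catalog = default_catalog()) {
  normalization <- match.arg(normalization)
  tl <- dmx_timeline(log, catalog)
  v <- if (normalization == "rank") {
    tl$values
  } else {
    # share variant: linear in share, uniform share (1/g) maps to 50
    pmin(100, 50 * ncol(tl$ranks) * tl$shares)
  }
  structure(
    list(dmx_score = mean(v), decision_values = v,
         normalization = normalization),
    class = "dmx_result"
  )
}

#' @export
print.dmx_result <- function(x, ...) {
  cat(sprintf("DMX score: %.2f (%s normalization, %d decisions)\n",
              x$dmx_score, x$normalization, length(x$decision_values)))
  invisible(x)
}
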