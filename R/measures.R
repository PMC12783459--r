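#' Session-level performance measures
#'
#' `total_tickets()` is the overall-performance measure: the exact sum
#' of tickets earned across all plays of a cleaned session (it confounds
#' game skill with game selection, which is what the DMX score
#' separates). `count_games()` is the number of distinct games played;
#' `count_switches()` is the number of transitions between consecutive
#' segments with differing games, so revisiting an earlier game counts
#' as a switch and consecutive replays of the same machine do not.
#'
#' @param log a cleaned [session_log()].
#' @return a single number.
#' @export
total_tickets <- function(log) {
  sum(log$segments$tickets)
}

#' @rdname total_tickets
#' @export
count_games <- function(log) {
  length(unique(log$segments$game_id))
}

#' @rdname total_tickets
#' @export
count_switches <- function(log) {
  g <- log$segments$game_id
  if (length(g) < 2L) return(0L)
  sum(g[-1L] != g[-length(g)])
}

check_items <- function(responses, n_items, lo, hi, scale) {
  responses <- as.numeric(responses)
  if (length(responses) != n_items) {
    stop(scale, " expects ", n_items, " item responses, got ", length(responses))
  }
  bad <- which(is.na(responses) | responses < lo | responses > hi |
                 responses != round(responses))
  if (length(bad) > 0L) {
    stop(scale, " item(s) out of range [", lo, ", ", hi, "]: item ",
         paste(bad, collapse = ", "))
  }
  responses
}

#' Questionnaire scoring
#'
#' `score_crt()` scores the 7-item multiple-choice Cognitive Reflection
#' Test: responses are either already-graded 0/1 correctness indicators,
#' or raw choices graded against `key`; the score is the number correct
#' (0-7). `score_aomtb()` scores the 11-item Actively Open-Minded
#' Thinking Beliefs scale on its 1-6 agreement anchors (the printed
#' 11-66 range only arises with six anchors); reverse-keyed items are
#' reflected about the midpoint (x -> 7 - x) before summation.
#' `score_ncs()` scores the 18-item short Need for Cognition scale on
#' its -2..2 anchors (reverse keying is sign flip), total -36..36.
#' Which items are reverse-keyed is instrument configuration, supplied
#' by the caller; the package default for simulation matches the common
#' published keying of the 18-item NCS.
#'
#' @param responses numeric response vector (see each scale).
#' @param key for CRT: optional vector of correct choices; when `NULL`,
#'   responses are taken as 0/1 correctness.
#' @param reverse_items integer indices of reverse-keyed items.
#' @return integer total score.
#' @export
score_crt <- function(responses, key = NULL) {
  if (!is.null(key)) {
    if (length(key) != 7L) stop("CRT key must have 7 entries")
    if (length(responses) != 7L) stop("CRT expects 7 item responses, got ", length(responses))
    return(sum(responses == key, na.rm = FALSE))
  }
  responses <- check_items(responses, 7L, 0, 1, "CRT")
  as.integer(sum(responses))
}

#' @rdname score_crt
#' @export
score_aomtb <- function(responses, reverse_items = integer()) {
  responses <- check_items(responses, 11L, 1, 6, "AOMTB")
  responses[reverse_items] <- 7 - responses[reverse_items]
  as.integer(sum(responses))
}

#' @rdname score_crt
#' @export
score_ncs <- function(responses, reverse_items = integer()) {
  responses <- check_items(responses, 18L, -2, 2, "NCS")
  responses[reverse_items] <- -responses[reverse_items]
  as.integer(sum(responses))
}

#' Default reverse-keyed item sets used by the simulator
#'
#' The instruments' reverse-keyed items are configuration, not derivable
#' from session data. The NCS set is the common published keying of the
#' 18-item short form; the AOMTB set is a package convention used by the
#' synthetic cohort generator.
#' @return list with integer vectors `aomtb` and `ncs`.
#' @export
default_reverse_items <- function() {
  list(aomtb = c(2L, 5L, 8L, 10L),
       ncs = c(3L, 4L, 5L, 7L, 8L, 9L, 12L, 16L, 17L))
}

#' Score a set of session logs into a participant table
#'
#' Cleans (unless told not to) and scores each log, producing one row
#' per participant with the four session measures.
#'
#' @param logs list of [session_log()] objects.
#' @param catalog a [game_catalog()].
#' @param normalization passed to [dmx_score()].
#' @param clean apply [clean_session_log()] first (default TRUE).
#' @return data.frame with columns participant_id, tickets, dmx, games,
#'   switches.
#' @export
score_sessions <- function(logs, catalog = default_catalog(),
                           normalization = "rank", clean = TRUE) {
  rows <- lapply(logs, function(log) {
    if (clean) log <- clean_session_log(log)$log
    data.frame(
      participant_id = log$participant_id,
      tickets = total_tickets(log),
      dmx = dmx_score(log, normalization = normalization,
                      catalog = catalog)$dmx_score,
      games = count_games(log),
      switches = count_switches(log),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
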