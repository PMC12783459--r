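#' Arcade game catalog
#'
#' A `game_catalog` describes the arcade the sessions were recorded in:
#' one row per machine, with the reward dynamics that the simulator and
#' the scoring engine need. The reference arcade has 21 active machines
#' spread over 5 rooms; some games cap the number of plays and some pay
#' diminishing ticket yields on repeat plays.
#'
#' @param games data.frame with columns `game_id` (unique, non-empty
#'   strings), `display_name`, `room` (integer 1..5), `base_rate`
#'   (expected tickets/second for a reference-skill player, >= 0),
#'   `max_plays` (positive integer, or `Inf` for unlimited),
#'   `yield_decay` (multiplicative ticket-rate factor per completed
#'   play, in \[0, 1\]), `play_duration` (typical seconds per play, > 0).
#' @param n_games required number of games; the reference arcade has 21.
#'   Set to `NA` to allow toy catalogs of any size.
#' @return A `game_catalog` (a validated data.frame).
#' @seealso [default_catalog()], [read_catalog()]
#' @export
game_catalog <- function(games, n_games = 21L) {
  required <- c("game_id", "display_name", "room", "base_rate",
                "max_plays", "yield_decay", "play_duration")
  if (!is.data.frame(games)) stop("`games` must be a data.frame")
  missing_cols <- setdiff(required, names(games))
  if (length(missing_cols) > 0L) {
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  games <- as.data.frame(games)[required]
  games$game_id <- as.character(games$game_id)
  if (!is.na(n_games) && nrow(games) != n_games) {
    stop("catalog must contain exactly ", n_games, " games, got ", nrow(games))
  }
  if (anyDuplicated(games$game_id)) stop("game_id values must be unique")
  if (any(!nzchar(games$game_id))) stop("game_id values must be non-empty")
  if (any(!is.finite(games$base_rate)) || any(games$base_rate < 0)) {
    stop("base_rate must be finite and >= 0")
  }
  if (any(games$yield_decay < 0 | games$yield_decay > 1)) {
    stop("yield_decay must lie in [0, 1]")
  }
  if (any(games$max_plays < 1)) stop("max_plays must be >= 1 (use Inf for unlimited)")
  if (any(games$play_duration <= 0)) stop("play_duration must be > 0")
  structure(games, class = c("game_catalog", "data.frame"))
}

#' Built-in synthetic arcade catalog
#'
#' A fixed, fully synthetic instantiation of the 21-machine arcade used
#' as the default throughout the package. Base ticket rates are a
#' log-normal spread (quantiles of lognormal(log 0.62, 0.5), so a
#' typical machine pays a bit over half a ticket per second and a
#' mid-skill cohort banks on the order of 1400-1550 tickets a session); the two mental
#' rotation machines are capped at 2 plays; a subset of games pays a
#' geometric 0.8 yield decay per completed play. The game identities are
#' classic psychological tasks in several difficulty versions, but only
#' their ticket-emission statistics matter here.
#'
#' @return A [game_catalog()] with 21 rows.
#' @export
default_catalog <- function() {
  ids <- c("corsi_basic", "corsi_advanced",
           "gonogo_basic", "gonogo_fast",
           "iowa_gambling",
           "mackworth_short", "mackworth_long",
           "hanoi_basic", "hanoi_intermediate", "hanoi_expert",
           "stroop_color", "stroop_reverse",
           "rotation_2d", "rotation_3d",
           "posner_letters", "posner_symbols",
           "digit_span_forward", "digit_span_backward",
           "search_easy", "search_hard", "pattern_match")
  display <- c("Corsi Blocks", "Corsi Blocks Advanced",
               "Go/No-Go", "Go/No-Go Fast",
               "Iowa Gambling",
               "Mackworth Clock Short", "Mackworth Clock Long",
               "Tower of Hanoi - Basic", "Tower of Hanoi - Intermediate",
               "Tower of Hanoi - Expert",
               "Stroop Colors", "Stroop Reversed",
               "Mental Rotation 2D", "Mental Rotation 3D",
               "Posner Letter Match", "Posner Symbol Match",
               "Digit Span Forward", "Digit Span Backward",
               "Visual Search Easy", "Visual Search Hard", "Pattern Match")
  # fixed log-normal spread of base rates; the permutation decouples
  # rate from catalog order so room layout carries no information
  rates <- round(stats::qlnorm(stats::ppoints(21), meanlog = log(0.62), sdlog = 0.5), 3)
  perm <- c(8L, 15L, 3L, 19L, 11L, 1L, 21L, 6L, 13L, 17L, 4L,
            10L, 20L, 16L, 2L, 12L, 7L, 18L, 5L, 14L, 9L)
  decay <- rep(1, 21)
  decay[c(5L, 8L, 9L, 10L, 19L, 20L)] <- 0.8
  maxp <- rep(Inf, 21)
  maxp[c(13L, 14L)] <- 2
  dur <- c(60, 75, 45, 45, 90, 60, 120, 75, 90, 120,
           45, 60, 60, 90, 45, 45, 60, 75, 45, 60, 90)
  game_catalog(data.frame(
    game_id = ids,
    display_name = display,
    room = rep(1:5, c(4L, 4L, 4L, 4L, 5L)),
    base_rate = rates[perm],
    max_plays = maxp,
    yield_decay = decay,
    play_duration = dur,
    stringsAsFactors = FALSE
  ))
}

#' Read or write a catalog as JSON
#'
#' The on-disk catalog format is a JSON array of game objects with the
#' fields documented in [game_catalog()]; `max_plays = null` encodes
#' unlimited plays.
#'
#' @param path file path.
#' @return `read_catalog()` returns a [game_catalog()].
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- jsonlite::fromJSON(path)
  if (is.null(raw$max_plays)) raw$max_plays <- Inf
  raw$max_plays[is.na(raw$max_plays)] <- Inf
  game_catalog(raw)
}

#' @rdname read_catalog
#' @param catalog a [game_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  out <- as.data.frame(catalog)
  out$max_plays[!is.finite(out$max_plays)] <- NA
  jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

game_index <- function(catalog, game_id) {
  idx <- match(game_id, catalog$game_id)
  if (anyNA(idx)) {
    stop("unknown game_id(s): ",
         paste(unique(game_id[is.na(idx)]), collapse = ", "))
  }
  idx
}
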