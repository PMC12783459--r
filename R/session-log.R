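#' Session logs
#'
#' A `session_log` holds one participant's ordered play segments over a
#' 30-minute (1800 s) arcade session. Times are seconds from session
#' start, 0-based, and every segment occupies the half-open interval
#' `[start_s, end_s)`. Gaps between segments are travel or idle time.
#' Raw logs straight from [read_session_log()] may still contain the
#' known recording defects (a trailing segment past the time limit,
#' duplicated terminal summary rows, mislabeled games); use
#' [clean_session_log()] before scoring.
#'
#' @param participant_id scalar id.
#' @param segments data.frame with columns `game_id`, `start_s`,
#'   `end_s`, `tickets`. May be zero-row.
#' @param duration_s session length in seconds (1800 for the reference
#'   protocol; shorter values are allowed for toy examples).
#' @param summary_rows optional data.frame of non-play rows carried
#'   through from the raw file (kept verbatim; cleaned separately).
#' @return A `session_log` object.
#' @export
session_log <- function(participant_id, segments, duration_s = 1800,
                        summary_rows = NULL) {
  required <- c("game_id", "start_s", "end_s", "tickets")
  if (!is.data.frame(segments)) stop("`segments` must be a data.frame")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0L) {
    stop("segments missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  segments <- as.data.frame(segments)[required]
  segments$game_id <- as.character(segments$game_id)
  for (col in c("start_s", "end_s", "tickets")) {
    if (!is.numeric(segments[[col]])) stop("segment column `", col, "` must be numeric")
  }
  if (nrow(segments) > 0L) {
    if (any(segments$start_s < 0)) stop("start_s must be >= 0")
    if (any(segments$end_s <= segments$start_s)) stop("segments must have end_s > start_s")
    if (any(segments$tickets < 0)) stop("tickets must be >= 0")
    if (is.unsorted(segments$start_s, strictly = FALSE)) {
      segments <- segments[order(segments$start_s), , drop = FALSE]
    }
    if (nrow(segments) > 1L &&
        any(segments$start_s[-1L] < segments$end_s[-nrow(segments)] - 1e-9)) {
      stop("segments overlap in time")
    }
  }
  rownames(segments) <- NULL
  structure(
    list(participant_id = as.character(participant_id)[1L],
         segments = segments,
         duration_s = duration_s,
         summary_rows = summary_rows),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat("session_log:", x$participant_id, "-", nrow(x$segments), "segments,",
      x$duration_s, "s budget\n")
  if (nrow(x$segments) > 0L) {
    cat("  games:", length(unique(x$segments$game_id)),
        " tickets:", round(sum(x$segments$tickets), 2), "\n")
  }
  invisible(x)
}

#' Read a session log from CSV
#'
#' The documented dialect is one UTF-8 CSV row per play segment with a
#' required header and columns `participant_id, game_id, start_s, end_s,
#' tickets`, plus an optional `row_type` column (`"play"`, the default,
#' or `"summary"` for end-of-session bookkeeping rows). The reader is
#' deliberately non-lossy: summary rows, out-of-limit segments and
#' duplicated rows are all retained so that [clean_session_log()] can
#' report what it removed.
#'
#' @param path path to a CSV file.
#' @param duration_s session budget in seconds.
#' @return A [session_log()].
#' @export
read_session_log <- function(path, duration_s = 1800) {
  if (!file.exists(path)) stop("session log not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("participant_id", "game_id", "start_s", "end_s", "tickets")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("session log ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"row_type" %in% names(raw)) raw$row_type <- "play"
  raw$row_type[is.na(raw$row_type) | raw$row_type == ""] <- "play"
  play <- raw[raw$row_type == "play", , drop = FALSE]
  summary_rows <- raw[raw$row_type != "play", , drop = FALSE]
  rownames(summary_rows) <- NULL

  parse_num <- function(x, col, rows) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x) | is.na(x))
    if (length(bad) > 0L) {
      stop("non-numeric `", col, "` in ", path, " at data row(s) ",
           paste(rows[bad], collapse = ", "))
    }
    out
  }
  row_no <- as.integer(rownames(play))
  pid <- if (nrow(raw) > 0L) raw$participant_id[1L] else
    sub("\\.csv$", "", basename(path))
  session_log(
    participant_id = pid,
    segments = data.frame(
      game_id = play$game_id,
      start_s = parse_num(play$start_s, "start_s", row_no),
      end_s = parse_num(play$end_s, "end_s", row_no),
      tickets = parse_num(play$tickets, "tickets", row_no),
      stringsAsFactors = FALSE
    ),
    duration_s = duration_s,
    summary_rows = if (nrow(summary_rows) > 0L) summary_rows else NULL
  )
}

#' @rdname read_session_log
#' @param log a [session_log()].
#' @export
write_session_log <- function(log, path) {
  seg <- log$segments
  out <- data.frame(
    row_type = rep("play", nrow(seg)),
    participant_id = rep(log$participant_id, nrow(seg)),
    game_id = seg$game_id,
    start_s = seg$start_s,
    end_s = seg$end_s,
    tickets = seg$tickets,
    stringsAsFactors = FALSE
  )
  if (!is.null(log$summary_rows)) {
    sr <- log$summary_rows
    for (col in setdiff(names(out), names(sr))) sr[[col]] <- NA
    out <- rbind(out, sr[names(out)])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Known mislabelings corrected during cleaning
#'
#' The recording software wrote abbreviated labels for the two harder
#' Tower of Hanoi machines in some files; cleaning maps them back to the
#' catalog ids. Supply your own named character vector (names = wrong
#' label, values = corrected id) to extend or replace the map.
#'
#' @return named character vector.
#' @export
default_label_map <- function() {
  c("hanoi_int"    = "hanoi_intermediate",
    "hanoi_exp"    = "hanoi_expert",
    "Tower of Hanoi - Int." = "hanoi_intermediate",
    "Tower of Hanoi - Exp." = "hanoi_expert")
}

#' Clean a raw session log
#'
#' Applies the study's preprocessing rules, in order: (1) correct known
#' mislabeled game ids via `label_map`; (2) drop any segment starting at
#' or after the session budget (the recorder occasionally emitted one
#' extra trial row after 1800 s); (3) truncate a segment crossing the
#' budget at the budget, prorating its tickets by the retained fraction;
#' (4) remove exact duplicates of the final two summary rows (a known
#' recorder bug duplicated the end-time and total-tickets rows).
#' Cleaning is total (never errors) and idempotent.
#'
#' @param log a [session_log()].
#' @param label_map named character vector of game-id corrections.
#' @return list with elements `log` (the cleaned [session_log()]) and
#'   `report` (a `cleaning_report` with counts
#'   `rows_removed_after_limit`, `duplicate_rows_removed`,
#'   `labels_corrected`, `rows_truncated`).
#' @export
clean_session_log <- function(log, label_map = default_label_map()) {
  seg <- log$segments
  limit <- log$duration_s
  labels_corrected <- 0L
  if (length(label_map) > 0L && nrow(seg) > 0L) {
    hit <- seg$game_id %in% names(label_map)
    labels_corrected <- sum(hit)
    seg$game_id[hit] <- unname(label_map[seg$game_id[hit]])
  }
  over <- seg$start_s >= limit
  rows_removed <- sum(over)
  seg <- seg[!over, , drop = FALSE]
  crossing <- seg$end_s > limit
  rows_truncated <- sum(crossing)
  if (rows_truncated > 0L) {
    frac <- (limit - seg$start_s[crossing]) / (seg$end_s[crossing] - seg$start_s[crossing])
    seg$tickets[crossing] <- seg$tickets[crossing] * frac
    seg$end_s[crossing] <- limit
  }
  summary_rows <- log$summary_rows
  duplicate_rows_removed <- 0L
  if (!is.null(summary_rows) && nrow(summary_rows) >= 4L) {
    n <- nrow(summary_rows)
    last2 <- summary_rows[(n - 1L):n, , drop = FALSE]
    prev2 <- summary_rows[(n - 3L):(n - 2L), , drop = FALSE]
    rownames(last2) <- rownames(prev2) <- NULL
    if (identical(last2, prev2)) {
      summary_rows <- summary_rows[seq_len(n - 2L), , drop = FALSE]
      duplicate_rows_removed <- 2L
    }
  }
  report <- structure(
    list(rows_removed_after_limit = rows_removed,
         duplicate_rows_removed = duplicate_rows_removed,
         labels_corrected = labels_corrected,
         rows_truncated = rows_truncated),
    class = "cleaning_report"
  )
  cleaned <- session_log(log$participant_id, seg, duration_s = limit,
                         summary_rows = summary_rows)
  list(log = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("cleaning_report: removed-after-limit", x$rows_removed_after_limit,
      "| duplicate-summary-rows", x$duplicate_rows_removed,
      "| labels-corrected", x$labels_corrected,
      "| truncated", x$rows_truncated, "\n")
  invisible(x)
}
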