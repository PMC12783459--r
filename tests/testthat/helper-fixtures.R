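toy_log <- function(..., id = "p1", duration_s = 1800, summary_rows = NULL) {
  rows <- list(...)
  segments <- do.call(rbind, lapply(rows, function(r) {
    data.frame(game_id = r[[1L]], start_s = as.numeric(r[[2L]]),
               end_s = as.numeric(r[[3L]]), tickets = as.numeric(r[[4L]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(segments)) {
    segments <- data.frame(game_id = character(), start_s = numeric(),
                           end_s = numeric(), tickets = numeric())
  }
  session_log(id, segments, duration_s = duration_s,
              summary_rows = summary_rows)
}

# random toy log for the oracle-equivalence property: integer segment
# bounds inside [0, duration], <= 3 distinct games from the catalog
random_toy_log <- function(catalog, duration_s = 60) {
  games <- sample(catalog$game_id, sample(1:3, 1L))
  n_seg <- sample(1:4, 1L)
  bounds <- sort(sample(0:duration_s, 2L * n_seg))
  segs <- data.frame(
    game_id = sample(games, n_seg, replace = TRUE),
    start_s = bounds[seq(1L, by = 2L, length.out = n_seg)],
    end_s = bounds[seq(2L, by = 2L, length.out = n_seg)],
    tickets = sample(0:40, n_seg, replace = TRUE),
    stringsAsFactors = FALSE
  )
  segs <- segs[segs$end_s > segs$start_s, , drop = FALSE]
  session_log("toy", segs, duration_s = duration_s)
}

log_csv_text <- function(rows, header = "row_type,participant_id,game_id,start_s,end_s,tickets") {
  c(header, rows)
}

write_log_csv <- function(rows, ...) {
  path <- tempfile(fileext = ".csv")
  writeLines(log_csv_text(rows, ...), path)
  path
}
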