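#' Schandry heartbeat-counting accuracy index
#'
#' The standard heartbeat-tracking score: subjects silently count their
#' heartbeats over timed intervals while the true count is recorded. Each
#' interval contributes \eqn{1 - |recorded - counted| / recorded}; the index
#' is the unweighted mean over intervals (canonically 25, 35, 45 and 100 s).
#' A perfect counter scores 1; counting nothing scores 0. Overcounting
#' beyond twice the recorded beats makes an interval term negative; it is
#' kept as computed (with a warning), never clamped.
#'
#' @param records Data frame of counting records for one subject, with
#'   columns `counted` and `recorded` (and optionally `interval_s`,
#'   `subject_id`).
#' @return Object of class `iacc_score`: `subject_id` (or `NA`), `score`,
#'   and `per_interval`, the interval-wise accuracies.
#' @examples
#' rec <- data.frame(interval_s = c(25, 35, 45, 100),
#'                   counted = c(20, 30, 40, 90),
#'                   recorded = c(25, 35, 45, 100))
#' schandry_index(rec)$score   # 0.8615
#' @export
schandry_index <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("need at least one counting record")
  if (!all(c("counted", "recorded") %in% names(records)))
    stop("records must have columns `counted` and `recorded`")
  if (any(records$recorded < 1))
    stop("recorded beats must be >= 1 in every interval")
  per <- 1 - abs(records$recorded - records$counted) / records$recorded
  if (any(per < 0))
    warning("counted more than twice the recorded beats in ",
            sum(per < 0), " interval(s); negative accuracy term kept",
            call. = FALSE)
  structure(list(subject_id = if ("subject_id" %in% names(records))
                   records$subject_id[1] else NA_character_,
                 score = mean(per),
                 per_interval = per),
            class = "iacc_score")
}

#' @export
print.iacc_score <- function(x, ...) {
  cat(sprintf("<iacc_score> %s: %.4f over %d interval(s)\n",
              x$subject_id, x$score, length(x$per_interval)))
  invisible(x)
}
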