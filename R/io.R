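#' @title Trial-level and counting-task file I/O
#' @description Readers/writers for the two delimited-text interchange
#'   formats (forced-choice trials; heartbeat-counting records) and for the
#'   JSON analysis report. Validation is total: malformed input raises a
#'   diagnostic naming the offending column or row, never a partially loaded
#'   cohort.
#' @name io
NULL

trial_columns    <- c("subject_id", "trial_index", "stimulus", "response",
                      "confidence")
counting_columns <- c("subject_id", "interval_s", "counted", "recorded")

# Read a delimited file as character columns, auto-detecting comma vs tab.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    colClasses = "character", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
}

as_num <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("validation error in ", path, ": non-numeric ", what,
         " on data row ", bad[1])
  out
}

#' Construct a per-subject dataset
#'
#' The unit of analysis: one subject's forced-choice trials plus (optionally)
#' their heartbeat-counting records.
#'
#' @param subject_id Subject identifier.
#' @param trials Data frame with columns `subject_id`, `trial_index`,
#'   `stimulus` (`SELF_HEART`/`OTHER_HEART`), `response`
#'   (`SAYS_SELF`/`SAYS_OTHER`), `confidence` (0-100).
#' @param counting Optional data frame of counting records
#'   (`interval_s`, `counted`, `recorded`).
#' @param task_tag `"HEART_SOUND"` or `"BEEP_CONTROL"`.
#' @return An object of class `subject_dataset`.
#' @export
subject_dataset <- function(subject_id, trials, counting = NULL,
                            task_tag = c("HEART_SOUND", "BEEP_CONTROL")) {
  task_tag <- match.arg(task_tag)
  stopifnot(is.data.frame(trials))
  if (!all(trials$subject_id == subject_id))
    stop("all trial records must share subject_id ", subject_id)
  if (anyDuplicated(trials$trial_index))
    stop("duplicate trial_index for subject ", subject_id)
  if (any(trials$confidence < 0 | trials$confidence > 100))
    stop("confidence outside [0, 100] for subject ", subject_id)
  if (!all(trials$stimulus %in% stimulus_levels) ||
      !all(trials$response %in% response_levels))
    stop("invalid stimulus/response code for subject ", subject_id)
  if (!is.null(counting) && nrow(counting) &&
      !all(counting$subject_id == subject_id))
    stop("counting records must share subject_id ", subject_id)
  structure(list(subject_id = subject_id,
                 trials = trials[order(trials$trial_index), , drop = FALSE],
                 counting = counting,
                 task_tag = task_tag),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("<subject_dataset> ", x$subject_id, ": ", nrow(x$trials), " trials (",
      x$task_tag, "), ",
      if (is.null(x$counting)) 0L else nrow(x$counting),
      " counting records\n", sep = "")
  invisible(x)
}

#' Read a trials file into per-subject datasets
#'
#' Expects a delimited text file (comma or tab) with header
#' `subject_id,trial_index,stimulus,response,confidence`. Every row is
#' validated; a subject whose stimulus counts are not balanced 15/15 is kept
#' with a warning (downstream statistics use the actual counts).
#'
#' @param path Path to the trials file.
#' @param task_tag Task the file belongs to (`"HEART_SOUND"` default).
#' @return List of [subject_dataset()] objects, one per distinct
#'   `subject_id`, trials in file order.
#' @export
read_trials <- function(path, task_tag = c("HEART_SOUND", "BEEP_CONTROL")) {
  task_tag <- match.arg(task_tag)
  df <- read_delim_auto(path)
  check_columns(df, trial_columns, path)
  n <- nrow(df)
  if (n == 0) return(list())
  df$trial_index <- as_num(df$trial_index, "trial_index", path)
  df$confidence  <- as_num(df$confidence, "confidence", path)
  bad <- which(df$confidence < 0 | df$confidence > 100)
  if (length(bad))
    stop("validation error in ", path, ": confidence outside [0, 100] on ",
         "data row ", bad[1], " (value ", df$confidence[bad[1]], ")")
  bad <- which(!(df$stimulus %in% stimulus_levels))
  if (length(bad))
    stop("validation error in ", path, ": unknown stimulus code on data row ",
         bad[1])
  bad <- which(!(df$response %in% response_levels))
  if (length(bad))
    stop("validation error in ", path, ": unknown response code on data row ",
         bad[1])
  key <- paste(df$subject_id, df$trial_index)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("validation error in ", path, ": duplicate (subject_id, trial_index) ",
         "pair: ", d)
  }
  out <- lapply(split(df, factor(df$subject_id, levels = unique(df$subject_id))),
                function(sub) {
    tab <- table(factor(sub$stimulus, levels = stimulus_levels))
    if (tab[1] != tab[2])
      warning("subject ", sub$subject_id[1], ": unbalanced stimulus counts (",
              tab[1], " self / ", tab[2], " other); analysing actual counts",
              call. = FALSE)
    subject_dataset(sub$subject_id[1], sub, task_tag = task_tag)
  })
  names(out) <- NULL
  out
}

#' Write per-subject datasets to a trials file
#'
#' Inverse of [read_trials()]: `read_trials(write_trials(x, p))` reproduces
#' `x` field for field.
#'
#' @param datasets List of [subject_dataset()] objects.
#' @param path Output path (comma-separated).
#' @return `path`, invisibly.
#' @export
write_trials <- function(datasets, path) {
  df <- do.call(rbind, lapply(datasets, function(d)
    d$trials[, trial_columns, drop = FALSE]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read heartbeat-counting records
#'
#' Delimited text with header `subject_id,interval_s,counted,recorded`.
#' The four canonical intervals are 25, 35, 45 and 100 s, but any positive
#' intervals are accepted. `recorded` must be >= 1 (the accuracy index
#' divides by it).
#'
#' @param path Path to the counting file.
#' @return Data frame of validated records (possibly zero rows).
#' @export
read_counting <- function(path) {
  df <- read_delim_auto(path)
  check_columns(df, counting_columns, path)
  if (nrow(df) == 0) {
    df$interval_s <- numeric(0); df$counted <- numeric(0)
    df$recorded <- numeric(0)
    return(df[, counting_columns])
  }
  df$interval_s <- as_num(df$interval_s, "interval_s", path)
  df$counted    <- as_num(df$counted, "counted", path)
  df$recorded   <- as_num(df$recorded, "recorded", path)
  bad <- which(df$interval_s <= 0)
  if (length(bad))
    stop("validation error in ", path, ": interval_s <= 0 on data row ", bad[1])
  bad <- which(df$counted < 0)
  if (length(bad))
    stop("validation error in ", path, ": counted < 0 on data row ", bad[1])
  bad <- which(df$recorded < 1)
  if (length(bad))
    stop("validation error in ", path, ": recorded < 1 on data row ", bad[1],
         " (the accuracy index divides by recorded beats)")
  df[, counting_columns]
}

#' Write heartbeat-counting records
#' @param records Data frame as returned by [read_counting()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counting <- function(records, path) {
  utils::write.csv(records[, counting_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a pipeline report
#'
#' Serializes a [run_pipeline()] result to pretty-printed JSON. Numbers are
#' written at full precision so a write/read round trip reproduces the
#' values exactly.
#'
#' @param results A `pipeline_result` (or any nested list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.null(results$per_subject) || nrow(results$per_subject) == 0)
    stop("no subjects in results; refusing to write an empty report")
  jsonlite::write_json(unclass(results), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a pipeline report
#' @param path Path to a JSON report written by [write_report()].
#' @return Nested list with data frames restored where possible.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
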