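#' Load and validate a long-format trials table
#'
#' Reads one row per participant x stimulus with the choice rating and the
#' six auxiliary ratings. Column names can be remapped through `schema`
#' (a named character vector, `internal_name = "file_column"`). Rows that
#' violate scale ranges are rejected with row-level diagnostics.
#'
#' Scales: `choice` is on the six-point no-zero scale (-3..-1, 1..3); the
#' rating columns (`usefulness`, `feel_know`, `feel_not_know`,
#' `think_freq`, and optional `expectation`, `confidence`) are on -3..3.
#'
#' @param path CSV path, or a data.frame already in memory.
#' @param schema optional named character vector mapping internal column
#'   names to file column names.
#' @param drop_missing drop rows with missing mandatory fields (logged via
#'   message) rather than erroring.
#' @return a validated data.frame of trial records.
#' @export
load_trials <- function(path, schema = NULL, drop_missing = TRUE) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("participant_id", "timepoint", "item_id", "choice",
                 "usefulness", "feel_know", "feel_not_know", "think_freq")
  optional <- c("domain", "valence", "expectation", "confidence")
  if (!is.null(schema)) {
    for (int in names(schema)) {
      if (!schema[[int]] %in% names(df))
        stop("schema maps '", int, "' to missing column '", schema[[int]], "'",
             call. = FALSE)
      names(df)[names(df) == schema[[int]]] <- int
    }
  }
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in setdiff(optional, names(df))) df[[col]] <- NA
  if (!"valence" %in% names(df) || all(is.na(df$valence))) df$valence <- "none"

  rating_cols <- c("usefulness", "feel_know", "feel_not_know", "think_freq")
  incomplete <- !stats::complete.cases(df[c("participant_id", "timepoint",
                                            "item_id", "choice", rating_cols)])
  if (any(incomplete)) {
    if (!drop_missing)
      stop(sum(incomplete), " row(s) with missing mandatory fields", call. = FALSE)
    message("dropping ", sum(incomplete), " row(s) with missing mandatory fields")
    df <- df[!incomplete, , drop = FALSE]
  }

  bad <- validate_trial_ranges(df)
  if (nrow(bad))
    stop("out-of-range values:\n",
         paste(utils::capture.output(print(bad, row.names = FALSE)),
               collapse = "\n"), call. = FALSE)

  key <- paste(df$participant_id, df$timepoint, df$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate (participant, timepoint, item) key at row ", d, ": ",
         df$participant_id[d], " / ", df$timepoint[d], " / ", df$item_id[d],
         call. = FALSE)
  }
  row.names(df) <- NULL
  df
}

# Row-level range diagnostics: returns a data.frame (row, column, value, rule).
validate_trial_ranges <- function(df) {
  bad <- list()
  flag <- function(idx, column, value, rule) {
    if (length(idx))
      bad[[length(bad) + 1L]] <<- data.frame(row = idx, column = column,
                                             value = value[idx], rule = rule)
  }
  ch <- df$choice
  flag(which(!(ch %in% c(-3, -2, -1, 1, 2, 3))), "choice", ch,
       "choice must be in {-3,-2,-1,1,2,3} (0 not included)")
  for (col in c("usefulness", "feel_know", "feel_not_know", "think_freq",
                "expectation", "confidence")) {
    v <- df[[col]]
    ok <- is.na(v) | (v >= -3 & v <= 3)
    flag(which(!ok), col, v, paste0(col, " must lie in -3..3"))
  }
  if (!length(bad)) return(data.frame(row = integer(0), column = character(0),
                                      value = numeric(0), rule = character(0)))
  do.call(rbind, bad)
}

#' Load the participants (demographics) table
#'
#' @param path CSV path or data.frame with columns `participant_id`, `age`,
#'   `gender`, `attention_failures`.
#' @return validated data.frame.
#' @export
load_participants <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age", "gender", "attention_failures")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(df$attention_failures < 0 | df$attention_failures > 5, na.rm = TRUE))
    stop("attention_failures must lie in 0..5", call. = FALSE)
  df
}

#' Load questionnaire responses and factor weights
#'
#' `load_questionnaire` expects long-format columns `participant_id`,
#' `item_id`, `rating` (and optionally `instrument`); `load_factor_weights`
#' expects `item_id`, `dim_AD`, `dim_SW`, `dim_CIT` (and optionally
#' `instrument`).
#'
#' @param path CSV path or data.frame.
#' @return validated data.frame.
#' @export
load_questionnaire <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "item_id", "rating")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname load_questionnaire
#' @export
load_factor_weights <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "dim_AD", "dim_SW", "dim_CIT")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$item_id))
    stop("duplicate item_id in factor weights", call. = FALSE)
  if (!all(is.finite(as.matrix(df[c("dim_AD", "dim_SW", "dim_CIT")]))))
    stop("factor weights must be finite", call. = FALSE)
  df
}

#' Apply participant exclusion rules
#'
#' Reproduces the study-style screening: participants failing more than one
#' of five attention checks are excluded, as are participants for whom any
#' utility input (usefulness, the hedonic feel-difference, think-frequency)
#' — or, optionally, the choice itself — is constant across all their trials
#' at some timepoint, since their per-subject regression weights are then
#' undefined.
#'
#' @param trials validated trials data.frame (see [load_trials()]).
#' @param participants validated participants data.frame.
#' @param max_attention_failures retain participants with at most this many
#'   failed checks (default 1).
#' @param exclude_constant_choice also exclude on constant choice (default
#'   TRUE; the slope is undefined without choice variance).
#' @param min_trials minimum retained trials per participant per timepoint
#'   (default 20; sessions with a dropped repeated stimulus still qualify).
#' @return an object of class `exclusion_report`: lists
#'   `excluded_attention`, `excluded_zero_variance`, `retained`, plus a
#'   `flags` data.frame recording which scale was constant for whom.
#' @export
apply_exclusions <- function(trials, participants,
                             max_attention_failures = 1,
                             exclude_constant_choice = TRUE,
                             min_trials = 20) {
  ids <- unique(trials$participant_id)
  no_demo <- setdiff(ids, participants$participant_id)
  if (length(no_demo))
    stop("participant(s) with trials but no demographic row: ",
         paste(no_demo, collapse = ", "), call. = FALSE)

  att <- participants$attention_failures[match(ids, participants$participant_id)]
  excluded_attention <- ids[att > max_attention_failures]

  scales <- c("usefulness", "hedonic", "think_freq")
  if (exclude_constant_choice) scales <- c(scales, "choice")
  flags <- list()
  rest <- setdiff(ids, excluded_attention)
  excluded_zero_variance <- character(0)
  for (id in rest) {
    sub <- trials[trials$participant_id == id, , drop = FALSE]
    for (tp in unique(sub$timepoint)) {
      blk <- sub[sub$timepoint == tp, , drop = FALSE]
      vals <- list(usefulness = blk$usefulness,
                   hedonic = blk$feel_know - blk$feel_not_know,
                   think_freq = blk$think_freq,
                   choice = blk$choice)
      for (sc in scales) {
        if (length(unique(vals[[sc]])) <= 1L) {
          flags[[length(flags) + 1L]] <- data.frame(
            participant_id = id, timepoint = tp, scale = sc,
            reason = "constant across trials", stringsAsFactors = FALSE)
        }
      }
      if (nrow(blk) < min_trials)
        flags[[length(flags) + 1L]] <- data.frame(
          participant_id = id, timepoint = tp, scale = NA_character_,
          reason = sprintf("fewer than %d trials", min_trials),
          stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(participant_id = character(0), timepoint = character(0),
               scale = character(0), reason = character(0))
  excluded_zero_variance <- unique(flags$participant_id)
  retained <- setdiff(rest, excluded_zero_variance)

  out <- list(excluded_attention = excluded_attention,
              excluded_zero_variance = excluded_zero_variance,
              retained = retained, flags = flags,
              n_input = length(ids))
  class(out) <- "exclusion_report"
  out
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report:", x$n_input, "participants in\n")
  cat("  excluded (attention):    ", length(x$excluded_attention), "\n")
  cat("  excluded (zero variance/low n):", length(x$excluded_zero_variance), "\n")
  cat("  retained:                ", length(x$retained), "\n")
  invisible(x)
}

#' Filter a trials table to retained participants
#'
#' @param trials trials data.frame.
#' @param report an `exclusion_report`.
#' @return the subset of trials belonging to retained participants.
#' @export
retained_trials <- function(trials, report) {
  stopifnot(inherits(report, "exclusion_report"))
  out <- trials[trials$participant_id %in% report$retained, , drop = FALSE]
  row.names(out) <- NULL
  out
}
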