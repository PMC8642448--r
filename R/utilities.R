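#' Construct the three utility regressors from raw ratings
#'
#' Instrumental utility is the usefulness rating; hedonic utility is the
#' difference between the feel-if-known and feel-if-not-known ratings (range
#' -6..6); cognitive utility is the think-frequency rating. Confidence is
#' passed through, and the expectation rating is sign-reversed for
#' negative-valence items so that, after reversal, higher values always mean
#' better-than-expected news.
#'
#' @param trials validated trials data.frame (see [load_trials()]).
#' @return a data.frame (the utility table) with columns `participant_id`,
#'   `timepoint`, `item_id`, `choice`, `instrumental`, `hedonic`,
#'   `cognitive`, `confidence`, `expectation_valenced`.
#' @export
build_utilities <- function(trials) {
  out <- data.frame(
    participant_id = trials$participant_id,
    timepoint = trials$timepoint,
    item_id = trials$item_id,
    choice = as.numeric(trials$choice),
    instrumental = as.numeric(trials$usefulness),
    hedonic = as.numeric(trials$feel_know) - as.numeric(trials$feel_not_know),
    cognitive = as.numeric(trials$think_freq),
    confidence = if ("confidence" %in% names(trials))
      as.numeric(trials$confidence) else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
  out$expectation_valenced <- if (all(c("expectation", "valence") %in% names(trials)))
    reverse_valence(as.numeric(trials$expectation), trials$valence) else NA_real_
  out
}

#' Reverse an expectation rating for negative-valence items
#'
#' On the symmetric -3..+3 scale, reversal is a sign flip (equivalent to
#' reflecting the seven-point scale about its midpoint).
#'
#' @param expectation numeric vector on -3..3.
#' @param valence character vector: `"positive"`, `"negative"` or `"none"`.
#' @return numeric vector with negative-valence entries negated.
#' @export
reverse_valence <- function(expectation, valence) {
  known <- c("positive", "negative", "none")
  bad <- setdiff(unique(valence[!is.na(valence)]), known)
  if (length(bad))
    stop("unknown valence label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  ifelse(!is.na(valence) & valence == "negative", -expectation, expectation)
}

#' Center utility columns within participant-by-timepoint blocks
#'
#' Subtracts from each utility column its mean over the participant's
#' retained trials at that timepoint, appending `*_c` columns; raw columns
#' are kept. Centering is idempotent and leaves per-subject regression
#' slopes unchanged (only intercepts move).
#'
#' @param utilities a utility table from [build_utilities()].
#' @param columns columns to center.
#' @return the utility table with centered `*_c` columns appended.
#' @export
center_within_participant <- function(utilities,
                                      columns = c("instrumental", "hedonic",
                                                  "cognitive", "confidence")) {
  if (!nrow(utilities)) stop("empty utility table", call. = FALSE)
  blk <- interaction(utilities$participant_id, utilities$timepoint, drop = TRUE)
  for (col in columns) {
    v <- utilities[[col]]
    if (is.null(v)) next
    m <- stats::ave(v, blk, FUN = function(x) mean(x, na.rm = TRUE))
    utilities[[paste0(col, "_c")]] <- v - m
  }
  utilities
}
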