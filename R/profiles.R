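#' Classify each participant's dominant information-seeking motive
#'
#' Orders the three motive weights by size and assigns a dominance tier:
#' `twofold` when the largest weight is at least twice both others,
#' `one_25` when it is at least 1.25 times both others (but not twofold),
#' `none` otherwise. Motives are named `action` (instrumental), `affect`
#' (hedonic) and `cognition` (cognitive).
#'
#' By default weights are compared by absolute magnitude: avoidance-driving
#' (negative) weights count as strong motives, and ratio rules on signed
#' values are ill-defined under mixed signs. A signed comparison is kept for
#' sensitivity analysis. Exact equality at a threshold counts as meeting it,
#' and an exact tie for the largest weight yields `none`.
#'
#' @param weights data.frame of subject weights (see
#'   [fit_subject_weights()]).
#' @param comparison `"magnitude"` (default) or `"signed"`.
#' @return data.frame with `participant_id`, `timepoint`, `dominant`,
#'   `tier`, `weight_ratio_1` (largest / second), `weight_ratio_2`
#'   (largest / smallest).
#' @export
classify_dominance <- function(weights, comparison = c("magnitude", "signed")) {
  comparison <- match.arg(comparison)
  b <- as.matrix(weights[, c("beta_instrumental", "beta_hedonic",
                             "beta_cognitive")])
  if (!all(is.finite(b)))
    stop("non-finite motive weight(s)", call. = FALSE)
  v <- if (comparison == "magnitude") abs(b) else b
  motives <- c("action", "affect", "cognition")
  n <- nrow(v)
  dominant <- character(n); tier <- character(n)
  r1 <- numeric(n); r2 <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(v[i, ], decreasing = TRUE)
    m <- v[i, ord]
    r1[i] <- if (m[2] != 0) m[1] / m[2] else if (m[1] > 0) Inf else NaN
    r2[i] <- if (m[3] != 0) m[1] / m[3] else if (m[1] > 0) Inf else NaN
    tied <- m[1] == m[2]
    if (!tied && m[1] >= 2 * m[2]) {
      tier[i] <- "twofold"; dominant[i] <- motives[ord[1]]
    } else if (!tied && m[1] >= 1.25 * m[2]) {
      tier[i] <- "one_25"; dominant[i] <- motives[ord[1]]
    } else {
      tier[i] <- "none"; dominant[i] <- "none"
    }
  }
  data.frame(participant_id = weights$participant_id,
             timepoint = if ("timepoint" %in% names(weights))
               weights$timepoint else NA_character_,
             dominant = dominant, tier = tier,
             weight_ratio_1 = r1, weight_ratio_2 = r2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize dominance labels as percentages
#'
#' @param labels data.frame from [classify_dominance()].
#' @return list with `by_motive` and `by_tier` data.frames of counts and
#'   percentages (each partition sums to 100), plus `n`.
#' @export
profile_summary <- function(labels) {
  if (!nrow(labels)) stop("no dominance labels supplied", call. = FALSE)
  tab <- function(x, levels) {
    cnt <- table(factor(x, levels = levels))
    data.frame(category = names(cnt), n = as.integer(cnt),
               percent = 100 * as.integer(cnt) / length(x),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(by_motive = tab(labels$dominant,
                       c("action", "affect", "cognition", "none")),
       by_tier = tab(labels$tier, c("twofold", "one_25", "none")),
       n = nrow(labels))
}

#' One-sample t-test of mean choice against the scale midpoint
#'
#' Tests whether participants' average desire for information differs from
#' 0, the midpoint of the six-point no-zero choice scale.
#'
#' @param mean_choices numeric vector of per-participant mean choice
#'   ratings.
#' @return list with `mean`, `sd`, `t`, `df`, `p`.
#' @export
midpoint_test <- function(mean_choices) {
  if (length(mean_choices) < 2L)
    stop("need >= 2 participants", call. = FALSE)
  if (stats::sd(mean_choices) == 0) {
    if (all(mean_choices == 0))
      return(list(mean = 0, sd = 0, t = 0, df = length(mean_choices) - 1L,
                  p = 1))
    stop("zero variance across participants; t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(mean_choices, mu = 0)
  list(mean = mean(mean_choices), sd = stats::sd(mean_choices),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
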