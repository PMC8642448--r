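#' Euclidean distance between two motive-weight triples
#'
#' Distance in the three-dimensional weight space whose axes are the
#' instrumental, hedonic and cognitive weights:
#' `sqrt((x2-x1)^2 + (y2-y1)^2 + (z2-z1)^2)`.
#'
#' @param w1,w2 numeric length-3 vectors (instrumental, hedonic, cognitive),
#'   or single rows of a subject-weights data.frame.
#' @return nonnegative scalar.
#' @export
beta_distance <- function(w1, w2) {
  w1 <- as_beta_triple(w1); w2 <- as_beta_triple(w2)
  if (!all(is.finite(c(w1, w2))))
    stop("non-finite weight(s)", call. = FALSE)
  sqrt(sum((w2 - w1)^2))
}

as_beta_triple <- function(w) {
  if (is.data.frame(w))
    w <- unlist(w[1, c("beta_instrumental", "beta_hedonic", "beta_cognitive")])
  as.numeric(w)
}

# Align two subject-weights tables on shared participants; returns a list of
# two n x 3 matrices in matching row order.
align_weights <- function(weights_t1, weights_t2, verbose = TRUE) {
  cols <- c("beta_instrumental", "beta_hedonic", "beta_cognitive")
  shared <- intersect(weights_t1$participant_id, weights_t2$participant_id)
  dropped <- setdiff(union(weights_t1$participant_id,
                           weights_t2$participant_id), shared)
  if (length(dropped) && verbose)
    message("dropping ", length(dropped),
            " participant(s) missing a timepoint")
  if (length(shared) < 2L)
    stop("need >= 2 participants present at both timepoints", call. = FALSE)
  m1 <- as.matrix(weights_t1[match(shared, weights_t1$participant_id), cols])
  m2 <- as.matrix(weights_t2[match(shared, weights_t2$participant_id), cols])
  rownames(m1) <- rownames(m2) <- shared
  list(t1 = m1, t2 = m2, ids = shared)
}

# Uniform random permutation with no fixed point (every participant truly
# mismatched), by rejection sampling.
sample_mismatch_permutation <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Mismatched-pairing permutation test of weight stability
#'
#' Compares the mean distance participants actually moved in weight space
#' between two timepoints to a chance distribution built by repeatedly
#' mismatching one participant's timepoint-1 weights with another
#' participant's timepoint-2 weights. Each iteration draws a uniform random
#' permutation of the timepoint-2 assignments with no fixed point, so every
#' participant is genuinely paired with someone else's data;
#' `allow_fixed_points = TRUE` relaxes this for sensitivity analysis. The
#' actual pairing is not included in the null distribution.
#'
#' @param weights_t1,weights_t2 subject-weights data.frames (matched on
#'   `participant_id`; participants missing a timepoint are dropped with a
#'   message).
#' @param n_iter number of mismatched pairings (study-scale default 10000).
#' @param seed integer seed for the permutation draws.
#' @param allow_fixed_points permit permutations in which some participants
#'   keep their own timepoint-2 data.
#' @return an object of class `stability_permutation`: `actual_mean_distance`,
#'   `permuted_mean_distances`, `proportion_actual_smaller` (share of
#'   permuted means exceeding the actual mean), `mean_difference` (mean of
#'   permuted means minus actual), `difference_range`, `per_subject`
#'   distances, `n`, `n_iter`, `seed`.
#' @export
permutation_stability_test <- function(weights_t1, weights_t2,
                                       n_iter = 10000L, seed = 1L,
                                       allow_fixed_points = FALSE) {
  stopifnot(n_iter >= 1L)
  al <- align_weights(weights_t1, weights_t2)
  n <- length(al$ids)
  d_actual <- sqrt(rowSums((al$t2 - al$t1)^2))
  actual_mean <- mean(d_actual)

  set.seed(seed)
  perm_means <- vapply(seq_len(n_iter), function(i) {
    p <- if (allow_fixed_points) sample.int(n) else
      sample_mismatch_permutation(n)
    mean(sqrt(rowSums((al$t2[p, , drop = FALSE] - al$t1)^2)))
  }, numeric(1))

  diffs <- perm_means - actual_mean
  out <- list(actual_mean_distance = actual_mean,
              permuted_mean_distances = perm_means,
              proportion_actual_smaller = mean(perm_means > actual_mean),
              mean_difference = mean(diffs),
              difference_range = range(diffs),
              per_subject = data.frame(participant_id = al$ids,
                                       distance = d_actual,
                                       stringsAsFactors = FALSE,
                                       row.names = NULL),
              n = n, n_iter = as.integer(n_iter), seed = as.integer(seed),
              allow_fixed_points = allow_fixed_points)
  class(out) <- "stability_permutation"
  out
}

#' @export
print.stability_permutation <- function(x, ...) {
  cat(sprintf(paste0("Stability permutation test (n = %d, %d iterations)\n",
                     "  actual mean distance: %.4f\n",
                     "  permuted means larger than actual: %.1f%%\n",
                     "  mean difference (permuted - actual): %.4f ",
                     "(range %.4f..%.4f)\n"),
              x$n, x$n_iter, x$actual_mean_distance,
              100 * x$proportion_actual_smaller, x$mean_difference,
              x$difference_range[1], x$difference_range[2]))
  invisible(x)
}

#' Exhaustive version of the mismatched-pairing test
#'
#' Enumerates every admissible permutation (feasible for small n); used to
#' validate the Monte-Carlo test.
#'
#' @inheritParams permutation_stability_test
#' @return list with `proportion_actual_smaller`, `permuted_mean_distances`
#'   over all admissible pairings, and `actual_mean_distance`.
#' @export
exhaustive_stability_test <- function(weights_t1, weights_t2,
                                      allow_fixed_points = FALSE) {
  al <- align_weights(weights_t1, weights_t2)
  n <- length(al$ids)
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
  perms <- all_permutations(n)
  if (!allow_fixed_points)
    perms <- perms[vapply(perms, function(p) !any(p == seq_len(n)), TRUE)]
  actual_mean <- mean(sqrt(rowSums((al$t2 - al$t1)^2)))
  pm <- vapply(perms, function(p)
    mean(sqrt(rowSums((al$t2[p, , drop = FALSE] - al$t1)^2))), numeric(1))
  list(proportion_actual_smaller = mean(pm > actual_mean),
       permuted_mean_distances = pm,
       actual_mean_distance = actual_mean)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Intraclass correlation of each motive weight across timepoints
#'
#' Before correlating, the three weights are centered within each
#' participant-by-timepoint profile (each triple has its own mean across the
#' three motives subtracted), so the ICC measures agreement of the
#' *relative* motive profile over time. Grand-mean centering and no
#' centering are available as alternatives. For each motive a two-way
#' random-effects, absolute-agreement, single-measures ICC — ICC(2,1) — is
#' computed across the two timepoints with an F-based p-value; the
#' consistency form ICC(3,1) is available.
#'
#' @param weights_t1,weights_t2 subject-weights data.frames.
#' @param centering `"profile"` (default), `"grand"` or `"none"`.
#' @param form `"ICC2"` (absolute agreement) or `"ICC3"` (consistency).
#' @return data.frame with one row per motive: `icc`, `F`, `df1`, `df2`,
#'   `p`, `n`.
#' @export
icc_per_motive <- function(weights_t1, weights_t2,
                           centering = c("profile", "grand", "none"),
                           form = c("ICC2", "ICC3")) {
  centering <- match.arg(centering)
  form <- match.arg(form)
  al <- align_weights(weights_t1, weights_t2)
  if (length(al$ids) < 5L)
    warning("fewer than 5 matched participants; ICC estimates are unstable",
            call. = FALSE)
  ctr <- function(m) switch(centering,
    profile = m - rowMeans(m),
    grand = m - mean(m),
    none = m)
  m1 <- ctr(al$t1); m2 <- ctr(al$t2)
  motives <- c("instrumental", "hedonic", "cognitive")
  rows <- lapply(1:3, function(j) {
    res <- icc_two_raters(m1[, j], m2[, j], form = form)
    cbind(data.frame(motive = motives[j], stringsAsFactors = FALSE),
          as.data.frame(res))
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

# ICC for an n x 2 (subjects x sessions) layout from the two-way ANOVA mean
# squares: MSR (rows/subjects), MSC (columns/sessions), MSE (residual).
# ICC(2,1) = (MSR-MSE) / (MSR + (k-1)MSE + (k/n)(MSC-MSE));
# ICC(3,1) = (MSR-MSE) / (MSR + (k-1)MSE).
# Significance via F = MSR/MSE on (n-1, (n-1)(k-1)) df.
icc_two_raters <- function(x1, x2, form = "ICC2") {
  n <- length(x1); k <- 2
  dat <- cbind(x1, x2)
  grand <- mean(dat)
  row_m <- rowMeans(dat); col_m <- colMeans(dat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- if (form == "ICC2")
    msr + (k - 1) * mse + (k / n) * (msc - mse)
  else
    msr + (k - 1) * mse
  icc <- if (denom <= 0) {
    warning("non-positive ICC denominator (no between-subject variance); ",
            "reporting 0", call. = FALSE)
    0
  } else (msr - mse) / denom
  Fv <- if (mse > 0) msr / mse else Inf
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(icc = icc, F = Fv, df1 = df1, df2 = df2, p = p, n = n)
}
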