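#' Binarize a referral priority into a test result
#'
#' Immediate and urgent referrals are positive test results; possible
#' priority and no specific action are negative.
#'
#' @param priority character or factor of priority levels.
#' @return Character vector of `"positive"`/`"negative"`.
#' @export
binarize_priority <- function(priority) {
  priority <- as.character(priority)
  bad <- !(priority %in% PRIORITY_LEVELS)
  if (any(bad))
    stop("unknown priority level: ", paste(unique(priority[bad]),
                                           collapse = ", "), call. = FALSE)
  ifelse(priority %in% c("IMMEDIATE", "URGENT"), "positive", "negative")
}

#' Sensitivity of a test
#'
#' @param positives number of diseased records with a positive result.
#' @param total_with_disease number of diseased records.
#' @return `positives / total_with_disease`.
#' @export
sensitivity <- function(positives, total_with_disease) {
  if (total_with_disease <= 0)
    stop("sensitivity is undefined for zero diseased records",
         call. = FALSE)
  if (positives < 0 || positives > total_with_disease)
    stop("positives must lie in [0, total_with_disease]", call. = FALSE)
  positives / total_with_disease
}

check_binomial_args <- function(successes, n, confidence) {
  if (n <= 0 || successes < 0 || successes > n)
    stop("require 0 <= successes <= n with n > 0", call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)", call. = FALSE)
}

#' Wilson score interval for a binomial proportion
#'
#' The interval obtained by inverting the score test:
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}
#'       {1 + z^2/n}}
#' with \eqn{z} the standard-normal quantile for the confidence level.
#' Well behaved near 0 and 1; bounds clipped to \[0, 1\].
#'
#' @param successes,n binomial counts.
#' @param confidence confidence level in (0, 1); default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  check_binomial_args(successes, n, confidence)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  c(low = max(0, (centre - half) / denom),
    high = min(1, (centre + half) / denom))
}

#' Clopper-Pearson exact interval for a binomial proportion
#'
#' Exact interval from beta-distribution quantiles; conservative (never
#' narrower than the Wilson interval). By convention the lower bound is 0
#' when there are no successes and the upper bound is 1 when all trials
#' succeed.
#'
#' @inheritParams wilson_interval
#' @return Named numeric vector `c(low, high)`.
#' @export
clopper_pearson_interval <- function(successes, n, confidence = 0.95) {
  check_binomial_args(successes, n, confidence)
  alpha <- 1 - confidence
  low <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  high <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(low = low, high = high)
}

binomial_interval <- function(successes, n, confidence,
                              method = c("wilson", "clopper_pearson")) {
  method <- match.arg(method)
  switch(method,
         wilson = wilson_interval(successes, n, confidence),
         clopper_pearson = clopper_pearson_interval(successes, n,
                                                    confidence))
}

#' Cohen's kappa for two raters over nominal labels
#'
#' Chance-corrected agreement \eqn{(p_o - p_e)/(1 - p_e)}, with the
#' expected agreement \eqn{p_e} from the product of the raters' marginal
#' label frequencies. Unweighted (labels are nominal). The degenerate case
#' of perfect agreement with \eqn{p_e = 1} (both raters constant on the
#' same label) is defined as 1.
#'
#' @param ratings_a,ratings_b equal-length label vectors.
#' @return Kappa statistic in \[-1, 1\].
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must have equal length", call. = FALSE)
  if (!length(ratings_a))
    stop("rating vectors must be non-empty", call. = FALSE)
  labels <- sort(unique(c(as.character(ratings_a),
                          as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = labels)
  b <- factor(as.character(ratings_b), levels = labels)
  n <- length(a)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < .Machine$double.eps) {
    if (p_o >= 1 - .Machine$double.eps) return(1)
    stop("kappa undefined: expected agreement is 1 but observed is not",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Render a fraction as a percentage string, one decimal, half-up
#'
#' Matches the reporting style of clinical tables: multiply by 100 and
#' round half away from zero to one decimal (so 280/281 prints "99.6").
#'
#' @param x fraction(s) in \[0, 1\].
#' @return Character vector like `"24.6"`.
#' @export
percent1 <- function(x) {
  sprintf("%.1f", floor(x * 1000 + 0.5 + 1e-9) / 10)
}

#' Evaluate the triage tool over a cohort
#'
#' Runs the triage engine on every record, tallies the four priorities,
#' binarizes the recommendations (immediate/urgent positive) and computes
#' the tool's sensitivity over the confirmed-disease records, with a
#' binomial confidence interval. For a `CONSERVATIVE` run the engine is
#' also re-run under `BASE` and the demotion ledger — the records whose
#' priority dropped when unknown perianal symptoms were treated as present
#' — is recorded.
#'
#' @param cohort a cohort data frame; sensitivity is computed over the
#'   records with `crc_confirmed == "yes"` (a warning is noted in the
#'   result when the cohort mixes confirmation status).
#' @param policy a [missing_data_policy()] or mode string.
#' @param constants a [rule_constants()].
#' @param ci_method `"wilson"` (default) or `"clopper_pearson"`.
#' @param confidence confidence level, default 0.95.
#' @param threshold a priori adequacy threshold for sensitivity, default
#'   0.90.
#' @return An object of class `cohort_evaluation`: `n`, `counts` (named by
#'   [PRIORITY_LEVELS] in descending urgency), `positives`, `n_confirmed`,
#'   `sensitivity`, `ci_low`, `ci_high`, `ci_method`, `confidence`,
#'   `policy`, `threshold`, `meets_threshold`, `demoted` (data frame of
#'   demoted record ids with their priorities under both policies; only
#'   for CONSERVATIVE runs), `warnings`.
#' @examples
#' cohort <- build_validation_fixture()
#' evaluate_cohort(cohort, policy = "BASE")
#' @export
evaluate_cohort <- function(cohort, policy = missing_data_policy("BASE"),
                            constants = rule_constants(),
                            ci_method = c("wilson", "clopper_pearson"),
                            confidence = 0.95, threshold = 0.90) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("cohort must be a non-empty data frame", call. = FALSE)
  ci_method <- match.arg(ci_method)
  policy <- as_policy(policy)

  res <- triage_cohort(cohort, policy, constants)
  lev <- rev(PRIORITY_LEVELS)  # descending urgency for reporting
  counts <- vapply(lev, function(p) sum(res$priority == p), integer(1))

  confirmed <- cohort$crc_confirmed == "yes"
  warnings <- character(0)
  if (!all(confirmed)) {
    warnings <- paste0("sensitivity computed over the ", sum(confirmed),
                       " confirmed-CRC records of ", nrow(cohort))
  }
  if (!any(confirmed))
    stop("sensitivity is undefined: no record has crc_confirmed = 'yes'",
         call. = FALSE)

  pos <- binarize_priority(res$priority) == "positive"
  positives <- sum(pos & confirmed)
  n_confirmed <- sum(confirmed)
  sens <- sensitivity(positives, n_confirmed)
  ci <- binomial_interval(positives, n_confirmed, confidence, ci_method)

  demoted <- NULL
  if (policy$mode == "CONSERVATIVE") {
    base_res <- triage_cohort(cohort, missing_data_policy("BASE"),
                              constants)
    drop <- res$priority < base_res$priority
    demoted <- data.frame(id = res$id[drop],
                          base_priority = as.character(base_res$priority[drop]),
                          conservative_priority = as.character(res$priority[drop]),
                          stringsAsFactors = FALSE)
  }

  structure(list(n = nrow(cohort), counts = counts,
                 positives = positives, n_confirmed = n_confirmed,
                 sensitivity = sens,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 ci_method = ci_method, confidence = confidence,
                 policy = policy$mode, threshold = threshold,
                 meets_threshold = sens >= threshold,
                 demoted = demoted, warnings = warnings,
                 triage = res),
            class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

#' @export
summary.cohort_evaluation <- function(object, ...) {
  print(object)
  invisible(object)
}
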