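#' Area under the ROC curve
#'
#' Mann--Whitney concordance probability: the probability that a random
#' case outscores a random control, with ties counted as 1/2. Computed
#' from midranks.
#'
#' @param scores numeric case scores (higher = more case-like).
#' @param labels binary labels (0 = control, 1 = case).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  if (m == 0L || n == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

# Placement values: V10[i] = fraction of controls outscored by case i
# (ties 1/2); V01[j] = fraction of cases outscored by control j, reversed.
placement_values <- function(scores, labels) {
  cases <- scores[labels == 1L]
  ctrls <- scores[labels == 0L]
  m <- length(cases)
  n <- length(ctrls)
  r_all <- rank(c(cases, ctrls), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(cases, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(ctrls, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' DeLong confidence interval for an AUC
#'
#' Nonparametric variance from the placement-value (structural components)
#' estimator; the interval is formed on the identity scale and clipped to
#' `[0, 1]` (set `logit = TRUE` for the logit scale). A degenerate variance
#' (perfect or zero separation) returns a point interval with a warning.
#'
#' @param scores,labels as in [auc()]; at least 2 samples per class.
#' @param level confidence level.
#' @param logit form the interval on the logit scale.
#' @return List with `auc`, `ci_low`, `ci_high`, `se`.
#' @export
delong_ci <- function(scores, labels, level = 0.95, logit = FALSE) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L) {
    stop("DeLong CI requires at least 2 samples per class", call. = FALSE)
  }
  pv <- placement_values(scores, labels)
  v <- stats::var(pv$v10) / pv$m + stats::var(pv$v01) / pv$n
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (se == 0) {
    warning("degenerate AUC variance; returning a point interval")
    return(list(auc = pv$auc, ci_low = pv$auc, ci_high = pv$auc, se = 0))
  }
  if (logit) {
    a <- pmin(pmax(pv$auc, 1e-12), 1 - 1e-12)
    lg <- log(a / (1 - a))
    se_lg <- se / (a * (1 - a))
    lo <- stats::plogis(lg - z * se_lg)
    hi <- stats::plogis(lg + z * se_lg)
  } else {
    lo <- max(0, pv$auc - z * se)
    hi <- min(1, pv$auc + z * se)
  }
  list(auc = pv$auc, ci_low = lo, ci_high = hi, se = se)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided test of equal AUCs for two score vectors measured on the same
#' samples (paired design), using the covariance of placement values.
#' Identical score vectors give a difference of 0 and p = 1 by definition.
#'
#' @param scores_a,scores_b aligned score vectors.
#' @param labels shared binary labels.
#' @return List with `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("shape error: scores and labels must align", call. = FALSE)
  }
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  delta <- pa$auc - pb$auc
  v <- stats::var(pa$v10 - pb$v10) / pa$m + stats::var(pa$v01 - pb$v01) / pa$n
  if (v <= 0) {
    p <- if (abs(delta) < 1e-15) 1 else 0
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                z = if (abs(delta) < 1e-15) 0 else sign(delta) * Inf,
                p_value = p))
  }
  z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

youden_candidates <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1L) return(c(-Inf, Inf))
  c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
}

#' Youden-index decision threshold
#'
#' Returns the cut maximizing J = sensitivity + specificity - 1 over
#' midpoints between adjacent sorted unique scores (with infinite
#' sentinels). A sample is called a case iff its score is strictly greater
#' than the threshold. Ties in J are broken toward higher specificity
#' (the larger threshold), favoring fewer false positives in a screening
#' setting.
#'
#' @param scores,labels as in [auc()].
#' @return The threshold (possibly infinite).
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("Youden threshold requires both classes", call. = FALSE)
  }
  cand <- youden_candidates(scores)
  best_j <- -Inf
  best_spec <- -Inf
  best_t <- cand[1]
  for (t in cand) {
    cf <- confusion_at(scores, labels, t)
    j <- cf$sensitivity + cf$specificity - 1
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && cf$specificity > best_spec + 1e-12)) {
      best_j <- j
      best_spec <- cf$specificity
      best_t <- t
    }
  }
  best_t
}

#' Sensitivity and specificity at a threshold
#'
#' Predicted-positive convention: case iff score strictly greater than the
#' threshold.
#'
#' @param scores,labels as in [auc()].
#' @param threshold decision cut (finite or infinite).
#' @return List with `sensitivity`, `specificity`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- scores > threshold
  list(sensitivity = mean(pred[labels == 1L]),
       specificity = mean(!pred[labels == 0L]))
}

#' Full ROC curve
#'
#' Sensitivity/specificity at every candidate threshold (midpoints between
#' adjacent unique scores plus infinite sentinels), with the AUC and its
#' DeLong interval.
#'
#' @param scores,labels as in [auc()].
#' @param level CI level.
#' @return A `roc_result`: list with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `ci_low`, `ci_high`, `n_cases`, `n_controls`.
#' @export
roc_points <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  cand <- youden_candidates(scores)
  sens <- spec <- numeric(length(cand))
  for (i in seq_along(cand)) {
    cf <- confusion_at(scores, labels, cand[i])
    sens[i] <- cf$sensitivity
    spec[i] <- cf$specificity
  }
  ci <- if (sum(labels == 1L) >= 2L && sum(labels == 0L) >= 2L) {
    suppressWarnings(delong_ci(scores, labels, level))
  } else {
    a <- auc(scores, labels)
    list(auc = a, ci_low = a, ci_high = a)
  }
  structure(
    list(thresholds = cand, sensitivity = sens, specificity = spec,
         auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
         n_cases = sum(labels == 1L), n_controls = sum(labels == 0L)),
    class = "roc_result"
  )
}

#' Evaluate a model's scores over a discovery/validation split
#'
#' The decision threshold is fixed by maximizing the Youden index on the
#' discovery cohort and applied unchanged to the validation cohort — no
#' re-optimization on held-out data.
#'
#' @param scores_discovery,labels_discovery discovery-cohort scores/labels.
#' @param scores_validation,labels_validation validation-cohort
#'   scores/labels.
#' @param level CI level.
#' @return data.frame with one row per cohort: `cohort`, `auc`, `ci_low`,
#'   `ci_high`, `sensitivity`, `specificity`, `threshold`.
#' @export
evaluate_split <- function(scores_discovery, labels_discovery,
                           scores_validation, labels_validation,
                           level = 0.95) {
  thr <- youden_threshold(scores_discovery, labels_discovery)
  row_for <- function(cohort, sc, lb) {
    ci <- suppressWarnings(delong_ci(sc, lb, level))
    cf <- confusion_at(sc, lb, thr)
    data.frame(cohort = cohort, auc = ci$auc, ci_low = ci$ci_low,
               ci_high = ci$ci_high, sensitivity = cf$sensitivity,
               specificity = cf$specificity, threshold = thr)
  }
  rbind(row_for("discovery", scores_discovery, labels_discovery),
        row_for("validation", scores_validation, labels_validation))
}
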