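#' Confusion counts
#'
#' Container for a 2x2 classification outcome. `tp + fn` is the number of
#' true positives presented, `fp + tn` the number of true negatives.
#'
#' @param tp,fn,fp,tn Nonnegative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "confusion_counts")
}

#' Classification performance measures from confusion counts
#'
#' Computes sensitivity, specificity, balanced accuracy, precision and
#' F-measure on the 0-1 scale:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (sensitivity + specificity)/2 (balanced accuracy),
#' precision = TP/(TP+FP),
#' F = 2 * precision * sensitivity / (precision + sensitivity).
#' Ratios with a zero denominator are returned as `NA` (undefined), never
#' silently coerced to zero.
#'
#' @param counts A [confusion_counts()] object (or list with tp/fn/fp/tn).
#' @return A list of class `metrics_report` with fields `sensitivity`,
#'   `specificity`, `accuracy`, `precision`, `f_measure` plus the counts.
#' @export
confusion_metrics <- function(counts) {
  if (!all(c("tp", "fn", "fp", "tn") %in% names(counts))) {
    stop("counts must contain tp, fn, fp, tn", call. = FALSE)
  }
  counts <- confusion_counts(counts$tp, counts$fn, counts$fp, counts$tn)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(counts$tp, counts$tp + counts$fn)
  spec <- ratio(counts$tn, counts$tn + counts$fp)
  prec <- ratio(counts$tp, counts$tp + counts$fp)
  acc <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  f <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  structure(
    list(sensitivity = sens, specificity = spec, accuracy = acc,
         precision = prec, f_measure = f, auc = NA_real_, counts = counts),
    class = "metrics_report"
  )
}

#' @export
format.metrics_report <- function(x, ...) {
  vals <- unlist(x[c("sensitivity", "specificity", "accuracy",
                     "precision", "f_measure", "auc")])
  paste0(names(vals), "=", ifelse(is.na(vals), "NA",
                                  sprintf("%.1f%%", 100 * vals)),
         collapse = " ")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: P(score_pos > score_neg) + 0.5 P(tie),
#' computed from mid-ranks. Identical to trapezoidal integration of the
#' empirical ROC curve.
#'
#' @param scores Numeric scores, higher = more positive-like.
#' @param labels Logical or 0/1 vector, `TRUE`/1 marking the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auc_score requires both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Kendall tau-b trend test
#'
#' Tie-corrected Kendall rank correlation between a numeric feature and an
#' ordinal group coding, with a two-sided p-value from the normal
#' approximation using the tie-adjusted variance. The canonical variant-class
#' coding is neutral = 1 < pgx = 2 < disease = 3 (see [class_trend_codes()]),
#' the only coding consistent with the signs of all reported feature trends.
#'
#' @param feature Numeric vector.
#' @param group_code Ordinal (numeric/integer) coding, same length.
#' @return List with `tau` (tau-b), `p_value`, `n`. A constant feature or
#'   constant coding yields `tau = NA` (undefined marker) and `p_value = NA`.
#' @export
kendall_trend_test <- function(feature, group_code) {
  if (length(feature) != length(group_code)) {
    stop("feature and group_code lengths differ", call. = FALSE)
  }
  keep <- is.finite(feature) & is.finite(group_code)
  x <- feature[keep]
  y <- as.numeric(group_code)[keep]
  n <- length(x)
  if (n < 2L || length(unique(y)) < 2L || length(unique(x)) < 2L) {
    return(list(tau = NA_real_, p_value = NA_real_, n = n))
  }
  # concordant minus discordant via sign cross-table over pairs, computed
  # from the joint contingency table (O(levels^2), exact)
  tab <- table(x, y)
  xs <- as.numeric(rownames(tab))
  ys <- as.numeric(colnames(tab))
  S <- 0
  nr <- nrow(tab); nc <- ncol(tab)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      nij <- tab[i, j]
      if (nij == 0) next
      if (i < nr && j < nc) {
        S <- S + nij * sum(tab[(i + 1):nr, (j + 1):nc, drop = FALSE])
      }
      if (i < nr && j > 1) {
        S <- S - nij * sum(tab[(i + 1):nr, 1:(j - 1), drop = FALSE])
      }
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- as.numeric(rowSums(tab))
  ty <- as.numeric(colSums(tab))
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  tau <- S / denom
  # tie-adjusted variance of S (same form as stats::cor.test with ties)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- if (var_s > 0) S / sqrt(var_s) else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  list(tau = tau, p_value = min(p, 1), n = n)
}

#' Ordinal codes for the variant-class trend test
#'
#' @param labels Character vector with values in neutral/pgx/disease.
#' @return Integer codes: neutral = 1, pgx = 2, disease = 3.
#' @export
class_trend_codes <- function(labels) {
  codes <- c(neutral = 1L, pgx = 2L, disease = 3L)
  if (!all(labels %in% names(codes))) {
    stop("labels must be one of neutral, pgx, disease", call. = FALSE)
  }
  unname(codes[labels])
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with mid-ranks for ties. When both samples have
#' at most 8 observations the two-sided p-value is computed by exhaustive
#' enumeration of all rank assignments; otherwise the normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `statistic` (rank sum of `x`), `u` (Mann-Whitney U of
#'   `x`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx == 0L || ny == 0L) {
    stop("wilcoxon_rank_sum requires non-empty samples", call. = FALSE)
  }
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  if (nx <= 8L && ny <= 8L) {
    combos <- utils::combn(nx + ny, nx)
    ws <- colSums(matrix(r[combos], nrow = nx))
    # two-sided exact p: tail probability of |W - E[W]| at least as extreme
    dev <- abs(ws - mean(ws))
    p <- mean(dev >= abs(w - mean(ws)) - 1e-9)
    return(list(statistic = w, u = u, p_value = p, method = "exact"))
  }
  mu <- nx * (ny + nx + 1) / 2
  n <- nx + ny
  ties <- table(r)
  tie_adj <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_adj)
  diff <- w - mu
  z <- (diff - sign(diff) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = w, u = u, p_value = p, method = "normal")
}

#' Threshold-based binary classification of predictor scores
#'
#' Converts continuous pathogenicity scores to pathogenic/benign calls.
#' With `orientation = "lower"` (SIFT convention) a variant is pathogenic
#' iff its score is strictly below the threshold; with `"higher"`
#' (PolyPhen2/MutPred convention) iff strictly above.
#'
#' @param scores Numeric scores; `NA` propagates.
#' @param threshold Finite numeric cutoff.
#' @param orientation `"lower"` or `"higher"`: which side is pathogenic.
#' @return Logical vector, `TRUE` = pathogenic.
#' @export
threshold_classify <- function(scores, threshold,
                               orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (orientation == "lower") scores < threshold else scores > threshold
}

#' Confusion metrics from binary predictions
#'
#' @param predicted Logical vector, `TRUE` = predicted positive.
#' @param actual Logical vector, `TRUE` = actually positive.
#' @return A `metrics_report` (without AUC).
#' @export
binary_metrics <- function(predicted, actual) {
  keep <- !is.na(predicted) & !is.na(actual)
  predicted <- predicted[keep]
  actual <- actual[keep]
  confusion_metrics(confusion_counts(
    tp = sum(predicted & actual),
    fn = sum(!predicted & actual),
    fp = sum(predicted & !actual),
    tn = sum(!predicted & !actual)
  ))
}
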