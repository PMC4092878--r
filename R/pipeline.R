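# Pipeline orchestration: canonical schemas, the per-feature trend table,
# three-group and two-group weighted-forest discrimination, MAF summaries
# and external predictor-score evaluation.

structure_schema_cols <- function() {
  c("protein_id", "position", "ref", "alt", "label",
    "conservation", "consng", "nng", "acc", "ss",
    "bvalue", "stability", "d_hydro", "d_mw")
}

sequence_schema_cols <- function() {
  c("variant_id", "label", "conservation", "bvalue", "stability",
    "d_hydro", "d_mw", "extra_feature")
}

schema_feature_cols <- function(schema) {
  if (schema == "structure") {
    c("conservation", "consng", "nng", "acc", "ss",
      "bvalue", "stability", "d_hydro", "d_mw")
  } else {
    c("conservation", "bvalue", "stability", "d_hydro", "d_mw",
      "extra_feature")
  }
}

VALID_LABELS <- c("neutral", "disease", "pgx")

#' Load and validate a variant feature table
#'
#' Canonical CSV schemas: the structure set has 14 columns (protein_id,
#' position, ref, alt, label + 9 feature columns), the sequence set 8
#' (variant_id, label + 6 feature columns). Row and per-class counts and
#' per-column missing-value counts are reported via `message()`.
#'
#' @param path CSV file with header.
#' @param schema `"structure"` or `"sequence"`.
#' @return A validated `feature_table` data.frame (attributes `schema`,
#'   `missing_counts`).
#' @export
load_feature_table <- function(path, schema = c("structure", "sequence")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("schema error: unreadable CSV (",
                                         conditionMessage(e), ")",
                                         call. = FALSE))
  expected <- if (schema == "structure") structure_schema_cols() else
    sequence_schema_cols()
  miss <- setdiff(expected, colnames(d))
  if (length(miss)) {
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!d$label %in% VALID_LABELS)
  if (length(bad)) {
    stop("validation error: unknown label '", d$label[bad[1]],
         "' in row ", bad[1], call. = FALSE)
  }
  d <- d[, expected]
  missing_counts <- vapply(d, function(x) sum(is.na(x)), integer(1))
  message("loaded ", nrow(d), " variants (",
          paste(sprintf("%s=%d", names(table(d$label)), table(d$label)),
                collapse = ", "), ")")
  structure(d, schema = schema, missing_counts = missing_counts,
            class = c("feature_table", "data.frame"))
}

#' Write a feature table to CSV in the canonical schema
#' @param table Feature data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-feature class means and trend test
#'
#' For every feature column: per-class means (disease, PGx, neutral) and
#' the Kendall tau-b trend test under the ordinal class coding
#' neutral = 1 < pgx = 2 < disease = 3. Non-numeric features and constant
#' features are reported with an undefined-tau marker.
#'
#' @param table Feature data.frame with a `label` column.
#' @param features Feature columns; default = numeric schema features
#'   present in the table.
#' @return data.frame with columns `feature`, `mean_disease`, `mean_pgx`,
#'   `mean_neutral`, `tau`, `p_value`, `n`.
#' @export
run_trend_analysis <- function(table, features = NULL) {
  if (length(unique(table$label)) < 2L) {
    stop("trend analysis needs at least 2 classes", call. = FALSE)
  }
  if (is.null(features)) {
    # every schema feature is reported; non-numeric ones (secondary
    # structure) carry undefined-tau markers
    features <- setdiff(colnames(table),
                        c("protein_id", "position", "ref", "alt",
                          "label", "variant_id"))
  }
  codes <- class_trend_codes(table$label)
  rows <- lapply(features, function(f) {
    v <- table[[f]]
    if (!is.numeric(v)) {
      return(data.frame(feature = f, mean_disease = NA_real_,
                        mean_pgx = NA_real_, mean_neutral = NA_real_,
                        tau = NA_real_, p_value = NA_real_, n = NA_integer_))
    }
    cm <- tapply(v, table$label, mean, na.rm = TRUE)
    kt <- kendall_trend_test(v, codes)
    data.frame(
      feature = f,
      mean_disease = if ("disease" %in% names(cm)) cm[["disease"]] else NA,
      mean_pgx = if ("pgx" %in% names(cm)) cm[["pgx"]] else NA,
      mean_neutral = if ("neutral" %in% names(cm)) cm[["neutral"]] else NA,
      tau = kt$tau, p_value = kt$p_value, n = kt$n
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Three-group weighted-forest discrimination
#'
#' Trains the class-weighted forest on all three variant classes and
#' summarizes out-of-bag performance: per-class error rates, the
#' unweighted mean of per-class errors (headline, consistent with the
#' balanced-accuracy convention) and the pooled OOB error, plus the
#' per-variant normalized class scores for decision-simplex plotting.
#'
#' @param table Feature data.frame with `label`.
#' @param config A [forest_config()].
#' @param features Feature columns (default: schema features present).
#' @return List with `per_class_error`, `overall_error` (mean of
#'   per-class), `pooled_error`, `confusion`, `scores`, `model`.
#' @export
run_three_group <- function(table, config = forest_config(),
                            features = NULL) {
  if (!all(VALID_LABELS %in% table$label)) {
    stop("all three classes must be present", call. = FALSE)
  }
  if (is.null(features)) {
    features <- setdiff(colnames(table),
                        c("protein_id", "position", "ref", "alt",
                          "label", "variant_id"))
  }
  model <- train_weighted_forest(table, table$label, config, features)
  scores <- oob_scores(model)
  pred <- classify_three_group(scores)
  ok <- !is.na(pred)
  actual <- model$labels[ok]
  pred <- pred[ok]
  confusion <- table(actual = actual, predicted = pred)
  per_class <- vapply(sort(unique(actual)), function(cl) {
    mean(pred[actual == cl] != cl)
  }, numeric(1))
  list(
    per_class_error = per_class,
    overall_error = mean(per_class),
    pooled_error = mean(pred != actual),
    confusion = confusion,
    scores = scores,
    model = model
  )
}

#' Two-group discrimination suite
#'
#' The three pairwise comparisons (disease/neutral, PGx/disease,
#' PGx/neutral), positive class = first-named, each a class-weighted
#' forest evaluated on OOB scores.
#'
#' @param table Feature data.frame with `label`.
#' @param config A [forest_config()]; each comparison reuses its
#'   `n_trees`/`mtry`/`seed` with reciprocal-size weights for the pair.
#' @param features Feature columns.
#' @return data.frame with one row per comparison and the six
#'   performance measures on the percent scale (1 decimal).
#' @export
run_two_group_suite <- function(table, config = forest_config(),
                                features = NULL) {
  if (is.null(features)) {
    features <- setdiff(colnames(table),
                        c("protein_id", "position", "ref", "alt",
                          "label", "variant_id"))
  }
  comparisons <- list(
    c("disease", "neutral"), c("pgx", "disease"), c("pgx", "neutral")
  )
  rows <- lapply(comparisons, function(cmp) {
    pair_cfg <- forest_config(n_trees = config$n_trees,
                              mtry = config$mtry, min_node = config$min_node,
                              seed = config$seed)
    rep <- run_two_group(table, table$label, cmp[1], cmp[2],
                         config = pair_cfg, features = features)
    data.frame(
      classification = paste(cmp, collapse = "/"),
      sensitivity = pct(rep$sensitivity),
      specificity = pct(rep$specificity),
      accuracy = pct(rep$accuracy),
      precision = pct(rep$precision),
      f_measure = pct(rep$f_measure),
      auc = pct(rep$auc)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pct <- function(x) if (is.na(x)) NA_real_ else round(100 * x, 1)

#' Minor-allele-frequency summary per variant class
#'
#' Per class: fraction of variants with observed (non-missing) MAF, mean
#' MAF over observed values, and pairwise Wilcoxon rank-sum p-values
#' between classes on the observed values.
#'
#' @param scores_table data.frame with `label` and `maf` columns (`NA` =
#'   not observed in the population panel).
#' @return List with `per_class` (data.frame: label, n, observed_frac,
#'   mean_maf) and `pairwise_p` (named numeric vector).
#' @export
run_maf_analysis <- function(scores_table) {
  if (!"maf" %in% colnames(scores_table)) {
    stop("scores table must contain a maf column", call. = FALSE)
  }
  labs <- intersect(VALID_LABELS, unique(scores_table$label))
  per_class <- do.call(rbind, lapply(labs, function(cl) {
    v <- scores_table$maf[scores_table$label == cl]
    obs <- v[!is.na(v)]
    data.frame(label = cl, n = length(v),
               observed_frac = length(obs) / length(v),
               mean_maf = if (length(obs)) mean(obs) else NA_real_)
  }))
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  pairwise_p <- vapply(pairs, function(p) {
    x <- scores_table$maf[scores_table$label == p[1]]
    y <- scores_table$maf[scores_table$label == p[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) return(NA_real_)
    wilcoxon_rank_sum(x, y)$p_value
  }, numeric(1))
  names(pairwise_p) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  list(per_class = per_class, pairwise_p = pairwise_p)
}

#' Evaluate external pathogenicity predictors
#'
#' For each available score column (sift, polyphen2, mutpred) and each
#' pairwise comparison: threshold-based confusion metrics (SIFT pathogenic
#' iff score < 0.05; PolyPhen2/MutPred pathogenic iff score > threshold,
#' default 0.5) and the threshold-free rank AUC of the pathogenic
#' orientation. Rows with a missing score are excluded per comparison
#' with a recorded count.
#'
#' @param scores_table data.frame with `label` and score columns.
#' @param thresholds Named list of per-tool thresholds.
#' @param positive_first Positive class is the first-named class of each
#'   comparison (the Table 3 convention); set `FALSE` to use the more
#'   pathogenic class as positive regardless of ordering.
#' @return data.frame: tool, classification, the six measures (%),
#'   n_used, n_missing.
#' @export
run_tool_eval <- function(scores_table,
                          thresholds = list(sift = 0.05, polyphen2 = 0.5,
                                            mutpred = 0.5),
                          positive_first = TRUE) {
  tools <- intersect(c("sift", "polyphen2", "mutpred"),
                     colnames(scores_table))
  if (!length(tools)) {
    stop("no score column (sift/polyphen2/mutpred) present", call. = FALSE)
  }
  comparisons <- list(
    c("disease", "neutral"), c("pgx", "disease"), c("pgx", "neutral")
  )
  rows <- list()
  for (tool in tools) {
    orientation <- if (tool == "sift") "lower" else "higher"
    for (cmp in comparisons) {
      sel <- scores_table$label %in% cmp
      sc <- scores_table[[tool]][sel]
      lab <- scores_table$label[sel]
      n_missing <- sum(is.na(sc))
      ok <- !is.na(sc)
      sc <- sc[ok]; lab <- lab[ok]
      pos <- if (positive_first) cmp[1] else {
        if ("disease" %in% cmp) "disease" else "pgx"
      }
      if (!length(sc) || length(unique(lab)) < 2L) next
      pathogenic <- threshold_classify(sc, thresholds[[tool]], orientation)
      actual <- lab == pos
      # threshold calls are pathogenic/benign; the positive class of the
      # comparison is treated as the pathogenic side
      rep <- binary_metrics(pathogenic, actual)
      auc_sc <- if (orientation == "lower") -sc else sc
      auc <- auc_score(auc_sc, lab == pos)
      rows[[length(rows) + 1L]] <- data.frame(
        tool = tool, classification = paste(cmp, collapse = "/"),
        sensitivity = pct(rep$sensitivity),
        specificity = pct(rep$specificity),
        accuracy = pct(rep$accuracy),
        precision = pct(rep$precision),
        f_measure = pct(rep$f_measure),
        auc = pct(auc),
        n_used = length(sc), n_missing = n_missing
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full analysis report
#'
#' Runs every requested section and assembles an `analysis_report`:
#' the per-feature trend table, three-group error rates, the two-group
#' suite, MAF summaries and external-tool evaluation (the latter two only
#' when a scores table is supplied).
#'
#' @param table Feature table (structure or sequence schema).
#' @param scores_table Optional MAF/predictor-score data.frame.
#' @param config A [forest_config()].
#' @return An `analysis_report` list with elements `table2`, `table3`,
#'   `three_group`, `maf`, `tool_eval` (skipped sections carry a reason
#'   string).
#' @export
run_analysis <- function(table, scores_table = NULL,
                         config = forest_config()) {
  three <- if (all(VALID_LABELS %in% table$label)) {
    tg <- run_three_group(table, config)
    tg[c("per_class_error", "overall_error", "pooled_error", "confusion")]
  } else "skipped: not all three classes present"
  report <- list(
    table2 = run_trend_analysis(table),
    three_group = three,
    table3 = run_two_group_suite(table, config),
    maf = if (is.null(scores_table)) "skipped: no scores table" else
      run_maf_analysis(scores_table),
    tool_eval = if (is.null(scores_table)) "skipped: no scores table" else
      run_tool_eval(scores_table)
  )
  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Feature trends (class means + Kendall tau) ==\n")
  print(x$table2, digits = 3)
  cat("\n== Three-group discrimination (OOB error rates) ==\n")
  if (is.character(x$three_group)) {
    cat(x$three_group, "\n")
  } else {
    pc <- x$three_group$per_class_error
    cat(sprintf("overall %.0f%% (pooled %.0f%%); %s\n",
                100 * x$three_group$overall_error,
                100 * x$three_group$pooled_error,
                paste(sprintf("%s %.0f%%", names(pc), 100 * pc),
                      collapse = ", ")))
  }
  cat("\n== Two-group discrimination ==\n")
  print(x$table3)
  if (!is.character(x$maf)) {
    cat("\n== MAF by class ==\n")
    print(x$maf$per_class, digits = 3)
    cat("pairwise Wilcoxon p:",
        paste(sprintf("%s=%.2g", names(x$maf$pairwise_p),
                      x$maf$pairwise_p), collapse = ", "), "\n")
  }
  if (!is.character(x$tool_eval)) {
    cat("\n== External predictor evaluation ==\n")
    print(x$tool_eval)
  }
  invisible(x)
}
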