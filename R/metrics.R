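# Evaluation: AUROC with DeLong confidence intervals, threshold metrics,
# and train-vs-validation cohort comparison statistics.

#' AUROC with a DeLong confidence interval
#'
#' The AUROC is the Mann-Whitney statistic (half credit for ties); its
#' variance comes from DeLong's structural components (via pROC) and the
#' interval is `auroc +/- z * se`, clipped to `[0, 1]`.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels logical (or 0/1) outcomes; both classes must be present.
#' @param level confidence level (default 0.95).
#' @return List with `auroc`, `ci_low`, `ci_high`, `level`.
#' @export
auroc_delong <- function(scores, labels, level = 0.95) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2L)
    dhf_stop("labels contain a single class; AUROC undefined")
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  # pROC warns that a degenerate AUC of 1 gives a degenerate interval;
  # that is the documented behaviour here, not a user error
  ci <- suppressWarnings(pROC::ci.auc(r, conf.level = level, method = "delong"))
  list(auroc = as.numeric(pROC::auc(r)),
       ci_low = max(0, as.numeric(ci[1L])),
       ci_high = min(1, as.numeric(ci[3L])),
       level = level)
}

#' Threshold classification metrics
#'
#' Confusion-matrix metrics at a score threshold plus the AUROC with its
#' DeLong interval. With no predicted positives, precision is reported as
#' 0 with a warning.
#'
#' @inheritParams auroc_delong
#' @param threshold score cut-off for calling a positive (default 0.5).
#' @return A `metrics_report` list: `auroc`, `ci_low`, `ci_high`,
#'   `precision`, `sensitivity`, `accuracy`, `f_score`, `threshold`, `n`,
#'   `n_positive`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  if (tp + fp == 0L) {
    warning("no predicted positives; precision reported as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  sensitivity <- if (tp + fn > 0L) tp / (tp + fn) else 0
  accuracy <- (tp + tn) / length(y)
  f_score <- if (precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else 0
  dl <- auroc_delong(scores, labels)
  structure(list(
    auroc = dl$auroc, ci_low = dl$ci_low, ci_high = dl$ci_high,
    precision = precision, sensitivity = sensitivity, accuracy = accuracy,
    f_score = f_score, threshold = threshold,
    n = length(y), n_positive = sum(y)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "AUROC %.3f [%.3f-%.3f]  precision %.3f  sensitivity %.3f  accuracy %.3f  F %.3f  (n=%d, %d positive)\n",
    x$auroc, x$ci_low, x$ci_high, x$precision, x$sensitivity, x$accuracy,
    x$f_score, x$n, x$n_positive))
  invisible(x)
}

#' Compare two cohorts variable by variable
#'
#' Chi-square tests for categorical variables and two-sided two-sample
#' t-tests for continuous variables, flagged significant at p < 0.05.
#' Zero-variance continuous variables report p = 1 with a note.
#'
#' @param a,b data frames with identical columns (one row per patient).
#' @return Data frame with `variable`, `type`, `statistic`, `p_value`,
#'   `significant`, `note`.
#' @export
compare_cohorts <- function(a, b) {
  if (!identical(sort(names(a)), sort(names(b))))
    stop_config("cohort tables must share the same variables")
  rows <- lapply(names(a), function(v) {
    xa <- a[[v]]; xb <- b[[v]]
    if (is.numeric(xa)) {
      if (stats::sd(c(xa, xb)) < 1e-12) {
        return(data.frame(variable = v, type = "continuous", statistic = 0,
                          p_value = 1, note = "zero variance"))
      }
      tt <- tryCatch(stats::t.test(xa, xb), error = function(e) NULL)
      if (is.null(tt))
        return(data.frame(variable = v, type = "continuous", statistic = 0,
                          p_value = 1, note = "degenerate"))
      data.frame(variable = v, type = "continuous",
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 note = "")
    } else {
      tabl <- table(factor(c(rep("a", length(xa)), rep("b", length(xb)))),
                    factor(c(as.character(xa), as.character(xb))))
      ct <- suppressWarnings(stats::chisq.test(tabl))
      data.frame(variable = v, type = "categorical",
                 statistic = unname(ct$statistic), p_value = ct$p.value,
                 note = "")
    }
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < 0.05
  out[, c("variable", "type", "statistic", "p_value", "significant", "note")]
}

#' Patient-level comparison table for two cohort splits
#'
#' Builds the descriptive variable table (readmission label, age, gender,
#' ethnicity, pooled lab means) for two splits and runs
#' [compare_cohorts()].
#'
#' @param tables an `ehr_tables` object.
#' @param members_a,members_b two `hf_cohort` data frames.
#' @return The [compare_cohorts()] result.
#' @export
cohort_comparison <- function(tables, members_a, members_b) {
  describe <- function(members) {
    pat <- tables$patients
    i <- match(members$patient_id, pat$SUBJECT_ID)
    adm <- tables$admissions
    j <- match(members$index_admission_id, adm$HADM_ID)
    le <- tables$labevents
    le$lab <- tables$d_labitems$LABEL[match(le$ITEMID, tables$d_labitems$ITEMID)]
    labs <- sort(unique(tables$d_labitems$LABEL))
    ids <- lapply(seq_len(nrow(members)), function(k)
      c(members$prior_admission_ids[[k]], members$index_admission_id[k]))
    lab_means <- t(vapply(ids, function(id) {
      sub <- le[le$HADM_ID %in% id, ]
      vapply(labs, function(l) {
        v <- sub$VALUENUM[sub$lab == l]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    }, numeric(length(labs))))
    df <- data.frame(
      readmission = members$label,
      age = (adm$ADMITTIME[j] - pat$DOB[i]) / (365.25 * DAY_S),
      gender = pat$GENDER[i], ethnicity = pat$ETHNICITY[i])
    cbind(df, as.data.frame(lab_means))
  }
  compare_cohorts(describe(members_a), describe(members_b))
}
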