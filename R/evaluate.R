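# Metrics and figures: confusion matrices at spectrum and sample level,
# one-vs-rest sensitivity/specificity, overall and balanced accuracy,
# ROC/AUC for 2-group models, LD scatter/histogram plot data, and a
# reproducible report bundle.

#' Confusion matrix from a cross-validation result
#'
#' @param cv A [losocv()] result.
#' @param level `"sample"` (majority-vote predictions) or `"spectrum"`
#'   (per-spectrum predictions).
#' @return Object of class `"confusion_matrix"`: integer `counts`
#'   (true x predicted), `percent` (row-normalised, rows sum to 100 for
#'   non-empty rows), `classes`, `level`.
#' @export
confusion <- function(cv, level = c("sample", "spectrum")) {
  stopifnot(inherits(cv, "spath_cv"))
  level <- match.arg(level)
  df <- if (level == "sample") cv$samples else cv$spectra
  if (!nrow(df)) stop("empty cross-validation result", call. = FALSE)
  counts <- table(
    true = factor(df$true, levels = cv$classes),
    predicted = factor(df$predicted, levels = cv$classes)
  )
  counts <- unclass(counts)
  rs <- rowSums(counts)
  percent <- 100 * counts / ifelse(rs > 0, rs, NA)
  structure(list(counts = counts, percent = percent, classes = cv$classes,
                 level = level),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> (%s level; rows = true, cols = predicted)\n",
              x$level))
  print(x$counts)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest per class: sensitivity = TP/(TP+FN); specificity = TN/(TN+FP)
#' with all other classes pooled. Averages are unweighted means over classes;
#' overall accuracy is the correct fraction (trace/total); balanced accuracy
#' is the mean of average sensitivity and average specificity — both
#' accuracy readings are reported since either may be meant by an "accuracy"
#' headline. A class with no true instances has undefined sensitivity,
#' reported as `NA` and excluded from averages with a warning.
#'
#' @param cm A [confusion()] result.
#' @return Object of class `"classification_metrics"`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  if (nrow(counts) < 2) stop("metrics need >= 2 classes", call. = FALSE)
  total <- sum(counts)
  tp <- diag(counts)
  fn <- rowSums(counts) - tp
  fp <- colSums(counts) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  if (anyNA(sens)) {
    warning("class(es) with no true instances: sensitivity undefined, excluded from averages",
            call. = FALSE)
  }
  avg_sens <- mean(sens, na.rm = TRUE)
  avg_spec <- mean(spec, na.rm = TRUE)
  structure(list(
    sensitivity = sens, specificity = spec,
    average_sensitivity = avg_sens, average_specificity = avg_spec,
    overall_accuracy = sum(tp) / total,
    balanced_accuracy = (avg_sens + avg_spec) / 2,
    level = cm$level, classes = cm$classes
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("<classification_metrics> (%s level)\n", x$level))
  df <- data.frame(sensitivity = round(x$sensitivity, 3),
                   specificity = round(x$specificity, 3))
  print(df)
  cat(sprintf("  average sensitivity %.1f%%, average specificity %.1f%%\n",
              100 * x$average_sensitivity, 100 * x$average_specificity))
  cat(sprintf("  overall accuracy %.1f%%, balanced accuracy %.1f%%\n",
              100 * x$overall_accuracy, 100 * x$balanced_accuracy))
  invisible(x)
}

#' ROC curve and AUC for a 2-group model
#'
#' Sweeps a threshold over the pooled held-out scores: at the spectrum level
#' the positive-class posterior (or first LD score) of every test spectrum
#' across folds, at the sample level each sample's vote fraction for the
#' positive class. AUC is the concordance probability (ties count one half).
#' With more than 2 classes, set `one_vs_rest = TRUE` to score
#' `positive_class` against the pooled rest (an off-label convenience).
#'
#' @param cv A [losocv()] result.
#' @param positive_class The class treated as positive.
#' @param level `"spectrum"` or `"sample"`.
#' @param score `"posterior"` (default) or `"ld"` (spectrum level only).
#' @param one_vs_rest Allow > 2 classes by pooling the rest.
#' @return Object of class `"spath_roc"`: `thresholds`, `tpr`, `fpr`
#'   (non-decreasing, endpoints (0,0) and (1,1)), `auc`, `positive_class`,
#'   `level`.
#' @export
roc_curve <- function(cv, positive_class, level = c("spectrum", "sample"),
                      score = c("posterior", "ld"), one_vs_rest = FALSE) {
  stopifnot(inherits(cv, "spath_cv"))
  level <- match.arg(level)
  score <- match.arg(score)
  if (length(cv$classes) > 2 && !one_vs_rest) {
    stop("ROC is defined for 2-group models; use one_vs_rest = TRUE for a one-vs-rest curve",
         call. = FALSE)
  }
  stopifnot(positive_class %in% cv$classes)
  if (level == "spectrum") {
    truth <- cv$spectra$true == positive_class
    sc <- if (score == "posterior") {
      cv$spectra[[paste0("posterior.", positive_class)]]
    } else {
      cv$spectra$ld1
    }
  } else {
    truth <- cv$samples$true == positive_class
    sc <- cv$samples[[paste0("fraction.", positive_class)]]
  }
  if (any(!is.finite(sc))) stop("scores must be finite", call. = FALSE)
  r <- pROC::roc(response = truth, predictor = sc, levels = c(FALSE, TRUE),
                 direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  structure(list(thresholds = r$thresholds[ord],
                 tpr = r$sensitivities[ord],
                 fpr = 1 - r$specificities[ord],
                 auc = as.numeric(r$auc),
                 positive_class = positive_class, level = level),
            class = "spath_roc")
}

#' @export
print.spath_roc <- function(x, ...) {
  cat(sprintf("<spath_roc> positive = %s (%s level): AUC = %.3f\n",
              x$positive_class, x$level, x$auc))
  invisible(x)
}

#' @export
plot.spath_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false-positive rate", ylab = "true-positive rate",
                 main = sprintf("ROC (%s, %s level): AUC = %.2f",
                                x$positive_class, x$level, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' LD scatter / histogram plot data
#'
#' `ld_scatter()` returns the first (up to) 3 linear-discriminant scores of
#' every held-out spectrum with its true group; `ld_histograms()` returns
#' the single LD score per group for a 2-group model.
#'
#' @param cv A [losocv()] result carrying LD scores.
#' @return data.frame of plot data (one row per spectrum).
#' @export
ld_scatter <- function(cv) {
  stopifnot(inherits(cv, "spath_cv"))
  ld_cols <- grep("^ld[0-9]+$", names(cv$spectra), value = TRUE)
  ld_cols <- utils::head(ld_cols, 3)
  cv$spectra[, c("sample_id", "true", ld_cols), drop = FALSE]
}

#' @rdname ld_scatter
#' @export
ld_histograms <- function(cv) {
  stopifnot(inherits(cv, "spath_cv"))
  if (length(cv$classes) != 2) {
    stop("LD histograms are defined for 2-group models", call. = FALSE)
  }
  data.frame(group = cv$spectra$true, ld1 = cv$spectra$ld1)
}

#' Write a report bundle
#'
#' Writes metrics (JSON), confusion matrices at both levels (CSV),
#' per-spectrum and per-sample predictions (CSV), LD plot data (CSV), ROC
#' data for 2-group models (CSV), rendered figures (PNG) and the
#' configuration snapshot. The JSON and CSV artefacts are byte-reproducible
#' for a given cross-validation result.
#'
#' @param cv A [losocv()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named list of files written.
#' @export
run_report <- function(cv, dir) {
  stopifnot(inherits(cv, "spath_cv"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  w <- function(name) file.path(dir, name)

  metrics <- list(
    spectrum = unclass(classification_metrics(confusion(cv, "spectrum"))),
    sample = unclass(classification_metrics(confusion(cv, "sample"))),
    config = cv$config
  )
  two_group <- length(cv$classes) == 2
  if (two_group) {
    pos <- cv$classes[2]
    roc_sp <- roc_curve(cv, pos, "spectrum")
    roc_sa <- roc_curve(cv, pos, "sample")
    metrics$roc <- list(positive_class = pos,
                        auc_spectrum = roc_sp$auc, auc_sample = roc_sa$auc)
  }
  paths$metrics <- w("metrics.json")
  jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  for (lev in c("spectrum", "sample")) {
    cm <- confusion(cv, lev)
    p <- w(sprintf("confusion_%s.csv", lev))
    utils::write.csv(cm$counts, p)
    paths[[paste0("confusion_", lev)]] <- p
  }
  paths$predictions_spectrum <- w("predictions_spectrum.csv")
  utils::write.csv(cv$spectra, paths$predictions_spectrum, row.names = FALSE)
  paths$predictions_sample <- w("predictions_sample.csv")
  utils::write.csv(cv$samples, paths$predictions_sample, row.names = FALSE)
  paths$ld_scatter <- w("ld_scatter.csv")
  utils::write.csv(ld_scatter(cv), paths$ld_scatter, row.names = FALSE)

  if (two_group) {
    df <- data.frame(threshold = roc_sp$thresholds, tpr = roc_sp$tpr,
                     fpr = roc_sp$fpr)
    paths$roc_spectrum <- w("roc_spectrum.csv")
    utils::write.csv(df, paths$roc_spectrum, row.names = FALSE)
    paths$ld_histogram <- w("ld_histogram.csv")
    utils::write.csv(ld_histograms(cv), paths$ld_histogram, row.names = FALSE)
    paths$roc_png <- w("roc.png")
    grDevices::png(paths$roc_png, width = 600, height = 600)
    plot(roc_sp)
    grDevices::dev.off()
  }
  paths$ld_png <- w("ld_scatter.png")
  grDevices::png(paths$ld_png, width = 600, height = 600)
  plot(cv)
  grDevices::dev.off()
  invisible(paths)
}
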