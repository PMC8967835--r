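#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney two-sample statistic (ties count one half);
#' the 95\% confidence interval uses the DeLong variance estimator.
#'
#' @param scores continuous scores, higher = more positive-like.
#' @param labels 0/1 (or logical) class labels.
#' @return An object of class \code{"eval_result"}: list with
#'   \code{auc}, \code{auc_ci_95} (lo, hi), \code{roc_points} (data
#'   frame \code{threshold}, \code{fpr}, \code{tpr}), \code{n_pos},
#'   \code{n_neg}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2) stop("need both classes", call. = FALSE)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  # a degenerate CI at AUC exactly 1 is expected on separable toy data
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  pts <- data.frame(threshold = r$thresholds,
                    fpr = 1 - r$specificities,
                    tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  structure(list(auc = as.numeric(pROC::auc(r)),
                 auc_ci_95 = c(ci[1], ci[3]),
                 roc_points = pts,
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0),
                 roc = r),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result AUC %.4f (95%% CI %.4f-%.4f), %d pos / %d neg>\n",
              x$auc, x$auc_ci_95[1], x$auc_ci_95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired AUC comparison (DeLong)
#'
#' Compares the AUCs of two score vectors over the same segments with
#' the paired DeLong test; antisymmetric in (a, b).
#'
#' @param scores_a,scores_b two score vectors over identical rows.
#' @param labels shared 0/1 labels.
#' @return list with \code{delta_auc} (AUC_a - AUC_b), \code{p_value}.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("length mismatch", call. = FALSE)
  labels <- as.integer(labels)
  ra <- pROC::roc(labels, scores_a, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(labels, scores_b, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  if (isTRUE(all.equal(scores_a, scores_b)))
    return(list(delta_auc = 0, p_value = 1))
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(delta_auc = as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)),
       p_value = tst$p.value)
}

#' Operating-point metrics at a ROC threshold
#'
#' Threshold chosen by maximal Youden's J (sensitivity + specificity -
#' 1) on the empirical ROC; ties resolve to the lower threshold (higher
#' sensitivity). Metrics are reported in percent.
#'
#' @param scores continuous scores, higher = more positive-like.
#' @param labels 0/1 labels.
#' @param threshold optional fixed threshold (classify positive when
#'   score >= threshold); overrides the Youden rule.
#' @return list with \code{threshold}, \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv}, \code{accuracy} (all
#'   percent), and the confusion counts \code{tp}, \code{fp}, \code{tn},
#'   \code{fn}.
#' @export
operating_metrics <- function(scores, labels, threshold = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("need both classes", call. = FALSE)
  if (is.null(threshold)) {
    cand <- sort(unique(scores))
    # candidate thresholds: each observed score (predict positive if >=)
    best_j <- -Inf
    threshold <- cand[1]
    for (th in cand) {
      sens <- mean(scores[labels == 1] >= th)
      spec <- mean(scores[labels == 0] < th)
      j <- sens + spec - 1
      if (j > best_j + 1e-12) { best_j <- j; threshold <- th }
    }
  }
  tp <- sum(scores >= threshold & labels == 1)
  fp <- sum(scores >= threshold & labels == 0)
  tn <- sum(scores < threshold & labels == 0)
  fn <- sum(scores < threshold & labels == 1)
  pct <- function(a, b) if (a + b == 0) NA_real_ else 100 * a / (a + b)
  list(threshold = threshold,
       sensitivity = pct(tp, fn), specificity = pct(tn, fp),
       ppv = pct(tp, fp), npv = pct(tn, fn),
       accuracy = 100 * (tp + tn) / length(labels),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Univariate feature comparison between two classes
#'
#' Mean and SD per class with a Welch two-sample t-test per feature
#' column — the standard per-feature screening table of an AF-vs-SR
#' feature panel.
#'
#' @param table feature table with a \code{label} column.
#' @param class_a,class_b the two label values to compare (default AF vs
#'   SR).
#' @param features feature columns (default: every numeric column except
#'   bookkeeping).
#' @return data frame: \code{feature}, \code{mean_a}, \code{sd_a},
#'   \code{mean_b}, \code{sd_b}, \code{p_value}.
#' @export
univariate_report <- function(table, class_a = "AF", class_b = "SR",
                              features = NULL) {
  if (is.null(features)) {
    skip <- c("patient_id", "start_time", "label", "block")
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        skip)
  }
  a <- table[table$label == class_a, , drop = FALSE]
  b <- table[table$label == class_b, , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need >= 2 rows per class", call. = FALSE)
  rows <- lapply(features, function(f) {
    xa <- a[[f]]; xb <- b[[f]]
    p <- if (sd(xa) == 0 && sd(xb) == 0) {
      if (mean(xa) == mean(xb)) 1 else 0
    } else t.test(xa, xb)$p.value
    data.frame(feature = f, mean_a = mean(xa), sd_a = sd(xa),
               mean_b = mean(xb), sd_b = sd(xb), p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
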