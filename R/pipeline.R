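#' Extract quality-gated N-beat segments from one recording
#'
#' Runs conditioning, motion gating, peak detection and segmentation on
#' a single \code{"recording"}.
#'
#' @param rec a \code{"recording"} (see \code{\link{make_dataset}}).
#' @param n_beats intervals per segment.
#' @param params a \code{\link{spline_params}}.
#' @param thresholds a \code{\link{quality_thresholds}}.
#' @return list with \code{segments} (a \code{"ppi_segments"}),
#'   \code{processed} (a \code{"processed_ppg"}), \code{motion}.
#' @export
process_recording <- function(rec, n_beats = 25, params = spline_params(),
                              thresholds = quality_thresholds()) {
  stopifnot(inherits(rec, "recording"))
  processed <- preprocess_ppg(rec$ppg, params, thresholds)
  motion <- motion_flags(rec$acc, thresholds)
  beats <- detect_peaks(processed)
  segs <- segment_ppis(beats, rec$annotations, n_beats = n_beats,
                       patient_id = rec$patient_id, quality = processed$windows,
                       motion = motion, thresholds = thresholds)
  list(segments = segs, processed = processed, motion = motion,
       beats = beats)
}

#' Feature table for a whole dataset
#'
#' @param dataset a \code{"ppg_dataset"} (list of recordings).
#' @param n_beats intervals per segment.
#' @param feature_set see \code{\link{feature_columns}}.
#' @param params,thresholds conditioning and gating parameters.
#' @return feature data frame over all patients, plus attributes
#'   \code{"segment_log"} (per-candidate bookkeeping) and
#'   \code{"counts"} (kept segments per label).
#' @export
dataset_features <- function(dataset, n_beats = 25,
                             feature_set = "base8+extended",
                             params = spline_params(),
                             thresholds = quality_thresholds()) {
  tables <- list(); logs <- list()
  for (rec in dataset) {
    pr <- process_recording(rec, n_beats, params, thresholds)
    logs[[length(logs) + 1L]] <- cbind(patient_id = rec$patient_id,
                                       pr$segments$log)
    if (length(pr$segments$segments) == 0) next
    tables[[length(tables) + 1L]] <-
      build_feature_table(pr$segments, pr$processed, feature_set)
  }
  if (length(tables) == 0) stop("no usable segments in dataset",
                                call. = FALSE)
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  attr(out, "segment_log") <- do.call(rbind, logs)
  attr(out, "counts") <- table(out$label)
  out
}

#' Run the full detection pipeline on a synthetic cohort
#'
#' Generates (or accepts) a dataset, extracts quality-gated segments and
#' features, trains the configured classifier under the split plan, and
#' evaluates pooled out-of-fold scores. The labels are collapsed to AF
#' vs non-AF for classification.
#'
#' @param config a \code{\link{dataset_config}} (or a prebuilt
#'   \code{"ppg_dataset"} via \code{dataset}).
#' @param dataset optional prebuilt dataset (overrides \code{config}).
#' @param n_beats intervals per segment.
#' @param model a \code{\link{model_config}}.
#' @param plan a \code{\link{split_plan}}.
#' @param params,thresholds conditioning and gating parameters.
#' @param seed master seed (dataset generation and fold assignment).
#' @param out_dir optional directory: writes feature table, segment log,
#'   ROC points CSV and a provenance JSON.
#' @return list with \code{features}, \code{cv}, \code{eval}
#'   (\code{\link{roc_auc}} result), \code{metrics}
#'   (\code{\link{operating_metrics}}), \code{counts}.
#' @export
run_pipeline <- function(config = dataset_config(), dataset = NULL,
                         n_beats = 25,
                         model = model_config("LINEAR_SVM"),
                         plan = split_plan(seed = 1L),
                         params = spline_params(),
                         thresholds = quality_thresholds(),
                         seed = 1L, out_dir = NULL) {
  if (is.null(dataset)) dataset <- make_dataset(config, seed = seed)
  feature_set <- model$feature_set
  feats <- dataset_features(dataset, n_beats = n_beats,
                            feature_set = feature_set,
                            params = params, thresholds = thresholds)
  plan$seed <- as.integer(seed)
  cv <- crossvalidate(feats, plan, model)
  ev <- roc_auc(cv$scores, af_binary(cv$labels))
  om <- operating_metrics(cv$scores, af_binary(cv$labels))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
    write.csv(attr(feats, "segment_log"),
              file.path(out_dir, "segment_log.csv"), row.names = FALSE)
    write.csv(ev$roc_points, file.path(out_dir, "roc_points.csv"),
              row.names = FALSE)
    write_provenance(list(n_beats = n_beats, model = unclass(model),
                          plan = unclass(plan)), seed,
                     file.path(out_dir, "provenance.json"))
  }
  list(features = feats, cv = cv, eval = ev, metrics = om,
       counts = attr(feats, "counts"))
}
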