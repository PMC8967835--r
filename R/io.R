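# CSV / YAML interfaces. Signal CSVs carry a mandatory header:
#   PPG: t_s,value      (missing sample = empty value field)
#   ACC: t_s,ax,ay,az
# Annotations: start_s,end_s,label   with label in {AF, SR, PVC, PAC}.

#' Write a PPG or ACC record to CSV
#'
#' @param record a \code{"ppg_record"} or \code{"acc_record"}.
#' @param path output file.
#' @export
write_signal_csv <- function(record, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  if (inherits(record, "ppg_record")) {
    t_s <- (seq_along(record$samples) - 1L) / record$fs
    df <- data.frame(t_s = fmt(t_s), value = fmt(record$samples))
  } else if (inherits(record, "acc_record")) {
    t_s <- (seq_along(record$ax) - 1L) / record$fs
    df <- data.frame(t_s = fmt(t_s), ax = fmt(record$ax),
                     ay = fmt(record$ay), az = fmt(record$az))
  } else stop("unsupported record type", call. = FALSE)
  # %.17g preserves doubles exactly across the round trip
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a PPG or ACC record from CSV
#'
#' Validates the header and monotone timestamps, infers the sampling
#' rate from the median timestamp step (cross-checked against
#' \code{fs_expected} when given, 1\% tolerance), and materializes
#' timestamp gaps as runs of missing samples so the in-memory grid is
#' uniform.
#'
#' @param path CSV file.
#' @param kind \code{"ppg"} or \code{"acc"}.
#' @param fs_expected optional expected sampling rate, Hz.
#' @param saturation_value saturation ceiling recorded with a PPG signal
#'   (not stored in the CSV).
#' @return a \code{"ppg_record"} or \code{"acc_record"}.
#' @export
read_signal_csv <- function(path, kind = c("ppg", "acc"),
                            fs_expected = NULL, saturation_value = Inf) {
  kind <- match.arg(kind)
  df <- read.csv(path)
  need <- if (kind == "ppg") c("t_s", "value") else c("t_s", "ax", "ay", "az")
  if (!identical(names(df)[seq_along(need)], need))
    stop("bad header: expected ", paste(need, collapse = ","), call. = FALSE)
  t <- df$t_s
  if (any(diff(t) <= 0)) stop("timestamps not strictly increasing",
                              call. = FALSE)
  dt <- median(diff(t))
  fs <- 1 / dt
  if (!is.null(fs_expected)) {
    if (abs(fs - fs_expected) / fs_expected > 0.01)
      stop(sprintf("sampling rate mismatch: inferred %.2f Hz, expected %g Hz",
                   fs, fs_expected), call. = FALSE)
    fs <- fs_expected
  }
  # place samples on a uniform grid; gaps become missing runs
  idx <- round((t - t[1]) * fs) + 1L
  jitter <- max(abs((t - t[1]) * fs - (idx - 1L)))
  if (jitter > 0.5) stop("timestamp jitter exceeds half a sample period",
                         call. = FALSE)
  n <- idx[length(idx)]
  grid <- function(v) { out <- rep(NA_real_, n); out[idx] <- v; out }
  if (kind == "ppg") {
    structure(list(samples = grid(df$value), fs = fs,
                   saturation_value = saturation_value,
                   start_time = t[1], truth_beats = NULL),
              class = "ppg_record")
  } else {
    structure(list(ax = grid(df$ax), ay = grid(df$ay), az = grid(df$az),
                   fs = fs),
              class = "acc_record")
  }
}

#' Write rhythm annotations to CSV
#'
#' @param annotations data frame \code{start_s}, \code{end_s},
#'   \code{label}.
#' @param path output file.
#' @export
write_annotation_csv <- function(annotations, path) {
  stopifnot(all(c("start_s", "end_s", "label") %in% names(annotations)))
  write.csv(annotations[, c("start_s", "end_s", "label")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read rhythm annotations from CSV
#'
#' @param path CSV with header \code{start_s,end_s,label}; labels must be
#'   AF, SR, PVC or PAC; intervals are half-open \code{[start_s, end_s)}
#'   and must not overlap.
#' @return data frame.
#' @export
read_annotation_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:3], c("start_s", "end_s", "label")))
    stop("bad header: expected start_s,end_s,label", call. = FALSE)
  if (!all(df$label %in% c("AF", "SR", "PVC", "PAC")))
    stop("labels must be AF, SR, PVC or PAC", call. = FALSE)
  df <- df[order(df$start_s), , drop = FALSE]
  if (any(df$end_s <= df$start_s)) stop("empty or inverted interval",
                                        call. = FALSE)
  if (nrow(df) > 1 && any(df$start_s[-1] < df$end_s[-nrow(df)]))
    stop("overlapping annotation intervals", call. = FALSE)
  df
}

#' Write a segment log table to CSV
#'
#' One row per candidate segment with its keep/drop decision and reason
#' codes; kept segments additionally carry their interval and
#' peak-height values as \code{ppi_1..ppi_N} and \code{h_1..h_{N+1}}
#' columns.
#'
#' @param segs a \code{"ppi_segments"} object.
#' @param path output file.
#' @export
write_segment_csv <- function(segs, path) {
  stopifnot(inherits(segs, "ppi_segments"))
  log <- segs$log
  if (length(segs$segments) > 0) {
    n <- segs$segments[[1]]$n_beats
    wide <- matrix(NA_real_, nrow(log), 2 * n + 1,
                   dimnames = list(NULL, c(paste0("ppi_", 1:n),
                                           paste0("h_", 1:(n + 1)))))
    kept_rows <- which(log$kept)
    for (i in seq_along(segs$segments)) {
      s <- segs$segments[[i]]
      wide[kept_rows[i], ] <- c(s$ppis, s$heights)
    }
    log <- cbind(log, as.data.frame(wide))
  }
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' Write the per-window quality report to CSV
#'
#' @param processed a \code{"processed_ppg"} (see
#'   \code{\link{preprocess_ppg}}).
#' @param path output file.
#' @export
write_quality_csv <- function(processed, path) {
  stopifnot(inherits(processed, "processed_ppg"))
  w <- processed$windows
  reasons <- apply(w[, c("saturated", "missing_exceeded", "hf_noise",
                         "too_short")], 1,
                   function(r) paste(names(r)[as.logical(r)], collapse = ";"))
  w$reason <- reasons
  write.csv(w, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the constructor arguments of
#' \code{\link{quality_thresholds}} (\code{thresholds}),
#' \code{\link{spline_params}} (\code{spline}),
#' \code{\link{model_config}} (\code{model}),
#' \code{\link{split_plan}} (\code{split}) and
#' \code{\link{dataset_config}} (\code{dataset}, with rhythm blocks as
#' a list of \code{kind}/\code{duration_s} pairs under \code{blocks}
#' and \code{\link{noise_spec}} fields under \code{noise}), plus
#' \code{n_beats}, \code{fs_ppg}, \code{seed} and the input/output
#' \code{paths}.
#'
#' @param path YAML file.
#' @return list of parsed configuration objects (class
#'   \code{"pipeline_config"}).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- list(
    n_beats = y$n_beats %||% 25,
    fs_ppg = y$fs_ppg %||% 512,
    seed = y$seed %||% 1L,
    paths = y$paths %||% list(),
    thresholds = do.call(quality_thresholds, y$thresholds %||% list()),
    spline = do.call(spline_params, y$spline %||% list()),
    model = do.call(model_config, y$model %||% list()),
    split = do.call(split_plan, y$split %||% list()))
  if (!is.null(y$dataset)) {
    dargs <- y$dataset
    if (!is.null(dargs$blocks)) {
      dargs$block_plan <- do.call(rbind, lapply(dargs$blocks, function(b)
        data.frame(kind = b$kind, duration_s = b$duration_s)))
      dargs$blocks <- NULL
    }
    if (!is.null(dargs$noise)) dargs$noise <- do.call(noise_spec, dargs$noise)
    dargs$fs_ppg <- dargs$fs_ppg %||% cfg$fs_ppg
    cfg$dataset <- do.call(dataset_config, dargs)
  }
  structure(cfg, class = "pipeline_config")
}

#' Write a provenance record for a pipeline run
#'
#' @param config the configuration used (serializable list).
#' @param seed master seed.
#' @param path output JSON file.
#' @export
write_provenance <- function(config, seed, path) {
  rec <- list(
    package = "ppgaf",
    version = as.character(utils::packageVersion("ppgaf")),
    r_version = R.version.string,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
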