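#' Canonical feature names
#'
#' The 31 subject-level parameters in their fixed column order: 6 P-wave
#' morphology parameters followed by 11 time-domain, 7 frequency-domain
#' and 7 nonlinear HRV parameters.
#'
#' @return Character vector of length 31.
#' @export
paf_feature_names <- function() {
  c("PW", "PA", "PD", "A", "C", "W",
    "RRmean", "SDNN", "HRmean", "SDHR", "MinHR", "MaxHR", "RMSSD",
    "NN50", "pNN50", "HRVTriangularIndex", "TINN",
    "VLFpower", "LFpower", "HFpower", "LF_HF", "TP", "nLF", "nHF",
    "SD1", "SD2", "SD2_SD1", "ApEn", "SampEn", "alpha1", "alpha2")
}

#' Extract the 31-parameter feature vector from an ECG record
#'
#' Runs the full per-subject pipeline: R-peak detection, P-wave
#' delineation, direct P-wave parameters (PW, PA, PD), Gaussian fit
#' parameters (A, C, W) by the hybrid Taguchi-genetic algorithm, then
#' time-domain, frequency-domain and nonlinear HRV parameters from the
#' RR series. When P-wave delineation fails (e.g. no visible P-wave) the
#' six P-wave slots are returned as `NA` and the HRV slots are still
#' populated; failures in R-peak detection or the RR-based stages
#' propagate as errors naming the stage.
#'
#' @param record An [ecg_record()].
#' @param config A [pipeline_config()].
#' @return A one-row data frame with `subject_id`, the 31 features in
#'   canonical order, and `label`.
#' @export
extract_features <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("%s stage failed for '%s': %s", name, record$subject_id,
            conditionMessage(e)))
  }
  peaks <- stage("r-peak detection",
                 detect_r_peaks(record,
                                refractory_ms = config$delineation$refractory_ms))
  rr <- stage("rr derivation", rr_from_peaks(peaks, record$fs))

  p_feats <- tryCatch({
    fid <- delineate_p_wave(record, peaks,
                            search_window = config$delineation$search_window,
                            min_p_amp = config$delineation$min_p_amp)
    basic <- pwave_basic_features(record, fid)
    g <- config$gaussfit
    gf <- gaussfit_features(record, fid,
                            config = htga_config(
                              population_size = g$population_size,
                              generations = g$generations,
                              crossover_rate = g$crossover_rate,
                              mutation_rate = g$mutation_rate,
                              seed = derive_seed(config$seed, 11L)),
                            max_beats = g$max_beats)
    list(PW = basic$PW, PA = basic$PA, PD = basic$PD,
         A = gf$A, C = gf$C, W = gf$W)
  }, error = function(e) {
    list(PW = NA_real_, PA = NA_real_, PD = NA_real_,
         A = NA_real_, C = NA_real_, W = NA_real_)
  })

  h <- config$hrv
  td <- stage("time-domain HRV",
              time_domain_features(rr, binwidth_ms = h$binwidth_ms,
                                   pnn50_denominator = h$pnn50_denominator))
  fd <- stage("frequency-domain HRV",
              freq_domain_features(rr, estimator = h$estimator,
                                   target_fs = h$target_fs,
                                   segment_length = h$segment_length,
                                   overlap = h$overlap,
                                   ar_order = h$ar_order))
  nl <- stage("nonlinear HRV",
              nonlinear_features(rr, m = h$entropy_m,
                                 r_factor = h$entropy_r_factor,
                                 short_range = h$dfa_short,
                                 long_range = h$dfa_long))

  vals <- c(p_feats,
            unclass(td)[c("RRmean", "SDNN", "HRmean", "SDHR", "MinHR",
                          "MaxHR", "RMSSD", "NN50", "pNN50",
                          "HRVTriangularIndex", "TINN")],
            unclass(fd)[c("VLFpower", "LFpower", "HFpower", "LF_HF",
                          "TP", "nLF", "nHF")],
            unclass(nl)[c("SD1", "SD2", "SD2_SD1", "ApEn", "SampEn",
                          "alpha1", "alpha2")])
  out <- as.data.frame(lapply(vals, as.numeric))[paf_feature_names()]
  cbind(data.frame(subject_id = record$subject_id), out,
        data.frame(label = record$label))
}

#' Assemble a labeled feature table for a cohort
#'
#' @param records List of [ecg_record()]s with unique subject ids.
#' @param config A [pipeline_config()].
#' @param progress Print one line per subject.
#' @return Data frame: one row per subject, columns `subject_id`, the 31
#'   features in canonical order, `label`.
#' @export
feature_table <- function(records, config = pipeline_config(),
                          progress = FALSE) {
  if (length(records) == 0L)
    stopf("need at least one record")
  ids <- vapply(records, function(r) r$subject_id, character(1))
  if (anyDuplicated(ids))
    stopf("duplicate subject_id: %s", ids[duplicated(ids)][1L])
  rows <- lapply(records, function(r) {
    if (progress) message("extracting ", r$subject_id)
    extract_features(r, config)
  })
  do.call(rbind, rows)
}

#' Read and write feature CSV files
#'
#' Header row with the canonical feature names, one subject per row,
#' `label` column with values `PAF`/`normal`. Values round-trip to full
#' double precision.
#'
#' @param features A feature data frame from [feature_table()].
#' @param path File path.
#' @return `read_feature_table()` returns the data frame; the writer
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(features, path) {
  df <- features
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_exact)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", paf_feature_names(), "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("feature table missing column(s): %s", paste(miss, collapse = ", "))
  df[need]
}
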