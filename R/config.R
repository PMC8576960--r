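#' Pipeline configuration
#'
#' One document holding every tunable of the extraction and modelling
#' pipeline, with documented defaults. Override any subset by passing
#' nested named lists; unknown keys are rejected.
#'
#' Groups and defaults:
#' \describe{
#'   \item{delineation}{`search_window = c(250, 60)` ms pre-R,
#'     `min_p_amp = 0.05` mV, `refractory_ms = 200`.}
#'   \item{gaussfit}{HTGA settings (see [htga_config()]) plus
#'     `max_beats = 20` beats fitted per subject.}
#'   \item{hrv}{`pnn50_denominator = "diffs"`, `binwidth_ms = 7.8125`,
#'     `target_fs = 4` Hz, `estimator = "welch"`,
#'     `segment_length = 256`, `overlap = 0.5`, `ar_order = 16`,
#'     `entropy_m = 2`, `entropy_r_factor = 0.2`,
#'     `dfa_short = 4:16`, `dfa_long = 16:64`.}
#'   \item{ensemble}{`n_members = 100`, `cp = 0.1`,
#'     `layer1 = c("bagging", "adaboost")`, `oof_meta = TRUE`,
#'     `oof_folds = 5`, `max_retries = 50`.}
#'   \item{cv}{`folds = 10`.}
#'   \item{seed}{Root seed for all stage seeds.}
#' }
#'
#' @param ... Nested overrides, e.g.
#'   `pipeline_config(hrv = list(estimator = "ar"), seed = 7)`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    delineation = list(search_window = c(250, 60), min_p_amp = 0.05,
                       refractory_ms = 200),
    gaussfit = list(population_size = 50, generations = 100,
                    crossover_rate = 0.8, mutation_rate = 0.1,
                    max_beats = 20),
    hrv = list(pnn50_denominator = "diffs", binwidth_ms = 7.8125,
               target_fs = 4, estimator = "welch", segment_length = 256,
               overlap = 0.5, ar_order = 16, entropy_m = 2,
               entropy_r_factor = 0.2, dfa_short = 4:16,
               dfa_long = 16:64),
    ensemble = list(n_members = 100, cp = 0.1,
                    layer1 = c("bagging", "adaboost"), oof_meta = TRUE,
                    oof_folds = 5, max_retries = 50),
    cv = list(folds = 10),
    seed = 1
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg))
      stopf("unknown configuration group '%s'", nm)
    if (is.list(dots[[nm]])) {
      bad <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stopf("unknown configuration key '%s$%s'", nm, bad[1L])
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}
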