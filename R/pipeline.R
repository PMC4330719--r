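#' Pipeline configuration
#'
#' Bundles the knobs of the full per-session analysis: the chronological
#' train fraction, which preprocessing variants to evaluate, repetition and
#' permutation counts, and the master seed from which all named random
#' substreams are derived.
#'
#' @param train_fraction fraction of each label's earliest trials used for
#'   training (0.75 gives 150/150 train and 50/50 test from a 200 + 200
#'   session).
#' @param variants subset of `"pre_ica"` (channel features, the no-processing
#'   baseline), `"ica"`, `"pre_ica_kalman"`, `"ica_kalman"`.
#' @param n_repeats repetitions of the inner-CV selection + test evaluation.
#' @param n_perm permutation-test shuffles (0 skips the test).
#' @param n_nested re-runs for [nested_comparison()].
#' @param alpha nominal significance level echoed into reports.
#' @param seed master seed.
#' @param asr_cutoff ASR rejection threshold (calibration SDs).
#' @param n_components ICA components selected for classification.
#' @param ica_max_iter iteration cap for the ICA weight fit.
#' @param n_folds inner-CV folds.
#' @param filter_low_hz,filter_high_hz,filter_order front-end band-pass.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(train_fraction = 0.75,
                            variants = c("pre_ica", "ica", "pre_ica_kalman",
                                         "ica_kalman"),
                            n_repeats = 100, n_perm = 100, n_nested = 10,
                            alpha = 0.05, seed = 1, asr_cutoff = 5,
                            n_components = 2, ica_max_iter = 512,
                            n_folds = 10,
                            filter_low_hz = 2, filter_high_hz = 30,
                            filter_order = 496) {
  variants <- match.arg(variants, several.ok = TRUE)
  stopifnot(train_fraction > 0, train_fraction < 1, length(variants) >= 1,
            n_repeats >= 1, n_perm >= 0, n_nested >= 0)
  structure(list(train_fraction = train_fraction, variants = variants,
                 n_repeats = n_repeats, n_perm = n_perm, n_nested = n_nested,
                 alpha = alpha, seed = seed, asr_cutoff = asr_cutoff,
                 n_components = n_components, ica_max_iter = ica_max_iter,
                 n_folds = n_folds,
                 filter_low_hz = filter_low_hz,
                 filter_high_hz = filter_high_hz,
                 filter_order = filter_order),
            class = "pipeline_config")
}

#' Chronological train/test split of events
#'
#' Within each label, the earliest `ceiling(fraction * n)` events go to the
#' training set and the remainder to the test set, preserving order - the
#' training data always precede the test data in time.
#'
#' @param events an [event_list()].
#' @param train_fraction fraction per label assigned to training.
#' @return List with `train` and `test` event lists.
#' @export
chronological_split <- function(events, train_fraction = 0.75) {
  stopifnot(inherits(events, "event_list"), nrow(events) > 0)
  fs <- attr(events, "fs")
  tr_idx <- logical(nrow(events))
  for (lb in levels(events$label)) {
    idx <- which(events$label == lb)
    if (length(idx) < 2)
      stop("label ", lb, " has fewer than 2 events; cannot split")
    n_tr <- ceiling(train_fraction * length(idx))
    n_tr <- min(n_tr, length(idx) - 1L)
    tr_idx[idx[seq_len(n_tr)]] <- TRUE      # events are onset-sorted
  }
  list(train = event_list(events$onset_sample[tr_idx], events$label[tr_idx], fs),
       test = event_list(events$onset_sample[!tr_idx], events$label[!tr_idx], fs))
}

# Epoch a set of traces (signals x samples) at events and concatenate the
# per-trace epochs into one trials x (n_traces * epoch samples) matrix.
build_trial_features <- function(traces, events, window_s = 0.5, fs) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  blocks <- lapply(seq_len(nrow(traces)), function(i)
    epoch_signal(traces[i, ], events, window_s, fs))
  list(x = do.call(cbind, blocks), y = events$label)
}

#' Run the full analysis on one recording
#'
#' Executes the complete protocol: band-pass filter; chronological split;
#' bad-channel detection on the training span only (flagged channels are
#' dropped from both spans); ASR calibrated on clean training segments and
#' applied with fixed parameters to the whole recording; then, per variant,
#' ICA weight fitting on the training span with component selection, and/or
#' Kalman filtering driven by all trial onsets; 0-500 ms feature epochs;
#' repeated inner-CV model selection and test evaluation; permutation
#' testing. A variant that fails is reported with its stage error while the
#' remaining variants still run.
#'
#' @param recording an [eeg_recording()] with balanced chirp/silent events.
#' @param config a [pipeline_config()].
#' @return A `condition_report`: per-variant `metrics_distribution` and
#'   permutation p-values, removed channels, selected components, config
#'   echo and package version.
#' @export
run_condition <- function(recording, config = pipeline_config()) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(config, "pipeline_config"))
  fs <- recording$fs
  events <- recording$events
  if (is.null(events)) stop("recording carries no events")

  spec <- design_fir_bandpass(config$filter_low_hz, config$filter_high_hz,
                              config$filter_order, fs)
  rec <- apply_filter(spec, recording)

  split <- chronological_split(events, config$train_fraction)
  boundary <- min(split$test$onset_sample) # first test onset, 0-based
  train_span <- crop_recording(rec, 1L, boundary)

  bad <- detect_bad_channels(train_span)
  keep <- !(rec$channel_labels %in% bad)
  if (sum(keep) < 2) stop("bad-channel rejection removed nearly all channels")
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$channel_labels <- rec$channel_labels[keep]
  train_span <- crop_recording(rec, 1L, boundary)

  mask <- select_calibration_mask(train_span)
  asr <- asr_fit(train_span$data[, mask, drop = FALSE], fs = fs,
                 cutoff = config$asr_cutoff)
  rec$data <- asr_process(asr, rec$data)

  all_onsets <- events$onset_sample
  variant_out <- list()
  selected_components <- list()
  ica_cache <- NULL

  get_ica <- function() {
    if (is.null(ica_cache)) {
      dec <- suppressWarnings(
        fit_extended_infomax(rec$data[, 1:boundary, drop = FALSE],
                             seed = derive_seed(config$seed, "ica"),
                             max_iter = config$ica_max_iter))
      act <- project_components(dec, rec$data)
      sel <- select_erp_components(dec, act[, 1:boundary, drop = FALSE],
                                   split$train, fs, k = config$n_components)
      if (!length(sel)) sel <- seq_len(nrow(act))
      ica_cache <<- list(dec = dec, act = act, sel = sel)
    }
    ica_cache
  }

  for (v in config$variants) {
    variant_out[[v]] <- tryCatch({
      traces <- if (v %in% c("ica", "ica_kalman")) {
        ic <- get_ica()
        selected_components[[v]] <- as.integer(ic$sel)
        ic$act[ic$sel, , drop = FALSE]
      } else rec$data
      if (v %in% c("pre_ica_kalman", "ica_kalman")) {
        model <- build_erp_model(fs)
        traces <- t(vapply(seq_len(nrow(traces)), function(i)
          kalman_filter_erp(model, traces[i, ], all_onsets)$estimate,
          numeric(ncol(traces))))
      }
      ftr <- build_trial_features(traces, split$train, fs = fs)
      fte <- build_trial_features(traces, split$test, fs = fs)
      dist <- evaluate_repeated(ftr$x, ftr$y, fte$x, fte$y,
                                n_repeats = config$n_repeats,
                                seed = derive_seed(config$seed, paste0("eval-", v)),
                                n_folds = config$n_folds)
      perm <- NULL
      if (config$n_perm > 0) {
        perm <- permutation_test(ftr$x, ftr$y, fte$x, fte$y,
                                 observed = dist$mean$accuracy,
                                 n_perm = config$n_perm,
                                 seed = derive_seed(config$seed,
                                                    paste0("perm-", v)),
                                 n_folds = config$n_folds)
      }
      list(metrics = dist, permutation = perm, error = NULL)
    }, error = function(e)
      list(metrics = NULL, permutation = NULL,
           error = paste0("variant ", v, ": ", conditionMessage(e))))
  }

  structure(list(variants = variant_out,
                 removed_channels = as.character(bad),
                 removed_reasons = attr(bad, "reasons"),
                 selected_components = selected_components,
                 n_train = nrow(split$train), n_test = nrow(split$test),
                 config = config,
                 version = as.character(utils::packageVersion("aepdecode"))),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report> %d train / %d test trials, %d channels removed\n",
              x$n_train, x$n_test, length(x$removed_channels)))
  for (v in names(x$variants)) {
    vo <- x$variants[[v]]
    if (!is.null(vo$error)) {
      cat(sprintf("  %-16s FAILED: %s\n", v, vo$error))
    } else {
      p <- if (!is.null(vo$permutation))
        sprintf(", perm p = %.4f", vo$permutation$p_value) else ""
      cat(sprintf("  %-16s accuracy %.1f%% (SE %.2f)%s\n", v,
                  100 * vo$metrics$mean$accuracy,
                  100 * vo$metrics$se$accuracy, p))
    }
  }
  invisible(x)
}

#' Nested cross-validation comparison between variants
#'
#' Re-runs the full per-variant analysis `n_nested` times with fresh seeds
#' (model stability), then compares each pair of variants with the paired
#' Wilcoxon signed-rank test on accuracy, FPR and FNR.
#'
#' @param recording an [eeg_recording()] with events.
#' @param config a [pipeline_config()] with `n_nested >= 2`; permutation
#'   testing is disabled during the re-runs.
#' @param pairs optional list of 2-element character vectors naming the
#'   variant contrasts; defaults to all pairs of `config$variants`.
#' @return List: `per_run` (data frame of per-run mean metrics) and
#'   `comparisons` (data frame variant_a, variant_b, metric, p_value).
#' @export
nested_comparison <- function(recording, config = pipeline_config(),
                              pairs = NULL) {
  stopifnot(config$n_nested >= 2)
  cf <- config
  cf$n_perm <- 0
  runs <- vector("list", config$n_nested)
  for (r in seq_len(config$n_nested)) {
    cf$seed <- derive_seed(config$seed, "nested", r)
    rep_r <- run_condition(recording, cf)
    rows <- lapply(names(rep_r$variants), function(v) {
      vo <- rep_r$variants[[v]]
      if (is.null(vo$metrics)) return(NULL)
      data.frame(run = r, variant = v,
                 accuracy = vo$metrics$mean$accuracy,
                 false_positive_rate = vo$metrics$mean$false_positive_rate,
                 false_negative_rate = vo$metrics$mean$false_negative_rate)
    })
    runs[[r]] <- do.call(rbind, rows)
  }
  per_run <- do.call(rbind, runs)
  if (is.null(pairs)) {
    vs <- config$variants
    pairs <- if (length(vs) >= 2) utils::combn(vs, 2, simplify = FALSE)
             else list()
  }
  comp <- list()
  for (pr in pairs) {
    for (m in c("accuracy", "false_positive_rate", "false_negative_rate")) {
      a <- per_run[per_run$variant == pr[1], m]
      b <- per_run[per_run$variant == pr[2], m]
      p <- if (identical(pr[1], pr[2])) 1 else compare_conditions(a, b)$p_value
      comp[[length(comp) + 1]] <- data.frame(variant_a = pr[1],
                                             variant_b = pr[2],
                                             metric = m, p_value = p)
    }
  }
  list(per_run = per_run, comparisons = do.call(rbind, comp))
}

#' Serialise a condition report to JSON
#'
#' Versioned schema with per-variant mean/SE metrics, per-repeat tables,
#' permutation p-values, removed channels and selected components.
#'
#' @param report a `condition_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(schema = "aepdecode-report-1",
              version = report$version,
              n_train = report$n_train, n_test = report$n_test,
              removed_channels = report$removed_channels,
              selected_components = report$selected_components,
              variants = lapply(report$variants, function(vo) {
                if (!is.null(vo$error)) return(list(error = vo$error))
                list(mean = vo$metrics$mean, se = vo$metrics$se,
                     per_repeat = vo$metrics$per_repeat,
                     permutation_p = if (!is.null(vo$permutation))
                       vo$permutation$p_value else NULL)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
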