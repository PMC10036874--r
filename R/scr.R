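#' Score one trial's skin-conductance response
#'
#' Baseline-to-peak scoring: the baseline is the mean conductance in the
#' first second after CS onset (`[onset, onset+1)`), the peak is the maximum
#' in the 1-6 s window (`[onset+1, onset+6]`). The response amplitude is the
#' peak minus the baseline when that difference exceeds 0.02 microsiemens,
#' and zero otherwise; it is never negative.
#'
#' @param trace an `scr_trace` (see [simulate_scr_trace()]) or any list with
#'   `values` (uS) and `sampling_rate` (Hz).
#' @param onset CS onset in seconds from trace start.
#' @return List with `raw_amplitude` (uS), `transformed` (sqrt uS), `valid`
#'   (`TRUE` when the amplitude cleared the 0.02 uS floor).
#' @export
score_trial <- function(trace, onset) {
  rate <- trace$sampling_rate
  n <- length(trace$values)
  tgrid <- (seq_len(n) - 1) / rate
  if (onset < 0 || onset + 6 > tgrid[n] + 1 / rate)
    stop("scoring window [onset, onset+6 s] extends beyond the trace",
         call. = FALSE)
  base_idx <- tgrid >= onset & tgrid < onset + 1
  peak_idx <- tgrid >= onset + 1 & tgrid <= onset + 6
  baseline <- mean(trace$values[base_idx])
  peak <- max(trace$values[peak_idx])
  raw <- peak - baseline
  if (!(raw > 0.02)) raw <- 0
  list(raw_amplitude = raw, transformed = sqrt(raw), valid = raw > 0)
}

#' Square-root transform of SCR amplitudes
#'
#' @param raw non-negative amplitude(s) in microsiemens.
#' @return `sqrt(raw)`.
#' @export
sqrt_transform <- function(raw) {
  if (any(raw < 0)) stop("SCR amplitudes must be non-negative", call. = FALSE)
  sqrt(raw)
}

#' Score every trial of a run
#'
#' @param trace an `scr_trace` covering the run.
#' @param run_events the run's trial events (data frame with `onset`).
#' @return Data frame with one row per trial: run/trial indices, condition
#'   labels, `raw_amplitude`, `transformed`, `valid`.
#' @export
score_run <- function(trace, run_events) {
  scored <- lapply(run_events$onset, function(o) score_trial(trace, o))
  data.frame(
    run_index = run_events$run_index,
    trial_index = run_events$trial_index,
    modality = run_events$modality,
    cs_type = run_events$cs_type,
    reinforced = run_events$reinforced,
    raw_amplitude = vapply(scored, `[[`, 0, "raw_amplitude"),
    transformed = vapply(scored, `[[`, 0, "transformed"),
    valid = vapply(scored, `[[`, TRUE, "valid"),
    stringsAsFactors = FALSE)
}

#' Condition means of transformed SCRs
#'
#' Averages square-root-transformed amplitudes over the analysis trials of
#' each (modality, CS type) cell of an acquisition schedule. Reinforced
#' (shock) trials and the per-run boundary CS- trials of the conditioned
#' modality are excluded via [select_analysis_trials()]; zero-scored trials
#' are retained in the means.
#'
#' @param scores per-trial score table (rows matching the schedule's runs
#'   and trial indices, as from [score_run()] over all runs).
#' @param schedule the acquisition `trial_schedule` the scores belong to.
#' @return Data frame: `phase`, `modality`, `cs_type`, `mean_scr`, `n_trials`.
#' @export
aggregate_condition_means <- function(scores, schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  phase <- attr(schedule, "phase")
  key <- function(df) paste(df$run_index, df$trial_index)
  out <- list()
  for (m in c("imagine", "view")) {
    keep <- select_analysis_trials(schedule, m)
    sel <- scores[key(scores) %in% key(keep), ]
    for (cs in c("CSplus", "CSminus")) {
      cell <- sel$transformed[sel$cs_type == cs]
      if (length(cell) == 0)
        stop(sprintf("no scored analysis trials in cell %s/%s/%s",
                     phase, m, cs), call. = FALSE)
      out[[length(out) + 1]] <- data.frame(
        phase = phase, modality = m, cs_type = cs,
        mean_scr = mean(cell), n_trials = length(cell),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Flag skin-conductance non-responders
#'
#' A participant whose scored amplitude is zero on every reinforced (shock)
#' trial shows no detectable response to the US and is flagged for
#' exclusion.
#'
#' @param scores per-trial score table including reinforced trials.
#' @return `TRUE` if the participant is a non-responder.
#' @export
is_nonresponder <- function(scores) {
  shock <- scores$raw_amplitude[scores$reinforced]
  length(shock) > 0 && all(shock == 0)
}
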