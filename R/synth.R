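#' Configuration for the synthetic-experiment generator
#'
#' Bundles every knob of the generative model: group size, ROI size, the
#' multivoxel class separation and its cross-modality overlap, the
#' skin-conductance response amplitudes, the BOLD noise model and the
#' latent-scale shift behind the Likert ratings. Defaults emulate a
#' two-phase differential-conditioning study with 27 participants, an
#' anterior-insula-sized ROI (248 voxels) and moderate, partially shared
#' threat-discriminative patterns.
#'
#' @param n_participants number of synthetic participants.
#' @param roi_n_voxels voxels per ROI pattern.
#' @param pattern_effect separation between CS+ and CS- class means, in
#'   units of the isotropic pattern noise SD (a Mahalanobis distance).
#' @param shared_fraction fraction (0..1) of the discriminative direction's
#'   energy shared between the view and imagine modalities; 1 means the two
#'   modalities use the same direction, 0 orthogonal directions.
#' @param pattern_noise_sd isotropic voxel noise SD.
#' @param effect_rel_sd SD of the per-participant log-normal multiplier on
#'   `pattern_effect` (multiplicative, so a zero effect stays exactly zero).
#' @param scr_amp_csplus,scr_amp_csminus mean SCR amplitudes (microsiemens)
#'   for conditioned-modality CS+ and CS- trials.
#' @param scr_generalization fraction of the CS+/CS- amplitude difference
#'   expressed in the non-conditioned modality.
#' @param scr_zero_prob probability that a trial evokes no response at all.
#' @param scr_noise_sd Gaussian noise SD on the conductance trace (uS).
#' @param scr_tonic tonic conductance level (uS).
#' @param scr_drift linear tonic drift (uS per second).
#' @param amp_rel_sd SD of the per-participant log-normal multiplier on SCR
#'   amplitudes.
#' @param sampling_rate simulated conductance sampling rate (Hz).
#' @param bold_noise_sd marginal SD of the AR(1) BOLD noise.
#' @param ar1_coef lag-1 autocorrelation of the BOLD noise, in (-1, 1).
#' @param tr repetition time of the simulated BOLD series (seconds).
#' @param rating_shift latent-scale shift of CS+ over CS- ratings
#'   (conditioned modality; 7-point Likert scale units).
#' @param rating_generalization fraction of `rating_shift` expressed in the
#'   non-conditioned modality.
#' @param rating_subject_sd SD of the per-participant latent intercept.
#' @param rating_noise_sd SD of the per-cell latent noise.
#' @param seed default seed used when a simulation function is not given one.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_participants = 27,
                         roi_n_voxels = 248,
                         pattern_effect = 0.8,
                         shared_fraction = 0.6,
                         pattern_noise_sd = 1,
                         effect_rel_sd = 0.3,
                         scr_amp_csplus = 0.4,
                         scr_amp_csminus = 0.2,
                         scr_generalization = 0.3,
                         scr_zero_prob = 0.25,
                         scr_noise_sd = 0.02,
                         scr_tonic = 2,
                         scr_drift = 0,
                         amp_rel_sd = 0.3,
                         sampling_rate = 100,
                         bold_noise_sd = 1,
                         ar1_coef = 0.3,
                         tr = 2,
                         rating_shift = 1.5,
                         rating_generalization = 0.6,
                         rating_subject_sd = 0.5,
                         rating_noise_sd = 1,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_participants >= 1, roi_n_voxels >= 1,
    pattern_effect >= 0, shared_fraction >= 0, shared_fraction <= 1,
    pattern_noise_sd >= 0,
    scr_amp_csplus >= 0, scr_amp_csminus >= 0,
    scr_zero_prob >= 0, scr_zero_prob <= 1,
    scr_generalization >= 0, scr_generalization <= 1,
    sampling_rate >= 10,
    abs(ar1_coef) < 1, tr > 0
  )
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

## --- SCR response kernel ------------------------------------------------
## sigmoid rise x exponential decay, onset latency 1 s, unit peak at ~3 s.
.kernel_cache <- new.env(parent = emptyenv())

scr_kernel_raw <- function(t) {
  rise <- stats::plogis((t - 2.25) / 0.4) - stats::plogis((1 - 2.25) / 0.4)
  rise <- pmax(rise, 0)
  out <- rise * exp(-pmax(t - 1, 0) / 3)
  out[t < 1] <- 0
  out
}

#' Canonical skin-conductance response kernel
#'
#' Unit-peak event kernel: zero during the first second after the event
#' (response latency), sigmoidal rise, exponential decay, peaking close to
#' 3 s post event -- inside the 1-6 s scoring window.
#'
#' @param t time since event onset (seconds; vectorised).
#' @return Kernel values (unit peak).
#' @export
scr_kernel <- function(t) {
  if (is.null(.kernel_cache$peak)) {
    opt <- stats::optimize(scr_kernel_raw, c(1, 6), maximum = TRUE)
    .kernel_cache$peak <- opt$objective
    .kernel_cache$peak_time <- opt$maximum
  }
  scr_kernel_raw(t) / .kernel_cache$peak
}

## per-trial mean amplitude given condition and phase
scr_trial_amplitude <- function(events, phase, config) {
  cond <- conditioned_modality(phase)
  dplus <- config$scr_amp_csplus - config$scr_amp_csminus
  amp <- rep(config$scr_amp_csminus, nrow(events))
  is_plus <- events$cs_type == "CSplus"
  amp[is_plus & events$modality == cond] <- config$scr_amp_csplus
  amp[is_plus & events$modality != cond] <-
    config$scr_amp_csminus + config$scr_generalization * dplus
  amp
}

#' Simulate a skin-conductance trace for one run
#'
#' Tonic level (plus optional linear drift) with one event-locked response
#' per trial: with probability `1 - scr_zero_prob` the unit-peak kernel
#' scaled by the condition's mean amplitude (times an optional participant
#' multiplier) is added at the trial onset, then Gaussian noise.
#'
#' @param run_events events of a single run (rows of a `trial_schedule`).
#' @param config a [synth_config()].
#' @param seed integer seed (deterministic trace per seed).
#' @param run_duration run length in seconds; defaults to the schedule
#'   attribute when `run_events` carries one.
#' @param amp_multiplier participant-level multiplicative random effect.
#' @return An `scr_trace`: list with `sampling_rate`, `values` (uS),
#'   `event_onsets` and `run_duration`.
#' @export
simulate_scr_trace <- function(run_events, config, seed = config$seed,
                               run_duration = attr(run_events, "run_duration"),
                               amp_multiplier = 1) {
  if (is.null(run_duration))
    run_duration <- max(run_events$onset + run_events$cs_duration) + 10
  rate <- config$sampling_rate
  n <- round(run_duration * rate)
  tgrid <- (seq_len(n) - 1) / rate
  phase <- run_events$phase[1]
  with_local_seed(seed, {
    values <- config$scr_tonic + config$scr_drift * tgrid
    amps <- scr_trial_amplitude(run_events, phase, config) * amp_multiplier
    respond <- runif(nrow(run_events)) >= config$scr_zero_prob
    for (i in seq_len(nrow(run_events))) {
      if (!respond[i] || amps[i] == 0) next
      rel <- tgrid - run_events$onset[i]
      idx <- which(rel >= 0 & rel <= 20)
      values[idx] <- values[idx] + amps[i] * scr_kernel(rel[idx])
    }
    if (config$scr_noise_sd > 0)
      values <- values + rnorm(n, 0, config$scr_noise_sd)
    structure(list(sampling_rate = rate, values = pmax(values, 0),
                   event_onsets = run_events$onset,
                   run_duration = run_duration),
              class = "scr_trace")
  })
}

## --- multivoxel patterns ------------------------------------------------

#' Construct a trial-wise pattern dataset
#'
#' Container for a trials-by-voxels matrix of (normalised) parameter
#' estimates with per-trial condition labels.
#'
#' @param X numeric matrix, trials x voxels, finite values.
#' @param labels data frame with one row per trial; must contain a
#'   `cs_type` column (`"CSplus"`/`"CSminus"`), normally also `modality`,
#'   `run`, `trial_id`.
#' @param participant_id participant label.
#' @return A `pattern_dataset`.
#' @export
pattern_dataset <- function(X, labels, participant_id = "p01") {
  X <- as.matrix(X)
  stopifnot(is.data.frame(labels), "cs_type" %in% names(labels))
  new_pattern_dataset(X, labels, participant_id)
}

new_pattern_dataset <- function(X, labels, participant_id) {
  stopifnot(nrow(X) == nrow(labels), all(is.finite(X)))
  structure(list(X = X, labels = labels, participant_id = participant_id),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf("<pattern_dataset> %s: %d trials x %d voxels (%s)\n",
              x$participant_id, nrow(x$X), ncol(x$X),
              paste(names(table(x$labels$modality)), collapse = "/")))
  invisible(x)
}

#' Subset a pattern dataset by trial labels
#'
#' @param pd a `pattern_dataset`.
#' @param modality optional modality filter (`"view"`/`"imagine"`).
#' @param cs_type optional CS-type filter.
#' @return The filtered `pattern_dataset`.
#' @export
subset_patterns <- function(pd, modality = NULL, cs_type = NULL) {
  keep <- rep(TRUE, nrow(pd$labels))
  if (!is.null(modality)) keep <- keep & pd$labels$modality %in% modality
  if (!is.null(cs_type)) keep <- keep & pd$labels$cs_type %in% cs_type
  new_pattern_dataset(pd$X[keep, , drop = FALSE],
                      pd$labels[keep, , drop = FALSE], pd$participant_id)
}

#' Participant-level latent effects
#'
#' Draws, per participant, the discriminative directions for the two
#' modalities (sharing `shared_fraction` of their energy) and the
#' multiplicative random effects on pattern separation and SCR amplitude.
#' The same latents are reused across that participant's phases so that
#' cross-phase transfer is possible.
#'
#' @param config a [synth_config()].
#' @param participant_id participant label (enters the seed derivation).
#' @param seed base seed.
#' @return List with `u_view`, `u_imagine` (unit vectors), `effect`,
#'   `amp_multiplier`.
#' @export
participant_latents <- function(config, participant_id, seed = config$seed) {
  with_local_seed(derive_seed(seed, paste0("latent-", participant_id)), {
    V <- config$roi_n_voxels
    Q <- qr.Q(qr(matrix(rnorm(V * 3), V, 3)))
    sf <- config$shared_fraction
    u_view <- sqrt(sf) * Q[, 1] + sqrt(1 - sf) * Q[, 2]
    u_imagine <- sqrt(sf) * Q[, 1] + sqrt(1 - sf) * Q[, 3]
    list(
      u_view = u_view, u_imagine = u_imagine,
      effect = config$pattern_effect *
        exp(rnorm(1, 0, config$effect_rel_sd)),
      amp_multiplier = exp(rnorm(1, 0, config$amp_rel_sd))
    )
  })
}

#' Simulate a trial-wise ROI pattern dataset
#'
#' One row per analysis trial of the acquisition schedule (both modalities,
#' reinforced and boundary trials already excluded). Each row is the class
#' mean -- plus or minus half the participant's pattern separation along the
#' modality's discriminative direction -- plus isotropic Gaussian noise.
#'
#' @param schedule an acquisition `trial_schedule`.
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param latents optional [participant_latents()] (drawn from `seed`
#'   otherwise); supply the same object across phases to make the
#'   discriminative structure transfer.
#' @return A `pattern_dataset` with labels `trial_id`, `cs_type`,
#'   `modality`, `run`, `phase`.
#' @export
simulate_pattern_dataset <- function(schedule, config, seed = config$seed,
                                     latents = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"),
            attr(schedule, "schedule_type") == "acquisition")
  pid <- attr(schedule, "participant_id")
  if (is.null(latents)) latents <- participant_latents(config, pid, seed)
  phase <- attr(schedule, "phase")
  trials <- rbind(select_analysis_trials(schedule, "imagine"),
                  select_analysis_trials(schedule, "view"))
  trials <- trials[order(trials$run_index, trials$onset), ]
  with_local_seed(derive_seed(seed, paste0("pattern-", pid, "-", phase)), {
    V <- config$roi_n_voxels
    X <- matrix(rnorm(nrow(trials) * V, 0, config$pattern_noise_sd),
                nrow(trials), V)
    sgn <- ifelse(trials$cs_type == "CSplus", 1, -1)
    for (m in c("view", "imagine")) {
      u <- if (m == "view") latents$u_view else latents$u_imagine
      idx <- which(trials$modality == m)
      X[idx, ] <- X[idx, ] +
        tcrossprod(sgn[idx] * latents$effect / 2, u)
    }
    labels <- data.frame(
      trial_id = sprintf("%s_run%d_t%02d", phase, trials$run_index,
                         trials$trial_index),
      cs_type = trials$cs_type, modality = trials$modality,
      run = trials$run_index, phase = phase, stringsAsFactors = FALSE)
    new_pattern_dataset(X, labels, pid)
  })
}

## --- BOLD ----------------------------------------------------------------

#' Simulate a BOLD run from trial onsets
#'
#' Builds the trial-wise design matrix for the run (double-gamma HRF) and
#' generates `Y = X B + E` where `B` holds per-regressor, per-voxel true
#' effects and `E` is AR(1) Gaussian noise with marginal SD
#' `bold_noise_sd`. The true coefficients are returned for recovery
#' testing.
#'
#' @param run_events events of one acquisition run.
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param n_voxels number of voxels (defaults to `config$roi_n_voxels`).
#' @param true_beta optional coefficient matrix (regressors x voxels);
#'   drawn standard normal if missing.
#' @param run_duration run length in seconds (schedule attribute default).
#' @return List with `Y` (volumes x voxels), `true_beta`, `design`.
#' @export
simulate_bold_run <- function(run_events, config, seed = config$seed,
                              n_voxels = config$roi_n_voxels,
                              true_beta = NULL,
                              run_duration = attr(run_events, "run_duration")) {
  if (is.null(run_duration)) run_duration <- ACQUISITION_DURATION
  n_vol <- round(run_duration / config$tr)
  design <- build_trialwise_design(run_events, tr = config$tr,
                                   n_volumes = n_vol)
  p <- ncol(design$X)
  with_local_seed(derive_seed(seed, "bold"), {
    if (is.null(true_beta)) true_beta <- matrix(rnorm(p * n_voxels), p, n_voxels)
    stopifnot(nrow(true_beta) == p)
    signal <- design$X %*% true_beta
    if (config$bold_noise_sd > 0) {
      innov_sd <- config$bold_noise_sd * sqrt(1 - config$ar1_coef^2)
      E <- matrix(rnorm(n_vol * n_voxels, 0, innov_sd), n_vol, n_voxels)
      if (config$ar1_coef != 0)
        E <- apply(E, 2, function(e)
          as.numeric(stats::filter(e, config$ar1_coef, method = "recursive")))
      signal <- signal + E
    }
    list(Y = signal, true_beta = true_beta, design = design)
  })
}

## --- ratings -------------------------------------------------------------

#' Simulate 7-point Likert fear ratings
#'
#' Latent-normal model: per participant, each of the eight (phase x
#' modality x CS type) cells has latent mean 4 plus a participant
#' intercept; CS+ cells are shifted by `rating_shift` in the conditioned
#' modality and by `rating_shift * rating_generalization` in the other
#' modality. Latents are rounded and clamped to the 1..7 scale.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return Long data frame: `participant`, `phase`, `modality`, `cs_type`,
#'   `rating` (integer 1..7).
#' @export
simulate_ratings <- function(config, seed = config$seed) {
  cells <- expand.grid(phase = PHASES, modality = c("imagine", "view"),
                       cs_type = c("CSplus", "CSminus"),
                       stringsAsFactors = FALSE)
  with_local_seed(derive_seed(seed, "ratings"), {
    out <- lapply(seq_len(config$n_participants), function(i) {
      b <- rnorm(1, 0, config$rating_subject_sd)
      shift <- ifelse(
        cells$cs_type == "CSplus",
        ifelse(cells$modality == vapply(cells$phase, conditioned_modality, ""),
               config$rating_shift,
               config$rating_shift * config$rating_generalization),
        0)
      latent <- 4 + b + shift + rnorm(nrow(cells), 0, config$rating_noise_sd)
      data.frame(participant = sprintf("p%02d", i), cells,
                 rating = pmin(pmax(round(latent), 1), 7),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

## --- whole participants --------------------------------------------------

#' Simulate one participant's full dataset
#'
#' Acquisition schedules for both phases, the shared participant latents,
#' and per-phase trial-wise ROI pattern datasets. Optionally also the
#' skin-conductance traces of every acquisition run.
#'
#' @param config a [synth_config()].
#' @param participant_id participant label.
#' @param seed integer seed.
#' @param scr simulate conductance traces too? (slower; default `FALSE`).
#' @return List with `schedules`, `patterns` (one per phase), `latents`,
#'   and optionally `scr_traces` (per phase, one trace per run).
#' @export
simulate_participant <- function(config, participant_id = "p01",
                                 seed = config$seed, scr = FALSE) {
  latents <- participant_latents(config, participant_id, seed)
  schedules <- lapply(PHASES, build_acquisition_schedule,
                      participant_id = participant_id,
                      seed = derive_seed(seed, participant_id))
  names(schedules) <- PHASES
  patterns <- lapply(PHASES, function(ph)
    simulate_pattern_dataset(schedules[[ph]], config, seed, latents))
  names(patterns) <- PHASES
  out <- list(schedules = schedules, patterns = patterns, latents = latents)
  if (scr) {
    out$scr_traces <- lapply(PHASES, function(ph) {
      sch <- schedules[[ph]]
      lapply(1:6, function(r)
        simulate_scr_trace(sch[sch$run_index == r, ], config,
                           seed = derive_seed(seed, paste0("scr-", participant_id,
                                                           "-", ph, "-", r)),
                           run_duration = attr(sch, "run_duration"),
                           amp_multiplier = latents$amp_multiplier))
    })
    names(out$scr_traces) <- PHASES
  }
  out
}
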