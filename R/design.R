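#' @useDynLib fearcond, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd
NULL

PHASES <- c("imagery_acquisition", "visual_acquisition")

#' Conditioned modality of a phase
#'
#' In the imagery acquisition phase the shock is paired with *imagining* the
#' CS+, in the visual acquisition phase with *viewing* it.
#'
#' @param phase `"imagery_acquisition"` or `"visual_acquisition"`.
#' @return `"imagine"` or `"view"`.
#' @export
conditioned_modality <- function(phase) {
  phase <- match.arg(phase, PHASES)
  if (phase == "imagery_acquisition") "imagine" else "view"
}

other_modality <- function(modality) if (modality == "imagine") "view" else "imagine"

## run timing constants: a trial is a 2 s auditory cue followed by a 4 s CS
## epoch; runs fill 73 (habituation) / 109 (acquisition) volumes at TR 2 s.
CUE_DURATION <- 2
CS_DURATION <- 4
TR_DEFAULT <- 2
HABITUATION_DURATION <- 146
ACQUISITION_DURATION <- 218

## Gabor orientations per phase (counterbalancing is bookkeeping only; the
## first orientation of each pair plays the CS+ role)
gabor_labels <- function(phase) {
  if (phase == "imagery_acquisition") c(CSplus = "left", CSminus = "vertical")
  else c(CSplus = "right", CSminus = "horizontal")
}

cue_label <- function(phase, modality, cs_type) {
  ori <- gabor_labels(phase)[[cs_type]]
  paste(if (modality == "imagine") "imagine" else "attend", ori)
}

## run seeded code without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## deterministic sub-seed derivation (polynomial rolling hash of a tag,
## folded into [0, 2^31) so the result is a valid integer seed)
derive_seed <- function(seed, tag) {
  h <- 17
  for (ch in utf8ToInt(paste0(tag, ":", seed))) {
    h <- (h * 8191 + ch) %% 2147483629
  }
  as.integer(h)
}

new_schedule <- function(df, participant_id, phase, type, run_duration, seed) {
  rownames(df) <- NULL
  structure(df,
    class = c("trial_schedule", "data.frame"),
    participant_id = participant_id, phase = phase,
    schedule_type = type, run_duration = run_duration, seed = seed)
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %s / %s / %s: %d trials in %d runs (%g s each)\n",
              attr(x, "participant_id"), attr(x, "phase"),
              attr(x, "schedule_type"), nrow(x),
              length(unique(x$run_index)), attr(x, "run_duration")))
  print(as.data.frame(utils::head(x, 4)))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

## assign onsets: lead-in + n trials (cue + CS) + gaps, uniform gaps rescaled
## so the run exactly fills run_duration
assign_onsets <- function(n_trials, run_duration) {
  trial_len <- CUE_DURATION + CS_DURATION
  free <- run_duration - n_trials * trial_len
  stopifnot(free > 0)
  gaps <- runif(n_trials + 1, 1, 2)
  gaps <- gaps * free / sum(gaps)
  cue_onsets <- cumsum(gaps)[seq_len(n_trials)] +
    (seq_len(n_trials) - 1) * trial_len
  cue_onsets + CUE_DURATION        # event onset = CS onset
}

run_frame <- function(phase, run_index, modality, cs_type, reinforced,
                      run_duration) {
  n <- length(modality)
  data.frame(
    phase = phase, run_index = run_index, trial_index = seq_len(n),
    modality = modality, cs_type = cs_type, reinforced = reinforced,
    onset = assign_onsets(n, run_duration),
    cs_duration = CS_DURATION,
    cue_label = mapply(cue_label, phase, modality, cs_type, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Build a habituation/practice schedule
#'
#' Six runs of eight trials each: two CS+ imagine, two CS- imagine, two CS+
#' view and two CS- view per run, in fully randomised order, with no
#' reinforcement. Across the six runs each CS is viewed 12 times and imagined
#' 12 times (48 trials).
#'
#' @param phase `"imagery_acquisition"` or `"visual_acquisition"`.
#' @param participant_id participant label.
#' @param seed integer seed; the schedule is a deterministic function of it.
#' @return A `trial_schedule` (data frame of trial events).
#' @export
build_habituation_schedule <- function(phase, participant_id = "p01", seed = 1L) {
  phase <- match.arg(phase, PHASES)
  stopifnot(is.finite(seed))
  with_local_seed(derive_seed(seed, paste0("hab-", phase, "-", participant_id)), {
    runs <- lapply(1:6, function(r) {
      cells <- expand.grid(modality = c("imagine", "view"),
                           cs_type = c("CSplus", "CSminus"),
                           rep = 1:2, stringsAsFactors = FALSE)
      ord <- sample.int(nrow(cells))
      run_frame(phase, r, cells$modality[ord], cells$cs_type[ord],
                reinforced = rep(FALSE, 8),
                run_duration = HABITUATION_DURATION)
    })
    new_schedule(do.call(rbind, runs), participant_id, phase,
                 "habituation", HABITUATION_DURATION, seed)
  })
}

## one acquisition run: positions 1 and 12 are CS- of the conditioned
## modality; reinforced CS+ trials are pinned (run 1: position 2 plus one in
## the second half; later runs: one per half, where the halves are positions
## 2-6 and 7-11); everything else is shuffled into the free slots
acquisition_run <- function(phase, run_index) {
  cond <- conditioned_modality(phase)
  oth <- other_modality(cond)
  n <- 12
  modality <- character(n); cs <- character(n); reinf <- logical(n)
  modality[c(1, n)] <- cond; cs[c(1, n)] <- "CSminus"
  if (run_index == 1) {
    r1 <- 2L
    r2 <- sample(7:11, 1)
  } else {
    r1 <- sample(2:6, 1)
    r2 <- sample(7:11, 1)
  }
  modality[c(r1, r2)] <- cond; cs[c(r1, r2)] <- "CSplus"; reinf[c(r1, r2)] <- TRUE
  rest <- data.frame(
    modality = c(cond, cond, cond, cond, oth, oth, oth, oth),
    cs_type = c("CSplus", "CSplus", "CSminus", "CSminus",
                "CSplus", "CSplus", "CSminus", "CSminus"),
    stringsAsFactors = FALSE)
  free <- setdiff(seq_len(n), c(1L, n, r1, r2))
  ord <- sample.int(8)
  modality[free] <- rest$modality[ord]
  cs[free] <- rest$cs_type[ord]
  run_frame(phase, run_index, modality, cs, reinf, ACQUISITION_DURATION)
}

#' Build a fear-acquisition schedule
#'
#' Six runs of twelve trials. Per run, for the phase's conditioned modality:
#' two reinforced CS+, two non-reinforced CS+ and four CS- trials; for the
#' other modality two CS+ and two CS- trials (never reinforced). Every run
#' begins and ends with a conditioned-modality CS- trial; run 1 places its
#' first reinforced trial at position 2 and its second in the second half of
#' the run, later runs place one reinforced trial per half. The CS+ of the
#' conditioned modality is therefore reinforced on exactly 50% of its
#' presentations.
#'
#' @inheritParams build_habituation_schedule
#' @return A `trial_schedule` of 72 trials.
#' @export
build_acquisition_schedule <- function(phase, participant_id = "p01", seed = 1L) {
  phase <- match.arg(phase, PHASES)
  stopifnot(is.finite(seed))
  with_local_seed(derive_seed(seed, paste0("acq-", phase, "-", participant_id)), {
    runs <- lapply(1:6, function(r) acquisition_run(phase, r))
    sched <- new_schedule(do.call(rbind, runs), participant_id, phase,
                          "acquisition", ACQUISITION_DURATION, seed)
    validate_schedule(sched)
    sched
  })
}

#' Validate a trial schedule against the design invariants
#'
#' Checks run/trial counts, per-run composition, reinforcement placement,
#' boundary-trial rules and onset monotonicity. Habituation schedules are
#' checked against the habituation invariants, acquisition schedules against
#' the acquisition invariants.
#'
#' @param schedule a `trial_schedule`.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  type <- attr(schedule, "schedule_type")
  phase <- attr(schedule, "phase")
  cond <- conditioned_modality(phase)
  oth <- other_modality(cond)
  fail <- function(...) stop(sprintf(...), call. = FALSE)
  if (!setequal(unique(schedule$run_index), 1:6))
    fail("schedule must contain runs 1..6")
  if (any(schedule$reinforced &
          !(schedule$cs_type == "CSplus" & schedule$modality == cond)))
    fail("reinforcement outside conditioned-modality CS+ trials")
  for (r in 1:6) {
    run <- schedule[schedule$run_index == r, ]
    run <- run[order(run$trial_index), ]
    if (any(diff(run$onset) <= 0)) fail("onsets not increasing in run %d", r)
    if (any(run$onset[-1] - (run$onset[-nrow(run)] + run$cs_duration[-nrow(run)]) < 0))
      fail("overlapping events in run %d", r)
    if (min(run$onset) < CUE_DURATION ||
        max(run$onset + run$cs_duration) > attr(schedule, "run_duration"))
      fail("events outside run %d", r)
    key <- paste(run$modality, run$cs_type, run$reinforced)
    count <- function(m, c, f) sum(key == paste(m, c, f))
    if (type == "habituation") {
      if (nrow(run) != 8) fail("habituation run %d has %d trials", r, nrow(run))
      if (any(run$reinforced)) fail("reinforced trial in habituation run %d", r)
      ok <- count("imagine", "CSplus", FALSE) == 2 &&
        count("imagine", "CSminus", FALSE) == 2 &&
        count("view", "CSplus", FALSE) == 2 &&
        count("view", "CSminus", FALSE) == 2
      if (!ok) fail("habituation run %d composition wrong", r)
    } else {
      if (nrow(run) != 12) fail("acquisition run %d has %d trials", r, nrow(run))
      ok <- count(cond, "CSplus", TRUE) == 2 &&
        count(cond, "CSplus", FALSE) == 2 &&
        count(cond, "CSminus", FALSE) == 4 &&
        count(oth, "CSplus", FALSE) == 2 &&
        count(oth, "CSminus", FALSE) == 2
      if (!ok) fail("acquisition run %d composition wrong", r)
      bound <- run[c(1, 12), ]
      if (!all(bound$modality == cond & bound$cs_type == "CSminus"))
        fail("run %d does not begin and end with a conditioned-modality CS-", r)
      rpos <- run$trial_index[run$reinforced]
      if (r == 1) {
        if (!(2 %in% rpos)) fail("run 1 trial 2 is not reinforced")
        if (!any(rpos >= 7 & rpos <= 11))
          fail("run 1 second reinforced trial not in second half")
      } else {
        if (!(sum(rpos >= 2 & rpos <= 6) == 1 && sum(rpos >= 7 & rpos <= 11) == 1))
          fail("run %d reinforced trials not one per half", r)
      }
    }
  }
  invisible(TRUE)
}

#' Select the trials entering analyses
#'
#' Applies the analysis exclusions for one modality of an acquisition
#' schedule: reinforced (shock) trials are dropped, and for the conditioned
#' modality the first and last CS- trial of each run (the fixed boundary
#' trials) are dropped, leaving equal CS+ and CS- counts (12 and 12).
#'
#' @param schedule an acquisition `trial_schedule`.
#' @param modality `"imagine"` or `"view"`.
#' @return Data frame of retained trial events.
#' @export
select_analysis_trials <- function(schedule, modality = c("imagine", "view")) {
  stopifnot(inherits(schedule, "trial_schedule"))
  modality <- match.arg(modality)
  if (attr(schedule, "schedule_type") != "acquisition")
    stop("analysis-trial selection applies to acquisition schedules only",
         call. = FALSE)
  cond <- conditioned_modality(attr(schedule, "phase"))
  ev <- schedule[schedule$modality == modality & !schedule$reinforced, ]
  if (modality == cond) {
    drop <- unlist(lapply(split(ev, ev$run_index), function(run) {
      csm <- run[run$cs_type == "CSminus", ]
      csm <- csm[order(csm$onset), ]
      paste(csm$run_index[c(1, nrow(csm))], csm$trial_index[c(1, nrow(csm))])
    }))
    ev <- ev[!(paste(ev$run_index, ev$trial_index) %in% drop), ]
  }
  rownames(ev) <- NULL
  as.data.frame(ev)
}

#' Mark analysis status of every trial in a run
#'
#' @param run_events events of a single acquisition run (data frame).
#' @param phase the schedule phase (to identify the conditioned modality).
#' @return character vector per trial: `"analysis"`, `"reinforced"` or
#'   `"boundary"` (first/last conditioned-modality CS-).
#' @keywords internal
trial_roles <- function(run_events, phase) {
  cond <- conditioned_modality(phase)
  role <- rep("analysis", nrow(run_events))
  role[run_events$reinforced] <- "reinforced"
  csm <- which(run_events$modality == cond & run_events$cs_type == "CSminus")
  csm <- csm[order(run_events$onset[csm])]
  if (length(csm) > 0) role[csm[c(1, length(csm))]] <- "boundary"
  role
}
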