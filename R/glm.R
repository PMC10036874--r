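#' Double-gamma haemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking at 6 s
#' and an undershoot peaking at 16 s with one sixth of its weight, over a
#' 32 s support, rescaled to unit peak.
#'
#' @param dt sampling interval in seconds.
#' @param duration kernel length in seconds.
#' @return Numeric kernel sampled at `seq(0, duration, by = dt)`.
#' @export
double_gamma_hrf <- function(dt, duration = 32) {
  stopifnot(dt > 0)
  t <- seq(0, duration, by = dt)
  # gamma(shape a, rate 1) has mode a - 1: shapes 7 and 17 give peaks 6 / 16
  h <- stats::dgamma(t, shape = 7, rate = 1) -
    stats::dgamma(t, shape = 17, rate = 1) / 6
  h / max(h)
}

#' Build a trial-wise (beta-series) design matrix for one run
#'
#' Each analysis trial receives its own regressor: a boxcar of the CS
#' duration at the trial onset convolved with the double-gamma HRF and
#' sampled at the volume acquisition times. Reinforced (shock) trials are
#' collapsed into one nuisance regressor and the run's boundary CS- trials
#' (first and last conditioned-modality CS-) into another; an intercept and
#' optional polynomial drift terms complete the matrix.
#'
#' @param run_events events of a single acquisition run (needs `onset`,
#'   `cs_duration`, `modality`, `cs_type`, `reinforced`, `phase`).
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes in the run.
#' @param drift_order degree of polynomial drift regressors (0 = none).
#' @return A `design_matrix`: list with `X` (volumes x columns), `trial_cols`
#'   (indices of the per-trial columns), `trial_info` (labels for those
#'   trials), `frame_times`.
#' @export
build_trialwise_design <- function(run_events, tr, n_volumes,
                                   drift_order = 0) {
  if (nrow(run_events) == 0) stop("run contains no events", call. = FALSE)
  if (any(run_events$onset < 0) ||
      any(run_events$onset >= n_volumes * tr))
    stop("trial onset outside the run", call. = FALSE)
  role <- trial_roles(run_events, run_events$phase[1])

  dt <- 0.1
  run_len <- n_volumes * tr
  fine_t <- seq(0, run_len - dt, by = dt)
  hrf <- double_gamma_hrf(dt)
  frame_times <- (seq_len(n_volumes) - 1) * tr
  vol_idx <- round(frame_times / dt) + 1

  regressor <- function(onsets, durations) {
    stick <- numeric(length(fine_t))
    for (k in seq_along(onsets)) {
      on <- onsets[k]
      stick[fine_t >= on & fine_t < on + durations[k]] <- 1
    }
    conv <- stats::convolve(stick, rev(hrf), type = "open")[seq_along(fine_t)]
    conv[vol_idx] * dt
  }

  trial_idx <- which(role == "analysis")
  cols <- lapply(trial_idx, function(i)
    regressor(run_events$onset[i], run_events$cs_duration[i]))
  names(cols) <- sprintf("trial_%02d", run_events$trial_index[trial_idx])
  nuisance <- list()
  if (any(role == "reinforced"))
    nuisance$nuis_shock <- regressor(run_events$onset[role == "reinforced"],
                                     run_events$cs_duration[role == "reinforced"])
  if (any(role == "boundary"))
    nuisance$nuis_boundary <- regressor(run_events$onset[role == "boundary"],
                                        run_events$cs_duration[role == "boundary"])
  nuisance$intercept <- rep(1, n_volumes)
  if (drift_order > 0) {
    tt <- scale(frame_times)
    for (d in seq_len(drift_order)) nuisance[[paste0("drift", d)]] <- tt^d
  }

  X <- do.call(cbind, c(cols, nuisance))
  if (any(colSums(abs(X[, seq_along(cols), drop = FALSE])) == 0))
    stop("a trial regressor is identically zero", call. = FALSE)
  info <- data.frame(
    trial_index = run_events$trial_index[trial_idx],
    run_index = run_events$run_index[trial_idx],
    modality = run_events$modality[trial_idx],
    cs_type = run_events$cs_type[trial_idx],
    onset = run_events$onset[trial_idx],
    stringsAsFactors = FALSE)
  structure(list(X = X, trial_cols = seq_along(cols), trial_info = info,
                 frame_times = frame_times),
            class = "design_matrix")
}

#' Estimate trial-wise parameter patterns by OLS
#'
#' Ordinary least squares per voxel on the trial-wise design; the
#' coefficients of the per-trial columns form the activation pattern rows.
#' With `normalize = TRUE` each voxel's trial betas are z-scored within the
#' run (the "normalized parameter estimate" convention used for the
#' multivoxel analyses).
#'
#' @param time_series numeric matrix, volumes x voxels.
#' @param design a `design_matrix` from [build_trialwise_design()].
#' @param normalize z-score trial betas per voxel within the run?
#' @return List with `patterns` (trials x voxels), `trial_info`,
#'   `all_beta` (full coefficient matrix, regressors x voxels).
#' @export
estimate_trial_betas <- function(time_series, design, normalize = TRUE) {
  stopifnot(inherits(design, "design_matrix"))
  time_series <- as.matrix(time_series)
  X <- design$X
  stopifnot(nrow(time_series) == nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  B <- qr.coef(qrX, time_series)
  pat <- B[design$trial_cols, , drop = FALSE]
  if (normalize) {
    pat <- scale(pat)
    pat[, attr(pat, "scaled:scale") == 0] <- 0   # flat voxels
    attributes(pat)[c("scaled:center", "scaled:scale")] <- NULL
  }
  rownames(pat) <- rownames(design$trial_info)
  list(patterns = pat, trial_info = design$trial_info, all_beta = B)
}
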