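# shared fixtures, built in code

# minimal pattern dataset around a trials x voxels matrix
make_pd <- function(X, cs_type, modality = "imagine", run = 1, pid = "p01") {
  pattern_dataset(X, data.frame(
    trial_id = sprintf("t%02d", seq_len(nrow(X))),
    cs_type = cs_type, modality = modality, run = run,
    stringsAsFactors = FALSE), pid)
}

# sample an analytic conductance curve f(t) into an scr_trace
analytic_trace <- function(f, duration, rate) {
  tgrid <- (seq_len(duration * rate) - 1) / rate
  structure(list(sampling_rate = rate, values = f(tgrid),
                 event_onsets = numeric(0), run_duration = duration),
            class = "scr_trace")
}

# independent Bayes-factor oracle: marginal likelihood of t under a
# noncentral-t sampling density mixed over a Cauchy prior on the
# standardised effect (a different integral than the package's g-mixture)
bf10_nct_oracle <- function(t, n, r = 0.707) {
  nu <- n - 1
  num <- stats::integrate(function(d) {
    suppressWarnings(stats::dt(t, nu, ncp = d * sqrt(n))) *
      stats::dcauchy(d, 0, r)
  }, -Inf, Inf, rel.tol = 1e-8)$value
  num / stats::dt(t, nu)
}

# long-format 2x2x2 within-subject data frame from an n x 8 cell matrix
cells_to_long <- function(M) {
  n <- nrow(M)
  grid <- expand.grid(cs_type = c("CSplus", "CSminus"),
                      modality = c("imagine", "view"),
                      phase = c("imagery_acquisition", "visual_acquisition"),
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(participant = sprintf("s%02d", i), grid, value = M[i, ])))
}
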