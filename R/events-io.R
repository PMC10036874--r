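#' Write a schedule as a BIDS-style events TSV
#'
#' One row per trial with columns `onset`, `duration`, `trial_type`, `run`,
#' `phase` (tab-delimited, `.` decimal). `trial_type` encodes modality, CS
#' type and reinforcement, e.g. `"imagine_CSplus_shock"`.
#'
#' @param schedule a `trial_schedule`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "trial_schedule"))
  tt <- paste0(schedule$modality, "_", schedule$cs_type,
               ifelse(schedule$reinforced, "_shock", ""))
  out <- data.frame(onset = schedule$onset,
                    duration = schedule$cs_duration,
                    trial_type = tt,
                    run = schedule$run_index,
                    phase = schedule$phase,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' Inverse of [write_events_tsv()]: decodes `trial_type` back into
#' `modality`, `cs_type` and `reinforced` columns.
#'
#' @param path events TSV path.
#' @return Data frame of trial events ordered by run and onset.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "run", "phase")
  if (!all(need %in% names(ev)))
    stop("events file lacks required columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "), call. = FALSE)
  parts <- strsplit(ev$trial_type, "_", fixed = TRUE)
  ev$modality <- vapply(parts, `[`, "", 1)
  ev$cs_type <- vapply(parts, `[`, "", 2)
  ev$reinforced <- vapply(parts, function(p) length(p) > 2 && p[3] == "shock",
                          logical(1))
  ev$run_index <- ev$run
  ev$cs_duration <- ev$duration
  ev <- ev[order(ev$run_index, ev$onset), ]
  ev$trial_index <- unlist(lapply(split(seq_len(nrow(ev)), ev$run_index),
                                  seq_along))
  rownames(ev) <- NULL
  ev
}
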