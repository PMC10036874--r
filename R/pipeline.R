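## End-to-end orchestration: generate -> score -> decode -> infer, with
## seeded reproducibility and a JSON report.

fnv1a_hash <- function(x) {
  h <- 2166136261
  for (ch in utf8ToInt(x)) {
    h <- (h + ch) %% 4294967296
    # 32-bit FNV-style mixing kept inside double-precision exact range
    h <- (h * 65599) %% 4294967291
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Pipeline configuration
#'
#' @param synth a [synth_config()] describing the synthetic group.
#' @param n_perm,n_boot resampling sizes for the two-level decoding
#'   inference.
#' @param seed global seed; every stage derives its own seed from it.
#' @param scr,mvpa,stats analysis toggles.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(n_participants = 8),
                            n_perm = 200, n_boot = 200, seed = 11L,
                            scr = TRUE, mvpa = TRUE, stats = TRUE) {
  stopifnot(n_perm >= 1, n_boot >= 1)
  structure(list(synth = synth, n_perm = n_perm, n_boot = n_boot,
                 seed = as.integer(seed), scr = scr, mvpa = mvpa,
                 stats = stats),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic experiment pipeline
#'
#' Simulates the group, writes BIDS-style events files, scores the
#' skin-conductance traces, runs the two cross-phase decoding analyses
#' (imagery-to-visual and visual-to-imagery) with permutation/bootstrap
#' inference, computes the repeated-measures ANOVA, paired t and Bayes
#' factor statistics on conductance and ratings, and writes a JSON report
#' carrying the seeds, parameters and a config hash. Re-running with an
#' identical config reproduces identical numbers.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`scr_means`,
#'   `ratings`, `mvpa`, `stats`, `report`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ev_dir <- file.path(out_dir, "events")
  dir.create(ev_dir, showWarnings = FALSE)
  scfg <- config$synth
  n_p <- scfg$n_participants
  seed <- config$seed
  t0 <- proc.time()[["elapsed"]]
  stage_time <- list()

  ## --- simulate group ----------------------------------------------------
  participants <- lapply(seq_len(n_p), function(i) {
    pid <- sprintf("p%02d", i)
    simulate_participant(scfg, pid, seed = derive_seed(seed, paste0("part-", pid)),
                         scr = config$scr)
  })
  names(participants) <- sprintf("p%02d", seq_len(n_p))
  for (pid in names(participants)) {
    for (ph in PHASES) {
      write_events_tsv(participants[[pid]]$schedules[[ph]],
                       file.path(ev_dir, sprintf("%s_%s_acq_events.tsv", pid, ph)))
    }
  }
  ratings <- simulate_ratings(scfg, seed = derive_seed(seed, "ratings"))
  write_tsv(ratings, file.path(out_dir, "ratings.tsv"))
  stage_time$simulate <- proc.time()[["elapsed"]] - t0

  results <- list(report = list())

  ## --- SCR scoring -------------------------------------------------------
  if (config$scr) {
    t1 <- proc.time()[["elapsed"]]
    all_scores <- list(); all_means <- list()
    for (pid in names(participants)) {
      part <- participants[[pid]]
      for (ph in PHASES) {
        sch <- part$schedules[[ph]]
        scores <- do.call(rbind, lapply(1:6, function(r)
          score_run(part$scr_traces[[ph]][[r]], sch[sch$run_index == r, ])))
        scores$participant <- pid
        scores$phase <- ph
        all_scores[[length(all_scores) + 1]] <- scores
        m <- aggregate_condition_means(scores, sch)
        m$participant <- pid
        all_means[[length(all_means) + 1]] <- m
      }
    }
    scores <- do.call(rbind, all_scores)
    scr_means <- do.call(rbind, all_means)
    write_tsv(scores, file.path(out_dir, "scr_scores.tsv"))
    write_tsv(scr_means, file.path(out_dir, "scr_condition_means.tsv"))
    results$scr_means <- scr_means
    stage_time$scr <- proc.time()[["elapsed"]] - t1
  }

  ## --- MVPA cross-classification ----------------------------------------
  if (config$mvpa) {
    t1 <- proc.time()[["elapsed"]]
    sets <- list(
      imagery_to_visual = list(train = c("imagery_acquisition", "imagine"),
                               test = c("visual_acquisition", "view")),
      visual_to_imagery = list(train = c("visual_acquisition", "view"),
                               test = c("imagery_acquisition", "imagine")))
    mvpa_rows <- list(); mvpa_summaries <- list()
    for (nm in names(sets)) {
      s <- sets[[nm]]
      train_list <- lapply(participants, function(p)
        subset_patterns(p$patterns[[s$train[1]]], modality = s$train[2]))
      test_list <- lapply(participants, function(p)
        subset_patterns(p$patterns[[s$test[1]]], modality = s$test[2]))
      res <- crossclass_group(train_list, test_list,
                              n_perm = config$n_perm, n_boot = config$n_boot,
                              seed = derive_seed(seed, paste0("mvpa-", nm)))
      mvpa_rows[[nm]] <- data.frame(
        participant = names(participants), analysis = nm,
        train_set = paste(s$train, collapse = ":"),
        test_set = paste(s$test, collapse = ":"),
        accuracy = res$participant_accuracy, stringsAsFactors = FALSE)
      mvpa_summaries[[nm]] <- list(
        group_mean_accuracy = res$group_mean,
        null_mean_accuracy = mean(res$group_null),
        p_value = res$p_value,
        significant = res$p_value < 0.05,
        n_perm = res$n_perm, n_boot = res$n_boot)
      results$mvpa[[nm]] <- res
    }
    write_tsv(do.call(rbind, mvpa_rows), file.path(out_dir, "mvpa_results.tsv"))
    jsonlite::write_json(mvpa_summaries, file.path(out_dir, "mvpa_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_time$mvpa <- proc.time()[["elapsed"]] - t1
  }

  ## --- group statistics --------------------------------------------------
  if (config$stats) {
    t1 <- proc.time()[["elapsed"]]
    stat_tabs <- list()
    run_stats <- function(df, dv, label) {
      an <- rm_anova_2x2x2(df, dv = dv, id = "participant",
                           factors = c("cs_type", "modality", "phase"))
      write_tsv(as.data.frame(an),
                file.path(out_dir, sprintf("anova_%s.tsv", label)))
      tt <- list()
      for (ph in PHASES) {
        m <- conditioned_modality(ph)
        xp <- df[[dv]][df$phase == ph & df$modality == m & df$cs_type == "CSplus"]
        xm <- df[[dv]][df$phase == ph & df$modality == m & df$cs_type == "CSminus"]
        pt <- paired_t(xp, xm)
        bf <- jzs_bf10(pt$t, pt$n)
        tt[[ph]] <- data.frame(measure = label, phase = ph,
                               contrast = sprintf("%s CS+ vs CS-", m),
                               t = pt$t, df = pt$df, p = pt$p, d = pt$d,
                               bf10 = bf$bf10, stringsAsFactors = FALSE)
      }
      list(anova = an, tests = do.call(rbind, tt))
    }
    if (config$scr) {
      scr_sorted <- results$scr_means[order(results$scr_means$participant), ]
      stat_tabs$scr <- run_stats(scr_sorted, "mean_scr", "scr")
    }
    stat_tabs$ratings <- run_stats(ratings, "rating", "ratings")
    write_tsv(do.call(rbind, lapply(stat_tabs, `[[`, "tests")),
              file.path(out_dir, "ttests.tsv"))
    results$stats <- stat_tabs
    stage_time$stats <- proc.time()[["elapsed"]] - t1
  }

  ## --- report ------------------------------------------------------------
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  report <- list(
    package_version = as.character(utils::packageVersion("fearcond")),
    seed = seed, n_participants = n_p,
    n_perm = config$n_perm, n_boot = config$n_boot,
    config_hash = fnv1a_hash(as.character(cfg_json)),
    config = jsonlite::fromJSON(cfg_json),
    stage_seconds = stage_time)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$report <- report
  invisible(results)
}
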