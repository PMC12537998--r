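# Orchestration: nested run configuration with schema validation, stage
# sequencing (simulate > preprocess > cluster statistics > decoding >
# behavior), and a machine-readable run report. Config -> report is a pure
# function of the configuration (all randomness is seeded from it).

#' Default pipeline configuration
#'
#' Nested list of every stage's parameters. Defaults follow the analysis
#' conventions the package implements: 0.2-20 Hz order-4 zero-phase
#' Butterworth band-pass, 5/3 SD channel/epoch rejection, 100 Hz decoding
#' rate, 5x20 stratified CV, 5000-replicate bootstraps, 200 ms minimum
#' significant duration, alpha = 0.05.
#'
#' @param seed Root seed for every stochastic stage.
#' @return A `run_config` list with components `simulation`, `preprocess`,
#'   `cluster`, `decoding`, `behavior`.
#' @export
default_config <- function(seed = 20251020) {
  structure(list(
    seed = seed,
    simulation = list(
      n_subjects = 13, n_trials_per_condition = 100, oddball_ratio = 0.20,
      isi_range = c(2.0, 2.4), fs = 250, epoch_window = c(-0.2, 1.0),
      p300_amplitude = c(underload = 8, overload = 4, flow = 1),
      p300_latency = 0.45, p300_width = 0.1, noise_slope = 1.0,
      noise_sd = 8, blink_rate = 12, ecg_rate = 70,
      from_continuous = FALSE),
    preprocess = list(low = 0.2, high = 20, order = 4, tmin = -0.2,
                      tmax = 1.0, channel_z = 5, epoch_z = 3, csd = TRUE,
                      spline_m = 4, spline_lambda = 1e-5,
                      head_radius = 0.085),
    cluster = list(n_perm = 1024, threshold = NA, adjacency_threshold = 0.78,
                   run_contrasts = TRUE),
    decoding = list(target_fs = 100, n_splits = 5, n_repeats = 20,
                    n_boot = 5000, min_duration = 0.200, level = 0.95),
    behavior = list(alpha = 0.05)),
    class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Merges user settings over [default_config()] and rejects unknown keys at
#' any nesting level.
#'
#' @param config Possibly partial nested list.
#' @param seed Root seed used when `config` does not carry one.
#' @return A complete validated `run_config`.
#' @export
validate_config <- function(config = list(), seed = 20251020) {
  base <- default_config(seed)
  merge_level <- function(def, usr, path) {
    extra <- setdiff(names(usr), names(def))
    if (length(extra)) {
      stop("unknown config key(s): ",
           paste(paste0(path, extra), collapse = ", "))
    }
    for (nm in names(usr)) {
      def[[nm]] <- if (is.list(def[[nm]]) && is.list(usr[[nm]])) {
        merge_level(def[[nm]], usr[[nm]], paste0(path, nm, "."))
      } else usr[[nm]]
    }
    def
  }
  out <- merge_level(unclass(base), unclass(config), "")
  class(out) <- "run_config"
  out
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with (a subset of) the [default_config()] keys.
#' @param seed Root seed fallback.
#' @return Validated `run_config`.
#' @export
read_config_yaml <- function(path, seed = 20251020) {
  usr <- yaml::read_yaml(path)
  # YAML lists arrive unnamed-numeric-safe; coerce known vector fields
  if (!is.null(usr$simulation$p300_amplitude)) {
    usr$simulation$p300_amplitude <- unlist(usr$simulation$p300_amplitude)
  }
  validate_config(usr, seed = seed)
}

.sim_config_from_run <- function(config) {
  s <- config$simulation
  simulation_config(
    n_subjects = s$n_subjects,
    n_trials_per_condition = s$n_trials_per_condition,
    oddball_ratio = s$oddball_ratio, isi_range = s$isi_range, fs = s$fs,
    epoch_window = s$epoch_window, p300_amplitude = s$p300_amplitude,
    p300_latency = s$p300_latency, p300_width = s$p300_width,
    noise_slope = s$noise_slope, noise_sd = s$noise_sd,
    blink_rate = s$blink_rate, ecg_rate = s$ecg_rate,
    seed = config$seed)
}

#' Run the full analysis pipeline
#'
#' Executes simulate > preprocess > cluster statistics > decoding >
#' behavioral statistics on a synthetic study and returns a
#' machine-readable report. With identical configuration (including the
#' seed) the report is reproducible.
#'
#' Stages: per subject and condition, oddball-locked clean epochs are
#' obtained either directly from the epoch simulator (baseline-corrected,
#' CSD-transformed) or through the full continuous chain
#' ([simulate_continuous_session()] + [preprocess_session()]). Cluster
#' statistics run on the subjects x conditions evoked array (F main effect,
#' plus pairwise t contrasts); decoding runs subject-wise at the decoding
#' rate with scores pooled across subjects for the bootstrap; behavioral
#' measures get the two-factor GG-corrected ANOVA and Tukey post hocs.
#'
#' @param config A `run_config` (see [validate_config()]); partial lists
#'   are merged over the defaults.
#' @param out_dir Optional directory; when given, the report (JSON) and
#'   per-contrast topography TSVs are written there.
#' @return A `run_report` list: `config`, `cluster`, `decoding` (per
#'   contrast: intervals, peak time/score, mean score), `behavior`,
#'   `version`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  config <- if (inherits(config, "run_config")) config else
    validate_config(config)
  montage <- build_standard_montage()
  adjacency <- compute_adjacency(
    montage, threshold = config$cluster$adjacency_threshold)
  sim <- .sim_config_from_run(config)
  conditions <- c("underload", "flow", "overload")
  pp <- config$preprocess

  # --- simulate + preprocess ----------------------------------------------
  study <- lapply(seq_len(sim$n_subjects), function(s) {
    out <- lapply(conditions, function(cond) {
      if (isTRUE(config$simulation$from_continuous)) {
        ses <- simulate_continuous_session(sim, cond, subject = s,
                                           montage = montage)
        preprocess_session(ses, montage, low = pp$low, high = pp$high,
                           order = pp$order, tmin = pp$tmin, tmax = pp$tmax,
                           channel_z = pp$channel_z, epoch_z = pp$epoch_z,
                           csd = pp$csd)$epochs
      } else {
        ep <- baseline_correct(simulate_epochs(sim, cond, subject = s,
                                               montage = montage),
                               window = c(pp$tmin, 0))
        if (pp$csd) {
          ep <- surface_laplacian_csd(ep, montage, m = pp$spline_m,
                                      lambda = pp$spline_lambda,
                                      head_radius = pp$head_radius)
        }
        ep
      }
    })
    names(out) <- conditions
    out
  })

  # --- cluster statistics --------------------------------------------------
  ev0 <- evoked(study[[1]][[1]])
  group <- array(0, dim = c(sim$n_subjects, length(conditions),
                            nrow(ev0), ncol(ev0)))
  for (s in seq_len(sim$n_subjects)) {
    for (ci in seq_along(conditions)) {
      group[s, ci, , ] <- evoked(study[[s]][[ci]])
    }
  }
  thr <- config$cluster$threshold
  if (is.null(thr) || is.na(thr)) thr <- NULL
  fres <- permutation_cluster_test(group, design = "F",
                                   n_perm = config$cluster$n_perm,
                                   threshold = thr, adjacency = adjacency,
                                   seed = derive_seed(config$seed, 41))
  cluster_rep <- list(F_main = .cluster_digest(fres))
  if (isTRUE(config$cluster$run_contrasts)) {
    pairs <- utils::combn(length(conditions), 2)
    for (i in seq_len(ncol(pairs))) {
      sel <- pairs[, i]
      tres <- permutation_cluster_test(
        group[, sel, , , drop = FALSE], design = "t",
        n_perm = config$cluster$n_perm, threshold = thr,
        adjacency = adjacency, seed = derive_seed(config$seed, 43, i))
      cluster_rep[[paste(conditions[sel], collapse = "_vs_")]] <-
        .cluster_digest(tres)
    }
  }

  # --- decoding ------------------------------------------------------------
  dec <- config$decoding
  study_ds <- lapply(study, function(subj) {
    lapply(subj, downsample_epochs, target_fs = dec$target_fs)
  })
  times_ds <- study_ds[[1]][[1]]$times
  ev_ds <- lapply(seq_along(conditions), function(ci) {
    arr <- array(0, dim = c(sim$n_subjects, length(montage$labels),
                            length(times_ds)))
    for (s in seq_len(sim$n_subjects)) {
      arr[s, , ] <- evoked(study_ds[[s]][[ci]])
    }
    arr
  })
  names(ev_ds) <- conditions
  mask <- univariate_ci_mask(ev_ds, n_boot = dec$n_boot, level = dec$level,
                             seed = derive_seed(config$seed, 47))
  contrasts <- list(c("underload", "flow"), c("underload", "overload"),
                    c("flow", "overload"), conditions)
  decoding_rep <- list()
  for (ct in contrasts) {
    nm <- paste(ct, collapse = "_vs_")
    res <- decode_group(study_ds, ct, n_splits = dec$n_splits,
                        n_repeats = dec$n_repeats, n_boot = dec$n_boot,
                        level = dec$level, min_duration = dec$min_duration,
                        seed = derive_seed(config$seed, 53, nchar(nm)),
                        mask = mask, evoked_by_condition = ev_ds[ct])
    decoding_rep[[nm]] <- res$summary
    if (!is.null(out_dir)) {
      .write_topomap_tsv(res, montage,
                         file.path(out_dir, paste0("patterns_", nm, ".tsv")))
    }
  }

  # --- behavior ------------------------------------------------------------
  btab <- simulate_behavior(sim, seed = derive_seed(config$seed, 59))
  behavior_rep <- lapply(unique(btab$measure), function(ms) {
    st <- behavior_stats(btab, ms, alpha = config$behavior$alpha)
    list(anova = st$anova, posthoc = st$posthoc)
  })
  names(behavior_rep) <- unique(btab$measure)

  report <- structure(list(config = unclass(config), cluster = cluster_rep,
                           decoding = decoding_rep, behavior = behavior_rep,
                           mask_fraction = mean(mask),
                           version = as.character(
                             utils::packageVersion("flowprobe"))),
                      class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(.report_json(report),
                         file.path(out_dir, "report.json"), digits = 10,
                         auto_unbox = TRUE, null = "null",
                         dataframe = "rows")
  }
  report
}

.cluster_digest <- function(res) {
  list(n_clusters = length(res$clusters),
       p_values = res$p_values, masses = res$masses,
       n_channels = vapply(res$clusters, function(m)
         length(unique(m[, "channel"])), 1L),
       min_p = if (length(res$p_values)) min(res$p_values) else NA_real_,
       threshold = res$threshold, method = res$method)
}

#' Group-level time-resolved decoding of one contrast
#'
#' Runs [sliding_decode()] subject-wise, pools the fold scores across
#' subjects per time point, bootstraps decoder and dummy identically, and
#' applies the minimum-duration significance criterion. Patterns are
#' averaged across subjects.
#'
#' @param study_ds List (per subject) of named condition [eeg_epochs]
#'   lists, already at the decoding sampling rate.
#' @param contrast Condition names (2 = AUC, 3 = weighted F1).
#' @param n_splits,n_repeats CV scheme per subject.
#' @param n_boot,level Bootstrap settings.
#' @param min_duration Significance duration criterion (s).
#' @param seed RNG seed.
#' @param mask,evoked_by_condition Optional spatiotemporal mask and evoked
#'   arrays for the peak-region summary.
#' @return List with `scores` (pooled folds x time), `dummy`, `boot`,
#'   `dummy_boot`, `intervals`, `patterns`, `peak`, `summary`.
#' @export
decode_group <- function(study_ds, contrast, n_splits = 5, n_repeats = 20,
                         n_boot = 5000, level = 0.95, min_duration = 0.200,
                         seed = 1, mask = NULL,
                         evoked_by_condition = NULL) {
  n_sub <- length(study_ds)
  times <- study_ds[[1]][[contrast[1]]]$times
  all_scores <- NULL
  all_dummy <- NULL
  pat_sum <- NULL
  for (s in seq_len(n_sub)) {
    res <- sliding_decode(study_ds[[s]], contrast, n_splits = n_splits,
                          n_repeats = n_repeats,
                          seed = derive_seed(seed, 2, s))
    y <- rep(contrast, vapply(study_ds[[s]][contrast], n_trials, 1L))
    dm <- dummy_scores(y, length(times), n_splits = n_splits,
                       n_repeats = n_repeats, seed = derive_seed(seed, 3, s))
    all_scores <- rbind(all_scores, res$scores)
    all_dummy <- rbind(all_dummy, dm)
    pat_sum <- if (is.null(pat_sum)) res$patterns / n_sub else
      pat_sum + res$patterns / n_sub
  }
  boot <- bootstrap_ci(all_scores, n_boot = n_boot, level = level,
                       seed = derive_seed(seed, 5))
  dummy_boot <- bootstrap_ci(all_dummy, n_boot = n_boot, level = level,
                             seed = derive_seed(seed, 7))
  intervals <- significant_intervals(boot, dummy_boot, times,
                                     min_duration = min_duration)
  peak <- peak_summary(boot, intervals, times, patterns = pat_sum,
                       evoked_by_condition = evoked_by_condition,
                       mask = mask, seed = derive_seed(seed, 11))
  sig_idx <- unlist(attr(intervals, "indices"))
  list(scores = all_scores, dummy = all_dummy, boot = boot,
       dummy_boot = dummy_boot, intervals = intervals, patterns = pat_sum,
       times = times, contrast = contrast, peak = peak,
       summary = list(
         contrast = paste(contrast, collapse = "_vs_"),
         metric = if (length(contrast) == 2) "auc" else "weighted_f1",
         n_folds = nrow(all_scores),
         intervals = unclass(intervals[, , drop = FALSE]),
         onset = if (nrow(intervals)) intervals[1, "start"] else NA_real_,
         peak_time = peak$peak_time, peak_score = peak$peak_score,
         mean_sig_score = if (length(sig_idx))
           mean(boot$mean[sig_idx]) else NA_real_,
         mean_dummy = mean(dummy_boot$mean)))
}

.write_topomap_tsv <- function(res, montage, path) {
  pk <- res$peak$peak_patterns
  if (is.null(pk)) return(invisible(NULL))
  pk <- if (is.null(dim(pk))) matrix(pk, nrow = 1) else pk
  df <- data.frame(channel = montage$labels, t(pk))
  names(df)[-1] <- if (nrow(pk) == 1) "pattern" else
    paste0("pattern_", res$contrast)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.report_json <- function(report) {
  rep <- unclass(report)
  rep$decoding <- lapply(rep$decoding, function(d) {
    d$intervals <- if (length(d$intervals)) {
      matrix(d$intervals, ncol = 2,
             dimnames = list(NULL, c("start", "end")))
    } else NULL
    d
  })
  rep
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n cluster stage:\n")
  for (nm in names(x$cluster)) {
    cat(sprintf("  %s: %d cluster(s), min p = %s\n", nm,
                x$cluster[[nm]]$n_clusters,
                format(x$cluster[[nm]]$min_p, digits = 3)))
  }
  cat(" decoding stage:\n")
  for (nm in names(x$decoding)) {
    d <- x$decoding[[nm]]
    cat(sprintf("  %s (%s): peak %.3f at %s s, mean sig %.3f\n", nm,
                d$metric, d$peak_score,
                format(d$peak_time, digits = 3), d$mean_sig_score))
  }
  invisible(x)
}
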