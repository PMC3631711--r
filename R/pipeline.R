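# Per-trial orchestration, cohort-level exclusion rules, aggregation to the
# repeated-measures design, within-subject ANOVA and reporting.

#' Pipeline analysis settings
#'
#' @param fc Gaussian filter cutoff, Hz.
#' @param displacement_threshold_m Primary segmentation threshold, metres.
#' @param threshold_fraction Velocity bound threshold as fraction of peak.
#' @param prominence_fraction Acceleration-peak prominence floor.
#' @param min_endpoint_radius_m Minimum endpoint distance for a stable
#'   pointed angle.
#' @param slow_duration_factor Exclusion rule 1: multiple of the cohort
#'   mean duration.
#' @param slow_duration_floor_s Exclusion rule 1: absolute duration floor
#'   (the long-condition stimulus duration, 2 s).
#' @param target_slope_min Exclusion rule 2: minimum pointed-vs-target
#'   regression slope.
#' @param lateral_cluster_tol_deg Exclusion rule 2: tolerance around +/-90
#'   degrees.
#' @param lateral_cluster_fraction Exclusion rule 2: fraction of endpoints
#'   that must cluster at +/-90 degrees.
#' @param short_trajectory_m Exclusion rule 3: minimum median trajectory
#'   length, metres.
#' @return A named list of settings.
#' @export
pipeline_settings <- function(fc = 5,
                              displacement_threshold_m = 0.02,
                              threshold_fraction = 0.03,
                              prominence_fraction = 0.05,
                              min_endpoint_radius_m = 0.05,
                              slow_duration_factor = 2,
                              slow_duration_floor_s = 2.0,
                              target_slope_min = 0.1,
                              lateral_cluster_tol_deg = 5,
                              lateral_cluster_fraction = 0.9,
                              short_trajectory_m = 0.10) {
  as.list(environment())
}

meta_row <- function(meta) {
  tibble::tibble(
    subject_id = meta$subject_id,
    condition = meta$condition,
    target_azimuth_deg = meta$target_azimuth_deg,
    stimulus_duration_ms = meta$stimulus_duration_ms,
    trial_index = meta$trial_index,
    avatar_shift_deg = meta$avatar_shift_deg
  )
}

na_features <- function() {
  tibble::tibble(
    duration_s = NA_real_, v_peak = NA_real_, v_mean = NA_real_,
    path_length_m = NA_real_, n_acc_peaks_total = NA_real_,
    n_acc_peaks_before_pvp = NA_real_, n_acc_peaks_after_pvp = NA_real_,
    pvp_relative_position = NA_real_,
    head_rom_deg = NA_real_, head_final_yaw_deg = NA_real_,
    head_n_acc_peaks_total = NA_real_, head_n_acc_peaks_before_pvp = NA_real_,
    head_n_acc_peaks_after_pvp = NA_real_,
    head_pvp_relative_position = NA_real_,
    pointed_azimuth_deg = NA_real_, signed_error_deg = NA_real_,
    abs_error_deg = NA_real_
  )
}

#' Analyse one trial end to end
#'
#' Filters and differentiates the hand trajectory, segments the movement
#' (displacement then relative-velocity thresholds), computes hand and head
#' features and the pointing error. Failures (no movement, unstable angle)
#' yield a flagged row rather than an error, so session-level bookkeeping
#' never silently drops trials.
#'
#' @param trial A [trial_record()].
#' @param settings A [pipeline_settings()] list.
#' @return A one-row tibble: metadata, hand/head features, pointing
#'   results, and a `flag` column ("ok", "no_movement" or
#'   "unstable_angle").
#' @export
analyze_trial <- function(trial, settings = pipeline_settings()) {
  stopifnot(inherits(trial, "trial_record"))
  row <- meta_row(trial$meta)
  out <- tryCatch({
    kin <- kinematics(trial$hand, fc = settings$fc)
    win <- primary_segment(trial$hand, trial$start_marker,
                           settings$displacement_threshold_m)
    bounds <- detect_bounds(kin, win, settings$threshold_fraction)
    hf <- hand_features(kin, bounds, settings$prominence_fraction)
    h <- extract_heading(trial$head, fc = settings$fc)
    head_f <- head_features(h, bounds,
                            prominence_fraction = settings$prominence_fraction)
    pa <- pointed_azimuth(kin$p_filt[bounds$i_end, ], trial$start_marker,
                          settings$min_endpoint_radius_m)
    pe <- pointing_errors(pa, trial$meta$target_azimuth_deg)
    dplyr::bind_cols(hf, head_f, pe, tibble::tibble(flag = "ok"))
  },
  error = function(e) {
    flag <- if (grepl("no movement|never left", conditionMessage(e)))
      "no_movement" else if (grepl("unstable", conditionMessage(e)))
        "unstable_angle" else "error"
    dplyr::bind_cols(na_features(), tibble::tibble(flag = flag))
  })
  dplyr::bind_cols(row, out)
}

#' Analyse every trial of one session
#'
#' @param session List with `trials` and `config` (from
#'   [generate_session()] or [load_session()]).
#' @param settings A [pipeline_settings()] list.
#' @param verbose Emit per-trial progress to stderr.
#' @return Tibble, one row per trial, with `group` (condition order) and
#'   `hrtf` factors from the config.
#' @export
analyze_session <- function(session, settings = pipeline_settings(),
                            verbose = FALSE) {
  cfg <- session$config
  grp <- if (identical(cfg$condition_order, CONDITIONS)) "regular" else
    "reversed"
  rows <- lapply(seq_along(session$trials), function(k) {
    if (verbose) {
      message(sprintf("analyzing %s trial %d/%d", cfg$subject_id, k,
                      length(session$trials)))
    }
    analyze_trial(session$trials[[k]], settings)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(group = grp,
                  hrtf = ifelse(cfg$hrtf_individual, "individual", "generic"),
                  .after = "subject_id")
}

#' Analyse a cohort of sessions
#'
#' @param sessions List of sessions (see [generate_cohort()]).
#' @param settings A [pipeline_settings()] list.
#' @param verbose Emit progress to stderr.
#' @return Tibble of per-trial feature rows for the whole cohort.
#' @export
analyze_cohort <- function(sessions, settings = pipeline_settings(),
                           verbose = FALSE) {
  dplyr::bind_rows(lapply(sessions, analyze_session, settings = settings,
                          verbose = verbose))
}

#' Apply the cohort-level subject exclusion rules
#'
#' Three rules, checked in order (a subject is attributed to the first rule
#' it trips):
#' \describe{
#'   \item{slow_indirect}{mean movement duration more than
#'     `slow_duration_factor` times the cohort mean AND longer than
#'     `slow_duration_floor_s` (the long-condition stimulus duration).}
#'   \item{no_target_dependence}{pointed directions do not depend on the
#'     target: regression slope of pointed on target azimuth below
#'     `target_slope_min`, or at least `lateral_cluster_fraction` of
#'     endpoints within `lateral_cluster_tol_deg` of +/-90 degrees.}
#'   \item{short_trajectory}{median trajectory length below
#'     `short_trajectory_m`, which makes the pointed angle unstable.}
#' }
#' The cohort mean duration is computed once over all subjects before any
#' removal, so the outcome does not depend on subject order.
#'
#' @param results Per-trial tibble from [analyze_cohort()].
#' @param settings A [pipeline_settings()] list.
#' @return List with `report` (tibble subject_id, rule for excluded;
#'   attribute-free) , `excluded` (character), `retained` (character), and
#'   `results` (the filtered per-trial tibble).
#' @export
apply_exclusions <- function(results, settings = pipeline_settings()) {
  ok <- results |> dplyr::filter(.data$flag == "ok")
  per_subj <- ok |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      mean_duration = mean(.data$duration_s),
      median_path = stats::median(.data$path_length_m),
      slope = if (stats::var(.data$target_azimuth_deg) > 0)
        stats::coef(stats::lm(pointed_azimuth_deg ~ target_azimuth_deg,
                              data = dplyr::pick(dplyr::everything())))[2]
      else 0,
      lateral_frac = mean(
        pmin(abs(.data$pointed_azimuth_deg - 90),
             abs(.data$pointed_azimuth_deg + 90)) <=
          settings$lateral_cluster_tol_deg),
      .groups = "drop"
    )
  # subjects whose every trial failed count as having no usable data
  all_subjects <- unique(results$subject_id)
  cohort_mean_dur <- mean(per_subj$mean_duration)
  rule_of <- function(sid) {
    row <- per_subj[per_subj$subject_id == sid, ]
    if (nrow(row) == 0) return("short_trajectory")
    if (row$mean_duration > settings$slow_duration_factor * cohort_mean_dur &&
        row$mean_duration > settings$slow_duration_floor_s) {
      return("slow_indirect")
    }
    if (row$slope < settings$target_slope_min ||
        row$lateral_frac >= settings$lateral_cluster_fraction) {
      return("no_target_dependence")
    }
    if (row$median_path < settings$short_trajectory_m) {
      return("short_trajectory")
    }
    NA_character_
  }
  rules <- vapply(all_subjects, rule_of, character(1))
  excluded <- all_subjects[!is.na(rules)]
  report <- tibble::tibble(subject_id = excluded,
                           rule = rules[!is.na(rules)])
  retained <- setdiff(all_subjects, excluded)
  list(report = report, excluded = excluded, retained = retained,
       results = dplyr::filter(results, .data$subject_id %in% retained))
}

FEATURE_COLS <- c(
  "duration_s", "v_peak", "v_mean", "path_length_m", "n_acc_peaks_total",
  "n_acc_peaks_before_pvp", "n_acc_peaks_after_pvp", "pvp_relative_position",
  "head_rom_deg", "head_final_yaw_deg", "head_n_acc_peaks_total",
  "head_n_acc_peaks_before_pvp", "head_n_acc_peaks_after_pvp",
  "head_pvp_relative_position", "pointed_azimuth_deg", "signed_error_deg",
  "abs_error_deg"
)

#' Aggregate trials to the subject x condition x target design
#'
#' Cell means of every feature over the non-flagged trials of each subject,
#' condition and target direction, with the grouping factors (condition
#' order, HRTF type) carried along. Missing cells for retained subjects
#' trigger a warning.
#'
#' @param results Per-trial tibble (after exclusions).
#' @return Tibble, one row per subject x condition x target.
#' @export
build_design_table <- function(results) {
  ok <- dplyr::filter(results, .data$flag == "ok")
  if (nrow(ok) == 0) stop("build_design_table: no analysable trials")
  tab <- ok |>
    dplyr::group_by(.data$subject_id, .data$group, .data$hrtf,
                    .data$condition, .data$target_azimuth_deg) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     dplyr::across(dplyr::all_of(FEATURE_COLS), mean),
                     .groups = "drop")
  n_cells <- length(CONDITIONS) * length(TARGET_AZIMUTHS)
  counts <- tab |> dplyr::count(.data$subject_id)
  short <- counts$subject_id[counts$n < n_cells]
  if (length(short) > 0) {
    warning("build_design_table: missing design cells for subject(s) ",
            paste(short, collapse = ", "))
  }
  tab
}

#' Repeated-measures ANOVA on one dependent variable
#'
#' Two within-subject factors (condition, 4 levels; target direction,
#' 5 levels) on the subject-level cell means, fitted as a univariate
#' mixed-model ANOVA with subject error strata
#' (`Error(subject/(condition*target))`), optionally crossed with
#' between-subject grouping factors. Degrees of freedom are the classical
#' uncorrected ones. Post-hoc Bonferroni-adjusted paired comparisons are
#' reported for all condition pairs.
#'
#' Subjects with incomplete cells are dropped with a warning (classical
#' repeated-measures ANOVA requires balance); a dependent variable that is
#' constant across all cells returns F = 0, p = 1 for every effect.
#'
#' @param table Design table from [build_design_table()].
#' @param dv Name of the dependent variable column.
#' @param between Optional character vector of between-subject factor
#'   columns ("group", "hrtf").
#' @return List of class `rm_anova` with `effects` (tibble: effect, df1,
#'   df2, F, p) and `posthoc_condition` (tibble of Bonferroni-adjusted
#'   paired t comparisons).
#' @export
rm_anova <- function(table, dv, between = NULL) {
  stopifnot(dv %in% names(table))
  n_cells <- length(CONDITIONS) * length(TARGET_AZIMUTHS)
  counts <- table |> dplyr::count(.data$subject_id)
  keep <- counts$subject_id[counts$n == n_cells]
  if (length(keep) < length(counts$subject_id)) {
    warning("rm_anova: dropping incomplete subject(s): ",
            paste(setdiff(counts$subject_id, keep), collapse = ", "))
  }
  if (length(keep) < 2) stop("rm_anova: need >= 2 complete subjects")
  d <- table |>
    dplyr::filter(.data$subject_id %in% keep) |>
    dplyr::transmute(
      subject = factor(.data$subject_id),
      condition = factor(.data$condition, levels = CONDITIONS),
      target = factor(.data$target_azimuth_deg, levels = TARGET_AZIMUTHS),
      group = factor(.data$group), hrtf = factor(.data$hrtf),
      y = .data[[dv]]
    )
  if (any(table(d$subject, d$condition, d$target) != 1)) {
    stop("rm_anova: unbalanced table (need one cell mean per subject x ",
         "condition x target)")
  }
  within_terms <- "condition * target"
  if (stats::var(d$y) < 1e-24) {
    eff_names <- c("condition", "target", "condition:target")
    ns <- length(keep)
    dfs <- c(3, 4, 12)
    effects <- tibble::tibble(
      effect = eff_names, df1 = dfs, df2 = dfs * (ns - 1),
      F = 0, p = 1
    )
  } else {
    fml <- stats::as.formula(paste(
      "y ~", paste(c(within_terms, between), collapse = " * "),
      "+ Error(subject/(condition*target))"))
    fit <- stats::aov(fml, data = d)
    effects <- summary(fit) |>
      unlist_aov_summary()
  }
  cond_means <- d |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop")
  ph <- posthoc_bonferroni(cond_means)
  structure(list(dv = dv, effects = effects, posthoc_condition = ph),
            class = "rm_anova")
}

unlist_aov_summary <- function(sm) {
  rows <- list()
  for (stratum in sm) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    terms <- trimws(rownames(tab))
    resid_df <- tab$Df[terms == "Residuals"]
    for (i in seq_len(nrow(tab))) {
      if (terms[i] == "Residuals" || is.na(tab$`F value`[i])) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        effect = terms[i], df1 = tab$Df[i], df2 = resid_df,
        F = tab$`F value`[i], p = tab$`Pr(>F)`[i]
      )
    }
  }
  dplyr::bind_rows(rows)
}

posthoc_bonferroni <- function(cond_means) {
  levs <- levels(cond_means$condition)
  pairs <- utils::combn(levs, 2)
  wide <- cond_means |>
    tidyr::pivot_wider(names_from = "condition", values_from = "y")
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diffs <- wide[[a]] - wide[[b]]
    if (stats::sd(diffs) < 1e-12) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(diffs)
    }
    tibble::tibble(pair = paste(a, b, sep = "-"),
                   mean_diff = mean(diffs),
                   t = unname(tt$statistic), p_raw = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on %s\n", x$dv))
  print(as.data.frame(x$effects), row.names = FALSE)
  cat("Post-hoc Bonferroni (condition pairs):\n")
  print(as.data.frame(x$posthoc_condition), row.names = FALSE)
  invisible(x)
}

#' Write the standard report files for an analysed cohort
#'
#' Emits three CSVs (per-trial features, design table, condition summary)
#' and four figures (absolute/signed pointing error, trajectory length,
#' heading ROM and final angle, peak-velocity-position histograms).
#'
#' @param results Per-trial tibble from [analyze_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
report <- function(results, out_dir) {
  if (nrow(results) == 0) stop("report: empty results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- build_design_table(results)
  cond_sum <- tab |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(FEATURE_COLS), mean),
                     .groups = "drop")
  files <- file.path(out_dir, c(
    "trial_features.csv", "design_table.csv", "condition_summary.csv",
    "fig_pointing_error.png", "fig_trajectory_length.png",
    "fig_heading.png", "fig_pvp_position.png"))
  readr::write_csv(results, files[1])
  readr::write_csv(tab, files[2])
  readr::write_csv(cond_sum, files[3])

  ok <- dplyr::filter(results, .data$flag == "ok")
  ci95 <- function(x) {
    if (length(x) < 2) return(NA_real_)
    stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
  }
  err_sum <- ok |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(m = mean(.data$abs_error_deg),
                     ci = ci95(.data$abs_error_deg), .groups = "drop")
  g1 <- ggplot2::ggplot(err_sum, ggplot2::aes(.data$condition, .data$m)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$ci,
                                        ymax = .data$m + .data$ci),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(y = "absolute pointing error (deg)", x = "condition")
  ggplot2::ggsave(files[4], g1, width = 5, height = 4, dpi = 120)
  len_sum <- ok |>
    dplyr::group_by(.data$condition, .data$target_azimuth_deg) |>
    dplyr::summarise(m = mean(.data$path_length_m), .groups = "drop")
  g2 <- ggplot2::ggplot(len_sum,
                        ggplot2::aes(factor(.data$target_azimuth_deg),
                                     .data$m, fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "target azimuth (deg)", y = "trajectory length (m)")
  ggplot2::ggsave(files[5], g2, width = 6, height = 4, dpi = 120)
  rom_sum <- ok |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(m = mean(.data$head_rom_deg),
                     ci = ci95(.data$head_rom_deg), .groups = "drop")
  g3 <- ggplot2::ggplot(rom_sum, ggplot2::aes(.data$condition, .data$m)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$ci,
                                        ymax = .data$m + .data$ci),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(y = "heading range of motion (deg)", x = "condition")
  ggplot2::ggsave(files[6], g3, width = 5, height = 4, dpi = 120)
  pvp_long <- dplyr::bind_rows(
    dplyr::transmute(ok, condition = .data$condition, effector = "hand",
                     rel = .data$pvp_relative_position),
    dplyr::transmute(ok, condition = .data$condition, effector = "head",
                     rel = .data$head_pvp_relative_position))
  g4 <- ggplot2::ggplot(pvp_long, ggplot2::aes(.data$rel,
                                               fill = .data$effector)) +
    ggplot2::geom_histogram(binwidth = 0.1, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "peak-velocity relative position")
  ggplot2::ggsave(files[7], g4, width = 7, height = 5, dpi = 120)
  invisible(files)
}
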