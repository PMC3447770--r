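#' Run the full lesioning study
#'
#' Trains `n_trials` networks, then runs the per-type degradation experiment
#' for all six lesionable cell types, the reduced-granule variant (granule
#' layer scaled to 10%), and size-weighted random degeneration; fits linear
#' and logarithmic trends to every curve; checks the proximity ordering
#' (whether Purkinje-cell removal degrades performance more than any other
#' type at maximal removal); runs the inter-stimulus-interval sweep; and
#' writes all tables to `output_dir`. The trained networks are shared across
#' the per-type experiments — for a given trial seed, the trained state is
#' identical whichever group is subsequently lesioned.
#'
#' @param config A `microzone_config`.
#' @param n_trials Trials per curve (reference study: 100).
#' @param base_seed Master seed; identical seeds give byte-identical outputs.
#' @param output_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param fast If TRUE, use 10 trials and scale the granule layer to 330
#'   cells — a reduced-size run with the same structure.
#' @param schedule_mode Passed to [build_schedule()]; `"table"` reproduces
#'   the printed removal totals.
#' @param run_hull Include the inter-stimulus-interval sweep.
#' @param final_only Measure only each schedule's final step (faster; enough
#'   for the summary table and ordering check, but not for trend fits, which
#'   are then skipped).
#' @return An object of class `experiment_report`.
#' @export
run_full_study <- function(config = default_config(), n_trials = 100L,
                           base_seed = 1L, output_dir = NULL, fast = FALSE,
                           schedule_mode = "table", run_hull = TRUE,
                           final_only = FALSE) {
  if (fast) {
    n_trials <- 10L
    config <- scale_group(config, "granule", 330 / group_count(config, "granule"))
  }
  groups <- c("mossy_fibers", "climbing_fibers", "granule", "golgi",
              "basket", "purkinje")
  fits <- lapply(seq_len(n_trials), function(t) {
    fit_microzone(config, seed = derive_seed(base_seed, t))
  })
  curves <- list()
  for (g in groups) {
    curves[[g]] <- run_degradation(config, g, n_trials, base_seed,
                                   mode = schedule_mode, fits = fits,
                                   final_only = final_only)
  }
  small_cfg <- scale_group(config, "granule", 0.1)
  curves[["granule_small"]] <- run_degradation(
    small_cfg, "granule", n_trials, derive_seed(base_seed, 71L),
    mode = schedule_mode, final_only = final_only)
  curves[["random"]] <- run_random_degeneration(config, n_trials, base_seed,
                                                fits = fits,
                                                final_only = final_only)
  trends <- if (final_only) NULL else {
    lapply(curves, function(cv) {
      if (length(cv$fractions) >= 4) return(fit_trend(cv))
      # single-step schedules (e.g. climbing fibers) admit no trend fit
      structure(list(group = cv$group, degenerate = TRUE, linear = NULL,
                     logarithmic = NULL, classification = NA_character_),
                class = "trend_fit")
    })
  }
  final_err <- vapply(curves, function(cv) {
    cv$mean_error[length(cv$mean_error)]
  }, 0)
  intrinsic <- c("granule", "golgi", "basket", "purkinje")
  ordering <- list(
    final_error = final_err,
    purkinje_greatest = all(final_err[["purkinje"]] >
                              final_err[setdiff(names(final_err),
                                                c("purkinje", "random"))]),
    proximity_rank = names(sort(final_err[intrinsic], decreasing = TRUE))
  )
  hull <- if (run_hull) {
    run_hull_test(config, seed = derive_seed(base_seed, 5L))
  } else NULL
  summary_tab <- do.call(rbind, lapply(names(curves), function(g) {
    cv <- curves[[g]]
    n <- round(cv$counts[length(cv$counts)] / max(cv$fractions))
    data.frame(group = g, total = n,
               removed = cv$counts[length(cv$counts)],
               remaining = n - cv$counts[length(cv$counts)],
               error_pct = cv$mean_error[length(cv$mean_error)],
               excluded_trials = cv$n_excluded)
  }))
  report <- structure(
    list(curves = curves, trends = trends, ordering = ordering,
         hull = hull, summary = summary_tab,
         meta = list(n_trials = n_trials, base_seed = as.integer(base_seed),
                     fast = fast, schedule_mode = schedule_mode,
                     config_hash = config_hash(config),
                     timestamp = NULL)),
    class = "experiment_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

group_count <- function(config, group) {
  nms <- vapply(config$groups, `[[`, "", "name")
  config$groups[[match(group, nms)]]$count
}

#' Write an experiment report to disk
#'
#' Emits per-curve CSVs (per-trial and means), the trend-fit table, the
#' summary table (group, total, removed, remaining, resulting error %), the
#' ISI sweep, and a JSON manifest with seeds and the config hash.
#'
#' @param report An `experiment_report`.
#' @param output_dir Directory to write into.
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  dir.create(file.path(output_dir, "curves"), recursive = TRUE,
             showWarnings = FALSE)
  for (g in names(report$curves)) {
    write_degradation_curve(
      report$curves[[g]],
      file.path(output_dir, "curves", paste0(g, ".csv")),
      file.path(output_dir, "curves", paste0(g, "_means.csv")))
  }
  if (!is.null(report$trends)) {
    tr <- do.call(rbind, lapply(report$trends, function(x) {
      if (isTRUE(x$degenerate)) {
        data.frame(group = x$group, classification = NA, linear_r2 = NA,
                   log_r2 = NA, linear_slope = NA, log_coefficient = NA)
      } else {
        data.frame(group = x$group, classification = x$classification,
                   linear_r2 = x$linear$r_squared,
                   log_r2 = x$logarithmic$r_squared,
                   linear_slope = x$linear$slope,
                   log_coefficient = x$logarithmic$coefficient)
      }
    }))
    utils::write.csv(tr, file.path(output_dir, "trends.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$summary, file.path(output_dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$hull)) {
    hl <- report$hull
    hdf <- data.frame(
      checkpoint = rep(rownames(hl$strength), each = length(hl$isi_grid)),
      isi = rep(hl$isi_grid, nrow(hl$strength)),
      strength = as.vector(t(hl$strength)),
      error_pct = as.vector(t(hl$error_pct)),
      reference = rep(hl$reference, nrow(hl$strength)))
    utils::write.csv(hdf, file.path(output_dir, "hull.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    meta = report$meta,
    ordering = report$ordering,
    hull_divergence = if (!is.null(report$hull)) report$hull$divergence,
    curves = lapply(report$curves, function(cv) {
      list(group = cv$group, base_seed = cv$base_seed,
           n_trials = cv$n_trials, n_excluded = cv$n_excluded,
           max_fraction = max(cv$fractions))
    })
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Microzone lesioning study: %d trials, seed %d%s\n",
              x$meta$n_trials, x$meta$base_seed,
              if (x$meta$fast) " (fast mode)" else ""))
  print(x$summary, row.names = FALSE)
  cat(sprintf("Purkinje degradation greatest: %s\n",
              x$ordering$purkinje_greatest))
  if (!is.null(x$hull)) {
    cat("ISI-sweep divergence (%):",
        paste(sprintf("%.1f", x$hull$divergence), collapse = ", "), "\n")
  }
  invisible(x)
}
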