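# report assembly: each run_* function drives one pipeline stage end to end,
# writing CSV/JSON payloads that are byte-identical across reruns with the
# same inputs (no timestamps in payloads).

read_responses <- function(responses) {
  if (is.character(responses)) {
    if (!file.exists(responses)) {
      abort_config(sprintf("responses file '%s' does not exist.", responses))
    }
    responses <- readr::read_csv(responses, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.data.frame(responses) || !nrow(responses)) {
    abort_validation("responses are empty or not tabular.")
  }
  responses
}

run_log <- function(out_dir, command, config, seed) {
  log <- list(
    command = command,
    config_hash = rlang::hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("pelletr")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(log, file.path(out_dir, paste0(command, "_log.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  log
}

round_str <- function(x, digits) formatC(round(x, digits), format = "f", digits = digits)

#' Run the screening stage and write its report
#'
#' Reads replicate responses (CSV path or data frame), runs [pb_screen()]
#' against the given design, and writes `anova.csv` (per-factor effect, SS,
#' MS, F, p, share, significance), `screen_report.json` (full-precision values
#' plus printed-precision strings, significance flags and shares) and a run
#' log with the configuration hash.
#'
#' @param responses CSV path or data frame (`trial` + replicate columns).
#' @param design Two-level `doe_design` (default the built-in 12-run screen).
#' @param alpha Significance level (default 0.05).
#' @param dummy Dummy column symbol (default `"X11"`).
#' @param out_dir Output directory (created if missing).
#' @param seed Recorded in the log for provenance (the stage is
#'   deterministic).
#' @return The `pb_screen` fit, invisibly.
#' @export
run_screen <- function(responses, design = pb12_design(), alpha = 0.05,
                       dummy = "X11", out_dir = ".", seed = NULL) {
  responses <- read_responses(responses)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- pb_screen(design, responses, dummy = dummy, alpha = alpha)
  tab <- tidy(fit)
  readr::write_csv(tab, file.path(out_dir, "anova.csv"))
  real <- tab[!tab$is_dummy, ]
  report <- list(
    analysis = "pb_screen",
    alpha = alpha, dummy = dummy, f_critical = fit$f_critical,
    significant = as.list(fit$significant),
    effects = as.list(stats::setNames(tab$effect, tab$factor)),
    shares_percent = as.list(stats::setNames(real$share, real$factor)),
    rounded = list(
      effect = as.list(stats::setNames(round_str(tab$effect, 3), tab$factor)),
      ss = as.list(stats::setNames(round_str(tab$ss, 3), tab$factor)),
      f = as.list(stats::setNames(round_str(tab$f, 1), tab$factor)),
      p = as.list(stats::setNames(round_str(tab$p, 3), tab$factor)),
      share_percent = as.list(stats::setNames(round_str(real$share, 0), real$factor))
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "screen_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_log(out_dir, "screen",
          list(design = design_codes(design), alpha = alpha, dummy = dummy),
          seed)
  invisible(fit)
}

#' Run the Taguchi optimization stage and write its report
#'
#' Runs [taguchi_sn()] on replicate responses (or precomputed per-trial S/N
#' ratios) and writes `taguchi.csv` (trial compositions, biomass and S/N),
#' `taguchi_summary.csv` (level means, SS, contributions, optimal levels),
#' `optimize_report.json` and a run log.
#'
#' @param responses CSV path or data frame (`trial` + replicate columns), or
#'   `NULL` when `sn` is given.
#' @param sn Optional precomputed per-trial S/N ratios.
#' @param design Three-level `doe_design` (default [l9_design()]).
#' @param out_dir Output directory.
#' @param seed Recorded in the log.
#' @return The `taguchi_fit`, invisibly.
#' @export
run_optimize <- function(responses = NULL, sn = NULL, design = l9_design(),
                         out_dir = ".", seed = NULL) {
  if (!is.null(responses)) responses <- read_responses(responses)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(responses) && nrow(responses) != nrow(design)) {
    abort_validation(sprintf("expected %d trials, got %d.", nrow(design), nrow(responses)))
  }
  fit <- taguchi_sn(design, responses = responses, sn = sn)
  recipe <- apply_factor_levels(design)
  trial_tbl <- dplyr::left_join(recipe, fit$trials, by = "trial")
  readr::write_csv(trial_tbl, file.path(out_dir, "taguchi.csv"))
  summary_tbl <- dplyr::left_join(
    tidyr::pivot_wider(fit$level_means, names_from = "level",
                       values_from = "sn_mean", names_prefix = "level_"),
    fit$anova, by = "factor")
  summary_tbl$optimal_level <- as.integer(fit$optimum[summary_tbl$factor])
  readr::write_csv(summary_tbl, file.path(out_dir, "taguchi_summary.csv"))
  report <- list(
    analysis = "taguchi_sn",
    grand_mean_sn = fit$grand_mean, sst = fit$sst,
    optimum = fit$optimum_label, predicted_sn = fit$predicted_sn,
    approximate_sn = fit$approximate,
    contributions_percent = as.list(stats::setNames(fit$anova$contribution,
                                                    fit$anova$factor)),
    rounded = list(
      sst = round_str(fit$sst, 2),
      predicted_sn = round_str(fit$predicted_sn, 2),
      contribution_percent = as.list(stats::setNames(
        round_str(fit$anova$contribution, 0), fit$anova$factor))
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "optimize_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_log(out_dir, "optimize", list(design = design_codes(design)), seed)
  invisible(fit)
}

#' Run pellet morphometry over one or more images and write reports
#'
#' Segments and measures each image, applies the size/roundness filter,
#' writes one `<image>_particles.csv` per image, and pools all filtered
#' particles into `morph_summary.json` (per-image counts plus pooled count,
#' mean +/- SD Feret diameter, CU, five-number summary and outliers). A blank
#' image contributes zero particles with a warning; if the pool is empty the
#' summary fields are null.
#'
#' @param images Character vector of image paths, or a (optionally named)
#'   list of numeric matrices.
#' @param scale Pixel scale in mm per pixel.
#' @param threshold,polarity,fill_holes Passed to [segment()].
#' @param min_size,roundness Passed to [filter_particles()].
#' @param out_dir Output directory.
#' @param seed Recorded in the log.
#' @return List with `particles` (named list of filtered `particle_set`s) and
#'   `summary` (`morph_summary` or `NULL`), invisibly.
#' @export
run_morph <- function(images, scale = 1, threshold = "otsu",
                      polarity = "dark", fill_holes = TRUE,
                      min_size = 0.01, roundness = c(0.1, 1),
                      out_dir = ".", seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(images)) {
    names(images) <- names(images) %||% tools::file_path_sans_ext(basename(images))
    mats <- lapply(images, read_pellet_image)
  } else {
    if (is.matrix(images)) images <- list(images)
    mats <- images
    names(mats) <- names(mats) %||% paste0("image_", seq_along(mats))
  }
  sets <- purrr::imap(mats, function(m, nm) {
    labs <- segment(m, threshold = threshold, polarity = polarity,
                    fill_holes = fill_holes)
    ps <- measure_particles(labs, scale = scale, image_id = nm)
    ps <- filter_particles(ps, min_size = min_size, roundness = roundness)
    readr::write_csv(
      dplyr::select(tibble::as_tibble(ps), "id", "area", "perimeter",
                    "feret", "circularity"),
      file.path(out_dir, paste0(nm, "_particles.csv")))
    ps
  })
  pooled <- dplyr::bind_rows(purrr::map(sets, tibble::as_tibble))
  summary <- NULL
  if (nrow(pooled)) {
    summary <- morph_summary(pooled)
  } else {
    warn("no particles across all images; pooled summary is null.")
  }
  report <- list(
    analysis = "morphometry",
    pixel_scale_mm = scale,
    filter = list(min_size = min_size, roundness = roundness),
    per_image_counts = purrr::map(sets, nrow),
    pooled = if (is.null(summary)) NULL else {
      g <- glance(summary)
      c(as.list(g), list(outliers = summary$outliers))
    }
  )
  jsonlite::write_json(report, file.path(out_dir, "morph_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  run_log(out_dir, "morph",
          list(scale = scale, threshold = threshold, polarity = polarity,
               min_size = min_size, roundness = roundness),
          seed)
  invisible(list(particles = sets, summary = summary))
}
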