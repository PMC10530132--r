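#' Larger-the-better signal-to-noise ratio
#'
#' The Taguchi larger-the-better S/N ratio, in decibels, of a set of replicate
#' responses: `-10 * log10(mean(1 / y^2))`. It rewards both a high mean and
#' low spread; for identical replicates `y` it reduces to `20 * log10(y)`.
#'
#' @param y Numeric vector of replicate responses, all strictly positive.
#' @return S/N ratio in dB.
#' @examples
#' sn_larger_better(c(1.99, 1.99, 1.99)) # ~6.0 dB
#' @export
sn_larger_better <- function(y) {
  if (!is.numeric(y) || !length(y) || anyNA(y)) {
    abort_validation("`y` must be a non-empty numeric vector without NAs.")
  }
  if (any(y <= 0)) {
    abort_domain("all responses must be strictly positive for a finite S/N ratio.")
  }
  -10 * log10(mean(1 / y^2))
}

align_sn <- function(design, sn) {
  if (is.data.frame(sn)) {
    if (!all(c("trial", "sn") %in% names(sn))) {
      abort_validation("a data-frame `sn` must have columns `trial` and `sn`.")
    }
    idx <- match(as.character(design$trial), as.character(sn$trial))
    if (anyNA(idx)) abort_validation("design trials and S/N trials do not match 1:1.")
    sn$sn[idx]
  } else {
    if (length(sn) != nrow(design)) {
      abort_validation("length of `sn` must equal the number of design trials.")
    }
    as.numeric(sn)
  }
}

#' Mean S/N ratio at each factor level
#'
#' For every factor of a three-level orthogonal array, averages the per-trial
#' S/N ratios of the trials run at each level (three trials per level in the
#' L9 array).
#'
#' @param design A three-level `doe_design`, e.g. [l9_design()].
#' @param sn Numeric vector of per-trial S/N ratios in design order, or a
#'   tibble with columns `trial` and `sn`.
#' @return Tibble with columns `factor`, `level`, `sn_mean`, with factors in
#'   design column order.
#' @export
sn_level_table <- function(design, sn) {
  codes <- design_codes(design)
  s <- align_sn(design, sn)
  purrr::map_dfr(colnames(codes), function(sym) {
    lv <- sort(unique(codes[, sym]))
    tibble(
      factor = sym, level = lv,
      sn_mean = vapply(lv, function(k) mean(s[codes[, sym] == k]), numeric(1))
    )
  })
}

#' Pick the optimum level combination from level-mean S/N ratios
#'
#' For each factor, selects the level with the largest mean S/N ratio; exact
#' ties break deterministically to the lowest level index. The label
#' concatenates factor symbol and chosen level in factor order, e.g.
#' `"A2B3C3D3"`.
#'
#' @param level_table Tibble from [sn_level_table()].
#' @return Named integer vector of chosen levels with attribute `label`; use
#'   `optimum_label()` for just the string.
#' @export
pick_optimum <- function(level_table) {
  if (!all(c("factor", "level", "sn_mean") %in% names(level_table))) {
    abort_validation("`level_table` must come from sn_level_table().")
  }
  facs <- unique(level_table$factor)
  picks <- vapply(facs, function(sym) {
    sub <- level_table[level_table$factor == sym, ]
    sub <- sub[order(sub$level), ]
    sub$level[which.max(sub$sn_mean)] # which.max takes the first (lowest level) on ties
  }, integer(1))
  structure(picks, label = paste0(facs, picks, collapse = ""))
}

#' @rdname pick_optimum
#' @param optimum Result of `pick_optimum()`.
#' @export
optimum_label <- function(optimum) attr(optimum, "label")

#' Factor sums of squares and contribution ratios for a Taguchi array
#'
#' In the saturated L9 analysis each factor's sum of squares is
#' `r * sum((level mean - grand mean)^2)` with `r` trials per level, the total
#' sum of squares is the squared deviation of every trial's S/N from the grand
#' mean, and a factor's contribution is `SS_i / SST * 100`. For the saturated
#' array the factor SS add up to SST exactly.
#'
#' @param level_table Tibble from [sn_level_table()].
#' @param sn Per-trial S/N ratios (vector or `trial`/`sn` tibble) used to form
#'   the grand mean and SST.
#' @return List with `table` (tibble: `factor`, `ss`, `contribution`), `sst`
#'   and `grand_mean`.
#' @export
taguchi_anova <- function(level_table, sn) {
  s <- if (is.data.frame(sn)) sn$sn else as.numeric(sn)
  grand <- mean(s)
  sst <- sum((s - grand)^2)
  facs <- unique(level_table$factor)
  reps <- length(s) / length(unique(level_table$level[level_table$factor == facs[1]]))
  ss <- vapply(facs, function(sym) {
    lm <- level_table$sn_mean[level_table$factor == sym]
    reps * sum((lm - grand)^2)
  }, numeric(1))
  if (sst == 0) {
    abort_domain("total S/N variation is zero; contributions are undefined.")
  }
  list(
    table = tibble(factor = facs, ss = unname(ss),
                   contribution = unname(100 * ss / sst)),
    sst = sst, grand_mean = grand
  )
}

parse_combination <- function(combination, level_table) {
  facs <- unique(level_table$factor)
  if (is.character(combination) && length(combination) == 1L) {
    m <- regmatches(combination,
                    gregexpr("([A-Za-z][A-Za-z0-9_]*?)([0-9]+)(?=[A-Za-z]|$)",
                             combination, perl = TRUE))[[1]]
    lev <- as.integer(sub("^.*?([0-9]+)$", "\\1", m))
    names(lev) <- sub("[0-9]+$", "", m)
    combination <- lev
  }
  if (is.null(names(combination)) && length(combination) == length(facs)) {
    names(combination) <- facs
  }
  if (!all(facs %in% names(combination))) {
    abort_validation("`combination` must name a level for every factor.")
  }
  combination[facs]
}

#' Additive-model prediction of the S/N ratio at a level combination
#'
#' Predicts the S/N ratio of an (often untested) level combination as the
#' grand mean plus the sum of each selected level's deviation from it --
#' the usual Taguchi additive model without interactions.
#'
#' @param level_table Tibble from [sn_level_table()] (or a `taguchi_fit`).
#' @param combination A label like `"A2B3C3D3"` or a named integer vector of
#'   levels.
#' @param sn Per-trial S/N ratios, needed to form the grand mean when
#'   `level_table` is a bare tibble.
#' @return Predicted S/N ratio in dB.
#' @export
predict_additive_sn <- function(level_table, combination, sn = NULL) {
  if (inherits(level_table, "taguchi_fit")) {
    fit <- level_table
    level_table <- fit$level_means
    grand <- fit$grand_mean
  } else {
    if (is.null(sn)) abort_validation("supply `sn` to establish the grand mean.")
    s <- if (is.data.frame(sn)) sn$sn else as.numeric(sn)
    grand <- mean(s)
  }
  combo <- parse_combination(combination, level_table)
  dev <- vapply(names(combo), function(sym) {
    sub <- level_table[level_table$factor == sym, ]
    hit <- sub$sn_mean[sub$level == combo[[sym]]]
    if (!length(hit)) {
      abort_validation(sprintf("level %d is not available for factor %s.", combo[[sym]], sym))
    }
    hit - grand
  }, numeric(1))
  grand + sum(dev)
}

#' Compare baseline and optimized cultures
#'
#' @param baseline,optimized Numeric vectors of replicate biomass values
#'   (g/dL) for the basal and optimized medium.
#' @return One-row tibble: means, SDs, fold change (optimized/baseline), S/N
#'   of each set and their difference in dB.
#' @examples
#' confirmation_summary(c(0.92, 0.92, 0.92), c(1.99, 1.99, 1.99))
#' @export
confirmation_summary <- function(baseline, optimized) {
  for (v in list(baseline, optimized)) {
    if (!is.numeric(v) || !length(v) || any(v <= 0)) {
      abort_validation("both replicate sets must be non-empty and strictly positive.")
    }
  }
  mb <- mean(baseline); mo <- mean(optimized)
  if (mb == 0) abort_domain("baseline mean is zero; fold change undefined.")
  tibble(
    baseline_mean = mb, baseline_sd = if (length(baseline) > 1) sd(baseline) else 0,
    optimized_mean = mo, optimized_sd = if (length(optimized) > 1) sd(optimized) else 0,
    fold = mo / mb,
    baseline_sn = sn_larger_better(baseline),
    optimized_sn = sn_larger_better(optimized),
    delta_sn = sn_larger_better(optimized) - sn_larger_better(baseline)
  )
}

#' Run the full Taguchi S/N analysis on an orthogonal array
#'
#' Computes per-trial larger-the-better S/N ratios (from replicates, or
#' accepts precomputed S/N values), the factor-by-level mean S/N table, factor
#' sums of squares and contribution ratios, the optimum level combination,
#' and the additive-model prediction at that optimum.
#'
#' When a trial carries a single value (a published mean rather than raw
#' replicates) its S/N ratio is the identical-replicate form
#' `20 * log10(mean)`; the fit is then marked `approximate` because replicate
#' spread cannot be recovered from a mean.
#'
#' @param design A three-level `doe_design` (default [l9_design()]).
#' @param responses Replicate data frame (`trial` + replicate columns).
#'   Ignored when `sn` is given.
#' @param sn Optional precomputed per-trial S/N ratios (vector or
#'   `trial`/`sn` tibble).
#' @return A `taguchi_fit` object; see [tidy.taguchi_fit()],
#'   [glance.taguchi_fit()] and [autoplot.taguchi_fit()].
#' @examples
#' fx <- load_fixture("table4")
#' fit <- taguchi_sn(l9_design(), sn = fx$sn)
#' glance(fit)
#' @export
taguchi_sn <- function(design = l9_design(), responses = NULL, sn = NULL) {
  validate_design(design)
  approximate <- FALSE
  if (is.null(sn)) {
    if (is.null(responses)) abort_validation("supply either `responses` or `sn`.")
    tm <- trial_means(responses)
    idx <- match(as.character(design$trial), tm$trial)
    if (anyNA(idx)) abort_validation("design trials and response trials do not match 1:1.")
    rep_cols <- setdiff(names(responses), "trial")
    sn_vals <- vapply(idx, function(i) {
      row <- match(tm$trial[i], as.character(responses$trial))
      y <- as.numeric(unlist(responses[row, rep_cols]))
      sn_larger_better(y[!is.na(y)])
    }, numeric(1))
    approximate <- any(tm$n == 1L)
    trial_tbl <- tibble(trial = as.character(design$trial),
                        n = tm$n[idx], mean = tm$mean[idx], sd = tm$sd[idx],
                        sn = sn_vals)
  } else {
    s <- align_sn(design, sn)
    trial_tbl <- tibble(trial = as.character(design$trial), n = NA_integer_,
                        mean = NA_real_, sd = NA_real_, sn = s)
    approximate <- TRUE
  }
  lt <- sn_level_table(design, trial_tbl$sn)
  an <- if (sum((trial_tbl$sn - mean(trial_tbl$sn))^2) == 0) {
    # constant S/N: level ties resolve to level 1, contributions are undefined
    warn("total S/N variation is zero; contributions are undefined (NA).")
    facs <- unique(lt$factor)
    list(table = tibble(factor = facs, ss = 0, contribution = NA_real_),
         sst = 0, grand_mean = mean(trial_tbl$sn))
  } else {
    taguchi_anova(lt, trial_tbl$sn)
  }
  opt <- pick_optimum(lt)
  structure(
    list(
      trials = trial_tbl, level_means = lt,
      anova = an$table, sst = an$sst, grand_mean = an$grand_mean,
      optimum = opt, optimum_label = optimum_label(opt),
      predicted_sn = {
        tmp <- list(level_means = lt, grand_mean = an$grand_mean)
        class(tmp) <- "taguchi_fit"
        predict_additive_sn(tmp, opt)
      },
      approximate = approximate, design = design
    ),
    class = "taguchi_fit"
  )
}

#' @export
print.taguchi_fit <- function(x, ...) {
  cat(sprintf("Taguchi S/N analysis (%d trials%s)\n", nrow(x$trials),
              if (isTRUE(x$approximate)) "; S/N approximate (means only)" else ""))
  cat(sprintf("Grand mean S/N: %.2f dB  SST: %.2f\n", x$grand_mean, x$sst))
  cat(sprintf("Optimum: %s  predicted S/N: %.2f dB\n\n", x$optimum_label, x$predicted_sn))
  wide <- tidyr::pivot_wider(x$level_means, names_from = "level",
                             values_from = "sn_mean", names_prefix = "level_")
  print(as.data.frame(dplyr::mutate(
    dplyr::left_join(wide, x$anova, by = "factor"),
    dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2))
  )), row.names = FALSE)
  invisible(x)
}

#' Tidy and summary views of a Taguchi fit
#'
#' `tidy()` returns one row per factor level (mean S/N, whether it is the
#' chosen optimum, the factor's SS and contribution); `glance()` a one-row
#' summary with grand mean, SST, optimum label and predicted S/N.
#'
#' @param x A `taguchi_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy taguchi_fit
#' @export
tidy.taguchi_fit <- function(x, ...) {
  out <- dplyr::left_join(x$level_means, x$anova, by = "factor")
  out$optimal <- mapply(function(f, l) x$optimum[[f]] == l, out$factor, out$level)
  out
}

#' @rdname tidy.taguchi_fit
#' @method glance taguchi_fit
#' @export
glance.taguchi_fit <- function(x, ...) {
  tibble(
    n_trials = nrow(x$trials), grand_mean_sn = x$grand_mean, sst = x$sst,
    optimum = x$optimum_label, predicted_sn = x$predicted_sn,
    approximate = x$approximate
  )
}
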