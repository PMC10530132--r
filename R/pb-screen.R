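#' Per-trial replicate means and standard deviations
#'
#' Collapses replicate biomass measurements (g/dL) to one mean per trial, the
#' form in which screening effects are computed. The SD is the sample standard
#' deviation (n - 1 denominator), the convention behind "mean +/- SD"
#' reporting of triplicate cultures; a single replicate gives SD 0.
#'
#' @param responses Data frame with a `trial` column and one or more numeric
#'   replicate columns (e.g. `rep_1`, `rep_2`, ...).
#' @return Tibble with columns `trial`, `n`, `mean`, `sd`.
#' @examples
#' trial_means(data.frame(trial = 1:2, r1 = c(1, 2), r2 = c(3, 2)))
#' @export
trial_means <- function(responses) {
  if (!is.data.frame(responses) || !"trial" %in% names(responses)) {
    abort_validation("`responses` must be a data frame with a `trial` column.")
  }
  rep_cols <- setdiff(names(responses), "trial")
  if (!length(rep_cols)) abort_validation("no replicate columns found.")
  reps <- lapply(seq_len(nrow(responses)), function(i) {
    y <- as.numeric(unlist(responses[i, rep_cols]))
    y <- y[!is.na(y)]
    if (!length(y)) {
      abort_validation(sprintf("trial %s has no replicate values.", responses$trial[i]))
    }
    if (any(y < 0)) {
      abort_validation(sprintf("trial %s has negative biomass values.", responses$trial[i]))
    }
    y
  })
  tibble(
    trial = as.character(responses$trial),
    n = lengths(reps),
    mean = vapply(reps, mean, numeric(1)),
    sd = vapply(reps, function(y) if (length(y) > 1L) sd(y) else 0, numeric(1))
  )
}

align_means <- function(design, means) {
  if (is.data.frame(means)) {
    col <- if ("mean" %in% names(means)) "mean" else setdiff(names(means), "trial")[1]
    if ("trial" %in% names(means)) {
      idx <- match(as.character(design$trial), as.character(means$trial))
      if (anyNA(idx)) abort_validation("design trials and response trials do not match 1:1.")
      means[[col]][idx]
    } else {
      means[[col]]
    }
  } else {
    as.numeric(means)
  }
}

#' Plackett-Burman main effects
#'
#' For each design column (real factors and dummy alike) the effect is the
#' mean response of the trials at the high (`+1`) level minus the mean of the
#' trials at the low (`-1`) level. Responses are per-trial means; collapse
#' replicates first with [trial_means()].
#'
#' @param design A two-level `doe_design`, e.g. [pb12_design()].
#' @param means Numeric vector of per-trial mean responses in design order, or
#'   a tibble from [trial_means()] (matched by `trial`).
#' @return Tibble with columns `factor`, `effect` (g/dL).
#' @examples
#' fx <- load_fixture("table3")
#' pb_effects(pb12_design(), fx$dcw_mean)
#' @export
pb_effects <- function(design, means) {
  codes <- design_codes(design)
  y <- align_means(design, means)
  if (length(y) != nrow(codes)) {
    abort_validation("length of `means` must equal the number of design trials.")
  }
  effects <- vapply(colnames(codes), function(sym) {
    up <- codes[, sym] == 1L
    if (sum(up) != sum(!up)) {
      abort_validation(sprintf("factor %s has unequal (+)/(-) group sizes.", sym))
    }
    mean(y[up]) - mean(y[!up])
  }, numeric(1))
  tibble(factor = colnames(codes), effect = unname(effects))
}

#' Dummy-factor ANOVA for a saturated Plackett-Burman screen
#'
#' Converts effects to sums of squares via `SS = n * effect^2 / 4` (df = 1,
#' so MS = SS) and tests each factor against the dummy column's mean square,
#' which estimates pure error in a saturated design: `F_i = MS_i / MS_dummy`
#' with a one-tailed upper-tail p-value at (1, 1) degrees of freedom. The
#' dummy itself gets F = 1, p = 0.5 by construction.
#'
#' @param effects Tibble from [pb_effects()] (columns `factor`, `effect`).
#' @param n_trials Number of design trials (12 for the PB12 screen).
#' @param dummy Symbol of the dummy column (default `"X11"`).
#' @return Tibble with columns `factor`, `effect`, `ss`, `df`, `ms`, `f`, `p`
#'   and logical `is_dummy`.
#' @export
anova_vs_dummy <- function(effects, n_trials, dummy = "X11") {
  if (!all(c("factor", "effect") %in% names(effects))) {
    abort_validation("`effects` must have columns `factor` and `effect`.")
  }
  check_number(n_trials, "n_trials", lower = 2)
  if (!dummy %in% effects$factor) {
    abort_config(sprintf("dummy factor '%s' not present in the effect table.", dummy))
  }
  ss <- n_trials * effects$effect^2 / 4
  ms <- ss / 1
  ms_dummy <- ms[effects$factor == dummy]
  if (ms_dummy == 0) {
    abort_domain(paste(
      "the dummy factor's mean square is exactly zero, so F ratios and",
      "significance are undefined; supply responses with replicate error."
    ))
  }
  f <- ms / ms_dummy
  tibble(
    factor = effects$factor, effect = effects$effect,
    ss = ss, df = 1L, ms = ms, f = f,
    p = pf(f, 1, 1, lower.tail = FALSE),
    is_dummy = effects$factor == dummy
  )
}

#' Upper-tail critical value of the F distribution
#'
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return The value exceeded with probability `alpha` under F(df1, df2).
#'   With a single error degree of freedom (df1 = df2 = 1) and alpha = 0.05
#'   this is approximately 161 - the stringent bar a saturated screen must
#'   clear.
#' @examples
#' critical_f(0.05, 1, 1)
#' @export
critical_f <- function(alpha, df1, df2) {
  check_number(alpha, "alpha", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(df1, "df1", lower = 1)
  check_number(df2, "df2", lower = 1)
  qf(alpha, df1, df2, lower.tail = FALSE)
}

#' Flag factors whose F ratio clears the critical value
#'
#' @param anova Tibble from [anova_vs_dummy()].
#' @param alpha Significance level (default 0.05).
#' @return Character vector of significant factor symbols; the dummy column is
#'   never flagged.
#' @export
flag_significant <- function(anova, alpha = 0.05) {
  need <- c("factor", "f", "is_dummy")
  if (!all(need %in% names(anova))) {
    abort_validation("`anova` must come from anova_vs_dummy().")
  }
  fcrit <- critical_f(alpha, 1, 1)
  anova$factor[!anova$is_dummy & anova$f > fcrit]
}

#' Effect shares across the real screening factors
#'
#' Ranks factors by the share each absolute effect takes of the summed
#' absolute effects over the real (non-dummy) factors, expressed as a
#' percentage. The dummy column is excluded from numerator and denominator.
#'
#' @param effects Tibble with columns `factor` and `effect`.
#' @param dummy Symbol of the dummy column to exclude (default `"X11"`).
#' @return Tibble with columns `factor`, `share` (percent; shares sum to 100).
#' @export
effect_shares <- function(effects, dummy = "X11") {
  real <- effects[effects$factor != dummy, , drop = FALSE]
  if (!nrow(real)) abort_validation("no real factors left after excluding the dummy.")
  denom <- sum(abs(real$effect))
  if (denom == 0) {
    abort_domain("all effects are zero; effect shares are undefined.")
  }
  tibble(factor = real$factor, share = 100 * abs(real$effect) / denom)
}

#' Run the full Plackett-Burman screening stage
#'
#' Collapses replicates to trial means, estimates the eleven column effects,
#' performs the dummy-factor ANOVA, flags significance at `alpha`, and ranks
#' the real factors by effect share.
#'
#' @param design A two-level `doe_design` (default the 12-run screen).
#' @param responses Replicate data frame (`trial` + replicate columns), a
#'   [trial_means()] tibble, or a numeric vector of per-trial means.
#' @param dummy Dummy column symbol (default `"X11"`).
#' @param alpha Significance level (default 0.05).
#' @return A `pb_screen` object; see [tidy.pb_screen()] and
#'   [glance.pb_screen()] for tabular views and [autoplot.pb_screen()] for a
#'   Pareto chart of shares.
#' @examples
#' fx <- load_fixture("table3")
#' fit <- pb_screen(pb12_design(), fx$dcw_mean)
#' glance(fit)
#' @export
pb_screen <- function(design = pb12_design(), responses, dummy = "X11", alpha = 0.05) {
  validate_design(design)
  means <- if (is.data.frame(responses) && !all(c("trial", "mean") %in% names(responses)) &&
               "trial" %in% names(responses)) {
    trial_means(responses)
  } else if (is.data.frame(responses)) {
    responses
  } else {
    tibble(trial = as.character(design$trial), n = 1L,
           mean = as.numeric(responses), sd = 0)
  }
  effects <- pb_effects(design, means)
  anova <- anova_vs_dummy(effects, nrow(design), dummy = dummy)
  shares <- effect_shares(effects, dummy = dummy)
  tab <- dplyr::left_join(anova, shares, by = "factor")
  tab$significant <- !tab$is_dummy & tab$f > critical_f(alpha, 1, 1)
  structure(
    list(
      table = tab, means = means, alpha = alpha, dummy = dummy,
      f_critical = critical_f(alpha, 1, 1), n_trials = nrow(design),
      significant = tab$factor[tab$significant]
    ),
    class = "pb_screen"
  )
}

#' @export
print.pb_screen <- function(x, ...) {
  cat(sprintf(
    "Plackett-Burman screen: %d trials, %d columns (dummy %s)\n",
    x$n_trials, nrow(x$table), x$dummy
  ))
  cat(sprintf("F critical (alpha = %g, df 1,1): %.1f\n", x$alpha, x$f_critical))
  cat("Significant factors:",
      if (length(x$significant)) paste(x$significant, collapse = ", ") else "(none)", "\n\n")
  print(as.data.frame(dplyr::mutate(
    x$table,
    dplyr::across(c("effect", "ss", "ms"), ~ round(.x, 3)),
    f = round(.data$f, 1), p = round(.data$p, 3),
    share = round(.data$share)
  )), row.names = FALSE)
  invisible(x)
}

#' Tidy and summary views of a Plackett-Burman screen
#'
#' `tidy()` returns the per-factor table (effect, SS, MS, F, p, share,
#' significance); `glance()` returns a one-row summary.
#'
#' @param x A `pb_screen` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pb_screen
#' @export
tidy.pb_screen <- function(x, ...) x$table

#' @rdname tidy.pb_screen
#' @method glance pb_screen
#' @export
glance.pb_screen <- function(x, ...) {
  tibble(
    n_trials = x$n_trials,
    n_factors = sum(!x$table$is_dummy),
    alpha = x$alpha,
    f_critical = x$f_critical,
    ms_dummy = x$table$ms[x$table$is_dummy][1],
    n_significant = length(x$significant)
  )
}
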