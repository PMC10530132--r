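#' Factor specifications for a designed experiment
#'
#' A factor specification maps a factor's symbol (e.g. `"X4"` or `"B"`) to its
#' name, units, and the ordered list of concrete levels tested: two levels for
#' a Plackett-Burman factor (the high, `+1`, level first), three for a Taguchi
#' L9 factor (levels 1, 2, 3 in order). Concentrations are per 100 mL of
#' medium.
#'
#' @param symbol Short factor symbol, unique within a design.
#' @param name Human-readable factor name.
#' @param units Measurement units (g or mL per 100 mL), `NA` for a dummy.
#' @param levels Numeric vector of 2 or 3 ordered concrete levels, all
#'   non-negative. May be `NA` for an unassigned (dummy) column, which then
#'   carries no concentration.
#'
#' @return A one-row tibble with columns `symbol`, `name`, `units` and the
#'   list-column `levels`. Bind rows of these to describe a whole design.
#' @examples
#' factor_spec("X4", "CaCO3", "g", c(0.5, 0))
#' @export
factor_spec <- function(symbol, name, units = NA_character_, levels = NA_real_) {
  if (!is.character(symbol) || length(symbol) != 1L || !nzchar(symbol)) {
    abort_validation("`symbol` must be a non-empty string.")
  }
  if (!all(is.na(levels))) {
    if (!is.numeric(levels) || !length(levels) %in% c(2L, 3L)) {
      abort_validation("`levels` must hold 2 or 3 numeric values (or NA for a dummy).")
    }
    if (any(levels < 0)) abort_validation("factor levels must be non-negative.")
  }
  tibble(
    symbol = symbol, name = as.character(name), units = as.character(units),
    levels = list(as.numeric(levels))
  )
}

#' Built-in factor specifications for the screening and optimization stages
#'
#' `pb_factor_specs()` returns the ten medium components (plus the unassigned
#' dummy column `X11`) screened in the 12-run Plackett-Burman stage with their
#' high (`+1`) and low (`-1`) concentrations. `l9_factor_specs()` returns the
#' four components of the L9 optimization stage (olive oil, CaCO3, yeast
#' extract, soy powder) with their three tested levels.
#'
#' @return A tibble with columns `symbol`, `name`, `units` and list-column
#'   `levels` (ordered concrete values; per 100 mL of medium).
#' @examples
#' pb_factor_specs()
#' l9_factor_specs()
#' @export
pb_factor_specs <- function() {
  raw <- read_extdata("pb_factors.csv")
  dplyr::bind_rows(purrr::pmap(raw, function(symbol, name, units, level_plus, level_minus) {
    lv <- if (is.na(level_plus)) NA_real_ else c(level_plus, level_minus)
    factor_spec(symbol, name, units, lv)
  }))
}

#' @rdname pb_factor_specs
#' @export
l9_factor_specs <- function() {
  raw <- read_extdata("l9_factors.csv")
  dplyr::bind_rows(purrr::pmap(raw, function(symbol, name, units, level_1, level_2, level_3) {
    factor_spec(symbol, name, units, c(level_1, level_2, level_3))
  }))
}

new_design <- function(codes, type, trials = NULL, specs = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  trials <- trials %||% as.character(seq_len(nrow(codes)))
  if (anyDuplicated(colnames(codes))) abort_validation("factor symbols must be unique.")
  out <- dplyr::bind_cols(tibble(trial = as.character(trials)), as_tibble(codes))
  attr(out, "design_type") <- type
  attr(out, "factor_specs") <- specs
  class(out) <- c("doe_design", class(out))
  out
}

#' Extract the coded level matrix of a design
#'
#' @param design A `doe_design` tibble as returned by [pb12_design()] or
#'   [l9_design()].
#' @return Integer matrix of level codes, trials in rows, factors in columns.
#' @export
design_codes <- function(design) {
  if (!inherits(design, "doe_design")) {
    if (!is.data.frame(design) || !"trial" %in% names(design)) {
      abort_validation("`design` must be a doe_design or a data frame with a `trial` column.")
    }
  }
  m <- as.matrix(design[setdiff(names(design), "trial")])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(design$trial)
  m
}

design_type <- function(design) {
  attr(design, "design_type") %||%
    if (all(design_codes(design) %in% c(-1L, 1L))) "two_level" else "three_level"
}

#' The 12-run Plackett-Burman screening design
#'
#' Returns the coded 12-trial, 11-column two-level matrix used for medium
#' screening: ten real factors `X1`-`X10` plus the unassigned dummy column
#' `X11` whose apparent effect estimates experimental error. Codes follow the
#' convention that level 1 of a factor (its high concentration) is `+1`.
#'
#' Two arrangements are available. `"published"` is the canonical trial order
#' used throughout the worked examples; its dummy column is the unique
#' balanced column (up to sign) that completes the ten assigned columns to a
#' mutually orthogonal set. `"cyclic"` builds the classical cyclic-Hadamard
#' arrangement from the generating row `(+ + - + + + - - - + -)` with an
#' all-minus final row. Both satisfy the same balance and orthogonality
#' invariants, and every analysis function accepts either.
#'
#' @param arrangement `"published"` (default) or `"cyclic"`.
#' @return A `doe_design` tibble (12 trials, columns `trial`, `X1`..`X11`)
#'   carrying the screening factor specifications as an attribute.
#' @examples
#' d <- pb12_design()
#' colSums(design_codes(d)) # every column balanced
#' @export
pb12_design <- function(arrangement = c("published", "cyclic")) {
  arrangement <- match.arg(arrangement)
  if (arrangement == "published") {
    raw <- read_extdata("pb12_coded.csv")
    codes <- as.matrix(raw[-1])
    trials <- raw$trial
  } else {
    gen <- c(1L, 1L, -1L, 1L, 1L, 1L, -1L, -1L, -1L, 1L, -1L)
    codes <- t(vapply(0:10, function(s) {
      if (s == 0L) gen else c(gen[-seq_len(s)], gen[seq_len(s)])
    }, integer(11)))
    codes <- rbind(codes, rep(-1L, 11))
    colnames(codes) <- paste0("X", 1:11)
    trials <- 1:12
  }
  validate_design(new_design(codes, "two_level", trials, pb_factor_specs()))
}

#' The Taguchi L9(3^4) orthogonal array
#'
#' Returns the standard 9-trial, 4-factor three-level orthogonal array used to
#' tune olive oil (`A`), CaCO3 (`B`), yeast extract (`C`) and soy powder
#' (`D`). Each column contains every level three times and every ordered pair
#' of levels appears exactly once across any two columns.
#'
#' @return A `doe_design` tibble (trials `L1`..`L9`, columns `A`..`D`)
#'   carrying the optimization factor specifications as an attribute.
#' @examples
#' apply_factor_levels(l9_design(), l9_factor_specs())
#' @export
l9_design <- function() {
  codes <- matrix(c(
    1L, 1L, 1L, 1L,
    1L, 2L, 2L, 2L,
    1L, 3L, 3L, 3L,
    2L, 1L, 2L, 3L,
    2L, 2L, 3L, 1L,
    2L, 3L, 1L, 2L,
    3L, 1L, 3L, 2L,
    3L, 2L, 1L, 3L,
    3L, 3L, 2L, 1L
  ), ncol = 4, byrow = TRUE, dimnames = list(NULL, c("A", "B", "C", "D")))
  validate_design(new_design(codes, "three_level", paste0("L", 1:9), l9_factor_specs()))
}

#' Validate the balance and orthogonality invariants of a design
#'
#' Two-level designs must have codes in \{-1, +1\}, equally many of each per
#' column, and zero inner product between every pair of columns. Three-level
#' orthogonal arrays must contain each level equally often per column and
#' every ordered level pair equally often across every pair of columns.
#'
#' @param design A `doe_design` (or data frame with a `trial` column).
#' @return The design, invisibly, if all invariants hold; otherwise an error.
#' @export
validate_design <- function(design) {
  codes <- design_codes(design)
  type <- design_type(design)
  if (type == "two_level") {
    if (!all(codes %in% c(-1L, 1L))) {
      abort_validation("two-level design codes must be -1 or +1.")
    }
    if (any(colSums(codes) != 0L)) {
      abort_validation("two-level design is unbalanced: column sums must be zero.")
    }
    ip <- crossprod(codes)
    if (any(ip[upper.tri(ip)] != 0L)) {
      abort_validation("two-level design columns are not mutually orthogonal.")
    }
  } else {
    lev <- sort(unique(as.vector(codes)))
    if (!identical(lev, seq_along(lev)) && !all(lev %in% seq_len(max(lev)))) {
      abort_validation("three-level design codes must be positive integers 1..k.")
    }
    k <- max(codes)
    per <- nrow(codes) / k
    ok_col <- apply(codes, 2, function(x) all(tabulate(x, k) == per))
    if (!all(ok_col)) {
      abort_validation("orthogonal-array column is unbalanced: each level must appear equally often.")
    }
    pair_n <- nrow(codes) / k^2
    for (i in seq_len(ncol(codes) - 1)) {
      for (j in seq(i + 1, ncol(codes))) {
        tab <- table(factor(codes[, i], seq_len(k)), factor(codes[, j], seq_len(k)))
        if (!all(tab == pair_n)) {
          abort_validation(sprintf(
            "columns %s and %s do not carry every ordered level pair equally often.",
            colnames(codes)[i], colnames(codes)[j]
          ))
        }
      }
    }
  }
  invisible(design)
}

#' Decode a design into concrete medium concentrations
#'
#' Translates coded levels into the concrete per-100-mL concentrations given
#' by the factor specifications: for a two-level design `+1` maps to the first
#' (high) listed level and `-1` to the second; for a three-level design code
#' `k` maps to the k-th listed level. A dummy factor (all-`NA` levels) decodes
#' to `NA` since it corresponds to no ingredient.
#'
#' @param design A `doe_design`.
#' @param specs Factor specification tibble covering every design symbol;
#'   defaults to the specs attached to the design.
#' @return A recipe tibble: `trial` plus one concentration column per factor.
#' @examples
#' apply_factor_levels(pb12_design(), pb_factor_specs())
#' @export
apply_factor_levels <- function(design, specs = attr(design, "factor_specs")) {
  codes <- design_codes(design)
  if (is.null(specs)) abort_config("no factor specifications supplied or attached.")
  missing <- setdiff(colnames(codes), specs$symbol)
  if (length(missing)) {
    abort_config(sprintf(
      "no factor specification for design symbol(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  vals <- vapply(colnames(codes), function(sym) {
    lv <- specs$levels[[match(sym, specs$symbol)]]
    code <- codes[, sym]
    if (all(is.na(lv))) return(rep(NA_real_, length(code)))
    idx <- if (design_type(design) == "two_level") {
      ifelse(code == 1L, 1L, ifelse(code == -1L, 2L, NA_integer_))
    } else {
      ifelse(code >= 1L & code <= length(lv), code, NA_integer_)
    }
    if (anyNA(idx)) {
      abort_validation(sprintf("code outside the level range of factor %s.", sym))
    }
    lv[idx]
  }, numeric(nrow(codes)))
  dplyr::bind_cols(tibble(trial = design$trial), as_tibble(vals))
}

#' Re-code a concrete recipe table against factor specifications
#'
#' The inverse of [apply_factor_levels()]: matches each concentration back to
#' its position in the factor's level list. Together the two functions satisfy
#' `infer_codes(apply_factor_levels(d, s), s)` = codes of `d`.
#'
#' @param recipe Tibble with `trial` plus one concentration column per factor.
#' @param specs Factor specification tibble covering every recipe column.
#' @return A `doe_design` tibble of integer codes.
#' @export
infer_codes <- function(recipe, specs) {
  syms <- setdiff(names(recipe), "trial")
  missing <- setdiff(syms, specs$symbol)
  if (length(missing)) {
    abort_config(sprintf(
      "no factor specification for recipe column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  n_lev <- lengths(specs$levels[match(syms, specs$symbol)])
  type <- if (all(n_lev == 2L)) "two_level" else "three_level"
  codes <- vapply(syms, function(sym) {
    lv <- specs$levels[[match(sym, specs$symbol)]]
    idx <- match(recipe[[sym]], lv)
    if (anyNA(idx)) {
      abort_validation(sprintf("value in column %s is not one of its specified levels.", sym))
    }
    if (type == "two_level") ifelse(idx == 1L, 1L, -1L) else as.integer(idx)
  }, integer(nrow(recipe)))
  new_design(codes, type, recipe$trial, specs)
}
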