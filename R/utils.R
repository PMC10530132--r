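# internal helpers shared across modules

abort_config <- function(msg) abort(msg, class = "pelletr_config_error")
abort_validation <- function(msg) abort(msg, class = "pelletr_validation_error")
abort_domain <- function(msg) abort(msg, class = "pelletr_domain_error")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort_validation(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", name,
      if (closed_lower) "[" else "(", format(lower),
      format(upper), if (closed_upper) "]" else ")", x
    ))
  }
  invisible(x)
}

# run `code` under a fixed seed when one is supplied, without disturbing the
# caller's RNG state otherwise
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "pelletr", mustWork = FALSE)
  if (!nzchar(path)) {
    abort_config(sprintf("bundled data file '%s' not found; reinstall pelletr.", file))
  }
  path
}

read_extdata <- function(file) {
  readr::read_csv(extdata_path(file), show_col_types = FALSE, progress = FALSE)
}
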