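#' Bundled published tables from the optimization study
#'
#' Returns the published experiment tables embedded in the package as
#' tibbles, verbatim at printed precision:
#'
#' * `"table1"` -- the ten screening factors with their high (`+1`) and low
#'   (`-1`) concentrations per 100 mL, plus the dummy column.
#' * `"table2"` -- the four optimization factors with their three levels.
#' * `"table3"` -- the 12 screening trials: concrete compositions, dry-cell
#'   weight mean and SD per trial (g/dL). The printed effect/SS/MS/F/p rows
#'   are attached as the `"printed_stats"` attribute.
#' * `"table4"` -- the 9 orthogonal-array trials: compositions (at printed,
#'   rounded precision), biomass mean and SD, and the printed per-trial S/N
#'   ratio. The printed level means, SS and contributions are attached as the
#'   `"printed_summary"` attribute.
#'
#' @param table_id One of `"table1"`, `"table2"`, `"table3"`, `"table4"`
#'   (case and whitespace insensitive, so `"Table 3"` also works).
#' @return A tibble (see above).
#' @examples
#' load_fixture("table3")$dcw_mean
#' attr(load_fixture("table4"), "printed_summary")
#' @export
load_fixture <- function(table_id) {
  if (!is.character(table_id) || length(table_id) != 1L) {
    abort_validation("`table_id` must be a single string.")
  }
  id <- gsub("[^a-z0-9]", "", tolower(table_id))
  switch(id,
    table1 = read_extdata("pb_factors.csv"),
    table2 = read_extdata("l9_factors.csv"),
    table3 = {
      out <- read_extdata("pbd_trials.csv")
      attr(out, "printed_stats") <- read_extdata("pbd_printed_stats.csv")
      out
    },
    table4 = {
      out <- read_extdata("l9_trials.csv")
      attr(out, "printed_summary") <- read_extdata("l9_printed_summary.csv")
      out
    },
    abort_config(sprintf(
      "unknown fixture '%s'; available: table1, table2, table3, table4.", table_id))
  )
}
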