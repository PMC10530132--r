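#' Simulate designed-experiment responses with planted effect structure
#'
#' Generates replicate biomass responses (g/dL) for a two- or three-level
#' design from an additive model plus Gaussian replicate noise, returning the
#' planted ground truth alongside so recovery can be checked.
#'
#' For a two-level design each trial's signal is
#' `baseline + sum(code_j * effect_j)` over the planted factors, so the
#' recoverable (+)-minus-(-) group difference of a factor is exactly twice its
#' planted per-unit effect. For a three-level design each factor contributes
#' the offset of the level run in that trial. Simulated values are kept
#' strictly positive by resampling the noise of non-positive draws (not by
#' clipping, which would pile mass at zero). The generator uses R's default
#' Mersenne-Twister RNG; identical seeds give bit-identical output.
#'
#' @param design A `doe_design` ([pb12_design()] or [l9_design()]).
#' @param baseline Baseline response in g/dL (default 1).
#' @param effects Two-level design: named numeric vector of per-coded-unit
#'   effects (g/dL), unnamed factors default to 0. Three-level design: named
#'   list of length-3 numeric level offsets per factor.
#' @param noise_sd Replicate noise standard deviation in g/dL (>= 0).
#' @param replicates Replicates per trial (>= 1, default 3).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return List with `responses` (tibble: `trial`, `rep_1`..`rep_k`) and
#'   `truth` (planted effects; for two-level designs including the implied
#'   `plus_minus_difference = 2 * effect`).
#' @examples
#' sim <- simulate_doe(pb12_design(), effects = c(X4 = 0.65), noise_sd = 0.1,
#'                     seed = 1)
#' pb_effects(pb12_design(), trial_means(sim$responses))
#' @export
simulate_doe <- function(design, baseline = 1, effects = NULL, noise_sd = 0.2,
                         replicates = 3, seed = NULL) {
  validate_design(design)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(replicates, "replicates", lower = 1)
  replicates <- as.integer(replicates)
  codes <- design_codes(design)
  type <- design_type(design)
  syms <- colnames(codes)

  if (type == "two_level") {
    eff <- stats::setNames(numeric(length(syms)), syms)
    if (!is.null(effects)) {
      if (is.null(names(effects)) || !all(names(effects) %in% syms)) {
        abort_config("two-level `effects` must be named after design factors.")
      }
      eff[names(effects)] <- as.numeric(effects)
    }
    signal <- baseline + as.vector(codes %*% eff)
    truth <- tibble(factor = syms, effect = unname(eff),
                    plus_minus_difference = unname(2 * eff))
  } else {
    k <- max(codes)
    offs <- lapply(syms, function(s) numeric(k))
    names(offs) <- syms
    if (!is.null(effects)) {
      if (is.null(names(effects)) || !all(names(effects) %in% syms)) {
        abort_config("three-level `effects` must be a named list of level offsets.")
      }
      for (s in names(effects)) {
        v <- as.numeric(effects[[s]])
        if (length(v) != k) {
          abort_config(sprintf("offsets for factor %s must have length %d.", s, k))
        }
        offs[[s]] <- v
      }
    }
    signal <- baseline + rowSums(vapply(syms, function(s) offs[[s]][codes[, s]],
                                        numeric(nrow(codes))))
    truth <- purrr::map_dfr(syms, function(s) {
      tibble(factor = s, level = seq_len(k), offset = offs[[s]])
    })
  }

  if (noise_sd == 0 && any(signal <= 0)) {
    abort_domain("noise-free signal is non-positive for some trials; raise `baseline`.")
  }

  y <- with_optional_seed(seed, {
    m <- signal + matrix(rnorm(length(signal) * replicates, 0, noise_sd),
                         nrow = length(signal))
    tries <- 0L
    while (any(bad <- m <= 0)) {
      tries <- tries + 1L
      if (tries > 1000L) {
        abort_domain("could not draw strictly positive responses; the signal is too close to zero for this noise SD.")
      }
      m[bad] <- signal[row(m)[bad]] + rnorm(sum(bad), 0, noise_sd)
    }
    m
  })
  colnames(y) <- paste0("rep_", seq_len(replicates))
  responses <- dplyr::bind_cols(tibble(trial = as.character(design$trial)),
                                as_tibble(y))
  list(responses = responses, truth = truth,
       baseline = baseline, noise_sd = noise_sd)
}
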