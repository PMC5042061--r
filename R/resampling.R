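#' Subsample one lake's fauna
#'
#' Simple random sample without replacement of
#' `max(min_n, ceiling(fraction * n))` species — the per-lake step of the
#' resampling null test. The ceiling keeps every lake at one species or
#' more before the floor is applied; the floor of two keeps size ranges
#' computable.
#'
#' @param s Vector of the lake's raw S values (or any per-species values).
#' @param fraction Fraction to resample, in (0, 1].
#' @param min_n Minimum subsample size; lakes with fewer than `min_n`
#'   species cannot be subsampled (error — callers drop such lakes).
#' @return A subsample of `s`.
#' @export
subsample_fauna <- function(s, fraction, min_n = 2) {
  n <- length(s)
  if (n < min_n)
    stop("lake has ", n, " species, fewer than the minimum ", min_n)
  m <- max(min_n, ceiling(fraction * n))
  s[sample.int(n, m)]
}

#' Subsample-resampling null test for richness-driven size correlations
#'
#' Tests whether an observed simple-regression slope between a fauna size
#' measure and a lake predictor (surface area or percent endemism) is an
#' artefact of species richness. Each replicate resamples `fraction`
#' (default 25%) of every lake's measured species without replacement,
#' recomputes the size measure per lake, and refits the simple regression;
#' the test P is the proportion of resampled slopes greater than the
#' observed slope (the literal convention; a two-sided magnitude variant
#' compares absolute slopes). The null model is that the observed
#' correlation is independent of species richness.
#'
#' Replicates are seeded from one master seed via pre-drawn per-replicate
#' seeds, so results are reproducible and independent of execution order.
#'
#' @param species,lakes Input tables; inclusion filters are applied
#'   internally.
#' @param predictor `"area"` (log10 km^2) or `"endemism"` (raw %).
#' @param measure One of `"S_range"`, `"S_max"`, `"S_min"`, `"S_mean"`.
#' @param config A [lakesize_config()]; supplies `fraction`,
#'   `repetitions`, `min_subsample` and the comparison mode.
#' @param seed Master seed (overrides `config$seed`).
#' @return Object of class `"resampling_result"`: `measure`, `predictor`,
#'   `observed_slope`, `slopes` (length = kept repetitions), `p_value`,
#'   `fraction`, `repetitions`, `n_discarded`, `mode`, `seed`.
#' @export
resampling_test <- function(species, lakes,
                            predictor = c("area", "endemism"),
                            measure = c("S_range", "S_max", "S_min", "S_mean"),
                            config = lakesize_config(),
                            seed = config$seed) {
  predictor <- match.arg(predictor)
  measure <- match.arg(measure)
  flt <- apply_inclusion_filters(species, lakes, config)
  s_by_lake <- split(shell_size(flt$species$height, flt$species$width),
                     flt$species$lake_id)
  lake_ids <- names(s_by_lake)
  px <- switch(predictor,
               area = log10(flt$lakes$area_km2),
               endemism = flt$lakes$pct_endemism)
  px <- px[match(lake_ids, flt$lakes$lake_id)]

  # scalar fast path: same definitions as fauna_size_summary, no data.frame
  measure_of <- switch(measure,
    S_max = function(s) log10(max(s)),
    S_min = function(s) log10(min(s)),
    S_mean = if (config$mean_method == "arithmetic")
      function(s) log10(mean(s)) else function(s) mean(log10(s)),
    S_range = if (config$range_method == "raw_diff")
      function(s) { r <- max(s) - min(s); if (r > 0) log10(r) else NA_real_ }
    else
      function(s) { r <- max(s) / min(s); if (r > 1) log10(r) else NA_real_ })
  slope_of <- function(y, xs) {
    ok <- !is.na(y)
    if (sum(ok) < 3) return(NA_real_)
    stats::cov(xs[ok], y[ok]) / stats::var(xs[ok])
  }

  observed <- slope_of(vapply(s_by_lake, measure_of, numeric(1)), px)
  if (is.na(observed)) stop("observed regression not computable")

  min_n <- config$min_subsample
  usable <- lengths(s_by_lake) >= min_n
  n_small <- sum(!usable)
  if (n_small > 0)
    warning(n_small, " lake(s) below the minimum subsample size dropped ",
            "from every replicate")

  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$repetitions)
  px_usable <- px[usable]
  slopes <- vapply(rep_seeds, function(s0) {
    set.seed(s0)
    y <- vapply(s_by_lake[usable], function(s)
      measure_of(subsample_fauna(s, config$fraction, min_n)), numeric(1))
    slope_of(y, px_usable)
  }, numeric(1))

  discarded <- sum(is.na(slopes))
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) == 0) stop("every replicate was discarded")
  if (discarded > 0.1 * config$repetitions)
    warning("more than 10% of replicates discarded (", discarded, " of ",
            config$repetitions, ")")
  p <- if (config$resample_mode == "literal") mean(slopes > observed)
       else mean(abs(slopes) > abs(observed))

  structure(list(measure = measure, predictor = predictor,
                 observed_slope = observed, slopes = slopes, p_value = p,
                 fraction = config$fraction,
                 repetitions = config$repetitions,
                 n_discarded = discarded, mode = config$resample_mode,
                 seed = seed),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("Resampling null test: %s ~ %s\n", x$measure, x$predictor))
  cat(sprintf("  observed slope %.4f; %d replicates at fraction %.2f (%d discarded)\n",
              x$observed_slope, x$repetitions, x$fraction, x$n_discarded))
  cat(sprintf("  P (%s) = %.3f\n", x$mode, x$p_value))
  invisible(x)
}

#' Run the resampling test battery
#'
#' All size measures crossed with both predictors (area, endemism) — the
#' eight combinations reported by the null analysis.
#'
#' @inheritParams resampling_test
#' @return Data.frame with one row per measure x predictor: observed
#'   slope, P, repetitions, fraction, discarded count, mode.
#' @export
resampling_battery <- function(species, lakes, config = lakesize_config(),
                               seed = config$seed) {
  grid <- expand.grid(measure = c("S_range", "S_max", "S_min", "S_mean"),
                      predictor = c("area", "endemism"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- resampling_test(species, lakes, grid$predictor[i], grid$measure[i],
                         config, seed = if (is.null(seed)) NULL else seed + i)
    data.frame(measure = r$measure, predictor = r$predictor,
               observed_slope = r$observed_slope, p_value = r$p_value,
               repetitions = r$repetitions, fraction = r$fraction,
               n_discarded = r$n_discarded, mode = r$mode,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
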